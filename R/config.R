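#' Task configuration for the buyer-seller game
#'
#' Bundles the global constants of the game: the sum constraint shared by
#' preferences, distances and prices; the lattice spacing on which all agents
#' reason; the inverse temperature of the softmax choice rule; the logarithm
#' base used by the information-theoretic instruments; the seller's pricing
#' objective; and the highest theory-of-mind level to tabulate.
#'
#' Preferences, walking distances and prices are each constrained to sum to
#' `sum_total` across the two items, so every pair is stored through its apple
#' component only and the orange component is always derived. All "integrals"
#' over the unknown preference are probability-mass sums over the lattice
#' (uniform mass `1/n` per point), which keeps every belief normalised exactly
#' and every divergence well-defined.
#'
#' @param sum_total Common sum of the two preferences, the two distances and
#'   the two prices, in shared reward/money units. Default 10.
#' @param grid_step Spacing of the discretisation lattice. Must divide
#'   `sum_total` exactly. Default 0.5.
#' @param beta Inverse temperature of the softmax (logistic) choice rule,
#'   shared by every agent and every agent's model of every other agent.
#'   `beta = 0` gives uniformly random choice; large `beta` approaches strict
#'   utility maximisation. Default 0.5.
#' @param log_base Base of all entropies and divergences; 2 reports bits,
#'   `exp(1)` reports nats. Default 2.
#' @param pricing_objective `"joint"` (default) maximises the seller's full
#'   expected revenue, summing the payoff branches of both items; this is the
#'   faithful expectation of the seller's reward, which pays the price of
#'   whichever item is bought. `"chosen_only"` maximises only the queried
#'   item's revenue branch, the literal single-item objective, and is kept as
#'   a documented diagnostic switch.
#' @param max_level Highest theory-of-mind level to build; buyers occupy the
#'   odd levels (-1, 1, 3, ...), sellers the even ones (0, 2, ...).
#'   Default 3.
#'
#' @return An object of class `tom_config`.
#' @examples
#' cfg <- tom_config()
#' build_grid(cfg)
#' @export
tom_config <- function(sum_total = 10, grid_step = 0.5, beta = 0.5,
                       log_base = 2,
                       pricing_objective = c("joint", "chosen_only"),
                       max_level = 3) {
  pricing_objective <- match.arg(pricing_objective)
  cfg <- structure(
    list(
      sum_total = as.numeric(sum_total),
      grid_step = as.numeric(grid_step),
      beta = as.numeric(beta),
      log_base = as.numeric(log_base),
      pricing_objective = pricing_objective,
      max_level = as.integer(max_level)
    ),
    class = "tom_config"
  )
  validate_tom_config(cfg)
}

config_error <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg),
               class = "tommarket_config_error")
}

validate_tom_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$sum_total) || cfg$sum_total <= 0)
    config_error("sum_total", "must be a single positive number")
  if (!num1(cfg$grid_step) || cfg$grid_step <= 0)
    config_error("grid_step", "must be a single positive number")
  ratio <- cfg$sum_total / cfg$grid_step
  if (abs(ratio - round(ratio)) > 1e-8)
    config_error("grid_step",
                 sprintf("%s does not divide sum_total = %s exactly",
                         format(cfg$grid_step), format(cfg$sum_total)))
  if (!num1(cfg$beta) || cfg$beta < 0)
    config_error("beta", "must be a single non-negative number")
  if (!num1(cfg$log_base) || cfg$log_base <= 0 || cfg$log_base == 1)
    config_error("log_base", "must be a positive number different from 1")
  if (!is.numeric(cfg$max_level) || length(cfg$max_level) != 1 ||
      cfg$max_level < -1)
    config_error("max_level", "must be a single integer >= -1")
  cfg
}

#' Discretisation lattice of a configuration
#'
#' Returns the lattice `{0, step, 2*step, ..., sum_total}` on which
#' preferences, distances and prices live and over which all posteriors and
#' sweeps are tabulated.
#'
#' @param config A [tom_config()].
#' @return Numeric vector of `sum_total / grid_step + 1` strictly increasing
#'   values starting at 0 and ending at `sum_total`.
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "tom_config"))
  n <- round(config$sum_total / config$grid_step)
  seq(0, config$sum_total, length.out = n + 1)
}

# Match values to lattice points, failing loudly for off-grid input.
grid_match <- function(x, grid, what = "value") {
  idx <- vapply(x, function(v) {
    i <- which(abs(grid - v) < 1e-9)
    if (length(i) != 1)
      rlang::abort(sprintf("%s %s does not lie on the grid", what, format(v)),
                   class = "tommarket_grid_error")
    i
  }, integer(1))
  idx
}

#' Uniform belief over the preference lattice
#'
#' The flat prior every seller starts from: equal probability mass on each
#' lattice value of the apple preference.
#'
#' @inheritParams build_grid
#' @return Numeric vector of probability masses summing to 1.
#' @export
uniform_belief <- function(config) {
  g <- build_grid(config)
  rep(1 / length(g), length(g))
}

check_belief <- function(belief, config, arg = "belief") {
  g <- build_grid(config)
  if (length(belief) != length(g))
    rlang::abort(sprintf("`%s` must have one mass per grid point (%d)",
                         arg, length(g)),
                 class = "tommarket_belief_error")
  if (any(belief < 0) || abs(sum(belief) - 1) > 1e-9)
    rlang::abort(sprintf("`%s` must be non-negative and sum to 1", arg),
                 class = "tommarket_belief_error")
  invisible(belief)
}

#' @export
print.tom_config <- function(x, ...) {
  cat("<tom_config>\n")
  cat(sprintf("  sum constraint     : %g\n", x$sum_total))
  cat(sprintf("  grid step          : %g  (%d lattice points)\n",
              x$grid_step, round(x$sum_total / x$grid_step) + 1))
  cat(sprintf("  inverse temperature: %g\n", x$beta))
  cat(sprintf("  log base           : %g\n", x$log_base))
  cat(sprintf("  pricing objective  : %s\n", x$pricing_objective))
  cat(sprintf("  max ToM level      : %d\n", x$max_level))
  invisible(x)
}

#' Read a task configuration from a flat YAML or JSON file
#'
#' The file holds a flat mapping whose keys are the [tom_config()] argument
#' names; missing keys fall back to the defaults and unknown keys are
#' rejected. Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the configuration file.
#' @param overrides Named list of values taking precedence over the file
#'   (used by the command line interface for flag overrides).
#' @return A [tom_config()].
#' @export
read_task_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    rlang::abort(sprintf("configuration file not found: %s", path),
                 class = "tommarket_config_error")
  ext <- tolower(sub(".*\\.", "", path))
  vals <- switch(ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    rlang::abort(sprintf("unsupported configuration format: .%s", ext),
                 class = "tommarket_config_error")
  )
  if (!is.list(vals)) vals <- as.list(vals)
  vals[names(overrides)] <- overrides
  known <- names(formals(tom_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    config_error(unknown[1], "is not a task configuration field")
  do.call(tom_config, vals)
}
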