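# Deterministic sweep experiments over the scenario lattice: build the
# hierarchy, evaluate every metric curve, export tables, render figures.

#' Run the full deterministic sweep
#'
#' Builds the hierarchy up to `config$max_level` and evaluates every
#' information-theoretic curve across the distance grid: mutual information
#' for each buyer level, the likely-item belief-update divergence for each
#' seller level, and the assumed-versus-actual policy discrepancy for each
#' (buyer, two-levels-below) pair. The whole pipeline is closed-form and
#' contains no randomness; a configuration hash is recorded so that re-runs
#' can be checked for bit-identical content.
#'
#' @param config A [tom_config()].
#' @return An object of class `tom_sweep` with elements `config`,
#'   `hierarchy`, `policies` / `prices` (long-format tibbles of every
#'   table), `metrics` (one tibble of all curves) and `provenance`.
#' @export
run_sweep <- function(config = tom_config()) {
  stopifnot(inherits(config, "tom_config"))
  h <- build_hierarchy(config)
  g <- h$grid

  policies <- do.call(rbind, lapply(names(h$policies), function(key) {
    tab <- h$policies[[key]]
    tibble::tibble(level = as.integer(key),
                   r_apple = rep(g, times = length(g)),
                   d_apple = rep(g, each = length(g)),
                   p_apple = as.vector(tab))
  }))
  prices <- do.call(rbind, lapply(names(h$prices), function(key) {
    tab <- h$prices[[key]]
    tibble::tibble(level = as.integer(key),
                   d_apple = rep(g, times = 2),
                   observed_item = rep(ITEMS, each = length(g)),
                   m_apple = as.vector(tab))
  }))

  buyer_levels <- as.integer(names(h$policies))
  seller_levels <- as.integer(names(h$prices))
  curves <- c(
    lapply(buyer_levels, mutual_information_curve, hierarchy = h,
           config = config),
    lapply(seller_levels, likely_item_update_curve, hierarchy = h,
           config = config),
    lapply(buyer_levels[buyer_levels >= 1], policy_discrepancy_curve,
           hierarchy = h, config = config)
  )
  metrics <- do.call(rbind, curves)

  structure(
    list(config = config, hierarchy = h,
         policies = policies, prices = prices, metrics = metrics,
         provenance = list(config_hash = config_hash(config),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "tom_sweep")
}

#' Hash of the numeric content of a configuration
#'
#' Re-running a sweep with an identical configuration yields identical
#' numeric content; the hash gives that statement a checkable witness.
#'
#' @param config A [tom_config()].
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' @export
print.tom_sweep <- function(x, ...) {
  cat("<tom_sweep>\n")
  cat(sprintf("  config hash : %s\n", x$provenance$config_hash))
  cat(sprintf("  policies    : %d rows (levels %s)\n", nrow(x$policies),
              paste(unique(x$policies$level), collapse = ", ")))
  cat(sprintf("  prices      : %d rows (levels %s)\n", nrow(x$prices),
              paste(unique(x$prices$level), collapse = ", ")))
  cat(sprintf("  metric rows : %d\n", nrow(x$metrics)))
  invisible(x)
}

# write.csv truncates doubles to 15 significant digits; 17 round-trips
# exactly, which write_sweep/read_sweep promise.
csv_write <- function(df, path) {
  for (col in names(df))
    if (is.double(df[[col]]))
      df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a sweep to a directory of CSV and JSON files
#'
#' One CSV per hierarchy table (columns `level, r_apple, d_apple, p_apple`
#' for policies; `level, d_apple, observed_item, m_apple` for prices), one
#' `metrics.csv` with every curve, and a `config.json` snapshot including
#' the provenance record. Comma-separated, header row, `.` decimal, no
#' index column. All content is assembled before anything is written, so a
#' failure never leaves partial output.
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "tom_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (key in names(sweep$hierarchy$policies)) {
    p <- file.path(dir, paste0("policy_level_", key, ".csv"))
    csv_write(sweep$policies[sweep$policies$level == as.integer(key), ], p)
    paths <- c(paths, p)
  }
  for (key in names(sweep$hierarchy$prices)) {
    p <- file.path(dir, paste0("prices_level_", key, ".csv"))
    csv_write(sweep$prices[sweep$prices$level == as.integer(key), ], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "metrics.csv")
  csv_write(sweep$metrics, p)
  paths <- c(paths, p)
  p <- file.path(dir, "config.json")
  jsonlite::write_json(c(unclass(sweep$config), sweep$provenance), p,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a sweep back from a directory
#'
#' Round-trips the output of [write_sweep()]: reconstructs the
#' configuration, the hierarchy tables and the metric curves.
#'
#' @param dir Directory previously written by [write_sweep()].
#' @return A `tom_sweep`.
#' @export
read_sweep <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path))
    rlang::abort(sprintf("no sweep found in %s (missing config.json); run a sweep first",
                         dir),
                 class = "tommarket_io_error")
  raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  keep <- intersect(names(raw), names(formals(tom_config)))
  config <- do.call(tom_config, raw[keep])
  g <- build_grid(config)

  h <- structure(list(config = config, grid = g,
                      policies = list(), prices = list()),
                 class = "tom_hierarchy")
  policies <- NULL
  prices <- NULL
  for (level in seq(-1L, config$max_level)) {
    key <- as.character(level)
    if (level %% 2 != 0) {
      p <- file.path(dir, paste0("policy_level_", key, ".csv"))
      if (!file.exists(p))
        rlang::abort(sprintf("sweep in %s is missing %s", dir, basename(p)),
                     class = "tommarket_io_error")
      df <- utils::read.csv(p)
      mat <- matrix(df$p_apple, length(g), length(g))
      h$policies[[key]] <- new_policy_table(mat, level, g)
      policies <- rbind(policies, tibble::as_tibble(df))
    } else {
      p <- file.path(dir, paste0("prices_level_", key, ".csv"))
      if (!file.exists(p))
        rlang::abort(sprintf("sweep in %s is missing %s", dir, basename(p)),
                     class = "tommarket_io_error")
      df <- utils::read.csv(p)
      mat <- matrix(df$m_apple, length(g), 2)
      h$prices[[key]] <- new_price_table(mat, level, g)
      prices <- rbind(prices, tibble::as_tibble(df))
    }
  }
  metrics <- tibble::as_tibble(utils::read.csv(file.path(dir, "metrics.csv")))
  metrics$observed_item[metrics$observed_item == ""] <- NA_character_
  structure(
    list(config = config, hierarchy = h,
         policies = policies, prices = prices, metrics = metrics,
         provenance = list(config_hash = raw$config_hash,
                           timestamp = raw$timestamp)),
    class = "tom_sweep")
}

#' Render the result surface as figure files
#'
#' Writes one raster file per panel group: policy heatmaps (apple-choice
#' probability over distance and preference) for every buyer level, price
#' curves after an apple observation for every seller level, and the three
#' metric panels (mutual information, belief-update divergence, policy
#' discrepancy) against distance. Rendering is idempotent: the same sweep
#' writes the same files.
#'
#' @param sweep A [run_sweep()] or [read_sweep()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the files written.
#' @export
render_figures <- function(sweep, dir) {
  stopifnot(inherits(sweep, "tom_sweep"))
  for (piece in c("policies", "prices", "metrics"))
    if (is.null(sweep[[piece]]) || nrow(sweep[[piece]]) == 0)
      rlang::abort(sprintf("sweep has no %s table; cannot render figures", piece),
                   class = "tommarket_io_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  pol <- sweep$policies
  pol$level_lab <- factor(paste0("ToM(", pol$level, ") buyer"),
                          levels = paste0("ToM(", sort(unique(pol$level)), ") buyer"))
  gp <- ggplot2::ggplot(pol, ggplot2::aes(x = .data$d_apple, y = .data$r_apple,
                                          fill = .data$p_apple)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~level_lab) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(apple)") +
    ggplot2::labs(x = "distance to apple", y = "apple preference",
                  title = "First-stage buyer policies") +
    ggplot2::theme_minimal()
  p <- file.path(dir, "policies.png")
  ggplot2::ggsave(p, gp, width = 8, height = 3.2, dpi = 120)
  paths <- c(paths, p)

  pri <- sweep$prices[sweep$prices$observed_item == "apple", ]
  pri$level_lab <- paste0("ToM(", pri$level, ") seller")
  gp <- ggplot2::ggplot(pri, ggplot2::aes(x = .data$d_apple, y = .data$m_apple,
                                          colour = .data$level_lab)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "distance to apple", y = "apple price",
                  colour = NULL, title = "Prices after an apple choice") +
    ggplot2::theme_minimal()
  p <- file.path(dir, "prices.png")
  ggplot2::ggsave(p, gp, width = 5.5, height = 3.5, dpi = 120)
  paths <- c(paths, p)

  panels <- list(
    mutual_information = "Preference-action mutual information",
    belief_update_kld = "Seller belief-update divergence (likely item observed)",
    policy_discrepancy = "Assumed-vs-actual policy divergence"
  )
  for (met in names(panels)) {
    mm <- sweep$metrics[sweep$metrics$metric == met, ]
    mm$who <- ifelse(is.na(mm$level_b),
                     paste0("ToM(", mm$level_a, ")"),
                     paste0("ToM(", mm$level_a, ") vs assumed ToM(", mm$level_b, ")"))
    gp <- ggplot2::ggplot(mm, ggplot2::aes(x = .data$d_apple,
                                           y = .data$value_bits,
                                           colour = .data$who)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "distance to apple", y = "value (log-base units)",
                    colour = NULL, title = panels[[met]]) +
      ggplot2::theme_minimal()
    p <- file.path(dir, paste0(met, ".png"))
    ggplot2::ggsave(p, gp, width = 5.5, height = 3.5, dpi = 120)
    paths <- c(paths, p)
  }
  invisible(paths)
}
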