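# Information-theoretic diagnostics of deception and skepticism, computed
# from tabulated policies and beliefs. All quantities use the configured
# log base (2 by default, i.e. bits) and the 0 * log 0 = 0 convention.

xlogx_ratio <- function(p, q, base) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log(p[nz] / q[nz], base = base)
  out
}

#' Mutual information between preference and first action
#'
#' How much the buyer's first choice reveals about its preference at a given
#' distance: the mutual information between the (binary) action and the
#' preference, with the preference marginalised under the prior. A policy
#' constant in the preference carries no information; a deterministic step
#' policy that splits the prior mass evenly attains the 1-bit maximum of a
#' binary signal. Deceptive buyers suppress this quantity.
#'
#' @param policy A policy table from [build_hierarchy()].
#' @param d_apple Distance at which to evaluate, on the grid.
#' @param prior Belief over the preference lattice (default uniform).
#' @param config A [tom_config()].
#' @return Mutual information in units of the configured log base.
#' @export
mutual_information <- function(policy, d_apple,
                               prior = uniform_belief(config),
                               config = tom_config()) {
  stopifnot(inherits(policy, "tom_policy"))
  check_belief(prior, config, "prior")
  g <- build_grid(config)
  j <- grid_match(d_apple, g, "d_apple")
  pa <- unname(policy[, j])
  # a policy constant in the preference is exactly uninformative
  if (diff(range(pa)) == 0) return(0)
  pbar <- sum(prior * pa)
  contrib <- xlogx_ratio(pa, rep(pbar, length(pa)), config$log_base) +
    xlogx_ratio(1 - pa, rep(1 - pbar, length(pa)), config$log_base)
  sum(prior * contrib)
}

#' Kullback-Leibler divergence of a belief update
#'
#' The strength of a seller's belief update: the divergence of its posterior
#' from its prior after seeing the buyer's first choice. Zero exactly when
#' the update leaves the belief untouched — the signature of a fully
#' skeptical receiver, or of a sender whose action carries no information.
#' The lower the divergence, the more skeptical the agent.
#'
#' @param posterior,prior Belief vectors over the preference lattice.
#' @param config A [tom_config()].
#' @return Divergence in units of the configured log base (non-negative).
#' @export
belief_update_kld <- function(posterior, prior, config = tom_config()) {
  check_belief(posterior, config, "posterior")
  check_belief(prior, config, "prior")
  if (any(posterior > 0 & prior == 0))
    rlang::abort("posterior puts mass where the prior has none",
                 class = "tommarket_support_error")
  sum(xlogx_ratio(posterior, prior, config$log_base))
}

#' Belief-update divergence after the more likely observation
#'
#' For each distance, the seller observes the buyer choose the closer (and
#' thus a priori more likely) item — the apple on the near half of the
#' sweep, the orange on the far half, with the equidistant tie resolved to
#' the apple — and the divergence of the resulting posterior from the
#' uniform prior is recorded. Comparing the level 0 and level 2 curves shows
#' where the skeptical seller discards the signal that the trusting seller
#' exploits.
#'
#' @param seller_level Even seller level present in `hierarchy`.
#' @param hierarchy A [build_hierarchy()] result.
#' @param config A [tom_config()].
#' @return A tibble with columns `metric`, `level_a`, `level_b`, `d_apple`,
#'   `observed_item`, `value_bits`.
#' @export
likely_item_update_curve <- function(seller_level, hierarchy,
                                     config = tom_config()) {
  assumed <- resolve_policy(hierarchy, seller_level - 1)
  g <- build_grid(config)
  prior <- uniform_belief(config)
  obs <- ifelse(g <= config$sum_total / 2, "apple", "orange")
  vals <- vapply(seq_along(g), function(j) {
    post <- irl_posterior(assumed, obs[j], g[j], prior, config)
    belief_update_kld(post, prior, config)
  }, numeric(1))
  tibble::tibble(metric = "belief_update_kld",
                 level_a = as.integer(seller_level),
                 level_b = NA_integer_,
                 d_apple = g, observed_item = obs, value_bits = vals)
}

#' Divergence between an actual and an assumed policy
#'
#' How wrong an observer's model of the sender is: the expected (under the
#' prior over preferences) binary Kullback-Leibler divergence between the
#' actual action distribution and the assumed one at a given distance. This
#' measures how effective the sender's deception is — distinct from mutual
#' information, which measures mere hiding.
#'
#' @param actual Policy table of the actual (higher-level) buyer.
#' @param assumed Policy table the observer attributes to the buyer.
#' @param d_apple Distance at which to evaluate, on the grid.
#' @param prior Belief over the preference lattice (default uniform).
#' @param config A [tom_config()].
#' @return Expected divergence in units of the configured log base.
#' @export
policy_discrepancy <- function(actual, assumed, d_apple,
                               prior = uniform_belief(config),
                               config = tom_config()) {
  stopifnot(inherits(actual, "tom_policy"), inherits(assumed, "tom_policy"))
  check_belief(prior, config, "prior")
  g <- build_grid(config)
  j <- grid_match(d_apple, g, "d_apple")
  pa <- actual[, j]
  pb <- assumed[, j]
  if (any((pa > 0 & pb == 0) | (pa < 1 & pb == 1)))
    rlang::abort("assumed policy assigns zero probability to an action the actual policy takes",
                 class = "tommarket_support_error")
  per_r <- xlogx_ratio(pa, pb, config$log_base) +
    xlogx_ratio(1 - pa, 1 - pb, config$log_base)
  sum(prior * per_r)
}

#' Mutual-information curve of a buyer level
#'
#' [mutual_information()] evaluated at every distance of the grid.
#'
#' @param buyer_level Odd buyer level present in `hierarchy`.
#' @param hierarchy A [build_hierarchy()] result.
#' @param config A [tom_config()].
#' @return A tibble in the same shape as [likely_item_update_curve()].
#' @export
mutual_information_curve <- function(buyer_level, hierarchy,
                                     config = tom_config()) {
  policy <- resolve_policy(hierarchy, buyer_level)
  g <- build_grid(config)
  prior <- uniform_belief(config)
  vals <- vapply(g, function(d) {
    mutual_information(policy, d, prior, config)
  }, numeric(1))
  tibble::tibble(metric = "mutual_information",
                 level_a = as.integer(buyer_level),
                 level_b = NA_integer_,
                 d_apple = g, observed_item = NA_character_,
                 value_bits = vals)
}

#' Policy-discrepancy curve for a buyer pair
#'
#' [policy_discrepancy()] between the actual policy of `level_actual` and
#' the policy a seller one level below it assumes (`level_actual - 2`),
#' evaluated at every distance.
#'
#' @param level_actual Odd level of the actual buyer (1 or 3 by default
#'   configurations).
#' @param hierarchy A [build_hierarchy()] result.
#' @param config A [tom_config()].
#' @return A tibble in the same shape as [likely_item_update_curve()].
#' @export
policy_discrepancy_curve <- function(level_actual, hierarchy,
                                     config = tom_config()) {
  actual <- resolve_policy(hierarchy, level_actual)
  assumed <- resolve_policy(hierarchy, level_actual - 2)
  g <- build_grid(config)
  prior <- uniform_belief(config)
  vals <- vapply(g, function(d) {
    policy_discrepancy(actual, assumed, d, prior, config)
  }, numeric(1))
  tibble::tibble(metric = "policy_discrepancy",
                 level_a = as.integer(level_actual),
                 level_b = as.integer(level_actual - 2),
                 d_apple = g, observed_item = NA_character_,
                 value_bits = vals)
}
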