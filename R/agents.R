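# The ToM hierarchy: alternating buyer policies (odd levels) and seller
# price tables (even levels), each constructed only from the artifact one
# level below, tabulated bottom-up over the scenario lattice.

new_policy_table <- function(mat, level, grid) {
  dimnames(mat) <- list(r_apple = format(grid, trim = TRUE),
                        d_apple = format(grid, trim = TRUE))
  structure(mat, level = as.integer(level), grid = grid,
            class = c("tom_policy", class(mat)))
}

new_price_table <- function(mat, level, grid) {
  dimnames(mat) <- list(d_apple = format(grid, trim = TRUE),
                        observed = ITEMS)
  structure(mat, level = as.integer(level), grid = grid,
            class = c("tom_prices", class(mat)))
}

#' Two-action softmax choice probability
#'
#' The probability of the focal action under a softmax over two action
#' values, i.e. the logistic of the inverse-temperature-scaled value
#' difference. With `beta = 0` choice is uniform; as `beta` grows the rule
#' approaches strict maximisation, saturating gracefully for large value
#' differences.
#'
#' @param q_self Action value of the focal action (vectorised).
#' @param q_other Action value of the alternative.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of the focal action, in `(0, 1)` for finite inputs.
#' @examples
#' binary_softmax(6, -6, 0.5)  # ~0.9975
#' @export
binary_softmax <- function(q_self, q_other, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stats::plogis(beta * (q_self - q_other))
}

# stage-1 apple probability of the naive buyer, vectorised over r and d;
# the Q-difference is 2*(r - d) because both pairs obey the sum constraint
p1_apple <- function(r_apple, d_apple, beta) {
  stats::plogis(2 * beta * (r_apple - d_apple))
}

# stage-3 apple probability at price m, same structure
p3_apple <- function(r_apple, m_apple, beta) {
  stats::plogis(2 * beta * (r_apple - m_apple))
}

#' Naive (ToM(-1)) first-stage policy
#'
#' The lowest buyer treats each stage as an isolated utility-maximisation
#' problem: its stage-1 action values are the stage-1 utilities themselves,
#' passed through the two-action softmax.
#'
#' @param scenario A [tom_scenario()].
#' @param config A [tom_config()].
#' @return Probability of walking to the apple.
#' @export
naive_stage1_policy <- function(scenario, config = tom_config()) {
  stopifnot(inherits(scenario, "tom_scenario"))
  binary_softmax(stage1_utility(scenario, "apple"),
                 stage1_utility(scenario, "orange"),
                 config$beta)
}

#' Third-stage purchase policy
#'
#' The softmax over the stage-3 utilities of the two items at the posted
#' prices. Every buyer level uses this rule at the final stage (the prices
#' are given, so there is nothing left to plan through), and every seller
#' uses it to forecast revenue.
#'
#' @param r_apple Buyer's apple preference (vectorised).
#' @param prices A [price_schedule()].
#' @param config A [tom_config()].
#' @return Probability of buying the apple.
#' @export
stage3_policy <- function(r_apple, prices, config = tom_config()) {
  stopifnot(inherits(prices, "tom_price_schedule"))
  p3_apple(r_apple, prices$m_apple, config$beta)
}

#' Bayesian inverse reinforcement learning update
#'
#' Inverts an assumed buyer policy: the posterior mass on each lattice value
#' of the apple preference is proportional to the assumed policy's
#' probability of the observed first choice at that preference and distance,
#' times the prior mass. Passing the ToM(-1) table yields the ToM(0)
#' seller's posterior; passing the ToM(1) table yields the skeptical ToM(2)
#' posterior — the update rule itself is level-agnostic.
#'
#' @param assumed_policy A policy table (see [build_hierarchy()]).
#' @param observed The first-stage choice that was observed.
#' @param d_apple Distance to the apple, on the grid.
#' @param prior Belief vector over the preference lattice (defaults to the
#'   uniform prior).
#' @param config A [tom_config()].
#' @return Normalised belief vector over the preference lattice.
#' @export
irl_posterior <- function(assumed_policy, observed, d_apple,
                          prior = uniform_belief(config),
                          config = tom_config()) {
  stopifnot(inherits(assumed_policy, "tom_policy"))
  observed <- check_item(observed)
  check_belief(prior, config, "prior")
  g <- build_grid(config)
  j <- grid_match(d_apple, g, "d_apple")
  lik <- unname(assumed_policy[, j])
  if (observed == "orange") lik <- 1 - lik
  # a preference-independent likelihood is the exact Bayes identity; return
  # the prior itself rather than a renormalised copy with rounding drift
  if (diff(range(lik)) == 0 && lik[1] > 0) return(prior)
  unnorm <- lik * prior
  total <- sum(unnorm)
  if (total <= 0)
    rlang::abort(
      sprintf("observation \"%s\" at d_apple = %g has zero probability under the assumed policy and prior",
              observed, d_apple),
      class = "tommarket_degenerate_evidence_error")
  unname(unnorm / total)
}

#' Seller's expected revenue at a candidate apple price
#'
#' Forecasts revenue against the stage-3 purchase softmax, marginalising the
#' unknown preference under the seller's posterior. Under the `"joint"`
#' objective both payoff branches count: the apple price weighted by the
#' purchase probability plus the orange price weighted by its complement —
#' the exact expectation of the seller's reward. Under `"chosen_only"` only
#' the apple branch is scored (the literal single-item objective).
#'
#' @param m_apple Candidate apple price.
#' @param posterior Belief vector over the apple preference.
#' @param config A [tom_config()].
#' @return Expected revenue in money units.
#' @export
expected_revenue <- function(m_apple, posterior, config = tom_config()) {
  check_belief(posterior, config, "posterior")
  g <- build_grid(config)
  pbuy <- p3_apple(g, m_apple, config$beta)
  if (config$pricing_objective == "joint") {
    sum(posterior * (m_apple * pbuy + (config$sum_total - m_apple) * (1 - pbuy)))
  } else {
    sum(posterior * m_apple * pbuy)
  }
}

#' Revenue-maximising price schedule against a posterior
#'
#' Scans the price lattice and returns the deterministic argmax of
#' [expected_revenue()]. Ties (within 1e-12) are broken toward the price
#' closest to `sum_total / 2`, then toward the lower price, which keeps the
#' rule deterministic and makes a mirror-symmetric revenue landscape price
#' the two items equivalently.
#'
#' @param posterior Belief vector over the apple preference.
#' @param config A [tom_config()].
#' @return A [price_schedule()].
#' @export
optimal_prices <- function(posterior, config = tom_config()) {
  g <- build_grid(config)
  revs <- vapply(g, expected_revenue, numeric(1),
                 posterior = posterior, config = config)
  cand <- g[revs > max(revs) - 1e-12]
  half <- config$sum_total / 2
  best <- cand[order(abs(cand - half), cand)][1]
  price_schedule(best, config)
}

#' Tabulate a seller level's price table
#'
#' For every (distance, observed first choice) pair, runs the Bayesian IRL
#' update with the buyer policy one level below as likelihood and the
#' uniform prior, then prices optimally against the resulting posterior.
#' Level 0 inverts the naive buyer; level 2 inverts the planning buyer and
#' thereby becomes skeptical wherever that buyer's choice carries no
#' information.
#'
#' @param level Even integer `>= 0`.
#' @param hierarchy A partial hierarchy containing the level `level - 1`
#'   policy table (see [build_hierarchy()]), or that policy table itself.
#' @param config A [tom_config()].
#' @return A price table: matrix of apple prices indexed by distance and
#'   observed item.
#' @export
seller_price_table <- function(level, hierarchy, config = tom_config()) {
  if (level %% 2 != 0 || level < 0)
    rlang::abort("seller levels are the even integers >= 0",
                 class = "tommarket_level_error")
  policy <- resolve_policy(hierarchy, level - 1)
  g <- build_grid(config)
  prior <- uniform_belief(config)
  mat <- matrix(NA_real_, length(g), 2)
  for (j in seq_along(g)) {
    for (k in 1:2) {
      post <- tryCatch(
        irl_posterior(policy, ITEMS[k], g[j], prior, config),
        tommarket_degenerate_evidence_error = function(e) {
          rlang::abort(
            sprintf("level %d price table: %s", level, conditionMessage(e)),
            class = "tommarket_degenerate_evidence_error")
        })
      mat[j, k] <- optimal_prices(post, config)$m_apple
    }
  }
  new_price_table(mat, level, g)
}

resolve_policy <- function(hierarchy, level) {
  if (inherits(hierarchy, "tom_policy")) return(hierarchy)
  tab <- if (inherits(hierarchy, "tom_hierarchy"))
    hierarchy$policies[[as.character(level)]]
  else hierarchy[[as.character(level)]]
  if (is.null(tab))
    rlang::abort(sprintf("hierarchy does not contain the level %d policy table",
                         level),
                 class = "tommarket_level_error")
  tab
}

resolve_prices <- function(hierarchy, level) {
  if (inherits(hierarchy, "tom_prices")) return(hierarchy)
  tab <- if (inherits(hierarchy, "tom_hierarchy"))
    hierarchy$prices[[as.character(level)]]
  else hierarchy[[as.character(level)]]
  if (is.null(tab))
    rlang::abort(sprintf("hierarchy does not contain the level %d price table",
                         level),
                 class = "tommarket_level_error")
  tab
}

#' Planning action values of a sophisticated buyer
#'
#' The buyer mentally simulates the seller: for each candidate first action
#' it looks up the deterministic price schedule the seller would set after
#' observing that action, and adds the expected third-stage utility under
#' its own stage-3 purchase softmax to the immediate stage-1 utility. The
#' expectation over the seller is degenerate because pricing is
#' deterministic.
#'
#' @param scenario A [tom_scenario()].
#' @param seller_table The price table of the seller one level below.
#' @param config A [tom_config()].
#' @return Named numeric vector: planning Q-values for first actions
#'   `apple` and `orange`.
#' @export
planning_q <- function(scenario, seller_table, config = tom_config()) {
  stopifnot(inherits(scenario, "tom_scenario"),
            inherits(seller_table, "tom_prices"))
  g <- build_grid(config)
  j <- grid_match(scenario$d_apple, g, "d_apple")
  q <- vapply(1:2, function(k) {
    a1 <- ITEMS[k]
    prices <- price_schedule(seller_table[j, k], config)
    pbuy <- stage3_policy(scenario$r_apple, prices, config)
    e3 <- stage3_utility(scenario, prices, "apple") * pbuy +
      stage3_utility(scenario, prices, "orange") * (1 - pbuy)
    stage1_utility(scenario, a1) + e3
  }, numeric(1))
  names(q) <- ITEMS
  q
}

#' Tabulate a planning buyer level's policy
#'
#' Applies the two-action softmax to [planning_q()] over the whole
#' (preference, distance) lattice. Level 1 plans through the level 0 price
#' table; level 3 plans through the skeptical level 2 table — the same
#' operation with a different input, as mandated by the strict nesting of
#' the hierarchy.
#'
#' @param level Odd integer `>= 1`.
#' @param hierarchy A partial hierarchy containing the level `level - 1`
#'   price table, or that table itself.
#' @param config A [tom_config()].
#' @return A policy table: matrix of apple-choice probabilities indexed by
#'   preference (rows) and distance (columns).
#' @export
planning_policy_table <- function(level, hierarchy, config = tom_config()) {
  if (level %% 2 == 0 || level < 1)
    rlang::abort("planning buyer levels are the odd integers >= 1",
                 class = "tommarket_level_error")
  ptab <- resolve_prices(hierarchy, level - 1)
  g <- build_grid(config)
  beta <- config$beta
  S <- config$sum_total
  # vectorised over r for each (d, a1): E3 = (r - m) * (2*sigma - 1)
  mat <- matrix(NA_real_, length(g), length(g))
  for (j in seq_along(g)) {
    d <- g[j]
    qs <- vapply(1:2, function(k) {
      m <- ptab[j, k]
      u1 <- if (k == 1) g - d else d - g
      u1 + (g - m) * (2 * p3_apple(g, m, beta) - 1)
    }, numeric(length(g)))
    mat[, j] <- binary_softmax(qs[, 1], qs[, 2], beta)
  }
  new_policy_table(mat, level, g)
}

#' Construct a policy table from a matrix
#'
#' Wraps a matrix of apple-choice probabilities (preference lattice in rows,
#' distance lattice in columns) as a policy table, e.g. for hand-built
#' likelihoods or tables read back from CSV. Hierarchy-produced tables never
#' contain exact 0/1 entries at finite `beta`; user-supplied ones may, and
#' downstream operations then fail loudly on degenerate evidence rather
#' than renormalising silently.
#'
#' @param p_apple Numeric matrix with entries in `[0, 1]`, dimensions
#'   matching the grid.
#' @param level Buyer level to record (odd integer, default 1).
#' @param config A [tom_config()].
#' @return A `tom_policy`.
#' @export
as_policy_table <- function(p_apple, level = 1L, config = tom_config()) {
  g <- build_grid(config)
  p_apple <- as.matrix(p_apple)
  if (!all(dim(p_apple) == length(g)))
    rlang::abort(sprintf("policy matrix must be %d x %d to match the grid",
                         length(g), length(g)),
                 class = "tommarket_table_error")
  if (any(p_apple < 0 | p_apple > 1))
    rlang::abort("policy entries must be probabilities in [0, 1]",
                 class = "tommarket_table_error")
  new_policy_table(p_apple, level, g)
}

#' Construct a price table from a matrix
#'
#' Wraps a matrix of apple prices (distance lattice in rows, observed item
#' in columns) as a price table, e.g. for hand-built seller models.
#'
#' @param m_apple Numeric matrix, one row per grid distance and columns for
#'   the two observed items, entries on the price grid.
#' @param level Seller level to record (even integer, default 0).
#' @param config A [tom_config()].
#' @return A `tom_prices`.
#' @export
as_price_table <- function(m_apple, level = 0L, config = tom_config()) {
  g <- build_grid(config)
  m_apple <- as.matrix(m_apple)
  if (nrow(m_apple) != length(g) || ncol(m_apple) != 2)
    rlang::abort(sprintf("price matrix must be %d x 2 to match the grid",
                         length(g)),
                 class = "tommarket_table_error")
  grid_match(as.vector(m_apple), g, "m_apple")
  new_price_table(m_apple, level, g)
}

naive_policy_table <- function(config) {
  g <- build_grid(config)
  mat <- outer(g, g, p1_apple, beta = config$beta)
  new_policy_table(mat, -1L, g)
}

#' Build the full theory-of-mind hierarchy
#'
#' Tabulates every level bottom-up: the naive ToM(-1) policy, the ToM(0)
#' price table that inverts it, the ToM(1) policy that plans through ToM(0),
#' the skeptical ToM(2) prices, the ToM(3) policy, and so on up to
#' `config$max_level`. Each table is computed once and reused, so the cost
#' is linear in the number of levels; the construction contains no
#' randomness and is a deterministic function of the configuration.
#'
#' @param config A [tom_config()].
#' @return An object of class `tom_hierarchy` with elements `policies`
#'   (named list of policy tables, odd levels) and `prices` (named list of
#'   price tables, even levels).
#' @examples
#' h <- build_hierarchy(tom_config(grid_step = 5, max_level = 1))
#' policy_table(h, 1)
#' @export
build_hierarchy <- function(config = tom_config()) {
  stopifnot(inherits(config, "tom_config"))
  h <- structure(list(config = config, grid = build_grid(config),
                      policies = list(), prices = list()),
                 class = "tom_hierarchy")
  for (level in seq(-1L, config$max_level)) {
    key <- as.character(level)
    if (level %% 2 != 0) {
      h$policies[[key]] <- if (level == -1L) naive_policy_table(config)
        else planning_policy_table(level, h, config)
    } else {
      h$prices[[key]] <- seller_price_table(level, h, config)
    }
  }
  h
}

#' Extract a buyer policy table from a hierarchy
#' @param hierarchy A [build_hierarchy()] result.
#' @param level Odd buyer level.
#' @return The policy table.
#' @export
policy_table <- function(hierarchy, level) {
  stopifnot(inherits(hierarchy, "tom_hierarchy"))
  resolve_policy(hierarchy, level)
}

#' Extract a seller price table from a hierarchy
#' @param hierarchy A [build_hierarchy()] result.
#' @param level Even seller level.
#' @return The price table.
#' @export
price_table <- function(hierarchy, level) {
  stopifnot(inherits(hierarchy, "tom_hierarchy"))
  resolve_prices(hierarchy, level)
}

#' @export
print.tom_hierarchy <- function(x, ...) {
  cat("<tom_hierarchy>\n")
  cat(sprintf("  grid: %d points, step %g, sum %g\n",
              length(x$grid), x$config$grid_step, x$config$sum_total))
  cat(sprintf("  buyer policy levels : %s\n",
              paste(names(x$policies), collapse = ", ")))
  cat(sprintf("  seller price levels : %s\n",
              paste(names(x$prices), collapse = ", ")))
  invisible(x)
}

#' @export
print.tom_policy <- function(x, ...) {
  cat(sprintf("<tom_policy level %d> %d x %d apple-choice probabilities\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.tom_prices <- function(x, ...) {
  cat(sprintf("<tom_prices level %d> apple prices for %d distances x {%s}\n",
              attr(x, "level"), nrow(x), paste(ITEMS, collapse = ", ")))
  invisible(x)
}
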