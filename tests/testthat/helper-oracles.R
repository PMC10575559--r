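# Shared fixtures and independent oracles. The oracles use only base R and
# first-principles arithmetic so they stay independent of the code paths
# they check.

default_cfg <- function(...) tom_config(...)

coarse_cfg <- function(...) tom_config(grid_step = 5, ...)

logistic <- function(x) 1 / (1 + exp(-x))

# Exhaustive game-tree oracle for the planning buyer's action values: walks
# every (first action, purchase) path, scoring utilities from scratch.
enumerate_q_oracle <- function(r_apple, d_apple, seller_m_apple, config) {
  S <- config$sum_total
  beta <- config$beta
  r <- c(apple = r_apple, orange = S - r_apple)
  d <- c(apple = d_apple, orange = S - d_apple)
  q <- c(apple = NA_real_, orange = NA_real_)
  for (a1 in c("apple", "orange")) {
    m <- c(apple = seller_m_apple[[a1]], orange = S - seller_m_apple[[a1]])
    # stage-3 softmax from first principles
    p3a <- logistic(beta * ((r[["apple"]] - m[["apple"]]) -
                              (r[["orange"]] - m[["orange"]])))
    total <- 0
    for (i3 in c("apple", "orange")) {
      path_prob <- if (i3 == "apple") p3a else 1 - p3a
      path_util <- (r[[a1]] - d[[a1]]) + (r[[i3]] - m[[i3]])
      total <- total + path_prob * path_util
    }
    q[[a1]] <- total
  }
  q
}

# Double-sum mutual information oracle over the explicit joint distribution.
mi_oracle <- function(p_apple_by_r, prior, base = 2) {
  p_apple_by_r <- unname(p_apple_by_r)
  joint <- rbind(prior * p_apple_by_r, prior * (1 - p_apple_by_r))
  pa <- rowSums(joint)
  total <- 0
  for (a in 1:2) for (k in seq_along(prior)) {
    j <- joint[a, k]
    if (j > 0) total <- total + j * log(j / (pa[a] * prior[k]), base = base)
  }
  total
}

# Entropy-decomposition route: I = H(marginal action) - E_r H(action | r).
mi_entropy_decomposition <- function(p_apple_by_r, prior, base = 2) {
  p_apple_by_r <- unname(p_apple_by_r)
  hbin <- function(p) {
    terms <- c(p, 1 - p)
    -sum(ifelse(terms > 0, terms * log(terms, base = base), 0))
  }
  hbin(sum(prior * p_apple_by_r)) -
    sum(prior * vapply(p_apple_by_r, hbin, numeric(1)))
}

kld_oracle <- function(q, p, base = 2) {
  q <- unname(q); p <- unname(p)
  sum(ifelse(q > 0, q * log(q / p, base = base), 0))
}

# Per-preference binary KLD averaged under the prior.
discrepancy_oracle <- function(p_actual, p_assumed, prior, base = 2) {
  p_actual <- unname(p_actual); p_assumed <- unname(p_assumed)
  total <- 0
  for (k in seq_along(prior)) {
    for (pr in list(c(p_actual[k], p_assumed[k]),
                    c(1 - p_actual[k], 1 - p_assumed[k]))) {
      if (pr[1] > 0) total <- total + prior[k] * pr[1] *
          log(pr[1] / pr[2], base = base)
    }
  }
  total
}
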