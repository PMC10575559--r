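test_that("the two-action softmax is the logistic of the scaled value gap", {
  expect_identical(binary_softmax(3, 3, 0.5), 0.5)
  expect_identical(binary_softmax(9, -4, 0), 0.5)
  expect_equal(binary_softmax(6, -6, 0.5), 1 / (1 + exp(-6)), tolerance = 1e-12)
  # saturates without overflow
  expect_equal(binary_softmax(1e6, -1e6, 1), 1)
  expect_equal(binary_softmax(-1e6, 1e6, 1), 0)
})

test_that("the naive buyer's first move follows its stage-1 utilities", {
  cfg <- tom_config()
  expect_identical(naive_stage1_policy(tom_scenario(5, 5, cfg), cfg), 0.5)
  expect_equal(naive_stage1_policy(tom_scenario(2, 8, cfg), cfg),
               1 / (1 + exp(-6)), tolerance = 1e-12)
  # monotone in preference at fixed distance, and in proximity at fixed preference
  h <- build_hierarchy(tom_config(max_level = -1))
  tab <- policy_table(h, -1)
  expect_true(all(apply(tab, 2, diff) > 0))
  expect_true(all(apply(tab, 1, diff) < 0))
})

test_that("every buyer level shares the same stage-3 purchase rule", {
  cfg <- tom_config()
  expect_identical(stage3_policy(5, price_schedule(5, cfg), cfg), 0.5)
  expect_equal(stage3_policy(8, price_schedule(7, cfg), cfg),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  g <- build_grid(cfg)
  for (m in c(0, 3.5, 7)) {
    expect_equal(stage3_policy(g, price_schedule(m, cfg), cfg),
                 1 - stage3_policy(10 - g, price_schedule(10 - m, cfg), cfg),
                 tolerance = 1e-12)
  }
})

test_that("Bayesian IRL inverts the assumed policy and respects Bayes identities", {
  cfg3 <- coarse_cfg()
  prior <- uniform_belief(cfg3)

  # preference-independent likelihood leaves the prior untouched
  flat <- as_policy_table(matrix(0.7, 3, 3), level = 1, config = cfg3)
  expect_identical(irl_posterior(flat, "apple", 5, prior, cfg3), prior)

  # three-point hand computation against the naive likelihood
  naive <- policy_table(build_hierarchy(coarse_cfg(max_level = -1)), -1)
  lik <- logistic(c(-5, 0, 5))
  expect_equal(as.vector(naive[, 2]), lik, tolerance = 1e-12)
  expect_equal(irl_posterior(naive, "apple", 5, prior, cfg3),
               lik / sum(lik), tolerance = 1e-12)
  expect_equal(round(irl_posterior(naive, "apple", 5, prior, cfg3), 5),
               c(0.00446, 0.33333, 0.66220))
  # observing the orange flips the likelihood
  expect_equal(irl_posterior(naive, "orange", 5, prior, cfg3),
               (1 - lik) / sum(1 - lik), tolerance = 1e-12)

  # monotone likelihood makes the posterior after APPLE dominate the prior
  cfg <- tom_config()
  naive21 <- policy_table(build_hierarchy(tom_config(max_level = -1)), -1)
  post <- irl_posterior(naive21, "apple", 3, uniform_belief(cfg), cfg)
  expect_true(all(diff(post) > 0))
  expect_true(all(cumsum(post) <= cumsum(uniform_belief(cfg)) + 1e-12))

  # an impossible observation under a user-built table fails loudly
  zero <- as_policy_table(matrix(0, 3, 3), level = 1, config = cfg3)
  expect_error(irl_posterior(zero, "apple", 5, prior, cfg3),
               class = "tommarket_degenerate_evidence_error")
})

test_that("expected revenue matches hand sums and the relabeling symmetry", {
  cfg <- tom_config()
  u <- uniform_belief(cfg)
  # pricing both items at the midpoint pays the midpoint whatever happens
  expect_identical(expected_revenue(5, u, cfg), 5)

  # independent 11-point oracle on the unit lattice
  cfg1 <- tom_config(grid_step = 1)
  u1 <- uniform_belief(cfg1)
  oracle <- mean(8 * logistic(0:10 - 8) + 2 * (1 - logistic(0:10 - 8)))
  expect_equal(expected_revenue(8, u1, cfg1), oracle, tolerance = 1e-12)
  expect_equal(round(expected_revenue(8, u1, cfg1), 2), 3.40)

  # mirror-symmetric posterior cannot prefer one labelling of the prices
  g <- build_grid(cfg)
  sym <- exp(-abs(g - 5)); sym <- sym / sum(sym)
  for (m in c(2, 3.5, 8)) {
    expect_equal(expected_revenue(m, sym, cfg),
                 expected_revenue(10 - m, sym, cfg), tolerance = 1e-12)
  }

  # chosen_only scores a single branch
  cfgc <- tom_config(pricing_objective = "chosen_only")
  expect_equal(expected_revenue(8, u1, tom_config(grid_step = 1,
                                                  pricing_objective = "chosen_only")),
               mean(8 * logistic(0:10 - 8)), tolerance = 1e-12)
  expect_lt(expected_revenue(8, uniform_belief(cfgc), cfgc),
            expected_revenue(8, u, cfg))
})

test_that("optimal pricing is a deterministic argmax with midpoint tie-break", {
  cfg <- tom_config()
  expect_identical(optimal_prices(uniform_belief(cfg), cfg)$m_apple, 5)
  conc <- c(rep(0, 20), 1)  # buyer certainly values the apple at 10
  m <- optimal_prices(conc, cfg)$m_apple
  g <- build_grid(cfg)
  revs <- vapply(g, expected_revenue, numeric(1), posterior = conc, config = cfg)
  expect_identical(m, g[which.max(revs)])
  expect_gte(m, 7.5)
})

test_that("seller price tables obey the relabeling symmetry", {
  h <- build_hierarchy(tom_config())
  g <- build_grid(tom_config())
  for (lv in c(0, 2)) {
    tab <- price_table(h, lv)
    mirrored <- 10 - rev(tab[, "orange"])
    expect_true(all(abs(tab[, "apple"] - mirrored) <= 0.5 + 1e-12))
  }
})

test_that("planning action values match the exhaustive game-tree oracle", {
  cfg3 <- coarse_cfg(max_level = 0)
  h <- build_hierarchy(cfg3)
  tab <- price_table(h, 0)
  g3 <- build_grid(cfg3)
  for (r in g3) for (d in g3) {
    sc <- tom_scenario(r_apple = r, d_apple = d, cfg3)
    got <- planning_q(sc, tab, cfg3)
    j <- match(d, g3)
    want <- enumerate_q_oracle(r, d, list(apple = tab[j, "apple"],
                                          orange = tab[j, "orange"]), cfg3)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # a hand-built two-price table exercises the oracle off the optimum too
  hand <- as_price_table(matrix(c(0, 5, 10, 5, 5, 0), 3, 2), 0, cfg3)
  for (r in g3) {
    got <- planning_q(tom_scenario(5, r, cfg3), hand, cfg3)
    want <- enumerate_q_oracle(r, 5, list(apple = hand[2, 1],
                                          orange = hand[2, 2]), cfg3)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("planning collapses to the naive policy when prices ignore the signal", {
  cfg <- tom_config()
  g <- build_grid(cfg)
  same <- as_price_table(matrix(6, length(g), 2), 0, cfg)
  planned <- planning_policy_table(1, same, cfg)
  naive <- policy_table(build_hierarchy(tom_config(max_level = -1)), -1)
  expect_equal(unclass(planned), unclass(naive), tolerance = 1e-12,
               ignore_attr = TRUE)
  # and the Q-gap reduces to the stage-1 utility gap
  sc <- tom_scenario(3, 8, cfg)
  q <- planning_q(sc, same, cfg)
  expect_equal(q[["apple"]] - q[["orange"]],
               stage1_utility(sc, "apple") - stage1_utility(sc, "orange"),
               tolerance = 1e-12)
})

test_that("policies at every level obey the mirror symmetry", {
  h <- build_hierarchy(tom_config())
  for (lv in c(-1, 1, 3)) {
    tab <- policy_table(h, lv)
    flipped <- 1 - tab[rev(seq_len(nrow(tab))), rev(seq_len(ncol(tab)))]
    expect_equal(unclass(tab), unclass(flipped), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(tab > 0 & tab < 1))
  }
  # planning Q-values share the symmetry
  cfg <- tom_config()
  tab0 <- price_table(h, 0)
  q1 <- planning_q(tom_scenario(2, 8, cfg), tab0, cfg)
  q2 <- planning_q(tom_scenario(8, 2, cfg), tab0, cfg)
  expect_equal(q1[["apple"]], q2[["orange"]], tolerance = 1e-9)
})

test_that("the hierarchy is built bottom-up, memoized, and deterministic", {
  h1 <- build_hierarchy(tom_config())
  expect_named(h1$policies, c("-1", "1", "3"))
  expect_named(h1$prices, c("0", "2"))
  h2 <- build_hierarchy(tom_config())
  expect_identical(lapply(h1$policies, as.vector),
                   lapply(h2$policies, as.vector))
  expect_identical(lapply(h1$prices, as.vector), lapply(h2$prices, as.vector))

  tiny <- build_hierarchy(tom_config(max_level = -1))
  expect_length(tiny$policies, 1)
  expect_length(tiny$prices, 0)

  expect_error(price_table(h1, 4), class = "tommarket_level_error")
  expect_error(seller_price_table(1, h1, tom_config()),
               class = "tommarket_level_error")
  expect_error(planning_policy_table(2, h1, tom_config()),
               class = "tommarket_level_error")
})

test_that("temperature limits recover uniform choice and strict maximisation", {
  # beta = 0: every choice is a coin flip and inference learns nothing
  cfg0 <- tom_config(beta = 0)
  h0 <- build_hierarchy(cfg0)
  for (lv in c(-1, 1, 3))
    expect_true(all(policy_table(h0, lv) == 0.5))
  prior <- uniform_belief(cfg0)
  expect_identical(irl_posterior(policy_table(h0, -1), "apple", 3, prior, cfg0),
                   prior)

  # beta = 100: the naive policy steps at r = d
  cfgB <- tom_config(beta = 100, max_level = -1)
  tabB <- policy_table(build_hierarchy(cfgB), -1)
  g <- build_grid(cfgB)
  ind <- outer(g, g, function(r, d) (r > d) + 0.5 * (r == d))
  off <- abs(tabB - ind)[outer(g, g, "!=")]
  expect_lt(max(off), 1e-6)
})
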