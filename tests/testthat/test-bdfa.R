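test_that("the temperature schedule interpolates tau_max to tau_min", {
  expect_equal(tau_schedule(0, 100), 4)
  expect_equal(tau_schedule(100, 100), 0.01)
  expect_equal(tau_schedule(50, 100), 2.005)
  expect_error(tau_schedule(-1, 100), "lie in")
  expect_error(tau_schedule(101, 100), "lie in")
})

test_that("the piecewise transfer function equals |tanh(x/tau)|", {
  expect_identical(transfer_function(0, 3), 0)
  set.seed(51)
  x <- runif(200, -10, 10)
  expect_equal(transfer_function(x, 2), transfer_function(-x, 2))
  for (tau in c(4, 2.005, 0.01)) {
    expect_equal(transfer_function(x, tau), abs(tanh(x / tau)),
                 tolerance = 1e-14)
  }
  expect_equal(transfer_function(4, 4), tanh(1), tolerance = 1e-14)
  expect_error(transfer_function(1, 0), "positive")
})

test_that("swarm behaviors match hand-evaluated formulas on a toy swarm", {
  # two dragonflies over three features
  positions <- rbind(c(1, 0, 1), c(0, 0, 1))
  steps <- rbind(c(0.5, -1, 2), c(1, 1, -1))
  food <- c(1, 1, 1); enemy <- c(0, 0, 0)
  b <- swarm_behaviors(positions, steps, 1, food, enemy)
  expect_equal(b$S, -(positions[1, ] - positions[2, ]))  # -(X_1 - X_2)
  expect_equal(b$A, steps[2, ])
  expect_equal(b$C, positions[2, ] - positions[1, ])
  expect_equal(b$F, food - positions[1, ])
  expect_equal(b$E, enemy + positions[1, ])

  # degenerate swarm: identical positions, zero steps
  pos0 <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  st0 <- matrix(0, 3, 3)
  b0 <- swarm_behaviors(pos0, st0, 2, c(1, 1, 0), c(1, 1, 0))
  expect_equal(b0$S, c(0, 0, 0))
  expect_equal(b0$A, c(0, 0, 0))
  expect_equal(b0$C, c(0, 0, 0))
  expect_equal(b0$F, c(0, 0, 0))  # at the food position
})

test_that("step updates combine behaviors linearly and clamp", {
  cfg <- bdfa_config()
  zero <- list(S = rep(0, 3), A = rep(0, 3), C = rep(0, 3),
               F = rep(0, 3), E = rep(0, 3))
  v <- c(1, -2, 0.5)
  expect_equal(step_update(zero, v, c(0, 0, 0), cfg), 0.85 * v)

  big <- list(S = rep(10, 3), A = rep(10, 3), C = rep(10, 3),
              F = rep(10, 3), E = rep(10, 3))
  expect_equal(step_update(big, rep(10, 3), c(1, 1, 1), cfg), rep(6, 3))

  bh <- list(S = c(1, 0, -1), A = c(0.2, 0.4, 0), C = c(-1, 1, 0),
             F = c(1, 1, 1), E = c(0, -1, 1))
  manual <- 0.1 * bh$S + 0.1 * bh$A + 0.7 * bh$C + 1 * bh$F + 1 * bh$E +
    0.85 * c(0.1, 0.2, 0.3)
  expect_equal(step_update(bh, c(0.1, 0.2, 0.3), c(0, 0, 0), cfg), manual,
               tolerance = 1e-12)
})

test_that("position updates follow the transfer probabilities", {
  # zero step -> T = 0 -> every bit is cleared under the printed rule
  set.seed(52)
  expect_identical(position_update(rep(0, 50), 2, rep(1, 50)), rep(0, 50))

  # large component -> bit set with probability ~ T
  p_hat <- with(list(), {
    set.seed(53)
    mean(replicate(40, position_update(rep(2, 250), 1, rep(0, 250))))
  })
  p_true <- tanh(2)
  se <- sqrt(p_true * (1 - p_true) / 1e4)
  expect_lt(abs(p_hat - p_true), 3 * se)

  set.seed(54); a <- position_update(rnorm(20), 1.5, rep(0, 20))
  set.seed(54); b <- position_update(rnorm(20), 1.5, rep(0, 20))
  expect_identical(a, b)

  # flip rule toggles rather than sets: zero step leaves bits alone
  set.seed(55)
  keep <- position_update(rep(0, 30), 2, rep(1, 30), rule = "flip")
  expect_identical(keep, rep(1, 30))
})

test_that("wrapper fitness reduces to alpha*error + beta*fraction", {
  tab <- generate_planted_table(200, 143, informative_idx = 1:19,
                                effect_size = 8, seed = 56)
  mask <- as.numeric(seq_len(143) %in% 1:19)
  f <- fitness(mask, tab, bdfa_config(seed = 56))
  expect_identical(f$error_rate, 0)  # perfectly separable at effect 8
  expect_equal(f$fitness, 0.01 * 19 / 143, tolerance = 1e-12)
  expect_identical(f$n_selected, 19L)

  expect_identical(fitness(rep(0, 143), tab)$fitness, 1)
  expect_error(fitness(rep(1, 10), tab), "mask length")

  # label-shuffled table: chance-level error
  errs <- vapply(1:5, function(s) {
    tab2 <- generate_planted_table(100, 20, 1:3, 4, seed = 60 + s)
    set.seed(600 + s)
    tab2$label <- sample(tab2$label)
    fitness(rep(1, 20), tab2, bdfa_config(seed = s))$error_rate
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("selection is elitist, deterministic, and recovers planted features", {
  tab <- generate_planted_table(100, 15, informative_idx = 1:3,
                                effect_size = 3, seed = 57)
  cfg <- bdfa_config(iterations = 30, seed = 57)
  res <- select_features(tab, cfg)
  expect_s3_class(res, "bdfa_result")
  expect_true(all(diff(res$history) <= 0))
  expect_gte(sum(res$mask), 1)
  expect_gte(length(intersect(res$selected, c("f001", "f002", "f003"))), 2L)

  res2 <- select_features(tab, cfg)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$history, res2$history)
})

test_that("selection never worsens the pure wrapper criterion", {
  tab <- generate_planted_table(80, 10, informative_idx = 2L,
                                effect_size = 4, seed = 58)
  cfg <- bdfa_config(iterations = 25, alpha = 1, beta = 0, seed = 58)
  res <- select_features(tab, cfg)
  full <- fitness(rep(1, 10), tab, cfg)
  expect_lte(res$error_rate, full$error_rate)
})

test_that("the selected-feature ratio is |C|/N", {
  expect_equal(selected_feature_ratio(as.numeric(seq_len(143) %in% 1:19)),
               19 / 143)
  expect_identical(selected_feature_ratio(rep(1, 10)), 1)
  expect_equal(selected_feature_ratio(c(1, rep(0, 99))), 0.01)
  expect_error(selected_feature_ratio(numeric()), "empty")
})
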