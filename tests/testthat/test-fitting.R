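test_that("the objective is zero for identity dynamics and non-negative always", {
  l <- random_landscape(20, 0.4, seed = 1)
  tgt <- pattern_summary(l)
  for (bj in list(c(0, 0), c(0.5, 0.3), c(-1, 1.2))) {
    expect_equal(fit_objective(bj[1], bj[2], l, tgt, n_steps = 0), 0)
  }
  withr::with_seed(2, {
    v <- fit_objective(0.2, 0.4, l, tgt, n_steps = 500)
    expect_gte(v, 0)
  })
})

test_that("annealing is deterministic given a seed and respects bounds", {
  l <- random_landscape(20, 0.5, seed = 3)
  tgt <- pattern_summary(simulate_landscape(l, ising_params(0.3, 0.4), 800, seed = 4))
  cfg <- anneal_config(n_iter = 40)
  f1 <- anneal_fit(l, tgt, 800, config = cfg, seed = 11)
  f2 <- anneal_fit(l, tgt, 800, config = cfg, seed = 11)
  expect_identical(f1, f2)
  expect_equal(f1$n_eval, 40L)
  expect_true(f1$B >= -2 && f1$B <= 2 && f1$J >= 0 && f1$J <= 2)
})

test_that("collapsing the bounds to a point returns that point", {
  l <- random_landscape(15, 0.5, seed = 5)
  tgt <- pattern_summary(l)
  cfg <- anneal_config(b_bounds = c(0.25, 0.25), j_bounds = c(0.4, 0.4),
                       n_iter = 10)
  f <- anneal_fit(l, tgt, 100, config = cfg, seed = 6)
  expect_equal(f$B, 0.25)
  expect_equal(f$J, 0.4)
})

test_that("anneal_config validates bounds, budget and starting point", {
  expect_error(anneal_config(b_bounds = c(2, -2)), "ordered")
  expect_error(anneal_config(n_iter = 0), "positive")
  expect_error(anneal_config(init = c(5, 0.5)), "inside the bounds")
  expect_s3_class(anneal_config(init = c(0, 0.5)), "anneal_config")
})

test_that("a singleton ensemble reduces to its only annealing run", {
  l <- random_landscape(15, 0.5, seed = 7)
  tgt <- pattern_summary(simulate_landscape(l, ising_params(0.2, 0.3), 450, seed = 8))
  cfg <- anneal_config(n_iter = 25)
  ef <- ensemble_fit(l, tgt, 450, config = cfg, n_replicates = 1, seed = 9)
  expect_equal(nrow(ef$replicates), 1)
  expect_equal(ef$selected$B, ef$replicates$B)
  expect_equal(ef$selected$J, ef$replicates$J)
  expect_equal(ef$selected$peak_count, 1L)
})

test_that("when every replicate lands in one bin the peak holds them all", {
  l <- random_landscape(15, 0.5, seed = 10)
  tgt <- pattern_summary(l)
  cfg <- anneal_config(b_bounds = c(0.1, 0.1), j_bounds = c(0.5, 0.5), n_iter = 3)
  ef <- ensemble_fit(l, tgt, 50, config = cfg, n_replicates = 6, seed = 11)
  expect_equal(ef$selected$peak_count, 6L)
  expect_equal(ef$selected$B, 0.1)
})

test_that("ensemble fits are bit-reproducible from the master seed", {
  l <- random_landscape(15, 0.5, seed = 12)
  tgt <- pattern_summary(simulate_landscape(l, ising_params(0.1, 0.4), 450, seed = 13))
  cfg <- anneal_config(n_iter = 15)
  e1 <- ensemble_fit(l, tgt, 450, config = cfg, n_replicates = 4, seed = 14)
  e2 <- ensemble_fit(l, tgt, 450, config = cfg, n_replicates = 4, seed = 14)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$selected, e2$selected)
  expect_s3_class(tidy(e1), "tbl_df")
  g <- glance(e1)
  expect_named(g, c("B", "J", "objective", "peak_count", "n_replicates",
                    "sd_B", "sd_J"))
  expect_output(print(e1), "selected B")
  expect_s3_class(autoplot(e1), "ggplot")
})

test_that("the objective near the generating truth beats displaced parameters", {
  d <- 40
  init <- equilibrated_landscape(d, ising_params(0, 0.45, Q = 0), 60 * d * d,
                                 seed = 15)
  truth <- c(0.2, 0.45)
  n_steps <- 2 * d * d
  tgt <- pattern_summary(simulate_landscape(init, ising_params(truth[1], truth[2]),
                                            n_steps, seed = 16))
  at_truth <- withr::with_seed(17, vapply(1:10, function(i) {
    fit_objective(truth[1], truth[2], init, tgt, n_steps)
  }, numeric(1)))
  displaced <- withr::with_seed(18, vapply(1:10, function(i) {
    fit_objective(truth[1] + 0.3, truth[2] + 0.3, init, tgt, n_steps)
  }, numeric(1)))
  expect_lt(stats::wilcox.test(at_truth, displaced, alternative = "less")$p.value,
            0.01)
})

test_that("response surfaces record means, spreads and distances per grid cell", {
  l <- random_landscape(15, 0.5, seed = 19)
  tgt <- pattern_summary(simulate_landscape(l, ising_params(0.2, 0.4), 450, seed = 20))
  rs1 <- response_surface(l, tgt, 450, b_grid = c(0, 0.2, 0.4),
                          j_grid = c(0.2, 0.4, 0.6), reps_per_cell = 2, seed = 21)
  rs2 <- response_surface(l, tgt, 450, b_grid = c(0, 0.2, 0.4),
                          j_grid = c(0.2, 0.4, 0.6), reps_per_cell = 2, seed = 21)
  expect_equal(nrow(rs1), 9)
  expect_named(rs1, c("B", "J", "m_mean", "m_sd", "c1_mean", "c1_sd", "distance"))
  expect_true(all(rs1$m_sd >= 0) && all(rs1$c1_sd >= 0))
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  expect_error(response_surface(l, tgt, 450, numeric(0), 0.4), "non-empty")
  expect_s3_class(autoplot(rs1), "ggplot")
})
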