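test_that("conditional moments of a constant estimator are exact", {
  d <- toy_design()
  const <- function(design, k, z) rep(3.2, length(z))
  for (k in 1:2) {
    cm <- conditional_moments(d, const, theta = 0.4, k = k)
    expect_equal(cm$mean, 3.2, tolerance = 1e-10)
    expect_equal(cm$second, 3.2^2, tolerance = 1e-9)
  }
})

test_that("open-design MLE moments are the normal mean and variance", {
  d <- two_stage_design(-Inf, Inf, I1 = 1, I2 = 2, delta = 0.5)
  cm <- conditional_moments(d, "MLE", theta = 0.7, k = 2)
  expect_equal(cm$mean, 0.7, tolerance = 1e-10)
  expect_equal(cm$second, 0.7^2 + 1 / 2, tolerance = 1e-10)
  # degenerate stage-1 conditioning is reported, not zeroed
  cm1 <- conditional_moments(d, "MLE", theta = 0.7, k = 1)
  expect_true(cm1$degenerate)
  expect_true(is.na(cm1$mean))
})

test_that("quadrature marginal MLE bias reproduces the analytic expression", {
  d <- example_designs()$example1_eff_fut
  for (th in seq(-2, 2, length.out = 9) * d$delta) {
    tab <- performance_row(d, "MLE", th)
    expect_lt(abs(tab$bias_marginal - mle_marginal_bias(d, th)), 1e-7)
  }
  # and the conditional pieces recombine to the marginal closed form
  th <- 0.15
  tab <- performance_row(d, "MLE", th)
  expect_equal(tab$s1 * tab$bias_k1 + tab$s2 * tab$bias_k2,
               mle_marginal_bias(d, th), tolerance = 1e-9)
  # stage-1 conditional bias has its own closed form as a cross-check
  expect_equal(tab$bias_k1, oracle_mle_bias_k1(d, th), tolerance = 1e-9)
  expect_equal(mle_conditional_bias(d, th, 1), oracle_mle_bias_k1(d, th),
               tolerance = 1e-10)
})

test_that("marginal rows are the stopping-probability-weighted conditionals", {
  d <- toy_design()
  tab <- evaluate_grid(d, estimators = c("MLE", "MAE2", "UMVUE", "CUMVUE"),
                       grid = theta_grid(d, n = 5))
  expect_equal(tab$bias_marginal,
               tab$s1 * tab$bias_k1 + tab$s2 * tab$bias_k2,
               tolerance = 1e-9)
  expect_equal(tab$rmse_marginal,
               tab$s1 * tab$rmse_k1 + tab$s2 * tab$rmse_k2,
               tolerance = 1e-9)
  # residual mean square error dominates squared bias
  expect_true(all(tab$rmse_k1 >= tab$bias_k1^2 - 1e-12))
  expect_true(all(tab$rmse_k2 >= tab$bias_k2^2 - 1e-12))
})

test_that("grid evaluation has the expected shape and determinism", {
  d <- example_designs()$example2
  tab1 <- evaluate_grid(d, estimators = "UMVUE", grid = 2.5)
  expect_equal(nrow(tab1), 1L)
  tab <- evaluate_grid(d, estimators = c("MLE", "UMVUE"),
                       grid = theta_grid(d, n = 3))
  expect_equal(nrow(tab), 6L)
  expect_identical(tab, evaluate_grid(d, estimators = c("MLE", "UMVUE"),
                                      grid = theta_grid(d, n = 3)))
  expect_equal(names(tab),
               c("estimator", "theta", "s1", "s2", "bias_k1", "bias_k2",
                 "bias_marginal", "rmse_k1", "rmse_k2", "rmse_marginal",
                 "flags"))
})

test_that("unbiasedness of the UMVUE and conditional unbiasedness of the CUMVUE", {
  d <- toy_design()
  tab <- evaluate_grid(d, estimators = c("UMVUE", "CUMVUE"),
                       grid = theta_grid(d, n = 7))
  expect_true(all(abs(tab$bias_marginal[tab$estimator == "UMVUE"]) < 1e-6))
  expect_true(all(abs(tab$bias_k2[tab$estimator == "CUMVUE"]) < 1e-6))
})

test_that("performance profiles are antisymmetric on the symmetric design", {
  d5 <- example_designs()$example5
  grid <- c(-1.2, -0.5, 0.5, 1.2)
  tab <- evaluate_grid(d5, estimators = c("MLE", "MAE2", "UMVUE", "CWMAE"),
                       grid = grid)
  for (nm in unique(tab$estimator)) {
    sub <- tab[tab$estimator == nm, ]
    lower <- sub[sub$theta < 0, ]; upper <- sub[sub$theta > 0, ]
    upper <- upper[order(-upper$theta), ]
    expect_equal(lower$bias_marginal, -upper$bias_marginal,
                 tolerance = 1e-8, label = paste(nm, "bias antisymmetry"))
    expect_equal(lower$rmse_marginal, upper$rmse_marginal,
                 tolerance = 1e-8, label = paste(nm, "rmse symmetry"))
  }
})

test_that("doubling quadrature resolution leaves results unchanged", {
  d <- example_designs()$example1_eff_fut
  grid <- c(-0.2, 0.1, 0.35)
  coarse <- evaluate_grid(d, estimators = c("MLE", "UMVUE"), grid = grid)
  fine <- evaluate_grid(d, estimators = c("MLE", "UMVUE"), grid = grid,
                        quad = list(nodes = 128L, panel_max = 1))
  for (col in c("bias_k1", "bias_k2", "bias_marginal",
                "rmse_k1", "rmse_k2", "rmse_marginal"))
    expect_lt(max(abs(coarse[[col]] - fine[[col]])), 1e-8)
})

test_that("estimator search flags propagate to performance rows", {
  d <- example_designs()$example2     # CMLE divergence region exists
  tab <- evaluate_grid(d, estimators = "CMLE", grid = -2 * d$delta)
  expect_true(is.finite(tab$bias_k2))
  expect_match(tab$flags, "truncated")
})
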