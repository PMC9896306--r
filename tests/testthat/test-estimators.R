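test_that("the MLE is z over root information", {
  d2 <- example_designs()$example2
  expect_identical(theta_mle(d2, 1, 0), 0)
  expect_equal(theta_mle(d2, 1, -1), -1 / sqrt(0.0575))
  expect_equal(theta_mle(d2, 2, sqrt(d2$I2) * 3.7), 3.7)
  z <- c(-1, -0.2)
  expect_equal(theta_mle(d2, 1, z), z / sqrt(d2$I1))
})

test_that("closed-form marginal MLE bias vanishes where symmetry dictates", {
  d5 <- example_designs()$example5        # l = -u
  expect_equal(mle_marginal_bias(d5, 0), 0)
  open <- two_stage_design(-Inf, Inf, 1, 2, 0.5)
  expect_equal(mle_marginal_bias(open, c(-1, 0, 2)), c(0, 0, 0))
  # antisymmetry for a symmetric design
  th <- c(0.3, 1.1)
  expect_equal(mle_marginal_bias(d5, -th), -mle_marginal_bias(d5, th))
})

test_that("stage-1 estimates collapse to the MLE where the theory says so", {
  for (d in list(toy_design(), example_designs()$example1_eff_fut,
                 example_designs()$example4)) {
    z <- c(d$l - 1.5, d$l - 0.1, if (is.finite(d$u)) d$u + 0.8)
    mle <- theta_mle(d, 1, z)
    expect_equal(as.numeric(theta_mue(d, 1, z)), mle)
    expect_equal(as.numeric(theta_umvue(d, 1, z)), mle)
    expect_equal(as.numeric(theta_cumvue(d, 1, z)), mle)
  }
})

test_that("with no stopping boundaries every estimator equals the MLE", {
  d <- two_stage_design(-Inf, Inf, I1 = 2, I2 = 5, delta = 0.4)
  for (z in c(-1.7, 0, 2.2)) {
    res <- estimate_all(d, 2, z)
    expect_equal(res$estimate, rep(z / sqrt(5), 9), tolerance = 1e-9)
  }
})

test_that("MAE1 satisfies its defining fixed-point equation", {
  set.seed(42)
  for (d in list(example_designs()$example1_eff_fut,
                 example_designs()$example2, toy_design())) {
    sim <- simulate_trials(d, theta = d$delta / 2, n_trials = 12, seed = 7)
    for (i in seq_len(nrow(sim))) {
      est <- as.numeric(theta_mae1(d, sim$k[i], sim$z[i]))
      resid <- est + mle_marginal_bias(d, est) -
        theta_mle(d, sim$k[i], sim$z[i])
      expect_lt(abs(resid), 1e-9)
    }
  }
})

test_that("MAE2 is the explicit plug-in adjustment and is antisymmetric under l = -u", {
  d <- toy_design()
  z <- c(-1.4, 2.2)
  mle <- theta_mle(d, 2, z)
  expect_equal(theta_mae2(d, 2, z), mle - mle_marginal_bias(d, mle))
  d5 <- example_designs()$example5
  for (k in 1:2) {
    z <- c(3.0, 3.6, 4.1)
    expect_equal(theta_mae2(d5, k, -z), -theta_mae2(d5, k, z))
  }
})

test_that("the MUE puts the observed outcome at the stage-wise median", {
  for (d in list(example_designs()$example1_eff_fut,
                 example_designs()$example5, toy_design())) {
    for (z in c(-0.8, 0.6, 2.4)) {
      est <- as.numeric(theta_mue(d, 2, z))
      expect_lt(abs(oracle_exceedance2(d, z, est) - 0.5), 1e-9)
    }
  }
  # open design: the exceedance reduces to the marginal normal tail
  open <- two_stage_design(-Inf, Inf, 1, 2, 0.5)
  expect_equal(as.numeric(theta_mue(open, 2, 1.3)), 1.3 / sqrt(2),
               tolerance = 1e-9)
})

test_that("the UMVUE matches the Rao-Blackwell conditional expectation", {
  for (d in list(example_designs()$example1_eff_fut,
                 example_designs()$example2, toy_design())) {
    for (z in c(-1.2, 0.3, 1.7, 3.0)) {
      expect_equal(theta_umvue(d, 2, z), oracle_umvue2(d, z),
                   tolerance = 1e-9)
    }
  }
  open <- two_stage_design(-Inf, Inf, 1, 2, 0.5)
  expect_equal(theta_umvue(open, 2, 1.3), 1.3 / sqrt(2))
})

test_that("the UMVUE stays finite and ordered in the far tails", {
  d <- example_designs()$example2     # l = 0, u = Inf
  z <- c(-30, -15, 15, 30)
  v <- theta_umvue(d, 2, z)
  expect_true(all(is.finite(v)))
  # far below the continuation region the conditional law of Z1
  # concentrates just above the futility boundary, so the estimate sits a
  # little above l / sqrt(I1) and approaches it as z decreases
  expect_gt(v[1], d$l / sqrt(d$I1))
  expect_lt(v[1] - d$l / sqrt(d$I1), 0.1)
  expect_true(all(diff(v) > 0))
})

test_that("the CMLE zeroes the conditional score and obeys the Fan identity", {
  for (d in list(example_designs()$example1_eff_fut, toy_design())) {
    for (kz in list(c(1, d$l - 0.7), c(1, d$u + 0.4), c(2, 0.9),
                    c(2, 2.6))) {
      k <- kz[1]; z <- kz[2]
      est <- theta_cmle(d, k, z)
      expect_null(attr(est, "flags"))
      est <- as.numeric(est)
      # numerical conditional score via the public density functions
      h <- 1e-5
      ll <- function(t) log(conditional_density(d, k, z, t))
      expect_lt(abs((ll(est + h) - ll(est - h)) / (2 * h)), 1e-6)
      # conditional analogue of the mean-adjustment fixed point
      expect_lt(abs(est + mle_conditional_bias(d, est, k) -
                      theta_mle(d, k, z)), 1e-7)
    }
  }
})

test_that("the CMLE flags divergence at the search bound when unbounded", {
  d <- example_designs()$example2     # futility-only: unbounded CMLE bias
  est <- theta_cmle(d, 2, -14)        # deep in the left tail
  expect_true(grepl("hit_search_bound", attr(est, "flags")[1]))
  expect_true(is.finite(as.numeric(est)))
})

test_that("the CWMAE shrinkage weight behaves as stated", {
  d <- toy_design()
  I1 <- d$I1
  # MLE equal to the prior guess: zero weight, bias evaluated at theta0
  z0 <- d$delta * sqrt(I1)
  expect_error(trial_outcome(d, 1, z0))  # inside continuation: use theta0 override
  zlow <- d$l - 0.3
  mle <- theta_mle(d, 1, zlow)
  est <- theta_cwmae(d, 1, zlow, theta0 = mle)
  expect_equal(as.numeric(est),
               mle - mle_conditional_bias(d, mle, 1), tolerance = 1e-10)
  # |MLE - theta0| = 1 / sqrt(I1): weight one half, theta* the midpoint
  t0 <- mle - 1 / sqrt(I1)
  est_half <- theta_cwmae(d, 1, zlow, theta0 = t0)
  expect_equal(as.numeric(est_half),
               mle - mle_conditional_bias(d, (mle + t0) / 2, 1),
               tolerance = 1e-10)
  # a remote prior guess leaves the estimate near the stage-1 CMLE-style
  # adjustment at the MLE itself (weight -> 1)
  far <- theta_cwmae(d, 1, zlow, theta0 = mle + 1e6)
  expect_equal(as.numeric(far), mle - mle_conditional_bias(d, mle, 1),
               tolerance = 1e-4)
  # stage 2 uses the MLE by convention, and says so
  est2 <- theta_cwmae(d, 2, 0.7)
  expect_equal(as.numeric(est2), theta_mle(d, 2, 0.7))
  expect_equal(attr(est2, "flags"), "stage_convention")
})

test_that("the CMUE is the conditional median, including disconnected stage-1 support", {
  for (d in list(example_designs()$example1_eff_fut, toy_design())) {
    cases <- list(c(1, d$l - 0.9), c(1, d$u + 0.2), c(2, -0.4), c(2, 2.1))
    for (kz in cases) {
      k <- kz[1]; z <- kz[2]
      est <- as.numeric(theta_cmue(d, k, z))
      expect_lt(abs(oracle_conditional_cdf(d, k, z, est) - 0.5), 1e-8)
    }
  }
  open <- two_stage_design(-Inf, Inf, 1, 2, 0.5)
  expect_equal(as.numeric(theta_cmue(open, 2, -0.9)), -0.9 / sqrt(2),
               tolerance = 1e-9)
  # futility-only design with high information: the conditional median can
  # sit where the stage-1 stopping probability is far below double
  # precision of its complement (regression: s(1 | theta) must not be
  # computed as 1 - s(2 | theta))
  d4 <- example_designs()$example4
  for (z in c(-0.3, -0.5, -1.5)) {
    est <- theta_cmue(d4, 1, z)
    expect_null(attr(est, "flags"))
    expect_lt(abs(oracle_conditional_cdf(d4, 1, z, as.numeric(est)) - 0.5),
              1e-8)
  }
})

test_that("the CUMVUE closed form matches the stage-2-increment Rao-Blackwell oracle", {
  for (d in list(example_designs()$example1_eff_fut, toy_design())) {
    for (z in c(-1.1, 0.5, 2.3)) {
      expect_equal(theta_cumvue(d, 2, z), oracle_cumvue2(d, z),
                   tolerance = 1e-9)
    }
  }
  open <- two_stage_design(-Inf, Inf, 1, 2, 0.5)
  expect_equal(theta_cumvue(open, 2, 1.1), 1.1 / sqrt(2))
  # stage-1 convention is the MLE, flagged
  d <- toy_design()
  est <- theta_cumvue(d, 1, d$l - 0.2)
  expect_equal(attr(est, "flags"), rep("stage_convention", 1))
})

test_that("all estimators are antisymmetric on the symmetric two-sided design", {
  d5 <- example_designs()$example5
  zs <- list(`1` = c(2.9, 3.4, 4.2), `2` = c(-2.5, -1.1, 0.4, 1.9))
  for (nm in estimator_names()) {
    fn <- function(k, z) {
      v <- switch(nm,
        MLE = theta_mle(d5, k, z), MAE1 = theta_mae1(d5, k, z),
        MAE2 = theta_mae2(d5, k, z), MUE = theta_mue(d5, k, z),
        UMVUE = theta_umvue(d5, k, z), CMLE = theta_cmle(d5, k, z),
        CWMAE = theta_cwmae(d5, k, z), CMUE = theta_cmue(d5, k, z),
        CUMVUE = theta_cumvue(d5, k, z))
      as.numeric(v)
    }
    for (k in 1:2) {
      z <- zs[[k]]
      expect_equal(fn(k, -z), -fn(k, z), tolerance = 1e-8,
                   label = paste(nm, "stage", k))
    }
  }
})

test_that("estimate_all returns the nine named estimates with flags", {
  d <- example_designs()$example2
  res <- estimate_all(d, 2, 2.1)
  expect_equal(res$estimator, estimator_names())
  expect_true(all(is.finite(res$estimate)))
  expect_equal(res$flag[res$estimator == "CWMAE"], "stage_convention")
  res1 <- estimate_all(d, 1, -0.4)
  expect_equal(res1$flag[res1$estimator == "CUMVUE"], "stage_convention")
  # the stage-1 identity block, through the top-level interface
  mle <- res1$estimate[res1$estimator == "MLE"]
  for (nm in c("MUE", "UMVUE", "CUMVUE"))
    expect_identical(res1$estimate[res1$estimator == nm], mle)
})
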