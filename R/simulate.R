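# Monte-Carlo generation of trial outcomes (K, Z). Generation uses the
# independent-increment (score) construction: Z1 ~ N(theta * sqrt(I1), 1);
# on continuation the stage-2 score increment X ~ N(theta (I2 - I1),
# I2 - I1) is added, so Z2 = (Z1 sqrt(I1) + X)/sqrt(I2). This realises the
# canonical covariance sqrt(I1/I2) by construction.

#' Simulate two-stage trial outcomes
#'
#' @inheritParams gs_density
#' @param n_trials Number of independent trials to simulate.
#' @param seed Integer seed; the same `(design, theta, n_trials, seed)`
#'   reproduces the batch exactly. The caller's RNG state is restored on
#'   exit.
#' @return A data frame of class `simulation_batch` with columns `k`
#'   (terminal stage) and `z` (terminal statistic) and attributes `design`,
#'   `theta`, `seed`.
#' @examples
#' d <- builtin_design("example2")
#' sim <- simulate_trials(d, theta = 5, n_trials = 1000, seed = 1)
#' table(sim$k)
#' @export
simulate_trials <- function(design, theta, n_trials, seed) {
  .check_design(design)
  stopifnot(length(theta) == 1L, is.finite(theta),
            length(n_trials) == 1L, n_trials >= 1,
            length(seed) == 1L, is.finite(seed))
  n_trials <- as.integer(n_trials)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  z1 <- rnorm(n_trials, theta * sqrt(design$I1), 1)
  x <- rnorm(n_trials, theta * (design$I2 - design$I1),
             sqrt(design$I2 - design$I1))
  stop1 <- z1 <= design$l | z1 >= design$u
  z2 <- (z1 * sqrt(design$I1) + x) / sqrt(design$I2)
  out <- data.frame(k = ifelse(stop1, 1L, 2L),
                    z = ifelse(stop1, z1, z2))
  attr(out, "z1") <- z1          # kept for covariance diagnostics
  attr(out, "design") <- design
  attr(out, "theta") <- theta
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("simulation_batch", "data.frame")
  out
}

#' Empirical bias and RMSE from a simulated batch
#'
#' Monte-Carlo counterpart of [performance_row()]: per-stage and marginal
#' mean error and mean squared error of an estimator over a batch from
#' [simulate_trials()], with standard errors. Used as the independent
#' stochastic oracle for the quadrature engine.
#'
#' @param batch A `simulation_batch` from [simulate_trials()].
#' @param estimator Estimator name or function `f(design, k, z)`.
#' @param theta0 Prior guess forwarded to the CWMAE.
#' @return A one-row data frame with columns `estimator`, `theta`, `n1`,
#'   `n2`, and for each stratum (`k1`, `k2`, `marginal`) the empirical
#'   `bias_*`, `rmse_*` and their standard errors `se_bias_*`, `se_rmse_*`.
#'   Strata with no outcomes are `NA`.
#' @export
empirical_performance <- function(batch, estimator, theta0 = NULL) {
  stopifnot(inherits(batch, "simulation_batch"), nrow(batch) >= 1L)
  design <- attr(batch, "design")
  theta <- attr(batch, "theta")
  est <- .resolve_estimator(estimator)
  err <- rep(NA_real_, nrow(batch))
  for (k in 1:2) {
    idx <- batch$k == k
    if (any(idx))
      err[idx] <- as.numeric(est$fn(design, k, batch$z[idx], theta0)) - theta
  }
  strat <- function(e) {
    n <- length(e)
    if (n == 0L)
      return(c(bias = NA, se_bias = NA, rmse = NA, se_rmse = NA))
    c(bias = mean(e), se_bias = sd(e) / sqrt(n),
      rmse = mean(e^2), se_rmse = sd(e^2) / sqrt(n))
  }
  s1 <- strat(err[batch$k == 1L]); s2 <- strat(err[batch$k == 2L])
  sm <- strat(err)
  data.frame(estimator = est$name, theta = theta,
             n1 = sum(batch$k == 1L), n2 = sum(batch$k == 2L),
             bias_k1 = s1[["bias"]], se_bias_k1 = s1[["se_bias"]],
             rmse_k1 = s1[["rmse"]], se_rmse_k1 = s1[["se_rmse"]],
             bias_k2 = s2[["bias"]], se_bias_k2 = s2[["se_bias"]],
             rmse_k2 = s2[["rmse"]], se_rmse_k2 = s2[["se_rmse"]],
             bias_marginal = sm[["bias"]], se_bias_marginal = sm[["se_bias"]],
             rmse_marginal = sm[["rmse"]], se_rmse_marginal = sm[["se_rmse"]],
             stringsAsFactors = FALSE)
}
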