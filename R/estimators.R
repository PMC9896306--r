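# The nine point estimators theta_hat(K, Z).
#
# Closed forms are used where they exist (MLE, MAE2, UMVUE, CUMVUE, the
# stage-1 identities); the remaining estimators are defined as roots or
# maxima of smooth monotone/unimodal functions of theta and are found by
# safeguarded bracketing searches with absolute residual target 1e-10.

.ESTIMATORS <- c("MLE", "MAE1", "MAE2", "MUE", "UMVUE",
                 "CMLE", "CWMAE", "CMUE", "CUMVUE")

#' Names of the available estimators
#' @return Character vector of the nine estimator names.
#' @export
estimator_names <- function() .ESTIMATORS

# mean of a standard normal truncated to (a, b), vectorised; evaluated via
# scaled complementary (log-space) forms beyond |argument| > 6 to avoid
# catastrophic cancellation in the Phi difference
.truncnorm_mean_std <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ai <- a[i]; bi <- b[i]
    if (ai == -Inf && bi == Inf) { out[i] <- 0; next }
    if (ai > 6) {
      lpa <- dnorm(ai, log = TRUE); lpb <- dnorm(bi, log = TRUE)
      lsa <- pnorm(ai, lower.tail = FALSE, log.p = TRUE)
      lsb <- pnorm(bi, lower.tail = FALSE, log.p = TRUE)
      out[i] <- exp(lpa - lsa) *
        if (bi == Inf) 1 else expm1(lpb - lpa) / expm1(lsb - lsa)
    } else if (bi < -6) {
      lpa <- dnorm(ai, log = TRUE); lpb <- dnorm(bi, log = TRUE)
      lsa <- pnorm(ai, log.p = TRUE); lsb <- pnorm(bi, log.p = TRUE)
      out[i] <- -exp(lpb - lsb) *
        if (ai == -Inf) 1 else expm1(lpa - lpb) / expm1(lsa - lsb)
    } else {
      out[i] <- (dnorm(ai) - dnorm(bi)) / .pnorm_diff(ai, bi)
    }
  }
  out
}

# expanding bracket for a monotone function g; returns c(lo, hi) with a
# sign change, or NULL
.expand_bracket <- function(g, centre, step, max_expand = 6L) {
  lo <- centre - step; hi <- centre + step
  glo <- g(lo); ghi <- g(hi)
  for (i in seq_len(max_expand + 1L)) {
    if (is.finite(glo) && is.finite(ghi) && glo * ghi <= 0)
      return(c(lo, hi))
    step <- step * 2
    lo <- centre - step; hi <- centre + step
    glo <- g(lo); ghi <- g(hi)
  }
  NULL
}

# root of monotone g with flagging; returns list(value, flag)
.safe_root <- function(g, centre, step, resid_tol = 1e-10) {
  br <- .expand_bracket(g, centre, step)
  if (is.null(br)) {
    cand <- c(centre - step * 2^6, centre + step * 2^6)
    gv <- abs(vapply(cand, g, numeric(1)))
    gv[!is.finite(gv)] <- Inf
    return(list(value = cand[which.min(gv)], flag = "hit_search_bound"))
  }
  root <- uniroot(g, br, tol = 1e-12)$root
  flag <- if (abs(g(root)) <= resid_tol) "" else "tolerance_not_met"
  list(value = root, flag = flag)
}

.with_flags <- function(value, flags) {
  if (any(nzchar(flags))) attr(value, "flags") <- flags
  value
}

#' Maximum likelihood estimator
#'
#' \eqn{\hat\theta_{MLE}(k, z) = z / \sqrt{I_k}}. Biased after sequential
#' stopping: the MLE typically overestimates the magnitude of \eqn{\theta}.
#'
#' @param design A [two_stage_design()].
#' @param k Terminal stage (1 or 2).
#' @param z Terminal standardised statistic (vectorised).
#' @return Estimate(s) of \eqn{\theta}.
#' @export
theta_mle <- function(design, k, z) {
  trial_outcome(design, k, z)
  z / sqrt(if (k == 1L) design$I1 else design$I2)
}

#' Marginal bias of the MLE (closed form)
#'
#' The analytical marginal bias of the maximum likelihood estimator,
#' \deqn{Bias(\hat\theta_{MLE} | \theta) = \frac{I_2 - I_1}{I_2 \sqrt{I_1}}
#'   \{\phi(u - \theta\sqrt{I_1}) - \phi(l - \theta\sqrt{I_1})\},}
#' where \eqn{\phi} is the standard normal density (terms with infinite
#' boundaries vanish).
#'
#' @inheritParams gs_density
#' @return Bias values (vectorised over `theta`).
#' @export
mle_marginal_bias <- function(design, theta) {
  .check_design(design)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite", call. = FALSE)
  m1 <- theta * sqrt(design$I1)
  (design$I2 - design$I1) / (design$I2 * sqrt(design$I1)) *
    (dnorm(design$u - m1) - dnorm(design$l - m1))
}

#' Conditional bias of the MLE
#'
#' \eqn{Bias(\hat\theta_{MLE} | \theta, k) = E(Z/\sqrt{I_k} | \theta, K = k)
#' - \theta}, computed by the same quadrature engine that underlies the
#' performance evaluations.
#'
#' @inheritParams gs_density
#' @return The conditional bias (scalar `theta`).
#' @export
mle_conditional_bias <- function(design, theta, k) {
  .check_design(design)
  k <- .check_stage(k)
  sqI <- sqrt(if (k == 1L) design$I1 else design$I2)
  mom <- .cond_moment(design, k, theta, function(z) z / sqI)
  mom$mean - theta
}

#' Mean adjusted estimator, fixed-point form (MAE1)
#'
#' The solution of \eqn{\hat\theta = \hat\theta_{MLE} -
#' Bias(\hat\theta_{MLE} | \hat\theta)}: the value of \eqn{\theta} under
#' which the expected MLE equals the observed MLE. Determined by a
#' bracketing search (the defining function is strictly increasing).
#'
#' @inheritParams theta_mle
#' @return Estimate(s); a `flags` attribute marks any search failure.
#' @export
theta_mae1 <- function(design, k, z) {
  mle <- theta_mle(design, k, z)
  step <- 10 / sqrt(design$I1)
  vals <- numeric(length(mle)); flags <- character(length(mle))
  for (i in seq_along(mle)) {
    g <- function(t) t + mle_marginal_bias(design, t) - mle[i]
    r <- .safe_root(g, mle[i], step)
    vals[i] <- r$value; flags[i] <- r$flag
  }
  .with_flags(vals, flags)
}

#' Mean adjusted estimator, plug-in form (MAE2)
#'
#' \eqn{\hat\theta_{MAE2} = \hat\theta_{MLE} - Bias(\hat\theta_{MLE} |
#' \hat\theta_{MLE})}: the MLE minus its own marginal bias evaluated at the
#' MLE. Closed form, no iteration.
#'
#' @inheritParams theta_mle
#' @return Estimate(s).
#' @export
theta_mae2 <- function(design, k, z) {
  mle <- theta_mle(design, k, z)
  mle - mle_marginal_bias(design, mle)
}

#' Median unbiased estimator under the stage-wise ordering (MUE)
#'
#' The value of \eqn{\theta} that makes the observed outcome the median of
#' the stage-wise ordering: \eqn{P\{(K, Z) \succ (k, z) | \hat\theta\} =
#' 0.5}. For a stage-1 stop this reduces exactly to the MLE; for stage 2 it
#' is found by a bracketing search (the exceedance probability is strictly
#' increasing in \eqn{\theta}).
#'
#' @inheritParams theta_mle
#' @return Estimate(s); a `flags` attribute marks any search failure.
#' @export
theta_mue <- function(design, k, z) {
  mle <- theta_mle(design, k, z)
  if (k == 1L) return(mle)
  step <- 10 / sqrt(design$I1)
  vals <- numeric(length(z)); flags <- character(length(z))
  for (i in seq_along(z)) {
    g <- function(t) exceedance_stagewise(design, 2L, z[i], t) - 0.5
    r <- .safe_root(g, mle[i], step)
    vals[i] <- r$value; flags[i] <- r$flag
  }
  .with_flags(vals, flags)
}

#' Uniform minimum variance unbiased estimator (UMVUE)
#'
#' The Rao-Blackwellisation of the unbiased stage-1 estimator
#' \eqn{Z_1/\sqrt{I_1}} given the sufficient statistic: \eqn{E(Z_1/\sqrt{I_1}
#' | K = k, Z = z)}. For \eqn{k = 1} this is the MLE; for \eqn{k = 2},
#' since \eqn{Z_1 | Z_2 = z \sim N(z\sqrt{I_1/I_2}, (I_2-I_1)/I_2)} free of
#' \eqn{\theta}, it is the mean of that normal truncated to the continuation
#' region, divided by \eqn{\sqrt{I_1}}. Marginally unbiased for every
#' \eqn{\theta} (uniformly minimum variance among truncation-adaptable
#' unbiased estimators).
#'
#' @inheritParams theta_mle
#' @return Estimate(s).
#' @export
theta_umvue <- function(design, k, z) {
  mle <- theta_mle(design, k, z)
  if (k == 1L) return(mle)
  m <- z * sqrt(design$I1 / design$I2)
  sv <- sqrt((design$I2 - design$I1) / design$I2)
  estd <- .truncnorm_mean_std((design$l - m) / sv, (design$u - m) / sv)
  (m + sv * estd) / sqrt(design$I1)
}

# conditional log-likelihood score d/dtheta log fcond(k, z | theta),
# scalar theta, scalar z
.cond_score <- function(design, k, z, theta) {
  sq1 <- sqrt(design$I1); sq2 <- sqrt(design$I2)
  m1 <- theta * sq1
  lphi_l <- dnorm(design$l - m1, log = TRUE)
  lphi_u <- dnorm(design$u - m1, log = TRUE)
  ls <- .log_stop_probability(design, k, theta)
  if (k == 1L) {
    sq1 * (z - m1) - sq1 * (exp(lphi_u - ls) - exp(lphi_l - ls))
  } else {
    sq2 * (z - theta * sq2) - sq1 * (exp(lphi_l - ls) - exp(lphi_u - ls))
  }
}

# conditional log-likelihood (up to constants), vectorised over theta
.cond_loglik <- function(design, k, z, theta) {
  vapply(theta, function(t) {
    m <- t * sqrt(if (k == 1L) design$I1 else design$I2)
    dnorm(z - m, log = TRUE) - .log_stop_probability(design, k, t)
  }, numeric(1))
}

#' Conditional maximum likelihood estimator (CMLE)
#'
#' The maximiser over \eqn{\theta} of the conditional likelihood
#' \eqn{f_{cond}(k, z | \theta)}, i.e. the likelihood given the stopping
#' stage. Equivalently (Fan-type identity) the solution of the conditional
#' analogue of the MAE1 fixed point, \eqn{\hat\theta = \hat\theta_{MLE} -
#' Bias(\hat\theta_{MLE} | \hat\theta, k)}. The search is confined to
#' `mle +/- search_bound`; when the optimum sits on that bound (which
#' occurs for some outcomes when one stopping boundary is absent, where the
#' estimator's bias is unbounded) the bound is returned with flag
#' `"hit_search_bound"`.
#'
#' @inheritParams theta_mle
#' @param search_bound Half-width of the search interval on the
#'   \eqn{\theta} scale; default \eqn{20/\sqrt{I_1}}.
#' @return Estimate(s); `flags` attribute may contain `"hit_search_bound"`
#'   or `"multimodal"`.
#' @export
theta_cmle <- function(design, k, z, search_bound = 20 / sqrt(design$I1)) {
  mle <- theta_mle(design, k, z)
  vals <- numeric(length(z)); flags <- character(length(z))
  for (i in seq_along(z)) {
    lo <- mle[i] - search_bound; hi <- mle[i] + search_bound
    grid <- seq(lo, hi, length.out = 81L)
    ll <- .cond_loglik(design, k, z[i], grid)
    ll[!is.finite(ll)] <- -Inf
    best <- which.max(ll)
    # multimodality: count interior local maxima on the scan grid
    n_max <- sum(ll[2:80] > ll[1:79] & ll[2:80] >= ll[3:81])
    fl <- if (n_max > 1L) "multimodal" else ""
    if (best == 1L || best == 81L) {
      vals[i] <- grid[best]
      flags[i] <- paste0(fl, if (nzchar(fl)) "+" else "", "hit_search_bound")
      next
    }
    g <- function(t) .cond_score(design, k, z[i], t)
    root <- tryCatch(
      uniroot(g, c(grid[best - 1L], grid[best + 1L]), tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.na(root)) { # score same sign on both neighbours; keep grid max
      vals[i] <- grid[best]
      flags[i] <- paste0(fl, if (nzchar(fl)) "+" else "", "score_root_failed")
    } else {
      vals[i] <- root; flags[i] <- fl
    }
  }
  .with_flags(vals, flags)
}

#' Conditional weighted mean adjusted estimator (CWMAE)
#'
#' A shrinkage estimator for use on early termination. With prior guess
#' \eqn{\theta_0} (by default the effect \eqn{\delta} the trial was powered
#' for), the stage-1 estimate is the MLE minus its *conditional-on-stage-1*
#' bias evaluated at the convex combination
#' \deqn{\theta^* = w\,\hat\theta_{MLE} + (1 - w)\,\theta_0, \qquad
#'   w = \frac{(\hat\theta_{MLE} - \theta_0)^2}
#'            {(\hat\theta_{MLE} - \theta_0)^2 + I_1^{-1}}.}
#' No stage-2 form is implied by the proposal; the MLE is used on
#' continuation (flag `"stage_convention"`), so that marginal performance
#' can be reported.
#'
#' @inheritParams theta_mle
#' @param theta0 Prior guess at \eqn{\theta}. Default (`NULL`): the powered
#'   effect `design$delta`; for designs built for a two-sided alternative
#'   (element `two_sided = TRUE`) the guess is sign-matched to the
#'   estimate, \eqn{\theta_0 = sign(\hat\theta_{MLE})\,\delta}, since the
#'   trial was powered at \eqn{\pm\delta} and shrinking towards the
#'   wrong-signed effect would be meaningless (this also preserves the
#'   estimator's antisymmetry under symmetric boundaries).
#' @return Estimate(s); `flags` attribute carries `"stage_convention"` for
#'   stage-2 outcomes.
#' @export
theta_cwmae <- function(design, k, z, theta0 = NULL) {
  mle <- theta_mle(design, k, z)
  if (k == 2L)
    return(.with_flags(mle, rep("stage_convention", length(z))))
  if (is.null(theta0))
    theta0 <- if (isTRUE(design$two_sided))
      sign(mle) * design$delta else design$delta
  w <- (mle - theta0)^2 / ((mle - theta0)^2 + 1 / design$I1)
  tstar <- w * mle + (1 - w) * theta0
  bias <- vapply(tstar, function(t) mle_conditional_bias(design, t, 1L),
                 numeric(1))
  mle - bias
}

#' Conditional median unbiased estimator (CMUE)
#'
#' The value of \eqn{\theta} for which the observed statistic is the median
#' of the conditional distribution of \eqn{Z} given the stopping stage:
#' \eqn{\int_{-\infty}^{z} f_{cond}(k, x | \hat\theta) dx = 0.5}. For
#' \eqn{k = 1} the integral runs over the disconnected stopping region
#' truncated at \eqn{z}. No ordering of the sample space is involved.
#' A stage-1 statistic exactly on a boundary is treated as belonging to
#' the stopping region on its own side of the continuation interval.
#'
#' @inheritParams theta_mle
#' @return Estimate(s); a `flags` attribute marks any search failure.
#' @export
theta_cmue <- function(design, k, z) {
  mle <- theta_mle(design, k, z)
  step <- 10 / sqrt(design$I1)
  vals <- numeric(length(z)); flags <- character(length(z))
  for (i in seq_along(z)) {
    g <- function(t) {
      p <- .conditional_cdf(design, k, z[i], t)
      if (is.na(p)) NaN else 0.5 - p   # increasing in theta
    }
    r <- .safe_root(g, mle[i], step)
    vals[i] <- r$value; flags[i] <- r$flag
  }
  .with_flags(vals, flags)
}

#' Conditional UMVUE (CUMVUE)
#'
#' The Rao-Blackwellisation of the unbiased estimator formed from the
#' stage-2 increment, \eqn{(S_2 - S_1)/(I_2 - I_1)}, given \eqn{(K = 2,
#' Z = z)}; conditionally unbiased given continuation to stage 2 for every
#' \eqn{\theta}. Closed form
#' \eqn{\{z\sqrt{I_2} - I_1 \hat\theta_{UMVUE}(2, z)\}/(I_2 - I_1)}.
#' No stage-1 form is implied; the MLE is used on a stage-1 stop (flag
#' `"stage_convention"`).
#'
#' @inheritParams theta_mle
#' @return Estimate(s); `flags` attribute carries `"stage_convention"` for
#'   stage-1 outcomes.
#' @export
theta_cumvue <- function(design, k, z) {
  if (k == 1L) {
    mle <- theta_mle(design, k, z)
    return(.with_flags(mle, rep("stage_convention", length(z))))
  }
  umv <- theta_umvue(design, k, z)
  (z * sqrt(design$I2) - design$I1 * umv) / (design$I2 - design$I1)
}

# dispatch table used by estimate_all(), the performance engine and the CLI
.estimator_fn <- function(name) {
  switch(name,
    MLE    = function(design, k, z, theta0) theta_mle(design, k, z),
    MAE1   = function(design, k, z, theta0) theta_mae1(design, k, z),
    MAE2   = function(design, k, z, theta0) theta_mae2(design, k, z),
    MUE    = function(design, k, z, theta0) theta_mue(design, k, z),
    UMVUE  = function(design, k, z, theta0) theta_umvue(design, k, z),
    CMLE   = function(design, k, z, theta0) theta_cmle(design, k, z),
    CWMAE  = function(design, k, z, theta0)
               theta_cwmae(design, k, z, theta0 = theta0),
    CMUE   = function(design, k, z, theta0) theta_cmue(design, k, z),
    CUMVUE = function(design, k, z, theta0) theta_cumvue(design, k, z),
    stop("unknown estimator '", name, "'; valid names: ",
         paste(.ESTIMATORS, collapse = ", "), call. = FALSE))
}

#' Compute all nine point estimates for one trial outcome
#'
#' @inheritParams theta_mle
#' @param theta0 Prior guess used by the CWMAE; `NULL` (default) uses
#'   the powered effect (sign-matched for two-sided designs).
#' @return A data frame with one row per estimator: columns `estimator`,
#'   `estimate` and `flag` (empty when the estimate required no search
#'   safeguards and no stage convention).
#' @examples
#' d <- builtin_design("example2")
#' estimate_all(d, k = 2, z = 2.1)
#' @export
estimate_all <- function(design, k, z, theta0 = NULL) {
  trial_outcome(design, k, z)
  stopifnot(length(z) == 1L)
  est <- numeric(length(.ESTIMATORS)); flg <- character(length(.ESTIMATORS))
  for (i in seq_along(.ESTIMATORS)) {
    v <- .estimator_fn(.ESTIMATORS[i])(design, k, z, theta0)
    est[i] <- as.numeric(v)
    f <- attr(v, "flags")
    flg[i] <- if (is.null(f)) "" else f[1]
  }
  data.frame(estimator = .ESTIMATORS, estimate = est, flag = flg,
             stringsAsFactors = FALSE)
}
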