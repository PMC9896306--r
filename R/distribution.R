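# Sampling distribution of the sufficient statistic (K, Z).
#
# Under the canonical joint distribution, (Z1, Z2) is bivariate normal with
# E(Zk) = theta * sqrt(Ik) and Cov(Z1, Z2) = sqrt(I1/I2). The trial stops at
# stage 1 iff z1 is outside the open continuation region (l, u). The stage-2
# density then has a closed form: the marginal normal density of Z2 times a
# normal-CDF difference in z (free of theta), which removes the need for a
# convolution integral.

# Phi(b) - Phi(a) for a <= b; adequate in double precision away from the
# joint far tail (log version below covers that regime)
.pnorm_diff <- function(a, b) {
  ifelse(a > 0, pnorm(-a) - pnorm(-b), pnorm(b) - pnorm(a))
}

# log(Phi(b) - Phi(a)), a <= b, stable in either tail
.log_pnorm_diff <- function(a, b) {
  if (a > 0) return(.log_pnorm_diff(-b, -a))
  la <- pnorm(a, log.p = TRUE)
  lb <- pnorm(b, log.p = TRUE)
  if (lb == -Inf) return(-Inf)
  lb + log1p(-exp(la - lb))
}

# log s(k | theta), scalar theta
.log_stop_probability <- function(design, k, theta) {
  m1 <- theta * sqrt(design$I1)
  a <- pnorm(design$l - m1, log.p = TRUE)                      # lower stop
  b <- pnorm(design$u - m1, lower.tail = FALSE, log.p = TRUE)  # upper stop
  if (k == 1L) {
    hi <- pmax(a, b); lo <- pmin(a, b)
    if (hi == -Inf) return(-Inf)
    hi + log1p(exp(lo - hi))
  } else {
    .log_pnorm_diff(design$l - m1, design$u - m1)
  }
}

.check_theta_z <- function(z, theta) {
  if (!is.numeric(z) || any(is.nan(z)) || any(is.infinite(z)) || any(is.na(z)))
    stop("'z' must be finite", call. = FALSE)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite", call. = FALSE)
}

#' Density of the terminal statistic of a two-stage trial
#'
#' The sampling density \eqn{f(k, z | \theta)} of the sufficient statistic
#' \eqn{(K, Z)}. At stage 1 this is the \eqn{N(\theta\sqrt{I_1}, 1)} density
#' restricted to the stopping region \eqn{z \notin (l, u)} (and 0 inside the
#' continuation region). At stage 2 it is the closed form
#' \deqn{f(2, z | \theta) = \phi(z - \theta\sqrt{I_2})\,
#'   [\Phi\{u; z\sqrt{I_1/I_2}, v\} - \Phi\{l; z\sqrt{I_1/I_2}, v\}],}
#' with \eqn{v = (I_2 - I_1)/I_2}, equivalent to the convolution of the
#' stage-1 continuation density with the independent stage-2 increment.
#'
#' @param design A [two_stage_design()].
#' @param k Terminal stage, 1 or 2.
#' @param z Terminal standardised statistic (finite; vectorised).
#' @param theta Effect value \eqn{\theta} (finite; vectorised, recycled
#'   against `z`).
#' @return Non-negative density values.
#' @examples
#' d <- builtin_design("example2")
#' gs_density(d, 2, 1.3, theta = 0.1)
#' @export
gs_density <- function(design, k, z, theta) {
  .check_design(design)
  k <- .check_stage(k)
  .check_theta_z(z, theta)
  if (k == 1L) {
    dens <- dnorm(z - theta * sqrt(design$I1))
    dens[z > design$l & z < design$u] <- 0
    dens
  } else {
    r <- sqrt(design$I1 / design$I2)
    sv <- sqrt((design$I2 - design$I1) / design$I2)
    dnorm(z - theta * sqrt(design$I2)) *
      .pnorm_diff((design$l - z * r) / sv, (design$u - z * r) / sv)
  }
}

#' Probability of stopping at each stage
#'
#' \eqn{s(1|\theta) = \Phi(l - \theta\sqrt{I_1}) + 1 - \Phi(u - \theta\sqrt{I_1})}
#' and \eqn{s(2|\theta) = 1 - s(1|\theta)}.
#'
#' @inheritParams gs_density
#' @return Probabilities in \[0, 1\] (vectorised over `theta`).
#' @export
stop_probability <- function(design, k, theta) {
  .check_design(design)
  k <- .check_stage(k)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite", call. = FALSE)
  m1 <- theta * sqrt(design$I1)
  # each stage computed directly: 1 - s(2|theta) would cancel to zero when
  # the stage-1 stopping probability is far below machine precision
  if (k == 1L)
    pnorm(design$l - m1) + pnorm(design$u - m1, lower.tail = FALSE)
  else
    .pnorm_diff(design$l - m1, design$u - m1)
}

#' Conditional density of Z given the stopping stage
#'
#' \eqn{f_{cond}(k, z | \theta) = f(k, z|\theta) / s(k|\theta)}, which
#' integrates to 1 over \eqn{z} for each stage with positive stopping
#' probability.
#'
#' @inheritParams gs_density
#' @return Density values; an error is raised when \eqn{s(k|\theta) = 0}
#'   (degenerate conditioning, e.g. stage 1 of a design with no stopping
#'   boundaries).
#' @export
conditional_density <- function(design, k, z, theta) {
  s <- stop_probability(design, k, theta)
  if (any(s < .Machine$double.xmin))
    stop("degenerate conditioning: s(k | theta) is zero", call. = FALSE)
  gs_density(design, k, z, theta) / s
}

# P(l < Z1 < u, Z2 <= z | theta) (lower = TRUE) or with Z2 >= z
# (lower = FALSE); vectorised over z, scalar theta. Computed by integrating
# the conditional normal CDF of Z2 | Z1 over the continuation region.
.stage2_joint <- function(design, z, theta, lower = TRUE,
                          panel_max = 2, n = 64L) {
  l <- design$l; u <- design$u
  m1 <- theta * sqrt(design$I1)
  m2 <- theta * sqrt(design$I2)
  r <- sqrt(design$I1 / design$I2)
  s12 <- sqrt(1 - design$I1 / design$I2)
  if (l == -Inf && u == Inf)
    return(pnorm(z - m2, lower.tail = lower))
  # centre the integration window on the mode of the *truncated* stage-1
  # law (the point of (l, u) nearest the mean): when the continuation
  # region sits in the far tail of N(m1, 1) its conditional mass piles up
  # against the nearer boundary, and an absolute window around m1 would
  # miss it entirely
  mode1 <- min(max(m1, l), u)
  a <- max(l, mode1 - 8.5); b <- min(u, mode1 + 8.5)
  if (!(a < b)) return(rep(0, length(z)))
  rule <- .panel_rule(a, b, panel_max, n)
  base <- rule$w * dnorm(rule$x - m1)
  cond_mean <- m2 + r * (rule$x - m1)
  vapply(z, function(zi)
    sum(base * pnorm((zi - cond_mean) / s12, lower.tail = lower)),
    numeric(1))
}

#' Stage-wise ordering exceedance probability
#'
#' The probability \eqn{P\{(K, Z) \succ (k, z) | \theta\}} that the trial
#' outcome falls above \eqn{(k, z)} in the stage-wise ordering, in which
#' stage-1 efficacy stops rank highest and stage-1 futility stops lowest:
#' \deqn{P = 1 - \Phi(z - \theta\sqrt{I_1}) \quad (k = 1),}
#' \deqn{P = 1 - \Phi(u - \theta\sqrt{I_1}) + \int_z^\infty f(2, x|\theta)dx
#'   \quad (k = 2).}
#' For fixed \eqn{(k, z)} it is strictly increasing in \eqn{\theta}, which
#' makes the median unbiased estimator's defining equation have a unique
#' root.
#'
#' @inheritParams gs_density
#' @return Probabilities (vectorised over `z`; `theta` scalar).
#' @export
exceedance_stagewise <- function(design, k, z, theta) {
  .check_design(design)
  k <- .check_stage(k)
  .check_theta_z(z, theta)
  stopifnot(length(theta) == 1L)
  if (k == 1L) {
    pnorm(z - theta * sqrt(design$I1), lower.tail = FALSE)
  } else {
    pnorm(design$u - theta * sqrt(design$I1), lower.tail = FALSE) +
      .stage2_joint(design, z, theta, lower = FALSE)
  }
}

# conditional CDF P(Z <= z | K = k, theta); scalar z and theta.
# For k = 1 the support is the disconnected set (-Inf, l] U [u, Inf).
.conditional_cdf <- function(design, k, z, theta) {
  m1 <- theta * sqrt(design$I1)
  s <- stop_probability(design, k, theta)
  if (s < 1e-300) return(NA_real_)
  if (k == 1L) {
    low <- pnorm(min(z, design$l) - m1)
    up <- if (z >= design$u)
      .pnorm_diff(design$u - m1, z - m1) else 0
    (low + up) / s
  } else {
    .stage2_joint(design, z, theta, lower = TRUE) / s
  }
}
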