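# Constructors for the five worked example designs: error-spending with a
# Pocock-like spending function (two-arm survival), a fixed minimax fixture
# (single-arm normal), one-sided power-family boundaries (crossover),
# Simon-type Bernoulli mapping, and two-sided O'Brien-Fleming boundaries
# (matched pairs). Each solves its boundary/information parameters from the
# requested error rates and is checked against the canonical joint
# distribution by quadrature.

# one-sided rejection probability P(Z1 >= u) + P(l < Z1 < u, Z2 >= c2)
.reject_one_sided <- function(l, u, c2, I1, I2, theta) {
  d <- two_stage_design(l = l, u = u, I1 = I1, I2 = I2, delta = 1)
  exceedance_stagewise(d, 2L, c2, theta)
}

# two-sided rejection probability with symmetric bounds b1 (stage 1) and
# b2 (stage 2): P(|Z1| >= b1) + P(-b1 < Z1 < b1, |Z2| >= b2). By symmetry
# of the canonical law this is the sum of the one-sided crossing
# probabilities at theta and -theta.
.reject_two_sided <- function(b1, b2, I1, I2, theta) {
  .reject_one_sided(-b1, b1, b2, I1, I2, theta) +
    .reject_one_sided(-b1, b1, b2, I1, I2, -theta)
}

#' Two-stage survival design via Pocock-like error spending
#'
#' Builds the two-arm log-rank survival design: interim half-way through
#' the maximal number of events (\eqn{I_2 = 2 I_1}, \eqn{I_k \approx
#' d_k/4}), fixed futility boundary `l` (default \eqn{-0.674 \approx
#' \Phi^{-1}(0.25)}, a 25\% chance of stopping for futility under the
#' null), and, when `efficacy = TRUE`, the stage-1 efficacy boundary from
#' the Lan-DeMets Pocock-like spending function \eqn{f(t) = \alpha
#' \ln\{1 + (e - 1)t\}} at information time \eqn{t = 1/2}. The final
#' critical value `c2` is then solved so the total one-sided type-I error
#' is `alpha` (futility treated as binding), and \eqn{I_1} so the power at
#' \eqn{\theta = \delta} is `1 - beta`.
#'
#' The effect scale is \eqn{\theta = -\log\lambda} for hazard ratio
#' \eqn{\lambda} (positive \eqn{\theta} = benefit, via \eqn{Z_k =
#' -S_k/\sqrt{I_k}} for log-rank score \eqn{S_k}).
#'
#' @param alpha One-sided type-I error rate.
#' @param beta Type-II error rate at `delta`.
#' @param delta Powered effect; default \eqn{-\log(0.8)}, i.e. a hazard
#'   ratio of 0.8.
#' @param l Fixed stage-1 futility boundary.
#' @param efficacy Include stage-1 efficacy stopping?
#' @param label Optional label.
#' @return A [two_stage_design()] with extra elements `c2` (final critical
#'   value), `d1` (stage-1 event count, \eqn{4 I_1} rounded), `alpha`,
#'   `beta`.
#' @export
design_survival_spending <- function(alpha = 0.025, beta = 0.1,
                                     delta = -log(0.8), l = -0.674,
                                     efficacy = TRUE, label = NULL) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, is.finite(delta),
            delta != 0, is.finite(l))
  u <- if (efficacy)
    qnorm(1 - alpha * log(1 + (exp(1) - 1) / 2)) else Inf
  # at theta = 0 the crossing probabilities depend on (l, u, c2) and the
  # information ratio only, so solve c2 at unit information
  c2 <- uniroot(function(c) .reject_one_sided(l, u, c, 1, 2, 0) - alpha,
                c(0, 6), tol = 1e-12)$root
  I1 <- uniroot(function(I1)
    .reject_one_sided(l, u, c2, I1, 2 * I1, delta) - (1 - beta),
    c(1e-6, 1e6), tol = 1e-9)$root
  d <- two_stage_design(l = l, u = u, I1 = I1, I2 = 2 * I1, delta = delta,
                        label = label)
  d$c2 <- c2; d$d1 <- round(4 * I1); d$alpha <- alpha; d$beta <- beta
  d
}

#' Two-stage design with one-sided power-family boundaries
#'
#' Solves the one-sided two-boundary power family (boundaries proportional
#' to \eqn{(k/K)^{\Delta - 1/2}}) for a two-stage design with equal
#' per-stage information increments: efficacy bounds \eqn{u_k = C_u
#' (k/2)^{\Delta - 1/2}}, futility bounds \eqn{l_k = \delta\sqrt{I_k} -
#' C_l (k/2)^{\Delta - 1/2}}, meeting at stage 2 (\eqn{l_2 = u_2}).
#' The constants \eqn{(C_u, C_l)} — and through the closure constraint
#' \eqn{C_u + C_l = \delta\sqrt{I_2}} the per-stage sample size — are
#' solved so the type-I error is `alpha` and the power at \eqn{\delta} is
#' `1 - beta`.
#'
#' @inheritParams design_survival_spending
#' @param shape Power-family shape parameter \eqn{\Delta}.
#' @param variance Variance \eqn{\sigma^2} converting information to
#'   per-stage sample size via \eqn{I_k = k n / \sigma^2}.
#' @return A [two_stage_design()] with extra elements `n` (sample size per
#'   sequence per stage), `c2` (\eqn{= C_u}, the shared stage-2 boundary),
#'   `Cu`, `Cl`, `shape`, `alpha`, `beta`.
#' @export
design_power_family <- function(alpha, beta, delta, shape, variance,
                                label = NULL) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, is.finite(delta),
            delta != 0, is.finite(shape), variance > 0)
  fac <- (1 / 2)^(shape - 1 / 2)
  resid <- function(x) {
    Cu <- x[1]; Cl <- x[2]
    I2 <- ((Cu + Cl) / delta)^2; I1 <- I2 / 2
    u1 <- Cu * fac; l1 <- delta * sqrt(I1) - Cl * fac
    if (!(l1 < u1) || I2 <= 0) return(c(NA_real_, NA_real_))
    c(.reject_one_sided(l1, u1, Cu, I1, I2, 0) - alpha,
      .reject_one_sided(l1, u1, Cu, I1, I2, delta) - (1 - beta))
  }
  x <- c(qnorm(1 - alpha), qnorm(1 - beta))
  ok <- FALSE
  for (iter in 1:50) {
    r0 <- resid(x)
    if (any(!is.finite(r0)))
      stop("power-family solve left the feasible region", call. = FALSE)
    if (max(abs(r0)) < 1e-11) { ok <- TRUE; break }
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + 1e-6
      J[, j] <- (resid(xp) - r0) / 1e-6
    }
    step <- tryCatch(solve(J, r0), error = function(e) NULL)
    if (is.null(step))
      stop("power-family solve failed (singular Jacobian)", call. = FALSE)
    x <- x - step
  }
  if (!ok)
    stop("power-family solve did not converge for (alpha, beta, shape)",
         call. = FALSE)
  Cu <- x[1]; Cl <- x[2]
  I2 <- ((Cu + Cl) / delta)^2; I1 <- I2 / 2
  d <- two_stage_design(l = delta * sqrt(I1) - Cl * fac, u = Cu * fac,
                        I1 = I1, I2 = I2, delta = delta, label = label)
  d$n <- I1 * variance; d$c2 <- Cu; d$Cu <- Cu; d$Cl <- Cl
  d$shape <- shape; d$alpha <- alpha; d$beta <- beta
  d
}

#' Two-sided two-stage O'Brien-Fleming design
#'
#' Equally spaced information levels with stage-\eqn{k} boundary
#' \eqn{C_B\sqrt{2/k}}: the constant \eqn{C_B} is solved so the total
#' two-sided type-I error under \eqn{\theta = 0} is `alpha`, then the
#' maximal information is scaled so the power at \eqn{|\theta| = \delta}
#' is `1 - beta`. The stage-1 continuation region is
#' \eqn{(-C_B\sqrt{2}, C_B\sqrt{2})}.
#'
#' @inheritParams design_power_family
#' @param variance Variance \eqn{\tilde\sigma^2} converting information to
#'   pairs per stage via \eqn{n_k = k I_1 \tilde\sigma^2}.
#' @return A [two_stage_design()] with extra elements `n` (pairs per
#'   stage), `c2` (\eqn{= C_B}, the stage-2 boundary), `CB`, `two_sided =
#'   TRUE`, `alpha`, `beta`.
#' @export
design_obrien_fleming <- function(alpha, beta, delta, variance,
                                  label = NULL) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, is.finite(delta),
            delta != 0, variance > 0)
  CB <- uniroot(function(C) .reject_two_sided(C * sqrt(2), C, 1, 2, 0) -
                  alpha, c(0.5, 6), tol = 1e-12)$root
  I2 <- uniroot(function(I2)
    .reject_two_sided(CB * sqrt(2), CB, I2 / 2, I2, abs(delta)) -
      (1 - beta), c(1e-6, 1e8), tol = 1e-9)$root
  d <- two_stage_design(l = -CB * sqrt(2), u = CB * sqrt(2),
                        I1 = I2 / 2, I2 = I2, delta = abs(delta),
                        label = label)
  d$n <- I2 / 2 * variance; d$c2 <- CB; d$CB <- CB; d$two_sided <- TRUE
  d$alpha <- alpha; d$beta <- beta
  d
}

#' Canonical mapping of a Simon-type Bernoulli design
#'
#' Maps a two-stage single-arm binomial design with futility rule "stop
#' after \eqn{n_1} participants if at most \eqn{r_1} respond" to the
#' canonical framework via \eqn{Z_k = (\bar X_k - \pi_0)\sqrt{I_k}},
#' \eqn{I_k = n_k / \{\pi_0(1 - \pi_0)\}}: the futility boundary becomes
#' \eqn{l = (r_1/n_1 - \pi_0)\sqrt{I_1}} with no efficacy stopping.
#'
#' @param pi0 Null (clinically uninteresting) response rate, in (0, 1).
#' @param n1,n2 Cumulative sample sizes at the two analyses (`n1 < n2`).
#' @param r1 Futility response count: stop if at most `r1` of `n1` respond.
#' @param delta Powered effect on the response-rate difference scale
#'   \eqn{\theta = \pi - \pi_0}.
#' @param label Optional label.
#' @return A [two_stage_design()] with `u = Inf`.
#' @export
design_bernoulli <- function(pi0, n1, n2, r1, delta, label = NULL) {
  stopifnot(pi0 > 0, pi0 < 1, n1 > 0, n2 > n1, r1 >= 0, r1 <= n1,
            is.finite(delta))
  I1 <- n1 / (pi0 * (1 - pi0))
  I2 <- n2 / (pi0 * (1 - pi0))
  two_stage_design(l = (r1 / n1 - pi0) * sqrt(I1), u = Inf,
                   I1 = I1, I2 = I2, delta = delta, label = label)
}

#' Names of the built-in example designs
#' @return Character vector of names accepted by [builtin_design()].
#' @export
builtin_design_names <- function() {
  c("example1_eff_fut", "example1_fut_only", "example2", "example3",
    "example4", "example5")
}

#' Built-in worked example designs
#'
#' Reconstructs one of five reference designs spanning common trial types:
#' \describe{
#'   \item{`example1_eff_fut`}{Two-arm survival (log-rank), error-spending
#'     efficacy bound 2.157 and futility bound -0.674, one-sided
#'     \eqn{\alpha = 0.025}, power 0.9 at hazard ratio 0.8.}
#'   \item{`example1_fut_only`}{As above with futility stopping only
#'     (`u = Inf`).}
#'   \item{`example2`}{Single-arm normal-outcome phase II minimax fixture:
#'     \eqn{n_1 = 92}, \eqn{n_2 = 139}, \eqn{l = 0}, \eqn{u = \infty},
#'     \eqn{\sigma^2 = 1600}, \eqn{\delta = 10}.}
#'   \item{`example3`}{2x2 crossover, one-sided power-family boundaries with
#'     shape -0.25, \eqn{\alpha = 0.05}, \eqn{\beta = 0.2}, \eqn{\delta =
#'     10}, \eqn{\sigma_e^2 = 326}.}
#'   \item{`example4`}{Simon-type Bernoulli design (\eqn{\pi_0 = 0.1},
#'     stop if \eqn{\le 1} of 12 respond, \eqn{n_2 = 35}, powered at
#'     \eqn{\delta = 0.2}).}
#'   \item{`example5`}{Matched pairs, two-sided O'Brien-Fleming boundaries,
#'     \eqn{\alpha = 0.05}, \eqn{\beta = 0.1}, \eqn{\delta = 1},
#'     \eqn{\tilde\sigma^2 = 6}.}
#' }
#'
#' @param name One of [builtin_design_names()].
#' @return A [two_stage_design()].
#' @examples
#' builtin_design("example5")
#' @export
builtin_design <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  switch(name,
    example1_eff_fut = design_survival_spending(
      efficacy = TRUE, label = "two-arm survival, efficacy + futility"),
    example1_fut_only = design_survival_spending(
      efficacy = FALSE, label = "two-arm survival, futility only"),
    example2 = two_stage_design(
      l = 0, u = Inf, I1 = 92 / 1600, I2 = 139 / 1600, delta = 10,
      label = "single-arm normal, minimax futility-only"),
    example3 = design_power_family(
      alpha = 0.05, beta = 0.2, delta = 10, shape = -0.25, variance = 326,
      label = "crossover, power-family boundaries"),
    example4 = design_bernoulli(
      pi0 = 0.1, n1 = 12, n2 = 35, r1 = 1, delta = 0.2,
      label = "single-arm Bernoulli, Simon-type futility"),
    example5 = design_obrien_fleming(
      alpha = 0.05, beta = 0.1, delta = 1, variance = 6,
      label = "matched pairs, O'Brien-Fleming two-sided"),
    stop("unknown design name '", name, "'; valid names: ",
         paste(builtin_design_names(), collapse = ", "), call. = FALSE))
}
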