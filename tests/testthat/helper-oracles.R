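# Independent brute-force oracles built on stats::integrate (adaptive
# quadrature), deliberately separate from the package's Gauss-Legendre
# engine and closed forms.

# stage-2 density as the explicit convolution over the continuation region
oracle_density2 <- function(design, z, theta) {
  with(design, sqrt(I2) * stats::integrate(function(z1)
    dnorm(z1, theta * sqrt(I1), 1) *
      dnorm(z * sqrt(I2) - z1 * sqrt(I1), theta * (I2 - I1),
            sqrt(I2 - I1)),
    max(l, theta * sqrt(I1) - 10), min(u, theta * sqrt(I1) + 10),
    rel.tol = 1e-13, abs.tol = 1e-13)$value)
}

# integral of f(k, z | theta) over an interval, by adaptive quadrature
oracle_mass <- function(design, k, lo, hi, theta) {
  if (!(lo < hi)) return(0)
  stats::integrate(function(z) gs_density(design, k, z, theta), lo, hi,
                   rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# total probability mass over both stages
oracle_total_mass <- function(design, theta) {
  m1 <- theta * sqrt(design$I1); m2 <- theta * sqrt(design$I2)
  s1 <- oracle_mass(design, 1, m1 - 10, min(design$l, m1 + 10), theta) +
    oracle_mass(design, 1, max(design$u, m1 - 10), m1 + 10, theta)
  s1 + oracle_mass(design, 2, m2 - 10, m2 + 10, theta)
}

# P{(K, Z) > (2, z) | theta} assembled from tail quadrature of the density
oracle_exceedance2 <- function(design, z, theta) {
  m1 <- theta * sqrt(design$I1); m2 <- theta * sqrt(design$I2)
  pnorm(design$u - m1, lower.tail = FALSE) +
    oracle_mass(design, 2, z, max(z, m2 + 10), theta)
}

# conditional CDF P(Z <= z | K = k, theta) by adaptive quadrature
oracle_conditional_cdf <- function(design, k, z, theta) {
  m <- theta * sqrt(if (k == 1) design$I1 else design$I2)
  s <- stop_probability(design, k, theta)
  if (k == 1) {
    lo <- oracle_mass(design, 1, m - 10, min(z, design$l), theta)
    hi <- if (z >= design$u)
      oracle_mass(design, 1, design$u, max(z, design$u), theta) else 0
    (lo + hi) / s
  } else {
    oracle_mass(design, 2, m - 10, z, theta) / s
  }
}

# E(Z1 / sqrt(I1) | K = 2, Z2 = z): Rao-Blackwell conditional expectation
# over the theta-free conditional law of Z1 given (continuation, Z2 = z)
oracle_umvue2 <- function(design, z) {
  m <- z * sqrt(design$I1 / design$I2)
  sv <- sqrt((design$I2 - design$I1) / design$I2)
  lo <- max(design$l, m - 10 * sv); hi <- min(design$u, m + 10 * sv)
  num <- stats::integrate(function(z1) z1 * dnorm(z1, m, sv), lo, hi,
                          rel.tol = 1e-13)$value
  den <- stats::integrate(function(z1) dnorm(z1, m, sv), lo, hi,
                          rel.tol = 1e-13)$value
  num / den / sqrt(design$I1)
}

# E{(S2 - S1)/(I2 - I1) | K = 2, Z2 = z}: the stage-2-increment estimator
# averaged over the same conditional law
oracle_cumvue2 <- function(design, z) {
  (z * sqrt(design$I2) -
     sqrt(design$I1) * oracle_umvue2(design, z) * sqrt(design$I1)) /
    (design$I2 - design$I1)
}

# closed-form conditional bias of the MLE given a stage-1 stop
oracle_mle_bias_k1 <- function(design, theta) {
  m <- theta * sqrt(design$I1)
  s1 <- stop_probability(design, 1, theta)
  (dnorm(design$u - m) - dnorm(design$l - m)) / (sqrt(design$I1) * s1)
}

# designs reused across tests (built once per test run)
example_designs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(stats::setNames(nm = builtin_design_names()),
                       builtin_design)
    cache
  }
})

# a small asymmetric design exercising finite boundaries on both sides
toy_design <- function() {
  two_stage_design(l = -0.5, u = 1.8, I1 = 4, I2 = 9, delta = 0.6,
                   label = "toy")
}
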