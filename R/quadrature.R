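# Composite Gauss-Legendre quadrature over the support of the terminal
# statistic. Integrands are smooth normal-mixture tails, so moderate-order
# panels reach (well below) the 1e-10 absolute target; the stage-1 support
# is split at the boundaries to respect its disconnected form.

.gl_cache <- new.env(parent = emptyenv())

.gl_rule <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

# nodes/weights for one interval [a, b], subdivided into panels of width
# at most 'panel_max'
.panel_rule <- function(a, b, panel_max = 2, n = 64L) {
  if (!(b > a)) return(list(x = numeric(0), w = numeric(0)))
  base <- .gl_rule(n)
  m <- max(1L, ceiling((b - a) / panel_max))
  edges <- seq(a, b, length.out = m + 1L)
  half <- diff(edges) / 2
  mid <- (edges[-1] + edges[-(m + 1L)]) / 2
  list(x = as.vector(outer(base$x, half) + rep(mid, each = n)),
       w = as.vector(outer(base$w, half)))
}

# quadrature rule over the support of Z at stage k, covering terminal means
# theta * sqrt(Ik) for theta in [theta_lo, theta_hi] plus 'halfwidth'
# standard deviations either side; segments with negligible mass for every
# theta in the range are dropped
.z_rule <- function(design, k, theta_lo, theta_hi, halfwidth = 8.5,
                    panel_max = 2, n = 64L) {
  sqI <- sqrt(if (k == 1L) design$I1 else design$I2)
  zlo <- min(theta_lo, theta_hi) * sqI - halfwidth
  zhi <- max(theta_lo, theta_hi) * sqI + halfwidth
  if (k == 2L) {
    rule <- .panel_rule(zlo, zhi, panel_max, n)
  } else {
    lower <- if (design$l > zlo)
      .panel_rule(zlo, min(design$l, zhi), panel_max, n)
    else list(x = numeric(0), w = numeric(0))
    upper <- if (design$u < zhi)
      .panel_rule(max(design$u, zlo), zhi, panel_max, n)
    else list(x = numeric(0), w = numeric(0))
    rule <- list(x = c(lower$x, upper$x), w = c(lower$w, upper$w))
  }
  rule
}
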