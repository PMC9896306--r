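# Exact conditional and marginal bias and RMSE of any estimator, by
# quadrature of the estimator against the conditional terminal-statistic
# density. Note the naming caveat: following common usage in this setting,
# "RMSE" denotes the residual mean square error Var + Bias^2 (i.e. the mean
# squared error), not its square root.

# floor below which conditioning on stage k is treated as degenerate
.S_FLOOR <- 1e-12

# quadrature of fn(z)^x against fcond(k, z | theta); scalar theta.
# Optionally reuses a precomputed rule and function values.
.cond_moment <- function(design, k, theta, fn, rule = NULL, fx = NULL,
                         quad = list()) {
  qa <- .quad_args(quad)
  if (is.null(rule))
    rule <- .z_rule(design, k, theta, theta, halfwidth = qa$halfwidth,
                    panel_max = qa$panel_max, n = qa$nodes)
  s <- stop_probability(design, k, theta)
  if (!is.finite(s) || s < .S_FLOOR)
    return(list(mean = NA_real_, second = NA_real_, s = s, degenerate = TRUE))
  if (is.null(fx)) fx <- fn(rule$x)
  wf <- rule$w * gs_density(design, k, rule$x, theta) / s
  list(mean = sum(wf * fx), second = sum(wf * fx^2), s = s,
       degenerate = FALSE)
}

.quad_args <- function(quad) {
  modifyList(list(nodes = 64L, panel_max = 2, halfwidth = 8.5), quad)
}

.resolve_estimator <- function(estimator) {
  if (is.function(estimator))
    return(list(fn = function(design, k, z, theta0) estimator(design, k, z),
                name = "custom"))
  stopifnot(is.character(estimator), length(estimator) == 1L)
  list(fn = .estimator_fn(estimator), name = estimator)
}

#' Conditional moments of an estimator
#'
#' First and second moments of \eqn{\hat\theta(k, Z)} conditional on the
#' trial stopping at stage `k`, \eqn{E(\hat\theta^x | \theta, k) = \int
#' \hat\theta(k, z)^x f_{cond}(k, z | \theta) dz} for \eqn{x = 1, 2},
#' computed by composite Gauss-Legendre quadrature over the stage-`k`
#' support (for `k = 1` the disconnected region outside \eqn{(l, u)}).
#'
#' @inheritParams gs_density
#' @param estimator An estimator name (see [estimator_names()]) or a
#'   function `f(design, k, z)` returning estimates for a vector `z`.
#' @param theta0 Prior guess forwarded to the CWMAE (`NULL`: powered
#'   effect, sign-matched for two-sided designs).
#' @param quad Optional list overriding quadrature settings: `nodes` (per
#'   panel, default 64), `panel_max` (maximum panel width, default 2) and
#'   `halfwidth` (integration range in standard deviations around the
#'   terminal mean, default 8.5).
#' @return A list with `mean`, `second` (second moment), `s` (the stopping
#'   probability) and `degenerate` (`TRUE` when \eqn{s(k|\theta)} is below
#'   the floor `1e-12`, in which case the moments are `NA` rather than 0).
#' @export
conditional_moments <- function(design, estimator, theta, k,
                                theta0 = NULL, quad = list()) {
  .check_design(design)
  k <- .check_stage(k)
  stopifnot(length(theta) == 1L, is.finite(theta))
  est <- .resolve_estimator(estimator)
  .cond_moment(design, k, theta, function(z) est$fn(design, k, z, theta0),
               quad = quad)
}

#' Evaluation grid of effect values
#'
#' By default 81 equally spaced points on \eqn{[-2\delta, 2\delta]}, the
#' range over which estimator performance is surveyed: it comfortably
#' covers all plausible effects when \eqn{\delta} is the powered effect.
#'
#' @inheritParams gs_density
#' @param n Number of grid points.
#' @param limits Length-2 numeric range; defaults to
#'   `c(-2, 2) * abs(design$delta)`.
#' @return A strictly increasing numeric vector.
#' @export
theta_grid <- function(design, n = 81L, limits = NULL) {
  .check_design(design)
  if (is.null(limits)) limits <- c(-2, 2) * abs(design$delta)
  stopifnot(length(limits) == 2L, all(is.finite(limits)),
            limits[1] < limits[2], n >= 1L)
  if (n == 1L) return(mean(limits))
  seq(limits[1], limits[2], length.out = n)
}

#' Bias and RMSE of estimators over a grid of effect values
#'
#' For each estimator and each \eqn{\theta} in `grid`, computes the
#' conditional (on stopping stage) and marginal bias and residual mean
#' square error, \eqn{RMSE = Var + Bias^2}; the marginal values are the
#' stopping-probability-weighted sums of the conditional ones. Estimator
#' values are precomputed once on shared quadrature nodes per stage (the
#' estimators do not depend on \eqn{\theta}) and reused across the grid.
#'
#' @inheritParams conditional_moments
#' @param estimators Character vector of estimator names (default: all
#'   nine), or a named list of functions `f(design, k, z)`.
#' @param grid Numeric vector of \eqn{\theta} values; see [theta_grid()].
#' @return A data frame with columns `estimator`, `theta`, `s1`, `s2`,
#'   `bias_k1`, `bias_k2`, `bias_marginal`, `rmse_k1`, `rmse_k2`,
#'   `rmse_marginal`, `flags`. Conditional entries are `NA` where the
#'   conditioning is degenerate (stopping probability below `1e-12`); such
#'   stages get zero weight in the marginal sums. `flags` collects search
#'   diagnostics from any quadrature node ("truncated" performance rows).
#' @examples
#' d <- builtin_design("example2")
#' evaluate_grid(d, estimators = c("MLE", "UMVUE"),
#'               grid = theta_grid(d, n = 5))
#' @export
evaluate_grid <- function(design, estimators = estimator_names(),
                          grid = theta_grid(design), theta0 = NULL,
                          quad = list()) {
  .check_design(design)
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(is.finite(grid)),
            !is.unsorted(grid, strictly = TRUE) || length(grid) == 1L)
  if (is.character(estimators)) {
    ests <- lapply(estimators, .resolve_estimator)
    names(ests) <- estimators
  } else {
    stopifnot(is.list(estimators), !is.null(names(estimators)))
    ests <- lapply(names(estimators), function(nm)
      list(fn = function(design, k, z, theta0) estimators[[nm]](design, k, z),
           name = nm))
    names(ests) <- names(estimators)
  }
  qa <- .quad_args(quad)
  rules <- lapply(1:2, function(k)
    .z_rule(design, k, min(grid), max(grid), halfwidth = qa$halfwidth,
            panel_max = qa$panel_max, n = qa$nodes))
  # precompute estimator values (and node-level flags) per stage
  vals <- lapply(ests, function(e) lapply(1:2, function(k) {
    x <- rules[[k]]$x
    if (length(x) == 0L) return(list(fx = numeric(0), flag = ""))
    v <- e$fn(design, k, x, theta0)
    fl <- attr(v, "flags")
    list(fx = as.numeric(v),
         flag = if (!is.null(fl) && any(nzchar(fl))) "truncated" else "")
  }))
  out <- vector("list", length(ests) * length(grid))
  row <- 0L
  for (ei in seq_along(ests)) {
    for (th in grid) {
      row <- row + 1L
      cm <- lapply(1:2, function(k)
        .cond_moment(design, k, th, NULL, rule = rules[[k]],
                     fx = vals[[ei]][[k]]$fx, quad = quad))
      s1 <- stop_probability(design, 1L, th); s2 <- 1 - s1
      bias <- vapply(1:2, function(k)
        if (cm[[k]]$degenerate) NA_real_ else cm[[k]]$mean - th, numeric(1))
      rmse <- vapply(1:2, function(k)
        if (cm[[k]]$degenerate) NA_real_ else
          (cm[[k]]$second - cm[[k]]$mean^2) + bias[k]^2, numeric(1))
      wsum <- function(v) sum(ifelse(c(s1, s2) < .S_FLOOR, 0, c(s1, s2) * v),
                              na.rm = TRUE)
      flags <- unique(c(vals[[ei]][[1]]$flag, vals[[ei]][[2]]$flag))
      flags <- paste(flags[nzchar(flags)], collapse = "+")
      out[[row]] <- data.frame(
        estimator = names(ests)[ei], theta = th, s1 = s1, s2 = s2,
        bias_k1 = bias[1], bias_k2 = bias[2], bias_marginal = wsum(bias),
        rmse_k1 = rmse[1], rmse_k2 = rmse[2], rmse_marginal = wsum(rmse),
        flags = flags, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Performance of one estimator at one effect value
#'
#' @inheritParams evaluate_grid
#' @inheritParams conditional_moments
#' @return A one-row data frame in the format of [evaluate_grid()].
#' @export
performance_row <- function(design, estimator, theta, theta0 = NULL,
                            quad = list()) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  est <- if (is.function(estimator)) {
    e <- list(estimator); names(e) <- "custom"; e
  } else estimator
  evaluate_grid(design, estimators = est, grid = theta,
                theta0 = theta0, quad = quad)
}

#' Plot bias/RMSE profiles from an evaluation table
#'
#' Draws the six-panel summary (conditional-on-stage-1, conditional-on-
#' stage-2 and marginal bias in the top row; the corresponding RMSE below)
#' from a table produced by [evaluate_grid()].
#'
#' @param tab Data frame from [evaluate_grid()].
#' @param ylim_bias,ylim_rmse Optional y-axis limits (shared across the
#'   respective row), useful to clamp the axes when an estimator with
#'   unbounded bias (e.g. the CMLE without an efficacy boundary) would
#'   otherwise dominate the scale.
#' @return Invisibly, `tab`.
#' @export
plot_performance <- function(tab, ylim_bias = NULL, ylim_rmse = NULL) {
  stopifnot(is.data.frame(tab),
            all(c("estimator", "theta", "bias_marginal") %in% names(tab)))
  ests <- unique(tab$estimator)
  cols <- grDevices::hcl.colors(max(3L, length(ests)), "Dark 3")
  panels <- list(c("bias_k1", "Bias | k = 1"), c("bias_k2", "Bias | k = 2"),
                 c("bias_marginal", "Marginal bias"),
                 c("rmse_k1", "RMSE | k = 1"), c("rmse_k2", "RMSE | k = 2"),
                 c("rmse_marginal", "Marginal RMSE"))
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in panels) {
    ylim <- if (grepl("bias", p[1])) ylim_bias else ylim_rmse
    if (is.null(ylim)) ylim <- range(tab[[p[1]]], finite = TRUE)
    graphics::plot(NA, xlim = range(tab$theta), ylim = ylim,
                   xlab = expression(theta), ylab = p[2], main = p[2])
    for (i in seq_along(ests)) {
      sub <- tab[tab$estimator == ests[i], ]
      graphics::lines(sub$theta, sub[[p[1]]], col = cols[i], lwd = 1.5)
    }
    if (p[1] == "bias_k1")
      graphics::legend("topright", legend = ests, col = cols[seq_along(ests)],
                       lwd = 1.5, cex = 0.6, bty = "n")
  }
  invisible(tab)
}
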