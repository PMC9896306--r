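#' Specify a two-stage group sequential design
#'
#' A two-stage design is fully described, for estimation purposes, by the
#' stage-1 continuation region \eqn{(l, u)}, the information levels
#' \eqn{I_1 < I_2} accrued at the two analyses, and the effect size
#' \eqn{\delta} at which the trial was powered. The trial continues to
#' stage 2 if and only if the stage-1 standardised statistic \eqn{z_1}
#' falls in the open interval \eqn{(l, u)}; it stops at stage 1 when
#' \eqn{z_1 \le l} (futility) or \eqn{z_1 \ge u} (efficacy).
#'
#' Infinite boundaries are first-class values: `l = -Inf` disables futility
#' stopping and `u = Inf` disables efficacy stopping. All distributional
#' formulas take the corresponding analytic limits.
#'
#' @param l Stage-1 futility boundary on the standardised-statistic scale;
#'   may be `-Inf`.
#' @param u Stage-1 efficacy boundary; may be `Inf`. Must satisfy `l < u`.
#' @param I1,I2 Information levels for \eqn{\theta} at the two analyses,
#'   with `I2 > I1 > 0`.
#' @param delta Powered effect \eqn{\delta} on the \eqn{\theta} scale
#'   (finite; sign unrestricted, two-sided designs store \eqn{\delta > 0}).
#' @param label Optional free-text label.
#'
#' @return An object of class `two_stage_design`: a list with elements
#'   `l`, `u`, `I1`, `I2`, `delta`, `label`. Design constructors may attach
#'   further elements (e.g. the final critical value `c2`, a per-stage
#'   sample size `n`).
#'
#' @examples
#' d <- two_stage_design(l = 0, u = Inf, I1 = 92 / 1600, I2 = 139 / 1600,
#'                       delta = 10)
#' d
#' @seealso [builtin_design()] for the worked example designs.
#' @export
two_stage_design <- function(l, u, I1, I2, delta, label = NULL) {
  stopifnot(is.numeric(l), is.numeric(u), is.numeric(I1), is.numeric(I2),
            is.numeric(delta), length(l) == 1L, length(u) == 1L,
            length(I1) == 1L, length(I2) == 1L, length(delta) == 1L)
  if (!is.finite(I1) || !is.finite(I2) || !(I1 > 0) || !(I2 > I1))
    stop("information levels must satisfy I2 > I1 > 0", call. = FALSE)
  if (!is.finite(delta))
    stop("'delta' must be finite", call. = FALSE)
  if (is.nan(l) || is.nan(u) || l == Inf || u == -Inf)
    stop("'l' may be finite or -Inf; 'u' may be finite or Inf", call. = FALSE)
  if (!(l < u))
    stop("boundaries must satisfy l < u", call. = FALSE)
  structure(
    list(l = l, u = u, I1 = I1, I2 = I2, delta = delta,
         label = if (is.null(label)) NA_character_ else as.character(label)),
    class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, digits = 4, ...) {
  cat("Two-stage group sequential design")
  if (!is.na(x$label)) cat(": ", x$label, sep = "")
  cat("\n")
  cat(sprintf("  continuation region: (%s, %s)\n",
              format(x$l, digits = digits), format(x$u, digits = digits)))
  cat(sprintf("  information levels:  I1 = %s, I2 = %s\n",
              format(x$I1, digits = digits), format(x$I2, digits = digits)))
  cat(sprintf("  powered effect:      delta = %s\n",
              format(x$delta, digits = digits)))
  extras <- setdiff(names(x), c("l", "u", "I1", "I2", "delta", "label"))
  for (nm in extras)
    cat(sprintf("  %-6s = %s\n", nm, format(x[[nm]], digits = digits)))
  invisible(x)
}

#' @export
format.two_stage_design <- function(x, ...) {
  sprintf("two_stage_design(l = %g, u = %g, I1 = %g, I2 = %g, delta = %g)",
          x$l, x$u, x$I1, x$I2, x$delta)
}

#' Test for a two-stage design object
#' @param x Object to test.
#' @return `TRUE` for objects created by [two_stage_design()].
#' @export
is.two_stage_design <- function(x) inherits(x, "two_stage_design")

.check_design <- function(design) {
  if (!is.two_stage_design(design))
    stop("'design' must be a two_stage_design object", call. = FALSE)
  design
}

.check_stage <- function(k) {
  if (length(k) != 1L || !(k %in% c(1, 2)))
    stop("'k' must be 1 or 2", call. = FALSE)
  as.integer(k)
}

#' Validate a trial outcome against a design
#'
#' Checks that the terminal stage/statistic pair \eqn{(k, z)} is a possible
#' outcome under `design`: `k` is 1 or 2, `z` is finite, and a stage-1
#' statistic does not lie inside the continuation region.
#'
#' @inheritParams gs_density
#' @return Invisibly, a list with elements `k` and `z`.
#' @export
trial_outcome <- function(design, k, z) {
  .check_design(design)
  k <- .check_stage(k)
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite", call. = FALSE)
  if (k == 1L && any(z > design$l & z < design$u))
    stop("a stage-1 outcome cannot lie inside the continuation region (l, u)",
         call. = FALSE)
  invisible(list(k = k, z = z))
}

#' Serialise a design to JSON
#'
#' Designs are written with keys `l`, `u`, `I1`, `I2`, `delta`, `label`;
#' infinite boundaries are encoded as the strings `"inf"` / `"-inf"` so the
#' files are valid JSON.
#'
#' @param design A [two_stage_design()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
design_to_json <- function(design, path = NULL) {
  .check_design(design)
  enc <- function(x) {
    if (is.infinite(x)) if (x > 0) "inf" else "-inf" else x
  }
  obj <- list(l = enc(design$l), u = enc(design$u),
              I1 = design$I1, I2 = design$I2, delta = design$delta,
              label = if (is.na(design$label)) NULL else design$label)
  # I(17) significant digits: doubles survive the round trip exactly
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                          null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a design from JSON
#'
#' @param x A file path or a JSON string produced by [design_to_json()].
#' @return A [two_stage_design()].
#' @export
design_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  dec <- function(v) {
    if (is.character(v)) {
      switch(tolower(v), "inf" = Inf, "-inf" = -Inf,
             stop("unrecognised boundary string: ", v, call. = FALSE))
    } else as.numeric(v)
  }
  two_stage_design(l = dec(obj$l), u = dec(obj$u),
                   I1 = as.numeric(obj$I1), I2 = as.numeric(obj$I2),
                   delta = as.numeric(obj$delta), label = obj$label)
}
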