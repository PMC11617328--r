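#' Meta-analytic residuals and precisions
#'
#' Residual of each effect from the posterior-mean fitted value (fixed plus
#' all random effects). Unlike the weighted effect sizes themselves, these
#' residuals are approximately independent, which is what makes the
#' modified Egger regression valid. Precision is the inverse standard
#' error, `1/sqrt(var_z) = sqrt(n - 3)`.
#'
#' @param fit A `meta_fit`.
#' @return Data frame with `effect_id`, `residual`, `se`, `precision`.
#' @export
meta_residuals <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  data.frame(
    effect_id = fit$effect_id,
    residual = fit$z - colMeans(fit$fitted),
    se = sqrt(fit$var_z),
    precision = 1 / sqrt(fit$var_z)
  )
}

#' Modified Egger regression on meta-analytic residuals
#'
#' The Egger regression in its standard-normal-deviate form, applied to
#' meta-analytic residuals: ordinary least squares of
#' `residual_i / SE_i = a + b * precision_i`. Dividing by the standard
#' error makes the regression errors homoskedastic (each standardized
#' residual has unit variance), so the intercept's t-test holds its
#' nominal level; a nonzero intercept indicates funnel asymmetry. Returns
#' the intercept with its standard error, `t = a/SE`, and the two-sided
#' p-value on `k - 2` df. When all precisions are equal the slope is
#' unidentifiable and an intercept-only fit (df `k - 1`) is returned with
#' a warning.
#'
#' @param residuals Numeric vector of meta-analytic residuals.
#' @param precisions Numeric vector of matching precisions (`1/SE`).
#' @return List of class `"egger_test"`: `intercept`, `se`, `t`, `p`, `df`,
#'   `slope`.
#' @export
egger_test <- function(residuals, precisions) {
  k <- length(residuals)
  if (k < 3) stop("egger_test: need at least 3 effects")
  if (length(precisions) != k) stop("egger_test: length mismatch")
  snd <- residuals * precisions
  if (stats::sd(precisions) == 0) {
    warning("egger_test: all precisions equal; returning intercept-only fit")
    m <- stats::lm(snd ~ 1)
    co <- summary(m)$coefficients
    out <- list(intercept = co[1, 1], se = co[1, 2], t = co[1, 3],
                p = co[1, 4], df = k - 1, slope = NA_real_)
  } else {
    m <- stats::lm(snd ~ precisions)
    co <- summary(m)$coefficients
    out <- list(intercept = co[1, 1], se = co[1, 2], t = co[1, 3],
                p = co[1, 4], df = k - 2, slope = co[2, 1])
  }
  class(out) <- "egger_test"
  out
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger regression: intercept %.3f +/- %.3f (t = %.2f, df = %d, p = %.4g)\n",
              x$intercept, x$se, x$t, x$df, x$p))
  invisible(x)
}

# One pass of the L0 estimator about a given center: signed ranks of the
# deviations, rank sum of the chosen tail, L0 = (4*Tn - n(n+1)) / (2n - 1).
.l0_estimate <- function(dev) {
  n <- length(dev)
  rk <- rank(abs(dev), ties.method = "average")
  Tn <- sum(rk[dev > 0])
  (4 * Tn - n * (n + 1)) / (2 * n - 1)
}

#' Trim-and-fill correction on meta-analytic residuals
#'
#' Duval-and-Tweedie L0 estimator of the number of suppressed effects,
#' iterated to convergence: estimate the fixed-effect weighted center from
#' the non-trimmed residuals, rank absolute deviations of all residuals
#' about that center, derive `k0` from the right-tail rank sum, trim the
#' `k0` largest values, and repeat until `k0` stabilizes. The `k0` imputed
#' points are the mirror images of the trimmed values about the final
#' center, carrying the same standard errors; the adjusted mean is the
#' fixed-effect weighted mean over observed plus imputed points.
#'
#' @param residuals Numeric vector of meta-analytic residuals (length >= 3).
#' @param ses Matching standard errors, all `> 0`.
#' @param side `"right"` trims large positive residuals (the default,
#'   matching selective reporting of positive findings); `"left"` mirrors;
#'   `"auto"` picks the side with the larger rank sum.
#' @param max_iter Iteration cap (warning on non-convergence).
#' @return List of class `"trim_and_fill"`: `k0`, `adjusted_mean`,
#'   `unadjusted_mean`, `imputed` (data frame of residual, se), `side`,
#'   `converged`.
#' @export
trim_and_fill <- function(residuals, ses, side = c("right", "left", "auto"),
                          max_iter = 20L) {
  side <- match.arg(side)
  k <- length(residuals)
  if (k < 3) stop("trim_and_fill: need at least 3 effects")
  if (length(ses) != k || any(ses <= 0)) stop("trim_and_fill: invalid standard errors")
  w <- 1 / ses^2
  unadj <- sum(w * residuals) / sum(w)
  if (side == "auto") {
    dev <- residuals - unadj
    rk <- rank(abs(dev), ties.method = "average")
    side <- if (sum(rk[dev > 0]) >= sum(rk[dev < 0])) "right" else "left"
  }
  x <- if (side == "left") -residuals else residuals
  ord <- order(x)
  x <- x[ord]; wx <- w[ord]; sex <- ses[ord]

  k0 <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    keep <- seq_len(k - k0)
    center <- sum(wx[keep] * x[keep]) / sum(wx[keep])
    l0 <- .l0_estimate(x - center)
    k0_new <- max(0L, min(k - 1L, as.integer(round(l0))))
    if (k0_new == k0) { converged <- TRUE; break }
    k0 <- k0_new
  }
  if (!converged) warning("trim_and_fill: k0 did not stabilize in ", max_iter,
                          " iterations; using last iterate")
  if (k0 == k - 1L && !converged) warning("trim_and_fill: k0 capped at k - 1")

  if (k0 > 0) {
    trimmed_idx <- seq(k - k0 + 1, k)
    keep <- seq_len(k - k0)
    center <- sum(wx[keep] * x[keep]) / sum(wx[keep])
    imp_x <- 2 * center - x[trimmed_idx]
    imp_se <- sex[trimmed_idx]
    all_x <- c(x, imp_x)
    all_w <- c(wx, 1 / imp_se^2)
    adj <- sum(all_w * all_x) / sum(all_w)
    if (side == "left") { adj <- -adj; imp_x <- -imp_x }
    imputed <- data.frame(residual = imp_x, se = imp_se)
  } else {
    adj <- unadj
    imputed <- data.frame(residual = numeric(0), se = numeric(0))
  }
  structure(list(k0 = k0, adjusted_mean = adj, unadjusted_mean = unadj,
                 imputed = imputed, side = side, converged = converged),
            class = "trim_and_fill")
}

#' @export
print.trim_and_fill <- function(x, ...) {
  cat(sprintf("trim-and-fill (%s side): k0 = %d imputed; mean %.4f -> %.4f\n",
              x$side, x$k0, x$unadjusted_mean, x$adjusted_mean))
  invisible(x)
}

#' Funnel-plot table with pseudo-confidence bounds
#'
#' Per-effect residuals and precisions plus, for each effect's standard
#' error, the symmetric 90/95/99% pseudo-confidence bounds about zero.
#' Intended for plotting contour-enhanced funnels with any graphics layer.
#'
#' @param residuals Data frame from [meta_residuals()].
#' @return Data frame with the input columns and `lo90/hi90/lo95/hi95/lo99/hi99`.
#' @export
funnel_table <- function(residuals) {
  z90 <- stats::qnorm(0.95); z95 <- stats::qnorm(0.975); z99 <- stats::qnorm(0.995)
  cbind(residuals,
        lo90 = -z90 * residuals$se, hi90 = z90 * residuals$se,
        lo95 = -z95 * residuals$se, hi95 = z95 * residuals$se,
        lo99 = -z99 * residuals$se, hi99 = z99 * residuals$se)
}

#' Publication-bias report
#'
#' Bundles the modified Egger regression and the trim-and-fill correction
#' computed on the residuals of a fitted model.
#'
#' @param fit A `meta_fit`.
#' @param side Trim-and-fill side (see [trim_and_fill()]).
#' @return List of class `"bias_report"` with elements `egger`,
#'   `trimfill`, and the `residuals` table.
#' @export
bias_report <- function(fit, side = "right") {
  res <- meta_residuals(fit)
  structure(list(
    egger = egger_test(res$residual, res$precision),
    trimfill = trim_and_fill(res$residual, res$se, side = side),
    residuals = res
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  print(x$egger); print(x$trimfill)
  invisible(x)
}
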