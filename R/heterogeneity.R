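#' Typical sampling variance of a set of effects
#'
#' The weighted summary of per-effect sampling variances used in
#' multilevel I2-type decompositions:
#' \deqn{\bar{s}^2 = \frac{\sum w_i (k-1)}{(\sum w_i)^2 - \sum w_i^2}, \quad w_i = 1/v_i.}
#' Equals the common variance when all `v` are equal.
#'
#' @param v Numeric vector of per-effect sampling variances, all `> 0`,
#'   length `>= 2`.
#' @return The typical sampling variance (positive scalar).
#' @export
typical_sampling_variance <- function(v) {
  if (length(v) < 2) stop("typical_sampling_variance: need at least 2 effects")
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("typical_sampling_variance: variances must be finite and > 0")
  }
  w <- 1 / v
  k <- length(v)
  sum(w) * (k - 1) / (sum(w)^2 - sum(w^2))
}

#' Decompose total heterogeneity into study, species and phylogenetic shares
#'
#' For each posterior draw the total is
#' `T = sigma2_phylo + sigma2_species + sigma2_study + s2_typical`, and the
#' shares are `I2_study = sigma2_study/T`, `I2_species = sigma2_species/T`
#' and the phylogenetic signal `H2 = sigma2_phylo/T`. Shares are computed
#' per draw and then summarized by their posterior mean (a ratio of
#' posterior means would be biased); the typical sampling variance is
#' computed once from the fixed `v_i`. I2 values are reported as
#' percentages, H2 as a proportion.
#'
#' @param fit A `meta_fit`.
#' @return List of class `"heterogeneity_report"`: `I2_study_pct`,
#'   `I2_species_pct` (percent), `H2_phylo` (proportion),
#'   `sampling_share_pct`, `typical_sampling_variance`, a `summary` data
#'   frame with 95% intervals, and `structural_zero` flags for components
#'   absent from the random structure.
#' @export
heterogeneity_decompose <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  s2_typ <- typical_sampling_variance(fit$var_z)
  s2 <- fit$sigma2
  total <- s2[, "phylo"] + s2[, "species"] + s2[, "study"] + s2_typ
  shares <- cbind(
    H2_phylo = s2[, "phylo"] / total,
    I2_species = s2[, "species"] / total,
    I2_study = s2[, "study"] / total,
    sampling = s2_typ / total
  )
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- do.call(rbind, lapply(colnames(shares), function(nm) {
    x <- shares[, nm]
    q <- qs(x)
    data.frame(component = nm, mean = mean(x), median = stats::median(x),
               lower = q[1], upper = q[2])
  }))
  rownames(summ) <- NULL
  structure(list(
    I2_study_pct = 100 * mean(shares[, "I2_study"]),
    I2_species_pct = 100 * mean(shares[, "I2_species"]),
    H2_phylo = mean(shares[, "H2_phylo"]),
    sampling_share_pct = 100 * mean(shares[, "sampling"]),
    typical_sampling_variance = s2_typ,
    summary = summ,
    structural_zero = setdiff(c("phylo", "species", "study"), fit$random)
  ), class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("heterogeneity: I2(study) = %.1f%%, I2(species) = %.1f%%, H2(phylo) = %.3f\n",
              x$I2_study_pct, x$I2_species_pct, x$H2_phylo))
  cat(sprintf("typical sampling variance = %.4f (%.1f%% of total)\n",
              x$typical_sampling_variance, x$sampling_share_pct))
  if (length(x$structural_zero)) {
    cat("structurally zero components:", paste(x$structural_zero, collapse = ", "), "\n")
  }
  invisible(x)
}
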