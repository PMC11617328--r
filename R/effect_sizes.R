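#' Correlation estimate from a t statistic
#'
#' Converts a two-group (or single-df) t statistic to a point-biserial
#' correlation via `r = t / sqrt(t^2 + df)`. The sign of the result equals
#' the sign of `t`.
#'
#' @param t Numeric t statistic(s).
#' @param df Residual degrees of freedom, `df >= 1`.
#' @return Correlation estimate(s) in (-1, 1).
#' @export
#' @examples
#' r_from_t(2, 4)   # 0.7071
r_from_t <- function(t, df) {
  if (any(!is.finite(t))) stop("r_from_t: non-finite t")
  if (any(!is.finite(df)) || any(df < 1)) stop("r_from_t: df must be >= 1")
  t / sqrt(t^2 + df)
}

#' Correlation estimate from a single-numerator-df F statistic
#'
#' `r = sqrt(F / (F + df2))`, signed by `direction`. Only valid when the
#' numerator degrees of freedom equal 1 (so that `F = t^2`); the caller is
#' responsible for that check.
#'
#' @param F_stat Nonnegative F statistic(s).
#' @param df2 Denominator degrees of freedom, `df2 >= 1`.
#' @param direction Sign (+1 or -1) of the underlying association.
#' @return Signed correlation estimate(s) with magnitude in [0, 1).
#' @export
r_from_F <- function(F_stat, df2, direction = 1) {
  if (any(!is.finite(F_stat)) || any(F_stat < 0)) {
    stop("r_from_F: F must be finite and nonnegative")
  }
  if (any(!is.finite(df2)) || any(df2 < 1)) stop("r_from_F: df2 must be >= 1")
  if (any(!direction %in% c(-1, 1))) stop("r_from_F: direction must be +1 or -1")
  direction * sqrt(F_stat / (F_stat + df2))
}

#' Correlation estimate from a 1-df chi-squared statistic
#'
#' The phi coefficient `r = sqrt(chisq / n)`, signed by `direction`.
#'
#' @param chisq Nonnegative chi-squared statistic(s) on 1 df.
#' @param n Total sample size, `n >= 1`.
#' @param direction Sign (+1 or -1) of the underlying association.
#' @return Signed correlation estimate(s) with magnitude in [0, 1].
#' @export
r_from_chisq <- function(chisq, n, direction = 1) {
  if (any(!is.finite(chisq)) || any(chisq < 0)) {
    stop("r_from_chisq: chisq must be finite and nonnegative")
  }
  if (any(!is.finite(n)) || any(n < 1)) stop("r_from_chisq: n must be >= 1")
  if (any(chisq > n)) {
    stop("r_from_chisq: chisq > n implies |r| > 1; inspect the source study")
  }
  if (any(!direction %in% c(-1, 1))) stop("r_from_chisq: direction must be +1 or -1")
  direction * sqrt(chisq / n)
}

#' Biserial correlation from two group means
#'
#' Two-step estimator for a continuous variable dichotomized into groups:
#' the point-biserial correlation
#' `r_pb = (m1 - m0)/sd * sqrt(n1 * n0 / (n * (n - 1)))`
#' is rescaled to the biserial scale by
#' `r_b = r_pb * sqrt(p * q) / dnorm(qnorm(p))` with `p = n1/n`. The
#' biserial estimate may legitimately exceed 1 in magnitude in finite
#' samples; see [clamp_correlation()].
#'
#' @param m1,m0 Group means (group 1 is the "high" or focal group).
#' @param sd Standard deviation of the outcome over all `n1 + n0` subjects
#'   (`> 0`); with this choice the first step is exactly the sample
#'   point-biserial correlation between the outcome and group membership.
#' @param n1,n0 Group sizes, each `>= 2`.
#' @return Biserial correlation estimate (possibly outside [-1, 1]).
#' @export
biserial_from_groups <- function(m1, m0, sd, n1, n0) {
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("biserial_from_groups: sd must be > 0")
  if (any(n1 < 2) || any(n0 < 2)) stop("biserial_from_groups: group sizes must be >= 2")
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  n <- n1 + n0
  r_pb <- (m1 - m0) / sd * sqrt(n1 * n0 / (n * (n - 1)))
  p <- n1 / n
  r_pb * sqrt(p * (1 - p)) / stats::dnorm(stats::qnorm(p))
}

#' Clamp a correlation estimate into [-0.99, 0.99]
#'
#' Biserial estimates can fall outside the unit interval, where the Fisher
#' Z transform is undefined. Values with magnitude above 0.99 are mapped to
#' sign(r) * 0.99 so that |z| stays bounded by arctanh(0.99) = 2.6467.
#'
#' @param r Finite correlation estimate(s).
#' @return List with `r` (clamped values) and `clamped` (logical flags).
#' @export
clamp_correlation <- function(r) {
  if (any(!is.finite(r))) stop("clamp_correlation: non-finite input")
  clamped <- abs(r) > 0.99
  list(r = ifelse(clamped, sign(r) * 0.99, r), clamped = clamped)
}

#' Fisher Z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r)/(1 - r))`. Inputs must be clamped
#' first ([clamp_correlation()]): magnitudes of 1 or more are an error.
#'
#' @param r Correlation(s) with `|r| <= 0.99`.
#' @return Fisher Z value(s), `|z| <= atanh(0.99)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z: |r| must be < 1 (clamp first)")
  }
  atanh(r)
}

#' Inverse Fisher Z transform
#'
#' @param z Finite Fisher Z value(s).
#' @return Correlation(s) `tanh(z)`.
#' @export
inverse_fisher_z <- function(z) {
  if (any(!is.finite(z))) stop("inverse_fisher_z: non-finite input")
  tanh(z)
}

#' Sampling variance and weight of a Fisher Z effect
#'
#' The large-sample variance of Fisher Z is `1/(n - 3)`; the meta-analytic
#' weight is the inverse standard error `sqrt(n - 3)`.
#'
#' @param n_total Total sample size(s), `>= 4`.
#' @return List with `var_z` and `weight`.
#' @export
z_variance_weight <- function(n_total) {
  if (any(!is.finite(n_total)) || any(n_total < 4)) {
    stop("z_variance_weight: n_total must be >= 4 so that 1/(n-3) is defined")
  }
  list(var_z = 1 / (n_total - 3), weight = sqrt(n_total - 3))
}

#' Harmonize a table of reported effects to Fisher Z
#'
#' Dispatches on `stat_type` per row, converts the reported statistic to a
#' correlation estimate, clamps it into [-0.99, 0.99], applies the Fisher Z
#' transform, and attaches the sampling variance `1/(n_total - 3)` and
#' weight. Recognized `stat_type` values and the columns they require:
#'
#' * `pearson_r`: `stat_value` (the correlation), `n_total`
#' * `t_test`: `stat_value`, `df`, `n_total`
#' * `F_test`: `stat_value`, `df` (denominator df), `direction`, `n_total`
#' * `chisq`: `stat_value`, `direction`, `n_total`
#' * `group_means`: `m1`, `m0`, `sd_pooled`, `n1`, `n0`, `n_total`
#'
#' Sign-less statistics (F, chi-squared) require an explicit `direction`
#' column (+1/-1); a missing direction is an error, not a silent +1.
#'
#' @param records Data frame of effect records (one row per effect) with at
#'   least `effect_id`, `stat_type`, `n_total` and the per-type columns.
#' @return Data frame with columns `effect_id`, `r_est`, `z`, `var_z`,
#'   `weight`, `conversion`, `clamped`, one row per input row and in input
#'   order.
#' @export
harmonize <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("effect_id", "stat_type", "n_total")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("harmonize: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$effect_id)) stop("harmonize: duplicate effect_id")
  n <- nrow(records)
  out <- data.frame(
    effect_id = as.character(records$effect_id),
    r_est = NA_real_, z = NA_real_, var_z = NA_real_, weight = NA_real_,
    conversion = NA_character_, clamped = NA,
    stringsAsFactors = FALSE
  )
  col <- function(nm, i) {
    if (!nm %in% names(records)) {
      stop("harmonize: effect ", records$effect_id[i], " needs column '", nm, "'")
    }
    v <- records[[nm]][i]
    if (is.na(v)) stop("harmonize: effect ", records$effect_id[i], " has missing '", nm, "'")
    v
  }
  for (i in seq_len(n)) {
    id <- records$effect_id[i]
    ntot <- col("n_total", i)
    if (ntot < 4) stop("harmonize: effect ", id, ": n_total must be >= 4")
    res <- tryCatch({
      type <- as.character(records$stat_type[i])
      r_raw <- switch(type,
        pearson_r = col("stat_value", i),
        t_test = r_from_t(col("stat_value", i), col("df", i)),
        F_test = r_from_F(col("stat_value", i), col("df", i), col("direction", i)),
        chisq = r_from_chisq(col("stat_value", i), ntot, col("direction", i)),
        group_means = {
          n1 <- col("n1", i); n0 <- col("n0", i)
          if (n1 + n0 != ntot) stop("group sizes must sum to n_total")
          biserial_from_groups(col("m1", i), col("m0", i), col("sd_pooled", i), n1, n0)
        },
        stop("unknown stat_type '", type, "'")
      )
      cl <- clamp_correlation(r_raw)
      vw <- z_variance_weight(ntot)
      conv <- switch(type,
        pearson_r = "identity", t_test = "t_to_r", F_test = "F_to_r",
        chisq = "phi", group_means = "biserial"
      )
      list(r = cl$r, z = fisher_z(cl$r), var = vw$var_z, w = vw$weight,
           conv = conv, clamped = cl$clamped)
    }, error = function(e) {
      stop("harmonize: effect ", id, ": ", conditionMessage(e), call. = FALSE)
    })
    out$r_est[i] <- res$r
    out$z[i] <- res$z
    out$var_z[i] <- res$var
    out$weight[i] <- res$w
    out$conversion[i] <- res$conv
    out$clamped[i] <- res$clamped
  }
  out
}
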