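test_that("residuals vanish on noiseless data and reflect the fitted model", {
  # two effects equidistant from the mean with equal variance -> residuals +/- d
  eff <- data.frame(effect_id = c("a", "b"), study_id = c("s1", "s2"),
                    species = c("A", "B"), z = c(0.1, 0.5), var_z = c(0.1, 0.1))
  f <- fit_meta(meta_dataset(eff), random = character(0),
                config = quick_config(iterations = 21000, burnin = 1000, thin = 2))
  res <- meta_residuals(f)
  expect_equal(res$residual, c(-0.2, 0.2), tolerance = 0.03)
  expect_equal(res$precision, 1 / sqrt(eff$var_z))
  # weighted residuals average to ~0 for intercept models
  expect_lt(abs(sum(res$residual / eff$var_z) / sum(1 / eff$var_z)), 0.01)
})

test_that("residuals recover the generator's latent structure", {
  lit <- small_literature(seed = 31, n_effects = 80, n_studies = 30,
                          sigma2_study = 0.3, n_range = c(60, 120))
  ds <- as_meta_dataset(lit)
  f <- fit_meta(ds, config = quick_config(iterations = 8000, burnin = 3000,
                                          thin = 2, seed = 3))
  res <- meta_residuals(f)
  eff <- ds$effects
  truth_fit <- lit$truth$z_true[match(eff$effect_id, lit$effects$effect_id)]
  # posterior-mean fitted values track the generating fixed+random structure
  expect_gt(cor(colMeans(f$fitted), truth_fit), 0.8)
  expect_equal(res$residual, eff$z - colMeans(f$fitted))
})

test_that("Egger regression recovers exact lines and handles degenerate input", {
  prec <- c(1, 2, 3, 4, 5)
  # standardized residuals lying exactly on snd = 2 + 3 * precision
  resid <- (2 + 3 * prec) / prec
  et <- suppressWarnings(egger_test(resid, prec))
  expect_equal(et$intercept, 2, tolerance = 1e-10)
  expect_equal(et$slope, 3, tolerance = 1e-10)
  expect_lt(et$se, 1e-8)
  expect_equal(et$df, 3)
  expect_error(egger_test(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(e0 <- egger_test(c(0.1, -0.2, 0.3), c(2, 2, 2)), "equal")
  expect_equal(e0$df, 2)
  # p consistent with t and df
  set.seed(1)
  e1 <- egger_test(rnorm(20), runif(20, 1, 5))
  expect_equal(e1$p, 2 * pt(-abs(e1$t), e1$df), tolerance = 1e-12)
})

test_that("the 13-point constructed set yields exactly 3 imputed points", {
  x <- c(-0.52, -0.41, -0.33, -0.22, -0.14, 0.11, 0.23, 0.31, 0.43, 0.54,
         2.0, 2.2, 2.4)
  se <- c(rep(0.1, 10), rep(1, 3))
  tf <- trim_and_fill(x, se)
  expect_equal(tf$k0, 3L)
  expect_true(tf$converged)
  expect_equal(nrow(tf$imputed), 3)
  expect_lt(abs(tf$adjusted_mean), abs(tf$unadjusted_mean))
  # brute-force rank-sum estimator at the converged center agrees
  w <- 1 / se^2
  keep <- order(x)[1:10]
  center <- sum(w[keep] * x[keep]) / sum(w[keep])
  expect_equal(round(brute_l0(x, center)), 3)
})

test_that("trim-and-fill matches the independent metafor L0 oracle", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (rep in 1:5) {
    x <- c(rnorm(20, 0, 0.3), abs(rnorm(4, 1.2, 0.3)))
    se <- c(runif(20, 0.05, 0.2), runif(4, 0.5, 1))
    mine <- trim_and_fill(x, se)
    oracle <- suppressWarnings(metafor::trimfill(
      metafor::rma(yi = x, vi = se^2, method = "FE"),
      estimator = "L0", side = "left"))
    expect_equal(mine$k0, oracle$k0)
    if (mine$k0 > 0) {
      expect_equal(mine$adjusted_mean, unname(coef(oracle)), tolerance = 1e-10)
    }
  }
})

test_that("trim-and-fill is symmetric under mirroring and caps degenerate sets", {
  x <- c(-0.52, -0.41, -0.33, -0.22, -0.14, 0.11, 0.23, 0.31, 0.43, 0.54,
         2.0, 2.2, 2.4)
  se <- c(rep(0.1, 10), rep(1, 3))
  right <- trim_and_fill(x, se, side = "right")
  left <- trim_and_fill(-x, se, side = "left")
  expect_equal(left$k0, right$k0)
  expect_equal(left$adjusted_mean, -right$adjusted_mean)
  # auto picks the heavier side
  expect_equal(trim_and_fill(x, se, side = "auto")$side, "right")
  expect_equal(trim_and_fill(-x, se, side = "auto")$side, "left")
  # exactly symmetric set: no imputation, no adjustment
  sym <- c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)
  tf0 <- trim_and_fill(sym, rep(0.1, 6))
  expect_equal(tf0$k0, 0L)
  expect_equal(tf0$adjusted_mean, tf0$unadjusted_mean)
  # one-sided monotone set stays within the k-1 cap without crashing
  mono <- trim_and_fill(seq(0.1, 1, by = 0.1), rep(0.1, 10))
  expect_lte(mono$k0, 9L)
  expect_error(trim_and_fill(c(1, 2), c(1, 1)), "at least 3")
})

test_that("funnel table carries pseudo-confidence bounds per effect", {
  res <- data.frame(effect_id = "e", residual = 0.2, se = 0.1, precision = 10)
  ft <- funnel_table(res)
  expect_equal(ft$hi95, qnorm(0.975) * 0.1)
  expect_equal(ft$lo99, -qnorm(0.995) * 0.1)
})

test_that("unbiased literatures rarely trigger imputation", {
  k0s <- numeric(20)
  for (i in 1:20) {
    lit <- simulate_effects(simulation_params(
      n_species = 20, n_studies = 40, n_effects = 169, beta0 = 0.25,
      sigma2_phylo = 0, sigma2_species = 0, sigma2_study = 0, seed = 95000 + i))
    f <- fit_meta(meta_dataset(lit$effects), random = character(0),
                  config = chain_config(iterations = 1200, burnin = 200,
                                        thin = 2, seed = 96000 + i))
    res <- meta_residuals(f)
    k0s[i] <- trim_and_fill(res$residual, res$se)$k0
  }
  expect_lte(median(k0s), 1)
})

test_that("censoring raises the Egger intercept relative to uncensored twins", {
  diffs <- numeric(30)
  for (i in 1:30) {
    lit <- simulate_effects(simulation_params(
      n_species = 20, n_studies = 40, n_effects = 169, beta0 = 0,
      sigma2_phylo = 0, sigma2_species = 0, sigma2_study = 0, seed = 97000 + i))
    cen <- censor_literature(lit, 0.8, seed = 98000 + i)
    eg <- function(effects, s) {
      f <- fit_meta(meta_dataset(effects), random = character(0),
                    config = chain_config(iterations = 1200, burnin = 200,
                                          thin = 2, seed = s))
      r <- meta_residuals(f)
      egger_test(r$residual, r$precision)$intercept
    }
    diffs[i] <- eg(cen$effects, 99000 + i) - eg(lit$effects, 99500 + i)
  }
  # the censored twin shows the larger (more positive) asymmetry intercept
  expect_gt(mean(diffs > 0), 0.7)
  expect_gt(mean(diffs), 0)
})
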