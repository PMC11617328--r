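test_that("statistic-to-correlation conversions match their identities", {
  expect_equal(r_from_t(0, 10), 0)
  expect_equal(r_from_t(2, 4), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r_from_t(-2, 4), -r_from_t(2, 4))
  expect_error(r_from_t(1, 0), "df")

  expect_equal(r_from_F(0, 8), 0)
  expect_equal(r_from_F(4, 4), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r_from_F(1, 1), sqrt(0.5), tolerance = 1e-12)
  expect_equal(r_from_F(4, 4, direction = -1), -1 / sqrt(2), tolerance = 1e-12)
  expect_error(r_from_F(-1, 4), "nonnegative")

  expect_equal(r_from_chisq(0, 50), 0)
  expect_equal(r_from_chisq(12.5, 50), 0.5)
  expect_equal(r_from_chisq(50, 50), 1)
  expect_error(r_from_chisq(51, 50), "inspect")
})

test_that("F and t conversions agree in magnitude on a grid", {
  for (t in c(0.3, 1, 2.5, 7)) {
    for (df in c(2, 11, 40)) {
      expect_equal(r_from_F(t^2, df), abs(r_from_t(t, df)), tolerance = 1e-12)
    }
  }
})

test_that("phi coefficient matches the chi-squared of a 2x2 table with that phi", {
  # build a 2x2 table with n = 40 and phi = (a-b)/(a+b) = 0.5,
  # recover chisq = phi^2 * n
  n <- 40
  tab <- matrix(c(15, 5, 5, 15), 2)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  expect_equal(unname(r_from_chisq(unname(chi), n)), 0.5, tolerance = 1e-12)
})

test_that("biserial conversion follows the two-step formula and its symmetries", {
  expect_equal(biserial_from_groups(5, 5, 2, 10, 10), 0)
  # p = q = 0.5, dnorm(0) = 0.39894: hand evaluation of the two-step formula
  r <- biserial_from_groups(1, 0, 1, 10, 10)
  expect_equal(r, sqrt(100 / 380) * 0.5 / dnorm(0), tolerance = 1e-12)
  expect_equal(round(r, 3), 0.643)
  expect_equal(biserial_from_groups(0, 1, 1, 10, 10), -r)
  expect_error(biserial_from_groups(1, 0, 0, 10, 10), "sd")
})

test_that("biserial estimates the latent correlation of a dichotomized normal", {
  # large bivariate-normal sample with latent correlation 0.643, median split
  set.seed(42)
  n <- 2e5
  rho <- 0.643
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  g <- x > median(x)
  m1 <- mean(y[g]); m0 <- mean(y[!g])
  est <- biserial_from_groups(m1, m0, sd(y), sum(g), sum(!g))
  expect_equal(est, rho, tolerance = 0.02)
  # first step is exactly the sample point-biserial correlation
  sub <- 1:500
  r_pb <- cor(y[sub], as.numeric(g[sub]))
  p <- mean(g[sub])
  est_sub <- biserial_from_groups(mean(y[sub][g[sub]]), mean(y[sub][!g[sub]]),
                                  sd(y[sub]), sum(g[sub]), sum(!g[sub]))
  expect_equal(est_sub, r_pb * sqrt(p * (1 - p)) / dnorm(qnorm(p)),
               tolerance = 1e-10)
})

test_that("clamping keeps Fisher Z bounded and flags the affected effects", {
  cl <- clamp_correlation(1.33)
  expect_equal(cl$r, 0.99)
  expect_true(cl$clamped)
  expect_equal(clamp_correlation(0.5)$r, 0.5)
  expect_false(clamp_correlation(0.5)$clamped)
  expect_equal(clamp_correlation(-1.2)$r, -0.99)
  expect_error(clamp_correlation(Inf), "finite")
  expect_equal(fisher_z(0.99), 0.5 * log(1.99 / 0.01), tolerance = 1e-12)
  expect_error(fisher_z(1), "clamp")
})

test_that("Fisher Z round-trips and reproduces the dual-scale reporting", {
  rs <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(inverse_fisher_z(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_equal(round(fisher_z(0.243), 3), 0.248)
  expect_equal(round(inverse_fisher_z(0.248), 3), 0.243)
  expect_equal(round(inverse_fisher_z(0.477), 3), 0.444)
})

test_that("variance and weight follow 1/(n-3)", {
  expect_equal(z_variance_weight(4), list(var_z = 1, weight = 1))
  expect_equal(z_variance_weight(103), list(var_z = 0.01, weight = 10))
  expect_equal(z_variance_weight(12), list(var_z = 1 / 9, weight = 3))
  expect_error(z_variance_weight(3), "n_total")
})

test_that("harmonize dispatches on stat_type and records provenance", {
  rec <- data.frame(
    effect_id = c("e1", "e2", "e3", "e4", "e5"),
    stat_type = c("pearson_r", "t_test", "F_test", "chisq", "group_means"),
    stat_value = c(0.5, 2, 4, 12.5, NA),
    df = c(NA, 4, 4, NA, NA), n_total = c(20, 6, 6, 50, 20),
    n1 = c(NA, NA, NA, NA, 10), n0 = c(NA, NA, NA, NA, 10),
    m1 = c(NA, NA, NA, NA, 1), m0 = c(NA, NA, NA, NA, 0),
    sd_pooled = c(NA, NA, NA, NA, 1), direction = c(NA, NA, -1, 1, NA)
  )
  out <- harmonize(rec)
  expect_equal(out$z[1], atanh(0.5), tolerance = 1e-12)
  expect_equal(out$var_z[1], 1 / 17)
  expect_equal(out$r_est[2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(out$r_est[3], -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(out$r_est[4], 0.5)
  expect_equal(round(out$r_est[5], 3), 0.643)
  expect_equal(out$conversion,
               c("identity", "t_to_r", "F_to_r", "phi", "biserial"))
  expect_false(any(out$clamped))
})

test_that("harmonize clamps out-of-range biserial estimates and fails loudly otherwise", {
  # group difference large enough that the biserial estimate exceeds 1
  rec <- data.frame(
    effect_id = "big", stat_type = "group_means", n_total = 20,
    n1 = 10, n0 = 10, m1 = 3, m0 = 0, sd_pooled = 1
  )
  out <- harmonize(rec)
  expect_true(out$clamped)
  expect_equal(out$z, atanh(0.99))
  # sign-less statistic without a direction column errors with the id attached
  bad <- data.frame(effect_id = "noF", stat_type = "F_test",
                    stat_value = 4, df = 4, n_total = 6)
  expect_error(harmonize(bad), "noF")
  expect_error(harmonize(data.frame(effect_id = "tiny", stat_type = "pearson_r",
                                    stat_value = 0.1, n_total = 3)), "n_total")
})

test_that("harmonized z is monotone in the reported statistic at fixed n and df", {
  ts <- seq(-3, 3, by = 0.25)
  zs <- atanh(r_from_t(ts, 10))
  expect_true(all(diff(zs) > 0))
  chis <- seq(0, 40, by = 2)
  zch <- atanh(pmin(r_from_chisq(chis, 50), 0.99))
  expect_true(all(diff(zch) >= 0))
})
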