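test_that("with no random structure the posterior mean is the weighted mean", {
  lit <- small_literature(seed = 2, sigma2_phylo = 0, sigma2_species = 0,
                          sigma2_study = 0)
  ds <- as_meta_dataset(lit)
  f <- fit_meta(ds, random = character(0),
                config = quick_config(iterations = 6000, burnin = 1000, thin = 1))
  wm <- sum(ds$effects$z / ds$effects$var_z) / sum(1 / ds$effects$var_z)
  sd_cf <- sqrt(1 / sum(1 / ds$effects$var_z))
  expect_lt(abs(mean(f$beta[, 1]) - wm), 4 * sd_cf / sqrt(5000))
  expect_equal(sd(f$beta[, 1]), sd_cf, tolerance = 0.1)
})

test_that("a single effect yields a posterior centered at it with sd near its SE", {
  eff <- data.frame(effect_id = "only", study_id = "s1", species = "A",
                    z = 0.4, var_z = 0.04)
  ds <- meta_dataset(eff)
  f <- fit_meta(ds, random = character(0),
                config = quick_config(iterations = 11000, burnin = 1000, thin = 1))
  expect_equal(mean(f$beta[, 1]), 0.4, tolerance = 0.01)
  expect_equal(sd(f$beta[, 1]), 0.2, tolerance = 0.02)
})

test_that("chains mix and are reproducible under a fixed seed", {
  ds <- as_meta_dataset(small_literature(seed = 5))
  cfg <- quick_config(seed = 99)
  f1 <- fit_meta(ds, config = cfg)
  f2 <- fit_meta(ds, config = cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_gte(effective_size(f1$beta[, 1]), 100)
})

test_that("posterior summaries are invariant to input row permutation", {
  lit <- small_literature(seed = 8)
  perm <- sample(nrow(lit$effects))
  ds1 <- meta_dataset(lit$effects, relatedness_matrix(lit$tree, sort(unique(lit$effects$species))))
  ds2 <- meta_dataset(lit$effects[perm, ], relatedness_matrix(lit$tree, sort(unique(lit$effects$species))))
  f1 <- fit_meta(ds1, config = quick_config(seed = 4))
  f2 <- fit_meta(ds2, config = quick_config(seed = 4))
  expect_identical(f1$summary, f2$summary)
})

test_that("DIC accessor validates draw count and pD is positive", {
  ds <- as_meta_dataset(small_literature(seed = 3))
  f <- fit_meta(ds, config = quick_config())
  d <- dic(f)
  expect_true(is.finite(d["dic"]))
  expect_gt(d["pd"], 0)
  short <- fit_meta(ds, config = chain_config(iterations = 300, burnin = 100,
                                              thin = 3, seed = 1))
  expect_error(dic(short), "100")
})

test_that("DIC is stable across seeds at the reference configuration", {
  ds <- as_meta_dataset(small_literature(seed = 6))
  f1 <- fit_meta(ds, config = quick_config(iterations = 12000, burnin = 2000,
                                           thin = 2, seed = 1))
  f2 <- fit_meta(ds, config = quick_config(iterations = 12000, burnin = 2000,
                                           thin = 2, seed = 2))
  expect_lt(abs(f1$dic - f2$dic), 1)
})

test_that("summaries report both scales with tanh applied to mean and endpoints", {
  ds <- as_meta_dataset(small_literature(seed = 9))
  f <- fit_meta(ds, config = quick_config())
  s <- f$summary
  zrow <- s[s$parameter == "(Intercept)" & s$scale == "fisher_z", ]
  rrow <- s[s$parameter == "(Intercept)" & s$scale == "pearson_r", ]
  expect_equal(rrow$mean, tanh(zrow$mean))
  expect_equal(rrow$lower, tanh(zrow$lower))
  expect_equal(rrow$upper, tanh(zrow$upper))
  expect_true(zrow$lower <= zrow$median && zrow$median <= zrow$upper)
})

test_that("moderator fits expose equal-weight marginal level means", {
  lit <- small_literature(
    seed = 11, n_effects = 60, n_studies = 30,
    moderator_effects = list(aggression_measure = c(indirect = 0.6))
  )
  ds <- as_meta_dataset(lit)
  f <- fit_meta(ds, fixed = c("aggression_measure", "plasticity"),
                config = quick_config(seed = 2))
  mm <- moderator_means(f, "aggression_measure")
  expect_equal(mm$level, c("direct", "indirect"))
  expect_gt(mm$mean[mm$level == "indirect"], mm$mean[mm$level == "direct"])
  expect_true(all(mm$lower < mm$mean & mm$mean < mm$upper))
  expect_error(moderator_means(f, "sex"), "not a fitted")
})

test_that("degenerate designs fail loudly", {
  eff <- data.frame(effect_id = c("a", "b"), study_id = c("s", "s"),
                    species = c("X", "X"), z = c(0.1, 0.2), var_z = c(0.1, 0.1),
                    color_class = c("eumelanin", "eumelanin"))
  ds <- meta_dataset(eff)
  expect_error(fit_meta(ds, random = "phylo", config = quick_config()),
               "relatedness")
  expect_error(fit_meta(ds, fixed = "color_class", config = quick_config()),
               "singular|contrasts")
  # single-species data with species random effect still runs
  f <- fit_meta(ds, random = c("species", "study"), config = quick_config())
  expect_true(is.finite(f$dic))
})

test_that("backward elimination detects the load-bearing study component", {
  lit <- small_literature(seed = 21, sigma2_phylo = 0, sigma2_species = 0,
                          sigma2_study = 0.4, n_effects = 60, n_studies = 25)
  ds <- as_meta_dataset(lit)
  tab <- backward_eliminate_random(ds, config = quick_config(iterations = 4000,
                                                             burnin = 1500,
                                                             thin = 2, seed = 3))
  expect_equal(nrow(tab), 8)  # all subsets of three candidate terms
  with_study <- grepl("study", tab$structure)
  expect_gt(min(tab$dic[!with_study]) - min(tab$dic[with_study]), 3)
})

test_that("moderator scan tabulates DIC against the random-only baseline", {
  lit <- small_literature(seed = 22, n_effects = 50, n_studies = 25)
  ds <- as_meta_dataset(lit)
  tab <- moderator_scan(ds, moderators = c("plasticity", "study_design"),
                        config = quick_config(iterations = 2500, burnin = 1000,
                                              thin = 2, seed = 5))
  expect_setequal(tab$model, c("(random only)", "plasticity", "study_design",
                               "plasticity + study_design"))
  expect_equal(tab$delta_dic[tab$model == "(random only)"], 0)
  expect_true(any(tab$consider))
  # scan over zero moderators returns only the baseline row
  base <- moderator_scan(ds, moderators = character(0),
                         config = quick_config(iterations = 2500, burnin = 1000,
                                               thin = 2, seed = 5))
  expect_equal(base$model, "(random only)")
})
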