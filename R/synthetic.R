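#' Parameters for a synthetic meta-analytic literature
#'
#' Defaults are the "paper-scale" preset: 56 species, 74 studies, 169
#' effects, a true mean Fisher Z of 0.25, variance components
#' (phylo 0.02, species 0.02, study 0.05), per-effect sample sizes drawn
#' log-uniformly over 8-120, and no censoring. These mirror the scale and
#' signal structure of a typical coloration-aggression literature, where
#' study-level clustering dominates the species-level terms.
#'
#' @param n_species,n_studies,n_effects Design dimensions; every study has
#'   at least one effect and every species at least one study
#'   (`n_studies >= n_species`).
#' @param beta0 True overall mean on the Fisher Z scale.
#' @param sigma2_phylo,sigma2_species,sigma2_study Variance components
#'   (nonnegative).
#' @param n_range Min/max per-effect total sample size (min >= 4).
#' @param moderator_effects Optional named list: moderator -> named numeric
#'   vector of per-level offsets added to the true mean (study level).
#' @param censor_severity Selective-reporting severity in [0, 1] applied by
#'   [censor_literature()].
#' @param birth_rate Speciation rate of the pure-birth tree simulation.
#' @param seed Master integer seed; per-stage substreams are derived from
#'   it by fixed offsets.
#' @return List of class `"simulation_params"`.
#' @export
simulation_params <- function(n_species = 56, n_studies = 74, n_effects = 169,
                              beta0 = 0.25, sigma2_phylo = 0.02,
                              sigma2_species = 0.02, sigma2_study = 0.05,
                              n_range = c(8, 120), moderator_effects = NULL,
                              censor_severity = 0, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 1, n_studies >= n_species, n_effects >= n_studies,
            sigma2_phylo >= 0, sigma2_species >= 0, sigma2_study >= 0,
            length(n_range) == 2, n_range[1] >= 4, n_range[2] >= n_range[1],
            censor_severity >= 0, censor_severity <= 1, birth_rate > 0)
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate an ultrametric pure-birth species tree
#'
#' Pure-birth (Yule) tree with depth normalized to 1, deterministic given
#' the seed. Tips are labelled `species_01`, `species_02`, ...
#'
#' @param n_species Number of tips (`>= 1`).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return A `phylo` object (for `n_species = 1`, a minimal single-tip tree).
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  if (n_species == 1) {
    return(read_newick(text = "(species_01:1);"))
  }
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("species_%02d", seq_len(n_species))
  tr
}

.draw_moderators <- function(n_studies) {
  # study-level moderator draws with frequencies typical of this literature
  pick <- function(x, p) sample(x, n_studies, replace = TRUE, prob = p)
  data.frame(
    color_class = pick(c("carotenoid", "eumelanin", "pheomelanin", "structural", "unknown"),
                       c(0.15, 0.45, 0.13, 0.14, 0.13)),
    plasticity = pick(c("fixed", "plastic"), c(0.6, 0.4)),
    sex = pick(c("both", "female", "male"), c(0.25, 0.15, 0.6)),
    life_stage = pick(c("adult", "juvenile"), c(0.9, 0.1)),
    population_type = pick(c("captive", "wild"), c(0.35, 0.65)),
    taxon = pick(c("invertebrate", "vertebrate"), c(0.07, 0.93)),
    seasonality = pick(c("breeding", "year_round"), c(0.45, 0.55)),
    aggression_measure = pick(c("direct", "indirect"), c(0.7, 0.3)),
    study_design = pick(c("experimental", "observational"), c(0.45, 0.55)),
    condition_control = pick(c("statistical", "uncontrolled"), c(0.6, 0.4)),
    rank_control = pick(c("mirror_or_video", "unfamiliar", "uncontrolled"),
                        c(0.3, 0.4, 0.3)),
    age_control = pick(c("statistical", "uncontrolled"), c(0.15, 0.85)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic literature of Fisher Z effects
#'
#' Generates effects from exactly the model the package fits:
#' `z_i = beta0 + x_i' beta_mod + a_sp + u_sp + s_st + e_i` with
#' `a ~ MVN(0, sigma2_phylo A)` (Brownian motion on the tree),
#' `u ~ N(0, sigma2_species I)`, `s ~ N(0, sigma2_study I)` and
#' `e_i ~ N(0, 1/(n_i - 3))`. Moderators are assigned at the study level,
#' so effects within a study share levels. All latent draws are recorded
#' in `truth` for generator bookkeeping.
#'
#' @param tree A `phylo` with at least `params$n_species` tips (defaults to
#'   a fresh pure-birth tree).
#' @param params A [simulation_params()].
#' @return List of class `"synthetic_literature"`: `effects` (data frame
#'   with `effect_id`, `study_id`, `species`, `z`, `var_z`, `weight`,
#'   `n_total` and moderators), `tree`, and `truth` (params plus all
#'   latent effects and the noiseless `z_true` per effect).
#' @export
simulate_effects <- function(params = simulation_params(),
                             tree = simulate_tree(params$n_species,
                                                  params$birth_rate,
                                                  params$seed)) {
  stopifnot(inherits(params, "simulation_params"))
  if (length(tree$tip.label) < params$n_species) {
    stop("simulate_effects: tree has fewer tips than n_species")
  }
  set.seed(params$seed + 1000L)
  ns <- params$n_species; nt <- params$n_studies; ne <- params$n_effects
  species <- sort(tree$tip.label)[seq_len(ns)]

  # every species hosts at least one study; extra studies pick species at random
  study_species <- c(species, sample(species, nt - ns, replace = TRUE))
  study_species <- study_species[sample.int(nt)]
  study_id <- sprintf("study_%03d", seq_len(nt))

  # allocate effects: one per study, remainder multinomial
  per_study <- rep(1L, nt)
  extra <- stats::rmultinom(1, ne - nt, rep(1, nt))[, 1]
  per_study <- per_study + extra

  mods <- .draw_moderators(nt)

  A <- relatedness_matrix(tree, species)
  a <- if (params$sigma2_phylo > 0) {
    drop(t(chol(A + diag(1e-10, ns))) %*% stats::rnorm(ns)) * sqrt(params$sigma2_phylo)
  } else rep(0, ns)
  u <- stats::rnorm(ns, 0, sqrt(params$sigma2_species))
  s <- stats::rnorm(nt, 0, sqrt(params$sigma2_study))
  names(a) <- names(u) <- species
  names(s) <- study_id

  st_of_effect <- rep(seq_len(nt), per_study)
  n_tot <- round(exp(stats::runif(ne, log(params$n_range[1]), log(params$n_range[2]))))
  n_tot <- pmax(4L, as.integer(n_tot))

  mod_offset <- rep(0, nt)
  if (!is.null(params$moderator_effects)) {
    for (m in names(params$moderator_effects)) {
      off <- params$moderator_effects[[m]]
      lv <- mods[[m]]
      hit <- lv %in% names(off)
      mod_offset[hit] <- mod_offset[hit] + off[lv[hit]]
    }
  }

  sp_idx <- match(study_species, species)
  z_true <- params$beta0 + mod_offset[st_of_effect] +
    a[sp_idx[st_of_effect]] + u[sp_idx[st_of_effect]] + s[st_of_effect]
  v <- 1 / (n_tot - 3)
  z <- z_true + stats::rnorm(ne, 0, sqrt(v))

  effects <- data.frame(
    effect_id = sprintf("effect_%03d", seq_len(ne)),
    study_id = study_id[st_of_effect],
    species = study_species[st_of_effect],
    z = z, var_z = v, weight = 1 / sqrt(v), n_total = n_tot,
    mods[st_of_effect, , drop = FALSE],
    stringsAsFactors = FALSE
  )
  rownames(effects) <- NULL
  structure(list(
    effects = effects, tree = tree,
    truth = list(params = params, a = a, u = u, s = s,
                 mod_offset_by_study = stats::setNames(mod_offset, study_id),
                 z_true = z_true)
  ), class = "synthetic_literature")
}

#' @export
print.synthetic_literature <- function(x, ...) {
  cat("synthetic_literature:", nrow(x$effects), "effects,",
      length(unique(x$effects$study_id)), "studies,",
      length(unique(x$effects$species)), "species\n")
  invisible(x)
}

#' Convert a synthetic literature to a meta_dataset
#'
#' Builds the relatedness matrix from the literature's tree and assembles
#' the fitting container.
#'
#' @param literature A `synthetic_literature`.
#' @return A [meta_dataset()].
#' @export
as_meta_dataset <- function(literature) {
  stopifnot(inherits(literature, "synthetic_literature"))
  sp <- sort(unique(literature$effects$species))
  meta_dataset(literature$effects, relatedness_matrix(literature$tree, sp))
}

#' Re-express synthetic Fisher Z effects as raw reported statistics
#'
#' The inverse of [harmonize()]: each effect's `r = tanh(z)` is expressed
#' as a Pearson correlation, a t statistic (`t = r sqrt(df/(1-r^2))`,
#' `df = n - 2`), a 1-df F (`F = t^2` plus a direction), a 1-df
#' chi-squared (`chisq = r^2 n` plus a direction), or two group means
#' reproducing the biserial estimate exactly (`sd = 1`, `m0 = 0`,
#' near-equal group split). Running [harmonize()] on the output recovers
#' each `z`.
#'
#' @param literature A `synthetic_literature`.
#' @param mix Named proportions over
#'   `c("pearson_r", "t_test", "F_test", "chisq", "group_means")`; must sum
#'   to 1.
#' @param seed Integer seed for the per-effect type assignment.
#' @return Data frame of effect records suitable for [harmonize()], with
#'   moderators carried along.
#' @export
disguise_as_raw_statistics <- function(literature,
                                       mix = c(pearson_r = 1),
                                       seed = 1) {
  stopifnot(inherits(literature, "synthetic_literature"))
  types <- c("pearson_r", "t_test", "F_test", "chisq", "group_means")
  if (is.null(names(mix)) || !all(names(mix) %in% types)) {
    stop("disguise_as_raw_statistics: mix names must be statistic types")
  }
  if (abs(sum(mix) - 1) > 1e-8) stop("disguise_as_raw_statistics: mix must sum to 1")
  eff <- literature$effects
  ne <- nrow(eff)
  set.seed(seed)
  type <- sample(names(mix), ne, replace = TRUE, prob = mix)
  r <- tanh(eff$z)
  n <- eff$n_total
  rec <- data.frame(
    effect_id = eff$effect_id, study_id = eff$study_id, species = eff$species,
    stat_type = type, stat_value = NA_real_, df = NA_real_, n_total = n,
    n1 = NA_integer_, n0 = NA_integer_, m1 = NA_real_, m0 = NA_real_,
    sd_pooled = NA_real_, direction = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(ne)) {
    ri <- r[i]; ni <- n[i]
    switch(type[i],
      pearson_r = { rec$stat_value[i] <- ri },
      t_test = {
        df <- ni - 2
        rec$stat_value[i] <- ri * sqrt(df / (1 - ri^2)); rec$df[i] <- df
      },
      F_test = {
        df <- ni - 2
        rec$stat_value[i] <- ri^2 * df / (1 - ri^2); rec$df[i] <- df
        rec$direction[i] <- if (ri < 0) -1 else 1
      },
      chisq = {
        rec$stat_value[i] <- ri^2 * ni
        rec$direction[i] <- if (ri < 0) -1 else 1
      },
      group_means = {
        n1 <- max(2L, ni %/% 2L); n0 <- ni - n1
        p <- n1 / ni
        r_pb <- ri * stats::dnorm(stats::qnorm(p)) / sqrt(p * (1 - p))
        diff <- r_pb * sqrt(ni * (ni - 1) / (n1 * n0))
        rec$n1[i] <- n1; rec$n0[i] <- n0
        rec$m1[i] <- diff; rec$m0[i] <- 0; rec$sd_pooled[i] <- 1
      }
    )
  }
  cbind(rec, eff[, intersect(.moderator_cols, names(eff)), drop = FALSE])
}

#' Apply selective-reporting censoring to a literature
#'
#' Each effect is dropped independently with probability
#' `severity * (1 - pnorm(z_i / SE_i))`: small or negative effects from
#' imprecise studies vanish preferentially, the mechanism funnel-based
#' diagnostics are meant to detect. Studies left without effects are
#' removed.
#'
#' @param literature A `synthetic_literature`.
#' @param severity Censoring severity in [0, 1]; 0 is the identity.
#' @param seed Integer seed.
#' @return The censored `synthetic_literature`; dropped effect ids recorded
#'   in `truth$censored_ids`.
#' @export
censor_literature <- function(literature, severity, seed = 1) {
  stopifnot(inherits(literature, "synthetic_literature"),
            severity >= 0, severity <= 1)
  eff <- literature$effects
  if (severity == 0 || nrow(eff) == 0) {
    literature$truth$censored_ids <- character(0)
    return(literature)
  }
  set.seed(seed)
  p_drop <- severity * (1 - stats::pnorm(eff$z / sqrt(eff$var_z)))
  drop <- stats::runif(nrow(eff)) < p_drop
  literature$truth$censored_ids <- eff$effect_id[drop]
  literature$effects <- eff[!drop, , drop = FALSE]
  rownames(literature$effects) <- NULL
  literature
}

#' Write a synthetic literature to disk
#'
#' Writes `effects.csv` (same dialect the pipeline reads), `tree.nwk`
#' (Newick) and `truth.json`.
#'
#' @param literature A `synthetic_literature`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(literature, dir) {
  stopifnot(inherits(literature, "synthetic_literature"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    effects = file.path(dir, "effects.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(literature$effects, paths["effects"], row.names = FALSE)
  ape::write.tree(literature$tree, paths["tree"])
  truth <- literature$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
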