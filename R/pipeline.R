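#' Per-effect forest table
#'
#' One row per harmonized effect with its Fisher Z value, the normal 95%
#' interval `z +/- 1.96 sqrt(var_z)`, color class and plasticity labels,
#' and a grouping key (taxonomic `family` column when present, otherwise
#' species, with a warning), plus a final row for the model mean with its
#' posterior credible interval.
#'
#' @param effects Data frame of harmonized effects (with `z`, `var_z` and
#'   any moderator columns).
#' @param fit Optional `meta_fit` supplying the model-mean row.
#' @return Data frame sorted by group then study label.
#' @export
forest_table <- function(effects, fit = NULL) {
  if (nrow(effects) == 0) {
    return(data.frame(effect_id = character(0), group = character(0),
                      study_id = character(0), z = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      color_class = character(0), plasticity = character(0)))
  }
  if ("family" %in% names(effects)) {
    group <- effects$family
  } else {
    warning("forest_table: no 'family' column; grouping by species")
    group <- effects$species
  }
  getcol <- function(nm) if (nm %in% names(effects)) effects[[nm]] else NA_character_
  half <- 1.96 * sqrt(effects$var_z)
  out <- data.frame(
    effect_id = effects$effect_id, group = group,
    study_id = getcol("study_id"),
    z = effects$z, lower = effects$z - half, upper = effects$z + half,
    color_class = getcol("color_class"), plasticity = getcol("plasticity"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$group, out$study_id, out$effect_id), , drop = FALSE]
  if (!is.null(fit)) {
    s <- fit$summary
    b0 <- s[s$parameter == "(Intercept)" & s$scale == "fisher_z", ]
    out <- rbind(out, data.frame(
      effect_id = "(model mean)", group = "(model)", study_id = "",
      z = b0$mean, lower = b0$lower, upper = b0$upper,
      color_class = "", plasticity = "", stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Run the full meta-analytic pipeline
#'
#' One call reproduces the whole analysis graph on a conforming dataset:
#' harmonize raw statistics to Fisher Z, prepare the tree (root at the
#' outgroup, repair zero branches, prune to the dataset species), run
#' backward elimination over the random structure, scan moderators by DIC,
#' fit the full random-effects model, decompose heterogeneity, and compute
#' the publication-bias report, funnel table and forest table. All
#' artifacts are written to `out_dir` along with a JSON manifest (seed,
#' config, input checksums, timings).
#'
#' @param effects Path to the effects CSV, or a data frame. Rows carrying a
#'   `stat_type` column are harmonized; rows already carrying `z` and
#'   `var_z` are used as-is.
#' @param tree Path to a Newick file, or a `phylo` object, or `NULL` to
#'   run without a phylogenetic term.
#' @param out_dir Output directory.
#' @param outgroup Optional outgroup tip label; rooted there then dropped.
#' @param moderators Moderator columns to scan (default: the known
#'   moderator columns present in the data). Set `character(0)` to skip.
#' @param interaction_pairs Interaction pairs passed to [moderator_scan()].
#' @param scan_pairwise Include additive two-way combinations in the scan.
#' @param subset Optional control subset (`"condition"`, `"rank"`, `"age"`,
#'   `"all_three"`) applied before fitting.
#' @param recode_unknown Recode unknown color classes as eumelanin first.
#' @param profile Chain profile, `"desk"` or `"paper"`.
#' @param seed Integer master seed.
#' @return Invisibly, a list with every computed object and the manifest.
#' @export
run_full_analysis <- function(effects, tree = NULL, out_dir,
                              outgroup = NULL, moderators = NULL,
                              interaction_pairs = list(),
                              scan_pairwise = TRUE,
                              subset = NULL, recode_unknown = FALSE,
                              profile = "desk", seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), s, units = "secs")), 3)
    res
  }

  checksums <- list()
  raw <- stage("read_effects", {
    if (is.character(effects)) {
      checksums$effects <- unname(tools::md5sum(effects))
      read_effects_csv(effects)
    } else effects
  })

  harmonized <- stage("harmonize", {
    if ("stat_type" %in% names(raw) && any(!is.na(raw$stat_type))) {
      h <- harmonize(raw)
      carry <- setdiff(names(raw), names(h))
      cbind(h, raw[, carry, drop = FALSE])
    } else {
      if (!all(c("z", "var_z") %in% names(raw))) {
        stop("effects need either stat_type columns or z/var_z")
      }
      raw
    }
  })
  write_effects_csv(harmonized, file.path(out_dir, "harmonized_effects.csv"))

  A <- stage("phylogeny", {
    if (is.null(tree)) NULL else {
      tr <- if (is.character(tree)) {
        checksums$tree <- unname(tools::md5sum(tree))
        read_newick(file = tree)
      } else tree
      if (!is.null(outgroup)) {
        tr <- root_at_outgroup(tr, outgroup)
        tr <- ape::drop.tip(tr, outgroup)
      }
      tr <- repair_zero_branches(tr)
      relatedness_matrix(tr, sort(unique(harmonized$species)))
    }
  })
  if (!is.null(A)) {
    utils::write.csv(data.frame(species = rownames(A), A, check.names = FALSE),
                     file.path(out_dir, "relatedness_matrix.csv"), row.names = FALSE)
  }

  dataset <- stage("assemble", meta_dataset(harmonized, A))
  if (recode_unknown) dataset <- stage("recode_unknown", recode_unknown_to_eumelanin(dataset))
  if (!is.null(subset)) dataset <- stage("subset", subset_by_control(dataset, subset))

  cfg <- chain_config(profile = profile, seed = seed)

  elim <- stage("random_structure", backward_eliminate_random(dataset, config = cfg))
  utils::write.csv(elim, file.path(out_dir, "dic_random_structure.csv"), row.names = FALSE)

  if (is.null(moderators)) {
    moderators <- intersect(.moderator_cols, names(dataset$effects))
  }
  scan <- stage("moderator_scan", {
    cfg_scan <- cfg; cfg_scan$seed <- seed + 100L
    moderator_scan(dataset, moderators, interaction_pairs,
                   config = cfg_scan, pairwise = scan_pairwise)
  })
  utils::write.csv(scan, file.path(out_dir, "dic_moderator_scan.csv"), row.names = FALSE)

  fit <- stage("fit", {
    cfg_fit <- cfg; cfg_fit$seed <- seed + 200L
    fit_meta(dataset, config = cfg_fit)
  })
  utils::write.csv(fit$summary, file.path(out_dir, "model_summary.csv"), row.names = FALSE)

  het <- stage("heterogeneity", heterogeneity_decompose(fit))
  utils::write.csv(het$summary, file.path(out_dir, "heterogeneity.csv"), row.names = FALSE)

  bias <- stage("pubbias", bias_report(fit))
  jsonlite::write_json(list(
    egger = unclass(bias$egger),
    trimfill = list(k0 = bias$trimfill$k0,
                    adjusted_mean = bias$trimfill$adjusted_mean,
                    unadjusted_mean = bias$trimfill$unadjusted_mean,
                    side = bias$trimfill$side)
  ), file.path(out_dir, "bias_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(funnel_table(bias$residuals),
                   file.path(out_dir, "funnel_table.csv"), row.names = FALSE)

  forest <- stage("forest", forest_table(dataset$effects, fit))
  utils::write.csv(forest, file.path(out_dir, "forest_table.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phylometa")),
    seed = seed, profile = profile,
    config = list(iterations = cfg$iterations, burnin = cfg$burnin,
                  thin = cfg$thin, prior_scale = cfg$prior_scale),
    moderators = moderators, subset = subset, recode_unknown = recode_unknown,
    input_checksums = checksums, timings = timings,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = dataset, elimination = elim, scan = scan, fit = fit,
                 heterogeneity = het, bias = bias, forest = forest,
                 manifest = manifest))
}
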