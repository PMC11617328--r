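#' Backward elimination over the random-effect structure
#'
#' Fits the intercept-only model under every subset of the candidate random
#' terms (sampling error always included) and tabulates DIC, so the
#' contribution of each term can be judged by how much its removal worsens
#' fit. Sorted by DIC with model complexity breaking ties.
#'
#' @param dataset A [meta_dataset()].
#' @param config A [chain_config()] applied to every fit. When `config$seed`
#'   is set, fit k uses `seed + k` so chains are independent.
#' @param candidates Random terms to consider; `"phylo"` is dropped
#'   automatically when the dataset has no relatedness matrix.
#' @return Data frame with columns `structure`, `n_terms`, `dic`, `pd`,
#'   sorted best (lowest DIC) first.
#' @export
backward_eliminate_random <- function(dataset, config = chain_config(),
                                      candidates = c("phylo", "species", "study")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (is.null(dataset$A)) candidates <- setdiff(candidates, "phylo")
  subsets <- list(character(0))
  for (term in candidates) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, term)))
  }
  rows <- lapply(seq_along(subsets), function(k) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + k
    f <- fit_meta(dataset, random = subsets[[k]], config = cfg)
    data.frame(
      structure = if (length(subsets[[k]])) paste(subsets[[k]], collapse = "+") else "(none)",
      n_terms = length(subsets[[k]]), dic = f$dic, pd = f$pd
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dic, out$n_terms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DIC scan over moderators
#'
#' Fits the full random-effects model plus, one model at a time, each
#' moderator alone, every additive two-way combination, and any requested
#' interaction pairs, and compares all of them to the random-effects-only
#' baseline by DIC. Models within 2 DIC of the best are flagged as
#' deserving consideration. No multiplicity correction is applied: model
#' choice here is by DIC, not p-values.
#'
#' @param dataset A [meta_dataset()].
#' @param moderators Character vector of moderator names to scan.
#' @param interaction_pairs List of length-2 character vectors fitted with
#'   their interaction term (e.g. `list(c("color_class", "plasticity"))`).
#' @param config A [chain_config()]; per-model seeds derived as in
#'   [backward_eliminate_random()].
#' @param pairwise Fit all additive two-way combinations (default TRUE).
#' @return Data frame with columns `model`, `dic`, `pd`, `delta_dic`
#'   (vs the random-effects-only model) and `consider` (within 2 of best).
#' @export
moderator_scan <- function(dataset, moderators = character(),
                           interaction_pairs = list(),
                           config = chain_config(), pairwise = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  usable <- character(0)
  for (m in moderators) {
    lv <- unique(stats::na.omit(dataset$effects[[m]]))
    if (length(lv) < 2) {
      warning("moderator_scan: dropping '", m, "' (fewer than 2 observed levels)")
    } else usable <- c(usable, m)
  }
  specs <- list(list(label = "(random only)", fixed = character(0), inter = list()))
  for (m in usable) {
    specs[[length(specs) + 1]] <- list(label = m, fixed = m, inter = list())
  }
  if (pairwise && length(usable) >= 2) {
    cmb <- utils::combn(usable, 2, simplify = FALSE)
    for (pr in cmb) {
      specs[[length(specs) + 1]] <- list(
        label = paste(pr, collapse = " + "), fixed = pr, inter = list())
    }
  }
  for (pr in interaction_pairs) {
    if (!all(pr %in% usable)) next
    specs[[length(specs) + 1]] <- list(
      label = paste(pr, collapse = " x "), fixed = pr, inter = list(pr))
  }
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + k
    f <- fit_meta(dataset, fixed = sp$fixed, interactions = sp$inter, config = cfg)
    data.frame(model = sp$label, dic = f$dic, pd = f$pd)
  })
  out <- do.call(rbind, rows)
  base_dic <- out$dic[out$model == "(random only)"]
  out$delta_dic <- out$dic - base_dic
  out$consider <- out$dic <= min(out$dic) + 2
  out <- out[order(out$dic), , drop = FALSE]
  rownames(out) <- NULL
  out
}
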