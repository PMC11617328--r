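#' @useDynLib phylometa, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# moderator columns the pipeline knows about; presence is optional except
# where an operation requires one (e.g. recode needs color_class)
.moderator_cols <- c(
  "color_class", "plasticity", "sex", "life_stage", "population_type",
  "taxon", "seasonality", "aggression_measure", "study_design",
  "condition_control", "rank_control", "age_control"
)

#' Assemble a meta-analytic dataset
#'
#' Binds harmonized Fisher Z effects to their species, studies, moderators
#' and the species relatedness matrix, validating that every species in the
#' data is covered by the matrix. Rows are canonicalized by `effect_id` so
#' downstream fits are invariant to the input row order.
#'
#' @param effects Data frame with at least `effect_id`, `study_id`,
#'   `species`, `z`, `var_z`; moderator columns are carried along.
#' @param A Relatedness matrix with species dimnames (see
#'   [relatedness_matrix()]), or `NULL` to omit the phylogenetic term.
#' @return An object of class `"meta_dataset"`.
#' @export
meta_dataset <- function(effects, A = NULL) {
  stopifnot(is.data.frame(effects))
  req <- c("effect_id", "study_id", "species", "z", "var_z")
  miss <- setdiff(req, names(effects))
  if (length(miss)) stop("meta_dataset: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(effects$effect_id)) stop("meta_dataset: duplicate effect_id")
  if (any(!is.finite(effects$z)) || any(effects$var_z <= 0)) {
    stop("meta_dataset: z must be finite and var_z > 0")
  }
  effects <- effects[order(as.character(effects$effect_id)), , drop = FALSE]
  rownames(effects) <- NULL
  species <- sort(unique(as.character(effects$species)))
  studies <- sort(unique(as.character(effects$study_id)))
  if (!is.null(A)) {
    if (is.null(rownames(A))) stop("meta_dataset: A needs species dimnames")
    missing_sp <- setdiff(species, rownames(A))
    if (length(missing_sp)) {
      stop("meta_dataset: species absent from relatedness matrix: ",
           paste(missing_sp, collapse = ", "))
    }
    A <- A[species, species, drop = FALSE]
  }
  structure(
    list(effects = effects, species = species, studies = studies, A = A),
    class = "meta_dataset"
  )
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("meta_dataset:", nrow(x$effects), "effects,",
      length(x$studies), "studies,", length(x$species), "species;",
      if (is.null(x$A)) "no phylogeny\n" else "with relatedness matrix\n")
  invisible(x)
}

#' Read an effects table from CSV
#'
#' One row per effect; UTF-8; missing values as empty cells. Character
#' columns are read as strings, never factors.
#'
#' @param path CSV file path.
#' @return Data frame of effect records.
#' @export
read_effects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Write harmonized effect sizes to CSV
#'
#' @param effects Data frame as returned by [harmonize()].
#' @param path Output file path.
#' @export
write_effects_csv <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
}

#' Recode unknown color classes as eumelanin
#'
#' Sensitivity recoding for the hypothesis that melanocortin-regulated
#' colors extend beyond melanins: every `color_class == "unknown"` becomes
#' `"eumelanin"`. All other fields are untouched.
#'
#' @param dataset A `meta_dataset`.
#' @return The recoded dataset, with attribute `n_recoded` giving the row
#'   count that changed (also reported via message).
#' @export
recode_unknown_to_eumelanin <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (!"color_class" %in% names(dataset$effects)) {
    stop("recode_unknown_to_eumelanin: no color_class column")
  }
  idx <- which(dataset$effects$color_class == "unknown")
  dataset$effects$color_class[idx] <- "eumelanin"
  message("recoded ", length(idx), " effect(s) from unknown to eumelanin")
  attr(dataset, "n_recoded") <- length(idx)
  dataset
}

#' Subset to studies that controlled for condition, rank or age
#'
#' Keeps rows whose control code differs from `"uncontrolled"` for the
#' requested moderator(s); `which = "all_three"` intersects all three
#' filters.
#'
#' @param dataset A `meta_dataset`.
#' @param which One of `"condition"`, `"rank"`, `"age"`, `"all_three"`.
#' @return The filtered `meta_dataset` (possibly empty, with a warning).
#' @export
subset_by_control <- function(dataset,
                              which = c("condition", "rank", "age", "all_three")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  which <- match.arg(which)
  cols <- switch(which,
    condition = "condition_control", rank = "rank_control",
    age = "age_control",
    all_three = c("condition_control", "rank_control", "age_control")
  )
  miss <- setdiff(cols, names(dataset$effects))
  if (length(miss)) stop("subset_by_control: missing columns: ", paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(dataset$effects))
  for (cc in cols) keep <- keep & dataset$effects[[cc]] != "uncontrolled"
  eff <- dataset$effects[keep, , drop = FALSE]
  message(which, " subset: ", nrow(eff), " of ", nrow(dataset$effects),
          " effects retained (", length(unique(eff$study_id)), " studies)")
  if (nrow(eff) == 0) {
    warning("subset_by_control: no effects remain after filtering")
    dataset$effects <- eff
    dataset$species <- character(0)
    dataset$studies <- character(0)
    if (!is.null(dataset$A)) dataset$A <- dataset$A[0, 0, drop = FALSE]
    return(dataset)
  }
  meta_dataset(eff, dataset$A)
}
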