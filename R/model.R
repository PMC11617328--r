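#' MCMC chain configuration
#'
#' The `"desk"` profile (50,000 iterations, 25,000 burn-in, thin 10) is the
#' default for interactive work and testing; the `"paper"` profile
#' (5,000,000 / 2,500,000 / 1,000) matches long production runs. Retained
#' draws must number at least 500 for reported runs.
#'
#' @param iterations,burnin,thin Chain length controls; `burnin < iterations`,
#'   `thin >= 1`.
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state alone.
#' @param prior_scale Scale of the half-Cauchy prior on each variance
#'   component's standard deviation (default 1; 0.5 and 2 are natural
#'   sensitivity settings). Fixed effects get a flat improper prior.
#' @param profile Named shortcut: `"desk"` or `"paper"`. Explicit
#'   `iterations`/`burnin`/`thin` override the profile.
#' @return A list of class `"chain_config"`.
#' @export
chain_config <- function(iterations = NULL, burnin = NULL, thin = NULL,
                         seed = NULL, prior_scale = 1,
                         profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  def <- switch(profile,
    desk = list(iterations = 50000L, burnin = 25000L, thin = 10L),
    paper = list(iterations = 5000000L, burnin = 2500000L, thin = 1000L)
  )
  cfg <- list(
    iterations = as.integer(if (is.null(iterations)) def$iterations else iterations),
    burnin = as.integer(if (is.null(burnin)) def$burnin else burnin),
    thin = as.integer(if (is.null(thin)) def$thin else thin),
    seed = seed, prior_scale = prior_scale, profile = profile
  )
  if (cfg$burnin >= cfg$iterations) stop("chain_config: burnin must be < iterations")
  if (cfg$thin < 1) stop("chain_config: thin must be >= 1")
  class(cfg) <- "chain_config"
  cfg
}

.build_design <- function(dataset, fixed, interactions) {
  eff <- dataset$effects
  if (length(fixed) == 0) {
    X <- matrix(1, nrow(eff), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, frame = NULL, formula = ~1))
  }
  miss <- setdiff(fixed, names(eff))
  if (length(miss)) stop("fit_meta: moderators not in dataset: ", paste(miss, collapse = ", "))
  frame <- eff[, fixed, drop = FALSE]
  for (m in fixed) {
    frame[[m]] <- droplevels(factor(frame[[m]]))  # alphabetical reference level
    if (nlevels(frame[[m]]) < 1) stop("fit_meta: moderator '", m, "' has no levels")
  }
  terms <- fixed
  for (pr in interactions) {
    if (length(pr) != 2 || !all(pr %in% fixed)) {
      stop("fit_meta: interactions must be pairs of declared moderators")
    }
    terms <- c(terms, paste(pr, collapse = ":"))
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, frame)
  if (qr(X)$rank < ncol(X)) stop("fit_meta: singular design matrix for moderators")
  list(X = X, frame = frame, formula = fml)
}

.incidence <- function(labels, levels) {
  Z <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(labels), match(labels, levels))] <- 1
  Z
}

#' Fit the Bayesian multilevel meta-analytic model
#'
#' Fits, by blocked Gibbs sampling,
#' \deqn{z_i \sim N(x_i'\beta + a_{sp(i)} + u_{sp(i)} + s_{st(i)},\; v_i)}
#' with phylogenetically correlated species deviations
#' \eqn{a \sim MVN(0, \sigma^2_{phylo} A)}, independent species deviations
#' \eqn{u \sim N(0, \sigma^2_{species} I)}, study deviations
#' \eqn{s \sim N(0, \sigma^2_{study} I)} and known sampling variances
#' \eqn{v_i = 1/(n_i - 3)}. Variance components carry half-Cauchy priors
#' on their standard deviations (parameter-expanded conjugate updates);
#' fixed effects a flat prior.
#'
#' @param dataset A [meta_dataset()].
#' @param fixed Character vector of moderator names for fixed effects
#'   (empty = intercept-only).
#' @param interactions List of length-2 character vectors naming two-way
#'   interactions among `fixed`.
#' @param random Subset of `c("phylo", "species", "study")`; the sampling
#'   error term is always present.
#' @param config A [chain_config()].
#' @param fixed_sigma2 Optional named numeric vector (names among
#'   `random`) holding those variance components fixed at given positive
#'   values instead of sampling them (used for conjugate checks).
#' @return Object of class `"meta_fit"` with posterior draws (`beta`,
#'   `sigma2`), per-draw `fitted` values and `deviance`, `dic`/`pd`, and a
#'   posterior `summary` table on the Fisher Z scale.
#' @export
fit_meta <- function(dataset, fixed = character(), interactions = list(),
                     random = c("phylo", "species", "study"),
                     config = chain_config(), fixed_sigma2 = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"), inherits(config, "chain_config"))
  if (length(random)) {
    random <- match.arg(random, c("phylo", "species", "study"), several.ok = TRUE)
  } else {
    random <- character(0)
  }
  eff <- dataset$effects
  if (nrow(eff) == 0) stop("fit_meta: empty dataset")
  des <- .build_design(dataset, fixed, interactions)
  X <- des$X
  p <- ncol(X)

  use <- c(phylo = "phylo" %in% random,
           species = "species" %in% random,
           study = "study" %in% random)
  if (use["phylo"] && is.null(dataset$A)) {
    stop("fit_meta: phylogenetic random effect requires a relatedness matrix")
  }
  sp <- as.character(eff$species); st <- as.character(eff$study_id)
  Zsp <- .incidence(sp, dataset$species)
  Zst <- .incidence(st, dataset$studies)

  W <- X
  blocks <- matrix(0L, 3, 2)  # [start, size], 0-based starts
  pos <- p
  if (use["phylo"]) { blocks[1, ] <- c(pos, ncol(Zsp)); W <- cbind(W, Zsp); pos <- pos + ncol(Zsp) }
  if (use["species"]) { blocks[2, ] <- c(pos, ncol(Zsp)); W <- cbind(W, Zsp); pos <- pos + ncol(Zsp) }
  if (use["study"]) { blocks[3, ] <- c(pos, ncol(Zst)); W <- cbind(W, Zst); pos <- pos + ncol(Zst) }

  Ainv <- Aphy <- matrix(0, 0, 0)
  if (use["phylo"]) {
    Aphy <- dataset$A
    Ainv <- tryCatch(chol2inv(chol(Aphy)), error = function(e) {
      chol2inv(chol(Aphy + diag(1e-8, nrow(Aphy))))
    })
  }

  sigma2_init <- c(phylo = 0.1, species = 0.1, study = 0.1)
  sigma2_fixed <- c(0L, 0L, 0L)
  if (!is.null(fixed_sigma2)) {
    bad <- setdiff(names(fixed_sigma2), random)
    if (length(bad)) stop("fit_meta: fixed_sigma2 names must be active random terms")
    if (any(fixed_sigma2 <= 0)) {
      stop("fit_meta: fixed_sigma2 values must be > 0; drop the term from `random` instead")
    }
    sigma2_init[names(fixed_sigma2)] <- fixed_sigma2
    sigma2_fixed[match(names(fixed_sigma2), c("phylo", "species", "study"))] <- 1L
  }

  n_keep <- (config$iterations - config$burnin + config$thin - 1) %/% config$thin
  if (n_keep < 2) stop("fit_meta: chain config retains fewer than 2 draws")

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .gibbs_meta(eff$z, eff$var_z, X, blocks, Aphy, Ainv, W,
                     sigma2_init, as.integer(sigma2_fixed), config$prior_scale,
                     config$iterations, config$burnin, config$thin)

  colnames(res$beta) <- colnames(X)
  colnames(res$sigma2) <- c("phylo", "species", "study")
  for (cmp in c("phylo", "species", "study")) {  # structurally absent -> zero
    if (!use[cmp]) res$sigma2[, cmp] <- 0
  }

  dbar <- mean(res$deviance)
  pd <- dbar - res$dhat
  dic <- dbar + pd

  fit <- structure(list(
    beta = res$beta, sigma2 = res$sigma2, fitted = res$fitted,
    deviance = res$deviance, dic = dic, pd = pd,
    fixed = fixed, interactions = interactions, random = random,
    frame = des$frame, formula = des$formula,
    effect_id = eff$effect_id, z = eff$z, var_z = eff$var_z,
    config = config, n_draws = nrow(res$beta)
  ), class = "meta_fit")
  fit$summary <- summarize_fit(fit)
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("meta_fit:", length(x$z), "effects;",
      "fixed:", if (length(x$fixed)) paste(x$fixed, collapse = "+") else "(intercept)",
      "; random:", if (length(x$random)) paste(x$random, collapse = "+") else "(none)", "\n")
  cat(sprintf("DIC = %.3f (pD = %.2f), %d retained draws\n", x$dic, x$pd, x$n_draws))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, computed on the
#' marginal likelihood: random effects are integrated out, so the deviance
#' is a function of the fixed effects and variance components only,
#' `D(beta, sigma2) = -2 log MVN(z; X beta, Sigma(sigma2))`. The plug-in
#' `theta_bar` uses the posterior mean of `beta` and the geometric mean
#' (mean on the log scale) of each variance component, since DIC is
#' parameterization-sensitive. The marginal form rewards a moderator that
#' genuinely explains between-study variance, instead of letting the
#' study-level random effects absorb it. Lower is better.
#'
#' @param fit A `meta_fit`.
#' @return Named numeric vector `c(dic, pd)`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  if (fit$n_draws < 100) {
    stop("dic: fewer than 100 retained draws; lengthen the chain")
  }
  c(dic = fit$dic, pd = fit$pd)
}

#' Posterior summary on Fisher Z and correlation scales
#'
#' Posterior mean, median and central 95% interval for every fixed effect
#' and variance component on the Fisher Z scale, plus the intercept
#' back-transformed with `tanh` applied to the mean and to each interval
#' endpoint (the convention used when reporting a meta-analytic mean on
#' the Pearson correlation scale).
#'
#' @param fit A `meta_fit`.
#' @return Data frame with columns `parameter`, `scale`, `mean`, `median`,
#'   `lower`, `upper`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  rows <- list()
  for (j in seq_len(ncol(fit$beta))) {
    x <- fit$beta[, j]
    q <- qs(x)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = colnames(fit$beta)[j], scale = "fisher_z",
      mean = mean(x), median = stats::median(x), lower = q[1], upper = q[2]
    )
  }
  for (cmp in c("phylo", "species", "study")) {
    if (!cmp %in% fit$random) next
    x <- fit$sigma2[, cmp]
    q <- qs(x)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("sigma2_", cmp), scale = "fisher_z",
      mean = mean(x), median = stats::median(x), lower = q[1], upper = q[2]
    )
  }
  if ("(Intercept)" %in% colnames(fit$beta)) {
    x <- fit$beta[, "(Intercept)"]
    q <- qs(x)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = "(Intercept)", scale = "pearson_r",
      mean = tanh(mean(x)), median = tanh(stats::median(x)),
      lower = tanh(q[1]), upper = tanh(q[2])
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Equal-weight marginal posterior means per moderator level
#'
#' For each level of `moderator`, averages the fixed-effect prediction over
#' a full factorial grid of the other fitted moderators' levels (equal
#' weights), per posterior draw, and summarizes the resulting draws.
#'
#' @param fit A `meta_fit` with `moderator` among its fixed effects.
#' @param moderator Moderator name.
#' @return Data frame with one row per level: posterior `mean`, `median`,
#'   95% `lower`/`upper` on the Fisher Z scale.
#' @export
moderator_means <- function(fit, moderator) {
  stopifnot(inherits(fit, "meta_fit"))
  if (!moderator %in% fit$fixed) stop("moderator_means: '", moderator, "' not a fitted moderator")
  levs <- lapply(fit$frame, levels)
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  for (m in names(levs)) grid[[m]] <- factor(grid[[m]], levels = levs[[m]])
  Xg <- stats::model.matrix(fit$formula, grid)
  pred <- Xg %*% t(fit$beta)          # grid rows x draws
  out <- lapply(levs[[moderator]], function(lv) {
    rows <- grid[[moderator]] == lv
    drw <- colMeans(pred[rows, , drop = FALSE])
    q <- stats::quantile(drw, c(0.025, 0.975), names = FALSE)
    data.frame(moderator = moderator, level = lv, mean = mean(drw),
               median = stats::median(drw), lower = q[1], upper = q[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Effective sample size of a chain
#'
#' Initial positive sequence estimator from the sample autocorrelations.
#'
#' @param x Numeric vector of posterior draws.
#' @return Estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}
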