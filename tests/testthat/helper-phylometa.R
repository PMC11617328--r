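# shared fixtures built in code

quick_config <- function(iterations = 3000, burnin = 1000, thin = 2, seed = 1) {
  chain_config(iterations = iterations, burnin = burnin, thin = thin, seed = seed)
}

# small literature for fast model tests
small_literature <- function(seed = 1, n_species = 15, n_studies = 20,
                             n_effects = 40, ...) {
  simulate_effects(simulation_params(
    n_species = n_species, n_studies = n_studies, n_effects = n_effects,
    seed = seed, ...
  ))
}

# closed-form posterior for the intercept under known variance components
# (flat prior): marginal model z ~ N(1 b0, Sigma),
# Sigma = s2p Z A Z' + s2u Z Z' + s2s Zs Zs' + diag(v)
closed_form_intercept <- function(dataset, s2p, s2u, s2s) {
  eff <- dataset$effects
  sp <- factor(eff$species, levels = dataset$species)
  st <- factor(eff$study_id, levels = dataset$studies)
  Z <- stats::model.matrix(~ sp - 1)
  Zs <- stats::model.matrix(~ st - 1)
  Sigma <- s2p * Z %*% dataset$A %*% t(Z) + s2u * tcrossprod(Z) +
    s2s * tcrossprod(Zs) + diag(eff$var_z)
  Si <- solve(Sigma)
  one <- rep(1, nrow(eff))
  prec <- drop(t(one) %*% Si %*% one)
  list(mean = drop(t(one) %*% Si %*% eff$z) / prec, sd = sqrt(1 / prec))
}

# brute-force one pass of the L0 rank-sum estimator about a given center
brute_l0 <- function(x, center) {
  dev <- x - center
  rk <- rank(abs(dev))
  Tn <- sum(rk[dev > 0])
  n <- length(x)
  (4 * Tn - n * (n + 1)) / (2 * n - 1)
}
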