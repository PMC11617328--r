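---
title: "Phylogenetic multilevel meta-analysis with phylometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic multilevel meta-analysis with phylometa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylometa implements a complete phylogenetic multilevel meta-analysis of
correlation-scale effect sizes, of the kind used to ask whether more
intensely colored animals are more aggressive. This vignette explains the
model, the choices behind each stage, what the synthetic-data generator
does and does not emulate, and the numerical details a careful user should
know.

## The model

Every literature effect is harmonized to a Fisher Z value
$z_i = \mathrm{arctanh}(r_i)$ with known sampling variance
$v_i = 1/(n_i - 3)$ and meta-analytic weight $1/\sqrt{v_i}$. The model is

$$ z_i \sim N(x_i^\top \beta + a_{sp(i)} + u_{sp(i)} + s_{st(i)},\; v_i) $$

with three random effects: phylogenetically correlated species deviations
$a \sim \mathrm{MVN}(0, \sigma^2_{phylo} A)$, independent species
deviations $u \sim N(0, \sigma^2_{species} I)$, and study deviations
$s \sim N(0, \sigma^2_{study} I)$. $A$ is the Brownian-motion relatedness
matrix of the species tree, normalized to correlation form (shared
root-to-MRCA path length divided by tree depth), so that all three
variance components live on the same scale and the phylogenetic signal
$H^2$ below is a proportion. The source tree is rooted at a distant
outgroup (dropped before analysis), zero-length edges are raised to
0.00001 so $A$ stays positive definite, and species present in the data
but absent from the tree are a hard error rather than a silent drop.

Moderators (color class, plasticity, sex, and so on) enter as fixed
effects with treatment contrasts, reference level alphabetical; two-way
interactions are supported. Marginal per-level means average predictions
over a full factorial grid of the other fitted moderators with equal
weights.

## Effect-size harmonization

Reported statistics are converted to correlation estimates before the
Fisher transform: $r = t/\sqrt{t^2 + df}$ for t statistics,
$r = \sqrt{F/(F + df_2)}$ for single-numerator-df F, the phi coefficient
$\sqrt{\chi^2/n}$ for 1-df chi-squared, and a two-step biserial estimate
for group means (point-biserial, then rescaled by
$\sqrt{pq}/\phi(\Phi^{-1}(p))$). F and chi-squared carry no sign, so the
input table must supply an explicit `direction` column; a missing
direction is an error, never an assumed positive. The `sd` entering the
biserial step is the total outcome standard deviation, which makes the
first step exactly the sample point-biserial correlation.

Biserial estimates can exceed 1 in magnitude in finite samples. Estimates
with $|r| > 0.99$ are clamped to $\pm 0.99$ — symmetric on both sides,
although published data sets typically only produce the positive case —
so $|z| \le \mathrm{arctanh}(0.99) \approx 2.6467$ always. A uniform
$v_i = 1/(n_i-3)$ is used for all conversion routes, including
biserial-derived effects; this is a simplification consistent with
defining weights as inverse standard errors of Fisher Z.

## Sampling and priors

The posterior is explored by a blocked Gibbs sampler written in C++:
$\beta$ and all random-effect vectors are drawn jointly from their
Gaussian full conditional (one Cholesky per iteration), and each variance
component is updated through the inverse-gamma scale-mixture
representation of a half-Cauchy prior on its standard deviation
($\sigma^2 \mid \lambda \sim IG(1/2, 1/\lambda)$,
$\lambda \sim IG(1/2, 1/c^2)$), giving conjugate updates while keeping
the heavy-tailed prior appropriate for Fisher Z scale parameters. The
default scale is $c = 1$; 0.5 and 2 are natural sensitivity settings.
Fixed effects carry a flat improper prior, which is proper a posteriori
whenever the design matrix has full rank (singular designs are rejected
up front).

Two chain profiles are built in. The `"desk"` profile (50,000 iterations,
25,000 burn-in, thin 10; 2,500 retained draws) is the default for
interactive use and is what the tests exercise; the `"paper"` profile
(5,000,000 / 2,500,000 / 1,000) reproduces long production runs. Because
the joint update is blocked, mixing is fast: with variance components
held fixed the retained draws are independent, and in realistic fits the
intercept's effective sample size is close to the retained draw count.
Fits sort effects by `effect_id` and index species and studies by sorted
name internally, so results are bitwise invariant to input row order at a
given seed.

## Model comparison by DIC

DIC is computed on the **marginal** likelihood: random effects are
integrated out and the deviance is a function of $(\beta, \sigma^2)$
only, with the plug-in at the posterior mean of $\beta$ and the geometric
mean of each $\sigma^2$ (variance components are averaged on the log
scale because DIC is parameterization-sensitive). The marginal form was
chosen over the conditional (latent-value) deviance deliberately: with a
study-level moderator, study random effects can absorb the moderator
signal entirely, leaving the conditional deviance — and hence conditional
DIC — almost unchanged whether or not the moderator is in the model. The
marginal DIC rewards a moderator that genuinely explains between-study
variance and penalizes one that does not, which is the behavior model
screening needs. A consequence is that absolute DIC values here are not
comparable to conditional-DIC values reported by other software; only
differences within a scan are meaningful. Ties in DIC tables are broken
by model complexity, and models within 2 DIC of the best are flagged as
deserving consideration.

Backward elimination fits all subsets of {phylo, species, study};
the moderator scan fits each moderator alone, additive two-way
combinations, and requested interaction pairs. No multiplicity
correction is applied across the scan — comparison is by DIC, not
p-values.

## Heterogeneity decomposition

With $\bar{s}^2$ the typical sampling variance
($\sum w_i (k-1) / [(\sum w_i)^2 - \sum w_i^2]$, $w_i = 1/v_i$) computed
once from the fixed $v_i$, each posterior draw yields a total
$T = \sigma^2_{phylo} + \sigma^2_{species} + \sigma^2_{study} + \bar{s}^2$
and shares $I^2_{study} = \sigma^2_{study}/T$,
$I^2_{species} = \sigma^2_{species}/T$, and the phylogenetic signal
$H^2 = \sigma^2_{phylo}/T$. Shares are computed per draw and then
averaged — a ratio of posterior means would be biased — and they sum to
100% on every draw by construction. $I^2$ values are reported as
percentages, $H^2$ as a proportion. Components absent from the random
structure are reported as structural zeros with a flag. Note that with
one species per study and few studies per species, $\sigma^2_{phylo}$ and
$\sigma^2_{species}$ are only weakly separated; $H^2$ is accordingly
wide and right-skewed, and its posterior mean can exceed the generating
value noticeably in small designs.

## Publication bias

Residuals are $z_i$ minus the posterior-mean fitted value (fixed plus all
random effects); unlike the weighted effects themselves these are
approximately independent. The modified Egger regression is run in
standard-normal-deviate form — the standardized residual
$residual_i/SE_i$ regressed on precision $1/SE_i$ — because dividing by
the standard error makes the regression errors homoskedastic and keeps
the intercept test at its nominal level (the raw-residual variant
rejects far too often under the null). The intercept, its SE, t, and a
two-sided p on $k-2$ df are reported; no significance decision is made.

Trim-and-fill uses the Duval–Tweedie L0 estimator on the residuals with
fixed-effect weighted centering, trimming the side of large positive
residuals by default (a `side` flag offers `"left"` and `"auto"`, which
picks the side with the heavier rank sum). The estimate of the number of
suppressed effects is iterated to convergence (capped at 20 iterations
with a warning), mirror-image points carry the standard errors of the
values they mirror, and the adjusted mean is the weighted mean over
observed plus imputed points. Funnel tables ship 90/95/99%
pseudo-confidence bounds so contour-enhanced funnels can be drawn with
any graphics layer.

## The synthetic-data generator

`simulate_effects()` draws from exactly the model above: a pure-birth
tree with depth normalized to 1, phylogenetically correlated and
independent species deviations, study deviations, and sampling noise with
variance $1/(n_i-3)$. The defaults are the paper-scale preset — 56
species, 74 studies, 169 effects, true mean Fisher Z 0.25, variance
components (phylo 0.02, species 0.02, study 0.05) — chosen once to mirror
the size and signal structure of a real coloration–aggression literature
in which study-level clustering dominates. Per-effect sample sizes are
drawn log-uniformly over 8–120, spanning the small-n regime where the
Fisher Z variance matters. Moderators are assigned at the study level, so
effects within a study share levels, matching the tight within-study
clustering of real data. A single master seed drives fixed per-stage
substreams, so identical parameters reproduce byte-identical CSV, Newick
and truth JSON outputs.

`disguise_as_raw_statistics()` re-expresses simulated Fisher Z values as
Pearson r, t, F, chi-squared or group-mean records (algebraic inverses of
the harmonization formulas), so the conversion layer can be exercised end
to end; all routes round-trip exactly except group means, which
round-trip within 0.05 on the correlation scale at moderate n.
`censor_literature()` drops each effect with probability
$severity \cdot (1 - \Phi(z_i/SE_i))$ — small or negative effects from
imprecise studies vanish preferentially, the mechanism funnel diagnostics
target.

What the generator does **not** emulate: real search-and-screening
pipelines, study quality variation, measurement heterogeneity beyond the
moderator machinery, non-Gaussian effect distributions, or correlated
moderators. Passing tests therefore demonstrate internal consistency of
the estimation machinery under its own assumptions, not robustness to the
messiness of real literatures.

## Problem sizes used by the test suite

The packaged tests run the conjugate-oracle comparison on 20 datasets of
20 effects, parameter recovery on 200 replicates of 40 effects / 15
species / 20 studies with short (3,000-iteration) chains, Egger
calibration on 500 null literatures of 169 effects without random
structure, and DIC screening on 50 replicate pairs of 50 effects. These
sizes were chosen so the whole suite provides stable Monte-Carlo
estimates while remaining quick to run; the generator's scientific
defaults (the paper-scale preset) are unchanged by them.

## Known limitations

* $v_i = 1/(n_i - 3)$ is applied to every conversion route; biserial-
  derived effects in truth have somewhat larger sampling variance.
* $H^2$ depends on the correlation normalization of $A$; an unnormalized
  covariance would shift the variance-component scale and hence the
  share attributed to phylogeny. Sensitivity to this choice should be
  reported, not assumed away.
* Only two-way interactions, Gaussian responses, and the three named
  random terms are supported; REML/frequentist fitting is out of scope.
* At small design sizes (tens of effects) the diffuse half-Cauchy priors
  noticeably inflate weakly identified variance components; credible
  intervals for the mean are then mildly conservative (overcover) and
  posterior-mean $H^2$ is right-skewed. Both effects shrink with the
  size of the literature.
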