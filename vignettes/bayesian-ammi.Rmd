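---
title: "Bayesian AMMI models with reversible-jump dimension selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian AMMI models with reversible-jump dimension selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Multi-environment trials evaluate a set of genotypes in several
environments, usually in randomized complete blocks. The response of plot
*r* of genotype *i* in environment *j* is modelled by the linear-bilinear
(AMMI) form

```
y = X1 beta + Z g + sum_{k=1}^{t} lambda_k diag(Z alpha_k) X2 gamma_k + e,
e ~ N(0, I sigma_e^2)
```

where `beta` holds block-within-environment effects (the `X1` incidence
matrix has one column per environment-block cell, which also absorbs
environment main effects), `g` holds genotype effects, and the bilinear
terms decompose the genotype-by-environment interaction (GEI): `lambda_k`
is the k-th singular value, and `alpha_k` (length g) and `gamma_k`
(length e) are the genotypic and environmental singular vectors. The
vectors satisfy the usual SVD constraints - unit norm, mutual
orthogonality within each side, and orthogonality to the ones vector
(because the interaction is double-centered) - and the singular values are
ordered, `lambda_1 >= ... >= lambda_t >= 0`. The number of bilinear axes
`t` is itself a parameter, between 0 (purely additive model) and
`min(g, e) - 1`.

Priors: flat normal on `beta`; hierarchical `g ~ N(0, I sigma_g^2)` with
`p(sigma_g^2) ∝ 1/sigma_g^2`; `p(sigma_e^2) ∝ 1/sigma_e^2`; uniform
spherical priors on the singular vectors inside their constraint
subspaces; a positive-truncated normal `N+(0, sigma_lambda_k^2)` on each
singular value; a Poisson(mu) prior truncated to `0..t_max` on `t`; and
`mu ~ Gamma(tau, upsilon)` (defaults 1, 1). The three model families
differ only in the prior on `sigma_lambda_k^2`:

* **BAMMI** - fixed at 1e8 (effectively flat; no shrinkage);
* **BAMMIS** - Jeffreys-type `p(s2) ∝ s2^(delta - 1)` with
  `0 < delta < 1/2` (default 1/4, the midpoint of the admissible
  interval; the conditional is inverse-gamma(1/2 - delta, lambda^2/2));
* **BAMMIE** - maximum-entropy inverse-gamma(a, b) with a = 1, b = 0
  (conditional inverse-gamma(3/2, lambda^2/2)).

The two shrinkage families couple the scale to the current singular value,
so axes that carry no signal collapse toward zero - BAMMIE most
aggressively (see the `lambda_3` comparisons in `ockham_table()` output on
planted rank-2 data, tested in `test-criteria.R`).

## Gibbs sampler

All full conditionals are standard given the constraint structure:
block and genotype effects are Gaussian (the genotype update is a ridge
with `sigma_e^2 / sigma_g^2` on the diagonal); each `lambda_k` is a
truncated normal on `(0, lambda_{k-1})` with `lambda_0 = +Inf`, which
maintains the ordering; each singular vector follows a von Mises-Fisher
(vMF) distribution with natural parameter `(lambda_k / sigma_e^2)` times
the projected linear coefficient, drawn *inside* the subspace orthogonal
to the ones vector and to the other vectors of its side; the variance
components are scaled inverse chi-square; and `mu` has the conjugate
`Gamma(tau + t, upsilon + 1)` update (the truncation correction on the
Poisson normalizer is ignored, standard practice when `t_max` rarely
binds).

Two printed forms of the conditionals in the source material are
dimensionally inconsistent and were resolved to the standard conjugate
algebra: the residual used by the genotype update subtracts `X1 beta`
(not `X2 beta`), and precision terms of the form "`X + sigma_e^2
sigma^2`" are ratios `X + sigma_e^2 / sigma^2`.

Numerical choices:

* The truncated-normal sampler uses the inverse CDF in the central
  region, Robert's shifted-exponential rejection in far tails, and an
  exact-to-first-order uniform draw when the truncation interval is so
  narrow that the density is locally constant. The last case matters in
  practice: under BAMMIE the collapsed axes drive both `lambda_k` and its
  scale toward zero jointly, producing intervals like `(0, 1e-200)`.
  Scales and singular values are floored at 1e-300 to stay representable.
* The vMF sampler is the tangent-normal decomposition with Wood's
  beta-envelope rejection for the cosine, valid in any dimension; the
  1-dimensional sphere `{-1, +1}` is handled exactly. Subspace draws
  project the natural parameter onto the orthogonal complement (QR-based
  null space), sample in complement coordinates, and map back, so every
  stored state satisfies the orthonormality and centering constraints to
  machine precision (verified at run time in the test suite).
* Initialization: least squares for `beta` and `g`, SVD of the residual
  cell-mean interaction for the axes, residual moments for the variances,
  `mu = 1`.

## Reversible-jump dimension moves

After each within-model sweep the sampler makes one dimension move:
with probability `pa` it proposes adding an axis, with `pd` deleting one,
with `p0` no change (defaults 1/3 each). A birth appends axis `t+1`,
drawing its singular vectors uniformly in the constraint complement
(their conditional at `lambda = 0`), then its singular value from the
truncated-normal conditional on `(0, lambda_t)` with a diffuse scale, then
the scale from its conditional - so the dimension-matching transformation
has unit Jacobian. A death removes the last (smallest) axis, the reverse
of a birth in the nested, ordered parameterization.

The acceptance ratio for a birth is

```
a(t, t+1) = L(y | t+1) / L(y | t) * mu / (t+1) * pd / pa
```

and the death ratio is its exact inverse evaluated at the reduced model.
The likelihood in the ratio is the Gaussian density at the current
parameter values (conditional likelihood), following the
drawn-from-full-conditionals proposal style for nested models. A design
note on the proposal correction: because the axes are nested and ordered,
a birth has exactly one reverse move (delete the last axis), so the
Hastings factor is `pd/pa` with no axis-count term. Corrections that
divide by the number of axes (as sometimes written for exchangeable-axis
formulations) break detailed balance here: we verified numerically that
they produce a stationary law on `t` proportional to
`mu^t / (t! * (t+1)!)`-type sequences rather than the truncated Poisson.
The implemented kernel passes the canonical correctness check - with the
likelihood ratio forced to one, the chain's `t`-marginal matches the
truncated Poisson prior by a chi-square goodness-of-fit test (the test
thins the `t`-trace by 20 before testing, since the chi-square test
assumes independent counts and the raw trace is autocorrelated). The same
check run with `mu` sampled recovers the Poisson-Gamma mixture, as it
should.

The selected model is the dimension visited most often after burn-in
(`visit_table()`), ties broken toward the smaller dimension. A practical
property of the conditional-likelihood decision rule worth knowing: the
likelihood gain of a surplus axis, once the vMF updates have rotated it
onto residual noise structure, is roughly (sqrt(g) + sqrt(e))^2 / 2
regardless of the error variance, which dwarfs the Poisson prior penalty.
Under the flat (BAMMI) family the visited dimension therefore ratchets
upward with run length, while the shrinkage families - BAMMIE especially -
collapse such axes toward zero, after which deletion is accepted, giving a
stable modal dimension at the planted rank. Rank-recovery checks in the
test suite accordingly use the maximum-entropy family.

## Posterior summaries

Singular vectors are sign-indeterminate, so draws are aligned
(`align_signs()`) against the first retained iteration before averaging;
posterior-mean score matrices are then orthonormalized by QR with a
positive-diagonal convention (`orthonormalize_uv()`). For reversible-jump
fits, `split_draws()` provides the *conditional* summaries (iterations at
the modal dimension) and *marginal* summaries (iterations at or above it,
truncated to the leading axes). HPD intervals use the sorted
shortest-window method. Bivariate credibility regions for the first two
axes' scores are normal-approximation ellipses from the posterior score
moments at the chi-square(2) quantile; a genotype or environment whose
region covers the origin is classified *stable* (no significant GEI
contribution). Regions are computed from the aligned raw draws; the
orthonormalization correction applies only to the point-estimate score
matrices. Biplot scores are raw singular-vector coordinates (no
`sqrt(lambda)` scaling), with scaling available as an option.

## Model comparison and cross-validation

`aic_bic()` evaluates the deviance at posterior means (posterior draws
are all the sampler provides; a maximum-likelihood plug-in is not
available) with Gollob degrees of freedom `g + e - 1 - 2k` per axis plus
block cells, genotype effects and the two variances. `aicm()` is the
posterior-simulation analogue `-2 (mean - variance)` of the
log-likelihood draws. `ockham_table()` collects the criteria, the
singular-value means and the cumulative interaction sum of squares
`SS = sum(lambda_k^2)` per dimension; that sum-of-squares convention is on
the cell-mean scale (the replicate count is not folded in), and the truth
oracle `svd_truth()` uses the same convention so the two columns are
directly comparable.

Cross-validation (`run_cv()`) withholds whole genotype-by-environment
cells ("total loss of the genotype" within an environment): the observed
cells are partitioned into 10 disjoint folds of 10% each,
rejection-resampled until every genotype and every environment keeps at
least one training record in every fold. Predictions for withheld cells
average, over retained iterations, the environment-mean block effect (the
withheld cell's own block effect is unavailable) plus the genotype effect
plus the bilinear interaction; reversible-jump fits use each iteration's
own dimension (marginal response). Cor is the Pearson correlation between
observed plots and predictions, and PRESS the mean squared prediction
error. Cross-validation refits use deliberately short chains (default 800
sweeps; 1500-2500 in the acceptance script) - the fold-level correlation
stabilizes well before the full-length chains used for inference.

## Chain diagnostics

`raftery_lewis()` implements the run-length control (dichotomize at the
target quantile, choose the thinning at which a first-order Markov chain
is BIC-preferred over a second-order one, then burn-in, required length
and the dependence factor `I` from the fitted two-state chain), with the
canonical settings q = 0.025, r = 0.005, s = 0.95. `heidelberger_welch()`
implements the Cramer-von Mises stationarity test on the standardized
Brownian bridge (spectral density at zero from an AIC-selected AR fit,
p-values from the Csorgo-Faraway series) with iterative initial-segment
discarding, plus the relative-halfwidth test. Both are implemented here
because no installed package provides them; they are validated against
closed-form behaviour (independent chains give `I ≈ 1`; AR(1) chains
inflate `I` monotonically in the coefficient; published CvM critical
values are reproduced to 1e-3).

The monitored set for `diagnostic_report()` is a deliberate choice: the
variances, `mu`, the log-likelihood, each singular value, the first
coordinate of each aligned singular vector, and *estimable contrasts* of
the linear effects (`g_1 - mean(g)`, `beta_1` minus its environment's
mean). Raw `g` and `beta` coordinates share one slowly mixing direction -
the additive level can move between the flat block effects and the
ridge-shrunk genotype effects with almost no data constraint - which
inflates their dependence factors while affecting no estimable quantity.

## The synthetic-trial generator

`simulate_met_trial()` reproduces the study design used throughout:
20 genotypes x 9 environments x 3 blocks; genotype effects N(0, 12);
environment effects N(0, 1); GEI in three subgroups - genotypes 1-5 with
+|N(0, 16)| effects in environments 1-4 and -|N(0, 16)| in 5-9, genotypes
6-10 mirrored, genotypes 11-20 N(0, 1) ("stable"); the interaction matrix
double-centered; block effects exactly zero (no distribution is specified
for them); plot errors N(0, 2.5). All normal laws are parameterized as
mean/variance. Subgroup draws are independent per cell, matching the
wording "for each genotype by environment combination".
`simulate_planted_trial()` builds an exactly rank-t interaction from
centered orthonormal factors for recovery studies, and `svd_truth()`
reports the true singular values and interaction sums of squares.

What the generator does *not* emulate: incomplete designs with varying
replicate counts (the model handles them, the generator does not create
them), heteroscedastic errors across environments, spatial trends within
blocks, or genotype-specific error variances. Passing tests on this
generator therefore demonstrate correctness of the samplers and
estimators under the stated homoscedastic randomized-block conditions,
not robustness to those departures.

A scale note that matters when comparing with published summaries of this
design: per-cell |N(0, 16)| subgroup draws produce an interaction whose
true leading singular values are about (28-31, 10, 9, 7, ...) with total
interaction SS above 1000. Realized datasets reported alongside this
design in the literature show markedly smaller interaction (total SS
~260, leading values ~13, 8, 5) - closer to what per-cell magnitudes of
sd ~ 2 would give. Under the faithful parameters the third and fourth
axes are genuinely strong relative to the cell-mean noise
(sd = sqrt(2.5/3) ≈ 0.91), so dimension selection correctly favours
three or more axes and the maximum-entropy family's modal dimension is
3-4, not 2. Likewise, more of a withheld cell's variance is interaction
that must be reconstructed from estimated scores, so cross-validated
correlations (fold means around 0.75-0.86, against a perfect-knowledge
oracle of ~0.92-0.95) fall short of bounds quoted for the weaker
realization. The
generator keeps the stated parameters; the sampler's calibration is
validated independently (prior recovery, planted-rank selection, planted
singular-value HPD coverage of 95% across seeds).

## Problem sizes used by the checks

The test suite and the acceptance script scale chains to the statistic
being checked, chosen once: prior recovery uses 50,000 dimension moves on
a 6 x 5 x 2 trial with `t_max = 4` and fixed `mu = 1`; conjugate-oracle
checks use 800-1200 independent sweeps from a fixed conditioning state on
a 4 x 3 x 2 trial; recovery and selection checks use the full 20 x 9 x 3
design with 1500-5000 sweeps; cross-validation uses 10 folds with
1200-2500-sweep refits. The reversible-jump run for model selection uses
8000 sweeps after a pilot-calibrated burn-in; visit frequencies are
already stable at that length (the modal dimension is unchanged from
2500-sweep runs).

## Known limitations

* Boundary moves are rejected rather than re-normalized (`pa`, `pd`, `p0`
  are not adjusted at `t = 0` or `t = t_max`); harmless for prior
  recovery when `t_max` is slack, slightly conservative otherwise.
* The birth proposal draws the new axis's parameters from one pass of
  their conditionals; the acceptance ratio treats that pass as the full
  conditional (the usual approximation for nested bilinear models).
* AIC/BIC plug in posterior means; with strong shrinkage the posterior
  mean of a collapsed axis is not the posterior mode, so the flat and
  shrinkage families' criteria are comparable within, not across,
  families.
* The Hu-Yang-style regions assume approximate bivariate normality of the
  score posteriors; an empirical convex-hull variant is not implemented.
* Heavy unbalance is supported by the samplers, but every genotype,
  environment and block cell must retain at least one record.
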