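---
title: "Modelling seasonal relative mobility from privatized OD flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal relative mobility from privatized OD flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the design decisions
taken where the design was genuinely open. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The response and its assumptions

Aggregated smartphone mobility data arrive as weekly OD counts per pair of
administrative units. After aggregation to months, the modelled quantity is
each unit's directional monthly total relative to its January total of the
same year, on the log10 scale:

$$\log_{10} R_{a,m,y} = \log_{10}\left(x_{a,m,y} / x_{a,\mathrm{Jan},y}\right).$$

The January anchor standardizes flows within each year (every observed
unit-year has $R = 1$, $\log R = 0$ in January, enforced exactly) and the
log transform makes a Gaussian error assumption tenable — `check_gaussian()`
provides the QQ diagnostics used to verify this on any given dataset.
Outflow (FR) and inflow (TO) totals are modelled separately; self-flows are
included in both by default because internal movement dominates the totals
(a flag disables this). Unit-years whose January total is missing or below
`min_january` keep their rows with the response marked missing rather than
being dropped, so the regional models can still predict them.

A week carries no month label in calendar sources, so `iso_week_month()`
assigns a week to the month containing its Thursday (the ISO majority
rule); the synthetic weekly mode instead carries explicit month labels and
splits months 4/5-wise so the aggregation path is exercised with exact
total conservation.

## Model structure

Both pathways are additive latent Gaussian models on $\log R$ over the 24
concatenated study months (the year subscript is dropped; a per-year AR1 is
available by configuration):

* a **BYM2** spatial effect per areal unit — the reparametrized
  Besag–York–Mollié effect $b = (\sqrt{1-\phi}\,v + \sqrt{\phi}\,u)/\sqrt{\tau}$
  with $v$ iid and $u$ an ICAR component scaled to unit typical marginal
  variance, so $\tau$ is a total precision and $\phi \in (0,1)$ an
  interpretable mixing weight;
* a stationary **AR1** effect over months with lag-one correlation $\rho$
  and marginal precision $\tau$ (tridiagonal precision; its inverse has
  entries $\rho^{|i-j|}/\tau$);
* a **space × time interaction**, either exchangeable over cells (type I)
  or the Kronecker product of the AR1 structure with the scaled ICAR
  structure (type IV), with the induced per-time sum-to-zero constraints;
* fixed covariate effects with independent $N(0, 1/0.001)$ priors.

The regional model replaces the single spatial term with three nested
scales: a BYM2 over the region's country adjacency graph (each province
reads its country's effect), a BYM2 over provinces using within-country
edges only, and a BYM2 over provinces on the full regional graph including
cross-border edges. Provinces of data-missing countries are latent nodes
with no likelihood contribution; their predictions flow entirely through
the spatial and temporal structure plus covariates. Countries disconnected
from the regional graph (islands) are excluded at build time with a
message, since the spatial machinery has nothing to borrow for them.

### Identifiability of the type-I interaction

With one observation per (unit, month) cell — the standard design here — an
exchangeable interaction is exactly confounded with the Gaussian
observation error: only the sum of their variances is identified, and the
marginal likelihood is flat along that ridge. Predictions and fixed-effect
inference are unaffected (the sum is what enters them), but the noise
precision alone is not interpretable in that configuration. The
parameter-recovery study therefore uses the structured type-IV interaction,
under which all variance components are identified. The exchangeable type
remains the default for the pathway models for tractability and because
the interaction's structure is not knowable from the data at these sizes.

## Inference: empirical Bayes on an exact engine

For a Gaussian response the latent posterior given hyperparameters is
exactly Gaussian, so no integration approximation is needed conditionally.
The engine maximizes the exact log marginal likelihood plus log hyperpriors
over internally transformed hyperparameters — log precisions, logit
mixing, Fisher-z correlation — with derivative-free Nelder–Mead (default
budget 1000 evaluations, relative tolerance 1e-8, one fresh-simplex
restart from the incumbent optimum; deterministic given data and init),
then reports the exact conditional posterior at the mode. Hyperpriors
follow the conventional latent-Gaussian defaults: Gamma(1, 5e-5) on each
precision and $N(0, \text{precision } 0.15)$ on the internal logit/z
parameters; all are configurable. Credible intervals condition on the
modal hyperparameters and therefore slightly understate hyperparameter
uncertainty — the classical empirical-Bayes trade-off, acceptable here
because the latent field, not the hyperparameters, is the target.

**Constraint handling.** ICAR and type-IV priors are intrinsic; their null
spaces are spanned by per-component (and per-time) indicators. Rather than
conditioning by kriging, the engine eliminates the constraints exactly: an
orthonormal basis $Z$ of $\{x : Cx = 0\}$ is built once per model — block
by block, since every constraint involves a single block — and all
computation runs on the reduced precision $Z^\top Q Z$, which is symmetric
positive definite for every valid hyperparameter. This is exact, avoids
the cancellation hazards of jitter-plus-correction on intrinsic precisions,
and because each block's prior precision is a linear combination of
constant sparse pieces, the reduced pieces are precomputed once and each
optimizer step only reassembles and factorizes small dense blocks. At the
package's problem sizes (reduced dimension in the hundreds) this is faster
than sparse bookkeeping would be; the covariance-domain dense oracle in the
test suite verifies means, marginal standard deviations and the log
marginal likelihood to 1e-8 through an entirely different route.

Two interval flavours are reported per prediction: the linear predictor
(for mapping the latent relative-mobility surface, back-transformed as
$10^q$ per quantile — monotone, so ordering is preserved) and the posterior
predictive including observation noise (for calibration against observed
values).

## Covariates and term selection

Covariates follow a fixed dictionary of 23 codes with per-code unit
transforms (log10 for e.g. GDP per capita and accessibility minutes,
log10(x+1) for rainfall-like sums and night-time lights, identity
otherwise). Zonal statistics (mean, median, min, max, sum over non-missing
pixels; the even-count median is the mean of the two middle values)
reproduce the raster-extraction step on synthetic grids. All covariates are
mean-centred at the model's scope before interactions are formed —
interaction columns are products of centred mains and are *not* re-centred,
keeping main effects interpretable at covariate means — and regional models
additionally scale by the per-code SD so estimates are comparable across
scales. Centring constants are frozen and reused when building prediction
designs for data-missing units; whether to pool them across directions was
open, and they are computed per direction.

Terms are selected by three stages of OLS stepwise search: (1)
bidirectional AIC over all candidate mains, (2) bidirectional AIC over all
pairwise interactions of the selected mains with the mains forced in, (3)
backward pruning that repeatedly drops the least significant droppable term
above the exit level, where a main is droppable only once no surviving
interaction uses it. AIC is $n\log(\mathrm{RSS}/n) + 2k$ (constant
dropped); ties between moves go to the smaller model; the accepted-path AIC
is asserted non-increasing at every move. The exit level defaults to
**0.05**: the pruning stage exists to eliminate marginally significant
terms so that the final model's terms are the ones reported as significant
at the 5% level, and a looser 0.10 exit demonstrably leaves such marginal
terms in place (it is configurable for users who prefer the laxer
convention). After pruning, an automated version of the usual manual
cleanup drops the least significant term while any VIF exceeds 10 or the
scaled-design condition number exceeds 30 (at most 10 iterations).
Diagnostics include PRESS-based predictive R² for overfitting.

## The synthetic-data generator

The generator emulates, with known ground truth: a jittered-grid planar
hierarchy (rook-contiguous provinces per country, hence connected;
countries adjacent through their layout; cross-border edges between
mutually nearest province centroids); covariates drawn directly on the
dictionary's transformed scale and ranges (climatic codes smoothly
12-month periodic with a region-level phase, socioeconomic codes constant
within a year, calendar codes integer days per country-month); OD counts
equal to a January baseline scaled by $10^{\log R}$ with $\log R$ drawn
from the additive model (January forced to 0, mirroring the anchoring);
a distance-decay allocation placing 60% of a unit's outflow on itself and
the rest decaying with distance, so within-country and adjacent-country
movement dominates; the privacy mechanism (zero-mean Laplace noise of
scale $1/\epsilon$, default $\epsilon = 0.66$; removal of cells whose noisy
count falls below 100; half-away-from-zero rounding of retained counts;
the $\delta$ parameter carried as metadata only — the threshold mechanism
is what is simulated, not the formal accounting); and country-shaped
missingness hitting each region's requested missing-province fraction as
closely as its country sizes allow.

January baselines are drawn log-uniform on $[10^3, 10^5]$ — the marginal
distribution of real OD counts is not documented anywhere usable, so this
is a modelling choice, made once: it keeps suppression rare on the
diagonal while tail OD pairs do get suppressed, which is the qualitative
behaviour that matters downstream. What the generator does **not**
emulate: user-level trips and their semantic segmentation, reporting
biases of opted-in smartphone users, true covariate–mobility relationships
(effects are whatever the chosen truth says), and real geography. Passing
tests on synthetic data therefore demonstrate the correctness and
calibration of the machinery under the stated model, not the realism of
any substantive conclusion about mobility.

## Numerical choices and degenerate inputs

* ICAR scaling uses the per-component eigendecomposition of the structure;
  the constrained generalized-inverse marginal variances are normalized to
  geometric mean 1. Singleton components are pinned at zero by their
  constraint and left unscaled.
* $\phi$ is kept in the open interval via its logit in assembled models;
  the exact $\phi \in \{0, 1\}$ limits are available through
  `bym2_effect()`.
* Reduced prior blocks are factorized by dense Cholesky; a failure is
  reported as a named non-positive-definite error rather than papered over
  with jitter.
* Rank-deficient OLS designs raise a singular-design error; zero-variance
  covariates raise a degenerate-covariate error when scaling is requested.
* Month ranks use dense ranks with the earlier month taking the lower rank
  on ties; the capture flag treats interval endpoints as captured;
  imprecision uses the $n-1$ denominator. All three conventions are
  undocumented in typical sources and had to be fixed somewhere.
* Countries are gated before fitting (default: at least 2 provinces and 6
  observed months); gated-out scopes are skipped with a recorded reason,
  never a crash.

## Problem sizes of the shipped studies

Chosen as the package's own study conditions: parameter recovery uses 50
replicates (30 in the acceptance report) of a 20-province × 24-month
country model with true $\beta = (0.05, 0.2, 0.05)$, noise precision 100
and type-IV interaction; interval calibration uses 50 replicates of 1000
observations over a 100-cell field, evaluated against replicate
observations at the true hyperparameters (capture on the training
observations themselves is mildly conservative because the intervals were
fitted to them); selection recovery uses 100 seeds of $n = 500$,
signal-to-noise 10, two true mains plus their interaction among 10
candidates; the hold-out study uses a 4-country × 4-province region with
strong country-level and cross-border spatial effects, withholding one
full country per seed. The end-to-end reproducibility check runs the whole
two-region pipeline twice and compares file checksums.

## Known limitations

* Empirical-Bayes intervals ignore hyperparameter uncertainty; a coarse
  grid integration would widen them and is a natural extension.
* The exchangeable interaction's variance is confounded with observation
  noise in single-observation-per-cell designs (see above).
* The three-scale regional spatial decomposition is weakly identified —
  the within-country and regional province effects compete for the same
  variation — which is tolerable for prediction but means individual
  spatial variance components should not be over-interpreted.
* The stepwise procedure inherits the usual selective-inference caveat:
  p-values and intervals of the final Bayesian fit do not account for the
  search that chose its terms.
* The generator's covariate fields are smooth and stationary; real
  covariates have discontinuities and trends the models would confront in
  practice.
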