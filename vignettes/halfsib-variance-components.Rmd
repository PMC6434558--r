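---
title: "Variance components, heritability and reaction norms in nested half-sib designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components, heritability and reaction norms in nested half-sib designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfsibQG)
```

## The design and the model

`halfsibQG` analyses a nested paternal half-sib, maternal full-sib
breeding design: each sire is mated to several dams, each dam contributes
a full-sib family, and families are created in temporal mating blocks
(sires nested in blocks, dams nested in sires).  Each family is split
between two rearing environments — a high- and a low-density treatment —
and offspring of both sexes are phenotyped once (body mass, development
time, boldness, total open-field activity) or repeatedly (per-minute
activity over a five-minute trial).

For a trait $y_{ijklm}$ the basic model is the Gaussian linear mixed
model

$$y = \mu + \beta_{dens}\,\mathrm{low} + \beta_{sex}\,\mathrm{male} +
\beta_{d \times s}\,\mathrm{low \cdot male} + b_{block} + s_{sire} +
d_{dam} + t_{day} + \varepsilon,$$

with independent Gaussian random intercepts for block, sire-in-block,
dam-in-sire and (for behavioural assays, which are scored over several
days) test day.  High density and female are the reference levels.
Fitting is by REML; variances are bounded at zero and correlations at
$\pm 1$ by the parameterisation of the optimizer, so boundary estimates
are reported as exactly 0 and flagged as singular rather than warned
away.

In this design the among-sire variance estimates one quarter of the
additive genetic variance, so the package uses $V_A = 4 V_S$ and

$$h^2 = \frac{4 V_S}{4 V_S + V_M + V_{block} + V_R}, \qquad
  m^2 = \frac{V_M}{4 V_S + V_M + V_{block} + V_R}.$$

Two reporting conventions deserve emphasis because they are easy to get
silently wrong:

* **Test-day (and individual-level) variance is excluded from the
  $h^2$/$m^2$ denominators** but **included** in the total used for
  per-component percentages of phenotypic variance, where $V_S$ enters
  once (not multiplied by 4).  This split is forced by the arithmetic of
  the published tables the package reproduces in its acceptance checks:
  for the boldness components, $m^2 = 0.020/2.459 \approx 0.01$ only if
  the test-day variance is left out, while the dam share of $V_P$ is
  $0.020/2.552 \approx 0.8\%$ only if it is kept in.
* For repeated per-minute traits, the individual intercept and slope
  variances likewise stay out of the $h^2$/$m^2$ denominators by default
  (the published ratio definitions name only $V_A$, $V_M$, $V_{block}$,
  $V_R$); `qg_summary(individual_in_denominator = TRUE)` switches to the
  alternate convention, which cannot be ruled out from the printed
  values for that trait.

### With and without block

Families cannot be randomized over temporal blocks — each family exists
in exactly one block — so the block intercept can absorb genuine
family-level (especially sire-level) variance.  `block_sensitivity()`
therefore fits every model twice, with and without the block intercept,
and flags the response of $V_A$ and $V_M$: a rise in both when block is
dropped is consistent with a block effect independent of families, while
a rise confined to $V_A$ suggests block variance was genetic variance in
disguise.  A caveat the package's own simulations make explicit: with
sires fully nested in blocks, an independent block effect also surfaces
almost entirely in $V_S$ when block is dropped (dam contrasts are
within-block), so the "both rise" signature is weak in this design and
the flag should be read together with the component deltas it reports.
The rise threshold is 2% of the with-block phenotypic variance by
default (`rise_tol`), a deliberately coarse screen rather than a test.

### Reaction-norm G×E

Genotype-by-environment interaction is modelled as a sire-level reaction
norm: a correlated random (intercept, slope) pair over the density
indicator within sire, high density being the intercept level.  The
slope variance and the intercept–slope covariance are tested jointly by
a likelihood-ratio test with 2 degrees of freedom against the
intercept-only model with the same fixed part (both fits REML).  Because
the null pins a variance to the boundary of its parameter space, the
chi-square reference distribution is conservative — the p-value can be
up to twice as large as under the correct 50:50 mixture — so `lrt_random()`
reports the unmodified p-value (matching the reporting convention of the
analysis the package reproduces) with the mixture p-value alongside and
a conservativeness note attached.  The same machinery runs with dams as
the slope factor for the maternal-by-environment analogue.  When the
G×E test is significant, `treatment_specific_components()` refits the
intercept-only structure to each density subset separately, with density
terms removed from the fixed part.

### Repeated per-minute activity

For the per-minute trait three random structures are compared, all with
the same fixed part (density, sex, their interaction, standardized time,
time squared, days after eclosion): (1) individual, dam, sire, block and
test-day intercepts; (2) a correlated individual (intercept, time-slope)
pair instead of the plain individual intercept; (3) a correlated sire
(intercept, time-slope) pair with the individual intercept retained.
Models 2 and 3 are each tested against model 1 by 2-df LRTs; model 1 is
kept unless a larger model is significant, in which case the significant
model with the greatest likelihood (equivalently lowest AIC, the fixed
parts being identical) wins.  REML comparison is valid here precisely
because the fixed parts agree; `information_criteria()` counts only
variance parameters under REML and adds fixed coefficients under ML.

### Bootstrap for fixed effects

Confidence intervals and p-values for fixed effects come from a case
bootstrap: individuals (whole individuals, for repeated measures) are
resampled with replacement, the model is refit on each resample, and
percentile 95% intervals are taken; the two-sided p-value is
$2\min(P(\hat\beta^* \le 0), P(\hat\beta^* \ge 0))$ floored at
$1/(B+1)$.  The resampling unit is the individual — not residuals and
not whole families — which is the common default for case resampling
and, for repeated measures, keeps within-individual correlation intact;
duplicated individuals are relabelled as distinct levels when the
individual is itself a grouping factor.  The reference analysis uses
$B = 10{,}000$; the test suite scales $B$ down (500 inner resamples in
the coverage study) since percentile endpoints stabilise well before
that.  Internally, resampled refits reuse the incidence-matrix rows of
the original fit and re-run only the profiled-REML optimisation, which
makes the $200 \times 500$ coverage study feasible on one CPU.

## The simulator

`build_pedigree()` generates the hierarchy with configurable per-block
sire counts (explicit or a min–max range under a total cap), dams per
sire, offspring per dam per treatment (default 6, 3 of each sex) and an
independent per-offspring attrition probability.  The defaults are the
study conditions the package models: 7 blocks, 23 sires with a median of
3 per block (range 2–6), 59 dams, 12 planned offspring per dam, and
`cricket_design()` adds the attrition rate (29/708) that thins the 708
planned offspring to about the 679 actually analysed.  The per-block
sire allocation `c(2, 2, 3, 3, 3, 4, 6)` is one explicit choice
consistent with the published median and range (the exact per-block
counts were not published); per-sire dam counts are likewise drawn from
the 2–3 range under the total of 59.

`simulate_trait()` adds Gaussian effects at every level — including
correlated sire (intercept, slope) pairs for G×E and, in
`simulate_repeated_activity()`, correlated individual (intercept,
time-slope) pairs — and exports every latent effect in a truth
attribute, so the test suite can verify the bookkeeping identity
(phenotype minus residual equals the sum of fixed part and ancestral
effects) exactly, and recovery tests can compare estimates with known
truth.  Test days are assigned round-robin within family over a shuffled
day order, so each family spans several days and each day several
families, as in the behavioural-testing protocol.  Emergence latencies
are generated on the $\log(\text{latency}+1)$ scale, back-transformed,
and right-censored at 1800 s with a censoring flag;
`boldness_score()` then reverse-scores them as
$\log(1801) - \log(\min(\text{latency}, 1800) + 1)$.  The cap transform
is used as the "maximum value" (not the sample maximum): whenever
censored animals are present the two coincide, and the cap keeps scores
comparable across datasets.  The $+1$ offset is required because
latencies of exactly 0 s occur; the published analysis does not state
its offset, and this is the documented convention here.

What the simulator does *not* emulate: non-Gaussian traits, dominance or
epistatic variance, multi-generation pedigrees, selection, or the
husbandry-level group-merging rules of the original rearing protocol
(these affect animal care, not the statistical model).  Passing recovery
tests on simulated data therefore shows the estimators are correct for
the assumed Gaussian variance-component model, not that real data meet
those assumptions.

## Numerical choices

* Fitting is delegated to `lme4`'s profiled-REML machinery, the standard
  implementation for this model class.  The precise default optimizer is
  BOBYQA with `rhoend = 1e-10`; at this tolerance REML estimates on
  balanced fixtures agree with closed-form expected-mean-squares
  estimators to better than $10^{-6}$ relative error, which the test
  suite asserts against independently coded Henderson formulas.  A
  non-converged fit is retried once with the nloptwrap optimizer and
  flagged, never silenced.  Bootstrap refits use looser tolerances
  (`1e-6`), ample for percentile endpoints.
* Nesting is encoded by composite labels (`sire_in_block`,
  `dam_in_sire`) built by `prepare_pheno()`, so grouping is explicit in
  the data rather than in formula syntax, and group relabelling or row
  reordering cannot change a fit (asserted in the suite).
* Missing values are deleted row-wise per model and counted
  (`$n_dropped`), mirroring per-analysis sample-size variation in the
  source data.
* LRT statistics are clamped at zero; identical full/reduced structures
  give the degenerate $\chi^2 = 0$, $p = 1$.

## Problem sizes used by the checks

The package's own acceptance checks run at deliberately chosen scales:
parameter recovery uses 200 simulated datasets at the study scale (23
sires / 59 dams / ~679 offspring) with truth proportioned like the
published mass-at-eclosion components; the boundary-conservativeness
check uses 500 replicates of the 2-df G×E test under a zero slope
variance; model selection uses 100 replicates of the per-minute
comparison; and bootstrap coverage uses 200 outer simulations of a
compact 20-dam maternal array with 500 inner resamples.  These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
while keeping the default suite runnable on a single CPU.

One acceptance property deserves an honest caveat.  With truth
proportioned like the mass-at-eclosion row, the dam variance is below
print precision — effectively zero — and a REML estimator constrained to
be nonnegative cannot be mean-unbiased at a boundary truth: its mean
over replicates is strictly positive (about $0.8\sigma$ of its sampling
spread, ~126 trait units² here) no matter how correct the
implementation.  The recovery check therefore passes the two-MC-SE
unbiasedness band for the interior components ($V_S$, $V_{block}$,
$V_R$) and for median heritability error, while the dam component's
sub-check fails for this structural reason; the suite keeps the strict
assertion rather than widening it, and this paragraph is the analysis of
why.

## Known limitations

Only Gaussian responses are supported (the source analysis's Cox-model
cross-checks are out of scope), random effects beyond the structures
above (crossed terms, multi-trait covariances, profile-likelihood or
bootstrap intervals for variance components) are not implemented, and
the bootstrap treats the individual as the exchangeable unit — for
strongly family-correlated fixed-effect designs a family-level bootstrap
would be the conservative alternative.
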