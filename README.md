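# halfsibQG

Quantitative-genetic analysis of nested paternal half-sib / maternal
full-sib breeding designs with split rearing environments, plus a
simulator that generates such designs with known ground truth.

## The problem

A classic way to ask how much of the variation in a trait is genetic is a
nested half-sib breeding design: sires are each mated to several dams,
dams are nested in sires, and families are created in temporal mating
blocks.  Splitting each full-sib family between two rearing environments
(here: high vs low density) additionally lets one ask whether genotypes
*respond differently* to the environment (G×E).  This package implements
that analysis for Gaussian traits:

- **Variance partitioning** by REML linear mixed models with random
  intercepts for dam-in-sire, sire-in-block, block and (for behavioural
  assays) test day, and for repeated per-minute measures an individual
  intercept or correlated intercept + time slope.
- **Heritability and maternal effects.**  Among-sire variance estimates a
  quarter of the additive variance, so `V_A = 4 V_S` and

  `h² = 4 V_S / (4 V_S + V_M + V_block + V_R)`,
  `m² = V_M / (4 V_S + V_M + V_block + V_R)`,

  with a without-block variant (`V_block` dropped) because families are
  not randomized over blocks, so the block intercept can absorb genetic
  variance.
- **Reaction-norm G×E**: correlated random intercept + slope over the
  density treatment within sire (high density is the intercept level),
  tested by a 2-df likelihood-ratio test.  Variance nulls lie on the
  boundary of the parameter space, so the unmodified chi-square p-value
  is conservative (up to 2× too large); the 50:50 mixture p-value is
  reported alongside.
- **Fixed effects** (density, sex, their interaction, timing covariates)
  with case-bootstrap percentile confidence intervals (individuals, or
  whole individuals for repeated measures, resampled with replacement).
- **A synthetic-data module** that simulates the full design
  (blocks → sires → dams → offspring, treatment and sex assignment,
  test-day rotation, attrition, right-censored latencies) and exports the
  latent effects, so every estimator can be checked against known truth.

## Worked example

```r
library(halfsibQG)

# a study-scale design: 7 blocks, 23 sires, 59 dams, ~679 offspring
design <- cricket_design(seed = 1)

truth <- trait_model(mu = 0, V_S = 1299, V_M = 300, V_block = 2096,
                     V_R = 14439, V_slope = 600, r_is = -0.2)
ph <- simulate_trait(design, truth, seed = 2)

spec <- model_spec("value",
                   fixed  = c("treatment", "sex", "treatment:sex"),
                   random = list(ran_intercept("dam_in_sire"),
                                 ran_intercept("sire_in_block"),
                                 ran_intercept("block")))
fit <- fit_reml(spec, ph)
qg_summary(fit)
```

```
Trait: value  (with block, subset: all, n = 670)
     component   variance pct_VP
   dam_in_sire   556.4774    2.8
 sire_in_block  2356.2935   12.0
         block  2322.1260   11.8
      residual 14375.1200   73.3
h2 = 0.35   m2 = 0.02
```

The percentages are each component's share of the summed fitted
components (sire counted once); `h2`/`m2` use the `4 V_S` numerator and
denominator above.  At 23 sires a single replicate is noisy — here the
sire component drew high, so ĥ² (0.35) overshoots the generating value
(0.24); `recovery_harness()` quantifies exactly this spread over many
replicates.  The G×E test on the same data:

```r
gxe_test(ph)
```

```
Reaction-norm G x E test (slopes within sire_in_block)
  slope variance 825.2, intercept-slope correlation -0.314
LRT: chi2 = 1.292, df = 2, p = 0.5241 (mixture p = 0.3899)
```

`run_full_analysis(analysis_config(...))` chains all the steps per trait
(with/without-block pair, G×E, treatment-specific components when G×E is
significant, bootstrap CIs, and the three-way random-structure comparison
for per-minute activity) and writes CSV/JSON artifacts; see
`inst/extdata/config_template.yaml`.

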