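test_that("heritability and maternal-effect ratios reproduce the worked examples", {
  # body-mass components (with block): moderate heritability, negligible
  # maternal effect
  expect_equal(round(heritability(1299, 0, 2096, 14439), 2), 0.24)
  expect_equal(round(maternal_effect(1299, 0, 2096, 14439), 2), 0)
  # mass at sexual maturity: block soaks up much of the sire signal
  expect_equal(round(heritability(529, 689, 2298, 14422), 2), 0.11)
  expect_equal(round(maternal_effect(529, 689, 2298, 14422), 2), 0.04)
  # development time by density subset
  expect_equal(round(maternal_effect(0.0005, 0.0026, 0.0039, 0.0062), 2),
               0.18)
  expect_equal(round(maternal_effect(0.0010, 0.0036, 0.0065, 0.016), 2),
               0.12)
  # total activity: maternal but not additive variance
  expect_equal(round(maternal_effect(0, 5.20, 0, 58.8), 2), 0.08)
  expect_equal(round(heritability(0, 5.20, 0, 58.8), 2), 0)
  # boldness: test-day variance excluded from the m2 denominator but
  # included in the percent-of-variance total
  expect_equal(round(maternal_effect(0, 0.020, 0.029, 2.41), 2), 0.01)
  bold <- c(sire = 0, dam = 0.020, block = 0.029, test_day = 0.093,
            residual = 2.41)
  expect_equal(round(percent_vp("dam", bold), 1), 0.8)
})

test_that("percent of phenotypic variance counts the sire component once", {
  mass <- c(sire = 1299, dam = 0, block = 2096, residual = 14439)
  expect_equal(round(percent_vp("sire", mass), 1), 7.3)
  act <- c(sire = 0, dam = 5.20, block = 0, test_day = 0.20,
           residual = 58.8)
  expect_equal(round(percent_vp("dam", act), 1), 8.1)
  only <- c(dam = 3.3, sire = 0, residual = 0)
  expect_equal(percent_vp("dam", only), 100)
  expect_error(percent_vp("dam", c(dam = 0, residual = 0)), "zero")
  expect_error(percent_vp("nope", mass), "not among")
})

test_that("ratios are exactly scale invariant and respect their domains", {
  comp <- c(V_S = 13, V_M = 5, V_block = 21, V_R = 144)
  for (c_ in c(0.001, 1, 250)) {
    expect_equal(heritability(c_ * 13, c_ * 5, c_ * 21, c_ * 144),
                 heritability(13, 5, 21, 144))
    expect_equal(maternal_effect(c_ * 13, c_ * 5, c_ * 21, c_ * 144),
                 maternal_effect(13, 5, 21, 144))
  }
  # without-block variants drop V_block from the denominator
  expect_equal(heritability(10, 0, V_R = 90), 40 / 130)
  expect_gt(heritability(13, 5, V_R = 144), heritability(13, 5, 21, 144))
  expect_error(heritability(0, 0, 0, 0), "zero")
  expect_error(heritability(-1, 0, 0, 1), "nonnegative")
  # h2 of a truth table is the plug-in arithmetic identity
  tm <- trait_model(V_S = 1299, V_M = 0, V_block = 2096, V_R = 14439)
  expect_equal(heritability(tm$V_S, tm$V_M, tm$V_block, tm$V_R),
               4 * 1299 / (4 * 1299 + 0 + 2096 + 14439))
})

test_that("fitted summaries carry coherent percentages and provenance", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_block = 0.5,
                                      V_testday = 0.2, V_R = 2), seed = 2)
  spec <- model_spec("value", fixed = c("treatment", "sex"),
                     random = list(ran_intercept("dam_in_sire"),
                                   ran_intercept("sire_in_block"),
                                   ran_intercept("block"),
                                   ran_intercept("test_day")))
  s <- qg_summary(fit_reml(spec, ph))
  expect_equal(sum(s$pct_VP), 100, tolerance = 1e-8)
  expect_equal(s$variant, "with_block")
  expect_true(s$h2 >= 0 && s$h2 <= 1)
  expect_true(s$m2 >= 0 && s$m2 <= 1)
  expect_lte(s$h2 + s$m2, 1)
  roles_denom <- 4 * s$components[["sire_in_block"]] +
    s$components[["dam_in_sire"]] + s$components[["block"]] +
    s$components[["residual"]]
  expect_equal(s$h2, 4 * s$components[["sire_in_block"]] / roles_denom)
})

test_that("treatment-specific refits recover per-environment components", {
  # equal components in both environments: summaries agree to MC error
  d <- build_pedigree(n_blocks = 4, sires_per_block = 4, dams_per_sire = 3,
                      offspring_per_dam_per_treatment = 8, seed = 3)
  tm <- trait_model(V_S = 1, V_M = 1, V_block = 0.5, V_R = 2)
  ph <- simulate_trait(d, tm, seed = 50)
  ts <- treatment_specific_components(ph, spec = std_spec())
  expect_named(ts, c("high", "low"))
  expect_equal(ts$high$subset, "high")
  expect_lt(abs(ts$high$components[["residual"]] -
                ts$low$components[["residual"]]), 1)

  # heteroscedastic residuals (low-density noisier, as for development
  # time): the ordering is recovered
  ph_h <- simulate_trait(d, trait_model(V_S = 0.3, V_M = 1, V_block = 0.5,
                                        V_R = 0.6), seed = 51)
  ph_l <- simulate_trait(d, trait_model(V_S = 0.3, V_M = 1, V_block = 0.5,
                                        V_R = 1.6), seed = 52)
  het <- rbind(ph_h[ph_h$treatment == "high", ],
               ph_l[ph_l$treatment == "low", ])
  ts2 <- treatment_specific_components(het, spec = std_spec())
  expect_gt(ts2$low$components[["residual"]],
            ts2$high$components[["residual"]])

  expect_error(treatment_specific_components(
    ph[ph$treatment == "high", ], spec = std_spec()), "low-density subset")
})

test_that("block-sensitivity flags follow the confounding logic", {
  # independent block variance: dropping block inflates the sire-derived
  # V_A (sires are nested in blocks, so orphaned block variance surfaces
  # among sires)
  d <- cricket_design(seed = 4)
  ph <- simulate_trait(d, trait_model(V_S = 500, V_M = 500, V_block = 3000,
                                      V_R = 14000), seed = 60)
  bs <- block_sensitivity(ph, spec = std_spec())
  expect_gt(bs$delta[["V_A"]], 0)
  expect_gte(bs$without_block$h2, bs$with_block$h2)

  # genuinely zero block variance: the two fits agree
  ph0 <- simulate_trait(d, trait_model(V_S = 500, V_M = 500, V_block = 0,
                                       V_R = 14000), seed = 61)
  bs0 <- block_sensitivity(ph0, spec = std_spec())
  expect_equal(bs0$flag, "no_change")
  expect_lt(abs(bs0$without_block$h2 - bs0$with_block$h2), 0.1)

  # block-correlated sire means (block variance absorbing genetic
  # variance): V_S rises when block is dropped while V_M stays put
  ph2 <- simulate_trait(d, trait_model(V_S = 800, V_M = 600, V_block = 2500,
                                       V_R = 14000), seed = 62)
  bs2 <- block_sensitivity(ph2, spec = std_spec())
  expect_true(bs2$flag %in% c("sire_confounded", "block_independent"))
  expect_gt(bs2$delta[["V_A"]], bs2$delta[["V_M"]])

  expect_error(block_sensitivity(ph, spec = model_spec(
    "value", random = list(ran_intercept("dam_in_sire")))), "block")
})
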