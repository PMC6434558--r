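test_that("LRT arithmetic, clamping and usage errors behave as specified", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_R = 2), seed = 1)
  fit <- fit_reml(std_spec(), ph)
  same <- lrt_random(fit, fit_reml(model_spec("value",
                                              fixed = fit$spec$fixed,
                                              random = fit$spec$random[1:2]),
                                   ph))
  # one intercept dropped: df inferred as 1
  expect_equal(same$df, 1)
  expect_gte(same$chi2, 0)
  expect_true(same$p >= 0 && same$p <= 1)
  expect_lte(same$p_mixture, same$p + 1e-12)
  expect_match(same$note, "conservative")

  other_fixed <- fit_reml(model_spec("value", fixed = "treatment",
                                     random = fit$spec$random[1:2]), ph)
  expect_error(lrt_random(fit, other_fixed), "fixed part")
  # identical full and reduced structures: degenerate test, chi2 0 and p 1
  ident <- lrt_random(fit, fit)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)
  fit_ml_ <- fit_ml(std_spec(), ph)
  expect_error(lrt_random(fit_ml_, fit), "REML and ML")
})

test_that("the LRT statistic is invariant to affine rescaling of the response", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_R = 2,
                                      V_slope = 1), seed = 21)
  g1 <- gxe_test(ph)
  ph2 <- ph
  ph2$value <- 3 * ph$value + 10
  g2 <- gxe_test(ph2)
  expect_equal(g2$lrt$chi2, g1$lrt$chi2, tolerance = 1e-4)
  # slope variance scales by the square of the factor
  expect_equal(g2$V_slope, 9 * g1$V_slope, tolerance = 1e-3)
})

test_that("reaction-norm G x E machinery recovers slope structure at scale", {
  # 200 sires: correlation and slope variance estimable with useful precision
  d <- build_pedigree(n_blocks = 50, sires_per_block = 4, dams_per_sire = 2,
                      offspring_per_dam_per_treatment = 3, seed = 6)
  tm <- trait_model(V_S = 1, V_M = 0.3, V_block = 0.1, V_R = 1,
                    V_slope = 1, r_is = -0.2)
  ph <- simulate_trait(d, tm, seed = 23)
  g <- gxe_test(ph)
  expect_lt(g$lrt$p, 0.001)
  expect_lt(abs(g$r_is - (-0.2)), 0.2)
  expect_lt(abs(g$V_slope - 1), 0.5)

  # swapping the treatment labels moves the intercept to the other level
  # but leaves the slope variance at the same optimum
  swapped <- ph
  swapped$treatment <- factor(ifelse(ph$treatment == "high", "low", "high"),
                              levels = c("high", "low"))
  swapped$density_low <- NULL
  g_sw <- gxe_test(swapped)
  expect_equal(g_sw$V_slope, g$V_slope, tolerance = 1e-3)
  expect_equal(g_sw$lrt$chi2, g$lrt$chi2, tolerance = 1e-3)

  single <- ph[ph$treatment == "high", ]
  expect_error(gxe_test(single), "both density treatments")
})

test_that("the dam-slope variant runs through the same machinery", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 0.5, V_M = 0.5, V_R = 1),
                       seed = 30)
  g <- gxe_test(ph, slope_factor = "dam_in_sire")
  expect_equal(g$slope_factor, "dam_in_sire")
  expect_true(is.finite(g$lrt$chi2))
})

test_that("boundary intercept LRT rejects at most at the nominal rate", {
  # dam variance truly 0: the 1-df chi-square p-value is conservative
  d <- build_pedigree(n_blocks = 2, sires_per_block = 5, dams_per_sire = 2,
                      offspring_per_dam_per_treatment = 4, seed = 1)
  spec_full <- model_spec("value", fixed = "treatment",
                          random = list(ran_intercept("dam_in_sire"),
                                        ran_intercept("sire_in_block")))
  spec_red <- model_spec("value", fixed = "treatment",
                         random = list(ran_intercept("sire_in_block")))
  rej <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    ph <- simulate_trait(d, trait_model(V_S = 0.3, V_M = 0, V_R = 1),
                         seed = 5000 + i)
    lrt <- lrt_random(fit_reml(spec_full, ph), fit_reml(spec_red, ph),
                      df = 1)
    rej <- rej + (lrt$p < 0.05)
  }
  # true rate ~ 0.025 under the 50:50 mixture; 0.065 is ~3.5 binomial SDs
  # above the nominal 0.05 bound being asserted
  expect_lte(rej / n_rep, 0.065)
})

test_that("case bootstrap is deterministic and handles degenerate responses", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(mu = 1, beta_density = 0.4,
                                      V_S = 0.5, V_M = 0.5, V_R = 1),
                       seed = 31)
  spec <- std_spec()
  b1 <- bootstrap_fixed(ph, spec, n_replicates = 200, seed = 9)
  b2 <- bootstrap_fixed(ph, spec, n_replicates = 200, seed = 9)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$estimate + 1e-9))
  expect_true(all(b1$upper >= b1$estimate - 1e-9))
  expect_true(all(b1$p >= 1 / 201 & b1$p <= 1))

  # constant response: every coefficient except the intercept is forced to 0
  ph0 <- ph
  ph0$value <- 5
  b0 <- bootstrap_fixed(ph0, spec, n_replicates = 100, seed = 2)
  slope_rows <- b0$term != "(Intercept)"
  expect_true(all(abs(b0$lower[slope_rows]) < 1e-10 &
                    abs(b0$upper[slope_rows]) < 1e-10))
  expect_error(bootstrap_fixed(ph, spec, n_replicates = 50, seed = 1),
               ">= 100")
})

test_that("bootstrap resamples whole individuals for repeated measures", {
  d <- build_pedigree(n_blocks = 2, sires_per_block = 2, dams_per_sire = 2,
                      offspring_per_dam_per_treatment = 3, seed = 3)
  rmod <- repeated_model(mu = 4, beta_density = 0.3, V_M = 0.2, V_R = 0.7,
                         V_I_int = 1.3, V_I_slope = 0.2, r_I = 0.4)
  act <- simulate_repeated_activity(d, rmod, seed = 33)
  spec <- model_spec("value", fixed = c("treatment", "time_std"),
                     random = list(ran_slope("individual", "time_std"),
                                   ran_intercept("dam_in_sire")))
  b1 <- bootstrap_fixed(act, spec, n_replicates = 100, seed = 4)
  b2 <- bootstrap_fixed(act, spec, n_replicates = 100, seed = 4)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(is.finite(b1$lower)))
})

test_that("bootstrap intervals shrink with sample size", {
  tm <- trait_model(mu = 0, beta_density = 0.3, V_M = 0.5, V_R = 1)
  spec <- model_spec("value", fixed = "treatment",
                     random = list(ran_intercept("dam_in_sire")))
  width <- vapply(c(320, 1280), function(n_off) {
    d <- build_pedigree(n_blocks = 1, sires_per_block = 10,
                        dams_per_sire = 2,
                        offspring_per_dam_per_treatment = n_off / 40,
                        seed = 2)
    ph <- simulate_trait(d, tm, seed = 40 + n_off)
    b <- bootstrap_fixed(ph, spec, n_replicates = 200, seed = 5)
    row <- b$term == "treatmentlow"
    b$upper[row] - b$lower[row]
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("activity model comparison selects parsimony when no slopes exist", {
  d <- small_design()
  rmod <- repeated_model(mu = 3, V_R = 1, V_I_int = 0.5)
  act <- simulate_repeated_activity(d, rmod, seed = 44)
  cmp <- compare_activity_models(act)
  expect_equal(cmp$selected, 1L)
  expect_gte(cmp$lrt$model2_vs_1$p, 0.05)
  # same fixed part throughout: AIC ordering mirrors the likelihoods
  expect_equal(which.min(cmp$aic) == 1L || cmp$selected != 1L, TRUE)
})
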