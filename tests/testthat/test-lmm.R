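test_that("REML matches the expected-mean-squares oracle in one-way balanced data", {
  set.seed(42)
  g <- 12; n <- 8
  grp <- factor(rep(sprintf("g%02d", 1:g), each = n))
  y <- rnorm(g, 0, 2)[as.integer(grp)] + rnorm(g * n, 0, 1.5)
  tab <- data.frame(dam = grp, value = y)
  ms <- anova(lm(y ~ grp))$"Mean Sq"
  v_between <- (ms[1] - ms[2]) / n          # EMS closed form
  fit <- fit_reml(model_spec("value", random = list(ran_intercept("dam"))),
                  tab)
  expect_lt(abs(fit$components[["dam"]] - v_between) / v_between, 1e-6)
  expect_lt(abs(fit$components[["residual"]] - ms[2]) / ms[2], 1e-6)

  # ML shrinks the between-group mean square by the known (g-1)/g factor
  fit_m <- fit_ml(model_spec("value", random = list(ran_intercept("dam"))),
                  tab)
  v_ml <- ((1 - 1 / g) * ms[1] - ms[2]) / n
  expect_lt(abs(fit_m$components[["dam"]] - v_ml) / v_ml, 1e-6)
  # identical refit reproduces the log-likelihood exactly
  refit <- fit_ml(model_spec("value", random = list(ran_intercept("dam"))),
                  tab)
  expect_equal(refit$loglik, fit_m$loglik)
})

test_that("REML matches Henderson estimators in the balanced nested design", {
  tab <- balanced_nested_table(s = 10, d = 2, k = 5, seed = 7)
  oracle <- henderson_nested(tab, k_per_dam = 5, dams_per_sire = 2)
  fit <- fit_reml(model_spec("value",
                             random = list(ran_intercept("dam"),
                                           ran_intercept("sire"))), tab)
  expect_lt(abs(fit$components[["sire"]] - oracle$V_S) / oracle$V_S, 1e-6)
  expect_lt(abs(fit$components[["dam"]] - oracle$V_M) / oracle$V_M, 1e-6)
  expect_lt(abs(fit$components[["residual"]] - oracle$V_R) / oracle$V_R,
            1e-6)
})

test_that("design expansion produces the expected column structure", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_R = 1), seed = 1)
  # intercept-only fixed part + one grouping factor
  bd <- build_design(model_spec("value",
                                random = list(ran_intercept("dam_in_sire"))),
                     ph)
  expect_equal(ncol(bd$X), 1)
  expect_equal(ncol(bd$Z[[1]]), 18)  # 3 blocks x 3 sires x 2 dams
  # density x sex: 4 fixed columns including the intercept
  bd2 <- build_design(std_spec(), ph)
  expect_equal(ncol(bd2$X), 4)
  # correlated intercept+slope: 2 columns per sire
  bd3 <- build_design(
    model_spec("value",
               random = list(ran_slope("sire_in_block", "density_low"))), ph)
  expect_equal(ncol(bd3$Z[[1]]), 2 * 9)
  expect_error(build_design(model_spec("value",
                                       random = list(ran_intercept("nope"))),
                            ph),
               "missing")
  expect_error(
    build_design(model_spec("value", fixed = c("treatment", "density_low"),
                            random = list(ran_intercept("block"))), ph),
    "rank deficient")
})

test_that("fits are invariant to row order and group relabeling", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_block = 0.5,
                                      V_R = 2), seed = 9)
  fit <- fit_reml(std_spec(), ph)
  set.seed(1)
  shuffled <- ph[sample(nrow(ph)), ]
  fit_sh <- fit_reml(std_spec(), shuffled)
  expect_equal(fit_sh$components, fit$components, tolerance = 1e-6)
  expect_equal(fit_sh$loglik, fit$loglik, tolerance = 1e-6)

  relab <- ph
  relab$sire <- paste0("X_", relab$sire)
  relab$dam <- paste0("Y_", relab$dam)
  fit_rl <- fit_reml(std_spec(), relab)
  expect_equal(unname(fit_rl$components), unname(fit$components),
               tolerance = 1e-6)
})

test_that("a larger random structure never has lower restricted likelihood", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_R = 2,
                                      V_slope = 0.5), seed = 10)
  reduced <- fit_reml(std_spec(), ph)
  full_random <- list(ran_intercept("dam_in_sire"),
                      ran_slope("sire_in_block", "density_low"),
                      ran_intercept("block"))
  full <- fit_reml(model_spec("value",
                              fixed = c("treatment", "sex", "treatment:sex"),
                              random = full_random), ph)
  expect_gte(full$loglik, reduced$loglik - 1e-6)
})

test_that("zero-variance components land on the boundary and are flagged", {
  d <- build_pedigree(n_blocks = 4, sires_per_block = 4, dams_per_sire = 2,
                      offspring_per_dam_per_treatment = 6, seed = 2)
  ph <- simulate_trait(d, trait_model(V_S = 0, V_M = 0, V_block = 4,
                                      V_R = 1), seed = 12)
  fit <- fit_reml(std_spec(), ph)
  expect_lt(fit$components[["sire_in_block"]], 0.05)
  expect_true(fit$singular)
  expect_true(fit$converged)
})

test_that("missing values are dropped row-wise and counted", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_R = 1), seed = 4)
  ph$value[c(3, 10, 20)] <- NA
  fit <- fit_reml(std_spec(), ph)
  expect_equal(fit$n_dropped, 3)
  expect_equal(fit$n_obs, nrow(ph) - 3)
})

test_that("information criteria follow the stated parameter-counting convention", {
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_R = 1), seed = 5)
  fit <- fit_reml(std_spec(), ph)
  ic <- information_criteria(fit)
  expect_equal(ic$k, 4)  # three intercept variances + residual
  expect_equal(ic$AIC, -2 * fit$loglik + 2 * 4)
  expect_equal(ic$BIC, -2 * fit$loglik + log(fit$n_obs) * 4)
  fit_m <- fit_ml(std_spec(), ph)
  expect_equal(information_criteria(fit_m)$k, 4 + 4)  # + fixed coefficients
  bad <- fit
  bad$converged <- FALSE
  expect_error(information_criteria(bad), "unconverged")
})

test_that("model specifications are validated", {
  expect_error(model_spec("y", random = list()), "at least one")
  expect_error(model_spec("y", random = list(ran_intercept("g"),
                                             ran_intercept("g"))),
               "twice")
  expect_error(model_spec("y", random = list(ran_slope("g", "x"),
                                             ran_slope("g", "z"))))
  d <- small_design()
  ph <- simulate_trait(d, trait_model(V_R = 1), seed = 1)
  expect_error(fit_reml(model_spec("value",
                                   random = list(ran_intercept("absent"))),
                        ph),
               "missing")
})
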