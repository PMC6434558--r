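# Hypothesis tests and uncertainty quantification for the variance
# components: boundary likelihood-ratio tests of random effects, the
# individual-level case bootstrap for fixed effects, the three-way
# random-structure comparison for the repeated per-minute trait, and the
# sire-level reaction-norm G-by-E test.

#' Likelihood-ratio test of a random effect
#'
#' `chi2 = 2 (loglik_full - loglik_reduced)` (clamped at 0 for numerical
#' jitter) referred to a chi-square with `df` degrees of freedom (1 for a
#' random intercept, 2 for a correlated slope+correlation pair).  Because
#' the null value of a variance lies on the boundary of its parameter
#' space, this p-value is conservative -- up to twice as large as the
#' boundary-respecting value; the 50:50 chi-square mixture p-value is
#' reported alongside as `p_mixture`, but `p` is the unmodified chi-square
#' tail.
#'
#' @param full,reduced `qg_fit`s on the same rows with identical fixed
#'   parts and likelihood type, the reduced random structure nested in the
#'   full one.
#' @param df degrees of freedom; inferred from the difference in variance
#'   parameters when omitted.
#' @return A `qg_lrt`: list with `chi2`, `df`, `p`, `p_mixture` and a
#'   boundary-conservativeness `note`.
#' @export
lrt_random <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "qg_fit"), inherits(reduced, "qg_fit"))
  if (full$n_obs != reduced$n_obs) {
    stop("full and reduced fits use different numbers of rows", call. = FALSE)
  }
  if (full$reml != reduced$reml) {
    stop("full and reduced fits mix REML and ML", call. = FALSE)
  }
  if (!identical(sort(full$spec$fixed), sort(reduced$spec$fixed))) {
    stop("full and reduced fits must share the same fixed part",
         call. = FALSE)
  }
  k_full <- n_varpar(full)
  k_red <- n_varpar(reduced)
  if (k_full < k_red) {
    stop("`reduced` must not have more variance parameters than `full`",
         call. = FALSE)
  }
  if (is.null(df)) df <- k_full - k_red
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) {
    # degenerate comparison of identical structures
    1
  } else {
    pchisq(chi2, df = df, lower.tail = FALSE)
  }
  p_mix <- if (chi2 == 0) {
    1
  } else if (df == 1) {
    0.5 * pchisq(chi2, 1, lower.tail = FALSE)
  } else {
    0.5 * pchisq(chi2, df - 1, lower.tail = FALSE) +
      0.5 * pchisq(chi2, df, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, df = df, p = p, p_mixture = p_mix,
                 note = paste("variance null lies on the parameter boundary;",
                              "the chi-square p-value is conservative",
                              "(up to 2x too large)")),
            class = "qg_lrt")
}

#' @export
print.qg_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, p = %.4g (mixture p = %.4g)\n",
              x$chi2, x$df, x$p, x$p_mixture))
  cat(" note:", x$note, "\n")
  invisible(x)
}

#' Case-bootstrap confidence intervals for fixed effects
#'
#' Resamples individuals with replacement (whole-individual blocks of rows
#' for repeated-measures tables), refits the model on each resample, and
#' summarises each fixed coefficient by its percentile 95% interval and a
#' two-sided sign-based p-value `2 min(P(b <= 0), P(b >= 0))` floored at
#' `1/(n_replicates + 1)`.  When the resampling unit is itself a grouping
#' factor of the model, duplicated individuals are relabelled so each copy
#' is a distinct level.
#'
#' @param table phenotype data frame.
#' @param spec a [model_spec()].
#' @param n_replicates bootstrap replicates (>= 100; the reference analysis
#'   uses 10,000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param cluster resampling-unit column (default `"individual"`).
#' @param level confidence level.
#' @return A `qg_bootstrap` data frame (term, estimate, lower, upper, p)
#'   with attributes `n_replicates`, `n_failed`, `seed`.  Replicates whose
#'   refit fails are dropped and counted; a warning is raised when more
#'   than 5% fail.
#' @export
bootstrap_fixed <- function(table, spec, n_replicates = 10000, seed = 1,
                            cluster = "individual", level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  n_replicates <- check_count(n_replicates, "n_replicates", min = 100L)
  check_seed(seed)
  fit0 <- fit_lmm(spec, table, reml = spec$reml)
  used <- fit0$data
  if (is.null(used[[cluster]])) {
    stop(sprintf("cluster column `%s` not found", cluster), call. = FALSE)
  }
  groups <- vapply(spec$random, function(t) t$group, character(1))
  repeated <- cluster %in% groups ||
    anyDuplicated(used[[cluster]]) > 0L
  coefs <- with_seed(seed, {
    if (repeated) {
      boot_refit_clusters(used, spec, n_replicates, cluster)
    } else {
      boot_refit_rows(used, spec, n_replicates)
    }
  })
  ok <- stats::complete.cases(coefs)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n_replicates) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, n_replicates))
  }
  coefs <- coefs[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  floor_p <- 1 / (n_replicates + 1)
  out <- data.frame(
    term = fit0$fixed$term,
    estimate = fit0$fixed$estimate,
    lower = apply(coefs, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(coefs, 2, quantile, probs = 1 - alpha, names = FALSE),
    p = apply(coefs, 2, function(b) {
      max(min(2 * min(mean(b <= 0), mean(b >= 0)), 1), floor_p)
    }),
    row.names = NULL
  )
  structure(out, class = c("qg_bootstrap", "data.frame"),
            n_replicates = n_replicates, n_failed = n_failed, seed = seed,
            level = level)
}

# Fast resample-refit path used when the resampling units are single rows:
# the model structure is built once and resampled rows reuse the original
# incidence-matrix rows, so each replicate only re-runs the profiled-REML
# optimisation.
boot_refit_rows <- function(used, spec, n_replicates) {
  ctrl <- qg_lmer_control(loose = TRUE)
  lf <- lme4::lFormula(spec_formula(spec), data = used, REML = spec$reml,
                       control = ctrl)
  Zt0 <- lf$reTrms$Zt
  X0 <- lf$X
  n <- nrow(used)
  p <- ncol(X0)
  coefs <- matrix(NA_real_, n_replicates, p,
                  dimnames = list(NULL, colnames(X0)))
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(n, n, replace = TRUE)
    lfr <- lf
    lfr$reTrms$Zt <- Zt0[, idx, drop = FALSE]
    lfr$X <- X0[idx, , drop = FALSE]
    lfr$fr <- lf$fr[idx, , drop = FALSE]
    b <- try({
      devfun <- do.call(lme4::mkLmerDevfun, lfr)
      opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap",
                                control = ctrl$optCtrl)
      devfun(opt$par)
      environment(devfun)$pp$beta(1)
    }, silent = TRUE)
    if (!inherits(b, "try-error") && all(is.finite(b))) coefs[r, ] <- b
  }
  coefs
}

# General path: resample whole clusters, relabelling duplicated copies so
# grouping factors treat them as distinct levels.
boot_refit_clusters <- function(used, spec, n_replicates, cluster) {
  ctrl <- qg_lmer_control(loose = TRUE)
  fml <- spec_formula(spec)
  ids <- unique(as.character(used[[cluster]]))
  rows_of <- split(seq_len(nrow(used)), as.character(used[[cluster]]))
  coefs <- NULL
  for (r in seq_len(n_replicates)) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(rows_of[take], use.names = FALSE)
    dat <- used[idx, , drop = FALSE]
    copy <- rep(seq_along(take), lengths(rows_of[take]))
    dat[[cluster]] <- factor(paste0(rep(take, lengths(rows_of[take])),
                                    ".", copy))
    b <- try({
      fit <- lme4::lmer(fml, data = dat, REML = spec$reml, control = ctrl)
      lme4::fixef(fit)
    }, silent = TRUE)
    if (is.null(coefs)) {
      nm <- if (!inherits(b, "try-error")) names(b) else NULL
      if (!is.null(nm)) {
        coefs <- matrix(NA_real_, n_replicates, length(nm),
                        dimnames = list(NULL, nm))
      }
    }
    if (!inherits(b, "try-error") && !is.null(coefs) &&
        all(is.finite(b))) {
      coefs[r, ] <- b
    }
  }
  if (is.null(coefs)) {
    stop("no bootstrap replicate converged", call. = FALSE)
  }
  coefs
}

#' @export
print.qg_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Case bootstrap, %d replicates (%d failed), %.0f%% CI:\n",
              attr(x, "n_replicates"), attr(x, "n_failed"),
              100 * attr(x, "level")))
  print.data.frame(x, digits = digits)
  invisible(x)
}

#' Compare the three random-effect structures for per-minute activity
#'
#' Model 1: random intercepts for individual, dam-in-sire, sire-in-block,
#' block and test day (no plasticity of the time course).  Model 2 replaces
#' the individual intercept with a correlated individual intercept + time
#' slope (individuals differ in their activity time course).  Model 3
#' instead gives the time slope to sires (a genotype-by-time effect).
#' Models 2 and 3 are each tested against model 1 by a 2-df LRT; model 1 is
#' retained unless a larger model is significant at `alpha`, in which case
#' the significant model with the greatest likelihood (equivalently lowest
#' AIC, fixed parts being equal) is selected.
#'
#' @param table long per-minute phenotype table (columns individual, sire,
#'   dam, block, test_day, minute and the response).
#' @param trait response column name.
#' @param fixed fixed-effect terms shared by all three models.
#' @param alpha significance level for the LRTs.
#' @return An `activity_model_comparison`: list with `selected` (1, 2 or
#'   3), `fits`, `lrt` (tests of models 2 and 3 vs 1) and `aic`.
#' @export
compare_activity_models <- function(table, trait = "value",
                                    fixed = c("treatment", "sex",
                                              "treatment:sex", "time_std",
                                              "time_std2", "days_std"),
                                    alpha = 0.05) {
  base_random <- list(ran_intercept("dam_in_sire"),
                      ran_intercept("sire_in_block"),
                      ran_intercept("block"),
                      ran_intercept("test_day"))
  specs <- list(
    model_spec(trait, fixed,
               c(list(ran_intercept("individual")), base_random)),
    model_spec(trait, fixed,
               c(list(ran_slope("individual", "time_std")), base_random)),
    model_spec(trait, fixed,
               c(list(ran_intercept("individual")),
                 list(ran_slope("sire_in_block", "time_std")),
                 base_random[-2L]))
  )
  fits <- lapply(specs, fit_reml, table = table)
  lrt2 <- lrt_random(fits[[2]], fits[[1]], df = 2)
  lrt3 <- lrt_random(fits[[3]], fits[[1]], df = 2)
  aic <- vapply(fits, function(f) information_criteria(f)$AIC, numeric(1))
  candidates <- c(if (lrt2$p < alpha) 2L, if (lrt3$p < alpha) 3L)
  selected <- if (!length(candidates)) {
    1L
  } else {
    candidates[which.max(vapply(fits[candidates], `[[`, numeric(1),
                                "loglik"))]
  }
  structure(list(selected = selected, fits = fits,
                 lrt = list(model2_vs_1 = lrt2, model3_vs_1 = lrt3),
                 aic = aic, alpha = alpha),
            class = "activity_model_comparison")
}

#' @export
print.activity_model_comparison <- function(x, ...) {
  cat("Random-structure comparison for per-minute activity\n")
  cat(sprintf("  model 1 (intercepts only): AIC %.2f\n", x$aic[1]))
  cat(sprintf("  model 2 (individual time slope): AIC %.2f, LRT p = %.3g\n",
              x$aic[2], x$lrt$model2_vs_1$p))
  cat(sprintf("  model 3 (sire time slope): AIC %.2f, LRT p = %.3g\n",
              x$aic[3], x$lrt$model3_vs_1$p))
  cat(sprintf("  selected: model %d\n", x$selected))
  invisible(x)
}

#' Reaction-norm genotype-by-environment test
#'
#' Fits the random-slope reaction-norm model -- a correlated intercept and
#' density slope within `slope_factor`, high density being the intercept
#' level -- against the same model without the slope+correlation pair, and
#' tests the pair by a 2-df LRT.  With the default `slope_factor` this is
#' the sire-by-environment (G x E) test; passing `"dam_in_sire"` gives the
#' dam-by-environment (M x E) analogue.
#'
#' @param table phenotype data frame containing both treatments.
#' @param trait response column name.
#' @param slope_factor grouping factor carrying the reaction-norm slopes.
#' @param fixed fixed-effect terms.
#' @param random reduced-model random terms; must contain an intercept for
#'   `slope_factor`.  Default: dam-in-sire, sire-in-block and block
#'   intercepts.
#' @return A `qg_gxe`: list with the full and reduced fits, the `qg_lrt`,
#'   the slope variance `V_slope` and intercept-slope correlation `r_is`.
#' @export
gxe_test <- function(table, trait = "value", slope_factor = "sire_in_block",
                     fixed = c("treatment", "sex", "treatment:sex"),
                     random = NULL) {
  table <- prepare_pheno(table)
  if (is.null(table$treatment) || length(unique(table$treatment)) < 2L) {
    stop("G x E test needs data from both density treatments", call. = FALSE)
  }
  if (is.null(random)) {
    random <- list(ran_intercept("dam_in_sire"),
                   ran_intercept("sire_in_block"),
                   ran_intercept("block"))
  }
  groups <- vapply(random, function(t) t$group, character(1))
  if (!slope_factor %in% groups) {
    stop(sprintf("`random` must include an intercept for `%s`",
                 slope_factor), call. = FALSE)
  }
  both <- table(table[[slope_factor]], table$treatment)
  if (sum(both[, "high"] > 0 & both[, "low"] > 0) < 2L) {
    stop("both treatments must be represented within at least 2 groups of the slope factor",
         call. = FALSE)
  }
  full_random <- lapply(random, function(t) {
    if (t$group == slope_factor) ran_slope(slope_factor, "density_low")
    else t
  })
  reduced <- fit_reml(model_spec(trait, fixed, random), table)
  full <- fit_reml(model_spec(trait, fixed, full_random), table)
  lrt <- lrt_random(full, reduced, df = 2)
  sl <- full$slopes[[slope_factor]]
  structure(list(fit_full = full, fit_reduced = reduced, lrt = lrt,
                 slope_factor = slope_factor,
                 V_slope = sl$var_slope, r_is = sl$correlation),
            class = "qg_gxe")
}

#' @export
print.qg_gxe <- function(x, ...) {
  cat(sprintf("Reaction-norm G x E test (slopes within %s)\n",
              x$slope_factor))
  cat(sprintf("  slope variance %.4g, intercept-slope correlation %s\n",
              x$V_slope, format(x$r_is, digits = 3)))
  print(x$lrt)
  invisible(x)
}
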