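# Linear mixed model engine: declarative model specifications fitted by
# (RE)ML through lme4, returning variance components on the scale the
# quantitative-genetic summaries need.  Nesting is encoded by composite
# group labels (dam-in-sire, sire-in-block) built by prepare_pheno(), so
# model formulas stay flat.

#' Random-effect term constructors
#'
#' `ran_intercept(group)` declares a random intercept for a grouping factor;
#' `ran_slope(group, covariate)` declares a correlated random intercept and
#' slope of a (numeric) covariate within the grouping factor, e.g. the
#' sire-level density reaction norm `ran_slope("sire_in_block",
#' "density_low")` or the individual time slope `ran_slope("individual",
#' "time_std")`.
#'
#' @param group name of the grouping-factor column.
#' @param covariate name of the numeric slope covariate.
#' @return A `ranterm` list.
#' @export
ran_intercept <- function(group) {
  stopifnot(is.character(group), length(group) == 1L)
  structure(list(type = "intercept", group = group, covariate = NULL),
            class = "ranterm")
}

#' @rdname ran_intercept
#' @export
ran_slope <- function(group, covariate) {
  stopifnot(is.character(group), length(group) == 1L,
            is.character(covariate), length(covariate) == 1L)
  structure(list(type = "slope", group = group, covariate = covariate),
            class = "ranterm")
}

#' Declarative mixed-model specification
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (an intercept is
#'   always included), e.g. `c("treatment", "sex", "treatment:sex")`.
#' @param random list of [ran_intercept()] / [ran_slope()] terms; at most
#'   one slope term per grouping factor.
#' @param reml fit by REML (default) or ML.
#' @return A `model_spec`.
#' @examples
#' spec <- model_spec("value", fixed = c("treatment", "sex"),
#'                    random = list(ran_intercept("dam_in_sire"),
#'                                  ran_intercept("sire_in_block"),
#'                                  ran_intercept("block")))
#' @export
model_spec <- function(response, fixed = character(), random = list(),
                       reml = TRUE) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed), is.list(random), is.logical(reml))
  if (!length(random)) {
    stop("at least one random term is required", call. = FALSE)
  }
  if (!all(vapply(random, inherits, logical(1), "ranterm"))) {
    stop("`random` must be a list of ran_intercept()/ran_slope() terms",
         call. = FALSE)
  }
  slope_groups <- vapply(Filter(function(t) t$type == "slope", random),
                         function(t) t$group, character(1))
  if (anyDuplicated(slope_groups)) {
    stop("at most one correlated intercept+slope term per grouping factor",
         call. = FALSE)
  }
  groups <- vapply(random, function(t) t$group, character(1))
  dup <- groups[duplicated(groups)]
  if (length(dup)) {
    stop(sprintf("grouping factor(s) used twice: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, random = random,
                 reml = isTRUE(reml)),
            class = "model_spec")
}

ranterm_label <- function(t) {
  if (t$type == "intercept") sprintf("(1 | %s)", t$group)
  else sprintf("(1 + %s | %s)", t$covariate, t$group)
}

spec_formula <- function(spec) {
  rhs_fixed <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ")
               else "1"
  rhs_ran <- paste(vapply(spec$random, ranterm_label, character(1)),
                   collapse = " + ")
  as.formula(paste(spec$response, "~", rhs_fixed, "+", rhs_ran),
             env = new.env(parent = baseenv()))
}

spec_columns <- function(spec) {
  fixed_vars <- all.vars(as.formula(
    paste("~", if (length(spec$fixed)) paste(spec$fixed, collapse = "+")
          else "1")))
  unique(c(spec$response, fixed_vars,
           unlist(lapply(spec$random,
                         function(t) c(t$group, t$covariate)))))
}

#' Default lme4 control used by the engine
#'
#' Derivative checks are disabled (boundary fits are expected and reported,
#' not warned about) and the optimizer tolerances tightened so that balanced
#' designs reproduce closed-form ANOVA estimators to high precision.
#'
#' @param loose use faster, looser tolerances (bootstrap refits).
#' @return An [lme4::lmerControl()] object.
#' @export
qg_lmer_control <- function(loose = FALSE) {
  if (loose) {
    lme4::lmerControl(optimizer = "nloptwrap", calc.derivs = FALSE,
                      check.conv.singular = "ignore",
                      check.nlev.gtreq.5 = "ignore",
                      optCtrl = list(xtol_abs = 1e-6, ftol_abs = 1e-6))
  } else {
    lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                      check.conv.singular = "ignore",
                      check.nlev.gtreq.5 = "ignore",
                      optCtrl = list(rhoend = 1e-10))
  }
}

#' Fixed design matrix and random-effect incidence structures
#'
#' Expands a [model_spec()] against a phenotype table: the fixed-effect
#' model matrix (with the stated reference codings: high density, female
#' sex) plus one sparse incidence matrix per random term (two columns per
#' group level for correlated intercept+slope terms).
#'
#' @param spec a [model_spec()].
#' @param table a phenotype data frame; [prepare_pheno()] is applied.
#' @return A list with `X` (dense fixed matrix), `Z` (named list of sparse
#'   n-by-q incidence matrices, one per random term) and `n_levels`.
#' @export
build_design <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  table <- prepare_pheno(table)
  missing_cols <- setdiff(spec_columns(spec), names(table))
  if (length(missing_cols)) {
    stop(sprintf("columns missing from table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  table <- table[complete.cases(table[spec_columns(spec)]), , drop = FALSE]
  fml <- spec_formula(spec)
  X <- model.matrix(
    as.formula(paste("~", if (length(spec$fixed))
      paste(spec$fixed, collapse = "+") else "1")), table)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  }
  lf <- lme4::lFormula(fml, data = table, REML = spec$reml,
                       control = qg_lmer_control())
  Z <- lapply(lf$reTrms$Ztlist, Matrix::t)
  names(Z) <- vapply(spec$random, ranterm_label, character(1))[
    order_reterms(spec, names(lf$reTrms$Ztlist))]
  n_levels <- vapply(lf$reTrms$flist, nlevels, integer(1))
  list(X = X, Z = Z, n_levels = n_levels)
}

# lme4 orders random terms by decreasing number of levels; map back to the
# order the spec declared them in.
order_reterms <- function(spec, zt_names) {
  declared <- vapply(spec$random, function(t) {
    if (t$type == "intercept") sprintf("1 | %s", t$group)
    else sprintf("1 + %s | %s", t$covariate, t$group)
  }, character(1))
  match(zt_names, declared)
}

fit_lmm <- function(spec, table, reml, control = qg_lmer_control()) {
  stopifnot(inherits(spec, "model_spec"))
  table <- prepare_pheno(table)
  cols <- spec_columns(spec)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(sprintf("columns missing from table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  used <- table[complete.cases(table[cols]), , drop = FALSE]
  n_dropped <- nrow(table) - nrow(used)
  used <- droplevels(used)
  for (t in spec$random) {
    g <- used[[t$group]]
    if (length(unique(g)) < 2L) {
      stop(sprintf("random factor `%s` needs at least 2 groups", t$group),
           call. = FALSE)
    }
  }
  fml <- spec_formula(spec)
  fit <- lme4::lmer(fml, data = used, REML = reml, control = control)
  if (fit@optinfo$conv$opt != 0) {
    # single retry with a different derivative-free optimizer
    fit2 <- try(lme4::lmer(fml, data = used, REML = reml,
                           control = lme4::lmerControl(
                             optimizer = "nloptwrap", calc.derivs = FALSE,
                             check.conv.singular = "ignore")),
                silent = TRUE)
    if (!inherits(fit2, "try-error") && fit2@optinfo$conv$opt == 0) {
      fit <- fit2
    }
  }
  converged <- fit@optinfo$conv$opt == 0 &&
    !length(fit@optinfo$conv$lme4$messages %||% character())
  vc <- lme4::VarCorr(fit)
  components <- c()
  slopes <- list()
  for (t in spec$random) {
    m <- vc[[t$group]]
    components[t$group] <- m[1, 1]
    if (t$type == "slope") {
      corr <- attr(m, "correlation")[1, 2]
      if (!is.finite(corr)) corr <- NA_real_
      slopes[[t$group]] <- list(covariate = t$covariate,
                                var_intercept = m[1, 1],
                                var_slope = m[2, 2],
                                correlation = corr)
    }
  }
  components["residual"] <- attr(vc, "sc")^2
  fixed_summ <- summary(fit)$coefficients
  structure(list(
    spec = spec,
    formula = fml,
    fit = fit,
    components = components,
    slopes = slopes,
    fixed = data.frame(term = rownames(fixed_summ),
                       estimate = fixed_summ[, "Estimate"],
                       se = fixed_summ[, "Std. Error"],
                       row.names = NULL),
    loglik = as.numeric(logLik(fit)),
    reml = reml,
    converged = converged,
    singular = lme4::isSingular(fit),
    n_obs = nrow(used),
    n_dropped = n_dropped,
    n_groups = vapply(spec$random,
                      function(t) length(unique(used[[t$group]])),
                      integer(1), USE.NAMES = FALSE) |>
      setNames(vapply(spec$random, function(t) t$group, character(1))),
    data = used
  ), class = "qg_fit")
}

#' Fit a linear mixed model by REML
#'
#' Maximizes the restricted likelihood over the variance parameters
#' (variances bounded at 0, correlations in `[-1, 1]` by construction of
#' the relative-covariance-factor parameterisation); fixed effects are the
#' generalized-least-squares estimates at the optimum.  Rows with missing
#' values in any referenced column are dropped and counted
#' (`$n_dropped`).  Boundary (singular) fits are flagged but valid;
#' non-convergence is flagged, never silent.
#'
#' @param spec a [model_spec()].
#' @param table phenotype data frame ([prepare_pheno()] is applied).
#' @param control an [lme4::lmerControl()]; see [qg_lmer_control()].
#' @return A `qg_fit` with elements `components` (named nonnegative
#'   variances, `residual` always present), `slopes` (per slope term:
#'   intercept/slope variances and their correlation), `fixed`
#'   (coefficient table), `loglik` (restricted log-likelihood at the
#'   optimum), `converged`, `singular`, `n_obs`, `n_groups`, `n_dropped`.
#' @examples
#' d <- build_pedigree(n_blocks = 3, sires_per_block = 3, dams_per_sire = 2,
#'                     offspring_per_dam_per_treatment = 4, seed = 1)
#' ph <- simulate_trait(d, trait_model(V_S = 1, V_M = 1, V_block = 1,
#'                                     V_R = 4), seed = 2)
#' fit <- fit_reml(model_spec("value", fixed = "treatment",
#'                            random = list(ran_intercept("dam_in_sire"),
#'                                          ran_intercept("sire_in_block"),
#'                                          ran_intercept("block"))), ph)
#' fit$components
#' @export
fit_reml <- function(spec, table, control = qg_lmer_control()) {
  fit_lmm(spec, table, reml = TRUE, control = control)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' As [fit_reml()] with the unrestricted likelihood; needed when comparing
#' models whose fixed parts differ.
#'
#' @inheritParams fit_reml
#' @return A `qg_fit`.
#' @export
fit_ml <- function(spec, table, control = qg_lmer_control()) {
  fit_lmm(spec, table, reml = FALSE, control = control)
}

# number of estimated variance-covariance parameters (slope terms carry an
# intercept variance, a slope variance and a correlation)
n_varpar <- function(fit) {
  sum(vapply(fit$spec$random,
             function(t) if (t$type == "slope") 3L else 1L, integer(1))) + 1L
}

#' Information criteria for a fitted model
#'
#' `AIC = -2 loglik + 2 k` with `k` the number of estimated variance
#' parameters, plus the fixed-effect coefficients under ML.  Under REML the
#' fixed part is profiled out, so REML criteria are only comparable between
#' models sharing the same fixed part.
#'
#' @param fit a `qg_fit`.
#' @return A list with `AIC`, `BIC`, `k` and `loglik`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "qg_fit"))
  if (!fit$converged) {
    stop("information criteria are undefined for an unconverged fit",
         call. = FALSE)
  }
  k <- n_varpar(fit) + if (fit$reml) 0L else nrow(fit$fixed)
  list(AIC = -2 * fit$loglik + 2 * k,
       BIC = -2 * fit$loglik + log(fit$n_obs) * k,
       k = k, loglik = fit$loglik)
}

#' @export
print.qg_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model (%s), %d obs%s\n",
              if (x$reml) "REML" else "ML", x$n_obs,
              if (x$n_dropped) sprintf(" (%d dropped, missing data)",
                                       x$n_dropped) else ""))
  cat("Variance components:\n")
  print(round(x$components, digits))
  if (length(x$slopes)) {
    for (g in names(x$slopes)) {
      s <- x$slopes[[g]]
      cat(sprintf("  slope of %s within %s: var %s, corr %s\n",
                  s$covariate, g, format(s$var_slope, digits = digits),
                  format(s$correlation, digits = digits)))
    }
  }
  cat("Fixed effects:\n")
  print(x$fixed, digits = digits)
  cat(sprintf("logLik %.3f | converged: %s | singular: %s\n",
              x$loglik, x$converged, x$singular))
  invisible(x)
}

#' Prepare a phenotype table for model fitting
#'
#' Idempotent preprocessing shared by all fitting functions: coerces
#' `treatment` (reference `"high"`) and `sex` (reference `"F"`) to factors,
#' adds the numeric low-density indicator `density_low`, builds the
#' composite nesting factors `sire_in_block` (sire nested in block) and
#' `dam_in_sire` (dam nested in sire), coerces `block`, `test_day` and
#' `individual` to factors, and standardizes `days_after_eclosion` into
#' `days_std` (0 when constant) and `minute` into `time_std` /
#' `time_std2` when present.
#'
#' @param table phenotype data frame.
#' @return The augmented data frame.
#' @export
prepare_pheno <- function(table) {
  stopifnot(is.data.frame(table))
  tab <- as.data.frame(table)
  if (!is.null(tab$treatment)) {
    tab$treatment <- factor(as.character(tab$treatment),
                            levels = c("high", "low"))
    tab$density_low <- as.numeric(tab$treatment == "low")
  }
  if (!is.null(tab$sex)) {
    tab$sex <- factor(as.character(tab$sex), levels = c("F", "M"))
  }
  for (col in c("block", "test_day", "individual", "sire", "dam")) {
    if (!is.null(tab[[col]])) tab[[col]] <- factor(tab[[col]])
  }
  if (!is.null(tab$sire) && !is.null(tab$block)) {
    tab$sire_in_block <- interaction(tab$block, tab$sire, sep = ":",
                                     drop = TRUE)
  }
  if (!is.null(tab$dam) && !is.null(tab$sire)) {
    tab$dam_in_sire <- interaction(tab$sire, tab$dam, sep = ":", drop = TRUE)
  }
  if (!is.null(tab$days_after_eclosion) && is.null(tab$days_std)) {
    dd <- tab$days_after_eclosion
    tab$days_std <- if (length(unique(dd[is.finite(dd)])) > 1L) {
      standardize_covariate(dd)
    } else {
      rep(0, nrow(tab))
    }
  }
  if (!is.null(tab$minute) && is.null(tab$time_std)) {
    tab$time_std <- standardize_covariate(tab$minute)
  }
  if (!is.null(tab$time_std) && is.null(tab$time_std2)) {
    tab$time_std2 <- tab$time_std^2
  }
  tab
}
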