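# Quantitative-genetic summaries: narrow-sense heritability and
# maternal-effect ratios from half-sib variance components, percentage of
# phenotypic variance, treatment-specific refits and the with/without-block
# sensitivity pair.
#
# In the nested paternal half-sib design the among-sire variance estimates a
# quarter of the additive genetic variance, so V_A = 4 V_S throughout.
# Test-day and individual-level variances are kept out of the h2/m2
# denominators (which use only V_A, V_M, V_block and V_R) but are part of
# the phenotypic-variance total used for percentages, where V_S enters once
# (not multiplied by 4).

check_qg_components <- function(V_S, V_M, V_block, V_R) {
  check_variance(V_S, "V_S"); check_variance(V_M, "V_M")
  if (!is.null(V_block)) check_variance(V_block, "V_block")
  check_variance(V_R, "V_R")
  denom <- 4 * V_S + V_M + (V_block %||% 0) + V_R
  if (denom <= 0) {
    stop("all variance components are zero; ratio undefined", call. = FALSE)
  }
  denom
}

#' Narrow-sense heritability from half-sib variance components
#'
#' `h2 = 4 V_S / (4 V_S + V_M + V_block + V_R)`; omit `V_block` (or pass
#' `NULL`) for the without-block variant `4 V_S / (4 V_S + V_M + V_R)`.
#' Full precision is returned; report tables round to 2 decimals.
#'
#' @param V_S,V_M,V_R sire, dam and residual variance components.
#' @param V_block block variance component, or `NULL` to omit.
#' @return The heritability ratio in `[0, 1]`.
#' @examples
#' heritability(1299, 0, 2096, 14439)   # 0.239...
#' @export
heritability <- function(V_S, V_M, V_block = NULL, V_R) {
  denom <- check_qg_components(V_S, V_M, V_block, V_R)
  4 * V_S / denom
}

#' Maternal-effect ratio from half-sib variance components
#'
#' `m2 = V_M / (4 V_S + V_M + V_block + V_R)`; omit `V_block` for the
#' without-block variant.  The dam component `V_M` captures maternal
#' (environmental plus remaining genetic) variance beyond the sire
#' component.
#'
#' @inheritParams heritability
#' @return The maternal-effect ratio in `[0, 1]`.
#' @examples
#' maternal_effect(0.0005, 0.0026, 0.0039, 0.0062)   # 0.176...
#' @export
maternal_effect <- function(V_S, V_M, V_block = NULL, V_R) {
  denom <- check_qg_components(V_S, V_M, V_block, V_R)
  V_M / denom
}

#' Percentage of phenotypic variance for one component
#'
#' `100 V_component / sum(all fitted random components)`, the sire variance
#' entering the total once (not multiplied by 4) and test-day and
#' individual-level variances included in the total.
#'
#' @param component a component name present in `components`, or a single
#'   numeric variance.
#' @param components named numeric vector of all fitted variance components
#'   (including the residual).
#' @return The percentage.
#' @examples
#' percent_vp("sire", c(sire = 1299, dam = 0, block = 2096,
#'                      residual = 14439))   # 7.28...
#' @export
percent_vp <- function(component, components) {
  if (!is.numeric(components) || is.null(names(components))) {
    stop("`components` must be a named numeric vector", call. = FALSE)
  }
  vapply(components, check_variance, numeric(1), name = "components")
  total <- sum(components)
  if (total <= 0) stop("total phenotypic variance is zero", call. = FALSE)
  v <- if (is.character(component)) {
    if (!component %in% names(components)) {
      stop(sprintf("component `%s` not among the fitted components",
                   component), call. = FALSE)
    }
    components[[component]]
  } else {
    check_variance(component, "component")
  }
  100 * v / total
}

# Map a qg_fit's group-labelled components onto the quantitative-genetic
# roles.  Individual slope variances enter the total via the slopes table.
qg_roles <- function(fit) {
  comp <- fit$components
  cget <- function(nm) if (nm %in% names(comp)) comp[[nm]] else NULL
  roles <- list(
    V_S = cget("sire_in_block") %||% cget("sire") %||% 0,
    V_M = cget("dam_in_sire") %||% cget("dam") %||% 0,
    V_block = cget("block"),
    V_testday = cget("test_day"),
    V_R = comp[["residual"]]
  )
  vp <- comp
  for (g in names(fit$slopes)) {
    vp[paste0(g, ".slope")] <- fit$slopes[[g]]$var_slope
  }
  roles$vp_components <- vp
  roles
}

#' Quantitative-genetic summary of a fitted model
#'
#' Computes `h2`, `m2` and the per-component percentages of phenotypic
#' variance from a `qg_fit`, recording the provenance (with/without block,
#' data subset).  Test-day and individual-level variances are excluded from
#' the h2/m2 denominators but included in the percentage total; set
#' `individual_in_denominator = TRUE` to add an individual intercept
#' variance to the denominators (alternate convention for repeated-measures
#' traits).
#'
#' @param fit a `qg_fit`.
#' @param trait trait name for the report.
#' @param subset `"all"`, `"high"` or `"low"` (provenance only).
#' @param individual_in_denominator include the individual intercept
#'   variance in the h2/m2 denominators.
#' @return A `qg_summary`: list with `trait`, `variant`, `subset`, `h2`,
#'   `m2`, `pct_VP` (named percentages summing to 100), `components` and
#'   `slopes`.
#' @export
qg_summary <- function(fit, trait = fit$spec$response, subset = "all",
                       individual_in_denominator = FALSE) {
  stopifnot(inherits(fit, "qg_fit"))
  roles <- qg_roles(fit)
  extra <- if (individual_in_denominator &&
               "individual" %in% names(fit$components)) {
    fit$components[["individual"]]
  } else {
    0
  }
  denom <- 4 * roles$V_S + roles$V_M + (roles$V_block %||% 0) +
    roles$V_R + extra
  structure(list(
    trait = trait,
    variant = if (is.null(roles$V_block)) "without_block" else "with_block",
    subset = subset,
    h2 = 4 * roles$V_S / denom,
    m2 = roles$V_M / denom,
    pct_VP = setNames(
      vapply(names(roles$vp_components), percent_vp, numeric(1),
             components = roles$vp_components),
      names(roles$vp_components)),
    components = fit$components,
    slopes = fit$slopes,
    n_obs = fit$n_obs
  ), class = "qg_summary")
}

#' @export
print.qg_summary <- function(x, ...) {
  cat(sprintf("Trait: %s  (%s, subset: %s, n = %d)\n", x$trait,
              gsub("_", " ", x$variant), x$subset, x$n_obs))
  tab <- data.frame(component = names(x$pct_VP),
                    variance = unname(c(x$components,
                      vapply(x$slopes, function(s) s$var_slope,
                             numeric(1))))[
                      match(names(x$pct_VP),
                            c(names(x$components),
                              paste0(names(x$slopes), ".slope")))],
                    pct_VP = round(unname(x$pct_VP), 1))
  print(tab, row.names = FALSE)
  cat(sprintf("h2 = %.2f   m2 = %.2f\n", round(x$h2, 2), round(x$m2, 2)))
  invisible(x)
}

#' Treatment-specific variance components
#'
#' Refits the random-intercept structure separately to the high- and
#' low-density subsets, with all density terms removed from the fixed part
#' (the usual follow-up once a significant G x E interaction shows the
#' components differ between environments).
#'
#' @param table phenotype data frame with both treatments.
#' @param trait response column name.
#' @param spec a [model_spec()] for the full data; density fixed terms and
#'   density random slopes are stripped for the subset fits.
#' @return A list with one [qg_summary()] per treatment level
#'   (`$high`, `$low`).
#' @export
treatment_specific_components <- function(table, trait = NULL, spec) {
  stopifnot(inherits(spec, "model_spec"))
  table <- prepare_pheno(table)
  trait <- trait %||% spec$response
  fixed_sub <- spec$fixed[!grepl("treatment|density", spec$fixed)]
  random_sub <- lapply(spec$random, function(t) {
    if (t$type == "slope" && identical(t$covariate, "density_low")) {
      ran_intercept(t$group)
    } else {
      t
    }
  })
  out <- lapply(c(high = "high", low = "low"), function(lev) {
    sub <- table[!is.na(table$treatment) & table$treatment == lev, ,
                 drop = FALSE]
    if (!nrow(sub)) {
      stop(sprintf("no rows in the %s-density subset", lev), call. = FALSE)
    }
    fit <- fit_reml(model_spec(spec$response, fixed_sub, random_sub,
                               reml = TRUE), sub)
    qg_summary(fit, trait = trait, subset = lev)
  })
  out
}

#' With/without-block sensitivity pair
#'
#' Fits the model with and without the block random intercept and flags how
#' the family components respond, following the logic that a block effect
#' truly independent of families should inflate both `V_A = 4 V_S` and
#' `V_M` when block is dropped, whereas a rise confined to one component
#' suggests block variance was absorbing that component (families are not
#' randomized over temporal blocks, so block can soak up genetic
#' variance).
#'
#' @param table phenotype data frame.
#' @param trait response column name.
#' @param spec a [model_spec()] whose random part includes
#'   `ran_intercept("block")`.
#' @param rise_tol a component counts as "risen" when it increases by more
#'   than this fraction of the with-block phenotypic variance (default
#'   2%).
#' @return A `block_sensitivity` list: `with_block` and `without_block`
#'   [qg_summary()]s, the component changes, and an interpretation `flag`
#'   in `"block_independent"`, `"sire_confounded"`, `"dam_confounded"`,
#'   `"no_change"`.
#' @export
block_sensitivity <- function(table, trait = NULL, spec, rise_tol = 0.02) {
  stopifnot(inherits(spec, "model_spec"))
  trait <- trait %||% spec$response
  groups <- vapply(spec$random, function(t) t$group, character(1))
  if (!"block" %in% groups) {
    stop("`spec` must include a block random intercept", call. = FALSE)
  }
  spec_wo <- model_spec(spec$response, spec$fixed,
                        spec$random[groups != "block"], reml = spec$reml)
  fit_w <- fit_reml(spec, table)
  fit_wo <- fit_reml(spec_wo, table)
  sum_w <- qg_summary(fit_w, trait = trait)
  sum_wo <- qg_summary(fit_wo, trait = trait)
  roles_w <- qg_roles(fit_w)
  roles_wo <- qg_roles(fit_wo)
  vp <- sum(roles_w$vp_components)
  d_VA <- 4 * (roles_wo$V_S - roles_w$V_S)
  d_VM <- roles_wo$V_M - roles_w$V_M
  rises <- c(VA = d_VA > rise_tol * vp, VM = d_VM > rise_tol * vp)
  flag <- if (all(rises)) {
    "block_independent"
  } else if (rises[["VA"]]) {
    "sire_confounded"
  } else if (rises[["VM"]]) {
    "dam_confounded"
  } else {
    "no_change"
  }
  structure(list(with_block = sum_w, without_block = sum_wo,
                 delta = c(V_A = d_VA, V_M = d_VM), flag = flag,
                 rise_tol = rise_tol),
            class = "block_sensitivity")
}

#' @export
print.block_sensitivity <- function(x, ...) {
  cat("Block-sensitivity pair\n")
  cat(sprintf("  h2 with block %.2f -> without %.2f;  m2 %.2f -> %.2f\n",
              x$with_block$h2, x$without_block$h2,
              x$with_block$m2, x$without_block$m2))
  cat(sprintf("  delta V_A = %.4g, delta V_M = %.4g  ->  flag: %s\n",
              x$delta[["V_A"]], x$delta[["V_M"]], x$flag))
  invisible(x)
}
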