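# End-to-end orchestration: configuration, schema validation, the per-trait
# analysis bundle (variance components, G x E, treatment-specific
# components, heritability summaries, fixed-effect bootstrap) and the
# simulate -> fit -> summarise recovery harness.

#' Assemble an analysis configuration
#'
#' @param input path to a delimited phenotype table (CSV), or `NULL` when
#'   simulating.
#' @param simulate list describing a simulation: `design` (arguments to
#'   [build_pedigree()]) and `traits` (named list; each entry has `type`
#'   in `"trait"`, `"repeated"`, `"latency"` and `model` arguments for the
#'   corresponding `*_model()` constructor).
#' @param traits named list of per-trait analysis settings; each entry may
#'   set `repeated` (long per-minute trait) and `behavioural` (adds the
#'   test-day random intercept and the days-after-eclosion covariate).
#' @param n_boot bootstrap replicates for fixed effects (default 10000).
#' @param alpha significance level for cascading decisions.
#' @param seed mandatory seed governing every stochastic step.
#' @param output_dir directory for report artifacts, or `NULL` to skip
#'   writing.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(input = NULL, simulate = NULL, traits,
                            n_boot = 10000, alpha = 0.05, seed = 1,
                            output_dir = NULL) {
  check_seed(seed)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(input) && is.null(simulate)) {
    stop("either `input` or `simulate` must be given", call. = FALSE)
  }
  if (!is.list(traits) || is.null(names(traits)) ||
      any(!nzchar(names(traits)))) {
    stop("`traits` must be a named list of per-trait settings",
         call. = FALSE)
  }
  structure(list(input = input, simulate = simulate, traits = traits,
                 n_boot = n_boot, alpha = alpha, seed = seed,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The file mirrors the arguments of [analysis_config()]; see
#' `system.file("extdata", "config_template.yaml", package = "halfsibQG")`
#' for a commented template.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' Validate a phenotype table against the expected schema
#'
#' Collects every violation (missing columns, non-numeric traits, bad
#' treatment/sex labels) and reports them in one aggregated error.
#'
#' @param table candidate phenotype data frame.
#' @param trait_cols trait columns that must be numeric.
#' @param required structural columns that must be present.
#' @return The table, invisibly, when valid.
#' @export
validate_pheno_table <- function(table,
                                 trait_cols = character(),
                                 required = c("individual", "dam", "sire",
                                              "block", "treatment",
                                              "sex")) {
  problems <- character()
  if (!is.data.frame(table)) {
    stop("phenotype input must be a data frame", call. = FALSE)
  }
  miss <- setdiff(c(required, trait_cols), names(table))
  if (length(miss)) {
    problems <- c(problems,
                  sprintf("missing column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  for (tc in intersect(trait_cols, names(table))) {
    if (!is.numeric(table[[tc]])) {
      problems <- c(problems, sprintf("trait column `%s` is not numeric", tc))
    }
  }
  if ("treatment" %in% names(table)) {
    bad <- setdiff(unique(as.character(table$treatment)), c("high", "low"))
    bad <- bad[!is.na(bad)]
    if (length(bad)) {
      problems <- c(problems,
                    sprintf("treatment labels other than high/low: %s",
                            paste(bad, collapse = ", ")))
    }
  }
  if ("sex" %in% names(table)) {
    bad <- setdiff(unique(as.character(table$sex)), c("F", "M"))
    bad <- bad[!is.na(bad)]
    if (length(bad)) {
      problems <- c(problems, sprintf("sex labels other than F/M: %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop(paste0("phenotype table fails schema validation:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(table)
}

default_trait_spec <- function(trait, behavioural = FALSE,
                               repeated = FALSE) {
  fixed <- c("treatment", "sex", "treatment:sex")
  random <- list(ran_intercept("dam_in_sire"),
                 ran_intercept("sire_in_block"),
                 ran_intercept("block"))
  if (behavioural) {
    fixed <- c(fixed, "days_std")
    random <- c(random, list(ran_intercept("test_day")))
  }
  if (repeated) {
    fixed <- c(fixed, "time_std", "time_std2")
    random <- c(list(ran_intercept("individual")), random)
  }
  model_spec(trait, fixed, random)
}

simulate_from_config <- function(config) {
  sim <- config$simulate
  design <- do.call(build_pedigree,
                    modifyList(sim$design %||% list(),
                               list(seed = config$seed)))
  tables <- list()
  k <- 0L
  for (nm in names(sim$traits)) {
    k <- k + 1L
    tr <- sim$traits[[nm]]
    type <- tr$type %||% "trait"
    seed_k <- config$seed + 1000L * k
    tables[[nm]] <- switch(type,
      trait = simulate_trait(design, do.call(trait_model, tr$model),
                             seed = seed_k, trait = nm),
      repeated = simulate_repeated_activity(
        design, do.call(repeated_model, tr$model), seed = seed_k,
        trait = nm),
      latency = simulate_latency(design, do.call(trait_model, tr$model),
                                 cap_s = tr$cap_s %||% 1800,
                                 seed = seed_k),
      stop(sprintf("unknown simulated trait type `%s`", type),
           call. = FALSE)
    )
  }
  list(design = design, tables = tables)
}

#' Run the full per-trait analysis
#'
#' For each configured trait: the with/without-block sensitivity pair, the
#' sire-level reaction-norm G x E test, treatment-specific variance
#' components when the G x E test is significant (configurable via
#' `alpha`), heritability / maternal-effect / percent-of-variance
#' summaries, and case-bootstrap confidence intervals for the fixed
#' effects.  Repeated per-minute traits additionally run the three-way
#' random-structure comparison.  When `output_dir` is set, Table-style CSV
#' artifacts and a JSON manifest (embedding the seed and settings) are
#' written; reruns with the same configuration are byte-identical.
#'
#' @param config an [analysis_config()].
#' @return A `qg_report` list: `manifest`, and per trait the fits,
#'   summaries, tests and bootstrap tables.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$input)) {
    table_all <- read.csv(config$input, stringsAsFactors = FALSE)
    validate_pheno_table(table_all, trait_cols = intersect(
      names(config$traits), names(table_all)))
    tables <- lapply(config$traits, function(x) table_all)
  } else {
    sim <- simulate_from_config(config)
    tables <- sim$tables
    lapply(tables, validate_pheno_table)
  }

  results <- list()
  k <- 0L
  for (nm in names(config$traits)) {
    k <- k + 1L
    settings <- config$traits[[nm]]
    tab <- prepare_pheno(tables[[nm]])
    behavioural <- isTRUE(settings$behavioural)
    repeated <- isTRUE(settings$repeated)
    trait_col <- if (nm %in% names(tab)) nm else settings$column %||% "value"
    spec <- default_trait_spec(trait_col, behavioural, repeated)

    res <- list(trait = nm)
    res$block_sensitivity <- block_sensitivity(tab, trait_col, spec)
    res$summary <- res$block_sensitivity$with_block

    res$gxe <- gxe_test(tab, trait_col,
                        fixed = spec$fixed[!grepl("time", spec$fixed)],
                        random = spec$random)
    if (res$gxe$lrt$p < config$alpha) {
      res$treatment_components <-
        treatment_specific_components(tab, trait_col, spec)
    }
    if (repeated) {
      res$activity_models <- compare_activity_models(
        tab, trait = trait_col,
        fixed = spec$fixed, alpha = config$alpha)
    }
    res$bootstrap <- bootstrap_fixed(tab, spec,
                                     n_replicates = config$n_boot,
                                     seed = config$seed + 5000L + k)
    results[[nm]] <- res
  }

  manifest <- list(
    package = "halfsibQG",
    seed = config$seed,
    alpha = config$alpha,
    n_boot = config$n_boot,
    traits = names(config$traits),
    input = config$input %||% "simulated",
    artifacts = character()
  )
  report <- structure(list(manifest = manifest, results = results),
                      class = "qg_report")
  if (!is.null(config$output_dir)) {
    report <- write_report(report, config$output_dir)
  }
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  artifacts <- character()
  for (nm in names(report$results)) {
    res <- report$results[[nm]]
    s <- res$summary
    comp_tab <- data.frame(
      component = names(s$pct_VP),
      variance = unname(s$pct_VP) * sum(s$components,
        vapply(s$slopes, function(x) x$var_slope, numeric(1))) / 100,
      pct_VP = round(unname(s$pct_VP), 1)
    )
    extra <- data.frame(
      component = c("h2", "m2", "gxe_chi2", "gxe_p"),
      variance = c(round(s$h2, 2), round(s$m2, 2),
                   round(res$gxe$lrt$chi2, 2), signif(res$gxe$lrt$p, 3)),
      pct_VP = NA_real_
    )
    f1 <- file.path(dir, paste0("components_", nm, ".csv"))
    write.csv(rbind(comp_tab, extra), f1, row.names = FALSE)
    f2 <- file.path(dir, paste0("fixed_", nm, ".csv"))
    write.csv(as.data.frame(res$bootstrap), f2, row.names = FALSE)
    artifacts <- c(artifacts, f1, f2)
  }
  report$manifest$artifacts <- basename(artifacts)
  jsonlite::write_json(report$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' @export
print.qg_report <- function(x, ...) {
  cat(sprintf("Analysis report: %d trait(s), seed %d\n",
              length(x$results), x$manifest$seed))
  for (nm in names(x$results)) {
    res <- x$results[[nm]]
    cat(sprintf("- %s: h2 = %.2f, m2 = %.2f, G x E p = %.3g%s\n", nm,
                res$summary$h2, res$summary$m2, res$gxe$lrt$p,
                if (!is.null(res$activity_models))
                  sprintf(", activity model %d",
                          res$activity_models$selected) else ""))
  }
  invisible(x)
}

#' Simulate -> fit -> summarise parameter-recovery harness
#'
#' Repeatedly simulates a trait over regenerated breeding designs, fits the
#' variance-component model, and reports per-parameter bias, RMSE and the
#' Monte-Carlo standard error of the mean estimate, plus the plug-in
#' heritability.
#'
#' @param truth a [trait_model()] holding the generating parameters.
#' @param n_replicates simulation replicates (>= 2; 50+ for stable
#'   summaries).
#' @param seed RNG seed; replicate seeds are derived from it.
#' @param design_args arguments to [build_pedigree()] (default: the
#'   study-scale design of [cricket_design()]).
#' @param spec optional [model_spec()]; default is the standard
#'   dam-in-sire / sire-in-block / block intercept model.
#' @return A `recovery_report` data frame (parameter, truth, mean, bias,
#'   rmse, mc_se) with the replicate estimates in `attr(, "estimates")`.
#' @export
recovery_harness <- function(truth, n_replicates = 50, seed = 1,
                             design_args = list(attrition = 29 / 708),
                             spec = NULL) {
  stopifnot(inherits(truth, "trait_model"))
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  check_seed(seed)
  spec <- spec %||% model_spec("value",
                               fixed = c("treatment", "sex",
                                         "treatment:sex"),
                               random = list(ran_intercept("dam_in_sire"),
                                             ran_intercept("sire_in_block"),
                                             ran_intercept("block")))
  pars <- c("V_S", "V_M", "V_block", "V_R", "h2")
  est <- matrix(NA_real_, n_replicates, length(pars),
                dimnames = list(NULL, pars))
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    res <- try({
      design <- do.call(build_pedigree,
                        modifyList(design_args, list(seed = seed + i)))
      ph <- simulate_trait(design, truth, seed = seed + 100000L + i)
      fit <- fit_reml(spec, ph)
      s <- qg_summary(fit)
      roles <- qg_roles(fit)
      c(roles$V_S, roles$V_M, roles$V_block %||% NA_real_, roles$V_R, s$h2)
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L
    else est[i, ] <- res
  }
  truth_vec <- c(truth$V_S, truth$V_M, truth$V_block, truth$V_R,
                 heritability(truth$V_S, truth$V_M, truth$V_block,
                              truth$V_R))
  out <- data.frame(
    parameter = pars,
    truth = truth_vec,
    mean = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - truth_vec,
    rmse = sqrt(colMeans((est - matrix(truth_vec, nrow(est), ncol(est),
                                       byrow = TRUE))^2, na.rm = TRUE)),
    mc_se = apply(est, 2, sd, na.rm = TRUE) / sqrt(colSums(!is.na(est))),
    row.names = NULL
  )
  structure(out, class = c("recovery_report", "data.frame"),
            estimates = est, seed = seed, n_failed = n_failed)
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed), seed %d\n",
              nrow(attr(x, "estimates")), attr(x, "n_failed"),
              attr(x, "seed")))
  print.data.frame(x, digits = digits)
  invisible(x)
}
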