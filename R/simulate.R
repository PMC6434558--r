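# Phenotype simulation over a breeding design.  All random draws are
# Gaussian; the latent per-level effects are exported alongside the
# phenotypes (attribute "truth") so that parameter-recovery tests can check
# bookkeeping exactly.

# Draw the shared random-effect structure (block, sire intercept+slope, dam,
# test day, per-individual covariates) for a design under the current RNG
# state.  Returns the flat pedigree table plus effect lookups.
simulate_structure <- function(design, model) {
  validate_design(design)
  tab <- as.data.frame(design)
  n <- nrow(tab)

  blocks <- design$blocks$block
  sires <- design$sires$sire
  dams <- design$dams$dam

  block_e <- setNames(rnorm(length(blocks), 0, sqrt(model$V_block)), blocks)
  sire_is <- draw_intercept_slope(length(sires), model$V_S, model$V_slope,
                                  if (model$V_slope > 0) model$r_is else 0)
  sire_int <- setNames(sire_is[, 1], sires)
  sire_slope <- setNames(sire_is[, 2], sires)
  dam_e <- setNames(rnorm(length(dams), 0, sqrt(model$V_M)), dams)

  days <- sprintf("T%02d", seq_len(model$n_testdays))
  day_e <- setNames(rnorm(length(days), 0, sqrt(model$V_testday)), days)

  # round-robin assignment of test days within each family over a shuffled
  # day order, so each family spans several days and each day several
  # families
  tab$test_day <- NA_character_
  for (idx in split(seq_len(n), factor(tab$dam, levels = dams))) {
    if (!length(idx)) next
    ord <- sample(days)
    tab$test_day[idx] <- ord[((seq_along(idx) - 1L) %% length(days)) + 1L]
  }
  tab$test_day <- factor(tab$test_day, levels = days)
  tab$days_after_eclosion <- sample(7:14, n, replace = TRUE)

  low <- as.numeric(tab$treatment == "low")
  male <- as.numeric(tab$sex == "M")
  fixed <- model$mu + model$beta_density * low + model$beta_sex * male +
    model$beta_density_sex * low * male

  list(tab = tab, n = n, low = low, male = male, fixed = fixed,
       block_e = block_e, sire_int = sire_int, sire_slope = sire_slope,
       dam_e = dam_e, day_e = day_e)
}

# Assemble the latent (residual-free) value and the truth table.
latent_value <- function(s) {
  s$fixed +
    s$block_e[s$tab$block] +
    s$sire_int[s$tab$sire] + s$sire_slope[s$tab$sire] * s$low +
    s$dam_e[s$tab$dam] +
    s$day_e[as.character(s$tab$test_day)]
}

truth_tables <- function(s, residual) {
  per_row <- data.frame(
    individual = s$tab$individual,
    fixed = s$fixed,
    block_effect = unname(s$block_e[s$tab$block]),
    sire_intercept = unname(s$sire_int[s$tab$sire]),
    sire_slope_contrib = unname(s$sire_slope[s$tab$sire] * s$low),
    dam_effect = unname(s$dam_e[s$tab$dam]),
    testday_effect = unname(s$day_e[as.character(s$tab$test_day)]),
    residual = residual
  )
  list(per_row = per_row,
       effects = list(block = s$block_e, sire_intercept = s$sire_int,
                      sire_slope = s$sire_slope, dam = s$dam_e,
                      test_day = s$day_e))
}

#' Simulate a single-measurement trait over a breeding design
#'
#' Generates one phenotype per offspring as the sum of the fixed part, the
#' block, sire (intercept plus density slope), dam and test-day effects, and
#' a Gaussian residual, per the generating [trait_model()].  High density is
#' the reaction-norm intercept level; the sire slope is added for
#' low-density offspring.
#'
#' @param design a `breeding_design` from [build_pedigree()].
#' @param model a [trait_model()].
#' @param seed RNG seed; output is deterministic given the seed.
#' @param trait name of the phenotype column (default `"value"`).
#' @return A phenotype data frame (individual, sire, dam, block, treatment,
#'   sex, test_day, days_after_eclosion, trait column) carrying the latent
#'   effects in `attr(, "truth")`.
#' @examples
#' d <- build_pedigree(n_blocks = 2, sires_per_block = 2, dams_per_sire = 2,
#'                     offspring_per_dam_per_treatment = 3, seed = 1)
#' ph <- simulate_trait(d, trait_model(mu = 5, V_S = 1, V_R = 4), seed = 2)
#' head(ph)
#' @export
simulate_trait <- function(design, model, seed = 1, trait = "value") {
  stopifnot(inherits(model, "trait_model"))
  with_seed(seed, {
    s <- simulate_structure(design, model)
    residual <- rnorm(s$n, 0, sqrt(model$V_R))
    value <- latent_value(s) + residual
    out <- s$tab[, c("individual", "sire", "dam", "block", "treatment",
                     "sex", "test_day", "days_after_eclosion")]
    out[[trait]] <- unname(value)
    attr(out, "truth") <- truth_tables(s, residual)
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate repeated per-minute activity
#'
#' Long-format simulation (one row per individual per minute) adding
#' individual-level correlated (intercept, time-slope) pairs and fixed
#' linear/quadratic time effects to the family structure of
#' [simulate_trait()].  Observation time is standardized to mean 0, SD 1
#' across the minute grid.
#'
#' @param design a `breeding_design`.
#' @param model a [repeated_model()].
#' @param seed RNG seed.
#' @param trait name of the response column.
#' @return A long phenotype data frame with `minute`, `time_std`, `time_std2`
#'   columns; latent effects (including per-individual intercepts/slopes) in
#'   `attr(, "truth")`.
#' @export
simulate_repeated_activity <- function(design, model, seed = 1,
                                       trait = "value") {
  if (!inherits(model, "repeated_model")) {
    stop("`model` must be a repeated_model()", call. = FALSE)
  }
  with_seed(seed, {
    s <- simulate_structure(design, model)
    ids <- s$tab$individual
    ind_is <- draw_intercept_slope(s$n, model$V_I_int, model$V_I_slope,
                                   if (model$V_I_slope > 0) model$r_I else 0)
    ind_int <- setNames(ind_is[, 1], ids)
    ind_slope <- setNames(ind_is[, 2], ids)

    minutes <- seq_len(model$n_minutes)
    t_std <- (minutes - mean(minutes)) / sd(minutes)
    base <- latent_value(s)

    long <- s$tab[rep(seq_len(s$n), each = model$n_minutes),
                  c("individual", "sire", "dam", "block", "treatment",
                    "sex", "test_day", "days_after_eclosion")]
    long$minute <- rep(minutes, times = s$n)
    long$time_std <- rep(t_std, times = s$n)
    long$time_std2 <- long$time_std^2
    rownames(long) <- NULL

    residual <- rnorm(nrow(long), 0, sqrt(model$V_R))
    long[[trait]] <- rep(base, each = model$n_minutes) +
      model$beta_time * long$time_std + model$beta_time2 * long$time_std2 +
      ind_int[long$individual] + ind_slope[long$individual] * long$time_std +
      residual
    long[[trait]] <- unname(long[[trait]])

    truth <- truth_tables(s, residual = NA_real_)
    truth$effects$individual_intercept <- ind_int
    truth$effects$individual_slope <- ind_slope
    truth$per_row <- NULL
    truth$residual <- residual
    attr(long, "truth") <- truth
    attr(long, "seed") <- seed
    long
  })
}

#' Simulate right-censored emergence latencies
#'
#' Generates a latent Gaussian log-latency (on the `log(latency + 1)` scale)
#' via the machinery of [simulate_trait()], back-transforms it to seconds,
#' and right-censors at `cap_s`: values at or above the cap are recorded as
#' exactly `cap_s` with a censoring flag, emulating trials stopped at a
#' maximum observation time.
#'
#' @param design a `breeding_design`.
#' @param model a [trait_model()] for the latent log-scale latency.
#' @param cap_s censoring cap in seconds (default 1800).
#' @param seed RNG seed.
#' @return A phenotype data frame with `latency_s` (censored, seconds) and
#'   logical `censored` columns; the uncensored latent log-latency is kept
#'   in `attr(, "truth")$per_row$latent_log_latency`.
#' @export
simulate_latency <- function(design, model, cap_s = 1800, seed = 1) {
  if (!is.numeric(cap_s) || length(cap_s) != 1L || cap_s <= 0) {
    stop("`cap_s` must be a single positive number", call. = FALSE)
  }
  out <- simulate_trait(design, model, seed = seed, trait = ".log_latency")
  log_lat <- out$.log_latency
  latency <- pmax(exp(log_lat) - 1, 0)
  out$.log_latency <- NULL
  out$latency_s <- pmin(latency, cap_s)
  out$censored <- latency >= cap_s
  truth <- attr(out, "truth")
  truth$per_row$latent_log_latency <- log_lat
  attr(out, "truth") <- truth
  out
}
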