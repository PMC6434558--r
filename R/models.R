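#' Generating model for a single-measurement trait
#'
#' Describes the Gaussian generative model the variance-component analysis
#' assumes: a grand mean, fixed effects of density treatment (low vs the
#' high-density reference), sex (male vs female) and their interaction, and
#' independent Gaussian random effects for temporal block, sire, dam and test
#' day plus a residual.  A sire-level reaction norm over the density
#' treatment is expressed as correlated sire (intercept, slope) pairs: the
#' intercept applies at high density and the slope is added at low density.
#'
#' @param mu grand mean (trait units).
#' @param beta_density,beta_sex,beta_density_sex fixed-effect coefficients
#'   for the low-density treatment, male sex, and their interaction.
#' @param V_S,V_M,V_block,V_testday,V_R sire, dam, block, test-day and
#'   residual variances (trait units squared).
#' @param V_slope sire-level variance of the density reaction-norm slope
#'   (0 disables the G-by-E term).
#' @param r_is correlation between sire intercepts and slopes; ignored when
#'   `V_slope = 0`.
#' @param n_testdays number of test days over which siblings are spread.
#' @return A `trait_model` list, validated.
#' @examples
#' tm <- trait_model(mu = 5, V_S = 1, V_M = 1, V_block = 1, V_R = 4)
#' @export
trait_model <- function(mu = 0, beta_density = 0, beta_sex = 0,
                        beta_density_sex = 0,
                        V_S = 0, V_M = 0, V_block = 0, V_testday = 0,
                        V_R = 1, V_slope = 0, r_is = 0, n_testdays = 10) {
  for (nm in c("V_S", "V_M", "V_block", "V_testday", "V_R", "V_slope")) {
    check_variance(get(nm), nm)
  }
  check_correlation(r_is, "r_is")
  n_testdays <- check_count(n_testdays, "n_testdays")
  for (nm in c("mu", "beta_density", "beta_sex", "beta_density_sex")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  structure(list(mu = mu, beta_density = beta_density, beta_sex = beta_sex,
                 beta_density_sex = beta_density_sex,
                 V_S = V_S, V_M = V_M, V_block = V_block,
                 V_testday = V_testday, V_R = V_R,
                 V_slope = V_slope, r_is = r_is,
                 n_testdays = n_testdays),
            class = "trait_model")
}

#' Generating model for a repeated per-minute trait
#'
#' Extends [trait_model()] with individual-level correlated (intercept,
#' time-slope) pairs and fixed linear and quadratic effects of standardized
#' observation time, for traits observed once per minute over a short trial
#' (default 5 minutes).
#'
#' @inheritParams trait_model
#' @param V_I_int,V_I_slope individual intercept and time-slope variances.
#' @param r_I correlation between individual intercepts and slopes.
#' @param beta_time,beta_time2 fixed coefficients of standardized time and
#'   its square.
#' @param n_minutes observations per individual (>= 2).
#' @return A `repeated_model` list, validated.
#' @export
repeated_model <- function(mu = 0, beta_density = 0, beta_sex = 0,
                           beta_density_sex = 0,
                           V_S = 0, V_M = 0, V_block = 0, V_testday = 0,
                           V_R = 1, V_slope = 0, r_is = 0, n_testdays = 10,
                           V_I_int = 0, V_I_slope = 0, r_I = 0,
                           beta_time = 0, beta_time2 = 0, n_minutes = 5) {
  base <- trait_model(mu, beta_density, beta_sex, beta_density_sex,
                      V_S, V_M, V_block, V_testday, V_R, V_slope, r_is,
                      n_testdays)
  check_variance(V_I_int, "V_I_int")
  check_variance(V_I_slope, "V_I_slope")
  check_correlation(r_I, "r_I")
  n_minutes <- check_count(n_minutes, "n_minutes", min = 2L)
  for (nm in c("beta_time", "beta_time2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  structure(c(unclass(base),
              list(V_I_int = V_I_int, V_I_slope = V_I_slope, r_I = r_I,
                   beta_time = beta_time, beta_time2 = beta_time2,
                   n_minutes = n_minutes)),
            class = c("repeated_model", "trait_model"))
}
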