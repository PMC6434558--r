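#' Boldness score from a censored emergence latency
#'
#' Reverse-scores refuge-emergence latency so that larger values mean bolder
#' animals: latencies are right-censored at `cap_s` and the log-latency is
#' subtracted from the log of the cap, i.e.
#' `score = log(cap_s + 1) - log(min(latency_s, cap_s) + 1)`.
#' The `+ 1` offset keeps the log defined at latency 0; an animal censored
#' at the cap scores exactly 0.  The cap transform (not the sample maximum)
#' is used as the "maximum value", which makes scores comparable across
#' datasets and coincides with the sample maximum whenever censored animals
#' are present.
#'
#' @param latency_s nonnegative latencies in seconds.
#' @param cap_s censoring cap in seconds (default 1800, i.e. a 30-minute
#'   trial).
#' @return Boldness scores in `[0, log(cap_s + 1)]`, strictly decreasing in
#'   (censored) latency.
#' @examples
#' boldness_score(c(0, 100, 1800))
#' @export
boldness_score <- function(latency_s, cap_s = 1800) {
  if (!is.numeric(latency_s) || any(latency_s < 0, na.rm = TRUE)) {
    stop("latencies must be nonnegative seconds", call. = FALSE)
  }
  if (!is.numeric(cap_s) || length(cap_s) != 1L || cap_s <= 0) {
    stop("`cap_s` must be a single positive number", call. = FALSE)
  }
  log(cap_s + 1) - log(pmin(latency_s, cap_s) + 1)
}

#' Declare how a raw measurement becomes an analysis trait
#'
#' @param name trait name used in model specifications.
#' @param raw_column column of the phenotype table holding the raw values.
#' @param transform one of `"identity"`, `"log"` (natural log, positive
#'   values only; used e.g. for development time in days), `"sqrt"`
#'   (nonnegative values; used for total distances), `"log1p"`
#'   (`log(x + 1)`, for nonnegative values that may be exactly 0 such as
#'   per-minute distances).
#' @param censor_cap optional right-censoring cap applied before the
#'   transform.
#' @param direction optional free-text note on the sign convention.
#' @return A `trait_definition` list.
#' @export
trait_definition <- function(name, raw_column = name,
                             transform = c("identity", "log", "sqrt",
                                           "log1p"),
                             censor_cap = NULL, direction = NULL) {
  transform <- match.arg(transform)
  if (!is.null(censor_cap) &&
      (!is.numeric(censor_cap) || length(censor_cap) != 1L ||
       censor_cap <= 0)) {
    stop("`censor_cap` must be a single positive number or NULL",
         call. = FALSE)
  }
  structure(list(name = name, raw_column = raw_column,
                 transform = transform, censor_cap = censor_cap,
                 direction = direction),
            class = "trait_definition")
}

#' Apply a trait transform
#'
#' @param values raw numeric values.
#' @param def a [trait_definition()] or the name of a transform.
#' @return Transformed values.
#' @examples
#' transform_trait(100, trait_definition("act", transform = "sqrt"))
#' @export
transform_trait <- function(values, def) {
  if (is.character(def)) def <- trait_definition("trait", transform = def)
  stopifnot(inherits(def, "trait_definition"))
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  if (!is.null(def$censor_cap)) values <- pmin(values, def$censor_cap)
  switch(def$transform,
    identity = values,
    log = {
      if (any(values <= 0, na.rm = TRUE)) {
        stop("log transform requires strictly positive values", call. = FALSE)
      }
      log(values)
    },
    sqrt = {
      if (any(values < 0, na.rm = TRUE)) {
        stop("sqrt transform requires nonnegative values", call. = FALSE)
      }
      sqrt(values)
    },
    log1p = {
      if (any(values < 0, na.rm = TRUE)) {
        stop("log1p transform requires nonnegative values", call. = FALSE)
      }
      log1p(values)
    }
  )
}

#' Standardize a covariate to mean 0 and sample SD 1
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return The centred and scaled vector.
#' @export
standardize_covariate <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  ok <- is.finite(values)
  if (length(unique(values[ok])) < 2L) {
    stop("cannot standardize a constant covariate", call. = FALSE)
  }
  (values - mean(values[ok])) / sd(values[ok])
}
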