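# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  check_seed(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  invisible(seed)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != round(x))) {
    stop(sprintf("`%s` must contain integer counts >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_variance <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single nonnegative number", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

check_correlation <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || abs(x) > 1) {
    stop(sprintf("`%s` must lie in [-1, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Draw n correlated (intercept, slope) pairs with the given variances and
# correlation; returns an n x 2 matrix.  Degenerate variances are allowed.
draw_intercept_slope <- function(n, v_int, v_slope, r) {
  if (v_slope == 0 && v_int == 0) {
    return(matrix(0, n, 2))
  }
  sigma <- matrix(c(v_int, r * sqrt(v_int * v_slope),
                    r * sqrt(v_int * v_slope), v_slope), 2, 2)
  out <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma, tol = 1e-8)
  if (n == 1L) out <- matrix(out, nrow = 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
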