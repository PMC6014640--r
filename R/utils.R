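# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}

# Round half away from zero to `digits` decimals (display convention for
# the evaluation tables; base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Full (polynomial) convolution of a long vector with a short filter.
# Time-domain via stats::filter: O(n * length(b)), immune to the bad-length
# FFT pathologies of stats::convolve.
conv_full <- function(a, b) {
  na <- length(a); nb <- length(b)
  xx <- c(rep(0, nb - 1L), a, rep(0, nb - 1L))
  y <- stats::filter(xx, b, method = "convolution", sides = 1L)
  as.numeric(y[nb:(na + 2L * nb - 2L)])
}

# Local extrema of a numeric series under the strict-neighbour convention.
# A run of equal values bounded by strictly smaller (larger) neighbours is a
# single maximum (minimum) located at the run's first index.  With
# `boundary = TRUE` the first/last runs may qualify by one-sided comparison.
# Returns list(max_idx, min_idx) of 1-based indices in the input series.
local_extrema <- function(x, boundary = FALSE) {
  r <- rle(as.numeric(x))
  v <- r$values
  k <- length(v)
  starts <- cumsum(c(1L, r$lengths[-k]))
  if (k == 1L) return(list(max_idx = integer(0), min_idx = integer(0)))
  is_max <- logical(k); is_min <- logical(k)
  if (k >= 3L) {
    i <- 2:(k - 1L)
    is_max[i] <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
    is_min[i] <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  }
  if (boundary) {
    is_max[1L] <- v[1L] > v[2L];      is_min[1L] <- v[1L] < v[2L]
    is_max[k]  <- v[k] > v[k - 1L];   is_min[k]  <- v[k] < v[k - 1L]
  }
  list(max_idx = starts[is_max], min_idx = starts[is_min])
}
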