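# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators never disturb user RNG streams
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# linear interpolation of the time at which `y` crosses `level`, searching the
# segment between samples i and i+1; y, t equal-length vectors
cross_time <- function(t, y, i, level) {
  y0 <- y[i]; y1 <- y[i + 1L]
  if (y1 == y0) return(t[i])
  t[i] + (level - y0) / (y1 - y0) * (t[i + 1L] - t[i])
}

# quadratic (three-point) sub-sample interpolation of an extremum at index i
# returns fractional offset in [-0.5, 0.5]
quad_peak_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den == 0) return(0)
  off <- 0.5 * (ym - yp) / den
  max(-0.5, min(0.5, off))
}
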