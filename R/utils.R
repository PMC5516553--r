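# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Truncated-normal draws by rejection sampling: resample until inside
# [lower, upper], never clip (clipping puts point mass on the boundary).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  stopifnot(lower < upper, sd >= 0)
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside [lower, upper]")
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to terminate; check the valid range")
  }
  out
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Display rounding for reported percentages: one decimal first, then integer
# (half away from zero at both stages). This two-stage chain reproduces the
# source tables' printed values, e.g. 93/209 = 44.498% -> 44.5 -> 45.
percent_round <- function(x) round_half_up(round_half_up(x, 1L))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_out_of_range <- function(x, lower, upper, what) {
  if (any(!is.finite(x)) || any(x < lower) || any(x > upper))
    stop(sprintf("%s must lie in [%s, %s]", what, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
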