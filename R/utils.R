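# Internal helpers shared across modules.

# Derive one reproducible sub-seed per replicate from a master seed, so
# replicate b is identical no matter how many replicates are requested or
# in what order they are generated.  Kept below 2^31 (R integers).
replicate_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# linear interpolation with clamped extrapolation
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# fast clamped linear interpolation: x must be sorted non-decreasing.
# Plateaus (dx == 0) take the left node; out-of-range values are clamped.
fast_interp <- function(x, y, xout) {
  n <- length(x)
  i <- findInterval(xout, x, all.inside = TRUE)
  dx <- x[i + 1L] - x[i]
  w <- ifelse(dx > 0, (xout - x[i]) / dx, 0)
  w <- pmin(pmax(w, 0), 1)
  y[i] * (1 - w) + y[i + 1L] * w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
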