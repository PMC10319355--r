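# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Bilinear interpolation of a numeric matrix at (possibly fractional)
# 1-based (row, col) coordinates; values outside the matrix read as 0.
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  if (r < 1 || r > nr || c < 1 || c > nc) return(0)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r1, c0] * fr * (1 - fc) +
    m[r0, c1] * (1 - fr) * fc + m[r1, c1] * fr * fc
}

# Quantiles by linear interpolation between order statistics (R type 7);
# the single quantile definition used for all boxplot-style summaries.
box_quantiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

# Running mean with a symmetric window that shrinks at the ends, so the
# first and last values stay anchored near the original endpoints.
running_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n < 3) return(x)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
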