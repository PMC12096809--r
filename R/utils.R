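#' Derive a child seed from a run-level seed and a label
#'
#' Every stochastic operation in the package takes an explicit seed. A single
#' run-level seed is fanned out to per-unit / per-stimulus RNG streams by
#' stable string hashing, so adding or reordering units never perturbs the
#' spike trains of the others.
#'
#' @param seed Integer run-level seed.
#' @param ... Character or numeric labels identifying the stream
#'   (e.g. unit id, stimulus id).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
fan_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  code
}

# Centered moving average with edge-value padding; n = window in samples.
moving_average <- function(x, n) {
  n <- as.integer(max(1L, n))
  if (n == 1L || length(x) < 2L) return(x)
  xp <- c(rep(x[1L], n), x, rep(x[length(x)], n))
  y <- stats::filter(xp, rep(1 / n, n), sides = 2)
  as.numeric(y)[(n + 1L):(n + length(x))]
}

# Magnitude of the analytic signal (FFT-based Hilbert transform). The signal
# is zero-padded to a fast FFT length (factors 2/3/5) and truncated back;
# synthesized calls start and end at ~zero amplitude, so the padding has no
# visible edge effect.
analytic_magnitude <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  if (n == 1L) return(abs(x))
  m <- stats::nextn(n, 2L)
  X <- stats::fft(c(x, numeric(m - n)))
  h <- numeric(m)
  h[1L] <- 1
  h[m / 2L + 1L] <- 1
  h[2L:(m / 2L)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

# Tukey (tapered cosine) window; alpha = fraction of window inside the ramps.
tukey_window <- function(n, alpha = 0.2) {
  if (n < 2L) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

# Classed error signalled when a unit shows no stimulus-evoked activity.
stop_nonresponsive <- function(msg = "unit is not responsive") {
  cond <- structure(
    class = c("vocsel_nonresponsive", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
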