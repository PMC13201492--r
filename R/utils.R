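# Internal helpers shared across stages.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Map firing rates between Hz and the normalized scale
#'
#' The simulator carries rates on a normalized [0, 1] scale, the affine
#' map from the mossy fibre physiological range. Values outside the range
#' are clamped.
#'
#' @param hz,x rates in Hz / on the normalized scale.
#' @param cfg a [NetworkConfig-class].
#' @return numeric vector of the same length.
#' @examples
#' cfg <- networkConfig()
#' normalizeHz(c(50, 175, 300), cfg)   # 0, 0.5, 1
#' @export
normalizeHz <- function(hz, cfg) {
  clamp01((hz - cfg@mossyRateMinHz) / (cfg@mossyRateMaxHz - cfg@mossyRateMinHz))
}

#' @rdname normalizeHz
#' @export
denormalizeHz <- function(x, cfg) {
  cfg@mossyRateMinHz + clamp01(x) * (cfg@mossyRateMaxHz - cfg@mossyRateMinHz)
}

# Evaluate expr under a locally scoped RNG seed; seed = NULL leaves the
# caller's RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stage seed from a run seed, kept inside 32-bit integer range.
stageSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Centred rolling mean; the window shrinks at the sequence ends so no bin
# is discarded. For even windows the extra bin is taken on the right.
rollingMean <- function(x, window) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  n <- length(x)
  if (window == 1L || n == 0L) return(as.numeric(x))
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Uniform draw of integers in [lo, hi], vectorized.
drawIntRange <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

# Weighted mean that tolerates uniform weights of any scale.
wmean <- function(x, w) sum(x * w) / sum(w)
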