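#' Construct a rate distribution specification
#'
#' @param family one of `"constant"`, `"uniform"`, `"normal"`,
#'   `"bimodal"`, `"discontinuous"`.
#' @param mean,sd location and spread in Hz (used by `constant`, `normal`;
#'   `sd` also by `bimodal`).
#' @param low,high hard bounds in Hz; every draw is clipped to them.
#' @param peaks numeric(2), peak locations of the bimodal mixture.
#' @param gap numeric(2), excised interval of the discontinuous family.
#' @return a [RateSpec-class].
#' @examples
#' rateSpec("uniform", low = 50, high = 300)
#' rateSpec("normal", mean = 150, sd = 25)
#' @export
rateSpec <- function(family = "uniform", mean = 175, sd = 25, low = 50,
                     high = 300, peaks = c(100, 250), gap = c(125, 225)) {
  new("RateSpec", family = family, mean = mean, sd = sd, low = low,
    high = high, peaks = peaks, gap = gap)
}

#' Draw mossy fibre firing rates
#'
#' `n` i.i.d. draws from the family described by `spec`, clipped to
#' `[low, high]`. Reproducible under `seed`.
#'
#' @param spec a [RateSpec-class].
#' @param n number of draws (> 0).
#' @param seed optional integer seed (locally scoped).
#' @return numeric vector of rates in Hz.
#' @export
drawRates <- function(spec, n, seed = NULL) {
  stopifnot(is(spec, "RateSpec"))
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  withSeed(seed, {
    x <- switch(spec@family,
      constant = rep(spec@mean, n),
      uniform = stats::runif(n, spec@low, spec@high),
      normal = stats::rnorm(n, spec@mean, spec@sd),
      bimodal = {
        pick <- sample(spec@peaks, n, replace = TRUE)
        stats::rnorm(n, pick, spec@sd)
      },
      discontinuous = {
        lo <- max(spec@gap[1], spec@low)
        hi <- min(spec@gap[2], spec@high)
        wLeft <- max(0, lo - spec@low)
        wRight <- max(0, spec@high - hi)
        if (wLeft + wRight <= 0)
          stop("discontinuous gap leaves no admissible range")
        side <- stats::runif(n) < wLeft / (wLeft + wRight)
        ifelse(side, stats::runif(n, spec@low, lo), stats::runif(n, hi, spec@high))
      },
      stop("unknown distribution family: ", spec@family)
    )
    pmin(spec@high, pmax(spec@low, x))
  })
}

#' Sinusoidal input profile across a row of microstrips
#'
#' Maps a fraction of one body wavelength onto `nStrips` microstrips:
#' strip i (0-based) receives a distribution centred on
#' `meanHz + ampHz * sin(phase + 2 * pi * waveFraction * i / (nStrips - 1))`,
#' with the per-strip spread and bounds taken from `spec`. This is the
#' commanded proprioceptive input of the anguilliform swimming model: each
#' myomere drives one strip, and neighbouring strips sit a small phase
#' step apart.
#'
#' @param nStrips number of strips (>= 2).
#' @param waveFraction fraction of one full body wavelength spanned by the
#'   row, in (0, 1].
#' @param phase cycle phase in radians.
#' @param meanHz,ampHz centre and amplitude of the commanded sinusoid.
#' @param spec template [RateSpec-class] providing family, spread and
#'   bounds; its `mean` is replaced per strip.
#' @return list of `nStrips` [RateSpec-class] objects.
#' @export
sineWaveProfile <- function(nStrips, waveFraction, phase, meanHz = 175,
                            ampHz = 125,
                            spec = rateSpec("normal", sd = 25)) {
  nStrips <- as.integer(nStrips)
  if (nStrips < 2L) stop("nStrips must be at least 2")
  if (waveFraction <= 0 || waveFraction > 1)
    stop("waveFraction must lie in (0, 1]")
  i <- seq_len(nStrips) - 1L
  centres <- meanHz + ampHz * sin(phase + 2 * pi * waveFraction * i /
    (nStrips - 1L))
  lapply(centres, function(m) {
    s <- spec
    s@mean <- m
    validObject(s)
    s
  })
}
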