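# Molecular layer: stellate sampling of the parallel fibre code,
# Purkinje dendritic-compartment integration, and the excitation /
# inhibition linear inversion.

#' Stellate cell sampling of the parallel fibre code
#'
#' Each sector j of the microzone overlies microfile j. Every stellate
#' cell of the sector receives `stellatePfContacts` (1000) parallel fibre
#' contacts, of which the active count k is Binomial(contacts,
#' activeFraction_j); the cell's rate is the mean of k rates sampled with
#' replacement from the microfile's pooled active rates (weighted when a
#' distal taper is configured). A cell with no active input sits at the
#' spontaneous floor (`stellateSpontaneous`).
#'
#' @param pf a [ParallelFiberCode-class].
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @return numeric matrix, sectors x `stellatePerSector`, normalized
#'   stellate rates.
#' @export
stellateInputs <- function(pf, cfg, seed = NULL) {
  nSec <- length(pf@rates)
  if (!nSec) stop("empty parallel fibre code")
  nSt <- cfg@stellatePerSector
  withSeed(seed, {
    out <- matrix(cfg@stellateSpontaneous, nrow = nSec, ncol = nSt)
    for (j in seq_len(nSec)) {
      k <- stats::rbinom(nSt, cfg@stellatePfContacts, pf@activeFraction[j])
      pool <- pf@rates[[j]]
      w <- pf@weights[[j]]
      tot <- sum(k)
      if (!length(pool) || tot == 0L) next
      draws <- pool[sample.int(length(pool), tot, replace = TRUE, prob = w)]
      grp <- rep.int(seq_len(nSt), k)
      means <- rowsum(draws, grp) / k[k > 0L]
      out[j, k > 0L] <- as.numeric(means)
    }
    out
  })
}

#' Purkinje dendritic-compartment integration
#'
#' Each sector holds `pcPerSector` (4) Purkinje cells. In every sector,
#' `stellatePerPcInner` (16) of the stellate cells -- 8 on each
#' mediolateral side -- are the inner-level cells afferent to Purkinje
#' cells. A stellate main axon runs sagittally (~450 um), so the pool in
#' range of one Purkinje side comprises the side's inner cells of its own
#' sector and of neighbouring sectors within
#' `stellateSagittalSpanSectors` (5, truncated at microzone ends). Each
#' of the `pcCompartments` (16) dendritic compartments takes the mean of
#' a random sample (size 8--12, without replacement) from one side's
#' pool, averaged with the matching sample mean from the other side. The
#' soma inhibition is the mean of the 16 compartment means, and the soma
#' firing rate follows by [linearInversion()].
#'
#' @param stellate matrix from [stellateInputs()].
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @return a [MolecularOutput-class].
#' @export
purkinjeCompartments <- function(stellate, cfg, seed = NULL) {
  nSec <- nrow(stellate)
  nSt <- ncol(stellate)
  if (!nSec || !nSt) stop("empty stellate pool")
  nPc <- cfg@pcPerSector
  nCmp <- cfg@pcCompartments
  half <- cfg@stellatePerPcInner %/% 2L
  h <- (cfg@stellateSagittalSpanSectors - 1L) %/% 2L
  sLo <- cfg@compartmentStellateSample[1]
  sHi <- cfg@compartmentStellateSample[2]
  mid <- nSt %/% 2L
  innerPerSide <- max(half, nSt %/% 4L)  # inner-level cells per side
  withSeed(seed, {
    # fixed inner-level identity per sector: `innerPerSide` cells per side
    innerA <- replicate(nSec, sample.int(mid, innerPerSide),
      simplify = FALSE)
    innerB <- replicate(nSec, mid + sample.int(nSt - mid, innerPerSide),
      simplify = FALSE)
    # each Purkinje cell is contacted by its own random `half` inner cells
    # per side in every sector of the sagittal span
    sidePool <- function(j, inner) {
      span <- max(1L, j - h):min(nSec, j + h)
      unlist(lapply(span, function(s)
        stellate[s, inner[[s]][sample.int(innerPerSide, half)]]),
        use.names = FALSE)
    }
    nTot <- nSec * nPc
    cmp <- matrix(0, nrow = nTot, ncol = nCmp)
    sector <- integer(nTot)
    row <- 0L
    for (j in seq_len(nSec)) {
      for (p in seq_len(nPc)) {
        row <- row + 1L
        sector[row] <- j
        poolA <- sidePool(j, innerA)
        poolB <- sidePool(j, innerB)
        nA <- length(poolA)
        nB <- length(poolB)
        sz <- matrix(drawIntRange(2L * nCmp, sLo, sHi), ncol = 2L)
        for (cc in seq_len(nCmp)) {
          m1 <- mean(poolA[sample.int(nA, min(sz[cc, 1L], nA))])
          m2 <- mean(poolB[sample.int(nB, min(sz[cc, 2L], nB))])
          cmp[row, cc] <- (m1 + m2) / 2
        }
      }
    }
    soma <- rowMeans(cmp)
    new("MolecularOutput",
      stellateRates = stellate,
      compartmentMeans = cmp,
      pcSomaInhibition = soma,
      pcSomaRate = linearInversion(soma, r0 = cfg@inversionR0,
        kE = cfg@inversionKE, kI = cfg@inversionKI),
      sector = sector)
  })
}

#' Excitation/inhibition linear inversion
#'
#' Purkinje firing is driven up by direct parallel fibre excitation and
#' down by the (steeper) feed-forward inhibition; both scale linearly with
#' parallel fibre drive, inhibition faster, so the net response is a
#' decreasing affine function clamped to [0, 1]:
#' `rate = clamp01(r0 + kE * drive - kI * drive)`.
#'
#' @param drive normalized parallel fibre drive in [0, 1].
#' @param r0 baseline rate at zero drive, in (0, 1].
#' @param kE,kI excitation and inhibition slopes, `kI > kE >= 0`.
#' @return normalized Purkinje rate(s).
#' @examples
#' linearInversion(0.5, r0 = 1, kE = 0.5, kI = 1.5)  # 0.5
#' @export
linearInversion <- function(drive, r0 = 1.0, kE = 0.5, kI = 1.5) {
  if (kI <= kE || kE < 0)
    stop("inversion requires kI > kE >= 0 (inhibition must dominate)")
  if (r0 <= 0 || r0 > 1) stop("r0 must lie in (0, 1]")
  clamp01(r0 + kE * drive - kI * drive)
}

#' Simulate the molecular layer of a microzone
#'
#' Stellate sampling then Purkinje compartment integration.
#'
#' @inheritParams stellateInputs
#' @return a [MolecularOutput-class].
#' @export
simulateMolecularLayer <- function(pf, cfg, seed = NULL) {
  st <- stellateInputs(pf, cfg, seed = stageSeed(seed, 11L))
  purkinjeCompartments(st, cfg, seed = stageSeed(seed, 12L))
}
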