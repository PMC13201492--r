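---
title: "The cerebellar network computation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cerebellar network computation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerenet)
```

# The model

`cerenet` simulates a linear model of the cerebellar network that controls
locomotor output: a feed-forward chain of anatomically constrained
random-sampling stages. Information is carried at population level, in the
instantaneous frequency distribution of firing rates of a topographically
defined cell group, not in the identity or timing of individual signals.
Each stage draws independent random samples from its afferent distribution
and outputs sample means; by the central limit theorem every stage makes
the distribution narrower and more normal while leaving its mean linearly
coupled to the input mean. The end result is that the ~50 deep cerebellar
nuclear (DCN) projection neurons of a network fire at effectively
synchronized rates that are a linear function of the mossy fibre input
statistics.

The chain, per network (41 afferent microstrips x 100 fields feeding one
microzone and one DCN group):

1. **Terminal clustering** (`deriveFieldRates`). Each field samples
   `mfPerField` = 180 mossy fibres from its strip's population; each
   contributes a cluster of 7-8 terminal copies of the same rate. Clusters
   are about the size of a field and straddle field boundaries, so each
   cluster keeps a Binomial share of its copies in-field (expected share
   `clusterInFieldFraction()` ~ 0.52, jittered +/-0.3 per cluster). That
   reconciles the three anatomical constants - 180 mossy fibres/field,
   ~700 glomeruli/field, clusters of 7-8 - without double counting:
   straddling clusters belong to both neighbouring fields, and each field
   draws its own sample from the common strip population. Copies add no
   new values (duplication is a wiring cost, not information).
2. **Golgi ensemble conversion** (`golgiConversion`). Ten Golgi cells per
   field each hold 5 dendritic states (means of 4 sampled terminals);
   somatic rates are dendritic means. Every glomerulus of a field then
   samples 8-12 somatic rates from the 30-cell, 3-field ensemble centred
   on its field (2-field ensembles at strip ends, where no third field
   exists). The glomerular spillover inhibition so obtained is narrow and
   tracks the mossy mean linearly.
3. **Granule activation** (`granuleActivation`). Each granule cell
   contacts 4 glomeruli carrying distinct mossy fibres; an input is
   dominant when its normalized rate exceeds `gain x` its own glomerulus's
   inhibition; a cell fires iff >= 3 inputs are dominant, at the mean of
   its dominant rates. `calibrateGain` bisects the gain to a target active
   fraction (~30% dense, ~1% sparse).
4. **Parallel fibre code** (`microfileAggregate`). Microfile j pools field
   j of all 41 strips: the code any sector of the microzone sees.
5. **Molecular layer** (`stellateInputs`, `purkinjeCompartments`).
   Stellate cells receive Binomial(1000, active fraction) active contacts
   and output the sample mean; Purkinje dendritic compartments average
   8-12 inner stellate cells per side, drawn from a sagittal span of 5
   sectors (stellate main axons extend ~450 um); the soma averages its 16
   compartments. `linearInversion` converts parallel-fibre drive to the
   Purkinje rate: excitation and feed-forward inhibition both grow
   linearly with drive, inhibition faster, so the net response is
   decreasing (defaults r0 = 1, kE = 0.5, kI = 1.5, i.e. slope -1).
6. **DCN group** (`dcnGroupRates`). Each of 50 DCNs averages a random
   30-50 Purkinje soma rates and outputs the normalized complement
   (DCN rates are inversely related to Purkinje rates). Spike-level
   convergence is modelled separately (`generateRaster`,
   `convergeAndSmooth`, `reliabilityCurve`): per-ms Bernoulli spiking
   from a shared time-varying discharge probability, summed over 10-80
   afferents and read through a 2-ms rolling window.
7. **STP timing** (`netInhibitionWave`, `measureTimeShift`). Net
   short-term plasticity at the Purkinje-DCN synapse is reduced to a term
   proportional to the derivative of the Purkinje rate wave, so summed
   inhibition is phase-advanced by `atan(k*w)` - nearly constant in
   milliseconds for wavelengths above ~100 ms, which suits compensation
   of fixed spinal conduction delays.
8. **Swimming pipeline** (`runSwimSnapshot`, `phaseSweep`). A fraction of
   one body wave maps onto the 41 strips
   (`sineWaveProfile`); the chain runs end to end and the readability
   index asks how much of the commanded modulation survives to the DCN
   group mean.

# Scales and units

All rates are carried both in Hz and on a normalized [0, 1] scale, the
affine map from the mossy fibre physiological range (50-300 Hz,
`normalizeHz`). Comparisons and thresholds act on the normalized scale;
exact calibration of each stage is not a system requirement, only
linearity and sign, so the inversion coefficients are exposed in the
configuration rather than fitted.

# Key parameters

All anatomical constants live in `NetworkConfig` (see `?NetworkConfig`
for the full list with defaults and units); none is hard-coded
downstream, and `readNetworkConfig()`/`writeNetworkConfig()` round-trip
the configuration through YAML or JSON. The tunables that matter most:

* `granuleTargetFraction` (0.01): the regulated sparse fraction of active
  granule cells; `calibrateGain` reaches any target in (0, 1) that the
  input supports.
* `gain` (calibrated): multiplies glomerular inhibition in the dominance
  test. Calibration uses common random numbers - the dendritic sampling
  structure is drawn once and re-thresholded - so the empirical active
  fraction is exactly non-increasing in the gain and bisection is clean;
  the search asserts monotonicity and reports diagnostics if the target
  cannot be bracketed.
* `stellateSagittalSpanSectors` (5): sagittal reach of stellate axons in
  sectors (~450 um at 200 um per sector). Purkinje compartments sample
  inner stellate cells across this span; with a span of 1 a Purkinje
  soma can only average its own sector's 16 afferent cells, which places
  an analytic floor of 1/4 on the soma/stellate SD ratio.
* `distalTaperMin` (1.0): pooling weight of the most distal strip.
  Parallel fibres make about half as many synapses distally, which a
  value of 0.5 represents; the default is uniform pooling because the
  taper itself leaves ~12% of a commanded full-body-wave amplitude in the
  pooled drive (the weighted circular mean of a sine no longer cancels),
  which would make full-wave input partially readable - contrary to the
  phase-invariance the full-wave experiment demonstrates.
* `inversionR0`, `inversionKE`, `inversionKI`: the Purkinje inversion;
  validity enforces kI > kE >= 0 (inhibition must dominate).
* `stpGainMs` (10): derivative gain k of the STP model, in ms.
* `silentSynapseFraction` (0.825): enters only as a multiplicative
  working-synapse fraction on the Purkinje cell's effective contact count
  (reported by `describeNetwork()`); no learning dynamics are modelled.

# Design choices in open territory

* **Strip-count conventions.** The anatomy uses 41 afferent strips (20
  each side plus the one beneath the microzone) for simulation and
  overlap calculations, but nominal per-network tallies (4,000 fields,
  350,000 parallel fibres per microfile) conventionally use 40; the
  configuration carries both and each accessor documents its convention.
* **Granule code density per experiment.** Regulation, stellate
  sampling and microzone synchrony run at the sparse code (~1%), where
  stellate cells see single-figure active inputs. The swimming pipeline
  defaults to the dense code (~30%): at sparse targets the calibrated
  dominance threshold sits ~1 SD above the local mean, and strips
  commanded near the 300 Hz ceiling cannot express a tail above it -
  they fall silent at peak phases and the readout collapses. At the
  dense target the threshold approximately equals the local mean, which
  is shift-invariant and ceiling-safe; the readability index depends
  only on pooled means, not on code density. `targetFraction` is an
  argument of the swim functions.
* **Glomerular sampling with replacement.** Step 2 of the Golgi
  conversion samples the 30-cell ensemble with replacement (the somatic
  integration step is without replacement across a cell's own
  dendrites); with samples of 8-12 from 30 the finite-population
  correction is small, and the acceptance oracle simulates the same
  declared scheme.
* **Ensemble ends.** The 3-field ensemble window truncates to 2 fields at
  strip ends; ensembles overlap continuously in reality and no end rule
  is stated, so truncation keeps every field defined.
* **Stellate spontaneous floor** (0.1 normalized): stellate cells fire
  spontaneously; a cell with no active parallel fibre input emits the
  floor rather than zero. At the sparse code the probability of zero
  active inputs is ~e^-10, so the floor is effectively never seen; it
  matters only for pathologically silent codes.
* **Rolling-average edges** shrink the window at sequence ends rather
  than discarding bins, conserving the spike count.
* **DCN inversion** is the normalized complement (1 - mean), not a
  biophysical pacemaker; spontaneous 70-110 Hz pacemaking and
  nucleo-olivary feedback are out of scope.
* **Time-shift measurement** uses circular cross-correlation over whole
  cycles with parabolic interpolation around the argmax, giving
  sub-millisecond resolution at 1-ms sampling; central differences keep
  the derivative phase-exact (the sinc amplitude bias at 1 ms sampling
  is < 0.1% for wavelengths >= 100 ms).

# What the synthetic inputs emulate - and what they do not

All inputs are synthesized: parameterized rate distributions (uniform,
normal, twin-peaked, discontinuous, constant - `rateSpec`), clipped to
the physiological range, and sinusoidal per-strip profiles for swimming.
They emulate a single instant of a sustained state: rates are treated as
analogue values, so granule bursting, spike irregularity (except in the
dedicated DCN convergence module), conduction delays, and temporal
dynamics of any kind are outside the generator. Passing tests therefore
show that the *statistical* claims hold under the stated anatomy - they
do not show that real mossy fibre distributions have these shapes, nor
that biophysical nonlinearities are in fact compensated into the linear
regime the model assumes. The granule-to-Golgi feedback loops that would
further align the active fraction across locations are deliberately not
modelled, so field-to-field dispersion here is an upper bound on the
model's own claim.

# Problem sizes

Simulations default to the full anatomy: 8,750 granule cells per field,
100 fields per strip, 41 strips, 8,000 stellate and 400 Purkinje cells
per microzone. The test and acceptance suites run most stages at that
scale; where a quantity is a mean or fraction that is insensitive to the
Monte-Carlo cell count, the granule count per field is reduced and stated
(2,000-4,000 for calibration and tracking; 1,000 for the swimming phase
sweeps, whose readability index depends only on pooled means). Spike
convergence uses 20 cycles of a 500-ms sinusoid and 10 replicate data
sets per ratio.

# Known limitations

* Purkinje soma values within and near a sector are positively
  correlated (shared stellate pools, shared microfile code), so
  independence-assuming two-sample tests on raw soma values are
  anti-conservative; compare summary statistics, or resample at the
  sector level.
* The per-field inhibition is set by only 30 ensemble Golgi cells
  sampling 20 terminals each, leaving ~1% (of range) field-to-field
  dispersion that the excluded feedback loops would reduce.
* The linear chain is exact only away from the rate floor and ceiling;
  sparse codes near the 300 Hz ceiling saturate (see the swim design
  choice above).
* One network, one instant: cross-network propagation, contralateral
  routing and myomere mechanics are represented only as metadata on a
  single network's run.
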