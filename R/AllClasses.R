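#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GatingModel
## ---------------------------------------------------------------------------

#' Markov gating model for a mechanosensitive channel
#'
#' A small continuous-time Markov scheme (by default the linear three-state
#' chain closed -- open -- inactivated) with one stimulus-coupled transition.
#' Off-diagonal entries of `baseRates` are the transition rates in 1/ms at
#' saturating stimulus; the rate identified by `coupled` (default the
#' closed-to-open opening rate) is scaled by a threshold-adjusted Boltzmann
#' function of the stimulus (see [boltzmannActivation()]). `gammaPS` and
#' `eRevMV` parameterize the unitary current \eqn{i = \gamma (V - E_{rev})}.
#'
#' @slot name label of the model (e.g. a preset name).
#' @slot stateNames ordered state labels; must contain `"O"`, the conducting
#'   state.
#' @slot baseRates square matrix of base transition rates (1/ms), zero
#'   diagonal, non-negative off-diagonal.
#' @slot coupled integer length-2 `(from, to)` index of the stimulus-coupled
#'   transition.
#' @slot sHalf half-activation stimulus (um for poke depth, mmHg for
#'   pressure), same coordinate as the protocols the model is used with.
#' @slot slope Boltzmann slope factor (> 0), same units as `sHalf`.
#' @slot gammaPS unitary conductance in pS (> 0).
#' @slot eRevMV reversal potential in mV.
#'
#' @seealso [buildPreset()], [generatorMatrix()], [openProbabilityTimecourse()]
#' @export
setClass("GatingModel",
  representation(
    name = "character",
    stateNames = "character",
    baseRates = "matrix",
    coupled = "integer",
    sHalf = "numeric",
    slope = "numeric",
    gammaPS = "numeric",
    eRevMV = "numeric"
  )
)

setValidity("GatingModel", function(object) {
  msg <- character()
  k <- length(object@stateNames)
  if (k < 2L) msg <- c(msg, "need at least two states")
  if (!"O" %in% object@stateNames) msg <- c(msg, "stateNames must contain the conducting state \"O\"")
  if (!all(dim(object@baseRates) == c(k, k))) {
    msg <- c(msg, "baseRates must be a square matrix matching stateNames")
  } else {
    if (any(!is.finite(object@baseRates))) msg <- c(msg, "all rates must be finite")
    if (any(object@baseRates < 0)) msg <- c(msg, "all rates must be >= 0")
    if (any(diag(object@baseRates) != 0)) msg <- c(msg, "baseRates diagonal must be 0")
  }
  if (length(object@coupled) != 2L || any(object@coupled < 1L) || any(object@coupled > k)) {
    msg <- c(msg, "coupled must index a (from, to) transition")
  }
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope <= 0) {
    msg <- c(msg, "slope factor must be > 0")
  }
  if (length(object@gammaPS) != 1L || !is.finite(object@gammaPS) || object@gammaPS <= 0) {
    msg <- c(msg, "gamma must be > 0")
  }
  if (length(object@eRevMV) != 1L || !is.finite(object@eRevMV)) msg <- c(msg, "e_rev must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("stateNames", "GatingModel", function(x) x@stateNames)

#' @rdname accessors
#' @export
setMethod("gammaPS", "GatingModel", function(x) x@gammaPS)

#' @rdname accessors
#' @export
setMethod("eRevMV", "GatingModel", function(x) x@eRevMV)

setMethod("show", "GatingModel", function(object) {
  cat("GatingModel \"", object@name, "\": ",
    paste(object@stateNames, collapse = " - "), "\n", sep = "")
  cat("  gamma = ", object@gammaPS, " pS, E_rev = ", object@eRevMV, " mV\n", sep = "")
  cat("  Boltzmann coupling on ",
    object@stateNames[object@coupled[1]], "->", object@stateNames[object@coupled[2]],
    ": s_half = ", object@sHalf, ", slope = ", object@slope, "\n", sep = "")
  cat("  base rates (1/ms):\n")
  m <- object@baseRates
  dimnames(m) <- list(object@stateNames, object@stateNames)
  print(m)
})

## ---------------------------------------------------------------------------
## StimulusProtocol
## ---------------------------------------------------------------------------

#' Mechanical stimulus protocol
#'
#' Describes one mechanical stimulus: a poke-depth step (instantaneous step to
#' `amplitude`) or a pressure step reached by a linear ramp at `rampRateMmHgMs`
#' (default 8.3 mmHg/ms, the maximum slew rate of a high-speed pressure
#' clamp). An optional strictly increasing `amplitudeSeries` describes a
#' depth/pressure series; [simulateWholeCell()] emits one sweep per entry.
#'
#' @slot kind `"poke"` (amplitude in um) or `"pressure"` (amplitude in mmHg).
#' @slot onsetMs stimulus onset (ms, >= 0).
#' @slot durationMs stimulus duration (ms, > 0).
#' @slot amplitude stimulus amplitude (um or mmHg).
#' @slot rampRateMmHgMs pressure slew rate (mmHg/ms, > 0); ignored for pokes.
#' @slot amplitudeSeries optional strictly increasing amplitudes.
#'
#' @seealso [stimulusProtocol()], [stimulusWaveform()]
#' @export
setClass("StimulusProtocol",
  representation(
    kind = "character",
    onsetMs = "numeric",
    durationMs = "numeric",
    amplitude = "numeric",
    rampRateMmHgMs = "numeric",
    amplitudeSeries = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("poke", "pressure")) msg <- c(msg, "kind must be \"poke\" or \"pressure\"")
  if (object@onsetMs < 0) msg <- c(msg, "onset must be >= 0")
  if (object@durationMs <= 0) msg <- c(msg, "duration must be > 0")
  if (object@rampRateMmHgMs <= 0) msg <- c(msg, "ramp rate must be > 0")
  if (length(object@amplitudeSeries) &&
    any(diff(object@amplitudeSeries) <= 0)) {
    msg <- c(msg, "amplitude series must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stimulus protocol
#'
#' @param kind `"poke"` or `"pressure"`.
#' @param onsetMs stimulus onset in ms.
#' @param durationMs stimulus duration in ms.
#' @param amplitude stimulus amplitude (um of indentation depth for pokes,
#'   mmHg for pressure steps).
#' @param rampRateMmHgMs pressure slew rate in mmHg/ms (default 8.3).
#' @param amplitudeSeries optional strictly increasing vector of amplitudes
#'   for a stimulus series.
#' @return A [StimulusProtocol-class] object.
#' @examples
#' stimulusProtocol("poke", onsetMs = 20, durationMs = 150, amplitude = 5)
#' @export
stimulusProtocol <- function(kind = c("poke", "pressure"), onsetMs, durationMs,
                             amplitude, rampRateMmHgMs = 8.3,
                             amplitudeSeries = numeric()) {
  kind <- match.arg(kind)
  new("StimulusProtocol",
    kind = kind, onsetMs = onsetMs, durationMs = durationMs,
    amplitude = amplitude, rampRateMmHgMs = rampRateMmHgMs,
    amplitudeSeries = as.numeric(amplitudeSeries)
  )
}

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol <", object@kind, ">: onset ", object@onsetMs,
    " ms, duration ", object@durationMs, " ms, amplitude ", object@amplitude,
    if (object@kind == "pressure") paste0(" mmHg (ramp ", object@rampRateMmHgMs, " mmHg/ms)") else " um",
    "\n", sep = "")
  if (length(object@amplitudeSeries)) {
    cat("  amplitude series:", paste(object@amplitudeSeries, collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation / recording configuration
#'
#' Recording conditions shared by the stochastic simulator and the current
#' renderer. The defaults mirror a standard patch-clamp acquisition chain:
#' 4-pole low-pass filtering at 1 kHz and digitization at 20 kHz.
#'
#' @slot nChannels number of channels in the membrane (>= 1).
#' @slot vHoldMV holding potential in mV.
#' @slot fsHz sampling rate in Hz (default 20000).
#' @slot filterCutoffHz low-pass -3 dB cutoff in Hz (default 1000); must be
#'   below the Nyquist frequency.
#' @slot noiseSdPA standard deviation of the Gaussian recording noise in pA,
#'   added before filtering (>= 0).
#' @slot sweepLengthMs sweep length in ms.
#' @slot seed integer seed for the simulation RNG (`NA` to use the current
#'   RNG state).
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nChannels = "integer",
    vHoldMV = "numeric",
    fsHz = "numeric",
    filterCutoffHz = "numeric",
    noiseSdPA = "numeric",
    sweepLengthMs = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "n_channels must be >= 1")
  if (object@fsHz <= 0) msg <- c(msg, "sampling rate must be > 0")
  if (!(object@filterCutoffHz > 0 && object@filterCutoffHz < object@fsHz / 2)) {
    msg <- c(msg, "filter cutoff must satisfy 0 < cutoff < fs/2")
  }
  if (object@noiseSdPA < 0) msg <- c(msg, "noise sd must be >= 0")
  if (object@sweepLengthMs <= 0) msg <- c(msg, "sweep length must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nChannels number of channels.
#' @param vHoldMV holding potential (mV).
#' @param fsHz sampling rate (Hz).
#' @param filterCutoffHz low-pass cutoff (Hz).
#' @param noiseSdPA Gaussian recording-noise sd (pA), added before filtering.
#' @param sweepLengthMs sweep length (ms).
#' @param seed integer seed (or `NA`).
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(nChannels = 500, vHoldMV = -80, sweepLengthMs = 250, seed = 7)
#' @export
simulationConfig <- function(nChannels, vHoldMV = -80, fsHz = 20000,
                             filterCutoffHz = 1000, noiseSdPA = 8,
                             sweepLengthMs = 300, seed = NA_integer_) {
  new("SimulationConfig",
    nChannels = as.integer(nChannels), vHoldMV = vHoldMV, fsHz = fsHz,
    filterCutoffHz = filterCutoffHz, noiseSdPA = noiseSdPA,
    sweepLengthMs = sweepLengthMs, seed = as.integer(seed)
  )
}

#' @rdname accessors
#' @export
setMethod("nChannels", "SimulationConfig", function(x) x@nChannels)

#' @rdname accessors
#' @export
setMethod("fsHz", "SimulationConfig", function(x) x@fsHz)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nChannels, " channel(s) at ",
    object@vHoldMV, " mV, ", object@sweepLengthMs, " ms sweep\n",
    "  fs = ", object@fsHz, " Hz, filter = ", object@filterCutoffHz,
    " Hz, noise sd = ", object@noiseSdPA, " pA, seed = ", object@seed,
    "\n", sep = "")
})

## ---------------------------------------------------------------------------
## OccupancyTrace
## ---------------------------------------------------------------------------

#' State-occupancy trace of a channel population
#'
#' Per-sample integer counts of channels in each Markov state, produced by
#' [simulateOccupancy()]. Counts at every sample sum to the number of
#' channels.
#'
#' @slot timesMs sample times (ms).
#' @slot counts integer matrix, one row per sample, one column per state.
#' @slot stateNames state labels (column names of `counts`).
#' @slot nChannels total channel count.
#'
#' @export
setClass("OccupancyTrace",
  representation(
    timesMs = "numeric",
    counts = "matrix",
    stateNames = "character",
    nChannels = "integer"
  )
)

setValidity("OccupancyTrace", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@timesMs)) {
    msg <- c(msg, "counts must have one row per sample")
  }
  if (ncol(object@counts) != length(object@stateNames)) {
    msg <- c(msg, "counts must have one column per state")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (any(rowSums(object@counts) != object@nChannels)) {
    msg <- c(msg, "state counts must sum to n_channels at every sample")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("timesMs", "OccupancyTrace", function(x) x@timesMs)

#' @rdname accessors
#' @export
setMethod("stateCounts", "OccupancyTrace", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("stateNames", "OccupancyTrace", function(x) x@stateNames)

#' @rdname accessors
#' @export
setMethod("nChannels", "OccupancyTrace", function(x) x@nChannels)

setMethod("show", "OccupancyTrace", function(object) {
  cat("OccupancyTrace: ", object@nChannels, " channel(s), ",
    length(object@timesMs), " samples over ",
    round(max(object@timesMs), 2), " ms\n", sep = "")
  cat("  states:", paste(object@stateNames, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Sweep and SweepSet
## ---------------------------------------------------------------------------

#' A single current sweep
#'
#' One recorded or simulated membrane-current trace with its sampling and
#' stimulus metadata. Inward current at negative potentials is stored as
#' negative pA; analysis functions report magnitudes over baseline.
#'
#' @slot id sweep identifier.
#' @slot currentPA current samples in pA (inward negative).
#' @slot fsHz sampling rate (Hz, > 0).
#' @slot vHoldMV holding potential (mV).
#' @slot stimOnsetMs stimulus onset (ms).
#' @slot stimDurationMs stimulus duration (ms).
#' @slot stimAmplitude stimulus amplitude (um or mmHg).
#' @slot stimKind `"poke"`, `"pressure"`, or `"none"`.
#' @slot annotations free-form metadata list; simulated sweeps carry their
#'   ground-truth parameters and seed here.
#'
#' @seealso [sweep-class constructors][newSweep()], [analyzeSweep()]
#' @export
setClass("Sweep",
  representation(
    id = "character",
    currentPA = "numeric",
    fsHz = "numeric",
    vHoldMV = "numeric",
    stimOnsetMs = "numeric",
    stimDurationMs = "numeric",
    stimAmplitude = "numeric",
    stimKind = "character",
    annotations = "list"
  )
)

setValidity("Sweep", function(object) {
  msg <- character()
  if (object@fsHz <= 0) msg <- c(msg, "fs must be > 0")
  if (any(!is.finite(object@currentPA))) msg <- c(msg, "samples must be finite")
  lenMs <- length(object@currentPA) / object@fsHz * 1000
  if (!is.na(object@stimOnsetMs) &&
    (object@stimOnsetMs < 0 || object@stimOnsetMs >= lenMs)) {
    msg <- c(msg, "stim_onset must lie within the sweep")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a sweep
#'
#' @param currentPA numeric vector of current samples (pA, inward negative).
#' @param fsHz sampling rate (Hz).
#' @param vHoldMV holding potential (mV).
#' @param stimOnsetMs,stimDurationMs,stimAmplitude stimulus metadata.
#' @param stimKind `"poke"`, `"pressure"` or `"none"`.
#' @param id sweep identifier.
#' @param annotations free-form metadata list.
#' @return A [Sweep-class] object.
#' @examples
#' sw <- newSweep(rnorm(2000), fsHz = 20000, stimOnsetMs = 20,
#'                stimDurationMs = 50, stimAmplitude = 3)
#' sweepTimesMs(sw)[1:5]
#' @export
newSweep <- function(currentPA, fsHz, vHoldMV = -80, stimOnsetMs = NA_real_,
                     stimDurationMs = NA_real_, stimAmplitude = NA_real_,
                     stimKind = "none", id = "sweep1", annotations = list()) {
  new("Sweep",
    id = id, currentPA = as.numeric(currentPA), fsHz = fsHz,
    vHoldMV = vHoldMV, stimOnsetMs = stimOnsetMs,
    stimDurationMs = stimDurationMs, stimAmplitude = stimAmplitude,
    stimKind = stimKind, annotations = annotations
  )
}

#' @rdname accessors
#' @export
setMethod("currentPA", "Sweep", function(x) x@currentPA)

#' @rdname accessors
#' @export
setMethod("fsHz", "Sweep", function(x) x@fsHz)

#' @rdname accessors
#' @export
setMethod("vHoldMV", "Sweep", function(x) x@vHoldMV)

#' @rdname accessors
#' @export
setMethod("stimOnsetMs", "Sweep", function(x) x@stimOnsetMs)

#' @rdname accessors
#' @export
setMethod("stimDurationMs", "Sweep", function(x) x@stimDurationMs)

#' @rdname accessors
#' @export
setMethod("stimAmplitude", "Sweep", function(x) x@stimAmplitude)

#' @rdname accessors
#' @export
setMethod("annotations", "Sweep", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("sweepId", "Sweep", function(x) x@id)

#' Sample times of a sweep
#'
#' @param sweep a [Sweep-class] object.
#' @return Numeric vector of sample times in ms (first sample at 0).
#' @export
sweepTimesMs <- function(sweep) {
  (seq_along(sweep@currentPA) - 1) / sweep@fsHz * 1000
}

setMethod("show", "Sweep", function(object) {
  cat("Sweep \"", object@id, "\": ", length(object@currentPA), " samples at ",
    object@fsHz, " Hz (", round(length(object@currentPA) / object@fsHz * 1000, 1),
    " ms), V_hold = ", object@vHoldMV, " mV\n", sep = "")
  if (!is.na(object@stimOnsetMs)) {
    cat("  stimulus <", object@stimKind, ">: onset ", object@stimOnsetMs,
      " ms, duration ", object@stimDurationMs, " ms, amplitude ",
      object@stimAmplitude, "\n", sep = "")
  }
})

#' An ordered collection of sweeps
#'
#' All sweeps in a set share a sampling rate and have unique ids. Set-level
#' metadata (preset name, seed, ground-truth parameters, recording
#' conditions) lives in `metadata`.
#'
#' @slot sweeps list of [Sweep-class] objects.
#' @slot metadata set-level metadata list.
#'
#' @seealso [newSweepSet()], [writeSweepSet()], [readSweepSet()]
#' @export
setClass("SweepSet",
  representation(sweeps = "list", metadata = "list")
)

setValidity("SweepSet", function(object) {
  msg <- character()
  if (!all(vapply(object@sweeps, is, logical(1), class2 = "Sweep"))) {
    msg <- c(msg, "all elements must be Sweep objects")
  } else if (length(object@sweeps)) {
    fs <- vapply(object@sweeps, fsHz, numeric(1))
    if (length(unique(fs)) != 1L) msg <- c(msg, "all sweeps must share fs")
    ids <- vapply(object@sweeps, sweepId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "sweep ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a sweep set
#'
#' @param sweeps list of [Sweep-class] objects sharing a sampling rate.
#' @param metadata set-level metadata list.
#' @return A [SweepSet-class] object.
#' @export
newSweepSet <- function(sweeps, metadata = list()) {
  new("SweepSet", sweeps = sweeps, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("sweeps", "SweepSet", function(x) x@sweeps)

#' @rdname accessors
#' @export
setMethod("annotations", "SweepSet", function(x) x@metadata)

#' @param i index.
#' @rdname accessors
#' @export
setMethod("[[", "SweepSet", function(x, i) x@sweeps[[i]])

#' @rdname accessors
#' @export
setMethod("length", "SweepSet", function(x) length(x@sweeps))

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet with", length(object@sweeps), "sweep(s)\n")
  if (length(object@sweeps)) {
    cat("  fs =", fsHz(object@sweeps[[1]]), "Hz\n")
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## MSCurrentMetrics
## ---------------------------------------------------------------------------

#' Whole-cell mechanosensitive current metrics for one sweep
#'
#' Produced by [analyzeSweep()]. Peak and slow currents are magnitudes over
#' baseline (pA); the slow current is read 75 ms after stimulus onset
#' (averaged over a short window). `slowFraction` is slow/peak and
#' `fastComponent` is peak - slow. Values that violate the usual ordering
#' (slow fraction > 1, negative fast component) are kept and flagged rather
#' than clipped.
#'
#' @slot sweepId identifier of the analyzed sweep.
#' @slot baselinePA baseline current (pA, signed).
#' @slot peakPA peak current magnitude over baseline (pA, >= 0).
#' @slot slowPA slow current magnitude over baseline (pA, >= 0).
#' @slot slowFraction slow / peak (dimensionless; `NA` when peak is 0).
#' @slot fastComponent peak - slow (pA).
#' @slot tauMs fitted inactivation time constant(s) in ms (may be empty).
#' @slot fitOk logical quality flag of the inactivation fit (`NA` if no fit).
#' @slot flags character vector of quality flags.
#'
#' @export
setClass("MSCurrentMetrics",
  representation(
    sweepId = "character",
    baselinePA = "numeric",
    peakPA = "numeric",
    slowPA = "numeric",
    slowFraction = "numeric",
    fastComponent = "numeric",
    tauMs = "numeric",
    fitOk = "logical",
    flags = "character"
  )
)

setValidity("MSCurrentMetrics", function(object) {
  msg <- character()
  if (!is.na(object@peakPA) && object@peakPA < 0) msg <- c(msg, "peak must be >= 0")
  if (!is.na(object@slowPA) && object@slowPA < 0) msg <- c(msg, "slow must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname metric-accessors
#' @export
setMethod("baselinePA", "MSCurrentMetrics", function(x) x@baselinePA)

#' @rdname metric-accessors
#' @export
setMethod("peakPA", "MSCurrentMetrics", function(x) x@peakPA)

#' @rdname metric-accessors
#' @export
setMethod("slowPA", "MSCurrentMetrics", function(x) x@slowPA)

#' @rdname metric-accessors
#' @export
setMethod("slowFraction", "MSCurrentMetrics", function(x) x@slowFraction)

#' @rdname metric-accessors
#' @export
setMethod("fastComponent", "MSCurrentMetrics", function(x) x@fastComponent)

#' @rdname accessors
#' @export
setMethod("sweepId", "MSCurrentMetrics", function(x) x@sweepId)

setMethod("show", "MSCurrentMetrics", function(object) {
  cat("MSCurrentMetrics [", object@sweepId, "]\n", sep = "")
  cat(sprintf(
    "  baseline %.2f pA | peak %.2f pA | slow(75 ms) %.2f pA | slow fraction %.3f | fast %.2f pA\n",
    object@baselinePA, object@peakPA, object@slowPA, object@slowFraction,
    object@fastComponent
  ))
  if (length(object@tauMs)) {
    cat("  tau:", paste(round(object@tauMs, 2), collapse = ", "), "ms; fit ok:", object@fitOk, "\n")
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## AmplitudeHistogram / LevelModel / ConductanceFit
## ---------------------------------------------------------------------------

#' Amplitude histogram of a sweep segment
#'
#' Histogram of current samples over a segment, with the raw sample values
#' retained: level fitting ([fitLevels()]) operates on the samples, so the
#' fitted level means are insensitive to bin width.
#'
#' @slot breaksPA uniform bin edges (pA).
#' @slot counts bin counts.
#' @slot samplesPA raw sample values in the segment (pA).
#' @slot segmentMs the `(start, end)` segment analyzed (ms).
#' @slot sourceId id of the source sweep.
#'
#' @seealso [buildHistogram()]
#' @export
setClass("AmplitudeHistogram",
  representation(
    breaksPA = "numeric",
    counts = "integer",
    samplesPA = "numeric",
    segmentMs = "numeric",
    sourceId = "character"
  )
)

setValidity("AmplitudeHistogram", function(object) {
  msg <- character()
  if (length(object@breaksPA) != length(object@counts) + 1L) {
    msg <- c(msg, "breaks must have one more element than counts")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (sum(object@counts) != length(object@samplesPA)) {
    msg <- c(msg, "total counts must equal number of samples binned")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmplitudeHistogram", function(object) {
  cat("AmplitudeHistogram [", object@sourceId, "]: ",
    length(object@samplesPA), " samples in ", length(object@counts),
    " bins over [", round(min(object@breaksPA), 2), ", ",
    round(max(object@breaksPA), 2), "] pA\n", sep = "")
})

#' Gaussian level model of an amplitude histogram
#'
#' Mixture-model description of the conductance levels in a patch recording.
#' Level 0 is the closed/baseline level; levels are ordered from the closed
#' level outward in the direction of channel current.
#'
#' @slot meansPA level means (pA), ordered from closed outward.
#' @slot sdsPA level standard deviations (pA).
#' @slot weights mixing weights of the levels (sum to 1; renormalized over
#'   the Gaussian components).
#' @slot noiseFraction weight assigned to the uniform transition/outlier
#'   component of the mixture.
#' @slot bic BIC table over candidate model orders.
#' @slot flags character quality flags (e.g. overlapping levels).
#'
#' @seealso [fitLevels()], [unitaryCurrent()], [idealizeSweep()]
#' @export
setClass("LevelModel",
  representation(
    meansPA = "numeric",
    sdsPA = "numeric",
    weights = "numeric",
    noiseFraction = "numeric",
    bic = "numeric",
    flags = "character"
  ),
  prototype(noiseFraction = 0)
)

setValidity("LevelModel", function(object) {
  msg <- character()
  k <- length(object@meansPA)
  if (length(object@sdsPA) != k || length(object@weights) != k) {
    msg <- c(msg, "means, sds and weights must have equal length")
  }
  if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (k >= 2) {
    d <- diff(object@meansPA)
    if (!(all(d > 0) || all(d < 0))) {
      msg <- c(msg, "level means must be strictly ordered in the current direction")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("levelMeans", "LevelModel", function(x) x@meansPA)

#' @rdname accessors
#' @export
setMethod("levelSds", "LevelModel", function(x) x@sdsPA)

#' @rdname accessors
#' @export
setMethod("levelWeights", "LevelModel", function(x) x@weights)

setMethod("show", "LevelModel", function(object) {
  cat("LevelModel with", length(object@meansPA), "level(s):\n")
  print(data.frame(
    level = seq_along(object@meansPA) - 1L,
    mean_pA = round(object@meansPA, 3),
    sd_pA = round(object@sdsPA, 3),
    weight = round(object@weights, 3)
  ), row.names = FALSE)
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Unitary conductance fit across voltages
#'
#' Ordinary least-squares fit of the unitary current/voltage relation
#' \eqn{i = \gamma (V - E_{rev})}. Voltages are command values and treated as
#' error-free; `eRevMV` is a free parameter of the line, not pinned to 0.
#'
#' @slot gammaPS fitted unitary conductance (pS).
#' @slot gammaSE standard error of gamma (pS).
#' @slot eRevMV fitted reversal potential (mV).
#' @slot eRevSE approximate (delta-method) standard error of E_rev (mV).
#' @slot points data frame of per-voltage unitary currents
#'   (`voltage_mV`, `unitary_pA`).
#'
#' @seealso [conductanceFit()]
#' @export
setClass("ConductanceFit",
  representation(
    gammaPS = "numeric",
    gammaSE = "numeric",
    eRevMV = "numeric",
    eRevSE = "numeric",
    points = "data.frame"
  )
)

setValidity("ConductanceFit", function(object) {
  msg <- character()
  if (length(unique(object@points$voltage_mV)) < 3L) {
    msg <- c(msg, "fit requires >= 3 distinct voltages")
  }
  if (!is.na(object@gammaPS) && object@gammaPS <= 0) msg <- c(msg, "gamma must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("gammaPS", "ConductanceFit", function(x) x@gammaPS)

#' @rdname accessors
#' @export
setMethod("eRevMV", "ConductanceFit", function(x) x@eRevMV)

setMethod("show", "ConductanceFit", function(object) {
  cat(sprintf(
    "ConductanceFit: gamma = %.2f +/- %.2f pS, E_rev = %.2f +/- %.2f mV (%d voltages)\n",
    object@gammaPS, object@gammaSE, object@eRevMV, object@eRevSE,
    length(unique(object@points$voltage_mV))
  ))
})

## ---------------------------------------------------------------------------
## SolutionSpec
## ---------------------------------------------------------------------------

#' Ionic solution composition
#'
#' Composition of a pipette or bath solution for junction-potential and
#' selectivity calculations. Electro-neutral components (HEPES, glucose,
#' EGTA) are either omitted or listed with `valence = 0`, in which case they
#' are ignored by the Henderson sums.
#'
#' @slot ions data frame with columns `ion` (label), `mM` (concentration,
#'   >= 0) and `valence` (integer; 0 marks neutral components).
#' @slot side `"pipette"` or `"bath"`.
#' @slot temperatureK temperature in K (default 298.15).
#'
#' @seealso [solutionSpec()], [hendersonLJP()]
#' @export
setClass("SolutionSpec",
  representation(ions = "data.frame", side = "character", temperatureK = "numeric")
)

setValidity("SolutionSpec", function(object) {
  msg <- character()
  need <- c("ion", "mM", "valence")
  if (!all(need %in% names(object@ions))) {
    msg <- c(msg, "ions must have columns ion, mM, valence")
  } else {
    if (any(object@ions$mM < 0)) msg <- c(msg, "concentrations must be >= 0")
    charged <- object@ions[object@ions$valence != 0 & object@ions$mM > 0, ]
    if (!any(charged$valence > 0) || !any(charged$valence < 0)) {
      msg <- c(msg, "solution needs at least one cation and one anion")
    }
  }
  if (!object@side %in% c("pipette", "bath")) msg <- c(msg, "side must be pipette or bath")
  if (object@temperatureK <= 0) msg <- c(msg, "temperature must be > 0 K")
  if (length(msg)) msg else TRUE
})

#' Construct a solution specification
#'
#' @param ... named concentrations in mM, e.g. `K = 150, Cl = 150`. Ion names
#'   must appear in `valences` (defaults cover the common patch-clamp ions).
#' @param side `"pipette"` or `"bath"`.
#' @param temperatureK temperature (K).
#' @param valences named integer vector mapping ion labels to valences; the
#'   default covers K, Na, Cl, Ca, Mg, Cs, Li, Gluconate, NMDG, HEPES (0) and
#'   Glucose (0).
#' @return A [SolutionSpec-class] object.
#' @examples
#' solutionSpec(K = 150, Cl = 150, side = "pipette")
#' solutionSpec(Na = 150, Cl = 150, side = "bath")
#' @export
solutionSpec <- function(..., side = c("bath", "pipette"), temperatureK = 298.15,
                         valences = c(
                           K = 1, Na = 1, Cl = -1, Ca = 2, Mg = 2, Cs = 1,
                           Li = 1, Gluconate = -1, NMDG = 1, HEPES = 0,
                           Glucose = 0, EGTA = 0
                         )) {
  side <- match.arg(side)
  conc <- c(...)
  if (is.null(names(conc)) || any(names(conc) == "")) {
    stop("ion concentrations must be named, e.g. solutionSpec(K = 150, Cl = 150)")
  }
  unknown <- setdiff(names(conc), names(valences))
  if (length(unknown)) {
    stop(
      "unknown ion(s): ", paste(unknown, collapse = ", "),
      "; supply their valence via the 'valences' argument"
    )
  }
  ions <- data.frame(
    ion = names(conc),
    mM = as.numeric(conc),
    valence = as.integer(valences[names(conc)]),
    stringsAsFactors = FALSE
  )
  new("SolutionSpec", ions = ions, side = side, temperatureK = temperatureK)
}

setMethod("show", "SolutionSpec", function(object) {
  cat("SolutionSpec <", object@side, "> at ", object@temperatureK, " K\n", sep = "")
  print(object@ions, row.names = FALSE)
})
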