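#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Model construction
## ---------------------------------------------------------------------------

#' Construct a gating model
#'
#' Builds a [GatingModel-class] from explicit rates. For the standard
#' presets use [buildPreset()].
#'
#' @param baseRates square matrix of base transition rates (1/ms) with zero
#'   diagonal; row/column order follows `stateNames`.
#' @param stateNames ordered state labels; must contain `"O"`.
#' @param coupled `(from, to)` indices of the stimulus-coupled transition.
#' @param sHalf,slope Boltzmann half-activation stimulus and slope factor,
#'   in the stimulus units of the protocols the model will be used with.
#' @param gammaPS unitary conductance (pS).
#' @param eRevMV reversal potential (mV).
#' @param name model label.
#' @return A [GatingModel-class] object.
#' @export
gatingModel <- function(baseRates, stateNames = c("C", "O", "I"),
                        coupled = c(1L, 2L), sHalf = 3, slope = 0.4,
                        gammaPS = 24.7, eRevMV = 0, name = "custom") {
  new("GatingModel",
    name = name, stateNames = stateNames, baseRates = baseRates,
    coupled = as.integer(coupled), sHalf = sHalf, slope = slope,
    gammaPS = gammaPS, eRevMV = eRevMV
  )
}

.presetNames <- c("canonical_fast", "mes_slow")

#' Built-in gating-model presets
#'
#' Two parameterizations of the three-state scheme C <-> O -> I (with slow
#' I -> O recovery), differing only in the inactivation rates:
#'
#' * `"canonical_fast"`: fast inactivation typical of a canonical
#'   Piezo-family channel. The slow relaxation eigenvalue of the generator at
#'   saturating stimulus corresponds to a decay time constant of about 13 ms
#'   (below 20 ms), and the open probability remaining 75 ms into a
#'   saturating step is about 1% of peak.
#' * `"mes_slow"`: the slowly-inactivating phenotype seen in mouse embryonic
#'   stem cells. Its O -> I rate was calibrated against the master-equation
#'   oracle plus a simulated whole-cell calibration batch so that the
#'   measured slow fraction (current remaining 75 ms into a saturating step,
#'   relative to peak) is 0.67.
#'
#' Both presets use a unitary conductance of 24.7 pS with a 0 mV reversal
#' potential, and couple the closed-to-open rate to the stimulus through a
#' threshold-adjusted Boltzmann (exactly zero at rest, saturating at the
#' base rate). The Boltzmann midpoint is an arbitrary choice of stimulus
#' scale (no activation-curve data constrain it), set at 3 um for poke
#' protocols and 30 mmHg for pressure protocols.
#'
#' @param name `"canonical_fast"` or `"mes_slow"`.
#' @param stimulus `"poke"` (midpoint 3 um, slope 0.4 um) or `"pressure"`
#'   (midpoint 30 mmHg, slope 4 mmHg); pick the kind of protocol the model
#'   will be driven with.
#' @return A fully parameterized [GatingModel-class].
#' @examples
#' m <- buildPreset("mes_slow")
#' m
#' @export
buildPreset <- function(name, stimulus = c("poke", "pressure")) {
  stimulus <- match.arg(stimulus)
  if (!is.character(name) || length(name) != 1L || !name %in% .presetNames) {
    stop(
      "unknown preset ", deparse(name), "; valid presets: ",
      paste(.presetNames, collapse = ", ")
    )
  }
  rates <- switch(name,
    canonical_fast = c(kCO = 1, kOC = 0.25, kOI = 0.1, kIO = 0.0005),
    mes_slow = c(kCO = 1, kOC = 0.25, kOI = 0.0074, kIO = 0.002)
  )
  R <- matrix(0, 3, 3)
  R[1, 2] <- rates[["kCO"]]
  R[2, 1] <- rates[["kOC"]]
  R[2, 3] <- rates[["kOI"]]
  R[3, 2] <- rates[["kIO"]]
  bolt <- switch(stimulus,
    poke = c(sHalf = 3, slope = 0.4),
    pressure = c(sHalf = 30, slope = 4)
  )
  gatingModel(R,
    stateNames = c("C", "O", "I"), coupled = c(1L, 2L),
    sHalf = bolt[["sHalf"]], slope = bolt[["slope"]],
    gammaPS = 24.7, eRevMV = 0, name = name
  )
}

## ---------------------------------------------------------------------------
## Stimulus coupling and generator assembly
## ---------------------------------------------------------------------------

#' Boltzmann stimulus activation
#'
#' Fractional activation of the stimulus-coupled rate at stimulus `s`:
#' a raw Boltzmann \eqn{b(s) = 1/(1 + e^{(s_{1/2} - s)/k})} shifted and
#' rescaled so that activation is exactly 0 at rest (`s = 0`) and 1 at
#' saturation. The zero-at-rest adjustment makes an unstimulated membrane
#' silent, which is how resting patches behave on the timescale of a sweep.
#'
#' @param model a [GatingModel-class].
#' @param s stimulus value(s), same units as the model's `sHalf`.
#' @return Activation in `[0, 1]`, same length as `s`.
#' @export
boltzmannActivation <- function(model, s) {
  b <- function(x) 1 / (1 + exp((model@sHalf - x) / model@slope))
  b0 <- b(0)
  pmax(0, (b(s) - b0) / (1 - b0))
}

#' Generator matrix at a stimulus value
#'
#' Assembles the infinitesimal generator Q of the Markov scheme at stimulus
#' `s`: off-diagonal entries are the transition rates (the coupled one scaled
#' by [boltzmannActivation()]), the diagonal is minus the row sum, so rows
#' sum to zero.
#'
#' @param model a [GatingModel-class].
#' @param s stimulus value (scalar).
#' @return Square numeric matrix (1/ms) with zero row sums.
#' @export
generatorMatrix <- function(model, s) {
  Q <- model@baseRates
  Q[model@coupled[1], model@coupled[2]] <-
    Q[model@coupled[1], model@coupled[2]] * boltzmannActivation(model, s)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(model@stateNames, model@stateNames)
  Q
}

#' Stationary state distribution at a fixed stimulus
#'
#' Solves pi Q = 0, sum(pi) = 1 for the generator at stimulus `s`.
#'
#' @inheritParams generatorMatrix
#' @return Named numeric vector of stationary state probabilities.
#' @export
stationaryDistribution <- function(model, s) {
  Q <- generatorMatrix(model, s)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  names(pi) <- model@stateNames
  pi
}

## ---------------------------------------------------------------------------
## Stimulus waveform / piecewise-constant segmentation
## ---------------------------------------------------------------------------

#' Stimulus waveform of a protocol
#'
#' Evaluates the stimulus coordinate s(t): a rectangular step for pokes, a
#' trapezoid (linear ramps at the clamp slew rate) for pressure steps.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param tMs times (ms).
#' @param amplitude optional amplitude override (used for amplitude series).
#' @return Numeric stimulus values at `tMs`.
#' @export
stimulusWaveform <- function(protocol, tMs, amplitude = protocol@amplitude) {
  on <- protocol@onsetMs
  off <- on + protocol@durationMs
  if (protocol@kind == "poke") {
    ifelse(tMs >= on & tMs < off, amplitude, 0)
  } else {
    rt <- abs(amplitude) / protocol@rampRateMmHgMs
    s <- numeric(length(tMs))
    up <- tMs >= on & tMs < on + rt
    s[up] <- amplitude * (tMs[up] - on) / rt
    hold <- tMs >= on + rt & tMs < off
    s[hold] <- amplitude
    down <- tMs >= off & tMs < off + rt
    s[down] <- amplitude * (1 - (tMs[down] - off) / rt)
    s
  }
}

## Piecewise-constant segmentation of the stimulus over [0, lengthMs].
## Ramps are chopped into sub-segments of at most dtMs, each held at its
## midpoint value. Returns data.frame(t0, t1, s).
.stimulusSegments <- function(protocol, lengthMs, amplitude = protocol@amplitude,
                              dtMs = 0.05) {
  on <- min(protocol@onsetMs, lengthMs)
  off <- min(on + protocol@durationMs, lengthMs)
  chopRamp <- function(t0, t1, s0, s1) {
    n <- max(1L, ceiling((t1 - t0) / dtMs))
    e <- seq(t0, t1, length.out = n + 1)
    mid <- (e[-1] + e[-(n + 1)]) / 2
    data.frame(t0 = e[-(n + 1)], t1 = e[-1], s = s0 + (s1 - s0) * (mid - t0) / (t1 - t0))
  }
  segs <- list()
  if (on > 0) segs <- c(segs, list(data.frame(t0 = 0, t1 = on, s = 0)))
  if (protocol@kind == "poke" || amplitude == 0) {
    if (off > on) segs <- c(segs, list(data.frame(t0 = on, t1 = off, s = amplitude)))
    if (lengthMs > off) segs <- c(segs, list(data.frame(t0 = off, t1 = lengthMs, s = 0)))
  } else {
    rt <- abs(amplitude) / protocol@rampRateMmHgMs
    upEnd <- min(on + rt, off, lengthMs)
    if (upEnd > on) {
      segs <- c(segs, list(chopRamp(on, upEnd, 0, amplitude * (upEnd - on) / rt)))
    }
    if (off > upEnd) segs <- c(segs, list(data.frame(t0 = upEnd, t1 = off, s = amplitude)))
    downEnd <- min(off + rt, lengthMs)
    if (downEnd > off && lengthMs > off) {
      segs <- c(segs, list(chopRamp(off, downEnd, amplitude, amplitude * (1 - (downEnd - off) / rt))))
    }
    if (lengthMs > downEnd) segs <- c(segs, list(data.frame(t0 = downEnd, t1 = lengthMs, s = 0)))
  }
  out <- do.call(rbind, segs)
  out[out$t1 > out$t0, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Master equation
## ---------------------------------------------------------------------------

#' Deterministic open-probability timecourse (master equation)
#'
#' Solves the master equation of the gating scheme under a stimulus protocol
#' by matrix exponentials on piecewise-constant stimulus segments (ramps are
#' discretized at the sampling interval). This is the deterministic oracle
#' for the stochastic simulator: state probabilities are exact up to the
#' ramp discretization.
#'
#' @param model a [GatingModel-class].
#' @param protocol a [StimulusProtocol-class].
#' @param gridMs increasing vector of times (ms) covering the protocol;
#'   typically `seq(0, sweepLengthMs, by = 1000/fsHz)`.
#' @param amplitude optional amplitude override.
#' @param init initial state distribution (default: all channels closed).
#' @return Matrix of state probabilities (rows = `gridMs`, columns = states)
#'   with attribute `"timesMs"`; every row sums to 1.
#' @examples
#' m <- buildPreset("canonical_fast")
#' p <- stimulusProtocol("poke", 10, 100, 5)
#' P <- openProbabilityTimecourse(m, p, seq(0, 150, by = 0.5))
#' max(P[, "O"]) # peak open probability
#' @export
openProbabilityTimecourse <- function(model, protocol, gridMs,
                                      amplitude = protocol@amplitude,
                                      init = NULL) {
  validObject(model)
  if (any(!is.finite(model@baseRates))) stop("non-finite rates")
  if (is.unsorted(gridMs, strictly = TRUE)) stop("grid must be strictly increasing")
  k <- length(model@stateNames)
  if (is.null(init)) init <- c(1, rep(0, k - 1))
  segs <- .stimulusSegments(protocol, max(gridMs), amplitude = amplitude)
  P <- matrix(NA_real_, length(gridMs), k, dimnames = list(NULL, model@stateNames))
  expCache <- new.env(parent = emptyenv())
  stepExp <- function(s, dt) {
    key <- paste0(format(s, digits = 15), "_", format(dt, digits = 15))
    if (is.null(expCache[[key]])) {
      expCache[[key]] <- as.matrix(Matrix::expm(generatorMatrix(model, s) * dt))
    }
    expCache[[key]]
  }
  p <- init
  tCur <- gridMs[1]
  if (tCur > 0) {
    # advance from 0 to the first grid point
    for (j in seq_len(nrow(segs))) {
      lo <- max(segs$t0[j], 0)
      hi <- min(segs$t1[j], tCur)
      if (hi > lo) p <- as.numeric(p %*% stepExp(segs$s[j], hi - lo))
    }
  }
  P[1, ] <- p
  for (i in seq_along(gridMs)[-1]) {
    t0 <- gridMs[i - 1]
    t1 <- gridMs[i]
    for (j in seq_len(nrow(segs))) {
      lo <- max(segs$t0[j], t0)
      hi <- min(segs$t1[j], t1)
      if (hi > lo) p <- as.numeric(p %*% stepExp(segs$s[j], hi - lo))
    }
    P[i, ] <- p
  }
  # clamp tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  attr(P, "timesMs") <- gridMs
  P
}
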