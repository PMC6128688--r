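#' @include gating-model.R
NULL

## run fn() under a local, seeded RNG stream without disturbing the caller's
## RNG state; seed = NA uses (and advances) the caller's stream.
.withSeed <- function(seed, fn) {
  if (is.na(seed)) {
    return(fn())
  }
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

## ---------------------------------------------------------------------------
## Exact stochastic simulation on aggregated counts
## ---------------------------------------------------------------------------

#' Stochastic occupancy simulation (exact, aggregated counts)
#'
#' Event-driven (Gillespie) simulation of the channel population on
#' aggregated state counts: with only a handful of states, the propensity of
#' each transition is `count[from] * rate`, so the cost scales with the
#' number of transition events, not with channels x samples. Rates are
#' piecewise-constant in time (ramps discretized at the sampling interval);
#' within each constant-rate span the simulation is exact.
#'
#' All channels start closed. Identical `(model, protocol, config)` with the
#' same seed give bit-identical traces.
#'
#' @param model a [GatingModel-class].
#' @param protocol a [StimulusProtocol-class].
#' @param config a [SimulationConfig-class]; `config@seed` seeds the
#'   simulation RNG (the caller's RNG state is left untouched unless the seed
#'   is `NA`).
#' @param amplitude optional stimulus-amplitude override.
#' @return An [OccupancyTrace-class] sampled at `config@fsHz`.
#' @examples
#' m <- buildPreset("canonical_fast")
#' p <- stimulusProtocol("poke", 10, 50, 5)
#' occ <- simulateOccupancy(m, p, simulationConfig(50, sweepLengthMs = 80, seed = 1))
#' range(rowSums(stateCounts(occ))) # always 50
#' @export
simulateOccupancy <- function(model, protocol, config,
                              amplitude = protocol@amplitude) {
  validObject(model)
  validObject(protocol)
  validObject(config)
  if (config@nChannels < 1L) stop("need at least one channel")
  k <- length(model@stateNames)
  # transition table
  tr <- which(model@baseRates > 0, arr.ind = TRUE)
  # keep the coupled transition even if its base rate is 0
  dtMs <- 1000 / config@fsHz
  segs <- .stimulusSegments(protocol, config@sweepLengthMs,
    amplitude = amplitude, dtMs = dtMs
  )
  nTr <- nrow(tr)
  simulate <- function() {
    n <- c(config@nChannels, rep(0L, k - 1L))
    cap <- 4096L
    evTime <- numeric(cap)
    evFrom <- integer(cap)
    evTo <- integer(cap)
    nEv <- 0L
    if (nTr > 0L) {
      for (j in seq_len(nrow(segs))) {
        t <- segs$t0[j]
        tEnd <- segs$t1[j]
        act <- boltzmannActivation(model, segs$s[j])
        rates <- model@baseRates[tr]
        ci <- which(tr[, 1] == model@coupled[1] & tr[, 2] == model@coupled[2])
        if (length(ci)) rates[ci] <- rates[ci] * act
        repeat {
          a <- rates * n[tr[, 1]]
          A <- sum(a)
          if (A <= 0) break
          t <- t - log(stats::runif(1)) / A
          if (t >= tEnd) break
          i <- findInterval(stats::runif(1) * A, cumsum(a)) + 1L
          n[tr[i, 1]] <- n[tr[i, 1]] - 1L
          n[tr[i, 2]] <- n[tr[i, 2]] + 1L
          nEv <- nEv + 1L
          if (nEv > cap) {
            cap <- cap * 2L
            length(evTime) <- cap
            length(evFrom) <- cap
            length(evTo) <- cap
          }
          evTime[nEv] <- t
          evFrom[nEv] <- tr[i, 1]
          evTo[nEv] <- tr[i, 2]
        }
      }
    }
    list(time = evTime[seq_len(nEv)], from = evFrom[seq_len(nEv)], to = evTo[seq_len(nEv)])
  }
  ev <- .withSeed(config@seed, simulate)

  # reconstruct counts at the sample grid from the event stream
  nSamples <- round(config@sweepLengthMs * config@fsHz / 1000)
  tGrid <- (seq_len(nSamples) - 1) * dtMs
  counts <- matrix(0L, nSamples, k, dimnames = list(NULL, model@stateNames))
  counts[, 1] <- config@nChannels
  if (length(ev$time)) {
    for (s in seq_len(k)) {
      delta <- integer(length(ev$time))
      delta[ev$to == s] <- delta[ev$to == s] + 1L
      delta[ev$from == s] <- delta[ev$from == s] - 1L
      cum <- cumsum(delta) + (if (s == 1L) config@nChannels else 0L)
      idx <- findInterval(tGrid, ev$time)
      counts[, s] <- ifelse(idx == 0L, if (s == 1L) config@nChannels else 0L, cum[pmax(idx, 1L)])
    }
  }
  new("OccupancyTrace",
    timesMs = tGrid, counts = counts,
    stateNames = model@stateNames, nChannels = config@nChannels
  )
}

## ---------------------------------------------------------------------------
## Current rendering
## ---------------------------------------------------------------------------

#' Render a current sweep from an occupancy trace
#'
#' Converts open-channel counts into a recorded current:
#' \eqn{I(t) = N_{open}(t)\, \gamma (V - E_{rev})} (pA, inward negative at
#' negative driving force), plus Gaussian recording noise of sd
#' `config@noiseSdPA`, passed through the 4-pole Bessel-type low-pass at
#' `config@filterCutoffHz` and sampled at `config@fsHz`.
#'
#' @param occupancy an [OccupancyTrace-class].
#' @param model the [GatingModel-class] that produced it (for gamma, E_rev).
#' @param config a [SimulationConfig-class] sharing the occupancy time base.
#' @param protocol optional [StimulusProtocol-class]; its metadata is copied
#'   onto the sweep.
#' @param filter apply the low-pass filter (default `TRUE`; set `FALSE` to
#'   inspect the unfiltered current).
#' @param noiseSeed optional seed for the noise stream.
#' @param id sweep id.
#' @return A [Sweep-class].
#' @export
renderCurrent <- function(occupancy, model, config, protocol = NULL,
                          filter = TRUE, noiseSeed = NA_integer_,
                          id = "sweep1") {
  nSamples <- round(config@sweepLengthMs * config@fsHz / 1000)
  if (length(occupancy@timesMs) != nSamples) {
    stop("occupancy and config do not share a time base (length mismatch)")
  }
  openIdx <- match("O", occupancy@stateNames)
  iUnit <- model@gammaPS * (config@vHoldMV - model@eRevMV) / 1000 # pA
  x <- occupancy@counts[, openIdx] * iUnit
  if (config@noiseSdPA > 0) {
    noise <- .withSeed(
      as.integer(noiseSeed),
      function() stats::rnorm(nSamples, 0, config@noiseSdPA)
    )
    x <- x + noise
  }
  if (filter) x <- lowpassFilter(x, config@fsHz, config@filterCutoffHz)
  ann <- list(
    simulated = TRUE, model = model@name, gamma_pS = model@gammaPS,
    e_rev_mV = model@eRevMV, n_channels = config@nChannels,
    noise_sd_pA = config@noiseSdPA, filter_cutoff_Hz = config@filterCutoffHz,
    seed = config@seed, noise_seed = as.integer(noiseSeed), filtered = filter
  )
  newSweep(x,
    fsHz = config@fsHz, vHoldMV = config@vHoldMV,
    stimOnsetMs = if (is.null(protocol)) NA_real_ else protocol@onsetMs,
    stimDurationMs = if (is.null(protocol)) NA_real_ else protocol@durationMs,
    stimAmplitude = if (is.null(protocol)) NA_real_ else protocol@amplitude,
    stimKind = if (is.null(protocol)) "none" else protocol@kind,
    id = id, annotations = ann
  )
}

## derive child seeds from a base seed, keeping them in 32-bit integer range
.childSeed <- function(seed, i, stream = 0L) {
  if (is.na(seed)) {
    return(NA_integer_)
  }
  as.integer((as.numeric(seed) * 7919 + i * 104729 + stream * 15485863) %% 2147483647)
}

#' Simulate a whole-cell stimulus series
#'
#' One sweep per amplitude in the protocol's `amplitudeSeries` (or per
#' repeat of the single amplitude): occupancy is simulated stochastically
#' and rendered through the recording chain. Each sweep is tagged with its
#' ground-truth parameters in `annotations` for recovery tests.
#'
#' @param model a [GatingModel-class].
#' @param protocol a [StimulusProtocol-class]; if `amplitudeSeries` is set it
#'   must be strictly increasing.
#' @param config a [SimulationConfig-class]; `config@seed` seeds the whole
#'   set, per-sweep seeds are derived deterministically from it.
#' @param nRepeats sweeps per amplitude (default 1).
#' @return A [SweepSet-class], one sweep per amplitude x repeat.
#' @examples
#' m <- buildPreset("canonical_fast")
#' p <- stimulusProtocol("poke", 10, 60, 5, amplitudeSeries = c(2, 4, 6))
#' ss <- simulateWholeCell(m, p, simulationConfig(100, sweepLengthMs = 100, seed = 2))
#' length(ss)
#' @export
simulateWholeCell <- function(model, protocol, config, nRepeats = 1L) {
  amps <- if (length(protocol@amplitudeSeries)) protocol@amplitudeSeries else protocol@amplitude
  sweepsOut <- list()
  idx <- 0L
  for (ai in seq_along(amps)) {
    for (r in seq_len(nRepeats)) {
      idx <- idx + 1L
      sSim <- .childSeed(config@seed, idx, 0L)
      sNoise <- .childSeed(config@seed, idx, 1L)
      cfg <- config
      cfg@seed <- sSim
      occ <- simulateOccupancy(model, protocol, cfg, amplitude = amps[ai])
      prot <- protocol
      prot@amplitude <- amps[ai]
      sw <- renderCurrent(occ, model, cfg,
        protocol = prot, noiseSeed = sNoise,
        id = sprintf("amp%03d_rep%02d", ai, r)
      )
      sw@annotations$amplitude <- amps[ai]
      sweepsOut[[idx]] <- sw
    }
  }
  newSweepSet(sweepsOut, metadata = list(
    preset = model@name, seed = config@seed, kind = protocol@kind,
    n_channels = config@nChannels, v_hold_mV = config@vHoldMV,
    gamma_pS = model@gammaPS, e_rev_mV = model@eRevMV,
    amplitudes = amps, n_repeats = nRepeats
  ))
}

#' Simulate pressure-evoked single-channel sweeps
#'
#' Repeated pressure-step sweeps from a patch containing a small number of
#' channels, as in excised outside-out recordings.
#'
#' @param model a [GatingModel-class] (use the `"pressure"` stimulus scale of
#'   [buildPreset()]).
#' @param protocol a pressure [StimulusProtocol-class].
#' @param config a [SimulationConfig-class] with `nChannels <= 5`.
#' @param nRepeats number of sweeps.
#' @return A [SweepSet-class].
#' @export
simulateSingleChannel <- function(model, protocol, config, nRepeats = 10L) {
  if (config@nChannels > 5L) {
    stop("single-channel simulation expects n_channels <= 5")
  }
  if (protocol@kind != "pressure") {
    stop("single-channel protocols are pressure steps")
  }
  p <- protocol
  p@amplitudeSeries <- numeric()
  out <- simulateWholeCell(model, p, config, nRepeats = nRepeats)
  out@metadata$mode <- "single_channel"
  out
}
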