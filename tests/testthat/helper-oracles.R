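# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# closed-form relaxation of the symmetric two-state scheme C <-> O with
# k_CO = k_OC = k, starting all-closed: Po(t) = 0.5 (1 - exp(-2 k t))
twoStatePo <- function(tMs, kPerMs) {
  0.5 * (1 - exp(-2 * kPerMs * tMs))
}

# RT/F in mV, independent constant set
rtfMV <- function(tK = 298.15) 1000 * 8.314462618 * tK / 96485.33212

# GHK current equation (per-ion constant-field current, arbitrary scale) for
# building synthetic I-V curves with a known reversal potential
ghkCurrentOracle <- function(vMV, ions) {
  vapply(vMV, function(v) {
    u <- v / rtfMV()
    i <- 0
    for (r in seq_len(nrow(ions))) {
      z <- ions$valence[r]
      zu <- z * u
      frac <- if (abs(zu) < 1e-12) {
        ions$inMM[r] - ions$outMM[r] # limit V -> 0
      } else {
        zu * (ions$inMM[r] - ions$outMM[r] * exp(-zu)) / (1 - exp(-zu))
      }
      i <- i + ions$pRel[r] * z * frac
    }
    i
  }, numeric(1))
}

# exhaustive-permutation one-tailed two-sample test oracle on the difference
# of means (direction "less": alternative mean(x) < mean(y))
permutationPOracle <- function(x, y, direction) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  obs <- mean(x) - mean(y)
  stat <- apply(idx, 2, function(ii) mean(pooled[ii]) - mean(pooled[-ii]))
  if (direction == "greater") mean(stat >= obs - 1e-12) else mean(stat <= obs + 1e-12)
}

# a noiseless mono-exponential "inactivating" sweep built by hand
expDecaySweep <- function(tauMs, baseline = -10, amplitude = -400,
                          onsetMs = 20, durationMs = 150, fsHz = 20000,
                          lengthMs = 220) {
  t <- (seq_len(lengthMs * fsHz / 1000) - 1) / fsHz * 1000
  i <- rep(baseline, length(t))
  stim <- t >= onsetMs & t < onsetMs + durationMs
  i[stim] <- baseline + amplitude * exp(-(t[stim] - onsetMs) / tauMs)
  newSweep(i,
    fsHz = fsHz, vHoldMV = -80, stimOnsetMs = onsetMs,
    stimDurationMs = durationMs, stimAmplitude = 5, stimKind = "poke",
    id = sprintf("exp_tau%g", tauMs)
  )
}
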