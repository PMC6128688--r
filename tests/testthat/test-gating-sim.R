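test_that("occupancy conserves channels and is seed-deterministic", {
  m <- buildPreset("canonical_fast")
  p <- stimulusProtocol("poke", 10, 60, 5)
  cfg <- simulationConfig(200, sweepLengthMs = 100, seed = 3, noiseSdPA = 0)
  occ1 <- simulateOccupancy(m, p, cfg)
  expect_true(all(rowSums(stateCounts(occ1)) == 200L))
  expect_true(all(stateCounts(occ1) >= 0L))
  occ2 <- simulateOccupancy(m, p, cfg)
  expect_identical(stateCounts(occ1), stateCounts(occ2)) # bit-identical
  cfg2 <- cfg
  cfg2@seed <- 4L
  occ3 <- simulateOccupancy(m, p, cfg2)
  expect_false(identical(stateCounts(occ1), stateCounts(occ3)))
})

test_that("zero stimulus with zero basal opening stays all-closed; n=1 is an indicator", {
  m <- buildPreset("mes_slow") # basal opening rate is exactly 0 by construction
  p <- stimulusProtocol("poke", 10, 60, 0)
  cfg <- simulationConfig(100, sweepLengthMs = 100, seed = 5)
  occ <- simulateOccupancy(m, p, cfg)
  expect_true(all(stateCounts(occ)[, "C"] == 100L))

  cfg1 <- simulationConfig(1, sweepLengthMs = 60, seed = 6)
  occ1 <- simulateOccupancy(m, stimulusProtocol("poke", 5, 40, 6), cfg1)
  expect_true(all(stateCounts(occ1) %in% c(0L, 1L)))
  expect_true(all(rowSums(stateCounts(occ1)) == 1L))
})

test_that("long-run occupancy matches the analytic stationary distribution", {
  # symmetric two-state scheme held at saturation; late window vs pi
  k <- 0.2
  R <- matrix(0, 2, 2)
  R[1, 2] <- k
  R[2, 1] <- k
  m <- gatingModel(R,
    stateNames = c("C", "O"), coupled = c(1L, 2L),
    sHalf = 0.001, slope = 1e-6, gammaPS = 24.7, name = "two_state_sat"
  )
  p <- stimulusProtocol("poke", 0, 100, 1)
  n <- 10000L
  cfg <- simulationConfig(n, sweepLengthMs = 100, seed = 11)
  occ <- simulateOccupancy(m, p, cfg)
  pi0 <- stationaryDistribution(m, 1)
  late <- timesMs(occ) >= 40
  fO <- mean(stateCounts(occ)[late, "O"]) / n
  # effective sample size: n channels x window / (2 x correlation time)
  tauCorr <- 1 / (2 * k)
  nEff <- n * (100 - 40) / (2 * tauCorr)
  se <- sqrt(pi0[["O"]] * (1 - pi0[["O"]]) / nEff)
  expect_lt(abs(fO - pi0[["O"]]), 3 * se)
})

test_that("Gillespie mean open counts agree with the master equation", {
  m <- buildPreset("canonical_fast")
  p <- stimulusProtocol("poke", 5, 30, 6)
  n <- 60L
  reps <- 200L
  checkMs <- seq(6, 33, by = 3) # 10 time points spanning rise and decay
  grid <- seq(0, 40, by = 0.05)
  P <- openProbabilityTimecourse(m, p, grid)
  expected <- n * P[match(checkMs, grid), "O"]
  openAt <- matrix(NA_real_, reps, length(checkMs))
  for (r in seq_len(reps)) {
    cfg <- simulationConfig(n, sweepLengthMs = 40, seed = 20000 + r)
    occ <- simulateOccupancy(m, p, cfg)
    openAt[r, ] <- stateCounts(occ)[match(checkMs, timesMs(occ)), "O"]
  }
  mu <- colMeans(openAt)
  se <- apply(openAt, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(mu - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("rendered current is the unitary current times the open count", {
  # one channel always open: O is absorbing from the start
  R <- matrix(0, 2, 2)
  R[1, 2] <- 1000 # instant opening at stimulus
  m <- gatingModel(R,
    stateNames = c("C", "O"), coupled = c(1L, 2L),
    sHalf = 0.001, slope = 1e-6, gammaPS = 24.7, eRevMV = 0, name = "open"
  )
  p <- stimulusProtocol("poke", 0, 50, 1)
  cfg <- simulationConfig(1,
    vHoldMV = -80, sweepLengthMs = 50, seed = 1,
    noiseSdPA = 0
  )
  occ <- simulateOccupancy(m, p, cfg)
  swRaw <- renderCurrent(occ, m, cfg, protocol = p, filter = FALSE)
  # i = 24.7 pS x (-80 mV) = -1.976 pA once open
  expect_equal(min(currentPA(swRaw)), -1.976, tolerance = 1e-9)
  late <- sweepTimesMs(swRaw) > 5
  expect_true(all(currentPA(swRaw)[late] == currentPA(swRaw)[late][1]))

  # filtered steady state keeps the DC value
  swF <- renderCurrent(occ, m, cfg, protocol = p, filter = TRUE)
  expect_equal(currentPA(swF)[length(currentPA(swF))], -1.976, tolerance = 1e-3)

  # zero open channels, no noise -> all-zero trace
  mClosed <- buildPreset("mes_slow")
  occ0 <- simulateOccupancy(mClosed, stimulusProtocol("poke", 0, 50, 0), cfg)
  sw0 <- renderCurrent(occ0, mClosed, cfg, protocol = p)
  expect_true(all(currentPA(sw0) == 0))
})

test_that("rendered noiseless current scales linearly with gamma and driving force", {
  m <- buildPreset("canonical_fast")
  p <- stimulusProtocol("poke", 5, 40, 6)
  cfg <- simulationConfig(50, vHoldMV = -80, sweepLengthMs = 60, seed = 9, noiseSdPA = 0)
  occ <- simulateOccupancy(m, p, cfg)
  sw1 <- renderCurrent(occ, m, cfg, protocol = p, filter = FALSE)
  m2 <- m
  m2@gammaPS <- 2 * m@gammaPS
  sw2 <- renderCurrent(occ, m2, cfg, protocol = p, filter = FALSE)
  expect_equal(currentPA(sw2), 2 * currentPA(sw1), tolerance = 1e-12)
  cfgV <- cfg
  cfgV@vHoldMV <- -40 # halves (V - E_rev)
  sw3 <- renderCurrent(occ, m, cfgV, protocol = p, filter = FALSE)
  expect_equal(currentPA(sw3), 0.5 * currentPA(sw1), tolerance = 1e-12)
})

test_that("the recording filter has the contracted -3 dB point and stopband", {
  fs <- 20000
  fc <- 1000
  tt <- (0:19999) / fs
  gainAt <- function(f) {
    y <- lowpassFilter(sin(2 * pi * f * tt), fs, fc)
    keep <- seq(5000, 20000) # skip startup
    sqrt(mean(y[keep]^2)) / sqrt(0.5)
  }
  g3 <- gainAt(fc)
  expect_equal(g3, 1 / sqrt(2), tolerance = 0.05) # -3 dB within 5% of cutoff
  att <- 20 * log10(gainAt(100) / gainAt(5000))
  expect_gt(att, 20) # > 20 dB attenuation at 5 kHz vs 100 Hz
})

test_that("whole-cell depth series grows with depth; sweeps carry ground truth", {
  m <- buildPreset("mes_slow")
  p <- stimulusProtocol("poke", 10, 80, 6, amplitudeSeries = c(1.5, 3, 6))
  cfg <- simulationConfig(200, sweepLengthMs = 120, seed = 21)
  ss <- simulateWholeCell(m, p, cfg, nRepeats = 8)
  expect_length(sweeps(ss), 24)
  expect_identical(annotations(ss)$preset, "mes_slow")
  peaks <- vapply(sweeps(ss), function(sw) {
    peakCurrent(sw, estimateBaseline(sw))
  }, numeric(1))
  amp <- vapply(sweeps(ss), stimAmplitude, numeric(1))
  meanPeak <- tapply(peaks, amp, mean)
  expect_true(all(diff(meanPeak[order(as.numeric(names(meanPeak)))]) > 0))
  # zero-amplitude protocol: noise around baseline
  p0 <- stimulusProtocol("poke", 10, 80, 0)
  ss0 <- simulateWholeCell(m, p0, cfg)
  x <- currentPA(ss0[[1]])
  expect_lt(abs(mean(x)), 1)
  expect_lt(stats::sd(x), 2 * cfg@noiseSdPA)
})
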