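mkSweep <- function(i, fs = 20000, onset = 50, dur = 100, amp = 3) {
  newSweep(i,
    fsHz = fs, vHoldMV = -80, stimOnsetMs = onset, stimDurationMs = dur,
    stimAmplitude = amp, stimKind = "poke"
  )
}

test_that("baseline estimation: flat value, CLT bound, window guards", {
  sw <- mkSweep(rep(-12, 4000))
  expect_identical(estimateBaseline(sw), -12)
  set.seed(1)
  swN <- mkSweep(-12 + rnorm(4000, 0, 2))
  b <- estimateBaseline(swN, c(0, 50)) # half-open window: samples 0..<50 ms
  n <- 1000
  expect_lt(abs(b + 12), 3 * 2 / sqrt(n))
  expect_error(estimateBaseline(sw, c(10, 60)), "overlaps")
  expect_error(estimateBaseline(sw, c(49.8, 50)), "10 samples")
})

test_that("peak current is a magnitude over baseline, symmetric in sign", {
  base <- rep(-12, 4400)
  t <- (seq_along(base) - 1) / 20
  pulse <- t >= 60 & t < 140
  inward <- base
  inward[pulse] <- -12 - 465
  swIn <- mkSweep(inward)
  b <- estimateBaseline(swIn)
  expect_equal(peakCurrent(swIn, b), 465)
  outward <- base
  outward[pulse] <- -12 + 465
  expect_equal(peakCurrent(mkSweep(outward), b), 465)
  # all-baseline noiseless trace: peak is 0
  expect_equal(peakCurrent(mkSweep(base), b), 0)
})

test_that("slow fraction: 1 on non-inactivating steps, exp(-75/tau) on full decays", {
  # rectangular, non-inactivating, noiseless -> slow fraction exactly 1
  rect <- rep(-10, 4400)
  t <- (seq_along(rect) - 1) / 20
  rect[t >= 50 & t < 150] <- -310
  m <- analyzeSweep(mkSweep(rect, dur = 100), blankMs = 0)
  expect_identical(slowFraction(m), 1)
  expect_identical(fastComponent(m), 0)

  # complete mono-exponential inactivation: slow fraction e^{-75/tau}
  for (tau in c(12, 20, 40)) {
    sw <- expDecaySweep(tau)
    b <- estimateBaseline(sw)
    pk <- peakCurrent(sw, b, blankMs = 0)
    sf <- slowCurrent(sw, b) / pk
    expect_equal(sf, exp(-75 / tau), tolerance = 6e-3)
  }

  # current that keeps growing past a short step reads out > 1 and is
  # flagged, not clipped (slow readout at 75 ms, peak window only 60 ms)
  grow <- rep(0, 4400)
  ramp <- t >= 50 & t < 140
  grow[ramp] <- -100 - 2 * (t[ramp] - 50)
  grow[t >= 140] <- grow[max(which(ramp))]
  mg <- analyzeSweep(mkSweep(grow, dur = 60), blankMs = 0)
  expect_gt(slowFraction(mg), 1)
  expect_true("slow_fraction_gt_1" %in% mg@flags)
  expect_true("negative_fast_component" %in% mg@flags)

  # sweep too short for the 75-ms readout
  shortSw <- mkSweep(rep(-5, 2000), onset = 40, dur = 50) # 100 ms total
  expect_error(slowCurrent(shortSw, -5), "too short")
})

test_that("metric identities hold exactly", {
  # fast + slow = peak, and 0 <= slow <= peak for monotone decays
  for (tau in c(5, 15, 60, 300)) {
    sw <- expDecaySweep(tau)
    m <- analyzeSweep(sw, blankMs = 0)
    expect_identical(fastComponent(m) + slowPA(m), peakPA(m))
    expect_gte(slowPA(m), 0)
    expect_lte(slowPA(m), peakPA(m))
  }
  # worked magnitudes: peak 465, slow 310 -> fast 155
  expect_equal(465 - 310, 155)
})

test_that("inactivation fits recover generating time constants", {
  # noiseless mono-exponential, tau = 15 ms -> within 1%
  sw <- expDecaySweep(15)
  f <- fitInactivation(sw, estimateBaseline(sw), form = "mono", blankMs = 0)
  expect_equal(f$tauMs, 15, tolerance = 0.01)
  expect_true(f$ok)

  # bi-exponential, equal amplitudes, noise sd 2 pA -> both within 10%
  fs <- 20000
  t <- (seq_len(fs) - 1) / fs * 1000 # 1000 ms
  onset <- 20
  dur <- 900
  i <- rep(-5, length(t))
  stim <- t >= onset & t < onset + dur
  td <- t[stim] - onset
  set.seed(42)
  i[stim] <- -5 - 200 * exp(-td / 10) - 200 * exp(-td / 200)
  i <- i + rnorm(length(i), 0, 2)
  swBi <- newSweep(i,
    fsHz = fs, stimOnsetMs = onset, stimDurationMs = dur,
    stimAmplitude = 5, stimKind = "poke"
  )
  fb <- fitInactivation(swBi, -5, form = "bi", blankMs = 0)
  expect_equal(fb$tauMs[1], 10, tolerance = 0.1)
  expect_equal(fb$tauMs[2], 200, tolerance = 0.1)

  # no decay segment: monotonically rising current during the step
  rise <- rep(0, 4400)
  tt <- (seq_along(rise) - 1) / 20
  rise[tt >= 50 & tt < 150] <- -(tt[tt >= 50 & tt < 150] - 50)
  expect_error(
    fitInactivation(mkSweep(rise, dur = 100), 0),
    "decay segment"
  )
})

test_that("simulated canonical_fast sweeps read out as fast-inactivating", {
  m <- buildPreset("canonical_fast")
  p <- stimulusProtocol("poke", 20, 150, 6)
  cfg <- simulationConfig(500, vHoldMV = -80, sweepLengthMs = 220, seed = 7)
  ss <- simulateWholeCell(m, p, cfg)
  met <- analyzeSweep(ss[[1]], fit = "mono")
  expect_lt(slowFraction(met), 0.2)
  expect_lte(met@tauMs[1], 20)
  expect_true(met@fitOk)
})

test_that("stage summaries and group comparison behave", {
  sw <- expDecaySweep(30)
  m <- analyzeSweep(sw, blankMs = 0)
  stage <- summarizeStage(rep(list(m), 30), "mESC")
  expect_identical(stage$n, 30L)
  expect_identical(stage$peak_sem_pA, 0)
  expect_identical(stage$slow_fraction_sem, 0)
  expect_error(summarizeStage(list(), "empty"), "empty")

  # Welch p-values are uniform under the null (same-distribution groups)
  set.seed(99)
  ps <- replicate(200, {
    compareSlowFraction(rnorm(15, 0.5, 0.1), rnorm(15, 0.5, 0.1))$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
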