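test_that("amplitude histograms bin correctly and conserve counts", {
  swConst <- newSweep(rep(-2, 1000), fsHz = 20000, id = "const")
  h <- buildHistogram(swConst, binWidthPA = 0.1)
  expect_identical(sum(h@counts > 0), 1L) # single occupied bin
  expect_identical(sum(h@counts), 1000L)

  # 50/50 two-level noiseless trace: two occupied bins with equal counts
  sw2 <- newSweep(rep(c(0, -2), each = 500), fsHz = 20000, id = "two")
  h2 <- buildHistogram(sw2, binWidthPA = 0.1)
  occ <- h2@counts[h2@counts > 0]
  expect_identical(length(occ), 2L)
  expect_identical(occ[1], occ[2])

  # total counts conserved under any bin width
  set.seed(3)
  swN <- newSweep(rnorm(5000), fsHz = 20000, id = "noise")
  for (bw in c(0.02, 0.1, 0.5)) {
    expect_identical(sum(buildHistogram(swN, binWidthPA = bw)@counts), 5000L)
  }
  expect_error(buildHistogram(swConst, segmentMs = c(10, 10)), "interval")
  expect_error(buildHistogram(swConst, binWidthPA = 0), "bin width")
})

test_that("level fitting recovers synthetic mixtures and selects the order", {
  set.seed(11)
  x <- c(rnorm(10000, 0, 0.3), rnorm(6000, -2, 0.3), rnorm(4000, -4, 0.3))
  sw <- newSweep(sample(x), fsHz = 20000, id = "mix")
  lv <- fitLevels(buildHistogram(sw, binWidthPA = 0.1), maxLevels = 4)
  expect_length(levelMeans(lv), 3L)
  expect_equal(levelMeans(lv), c(0, -2, -4), tolerance = 0.1 / 4)
  expect_equal(sum(levelWeights(lv)), 1, tolerance = 1e-9)
  # level 0 is the heaviest extreme; means ordered outward
  expect_equal(levelMeans(lv)[1], 0, tolerance = 0.05)

  # level means are invariant to bin width (fit uses the sample values)
  lv2 <- fitLevels(buildHistogram(sw, binWidthPA = 0.5), maxLevels = 4)
  expect_equal(levelMeans(lv2), levelMeans(lv), tolerance = 0.05 / 4)

  # single-level data -> model order 1
  set.seed(12)
  sw1 <- newSweep(rnorm(5000, -2, 0.2), fsHz = 20000, id = "one")
  expect_length(levelMeans(fitLevels(buildHistogram(sw1), maxLevels = 4)), 1L)

  expect_error(fitLevels(buildHistogram(sw1), maxLevels = 1), "max_levels")
  tiny <- newSweep(rnorm(8), fsHz = 20000, id = "tiny")
  expect_error(fitLevels(buildHistogram(tiny), maxLevels = 4), "fewer samples")
})

test_that("a 3-channel patch under saturating pressure shows 4 levels", {
  model <- buildPreset("mes_slow", stimulus = "pressure")
  prot <- stimulusProtocol("pressure", 40, 80, 60)
  cfg <- simulationConfig(3,
    vHoldMV = -80, noiseSdPA = 0.3,
    sweepLengthMs = 200, seed = 4242
  )
  ss <- simulateSingleChannel(model, prot, cfg, nRepeats = 15)
  pooled <- newSweep(unlist(lapply(sweeps(ss), currentPA)),
    fsHz = 20000,
    vHoldMV = -80, id = "pooled"
  )
  lv <- fitLevels(buildHistogram(pooled, binWidthPA = 0.05), maxLevels = 4)
  expect_length(levelMeans(lv), 4L)
  # adjacent spacings all near the unitary current gamma (V - E_rev)
  expect_equal(unname(diff(levelMeans(lv))), rep(-1.976, 3), tolerance = 0.08)
})

test_that("unitary current is the weight-weighted adjacent spacing", {
  mk <- function(mu, w) {
    new("LevelModel",
      meansPA = mu, sdsPA = rep(0.2, length(mu)), weights = w,
      noiseFraction = 0, bic = numeric(), flags = character()
    )
  }
  expect_equal(unitaryCurrent(mk(c(0, -1.976), c(0.6, 0.4))), -1.976)
  expect_equal(unitaryCurrent(mk(c(0, -2, -4), c(1, 1, 1) / 3)), -2)
  expect_equal(unitaryCurrent(mk(c(0, -2, -3.8), c(1, 1, 1) / 3)), -1.9)
  expect_error(unitaryCurrent(mk(0, 1)), "2 levels")
})

test_that("conductance fit: exact line, OLS standard errors, input guards", {
  v <- c(-80, -60, -40, 40, 60)
  exact <- data.frame(voltage_mV = v, unitary_pA = 0.025 * v)
  cf <- conductanceFit(exact)
  expect_equal(gammaPS(cf), 25, tolerance = 1e-12)
  expect_equal(eRevMV(cf), 0, tolerance = 1e-9)

  set.seed(7)
  noisy <- data.frame(voltage_mV = v, unitary_pA = 0.0247 * v + rnorm(5, 0, 0.1))
  cfN <- conductanceFit(noisy)
  # closed-form OLS slope SE
  res <- stats::residuals(stats::lm(unitary_pA ~ voltage_mV, noisy))
  s2 <- sum(res^2) / (5 - 2)
  seSlope <- sqrt(s2 / sum((v - mean(v))^2))
  expect_equal(cfN@gammaSE, seSlope * 1000, tolerance = 1e-9)

  expect_error(conductanceFit(exact[1:2, ]), "3 distinct voltages")
  same <- data.frame(voltage_mV = rep(-80, 4), unitary_pA = 1:4)
  expect_error(conductanceFit(same), "3 distinct voltages")
})

test_that("full pipeline recovers the generating conductance across voltages", {
  model <- buildPreset("mes_slow", stimulus = "pressure")
  prot <- stimulusProtocol("pressure", 40, 80, 30)
  volts <- c(-80, -60, -40, 40, 60)
  pts <- do.call(rbind, lapply(seq_along(volts), function(i) {
    cfg <- simulationConfig(2,
      vHoldMV = volts[i], noiseSdPA = 0.3,
      sweepLengthMs = 200, seed = 11 * 1000 + i
    )
    ss <- simulateSingleChannel(model, prot, cfg, nRepeats = 15)
    pooled <- newSweep(unlist(lapply(sweeps(ss), currentPA)),
      fsHz = 20000, vHoldMV = volts[i], id = "pooled"
    )
    lv <- fitLevels(buildHistogram(pooled, binWidthPA = 0.05), maxLevels = 3)
    data.frame(voltage_mV = volts[i], unitary_pA = unitaryCurrent(lv))
  }))
  cf <- conductanceFit(pts)
  expect_equal(gammaPS(cf), 24.7, tolerance = 2.5 / 24.7)
})

test_that("ensemble averages reconstruct the macroscopic open probability", {
  model <- buildPreset("mes_slow", stimulus = "pressure")
  prot <- stimulusProtocol("pressure", 20, 100, 60)
  cfg <- simulationConfig(1,
    vHoldMV = -80, noiseSdPA = 0.3,
    sweepLengthMs = 150, seed = 31
  )
  nSweeps <- 300L
  ss <- simulateSingleChannel(model, prot, cfg, nRepeats = nSweeps)
  avg <- ensembleAverage(ss)
  expect_identical(annotations(avg)$n_sweeps, 300L)

  grid <- sweepTimesMs(avg)
  P <- openProbabilityTimecourse(model, prot, grid)
  expected <- 24.7 * (-80) / 1000 * P[, "O"]
  checkMs <- seq(25, 115, by = 10)
  idx <- match(checkMs, round(grid, 6))
  # CLT bound: per-sweep current is Bernoulli(Po) x unitary + noise
  po <- P[idx, "O"]
  seI <- sqrt(po * (1 - po) * 1.976^2 + 0.1^2) / sqrt(nSweeps)
  expect_true(all(abs(currentPA(avg)[idx] - expected[idx]) <= 3 * seI))

  # ensemble kinetics match the whole-cell statistic of the same preset
  met <- analyzeSweep(avg)
  expect_equal(slowFraction(met), 0.67, tolerance = 0.05 / 0.67)

  # identical sweeps average to any one of them (zero-baseline case)
  one <- ss[[1]]
  copies <- lapply(1:3, function(i) {
    cp <- one
    cp@id <- paste0("copy", i)
    cp
  })
  same <- newSweepSet(copies)
  expect_equal(currentPA(ensembleAverage(same)),
    currentPA(one) - mean(currentPA(one)[sweepTimesMs(one) < 20]),
    tolerance = 1e-12
  )

  # i.i.d. noise variance shrinks by the ensemble size
  set.seed(5)
  mkNoise <- function(i) {
    newSweep(rnorm(2000), fsHz = 20000, id = paste0("n", i))
  }
  nset <- newSweepSet(lapply(1:16, mkNoise))
  vr <- stats::var(currentPA(ensembleAverage(nset)))
  expect_equal(vr, 1 / 16, tolerance = 0.25)

  # heterogeneous sweeps are rejected
  bad <- newSweepSet(list(one, newSweep(rnorm(100), fsHz = 20000, id = "short")))
  expect_error(ensembleAverage(bad), "share length|aligned")
})

test_that("idealization reconstructs state sequences", {
  mu <- c(0, -2)
  lv <- new("LevelModel",
    meansPA = mu, sdsPA = c(0.1, 0.1), weights = c(0.5, 0.5),
    noiseFraction = 0, bic = numeric(), flags = character()
  )
  truth <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(200, 100, 300, 150, 250))
  clean <- newSweep(mu[truth + 1L], fsHz = 20000, id = "clean")
  expect_identical(as.integer(idealizeSweep(clean, lv)), truth)

  set.seed(8)
  noisy <- newSweep(mu[truth + 1L] + rnorm(length(truth), 0, 0.2), # 0.1 x spacing
    fsHz = 20000, id = "noisy"
  )
  acc <- mean(as.integer(idealizeSweep(noisy, lv)) == truth)
  expect_gt(acc, 0.99)

  flat <- newSweep(rnorm(500, 0, 0.05), fsHz = 20000, id = "flat")
  expect_true(all(idealizeSweep(flat, lv) == 0L))

  # overlapping levels are flagged
  lvTight <- new("LevelModel",
    meansPA = c(0, -0.3), sdsPA = c(0.2, 0.2), weights = c(0.5, 0.5),
    noiseFraction = 0, bic = numeric(), flags = character()
  )
  out <- idealizeSweep(flat, lvTight)
  expect_true("overlapping_levels" %in% attr(out, "flags"))
})
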