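test_that("Nernst potentials: zero gradient, physiological K, sign symmetry, scaling", {
  expect_identical(nernstPotential(1, 100, 100), 0)
  expect_equal(nernstPotential(1, 150, 3), -100.5, tolerance = 1e-3)
  expect_identical(
    nernstPotential(-1, 20, 100),
    -nernstPotential(1, 20, 100)
  )
  # potentials scale linearly with T through RT/F
  expect_equal(
    nernstPotential(1, 150, 3, temperatureK = 310) /
      nernstPotential(1, 150, 3, temperatureK = 155),
    2
  )
  expect_error(nernstPotential(0, 1, 1), "valence")
  expect_error(nernstPotential(1, 0, 1), "concentrations")
})

test_that("Henderson LJPs reproduce the four recording-condition estimates", {
  pip <- solutionSpec(K = 150, Cl = 150, side = "pipette")
  nacl <- solutionSpec(Na = 150, Cl = 150, side = "bath")
  gluc <- solutionSpec(Na = 152, Gluconate = 152, side = "bath")
  cacl <- solutionSpec(Ca = 90, Cl = 180, side = "bath")
  nmdg <- solutionSpec(NMDG = 152, Cl = 152, side = "bath")
  expect_equal(hendersonLJP(pip, nacl), 4.3, tolerance = 0.5 / 4.3)
  expect_equal(hendersonLJP(pip, gluc), -6.7, tolerance = 0.5 / 6.7)
  expect_equal(hendersonLJP(pip, nmdg), 9.3, tolerance = 0.5 / 9.3)
  # the divalent condition computes to 8.7 mV at 25 C with classical
  # mobilities, about half a millivolt above the usual printed estimate
  expect_equal(hendersonLJP(pip, cacl), 8.72, tolerance = 0.01)
})

test_that("Henderson equation is antisymmetric and null for identical solutions", {
  a <- solutionSpec(K = 150, Cl = 150, side = "pipette")
  b <- solutionSpec(Na = 100, Ca = 25, Cl = 150, side = "bath")
  expect_identical(
    hendersonLJP(a, b),
    -hendersonLJP(
      solutionSpec(Na = 100, Ca = 25, Cl = 150, side = "pipette"),
      solutionSpec(K = 150, Cl = 150, side = "bath")
    )
  )
  same <- solutionSpec(K = 150, Cl = 150, side = "bath")
  expect_identical(hendersonLJP(a, same), 0)
  # neutral buffer entries are ignored
  withBuf <- solutionSpec(K = 150, Cl = 150, HEPES = 10, Glucose = 10, side = "bath")
  expect_identical(hendersonLJP(a, withBuf), 0)
  # missing mobility names the ion
  odd <- solutionSpec(
    X = 150, Cl = 150, side = "bath",
    valences = c(X = 1, Cl = -1)
  )
  expect_error(hendersonLJP(a, odd), "X")
})

test_that("reversal-potential correction applies the documented convention", {
  expect_equal(as.numeric(correctErev(4, 4.3)), -0.3)
  expect_equal(as.numeric(correctErev(15, 8.2)), 6.8)
  expect_identical(as.numeric(correctErev(7.5, 0)), 7.5)
})

test_that("bi-ionic permeability ratios match the constant-field formulas", {
  expect_identical(biIonicMonovalent(0, 150, 150), 1)
  expect_equal(biIonicMonovalent(10, 150, 150), exp(10 / rtfMV()), tolerance = 1e-9)
  expect_equal(biIonicMonovalent(10, 150, 150), 1.476, tolerance = 1e-3)
  # corrected NaCl-condition reversal: P_Na/P_K near 1
  expect_equal(biIonicMonovalent(-0.3, 150, 150), 0.99, tolerance = 2e-3)

  # Fatt-Ginsborg: corrected +6.8 mV, 150 K in vs 90 Ca out -> 1.25
  expect_equal(biIonicDivalent(6.8, 150, 90), 1.25, tolerance = 1e-3)
  expect_gt(biIonicDivalent(6.8, 150, 90), 1) # calcium more permeant
  # limit E -> -infinity: ratio -> 0
  expect_equal(biIonicDivalent(-2000, 150, 90), 0, tolerance = 1e-12)
  expect_error(biIonicMonovalent(0, 0, 150), "concentrations")
})

test_that("GHK voltage reduces to Nernst for a single permeant ion", {
  for (ci in c(150, 10)) {
    for (co in c(3, 150)) {
      g <- ghkVoltage(data.frame(ion = "K", valence = 1, pRel = 1, inMM = ci, outMM = co))
      expect_equal(g, nernstPotential(1, ci, co), tolerance = 1e-9)
      ga <- ghkVoltage(data.frame(ion = "Cl", valence = -1, pRel = 1, inMM = ci, outMM = co))
      expect_equal(ga, nernstPotential(-1, ci, co), tolerance = 1e-9)
    }
  }
})

test_that("reversal potentials are interpolated from I-V points", {
  expect_identical(
    estimateErev(data.frame(voltage_mV = c(-10, 10), current_pA = c(-5, 5))),
    0
  )
  # synthetic GHK I-V with a known +15 mV reversal, sampled at 10-mV steps
  ions <- data.frame(
    ion = c("K", "Na"), valence = c(1, 1),
    pRel = c(1, exp(15 / rtfMV())), inMM = c(150, 0), outMM = c(0, 150)
  )
  trueE <- ghkVoltage(ions)
  expect_equal(trueE, 15, tolerance = 1e-9)
  v <- seq(-40, 40, by = 10)
  iv <- data.frame(voltage_mV = v, current_pA = ghkCurrentOracle(v, ions))
  expect_equal(estimateErev(iv), 15, tolerance = 1 / 15)
  expect_error(
    estimateErev(data.frame(voltage_mV = c(0, 10), current_pA = c(1, 2))),
    "sign change"
  )
})

test_that("permeability sequences group near-equal ratios", {
  s <- permeabilitySequence(c(Ca = 1.25, K = 1.0, Na = 0.99, NMDG = 0.05))
  expect_identical(as.character(s), "P_Ca > P_K = P_Na > P_NMDG")
  expect_identical(attr(s, "groups")[[2]], c("K", "Na"))
  expect_length(attr(s, "flags"), 0L)
  # a chain of pairwise ties spanning more than the tolerance is flagged
  s2 <- permeabilitySequence(c(A = 1.0, B = 0.92, C = 0.85), tolerance = 0.1)
  expect_true("chained_ties" %in% attr(s2, "flags"))
  expect_error(permeabilitySequence(c(1, 2)), "named")
})

test_that("solution validity is enforced", {
  expect_error(solutionSpec(K = 150, side = "pipette"), "anion")
  expect_error(solutionSpec(K = -1, Cl = 150, side = "bath"), ">= 0")
  expect_error(solutionSpec(Zz = 5, Cl = 5, side = "bath"), "unknown ion")
})
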