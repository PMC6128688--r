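#' @include AllClasses.R
NULL

## RT/F in mV
.rtfMV <- function(temperatureK) {
  1000 * 8.314462618 * temperatureK / 96485.33212
}

#' Bundled limiting ionic mobility table
#'
#' Limiting equivalent ionic conductivities (S cm^2 / equiv, 25 C) used by
#' the Henderson junction-potential calculation. K+, Na+, Cl-, Ca2+ (per
#' equivalent), Mg2+, Cs+, Li+, H+ and OH- are the classical infinite-dilution
#' values from standard electrochemistry tables. Gluconate- (24.4) follows
#' the junction-potential literature for large organic anions; NMDG+ (28.0)
#' sits in the range quoted for N-methyl-D-glucamine in the same literature
#' (about 0.36-0.38 of the chloride mobility). HEPES- (22.0) is included for
#' completeness for users who assign the buffer an explicit valence.
#'
#' @return Data frame with columns `ion`, `lambda` (S cm^2/equiv) and
#'   `valence`.
#' @seealso [hendersonLJP()]
#' @export
defaultMobilityTable <- function() {
  data.frame(
    ion = c(
      "K", "Na", "Cl", "Ca", "Mg", "Cs", "Li", "H", "OH",
      "Gluconate", "NMDG", "HEPES"
    ),
    lambda = c(73.5, 50.1, 76.3, 59.5, 53.1, 77.2, 38.7, 349.8, 198.0, 24.4, 28.0, 22.0),
    valence = c(1L, 1L, -1L, 2L, 2L, 1L, 1L, 1L, -1L, -1L, 1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Nernst equilibrium potential
#'
#' \eqn{E = (RT/zF) \ln(c_{out}/c_{in})}, in mV.
#'
#' @param z ionic valence (integer, non-zero).
#' @param cInMM,cOutMM inside / outside concentrations (mM, > 0).
#' @param temperatureK temperature (K, default 298.15).
#' @return Equilibrium potential (mV).
#' @examples
#' nernstPotential(1, 150, 3) # K+ under physiological gradients, about -100 mV
#' @export
nernstPotential <- function(z, cInMM, cOutMM, temperatureK = 298.15) {
  if (z == 0) stop("valence must be non-zero")
  if (any(c(cInMM, cOutMM) <= 0)) stop("concentrations must be > 0")
  .rtfMV(temperatureK) / z * log(cOutMM / cInMM)
}

#' Henderson liquid-junction potential
#'
#' Evaluates the Henderson equation for the junction between the pipette and
#' bath solutions using the bundled limiting-mobility table. The value is
#' returned as the bath potential relative to the pipette (bath minus
#' pipette); with this convention a measured reversal potential is corrected
#' as `corrected = measured - LJP` (see [correctErev()]). The equation is
#' antisymmetric: swapping the solutions flips the sign exactly.
#'
#' Entries with `valence = 0` (HEPES, glucose and other buffers left
#' electro-neutral) are excluded from the sums. Concentrations are used as
#' activities.
#'
#' @param pipette,bath [SolutionSpec-class] objects.
#' @param table mobility table (data frame with `ion`, `lambda`); defaults to
#'   [defaultMobilityTable()].
#' @param temperatureK temperature (K); defaults to the solutions'
#'   temperature (which must agree).
#' @return Liquid junction potential in mV (bath minus pipette).
#' @examples
#' pip <- solutionSpec(K = 150, Cl = 150, side = "pipette")
#' bath <- solutionSpec(Na = 150, Cl = 150, side = "bath")
#' hendersonLJP(pip, bath) # about 4.4 mV
#' @export
hendersonLJP <- function(pipette, bath, table = defaultMobilityTable(),
                         temperatureK = NULL) {
  validObject(pipette)
  validObject(bath)
  if (is.null(temperatureK)) {
    if (abs(pipette@temperatureK - bath@temperatureK) > 1e-9) {
      stop("solutions disagree on temperature; pass temperatureK explicitly")
    }
    temperatureK <- pipette@temperatureK
  }
  collect <- function(sol) {
    d <- sol@ions[sol@ions$valence != 0L, c("ion", "mM", "valence")]
    stats::aggregate(mM ~ ion + valence, data = d, FUN = sum)
  }
  p <- collect(pipette)
  b <- collect(bath)
  ions <- unique(rbind(p[c("ion", "valence")], b[c("ion", "valence")]))
  ions <- ions[order(ions$ion, ions$valence), , drop = FALSE] # canonical order
  # (a fixed summation order makes hendersonLJP(A, B) == -hendersonLJP(B, A)
  # exact in floating point, together with the log difference below)
  miss <- setdiff(ions$ion, table$ion)
  if (length(miss)) {
    stop("no mobility for ion(s): ", paste(miss, collapse = ", "))
  }
  lam <- table$lambda[match(ions$ion, table$ion)]
  cP <- p$mM[match(ions$ion, p$ion)]
  cP[is.na(cP)] <- 0
  cB <- b$mM[match(ions$ion, b$ion)]
  cB[is.na(cB)] <- 0
  z <- ions$valence
  num <- sum(sign(z) * lam * (cB - cP))
  den <- sum(abs(z) * lam * (cB - cP))
  sP <- sum(abs(z) * lam * cP)
  sB <- sum(abs(z) * lam * cB)
  if (den == 0 || sP <= 0 || sB <= 0) {
    if (sum(abs(cB - cP)) == 0) return(0) # identical solutions
    stop("degenerate Henderson sums; check solution compositions")
  }
  .rtfMV(temperatureK) * (num / den) * (log(sP) - log(sB))
}

#' Correct a measured reversal potential for the junction potential
#'
#' With the bath-minus-pipette LJP convention of [hendersonLJP()], the true
#' membrane potential is the commanded one minus the LJP, so
#' `corrected = measured - LJP`.
#'
#' @param measuredMV measured (raw) reversal potential, mV.
#' @param ljpMV liquid junction potential, mV (bath minus pipette).
#' @return Corrected reversal potential (mV), with the convention recorded
#'   in the `"convention"` attribute.
#' @examples
#' correctErev(4, 4.3) # -0.3 mV
#' @export
correctErev <- function(measuredMV, ljpMV) {
  out <- measuredMV - ljpMV
  attr(out, "convention") <- "corrected = measured - LJP(bath - pipette)"
  out
}

#' Bi-ionic permeability ratio, monovalent/monovalent
#'
#' Under bi-ionic conditions (internal cation X_in, external cation X_out,
#' impermeant or common anion), the GHK voltage equation reduces to
#' \eqn{P_{out}/P_{in} = (c_{in}/c_{out}) e^{E F / RT}} with E the corrected
#' reversal potential.
#'
#' @param correctedErevMV corrected reversal potential (mV).
#' @param cCationInMM internal cation concentration (mM).
#' @param cCationOutMM external cation concentration (mM).
#' @param temperatureK temperature (K).
#' @return The permeability ratio P(external cation) / P(internal cation).
#' @examples
#' biIonicMonovalent(0, 150, 150) # 1: equally permeant
#' @export
biIonicMonovalent <- function(correctedErevMV, cCationInMM, cCationOutMM,
                              temperatureK = 298.15) {
  if (cCationInMM <= 0 || cCationOutMM <= 0) stop("concentrations must be > 0")
  (cCationInMM / cCationOutMM) * exp(correctedErevMV / .rtfMV(temperatureK))
}

#' Bi-ionic permeability ratio, divalent/monovalent (Fatt-Ginsborg)
#'
#' For an external divalent cation against an internal monovalent cation the
#' constant-field reversal potential gives the Fatt-Ginsborg relation
#' \deqn{P_{Ca}/P_K = \frac{[K]_{in}}{4 [Ca]_{out}} e^{E'F/RT} (1 + e^{E'F/RT})}
#' with E' the corrected reversal potential.
#'
#' @param correctedErevMV corrected reversal potential (mV).
#' @param cMonoInMM internal monovalent concentration (mM).
#' @param cDiOutMM external divalent concentration (mM).
#' @param temperatureK temperature (K).
#' @return The permeability ratio P(divalent) / P(monovalent).
#' @examples
#' biIonicDivalent(6.8, 150, 90) # about 1.25
#' @export
biIonicDivalent <- function(correctedErevMV, cMonoInMM, cDiOutMM,
                            temperatureK = 298.15) {
  if (cMonoInMM <= 0 || cDiOutMM <= 0) stop("concentrations must be > 0")
  xi <- exp(correctedErevMV / .rtfMV(temperatureK))
  (cMonoInMM / (4 * cDiOutMM)) * xi * (1 + xi)
}

#' GHK voltage equation (monovalent ions)
#'
#' Zero-current membrane potential of the constant-field (Goldman-Hodgkin-
#' Katz) voltage equation for a set of monovalent permeant ions. With a
#' single permeant ion present the result reduces to the Nernst potential.
#'
#' @param ions data frame with columns `ion`, `valence` (+1 or -1), `pRel`
#'   (relative permeability), `inMM`, `outMM`.
#' @param temperatureK temperature (K).
#' @return Reversal potential (mV).
#' @examples
#' ghkVoltage(data.frame(ion = "K", valence = 1, pRel = 1, inMM = 150, outMM = 3))
#' @export
ghkVoltage <- function(ions, temperatureK = 298.15) {
  need <- c("valence", "pRel", "inMM", "outMM")
  if (!all(need %in% names(ions))) stop("ions needs columns valence, pRel, inMM, outMM")
  if (any(abs(ions$valence) != 1)) {
    stop("the GHK voltage equation implemented here covers monovalent ions only")
  }
  cat <- ions$valence == 1
  num <- sum(ions$pRel[cat] * ions$outMM[cat]) + sum(ions$pRel[!cat] * ions$inMM[!cat])
  den <- sum(ions$pRel[cat] * ions$inMM[cat]) + sum(ions$pRel[!cat] * ions$outMM[!cat])
  if (num <= 0 || den <= 0) stop("GHK sums must be positive")
  .rtfMV(temperatureK) * log(num / den)
}

#' Reversal potential from I-V points
#'
#' Linear interpolation of the zero-current crossing between the bracketing
#' pair of points (the I-V relation is taken as locally monotone around the
#' reversal).
#'
#' @param ivPoints data frame with columns `voltage_mV`, `current_pA`,
#'   containing a sign change.
#' @return Interpolated reversal potential (mV).
#' @examples
#' estimateErev(data.frame(voltage_mV = c(-10, 10), current_pA = c(-5, 5))) # 0
#' @export
estimateErev <- function(ivPoints) {
  need <- c("voltage_mV", "current_pA")
  if (!all(need %in% names(ivPoints))) {
    stop("ivPoints needs columns voltage_mV and current_pA")
  }
  d <- ivPoints[order(ivPoints$voltage_mV), ]
  i <- d$current_pA
  v <- d$voltage_mV
  exact <- which(i == 0)
  if (length(exact)) return(v[exact[1]])
  k <- which(i[-length(i)] * i[-1] < 0)
  if (!length(k)) stop("I-V points do not bracket a sign change")
  k <- k[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Order permeability ratios into a permeability sequence
#'
#' Sorts per-ion permeability ratios (relative to the internal reference
#' cation) and groups ions whose ratios are equal within a tolerance into
#' `=` ties, producing a sequence string such as
#' `"P_Ca > P_K = P_Na > P_NMDG"`. Two ratios are tied when their ratio is
#' within `1 + tolerance`. A `"chained_ties"` flag marks groups whose
#' extremes differ by more than the tolerance even though neighbours tie.
#'
#' @param ratios named numeric vector of permeability ratios.
#' @param tolerance relative equality tolerance (default 0.1).
#' @return The sequence string, with attributes `"groups"` (list of ion
#'   names per tie group) and `"flags"`.
#' @examples
#' permeabilitySequence(c(Ca = 1.25, K = 1, Na = 0.99, NMDG = 0.05))
#' @export
permeabilitySequence <- function(ratios, tolerance = 0.1) {
  if (length(ratios) < 2L) stop("need at least 2 ratios to order")
  if (is.null(names(ratios)) || any(names(ratios) == "")) stop("ratios must be named")
  r <- sort(ratios, decreasing = TRUE)
  groups <- list(names(r)[1])
  gval <- r[1]
  flags <- character()
  for (i in seq_along(r)[-1]) {
    prev <- r[i - 1]
    if (prev / r[i] <= 1 + tolerance) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], names(r)[i])
      if (gval / r[i] > 1 + tolerance) flags <- unique(c(flags, "chained_ties"))
    } else {
      groups <- c(groups, list(names(r)[i]))
      gval <- r[i]
    }
  }
  s <- paste(
    vapply(groups, function(g) paste(paste0("P_", g), collapse = " = "), character(1)),
    collapse = " > "
  )
  attr(s, "groups") <- groups
  attr(s, "flags") <- flags
  s
}
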