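#' @include AllClasses.R
NULL

.msToIdx <- function(sweep, tMs) {
  pmin(pmax(1L, as.integer(round(tMs * sweep@fsHz / 1000)) + 1L), length(sweep@currentPA))
}

#' Baseline current of a sweep
#'
#' Mean current over a pre-stimulus window. Whole-cell mechanosensitive
#' metrics are magnitudes *over baseline*, so every analysis starts here.
#'
#' @param sweep a [Sweep-class].
#' @param windowMs `(start, end)` window in ms; must end at or before the
#'   stimulus onset and contain at least 10 samples. Defaults to everything
#'   before the stimulus.
#' @return Baseline current in pA (signed).
#' @examples
#' sw <- newSweep(rep(-12, 2000), fsHz = 20000, stimOnsetMs = 50,
#'                stimDurationMs = 40, stimAmplitude = 3)
#' estimateBaseline(sw) # -12
#' @export
estimateBaseline <- function(sweep, windowMs = c(0, sweep@stimOnsetMs)) {
  if (length(windowMs) != 2L || windowMs[2] <= windowMs[1]) {
    stop("window must be an increasing (start, end) pair in ms")
  }
  if (!is.na(sweep@stimOnsetMs) && windowMs[2] > sweep@stimOnsetMs + 1e-9) {
    stop("baseline window overlaps the stimulus (ends after stim_onset)")
  }
  tMs <- sweepTimesMs(sweep)
  i <- which(tMs >= windowMs[1] - 1e-9 & tMs < windowMs[2] - 1e-9) # half-open window
  if (length(i) < 10L) stop("baseline window must contain at least 10 samples")
  mean(sweep@currentPA[i])
}

## signed peak deviation and its index within the stimulus window
.peakInfo <- function(sweep, baseline, blankMs = 2) {
  if (is.na(sweep@stimOnsetMs) || is.na(sweep@stimDurationMs)) {
    stop("sweep has no stimulus window metadata")
  }
  lo <- sweep@stimOnsetMs + blankMs
  hi <- sweep@stimOnsetMs + sweep@stimDurationMs
  if (hi <= lo) stop("empty stimulus window after blanking")
  idx <- .msToIdx(sweep, lo):.msToIdx(sweep, hi)
  dev <- sweep@currentPA[idx] - baseline
  k <- which.max(abs(dev))
  list(valuePA = abs(dev[k]), sign = sign(dev[k]), index = idx[k])
}

#' Peak mechanosensitive current
#'
#' Maximum absolute deviation from baseline within the stimulus window,
#' reported as a positive magnitude in pA. The first `blankMs` after onset
#' are excluded to skip the capacitive transient of the step edge.
#'
#' @param sweep a [Sweep-class] with stimulus metadata.
#' @param baseline baseline current (pA), from [estimateBaseline()].
#' @param blankMs edge-blanking window after stimulus onset (ms, default 2).
#' @return Peak current magnitude over baseline (pA, >= 0).
#' @export
peakCurrent <- function(sweep, baseline, blankMs = 2) {
  .peakInfo(sweep, baseline, blankMs)$valuePA
}

#' Slow (75-ms) mechanosensitive current
#'
#' Magnitude over baseline of the current remaining `atMs` (default 75 ms)
#' after stimulus onset — the numerator of the slow fraction. The readout is
#' the mean over a short symmetric window (default 5 ms) centred on the time
#' point, for robustness to noise.
#'
#' @inheritParams peakCurrent
#' @param atMs readout time after stimulus onset (ms, default 75).
#' @param windowMs width of the averaging window (ms, default 5).
#' @return Slow current magnitude (pA, >= 0).
#' @export
slowCurrent <- function(sweep, baseline, atMs = 75, windowMs = 5) {
  if (is.na(sweep@stimOnsetMs)) stop("sweep has no stimulus metadata")
  tMid <- sweep@stimOnsetMs + atMs
  lenMs <- length(sweep@currentPA) / sweep@fsHz * 1000
  if (lenMs < tMid + windowMs / 2) {
    stop("sweep too short: must extend at least ", atMs, " ms past stimulus onset")
  }
  idx <- .msToIdx(sweep, tMid - windowMs / 2):.msToIdx(sweep, tMid + windowMs / 2)
  abs(mean(sweep@currentPA[idx]) - baseline)
}

#' Analyze one whole-cell sweep
#'
#' Computes the full metric set for a sweep: baseline, peak, slow current at
#' 75 ms, slow fraction, fast component and (optionally) an exponential
#' inactivation fit. Values that defy the usual ordering are flagged, never
#' clipped: `slow_fraction_gt_1` when the current grows during the step,
#' `negative_fast_component` when slow exceeds peak.
#'
#' @param sweep a [Sweep-class] with stimulus metadata.
#' @param baselineWindowMs baseline window (ms), default everything before
#'   the stimulus.
#' @param blankMs edge-blanking after onset (ms).
#' @param atMs slow-current readout time (ms after onset).
#' @param slowWindowMs slow-current averaging window (ms).
#' @param fit `"none"`, `"mono"` or `"bi"`: inactivation fit to attach.
#' @return An [MSCurrentMetrics-class].
#' @examples
#' m <- buildPreset("mes_slow")
#' p <- stimulusProtocol("poke", 20, 150, 6)
#' ss <- simulateWholeCell(m, p, simulationConfig(200, sweepLengthMs = 220, seed = 5))
#' analyzeSweep(ss[[1]])
#' @export
analyzeSweep <- function(sweep, baselineWindowMs = c(0, sweep@stimOnsetMs),
                         blankMs = 2, atMs = 75, slowWindowMs = 5,
                         fit = c("none", "mono", "bi")) {
  fit <- match.arg(fit)
  baseline <- estimateBaseline(sweep, baselineWindowMs)
  peak <- peakCurrent(sweep, baseline, blankMs)
  slow <- slowCurrent(sweep, baseline, atMs, slowWindowMs)
  flags <- character()
  sf <- if (peak > 0) slow / peak else NA_real_
  if (!is.na(sf) && sf > 1) flags <- c(flags, "slow_fraction_gt_1")
  fc <- peak - slow
  if (fc < 0) flags <- c(flags, "negative_fast_component")
  tau <- numeric()
  fitOk <- NA
  if (fit != "none") {
    ft <- tryCatch(
      fitInactivation(sweep, baseline, form = fit, blankMs = blankMs),
      error = function(e) NULL
    )
    if (!is.null(ft)) {
      tau <- ft$tauMs
      fitOk <- ft$ok
    } else {
      flags <- c(flags, "fit_failed")
      fitOk <- FALSE
    }
  }
  new("MSCurrentMetrics",
    sweepId = sweep@id, baselinePA = baseline, peakPA = peak, slowPA = slow,
    slowFraction = sf, fastComponent = fc, tauMs = tau, fitOk = fitOk,
    flags = flags
  )
}

#' Exponential inactivation fit
#'
#' Least-squares fit of the current decay from the time of peak to the end
#' of the stimulus, on the baseline-subtracted magnitude:
#' mono: \eqn{A e^{-t/\tau} + C}; bi: \eqn{A e^{-t/\tau_1} + B e^{-t/\tau_2} + C}.
#' Mechanosensitive decays are often irregular, so the result carries a
#' quality flag: `ok` is `FALSE` when R-squared falls below `r2Threshold` or
#' a time constant runs into its bounds — such fits should not be reported
#' as kinetics.
#'
#' @param sweep a [Sweep-class] with stimulus metadata.
#' @param baseline baseline current (pA).
#' @param form `"mono"` or `"bi"`.
#' @param blankMs edge-blanking after onset (ms).
#' @param r2Threshold minimum R-squared for `ok = TRUE` (default 0.8).
#' @return A list: `tauMs` (sorted time constants), `amplitudesPA`,
#'   `plateauPA`, `r2`, `ok`.
#' @export
fitInactivation <- function(sweep, baseline, form = c("mono", "bi"),
                            blankMs = 2, r2Threshold = 0.8) {
  form <- match.arg(form)
  pk <- .peakInfo(sweep, baseline, blankMs)
  endIdx <- .msToIdx(sweep, sweep@stimOnsetMs + sweep@stimDurationMs)
  if (endIdx - pk$index < 20L) {
    stop("no identifiable decay segment: peak lies at the stimulus end")
  }
  idx <- pk$index:endIdx
  t <- (idx - pk$index) / sweep@fsHz * 1000
  y <- pk$sign * (sweep@currentPA[idx] - baseline) # decaying positive magnitude
  span <- max(t)
  tauMax <- 10 * span
  tauMin <- 1e-3
  d <- data.frame(t = t, y = y)
  fit <- if (form == "mono") {
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
      data = d,
      start = list(A = max(y) - min(y), tau = span / 5, C = min(y)),
      lower = c(A = 0, tau = tauMin, C = -Inf),
      upper = c(A = Inf, tau = tauMax, C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-t / tau1) + B * exp(-t / tau2) + C,
      data = d,
      start = list(
        A = (max(y) - min(y)) / 2, tau1 = span / 20,
        B = (max(y) - min(y)) / 2, tau2 = span / 2, C = min(y)
      ),
      lower = c(A = 0, tau1 = tauMin, B = 0, tau2 = tauMin, C = -Inf),
      upper = c(A = Inf, tau1 = tauMax, B = Inf, tau2 = tauMax, C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  cf <- stats::coef(fit)
  taus <- sort(unname(cf[grep("^tau", names(cf))]))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  atBound <- any(taus <= tauMin * 1.01) || any(taus >= tauMax * 0.99)
  list(
    tauMs = taus,
    amplitudesPA = unname(cf[grep("^(A|B)$", names(cf))]),
    plateauPA = unname(cf[["C"]]),
    r2 = r2,
    ok = (r2 >= r2Threshold) && !atBound
  )
}

#' Metrics list to data frame
#'
#' @param metricsList list of [MSCurrentMetrics-class] objects.
#' @return A data frame, one row per sweep, with columns `sweep_id`,
#'   `baseline_pA`, `peak_pA`, `slow_pA`, `slow_fraction`, `fast_pA`,
#'   `tau_ms`, `fit_ok`, `flags`.
#' @export
metricsTable <- function(metricsList) {
  data.frame(
    sweep_id = vapply(metricsList, sweepId, character(1)),
    baseline_pA = vapply(metricsList, baselinePA, numeric(1)),
    peak_pA = vapply(metricsList, peakPA, numeric(1)),
    slow_pA = vapply(metricsList, slowPA, numeric(1)),
    slow_fraction = vapply(metricsList, slowFraction, numeric(1)),
    fast_pA = vapply(metricsList, fastComponent, numeric(1)),
    tau_ms = vapply(metricsList, function(m) {
      if (length(m@tauMs)) paste(signif(m@tauMs, 4), collapse = ";") else NA_character_
    }, character(1)),
    fit_ok = vapply(metricsList, function(m) m@fitOk, logical(1)),
    flags = vapply(metricsList, function(m) paste(m@flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Summarize a differentiation stage
#'
#' Mean and SEM (sd/sqrt(n)) of peak, slow and slow fraction across the
#' cells of one stage. Data from independent differentiations are pooled
#' without batch terms.
#'
#' @param metricsList list of [MSCurrentMetrics-class], one per cell.
#' @param stage stage label.
#' @return One-row data frame: `stage`, `n`, then `mean`/`sem` columns for
#'   `peak_pA`, `slow_pA`, `slow_fraction`.
#' @export
summarizeStage <- function(metricsList, stage) {
  if (!length(metricsList)) stop("empty group")
  ms <- function(v) c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  pk <- ms(vapply(metricsList, peakPA, numeric(1)))
  sl <- ms(vapply(metricsList, slowPA, numeric(1)))
  sf <- ms(vapply(metricsList, slowFraction, numeric(1)))
  data.frame(
    stage = stage, n = length(metricsList),
    peak_mean_pA = pk["mean"], peak_sem_pA = pk["sem"],
    slow_mean_pA = sl["mean"], slow_sem_pA = sl["sem"],
    slow_fraction_mean = sf["mean"], slow_fraction_sem = sf["sem"],
    row.names = NULL
  )
}

#' Compare slow fractions between two groups
#'
#' Two-sample unequal-variance (Welch) t-test, two-tailed, on the slow
#' fractions of two groups of cells.
#'
#' @param groupA,groupB numeric vectors of slow fractions, or lists of
#'   [MSCurrentMetrics-class].
#' @return The `htest` object from [stats::t.test()].
#' @export
compareSlowFraction <- function(groupA, groupB) {
  toNum <- function(g) {
    if (is.list(g)) vapply(g, slowFraction, numeric(1)) else as.numeric(g)
  }
  a <- toNum(groupA)
  b <- toNum(groupB)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
}
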