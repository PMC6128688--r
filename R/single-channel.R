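#' @include AllClasses.R
NULL

#' Amplitude histogram of a sweep segment
#'
#' Bins the current samples of a segment into uniform bins spanning their
#' range. The raw samples are retained on the object because level fitting
#' ([fitLevels()]) uses them directly — fitted level means are therefore
#' insensitive to the bin width, which only affects display.
#'
#' @param sweep a [Sweep-class].
#' @param segmentMs `(start, end)` segment in ms (default: whole sweep).
#' @param binWidthPA bin width in pA (> 0).
#' @return An [AmplitudeHistogram-class].
#' @examples
#' sw <- newSweep(rnorm(5000, -2, 0.1), fsHz = 20000)
#' buildHistogram(sw, binWidthPA = 0.1)
#' @export
buildHistogram <- function(sweep, segmentMs = NULL, binWidthPA = 0.1) {
  if (binWidthPA <= 0) stop("bin width must be > 0")
  lenMs <- length(sweep@currentPA) / sweep@fsHz * 1000
  if (is.null(segmentMs)) segmentMs <- c(0, lenMs)
  if (segmentMs[1] < 0 || segmentMs[2] > lenMs + 1e-9 || segmentMs[2] <= segmentMs[1]) {
    stop("segment must be a non-empty interval within the sweep")
  }
  tMs <- sweepTimesMs(sweep)
  x <- sweep@currentPA[tMs >= segmentMs[1] - 1e-9 & tMs < segmentMs[2] - 1e-9]
  if (!length(x)) stop("segment contains no samples")
  lo <- floor(min(x) / binWidthPA) * binWidthPA
  nb <- max(1L, ceiling((max(x) - lo) / binWidthPA + 1e-9))
  breaks <- lo + (0:nb) * binWidthPA
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE, right = FALSE)))
  new("AmplitudeHistogram",
    breaksPA = breaks, counts = counts, samplesPA = x,
    segmentMs = segmentMs, sourceId = sweep@id
  )
}

## initial centers at the local maxima of a kernel density estimate,
## supplemented by quantiles when fewer than G peaks exist
.densityPeakCenters <- function(x, G) {
  d <- stats::density(x, n = 1024)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1L
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  ctr <- d$x[pk]
  if (length(ctr) >= G) {
    return(sort(ctr[seq_len(G)]))
  }
  sort(unique(c(ctr, as.numeric(stats::quantile(x, seq(0.05, 0.95, length.out = G))))))[seq_len(G)]
}

## one EM run: equal-variance Gaussian levels + a uniform noise component
## absorbing filter-transition samples, initialized from hard assignment to
## `centers` with residual outliers seeded into the noise class
.emLevels <- function(x, G, centers) {
  n <- length(x)
  centers <- sort(centers)
  cl <- max.col(-abs(outer(x, centers, "-")))
  resid <- abs(x - centers[cl])
  s0 <- max(1.4826 * stats::mad(resid), 1e-6)
  z <- matrix(0, n, G + 1L)
  isNoise <- resid > 3.5 * s0
  z[cbind(which(!isNoise), cl[!isNoise])] <- 1
  z[isNoise, G + 1L] <- 1
  meE <- mclust::meE # me() resolves the model worker in the calling frame
  mclust::me(data = x, modelName = "E", z = z, Vinv = 1 / diff(range(x)))
}

#' Fit conductance levels to an amplitude histogram
#'
#' Fits a Gaussian mixture to the sample values of the histogram and selects
#' the number of levels among `1..maxLevels` by BIC. The mixture has equal
#' component variance (all levels see the same recording noise) plus one
#' uniform component that absorbs the samples a low-pass filter smears
#' between levels during transitions — without it, transition samples bias
#' the level means and the order selection. The EM is run from two
#' deterministic starts per candidate order (density-peak centers and
#' quantile centers), keeping the better likelihood.
#'
#' Levels are returned ordered from the closed/baseline level (level 0)
#' outward in the direction of channel current; the closed level is
#' identified as the extreme level with the larger mixing weight, which
#' holds whenever the analyzed segment contains the shut periods of the
#' recording.
#'
#' @param hist an [AmplitudeHistogram-class].
#' @param maxLevels maximum number of levels considered (>= 2).
#' @return A [LevelModel-class]. A `"overlapping_levels"` flag is set when
#'   adjacent levels are closer than twice their pooled sd.
#' @export
fitLevels <- function(hist, maxLevels = 4L) {
  if (maxLevels < 2L) stop("max_levels must be >= 2")
  x <- hist@samplesPA
  # 3 parameters per component: need comfortably more samples
  if (length(x) < 3L * maxLevels + 2L) stop("fewer samples than mixture parameters")
  n <- length(x)
  fits <- vector("list", maxLevels)
  bics <- rep(-Inf, maxLevels)
  for (G in seq_len(maxLevels)) {
    starts <- list(
      .densityPeakCenters(x, G),
      as.numeric(stats::quantile(x, seq(0.02, 0.98, length.out = G)))
    )
    best <- NULL
    for (st in starts) {
      st <- unique(st)
      if (length(st) != G) next
      f <- tryCatch(.emLevels(x, G, st), error = function(e) NULL)
      if (!is.null(f) && !is.na(f$loglik) &&
        (is.null(best) || f$loglik > best$loglik)) {
        best <- f
      }
    }
    if (is.null(best)) next
    # G means + 1 common variance + G free mixing proportions (incl. noise)
    bics[G] <- 2 * best$loglik - (2 * G + 1) * log(n)
    fits[[G]] <- best
  }
  if (all(!is.finite(bics))) stop("mixture fit failed")
  fit <- fits[[which.max(bics)]]
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sdv) == 1L) sdv <- rep(sdv, length(mu))
  pro <- as.numeric(fit$parameters$pro)
  noiseFraction <- pro[length(pro)]
  w <- pro[seq_along(mu)]
  w <- w / sum(w)
  o <- order(mu)
  mu <- mu[o]
  sdv <- sdv[o]
  w <- w[o]
  # closed level = extreme component with the larger weight; order outward
  if (length(mu) > 1L && w[1L] < w[length(w)]) {
    mu <- rev(mu)
    sdv <- rev(sdv)
    w <- rev(w)
  }
  flags <- character()
  if (length(mu) > 1L) {
    sp <- abs(diff(mu))
    pooled <- (sdv[-1] + sdv[-length(sdv)]) / 2
    if (any(sp < 2 * pooled)) flags <- c(flags, "overlapping_levels")
  }
  new("LevelModel",
    meansPA = mu, sdsPA = sdv, weights = w, noiseFraction = noiseFraction,
    bic = bics, flags = flags
  )
}

#' Unitary current from a level model
#'
#' Weight-weighted mean of adjacent-level spacings, signed in the direction
#' of channel current (negative for inward current). Using all adjacent
#' spacings (each weighted by the combined occupancy of its two levels)
#' is robust in multi-channel patches, where several open levels are
#' populated.
#'
#' @param levels a [LevelModel-class] with at least 2 levels.
#' @return Signed unitary current (pA).
#' @examples
#' lm <- new("LevelModel", meansPA = c(0, -2, -4), sdsPA = rep(0.2, 3),
#'           weights = c(0.5, 0.3, 0.2), bic = numeric(), flags = character())
#' unitaryCurrent(lm) # -2
#' @export
unitaryCurrent <- function(levels) {
  mu <- levels@meansPA
  if (length(mu) < 2L) stop("need at least 2 levels for a unitary current")
  sp <- diff(mu) # signed, in direction away from closed
  w <- levels@weights[-1] + levels@weights[-length(levels@weights)]
  sum(sp * w) / sum(w)
}

#' Single-channel conductance from per-voltage unitary currents
#'
#' Ordinary least-squares fit of \eqn{i = \gamma (V - E_{rev})} to unitary
#' currents measured at several holding potentials. Command voltages carry
#' negligible error, so OLS (not errors-in-variables) is appropriate; the
#' reversal potential is a free parameter of the line.
#'
#' @param points data frame with columns `voltage_mV` and `unitary_pA`
#'   (one row per voltage), or two numeric vectors via `voltage_mV=` /
#'   `unitary_pA=`.
#' @return A [ConductanceFit-class] with gamma in pS (+/- SE) and E_rev in mV.
#' @examples
#' pts <- data.frame(voltage_mV = c(-80, -40, 40), unitary_pA = c(-2, -1, 1))
#' conductanceFit(pts) # 25 pS through 0 mV
#' @export
conductanceFit <- function(points) {
  if (!is.data.frame(points)) stop("points must be a data frame")
  need <- c("voltage_mV", "unitary_pA")
  if (!all(need %in% names(points))) {
    stop("points needs columns voltage_mV and unitary_pA")
  }
  v <- points$voltage_mV
  if (length(unique(v)) < 3L) stop("need >= 3 distinct voltages")
  fit <- stats::lm(unitary_pA ~ voltage_mV, data = points)
  cf <- stats::coef(fit)
  # exact synthetic lines fit perfectly; the SE of 0 is then meaningful
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
    error = function(e) rep(NA_real_, 2)
  )
  slope <- cf[["voltage_mV"]] # pA/mV = nS
  gamma <- slope * 1000 # pS
  gammaSE <- se[["voltage_mV"]] * 1000
  eRev <- -cf[["(Intercept)"]] / slope
  # delta-method SE for -a/b with cov(a, b)
  V <- tryCatch(suppressWarnings(stats::vcov(fit)),
    error = function(e) matrix(NA_real_, 2, 2)
  )
  g <- c(-1 / slope, cf[["(Intercept)"]] / slope^2)
  eRevSE <- sqrt(drop(t(g) %*% V %*% g))
  new("ConductanceFit",
    gammaPS = gamma, gammaSE = gammaSE, eRevMV = eRev, eRevSE = eRevSE,
    points = points[, need]
  )
}

#' Ensemble average of aligned sweeps
#'
#' Pointwise mean across sweeps sharing sampling rate, length and stimulus
#' alignment, baseline-subtracted using the pre-stimulus window of the
#' average. The ensemble of many single-channel sweeps reconstructs the
#' apparent macroscopic current \eqn{N \gamma (V - E_{rev}) P_o(t)}.
#'
#' @param sweepSet a [SweepSet-class] of aligned sweeps.
#' @return A [Sweep-class] holding the baseline-subtracted average;
#'   `annotations$n_sweeps` records the ensemble size.
#' @export
ensembleAverage <- function(sweepSet) {
  sw <- sweeps(sweepSet)
  if (!length(sw)) stop("empty sweep set")
  lens <- vapply(sw, function(s) length(currentPA(s)), integer(1))
  fss <- vapply(sw, fsHz, numeric(1))
  ons <- vapply(sw, stimOnsetMs, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(fss)) != 1L) {
    stop("sweeps must share length and sampling rate")
  }
  if (length(unique(ons)) != 1L) stop("sweeps must be aligned to the same stimulus onset")
  avg <- rowMeans(vapply(sw, currentPA, numeric(lens[1])))
  tmp <- sw[[1]]
  base <- if (!is.na(ons[1]) && ons[1] > 0) {
    mean(avg[sweepTimesMs(tmp) < ons[1]])
  } else {
    0
  }
  newSweep(avg - base,
    fsHz = fss[1], vHoldMV = vHoldMV(tmp),
    stimOnsetMs = ons[1], stimDurationMs = stimDurationMs(tmp),
    stimAmplitude = stimAmplitude(tmp), stimKind = tmp@stimKind,
    id = "ensemble_average",
    annotations = list(n_sweeps = length(sw), baseline_subtracted = TRUE)
  )
}

#' Idealize a sweep against a level model
#'
#' Half-amplitude-style threshold idealization: each sample is assigned to
#' the nearest level, but a transition away from the current level requires
#' the sample to be closer to the new level by a hysteresis margin of 0.25
#' level-spacings, which suppresses noise-driven flicker at the midpoint.
#'
#' @param sweep a [Sweep-class].
#' @param levels a fitted [LevelModel-class].
#' @return Integer vector of per-sample level indices (0 = closed), with
#'   attribute `"flags"` (e.g. `"overlapping_levels"` when spacing < 2 sd).
#' @export
idealizeSweep <- function(sweep, levels) {
  mu <- levels@meansPA
  k <- length(mu)
  flags <- character()
  if (k >= 2L) {
    sp <- abs(diff(mu))
    if (any(sp < 2 * levels@sdsPA[-1])) flags <- c(flags, "overlapping_levels")
  }
  h <- if (k >= 2L) 0.25 * mean(abs(diff(mu))) else 0
  x <- sweep@currentPA
  out <- integer(length(x))
  cur <- 1L
  for (i in seq_along(x)) {
    d <- abs(x[i] - mu)
    best <- which.min(d)
    if (best != cur && d[best] < d[cur] - h) cur <- best
    out[i] <- cur - 1L
  }
  attr(out, "flags") <- flags
  out
}
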