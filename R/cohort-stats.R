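#' @include AllClasses.R
NULL

#' Normalize growth series
#'
#' Normalizes live-cell counts per line. The default anchor divides each
#' line's counts by that line's own day-0 value (so day 0 maps to 1.000
#' exactly); the alternative divides by the mean count of the line's
#' genotype at day 1, a convention some growth-curve figures use. The two
#' anchors answer slightly different questions, so the choice is explicit.
#'
#' @param series data frame with columns `line`, `genotype`, `day`, `count`;
#'   per line, days must be strictly increasing and counts non-negative.
#' @param anchor `"day0_per_line"` (default) or `"day1_per_genotype"`.
#' @return The series with an added `value` column of normalized counts.
#' @examples
#' gs <- data.frame(line = "A", genotype = "WT", day = c(0, 6), count = c(400, 8000))
#' normalizeGrowth(gs)$value # 1, 20
#' @export
normalizeGrowth <- function(series, anchor = c("day0_per_line", "day1_per_genotype")) {
  anchor <- match.arg(anchor)
  need <- c("line", "genotype", "day", "count")
  if (!all(need %in% names(series))) {
    stop("series needs columns line, genotype, day, count")
  }
  if (any(series$count < 0) || any(series$day < 0)) {
    stop("days and counts must be non-negative")
  }
  bad <- vapply(split(series$day, series$line), function(d) is.unsorted(d, strictly = TRUE), logical(1))
  if (any(bad)) stop("days must be strictly increasing within each line")
  out <- series
  if (anchor == "day0_per_line") {
    for (ln in unique(series$line)) {
      sel <- series$line == ln
      d0 <- series$count[sel & series$day == 0]
      if (length(d0) != 1L || d0 <= 0) {
        stop("line ", ln, " has no positive day-0 count to normalize by")
      }
      out$value[sel] <- series$count[sel] / d0
    }
  } else {
    for (g in unique(series$genotype)) {
      sel <- series$genotype == g
      ref <- mean(series$count[sel & series$day == 1])
      if (!is.finite(ref) || ref <= 0) {
        stop("genotype ", g, " has no positive day-1 counts to normalize by")
      }
      out$value[sel] <- series$count[sel] / ref
    }
  }
  out
}

#' Exponential growth-constant fit
#'
#' Nonlinear least-squares fit of \eqn{N(t) = N_0 e^{k t}} to (normalized)
#' counts in natural scale, per line. Natural-scale fitting weights the late,
#' large counts the way published growth-curve R-squared values behave; a
#' log-linear regression of log(count) on day is available as an option.
#'
#' @param series data frame with columns `day` and `value` (normalized
#'   counts), plus optionally `line` (fit per line) and `genotype`.
#' @param logLinear if `TRUE`, fit by linear regression on log(value)
#'   instead (requires positive values).
#' @return Data frame with one row per line: `line`, `genotype` (if
#'   present), `k` (1/day), `n0`, `r2`, `flag`. A constant positive series
#'   returns `k = 0` with flag `"constant_series"`.
#' @examples
#' d <- data.frame(day = c(0, 1, 3, 6), value = exp(0.5 * c(0, 1, 3, 6)))
#' fitExponentialGrowth(d)[, c("k", "r2")] # k = 0.5, r2 = 1
#' @export
fitExponentialGrowth <- function(series, logLinear = FALSE) {
  if (!all(c("day", "value") %in% names(series))) {
    stop("series needs columns day and value")
  }
  if (!"line" %in% names(series)) series$line <- "series"
  fit1 <- function(d) {
    if (nrow(d) < 3L) stop("need >= 3 time points per line")
    gtype <- if ("genotype" %in% names(d)) d$genotype[1] else NA_character_
    if (stats::sd(d$value) == 0) {
      if (d$value[1] == 0) stop("degenerate series: all counts are zero")
      return(data.frame(
        line = d$line[1], genotype = gtype, k = 0, n0 = d$value[1],
        r2 = NA_real_, flag = "constant_series", stringsAsFactors = FALSE
      ))
    }
    if (logLinear) {
      if (any(d$value <= 0)) stop("log-linear fit requires positive values")
      lf <- stats::lm(log(value) ~ day, data = d)
      k <- stats::coef(lf)[["day"]]
      n0 <- exp(stats::coef(lf)[["(Intercept)"]])
      r2 <- suppressWarnings(summary(lf)$r.squared)
    } else {
      # start values from a log-linear pass over the positive points
      pos <- d[d$value > 0, ]
      st <- if (nrow(pos) >= 2L) {
        lf <- stats::lm(log(value) ~ day, data = pos)
        list(n0 = exp(stats::coef(lf)[[1]]), k = stats::coef(lf)[[2]])
      } else {
        list(n0 = max(d$value, 1e-6), k = 0)
      }
      nf <- minpack.lm::nlsLM(value ~ n0 * exp(k * day),
        data = d, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      k <- stats::coef(nf)[["k"]]
      n0 <- stats::coef(nf)[["n0"]]
      r2 <- 1 - sum(stats::residuals(nf)^2) / sum((d$value - mean(d$value))^2)
    }
    data.frame(
      line = d$line[1], genotype = gtype, k = k, n0 = n0, r2 = r2,
      flag = "", stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(series, series$line), fit1))
  rownames(out) <- NULL
  out
}

#' Per-group mean and sample SD
#'
#' Arithmetic mean and n-1 denominator standard deviation per group.
#'
#' @param values numeric measurements (e.g. percent PH3-positive per line).
#' @param group group labels (e.g. genotype), same length as `values`.
#' @return Data frame with columns `group`, `n`, `mean`, `sd` (`sd` is `NA`
#'   when n = 1).
#' @examples
#' groupMeanSD(c(3.487, 2.961, 3.331, 3.268, 3.673),
#'             c("WT", "WT", "KO", "KO", "KO"))
#' @export
groupMeanSD <- function(values, group) {
  if (!length(values)) stop("empty input")
  if (length(values) != length(group)) stop("values and group lengths differ")
  sp <- split(values, factor(group, levels = unique(group)))
  data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-tailed unequal-variance (Welch) two-sample t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' one-tailed p-value. The tail direction is a required argument — it states
#' the alternative hypothesis being tested and is never defaulted.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param direction `"greater"` (alternative: mean(x) > mean(y)) or
#'   `"less"` (alternative: mean(x) < mean(y)).
#' @return A list with `t`, `df`, `p`, `direction` and `flag`. When both
#'   groups have zero variance and equal means the statistic is undefined;
#'   p = 0.5 is returned by convention with flag `"zero_variance"`.
#' @examples
#' welchOneTailed(c(3.487, 2.961), c(3.331, 3.268, 3.673), "less")$p # 0.292
#' @export
welchOneTailed <- function(x, y, direction) {
  if (missing(direction)) stop("tail direction is required (\"greater\" or \"less\")")
  direction <- match.arg(direction, c("greater", "less"))
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(
        t = 0, df = NA_real_, p = 0.5, direction = direction,
        flag = "zero_variance"
      ))
    }
    # means differ with zero spread: the one-tailed p is 0 or 1
    better <- if (direction == "greater") mean(x) > mean(y) else mean(x) < mean(y)
    return(list(
      t = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
      p = if (better) 0 else 1, direction = direction, flag = "zero_variance"
    ))
  }
  ht <- stats::t.test(x, y, alternative = direction, var.equal = FALSE)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, direction = direction, flag = ""
  )
}

#' Percent positive cells
#'
#' @param positive number of positive cells (0 <= positive <= total).
#' @param total total number of cells scored (> 0).
#' @return Percentage, `100 * positive / total`.
#' @examples
#' percentPositive(51, 1473) # about 3.46
#' @export
percentPositive <- function(positive, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(positive < 0) || any(positive > total)) {
    stop("positive must lie in [0, total]")
  }
  100 * positive / total
}
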