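#' @include AllClasses.R
NULL

## 4th-order Bessel analog prototype poles, normalized so |H(j w)| = 1/sqrt(2)
## at w = 1 (the -3 dB point). Standard tabulated values.
.bessel4Poles <- c(
  complex(real = -1.3700678305514334, imaginary = 0.4102497174937738),
  complex(real = -1.3700678305514334, imaginary = -0.4102497174937738),
  complex(real = -0.9952087643502022, imaginary = 1.2571057394546674),
  complex(real = -0.9952087643502022, imaginary = -1.2571057394546674)
)

## polynomial coefficients (descending powers) from roots, forced real
.polyFromRoots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Digital 4-pole Bessel-type low-pass filter coefficients
#'
#' Designs a digital approximation of the analog 4-pole Bessel low-pass used
#' in patch-clamp amplifiers, by bilinear transform of the tabulated
#' frequency-normalized (-3 dB) Bessel prototype with cutoff prewarping.
#' The -3 dB point of the digital filter lands within a few percent of
#' `cutoffHz` for cutoffs well below Nyquist.
#'
#' @param cutoffHz -3 dB cutoff frequency (Hz).
#' @param fsHz sampling rate (Hz); `cutoffHz` must be below `fsHz/2`.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (direct-form, descending powers of z^-1).
#' @seealso [lowpassFilter()]
#' @export
besselLowpassCoef <- function(cutoffHz, fsHz) {
  if (!(cutoffHz > 0 && cutoffHz < fsHz / 2)) {
    stop("cutoff must satisfy 0 < cutoff < fs/2")
  }
  wc <- 2 * fsHz * tan(pi * cutoffHz / fsHz) # prewarped analog cutoff (rad/s)
  pa <- .bessel4Poles * wc
  pz <- (2 * fsHz + pa) / (2 * fsHz - pa) # bilinear transform
  a <- .polyFromRoots(pz)
  b <- .polyFromRoots(rep(-1 + 0i, 4)) # 4 zeros at z = -1
  b <- b * sum(a) / sum(b) # unit DC gain
  list(b = b, a = a)
}

#' Apply the 4-pole Bessel-type low-pass filter to a signal
#'
#' Causal one-pass filtering (as in an acquisition chain), initialized at the
#' first sample value so a non-zero baseline does not produce a startup
#' transient.
#'
#' @param x numeric signal.
#' @param fsHz sampling rate (Hz).
#' @param cutoffHz -3 dB cutoff (Hz).
#' @return Filtered signal, same length as `x`.
#' @examples
#' y <- lowpassFilter(rnorm(2000), fsHz = 20000, cutoffHz = 1000)
#' sd(y) < 1 # noise bandwidth reduced
#' @export
lowpassFilter <- function(x, fsHz, cutoffHz) {
  cf <- besselLowpassCoef(cutoffHz, fsHz)
  x0 <- x[1]
  y <- signal::filter(signal::Arma(b = cf$b, a = cf$a), x - x0)
  as.numeric(y) + x0
}

## magnitude response of the designed digital filter at frequency f (Hz)
.filterGainAt <- function(fHz, fsHz, cutoffHz) {
  cf <- besselLowpassCoef(cutoffHz, fsHz)
  z <- exp(1i * 2 * pi * fHz / fsHz)
  num <- sum(cf$b * z^(-(seq_along(cf$b) - 1)))
  den <- sum(cf$a * z^(-(seq_along(cf$a) - 1)))
  Mod(num / den)
}
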