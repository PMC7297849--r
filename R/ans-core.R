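#' anslope: validity diagnostics for the ratio effect slope
#'
#' The approximate number system (ANS) represents a magnitude n as a
#' Gaussian random variable with mean n and standard deviation w * n,
#' where w is the Weber fraction (smaller w = sharper representation).
#' In a two-alternative number comparison task the difficulty of a pair
#' is driven by the overlap of the two representations, so performance
#' degrades as the ratio (larger/smaller) approaches 1 -- the ratio
#' effect. The slope of the ratio effect across ratios is widely used as
#' a stand-in for w, but the slope--w relation is nonlinear and can be
#' nonmonotonic, which makes the slope an invalid sensitivity index for
#' some combinations of number ratios and population Weber-fraction
#' ranges. This package computes the quantities needed to audit a
#' design: overlap curves, ratio-effect curves, expected slope ranges,
#' direction classification, Monte Carlo correlation attenuation, and
#' parameter recovery for the model-based (sigmoid-fit) estimator.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm rnorm rbinom optimize coef lm dbinom sd quantile cor
#' @importFrom utils write.csv read.csv
NULL

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("anslope_invalid_parameter", "anslope_error")))
}

check_weber <- function(w, allow_zero = FALSE) {
  if (!is.numeric(w) || anyNA(w)) stop_invalid("Weber fraction must be numeric and non-missing")
  if (allow_zero) {
    if (any(w < 0)) stop_invalid("Weber fraction must be >= 0")
  } else if (any(w <= 0)) stop_invalid("Weber fraction must be > 0")
  invisible(w)
}

check_ratio <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio)) stop_invalid("ratio must be numeric and non-missing")
  if (any(ratio < 1)) stop_invalid("ratio must be >= 1 (normalize as larger/smaller)")
  invisible(ratio)
}

#' Normalize a number pair to a comparison ratio
#'
#' The ratio of a to-be-compared pair is defined as the larger number
#' divided by the smaller number, so a ratio is always >= 1.
#'
#' @param a,b Positive magnitudes (vectors recycle element-wise).
#' @return Numeric vector of ratios, each >= 1.
#' @examples
#' as_ratio(6, 4)  # 1.5
#' as_ratio(4, 6)  # 1.5
#' @export
as_ratio <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop_invalid("magnitudes must be positive")
  pmax(a, b) / pmin(a, b)
}

#' Gaussian representations of a compared number pair
#'
#' Under the ANS model the two members of a comparison pair with a given
#' ratio are represented, after normalizing the smaller magnitude to 1,
#' as Gaussians with means (1, ratio) and standard deviations
#' (w, ratio * w): the SD of a magnitude's representation is the Weber
#' fraction times the magnitude (Weber's law).
#'
#' @param ratio Comparison ratio, >= 1.
#' @param w Weber fraction, > 0.
#' @return A list with components `small` and `large`, each a list with
#'   `mean` and `sd`.
#' @examples
#' make_pair_representations(2, 0.1)
#' @export
make_pair_representations <- function(ratio, w) {
  check_ratio(ratio)
  check_weber(w)
  if (length(ratio) != 1L || length(w) != 1L) stop_invalid("ratio and w must be scalars")
  list(
    small = list(mean = 1, sd = w),
    large = list(mean = ratio, sd = ratio * w)
  )
}

#' Overlap of two arbitrary Gaussian densities
#'
#' Computes the integral over the real line of the pointwise minimum of
#' two Gaussian densities, a number in \[0, 1\] (1 iff the densities are
#' identical). For unequal SDs the two densities cross at the two roots
#' of a quadratic (equality of log densities); the overlap is the sum of
#' the appropriate CDF segment masses, which is exact up to `pnorm`
#' accuracy. Equal SDs give a single crossing at the midpoint.
#'
#' @param mean1,sd1,mean2,sd2 Parameters of the two densities; SDs > 0.
#'   All arguments are vectorized and recycle.
#' @return Numeric vector of overlaps in \[0, 1\].
#' @examples
#' gaussian_overlap(0, 1, 0, 1)   # identical: 1
#' gaussian_overlap(0, 1, 2, 1)   # equal-SD crossing at 1
#' @export
gaussian_overlap <- function(mean1, sd1, mean2, sd2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) stop_invalid("standard deviations must be > 0")
  n <- max(length(mean1), length(sd1), length(mean2), length(sd2))
  mean1 <- rep_len(mean1, n); sd1 <- rep_len(sd1, n)
  mean2 <- rep_len(mean2, n); sd2 <- rep_len(sd2, n)
  out <- numeric(n)

  # orient so sd1 <= sd2; the narrower density wins in both tails
  swap <- sd1 > sd2
  if (any(swap)) {
    tm <- mean1[swap]; mean1[swap] <- mean2[swap]; mean2[swap] <- tm
    ts <- sd1[swap]; sd1[swap] <- sd2[swap]; sd2[swap] <- ts
  }

  same_sd <- abs(sd2 - sd1) < 1e-12 * sd2
  if (any(same_sd)) {
    d <- abs(mean2[same_sd] - mean1[same_sd])
    out[same_sd] <- 2 * pnorm(-d / (2 * sd1[same_sd]))
  }

  i <- which(!same_sd)
  if (length(i)) {
    m1 <- mean1[i]; s1 <- sd1[i]; m2 <- mean2[i]; s2 <- sd2[i]
    # log f1(x) = log f2(x)  <=>  A x^2 + B x + C = 0, with s1 < s2 so A > 0
    A <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
    B <- m2 / s2^2 - m1 / s1^2
    C <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - log(s2 / s1)
    disc <- B^2 - 4 * A * C
    disc[disc < 0] <- 0  # roundoff; densities then osculate, segment mass -> 0
    sq <- sqrt(disc)
    x1 <- (-B - sq) / (2 * A)
    x2 <- (-B + sq) / (2 * A)
    # between the roots the wide density f2 is the minimum; outside, f1
    out[i] <- pnorm(x1, m1, s1) + pnorm(x2, m1, s1, lower.tail = FALSE) +
      pnorm(x2, m2, s2) - pnorm(x1, m2, s2)
  }
  pmin(pmax(out, 0), 1)
}

#' Representational overlap for a ratio and a Weber fraction
#'
#' The overlap of the two representations of a comparison pair: the
#' integral of the minimum of the Gaussian densities with means
#' (1, ratio) and SDs (w, ratio * w). This is the model's difficulty
#' index for the pair: 1 at ratio 1 (indistinguishable) and decreasing
#' toward 0 as the ratio grows or the Weber fraction shrinks.
#'
#' The degenerate limit w = 0 (point masses) is defined as 1 if
#' ratio = 1 and 0 otherwise, so Weber-fraction scans may touch zero.
#'
#' @param ratio Comparison ratio(s), >= 1.
#' @param w Weber fraction(s), >= 0. Vectorized with `ratio`.
#' @return Numeric vector of overlaps in \[0, 1\].
#' @examples
#' overlap(1.25, 0.1)
#' overlap(c(1.25, 5), 0.4)
#' @export
overlap <- function(ratio, w) {
  check_ratio(ratio)
  check_weber(w, allow_zero = TRUE)
  n <- max(length(ratio), length(w))
  ratio <- rep_len(ratio, n)
  w <- rep_len(w, n)
  out <- numeric(n)
  unit <- ratio == 1
  out[unit] <- 1
  zero <- w == 0 & !unit
  out[zero] <- 0
  i <- which(!unit & !zero)
  if (length(i)) {
    out[i] <- gaussian_overlap(1, w[i], ratio[i], ratio[i] * w[i])
  }
  out
}

#' Grid-integration oracle for the representational overlap
#'
#' Riemann-sum approximation of the same integral as [overlap()],
#' evaluated on a dense grid spanning +/- 8 SD around both means. It is
#' deliberately independent of the closed-form route and is intended for
#' verification, not production use.
#'
#' @param ratio Comparison ratio, >= 1 (scalar).
#' @param w Weber fraction, > 0 (scalar).
#' @param grid_step Grid spacing in units of the smaller SD; must give
#'   at least 1e4 points across the support.
#' @return Overlap approximation in \[0, 1\].
#' @examples
#' overlap_oracle(1.25, 0.1)
#' @export
overlap_oracle <- function(ratio, w, grid_step = 1e-4) {
  check_ratio(ratio)
  check_weber(w)
  if (length(ratio) != 1L || length(w) != 1L) stop_invalid("ratio and w must be scalars")
  if (grid_step <= 0) stop_invalid("grid_step must be > 0")
  s1 <- w; s2 <- ratio * w
  lo <- min(1 - 8 * s1, ratio - 8 * s2)
  hi <- max(1 + 8 * s1, ratio + 8 * s2)
  step <- grid_step * s1
  if ((hi - lo) / step < 1e4) stop_invalid("grid_step too coarse: fewer than 1e4 points span the support")
  x <- seq(lo, hi, by = step)
  min(sum(pmin(dnorm(x, 1, s1), dnorm(x, ratio, s2))) * step, 1)
}
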