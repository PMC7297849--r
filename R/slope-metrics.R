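#' A ratio pair specification
#'
#' A comparison-task design element: the two number ratios whose
#' difference of representational overlaps defines the ratio effect.
#' Six pairs spanning small, large and mixed ratio regimes are the
#' default analysis set, see [reference_ratio_pairs()].
#'
#' @param r_small,r_large The two ratios, 1 <= r_small < r_large.
#' @return An object of class `ratio_pair`.
#' @examples
#' ratio_pair(1.25, 5)
#' @export
ratio_pair <- function(r_small, r_large) {
  check_ratio(c(r_small, r_large))
  if (length(r_small) != 1L || length(r_large) != 1L) stop_invalid("ratios must be scalars")
  if (r_small >= r_large) {
    stop(errorCondition("invalid ratio pair: need r_small < r_large",
                        class = c("anslope_invalid_pair", "anslope_error")))
  }
  structure(list(r_small = r_small, r_large = r_large), class = "ratio_pair")
}

#' @export
print.ratio_pair <- function(x, ...) {
  cat(sprintf("ratio pair %g-%g\n", x$r_small, x$r_large))
  invisible(x)
}

#' @export
format.ratio_pair <- function(x, ...) sprintf("%g-%g", x$r_small, x$r_large)

as_ratio_pair <- function(pair) {
  if (inherits(pair, "ratio_pair")) return(pair)
  if (is.numeric(pair) && length(pair) == 2L) return(ratio_pair(min(pair), max(pair)))
  stop_invalid("pair must be a ratio_pair or a length-2 numeric vector")
}

#' The six reference ratio pairs
#'
#' The standard analysis set covering small-ratio (steep limb of the
#' overlap-ratio curve), large-ratio (flat limb) and mixed designs:
#' 1.125-1.4, 1.125-2, 1.125-4, 1.5-5, 2-5 and 4-9.
#'
#' @return A named list of [ratio_pair()] objects.
#' @export
reference_ratio_pairs <- function() {
  pairs <- list(
    ratio_pair(1.125, 1.4), ratio_pair(1.125, 2.0), ratio_pair(1.125, 4.0),
    ratio_pair(1.5, 5.0), ratio_pair(2.0, 5.0), ratio_pair(4.0, 9.0)
  )
  names(pairs) <- vapply(pairs, format, character(1))
  pairs
}

#' Ratio effect for a ratio pair
#'
#' The ratio effect of a pair of ratios at a given Weber fraction:
#' overlap at the smaller ratio minus overlap at the larger ratio.
#' Because overlap is non-increasing in ratio the effect lies in
#' \[0, 1\]; it is the two-point version of the ratio effect slope
#' (up to the sign/scale identity documented in [linear_slope()]).
#'
#' @param pair A [ratio_pair()] or length-2 numeric vector.
#' @param w Weber fraction(s), > 0 (vectorized).
#' @return Numeric vector of effects in \[0, 1\].
#' @examples
#' ratio_effect(ratio_pair(1.25, 5), 0.4)
#' @export
ratio_effect <- function(pair, w) {
  pair <- as_ratio_pair(pair)
  check_weber(w, allow_zero = TRUE)
  pmax(overlap(pair$r_small, w) - overlap(pair$r_large, w), 0)
}

#' Least-squares ratio effect slope over a ratio list
#'
#' Ordinary-least-squares slope of representational overlap regressed
#' on ratio, across a list of ratios at a fixed Weber fraction -- the
#' multi-ratio generalization of the two-point ratio effect. For
#' exactly two ratios the slope equals
#' `-ratio_effect(pair, w) / (r_large - r_small)`: overlap falls with
#' ratio, so the fitted slope is the negated, ratio-scaled effect.
#'
#' @param ratios Numeric vector of >= 2 distinct ratios, each >= 1.
#' @param w Weber fraction, > 0 (scalar).
#' @return The OLS slope (a scalar, typically negative).
#' @examples
#' linear_slope(c(1.25, 5), 0.4)
#' linear_slope(c(1.125, 1.4, 2, 4), 0.2)
#' @export
linear_slope <- function(ratios, w) {
  check_ratio(ratios)
  check_weber(w)
  if (length(w) != 1L) stop_invalid("w must be a scalar")
  ratios <- unique(ratios)
  if (length(ratios) < 2L) {
    stop(errorCondition("need at least 2 distinct ratios for a slope",
                        class = c("anslope_invalid_input", "anslope_error")))
  }
  o <- overlap(ratios, w)
  sum((ratios - mean(ratios)) * (o - mean(o))) / sum((ratios - mean(ratios))^2)
}

#' Ratio-effect curve over a Weber-fraction grid
#'
#' Evaluates [ratio_effect()] element-wise over an increasing grid of
#' Weber fractions, giving the curve whose shape (monotonic or
#' rise-then-fall) decides whether the slope can index sensitivity.
#'
#' @param pair A [ratio_pair()] or length-2 numeric vector.
#' @param w_grid Strictly increasing vector of positive Weber fractions.
#' @return A data frame of class `slope_curve` with columns `w` and
#'   `ratio_effect`.
#' @examples
#' sc <- slope_curve(ratio_pair(1.25, 5), seq(0.04, 1, by = 0.01))
#' head(sc)
#' @export
slope_curve <- function(pair, w_grid) {
  pair <- as_ratio_pair(pair)
  check_weber(w_grid)
  if (length(w_grid) < 1L) stop_invalid("w_grid must be non-empty")
  if (length(w_grid) > 1L && any(diff(w_grid) <= 0)) stop_invalid("w_grid must be strictly increasing")
  structure(
    data.frame(w = w_grid, ratio_effect = ratio_effect(pair, w_grid)),
    class = c("slope_curve", "data.frame"),
    pair = pair
  )
}

weber_grid <- function(w_lo, w_hi, grid_step) {
  if (!is.numeric(w_lo) || !is.numeric(w_hi) || w_lo <= 0 || w_hi < w_lo) {
    stop(errorCondition("invalid Weber-fraction interval: need 0 < w_lo <= w_hi",
                        class = c("anslope_invalid_interval", "anslope_error")))
  }
  if (grid_step <= 0) stop_invalid("grid_step must be > 0")
  g <- seq(w_lo, w_hi, by = grid_step)
  if (g[length(g)] < w_hi) g <- c(g, w_hi)
  g
}

#' Expected range of the ratio effect over a Weber-fraction interval
#'
#' The minimum, maximum and range of the ratio effect over a dense grid
#' on a Weber-fraction interval. Because both overlaps and their
#' difference live in \[0, 1\], the range is a standardized index of the
#' slope variability a sample spanning that interval can show; small
#' range means poor signal-to-noise for the slope as an individual-
#' differences measure.
#'
#' @param pair A [ratio_pair()] or length-2 numeric vector.
#' @param w_lo,w_hi Interval bounds, 0 < w_lo <= w_hi.
#' @param grid_step Grid spacing on w (default 1e-3).
#' @return A list of class `slope_range` with elements `min_effect`,
#'   `max_effect`, `range`, `w_at_min`, `w_at_max`.
#' @examples
#' expected_range(ratio_pair(1.25, 5), 0.1, 0.4)
#' @export
expected_range <- function(pair, w_lo, w_hi, grid_step = 1e-3) {
  pair <- as_ratio_pair(pair)
  g <- weber_grid(w_lo, w_hi, grid_step)
  eff <- ratio_effect(pair, g)
  i_min <- which.min(eff); i_max <- which.max(eff)
  structure(list(
    pair = pair, w_lo = w_lo, w_hi = w_hi,
    min_effect = eff[i_min], max_effect = eff[i_max],
    range = eff[i_max] - eff[i_min],
    w_at_min = g[i_min], w_at_max = g[i_max]
  ), class = "slope_range")
}

#' @export
print.slope_range <- function(x, ...) {
  cat(sprintf("ratio pair %s on w in [%g, %g]: effect in [%.3f, %.3f], range %.3f\n",
              format(x$pair), x$w_lo, x$w_hi, x$min_effect, x$max_effect, x$range))
  invisible(x)
}

#' Direction of the slope-sensitivity relation over a Weber interval
#'
#' Classifies the relation between the Weber fraction and the ratio
#' effect over an interval as mostly negative, mostly positive, or
#' mixed, from the signs of successive finite differences of the
#' effect curve on a dense grid. Steps smaller than `step_tol` in
#' absolute value count as neither sign. A mixed label means the slope
#' is uninterpretable as a sensitivity index on that interval.
#'
#' @param pair A [ratio_pair()] or length-2 numeric vector.
#' @param w_lo,w_hi Interval bounds, 0 < w_lo < w_hi.
#' @param grid_step Grid spacing on w (default 1e-3).
#' @param neg_threshold Fraction of negative steps at or above which the
#'   label is "negative" (default 0.8).
#' @param pos_threshold Fraction at or below which it is "positive"
#'   (default 0.2).
#' @param step_tol Absolute step size below which a step is ignored.
#' @param weight_fun Optional function giving a nonnegative weight to
#'   each step, evaluated at the step midpoints on w. With the default
#'   (NULL) all steps weigh equally, i.e. "mostly" is read over the
#'   interval; passing a population density reads it over a population
#'   (see [run_audit()]).
#' @return A list of class `direction_class` with `label` (one of
#'   "negative", "positive", "mixed"), `fraction_negative_steps` (the
#'   weighted fraction of signed steps that are negative), and the step
#'   counts.
#' @examples
#' classify_direction(ratio_pair(1.125, 1.4), 0.04, 1)
#' classify_direction(ratio_pair(4, 9), 0.04, 1)
#' @export
classify_direction <- function(pair, w_lo, w_hi, grid_step = 1e-3,
                               neg_threshold = 0.8, pos_threshold = 0.2,
                               step_tol = 1e-6, weight_fun = NULL) {
  pair <- as_ratio_pair(pair)
  g <- weber_grid(w_lo, w_hi, grid_step)
  if (length(g) < 2L) {
    stop(errorCondition("interval too narrow for direction classification",
                        class = c("anslope_invalid_interval", "anslope_error")))
  }
  steps <- diff(ratio_effect(pair, g))
  wts <- if (is.null(weight_fun)) rep(1, length(steps))
  else weight_fun((g[-1] + g[-length(g)]) / 2)
  if (any(wts < 0) || anyNA(wts)) stop_invalid("step weights must be nonnegative")
  neg <- steps < -step_tol
  pos <- steps > step_tol
  n_neg <- sum(neg)
  n_pos <- sum(pos)
  signed_mass <- sum(wts[neg]) + sum(wts[pos])
  frac_neg <- if (signed_mass == 0) 0 else sum(wts[neg]) / signed_mass
  label <- if (signed_mass == 0) "positive"  # flat curve: no reversal
  else if (frac_neg >= neg_threshold) "negative"
  else if (frac_neg <= pos_threshold) "positive"
  else "mixed"
  structure(list(
    pair = pair, w_lo = w_lo, w_hi = w_hi, label = label,
    fraction_negative_steps = frac_neg, n_negative = n_neg, n_positive = n_pos
  ), class = "direction_class")
}

#' @export
print.direction_class <- function(x, ...) {
  cat(sprintf("ratio pair %s on w in [%g, %g]: %s (%.1f%% of signed steps negative)\n",
              format(x$pair), x$w_lo, x$w_hi, x$label, 100 * x$fraction_negative_steps))
  invisible(x)
}

#' Expected-range table across ratio pairs and Weber intervals
#'
#' Tabulates [expected_range()] for every combination of a list of
#' ratio pairs and a list of Weber-fraction intervals (rows = pairs,
#' one row per pair-interval combination).
#'
#' @param pairs List of [ratio_pair()] objects (default
#'   [reference_ratio_pairs()]).
#' @param intervals List of length-2 numeric intervals on w. Defaults to
#'   the adult (0.03-0.31) and adolescent (0.087-0.471) population
#'   intervals plus the full 0.04-1 scan range.
#' @param grid_step Grid spacing on w.
#' @return A data frame with columns `ratio_pair`, `w_lo`, `w_hi`,
#'   `min_effect`, `max_effect`, `range`.
#' @examples
#' slope_range_table(intervals = list(c(0.1, 0.4)))
#' @export
slope_range_table <- function(pairs = reference_ratio_pairs(),
                              intervals = list(adult = c(0.03, 0.31),
                                               adolescent = c(0.087, 0.471),
                                               full = c(0.04, 1.0)),
                              grid_step = 1e-3) {
  rows <- list()
  for (p in pairs) {
    for (iv in intervals) {
      sr <- expected_range(p, iv[1], iv[2], grid_step)
      rows[[length(rows) + 1L]] <- data.frame(
        ratio_pair = format(p), w_lo = iv[1], w_hi = iv[2],
        min_effect = sr$min_effect, max_effect = sr$max_effect, range = sr$range
      )
    }
  }
  do.call(rbind, rows)
}
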