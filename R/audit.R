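#' Audit a comparison-task design for ratio-effect-slope validity
#'
#' Composes the diagnostics into a single design verdict. A design is a
#' ratio pair plus either an expected Weber-fraction interval or a
#' population distribution (in which case the mean +/- 2 SD interval is
#' used and a correlation simulation is added). The rules:
#'
#' With an interval only, the verdict is driven by the direction
#' classification:
#'
#' * direction "mixed" on the interval: `not-recommended` -- the slope
#'   cannot be interpreted as a sensitivity index at all;
#' * expected slope range below `range_floor`: `not-recommended` -- too
#'   little variability for an individual-differences measure;
#' * otherwise, direction "positive" (effect grows with w, the
#'   conventional reading of the slope): `recommended`;
#' * direction "negative": `usable-with-reversed-sign` -- the slope is
#'   monotonic in w but its sign convention is inverted relative to the
#'   rising-limb expectation.
#'
#' With a population distribution, the audit runs the Monte Carlo
#' correlation simulation and judges usability the way a correlational
#' study experiences it: a usable design shows enough slope variability
#' (`range_floor`) together with a large-magnitude, low-spread
#' correlation between the slope and the (perfectly valid) criterion --
#' `|mean r| >= cor_floor` and `sd(r) <= cor_sd_cap`. The sign of the
#' mean correlation decides between `recommended` and
#' `usable-with-reversed-sign`. The direction classification is still
#' reported (weighted by the population density, so a reversal confined
#' to a thin tail does not dominate the label), but a strong, stable
#' correlation over the population can rescue a design whose interval-
#' wide direction is formally mixed.
#'
#' @param pair A [ratio_pair()] or length-2 numeric vector.
#' @param w_interval Length-2 numeric Weber-fraction interval, or NULL
#'   if `dist` is given.
#' @param dist Optional [weber_distribution()]; enables the correlation
#'   summary and supplies the interval when `w_interval` is NULL.
#' @param grid_step Grid spacing on w for the diagnostics.
#' @param range_floor Minimum acceptable expected slope range on the
#'   standardized \[0, 1\] index (default 0.1).
#' @param cor_floor Minimum acceptable |mean r| in population mode
#'   (default 0.6).
#' @param cor_sd_cap Maximum acceptable sd of r in population mode
#'   (default 0.25).
#' @param n_participants,n_replications,seed Correlation-simulation
#'   settings (used only when `dist` is given).
#' @return A list of class `audit_report` with `pair`, `w_interval`,
#'   `direction`, `slope_range`, `correlation` (or NULL) and `verdict`.
#' @examples
#' run_audit(ratio_pair(1.125, 4), c(0.04, 1))   # mixed: not recommended
#' run_audit(ratio_pair(4, 9), c(0.04, 1))       # positive: recommended
#' @export
run_audit <- function(pair, w_interval = NULL, dist = NULL, grid_step = 1e-3,
                      range_floor = 0.1, cor_floor = 0.6, cor_sd_cap = 0.25,
                      n_participants = 50, n_replications = 1000, seed = 1) {
  pair <- as_ratio_pair(pair)
  bad <- character(0)
  if (is.null(w_interval) && is.null(dist)) bad <- c(bad, "w_interval/dist")
  if (!is.null(w_interval) &&
      (!is.numeric(w_interval) || length(w_interval) != 2L ||
       w_interval[1] <= 0 || w_interval[2] <= w_interval[1])) {
    bad <- c(bad, "w_interval")
  }
  if (!is.null(dist) && !inherits(dist, "weber_distribution")) bad <- c(bad, "dist")
  if (length(bad)) {
    stop(errorCondition(paste("invalid audit configuration field(s):",
                              paste(bad, collapse = ", ")),
                        class = c("anslope_invalid_config", "anslope_error")))
  }
  if (is.null(w_interval)) {
    w_interval <- population_interval(dist)
    w_interval[1] <- max(w_interval[1], dist$floor)
  }

  weight_fun <- if (!is.null(dist)) function(w) dnorm(w, dist$mean, dist$sd)
  direction <- classify_direction(pair, w_interval[1], w_interval[2], grid_step,
                                  weight_fun = weight_fun)
  slope_range <- expected_range(pair, w_interval[1], w_interval[2], grid_step)
  correlation <- if (!is.null(dist)) {
    simulate_correlations(dist, pair, n_participants, n_replications, seed)
  }

  verdict <- if (slope_range$range < range_floor) {
    "not-recommended"
  } else if (is.null(correlation)) {
    switch(direction$label,
           mixed = "not-recommended",
           positive = "recommended",
           negative = "usable-with-reversed-sign")
  } else {
    m <- correlation$summary$mean
    s <- correlation$summary$sd
    if (!is.finite(m) || !is.finite(s) || abs(m) < cor_floor || s > cor_sd_cap) {
      "not-recommended"
    } else if (m > 0) "recommended" else "usable-with-reversed-sign"
  }

  structure(list(
    pair = pair, w_interval = w_interval, direction = direction,
    slope_range = slope_range, correlation = correlation,
    range_floor = range_floor, cor_floor = cor_floor, cor_sd_cap = cor_sd_cap,
    verdict = verdict
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("Design audit: ratio pair %s, expected w in [%g, %g]\n",
              format(x$pair), x$w_interval[1], x$w_interval[2]))
  cat(sprintf("  direction: %s (%.1f%% of signed steps negative)\n",
              x$direction$label, 100 * x$direction$fraction_negative_steps))
  cat(sprintf("  expected slope range: %.3f (floor %.2f)\n",
              x$slope_range$range, x$range_floor))
  if (!is.null(x$correlation)) {
    cat(sprintf("  simulated slope-criterion correlation: mean r = %.3f (sd %.3f)\n",
                x$correlation$summary$mean, x$correlation$summary$sd))
  }
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

audit_report_as_list <- function(x) {
  list(
    ratio_pair = format(x$pair),
    w_interval = x$w_interval,
    direction = x$direction$label,
    fraction_negative_steps = x$direction$fraction_negative_steps,
    slope_range = list(min = x$slope_range$min_effect,
                       max = x$slope_range$max_effect,
                       range = x$slope_range$range),
    correlation = if (!is.null(x$correlation)) list(
      mean_r = x$correlation$summary$mean,
      sd_r = x$correlation$summary$sd,
      n_replications = x$correlation$n_replications,
      n_dropped = x$correlation$n_dropped
    ),
    range_floor = x$range_floor,
    verdict = x$verdict
  )
}

#' Reproduce the full diagnostic analysis set
#'
#' Writes the standard analysis products to a directory: one ratio-
#' effect curve CSV per reference ratio pair (columns `w`,
#' `ratio_effect`), the expected-range table CSV, one correlation-
#' distribution CSV per cell of the standard 3 x 2 design grid
#' (columns `dist_label`, `pair`, `replication`, `r`), a direction-
#' classification report, and a JSON manifest recording every
#' parameter and seed needed to regenerate the files.
#'
#' @param outdir Output directory (created if needed).
#' @param n_replications Correlation replications per cell (default
#'   10000, the full study scale; scale down for quick runs).
#' @param n_participants Participants per correlation sample.
#' @param seed Integer root seed.
#' @param grid_step Grid spacing on w for curves, ranges and
#'   classification.
#' @param w_range Weber-fraction scan range for the curves (default
#'   0.04 to 1).
#' @return Invisibly, a character vector of the files written.
#' @export
reproduce_analysis <- function(outdir, n_replications = 10000,
                               n_participants = 50, seed = 1,
                               grid_step = 1e-3, w_range = c(0.04, 1.0)) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(errorCondition(paste("cannot create output directory:", outdir),
                                 class = c("anslope_io_error", "anslope_error")))
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  pairs <- reference_ratio_pairs()
  wg <- weber_grid(w_range[1], w_range[2], grid_step)
  for (p in pairs) {
    emit(slope_curve(p, wg),
         sprintf("slope_curve_%s.csv", gsub("[^0-9A-Za-z.]+", "_", format(p))))
  }

  emit(slope_range_table(pairs, grid_step = grid_step), "slope_range_table.csv")

  dir_rows <- lapply(pairs, function(p) {
    d <- classify_direction(p, w_range[1], w_range[2], grid_step)
    data.frame(ratio_pair = format(p), label = d$label,
               fraction_negative_steps = d$fraction_negative_steps)
  })
  emit(do.call(rbind, dir_rows), "direction_classification.csv")

  grid <- correlation_grid(n_participants, n_replications, seed)
  for (nm in names(grid$cells)) {
    cd <- grid$cells[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    emit(data.frame(dist_label = parts[1], pair = parts[2],
                    replication = seq_along(cd$r_values), r = cd$r_values),
         sprintf("correlations_%s_%s.csv", parts[1],
                 gsub("[^0-9A-Za-z.]+", "_", parts[2])))
  }
  emit(grid$summary, "correlation_summary.csv")

  manifest <- list(
    package = "anslope",
    seed = as.integer(seed),
    n_replications = as.integer(n_replications),
    n_participants = as.integer(n_participants),
    grid_step = grid_step,
    w_range = w_range,
    ratio_pairs = vapply(pairs, format, character(1)),
    correlation_pairs = c("1.125-2", "1.25-2", "2-5"),
    populations = list(
      adult = unclass(typical_weber_population("adult")),
      adolescent = unclass(typical_weber_population("adolescent"))
    ),
    files = basename(files)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}
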