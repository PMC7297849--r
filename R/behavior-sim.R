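#' Predicted error rate in a comparison trial
#'
#' Maps the representational overlap onto two-alternative comparison
#' performance via the equal-prior optimal observer: the probability of
#' choosing the wrong side is half the overlap (the mass of the losing
#' density beyond the optimal decision boundary), so the error rate is
#' `overlap(ratio, w) / 2`, in \[0, 0.5\]. This behavioral link is a
#' modeling choice of this package -- the generator and the estimator
#' share it, which is what makes parameter recovery well posed.
#'
#' @param ratio Comparison ratio(s), >= 1.
#' @param w Weber fraction(s), >= 0 (vectorized).
#' @return Error probabilities in \[0, 0.5\].
#' @examples
#' error_rate(1.25, 0.1)
#' error_rate(1, 0.3)  # indistinguishable: chance, 0.5
#' @export
error_rate <- function(ratio, w) {
  overlap(ratio, w) / 2
}

#' Simulate comparison-task trials
#'
#' Generates synthetic two-alternative number-comparison data for one
#' participant with a known Weber fraction: for each ratio, the error
#' count is binomial with `trials_per_ratio` trials and success
#' probability [error_rate()].
#'
#' @param w Weber fraction (>= 0; 0 gives errorless data).
#' @param ratios Distinct ratios, each >= 1.
#' @param trials_per_ratio Trials per ratio (>= 1).
#' @param seed Optional integer seed; if NULL the current RNG state is
#'   used.
#' @return A data frame of class `trial_set` with columns `ratio`,
#'   `n_trials`, `n_errors`.
#' @examples
#' simulate_trials(0.2, c(1.1, 1.3, 1.6, 2), 100, seed = 1)
#' @export
simulate_trials <- function(w, ratios, trials_per_ratio, seed = NULL) {
  check_weber(w, allow_zero = TRUE)
  check_ratio(ratios)
  if (anyDuplicated(ratios)) stop_invalid("ratios must be distinct")
  if (!is.numeric(trials_per_ratio) || trials_per_ratio < 1) {
    stop_invalid("trials_per_ratio must be >= 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(trials_per_ratio)
  p <- error_rate(ratios, w)
  structure(
    data.frame(ratio = ratios, n_trials = n, n_errors = rbinom(length(ratios), n, p)),
    class = c("trial_set", "data.frame")
  )
}

trial_log_lik <- function(w, trials) {
  p <- error_rate(trials$ratio, w)
  p <- pmin(pmax(p, 1e-12), 0.5)
  sum(dbinom(trials$n_errors, trials$n_trials, p, log = TRUE))
}

#' Estimate the Weber fraction from comparison-task data
#'
#' The model-based ("sigmoid fit") estimator: maximum-likelihood
#' estimation of w under the binomial model in which the per-ratio
#' error probability is the model-predicted accuracy curve
#' [error_rate()]. A one-dimensional bounded search maximizes the
#' binomial log-likelihood on `[lower, upper]`.
#'
#' Degenerate data -- no errors anywhere, or error rates at chance for
#' every ratio -- pin the optimum to a boundary; the estimate is then
#' returned with `converged = FALSE` rather than raising an error.
#'
#' @param trials A `trial_set` data frame (columns `ratio`, `n_trials`,
#'   `n_errors`), e.g. from [simulate_trials()] or [read_trials_csv()].
#' @param lower,upper Search bracket for w (defaults 1e-3 and 2).
#' @param tol Convergence tolerance on w (default 1e-6).
#' @return A list of class `weber_estimate`: `w_hat`, `log_lik`,
#'   `converged`.
#' @examples
#' tr <- simulate_trials(0.2, exp(seq(log(1.1), log(3), length.out = 8)), 500, seed = 1)
#' estimate_weber(tr)
#' @export
estimate_weber <- function(trials, lower = 1e-3, upper = 2, tol = 1e-6) {
  if (!is.data.frame(trials) ||
      !all(c("ratio", "n_trials", "n_errors") %in% names(trials))) {
    stop_invalid("trials must be a data frame with columns ratio, n_trials, n_errors")
  }
  if (any(trials$n_errors < 0) || any(trials$n_errors > trials$n_trials)) {
    stop_invalid("n_errors must lie in [0, n_trials]")
  }
  tr <- trials[trials$n_trials >= 1, , drop = FALSE]
  if (length(unique(tr$ratio)) < 2L) {
    stop(errorCondition("need at least 2 distinct ratios with trials",
                        class = c("anslope_invalid_input", "anslope_error")))
  }
  if (sum(tr$n_errors) == 0L) {
    # errorless data: the likelihood is flat wherever predicted rates
    # vanish, so w is only bounded from above -- report the bracket edge
    return(structure(list(w_hat = lower, log_lik = trial_log_lik(lower, tr),
                          converged = FALSE),
                     class = "weber_estimate"))
  }
  opt <- optimize(trial_log_lik, c(lower, upper), trials = tr,
                  maximum = TRUE, tol = tol)
  w_hat <- opt$maximum
  at_boundary <- (w_hat - lower) < 10 * tol || (upper - w_hat) < 10 * tol
  # boundary cases: likelihood still improving at the bracket edge,
  # i.e. the data do not pin down w inside the bracket
  converged <- !at_boundary
  structure(list(w_hat = w_hat, log_lik = opt$objective, converged = converged),
            class = "weber_estimate")
}

#' @export
print.weber_estimate <- function(x, ...) {
  cat(sprintf("Weber fraction estimate: w_hat = %.4f (log-lik %.2f%s)\n",
              x$w_hat, x$log_lik, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Write a trial set to CSV
#'
#' @param trials A `trial_set` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials[, c("ratio", "n_trials", "n_errors")], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial set from CSV
#'
#' @param path CSV file with columns `ratio`, `n_trials`, `n_errors`.
#' @return A `trial_set` data frame.
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path)
  need <- c("ratio", "n_trials", "n_errors")
  if (!all(need %in% names(df))) {
    stop_invalid(paste("trial CSV must have columns:", paste(need, collapse = ", ")))
  }
  structure(df[, need], class = c("trial_set", "data.frame"))
}
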