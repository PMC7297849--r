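# shared (ratio, w) lattice for property tests
lattice_ratios <- c(1.05, 1.125, 1.25, 1.5, 2, 3, 5, 9)
lattice_webers <- c(0.04, 0.1, 0.2, 0.4, 0.7, 1.0)

log_spaced_ratios <- function(n = 8, lo = 1.1, hi = 3) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# expected error counts rounded to nearest integer at a huge trial count;
# used for noiseless round-trip tests of the estimator
noiseless_trials <- function(w, ratios = log_spaced_ratios(), n = 1e6) {
  structure(
    data.frame(ratio = ratios, n_trials = n,
               n_errors = round(n * error_rate(ratios, w))),
    class = c("trial_set", "data.frame")
  )
}
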