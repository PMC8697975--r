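# Shared fixtures and independent oracles for the test suite.

# textbook one-way ANOVA F through R's linear-model machinery; used as the
# independent cross-check for the package's own between/within computation
oracle_anova_f <- function(samples) {
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  stats::anova(stats::lm(y ~ g))[["F value"]][1]
}

# upper-tail F quantile via numerical inversion of the regularized
# incomplete beta function (P(F > q) = I_{d2/(d2 + d1 q)}(d2/2, d1/2)),
# independent of qf()
oracle_critical_f <- function(alpha, d1, d2) {
  tail_p <- function(q) stats::pbeta(d2 / (d2 + d1 * q), d2 / 2, d1 / 2)
  stats::uniroot(function(q) tail_p(q) - alpha, c(1e-8, 1e8),
                 tol = 1e-12)$root
}

# minimal hand-built trial-wise TFR container for unit tests
make_tfr_set <- function(power, freqs = NULL, time_axis = NULL,
                         labels = NULL, fs = 1) {
  d <- dim(power)
  stopifnot(length(d) == 4L)
  lev <- sort(unique(labels %||% rep("a", d[1])))
  structure(list(
    power = power,
    freqs = freqs %||% as.numeric(seq_len(d[3])),
    time_axis = time_axis %||% (as.numeric(seq_len(d[4]) - 1L) / fs),
    fs = fs, labels = labels %||% rep("a", d[1]), condition_levels = lev,
    channel_labels = paste0("ch", seq_len(d[2])), montage = NULL,
    baseline_mode = "none", baseline_interval = NULL,
    wavelet = list(n_cycles = 7, output = "power"),
    coi = matrix(FALSE, d[3], d[4])),
    class = "tfr_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small grouped-trials object from explicit index lists
make_groups <- function(...) {
  structure(list(...), class = "grouped_trials")
}

# single-channel recording holding the values 0..(n-1)
ramp_recording <- function(n = 100, fs = 10) {
  recording(matrix(0:(n - 1), nrow = 1), fs, channel_labels = "ch1")
}
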