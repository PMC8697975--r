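#' Complex Morlet wavelet kernel
#'
#' A Gaussian-windowed complex exponential at `freq_hz`, sampled at `fs`,
#' normalized to unit energy (sum of squared magnitudes = 1). The temporal
#' SD is `sigma_t = n_cycles / (2 * pi * freq_hz)`; the discrete kernel has
#' odd length and covers +/- 5 SD.
#'
#' @param freq_hz center frequency (Hz), `0 < freq_hz < fs/2`.
#' @param fs sampling rate (Hz).
#' @param n_cycles number of cycles of the wavelet (dimensionless, > 0);
#'   default 7, a common neuroscience setting.
#' @return complex vector of odd length with attributes `freq_hz` and
#'   `sigma_t` (seconds).
#' @export
morlet_kernel <- function(freq_hz, fs, n_cycles = 7) {
  if (!is.numeric(freq_hz) || length(freq_hz) != 1L || freq_hz <= 0)
    stop_ftfa("freq_hz must be a positive scalar", class = "ftfa_frequency_error")
  if (freq_hz >= fs / 2)
    stop_ftfa(sprintf("freq_hz (%g) must be below Nyquist (%g)", freq_hz, fs / 2),
              class = "ftfa_frequency_error")
  if (!is.numeric(n_cycles) || n_cycles <= 0)
    stop_ftfa("n_cycles must be > 0", class = "ftfa_argument_error")
  sigma_t <- n_cycles / (2 * pi * freq_hz)
  half <- ceiling(5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq_hz * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  attr(w, "freq_hz") <- freq_hz
  attr(w, "sigma_t") <- sigma_t
  w
}

# FFT-based centered same-length convolution of one real signal with a bank
# of precomputed kernel spectra. kern_fft: nfft x nfreq; half_len: kernel
# half-lengths per frequency. Returns nfreq x n complex matrix.
cwt_bank <- function(x, kern_fft, half_len, nfft) {
  n <- length(x)
  X <- fft(c(x, rep(0, nfft - n)))
  conv <- stats::mvfft(kern_fft * X, inverse = TRUE) / nfft
  out <- matrix(0i, nrow = ncol(kern_fft), ncol = n)
  for (k in seq_len(ncol(kern_fft))) {
    idx <- (half_len[k] + 1L):(half_len[k] + n)
    # wrap-around safe: nfft >= n + kernel length - 1 by construction
    out[k, ] <- conv[idx, k]
  }
  out
}

prepare_kernel_bank <- function(freqs, fs, n_cycles, n) {
  kerns <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles)
  klen <- vapply(kerns, length, 1L)
  nfft <- nextn(n + max(klen) - 1L)
  kern_fft <- vapply(kerns, function(w)
    fft(c(as.complex(w), rep(0i, nfft - length(w)))), complex(nfft))
  list(kern_fft = kern_fft, half_len = (klen - 1L) %/% 2L, nfft = nfft,
       sigma_t = vapply(kerns, attr, numeric(1), which = "sigma_t"))
}

#' Wavelet power of a single signal
#'
#' Continuous wavelet transform of a 1-D signal with complex Morlet kernels
#' at the requested frequencies, returning per-frequency power over time.
#' Convolution is same-length with zero padding, so kernels may be longer
#' than the signal at low frequencies; edge samples inside the cone of
#' influence of a kernel are attenuated and should be interpreted with care
#' (see [coi_mask()]).
#'
#' @param x numeric vector (one channel of one trial, microvolts).
#' @param freqs numeric vector of analysis frequencies (Hz, ascending).
#' @param fs sampling rate (Hz).
#' @param n_cycles wavelet cycles (see [morlet_kernel()]).
#' @param output `"power"` for squared magnitude (default, microvolts^2 per
#'   unit-energy kernel) or `"magnitude"` for plain modulus.
#' @return numeric matrix, `length(freqs)` x `length(x)`.
#' @export
cwt_power <- function(x, freqs, fs, n_cycles = 7,
                      output = c("power", "magnitude")) {
  output <- match.arg(output)
  if (length(freqs) < 1L)
    stop_ftfa("freqs must be non-empty", class = "ftfa_argument_error")
  if (any(diff(freqs) <= 0))
    stop_ftfa("freqs must be strictly increasing", class = "ftfa_argument_error")
  bank <- prepare_kernel_bank(freqs, fs, n_cycles, length(x))
  w <- cwt_bank(as.numeric(x), bank$kern_fft, bank$half_len, bank$nfft)
  m <- Mod(w)
  if (output == "power") m <- m^2
  dimnames(m) <- NULL
  m
}

#' Cone-of-influence mask for a wavelet frequency grid
#'
#' Marks, for each frequency, the time samples lying within 5 temporal SDs
#' of either epoch edge, where zero padding attenuates wavelet power.
#'
#' @param freqs analysis frequencies (Hz).
#' @param n_times number of time samples.
#' @param fs sampling rate (Hz).
#' @param n_cycles wavelet cycles.
#' @return logical matrix freqs x times, `TRUE` where the estimate is
#'   edge-contaminated.
#' @export
coi_mask <- function(freqs, n_times, fs, n_cycles = 7) {
  half <- ceiling(5 * n_cycles / (2 * pi * freqs) * fs)
  m <- matrix(FALSE, length(freqs), n_times)
  for (k in seq_along(freqs)) {
    b <- min(half[k], n_times)
    m[k, seq_len(b)] <- TRUE
    m[k, (n_times - b + 1L):n_times] <- TRUE
  }
  m
}

#' Trial-wise time-frequency power of an epoch set
#'
#' Computes wavelet power independently for every trial and channel,
#' yielding the trials x channels x freqs x times tensor whose per-pixel
#' values enter the F-statistic.
#'
#' @param epochs an `epoch_set` from [epoch_extract()].
#' @param freqs analysis frequencies (Hz, ascending); default 1-100 Hz in
#'   1 Hz steps.
#' @param n_cycles wavelet cycles (default 7).
#' @param output `"power"` (squared magnitude, default) or `"magnitude"`.
#' @return an object of class `tfr_set`: `power` (trials x channels x freqs
#'   x times), `freqs`, `time_axis`, `fs`, `labels`, `channel_labels`,
#'   `baseline_mode` (`"none"`), `coi` (freqs x times logical), and the
#'   wavelet parameters.
#' @export
tfr_compute <- function(epochs, freqs = 1:100, n_cycles = 7,
                        output = c("power", "magnitude")) {
  output <- match.arg(output)
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(freqs) < 1L)
    stop_ftfa("freqs must be non-empty", class = "ftfa_argument_error")
  if (any(diff(freqs) <= 0))
    stop_ftfa("freqs must be strictly increasing", class = "ftfa_argument_error")
  if (any(freqs >= epochs$fs / 2))
    stop_ftfa("all freqs must be below Nyquist", class = "ftfa_frequency_error")
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]; n_t <- d[3]
  bank <- prepare_kernel_bank(freqs, epochs$fs, n_cycles, n_t)
  power <- array(NA_real_, dim = c(n_trials, n_ch, length(freqs), n_t))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      w <- cwt_bank(epochs$data[tr, ch, ], bank$kern_fft, bank$half_len,
                    bank$nfft)
      m <- Mod(w)
      power[tr, ch, , ] <- if (output == "power") m^2 else m
    }
  }
  structure(list(
    power = power, freqs = as.numeric(freqs), time_axis = epochs$time_axis,
    fs = epochs$fs, labels = epochs$labels,
    condition_levels = epochs$condition_levels,
    channel_labels = epochs$channel_labels, montage = epochs$montage,
    baseline_mode = "none", baseline_interval = NULL,
    wavelet = list(n_cycles = n_cycles, output = output),
    coi = coi_mask(freqs, n_t, epochs$fs, n_cycles)),
    class = "tfr_set")
}

#' @export
print.tfr_set <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_set> %d trials x %d channels x %d freqs x %d times, baseline: %s\n",
    d[1], d[2], d[3], d[4], x$baseline_mode))
  invisible(x)
}

#' Baseline-normalize trial-wise power per frequency
#'
#' Expresses power relative to the mean pre-cue power at the same frequency,
#' separately for every trial, channel, and frequency. Modes: `"ratio"` =
#' power / mu, `"percent"` = 100 * (power - mu) / mu, `"dB"` =
#' 10 * log10(power / mu), where mu is the mean power over the baseline
#' interval.
#'
#' @param tfr a `tfr_set` with `baseline_mode == "none"`.
#' @param interval numeric length-2, baseline window in seconds (within the
#'   epoch time axis); default `c(-2, 0)` (pre-cue).
#' @param mode one of `"ratio"` (default), `"percent"`, `"dB"`.
#' @return a `tfr_set` with normalized `power` and baseline metadata set.
#' @export
baseline_normalize <- function(tfr, interval = c(-2, 0),
                               mode = c("ratio", "percent", "dB")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tfr, "tfr_set"))
  if (length(interval) != 2L || interval[2] <= interval[1])
    stop_ftfa("baseline interval must be (lo, hi) with hi > lo",
              class = "ftfa_interval_error")
  ta <- tfr$time_axis
  if (interval[1] < min(ta) - 0.5 / tfr$fs || interval[2] > max(ta) + 1.5 / tfr$fs)
    stop_ftfa("baseline interval outside the epoch time axis",
              class = "ftfa_interval_error")
  sel <- which(ta >= interval[1] & ta < interval[2])
  if (!length(sel))
    stop_ftfa("baseline interval contains no samples", class = "ftfa_interval_error")
  # mu: trials x channels x freqs (mean over baseline times)
  mu <- apply(tfr$power[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  if (any(mu == 0))
    stop_ftfa("degenerate baseline: zero mean power at some (trial, channel, freq)",
              class = "ftfa_degenerate_baseline_error")
  n_t <- dim(tfr$power)[4]
  mu_full <- array(mu, dim = c(dim(mu), n_t))
  out <- tfr
  out$power <- switch(mode,
    ratio   = tfr$power / mu_full,
    percent = 100 * (tfr$power - mu_full) / mu_full,
    dB      = 10 * log10(tfr$power / mu_full))
  out$baseline_mode <- mode
  out$baseline_interval <- as.numeric(interval)
  out
}

#' Condition-wise mean time-frequency maps
#'
#' Arithmetic mean of the trial-wise power maps within each condition group
#' (the classic trial-averaged time-frequency analysis).
#'
#' @param tfr a `tfr_set`.
#' @param groups a `grouped_trials` partition (see [group_trials()]).
#' @return named list (one per condition) of channels x freqs x times
#'   arrays, with attributes `freqs` and `time_axis`.
#' @export
average_tfr_by_condition <- function(tfr, groups) {
  stopifnot(inherits(tfr, "tfr_set"))
  n_trials <- dim(tfr$power)[1]
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (!length(idx))
      stop_ftfa("empty group: ", g, class = "ftfa_empty_group_error")
    if (any(idx < 1L | idx > n_trials))
      stop_ftfa("group ", g, " references absent trial index",
                class = "ftfa_index_error")
    m <- apply(tfr$power[idx, , , , drop = FALSE], c(2, 3, 4), mean)
    attr(m, "freqs") <- tfr$freqs
    attr(m, "time_axis") <- tfr$time_axis
    m
  })
  names(out) <- names(groups)
  out
}
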