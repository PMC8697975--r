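#' Specification of a condition-specific ERD/ERS effect
#'
#' Describes a ground-truth band-power change tied to one condition: on
#' trials of `condition`, the band-limited amplitude at the listed channels
#' is multiplied by `amplitude_factor` inside the time window (relative to
#' the cue). Factors below 1 emulate event-related desynchronization (ERD),
#' above 1 event-related synchronization (ERS). Because the factor scales
#' amplitude (the envelope), band *power* scales by `amplitude_factor^2`.
#'
#' @param condition condition label the effect is tied to.
#' @param channels character vector of affected channel labels.
#' @param band numeric length-2, frequency band in Hz (within (0, Nyquist)).
#' @param window numeric length-2, time window in seconds relative to the
#'   cue.
#' @param amplitude_factor multiplicative amplitude change (> 0).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(condition, channels, band, window, amplitude_factor) {
  if (!is.numeric(amplitude_factor) || amplitude_factor <= 0)
    stop_ftfa("amplitude_factor must be > 0", class = "ftfa_argument_error")
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop_ftfa("band must be (f_lo, f_hi) with 0 < f_lo < f_hi",
              class = "ftfa_argument_error")
  if (length(window) != 2L || window[2] <= window[1])
    stop_ftfa("window must be (t0, t1) with t1 > t0", class = "ftfa_argument_error")
  structure(list(condition = as.character(condition),
                 channels = as.character(channels),
                 band = as.numeric(band), window = as.numeric(window),
                 amplitude_factor = amplitude_factor),
            class = "effect_spec")
}

#' Background-noise model for synthetic EEG
#'
#' Per-channel background: 1/f^beta broadband noise plus narrow-band
#' oscillatory components (by default an alpha rhythm at 10 Hz and a beta
#' rhythm at 20 Hz, giving realistically shaped resting spectra) plus a
#' white floor. All components are independent across channels; the seed
#' fixes the full sample path.
#'
#' @param background_exponent spectral slope beta of the 1/f^beta component
#'   (default 1).
#' @param background_rms RMS amplitude of the broadband component
#'   (microvolts, default 8).
#' @param band_components list of numeric length-3 vectors
#'   `c(center_hz, bandwidth_hz, rms_uv)`; default alpha (10, 2, 4) and
#'   beta (20, 4, 2).
#' @param white_rms RMS of the white floor (microvolts, default 1.5).
#' @param seed integer seed for the noise stream.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(background_exponent = 1, background_rms = 8,
                       band_components = list(c(10, 2, 4), c(20, 4, 2)),
                       white_rms = 1.5, seed = 1L) {
  rms <- c(background_rms, white_rms,
           vapply(band_components, function(b) b[3], 1))
  if (any(rms < 0))
    stop_ftfa("all RMS values must be >= 0", class = "ftfa_argument_error")
  structure(list(background_exponent = background_exponent,
                 background_rms = background_rms,
                 band_components = band_components,
                 white_rms = white_rms, seed = as.integer(seed)),
            class = "noise_spec")
}

# 1/f^beta noise via spectral shaping of white noise; zero-mean, unit RMS.
# FFT length padded to a highly composite size (R's mixed-radix FFT is slow
# for lengths with large prime factors); the first n samples are kept.
pink_noise <- function(n, beta, fs) {
  m <- nextn(n)
  x <- rnorm(m)
  X <- fft(x)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)           # two-sided frequency magnitude
  g <- c(0, f[-1]^(-beta / 2))   # kill DC
  y <- Re(fft(X * g, inverse = TRUE))[seq_len(n)] / m
  y / sd(y)
}

band_noise <- function(n, center, bw, fs) {
  lo <- max(center - bw / 2, 0.1)
  hi <- min(center + bw / 2, fs / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, rnorm(n))
  y / sd(y)
}

bandpass_extract <- function(x, band, fs) {
  lo <- max(band[1], 0.1)
  hi <- min(band[2], fs / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# raised-cosine on/off window over sample indices i0..i1 with ramp samples r
ramped_window <- function(n, i0, i1, r) {
  g <- numeric(n)
  i0 <- max(i0, 1L); i1 <- min(i1, n)
  if (i1 < i0) return(g)
  g[i0:i1] <- 1
  len <- i1 - i0 + 1L
  r <- min(r, len %/% 2L)
  if (r > 0) {
    ramp <- (1 - cos(pi * seq_len(r) / r)) / 2
    g[i0:(i0 + r - 1L)] <- ramp
    g[(i1 - r + 1L):i1] <- rev(ramp)
  }
  g
}

#' Generate a cue-based event table for a multi-run paradigm
#'
#' Emulates a motor-imagery session: `n_runs` runs, each containing
#' `trials_per_condition_per_run` trials of every condition in randomized
#' order, trials uniformly spaced `trial_period_s` apart. Each trial begins
#' with a 2 s fixation-cross period; the returned event marks the cue
#' (arrow) onset 2 s after trial start. Six runs of 12 trials per condition
#' with four conditions give 288 events, 72 per condition.
#'
#' @param n_runs number of runs (>= 1).
#' @param trials_per_condition_per_run trials of each condition per run
#'   (>= 1).
#' @param conditions character vector of condition labels.
#' @param trial_period_s trial-to-trial spacing in seconds (>= 7.25: 2 s
#'   cross + imagery interval + break).
#' @param fs sampling rate (Hz) used to place events on the sample grid.
#' @param seed integer; fixes the condition order.
#' @return an [event_table()] with attribute `trial_period_s`.
#' @export
generate_paradigm <- function(n_runs, trials_per_condition_per_run, conditions,
                              trial_period_s = 8, fs = 250, seed = 1L) {
  if (n_runs < 1L || trials_per_condition_per_run < 1L || length(conditions) < 1L)
    stop_ftfa("counts and condition set must be positive",
              class = "ftfa_argument_error")
  if (trial_period_s < 7.25)
    stop_ftfa("trial_period_s must be >= 7.25 s (2 s cross + imagery + break)",
              class = "ftfa_argument_error")
  set.seed(derive_seed(seed, "paradigm"))
  lead_in_s <- 1           # head room before the first cross
  cross_to_cue_s <- 2      # fixation cross precedes the arrow by 2 s
  order_all <- unlist(lapply(seq_len(n_runs), function(r)
    sample(rep(conditions, each = trials_per_condition_per_run))))
  k <- seq_along(order_all) - 1L
  cue_s <- lead_in_s + k * trial_period_s + cross_to_cue_s
  ev <- event_table(sample = round(cue_s * fs) + 1L, condition = order_all,
                    levels = sort(unique(as.character(conditions))))
  attr(ev, "trial_period_s") <- trial_period_s
  ev
}

#' Simulate a continuous multichannel EEG session with known ERD/ERS
#'
#' Builds, per channel, a background of 1/f^beta noise, narrow-band
#' oscillatory components and a white floor (see [noise_spec()]), then for
#' every event of condition `c` and every matching [effect_spec()] rescales
#' the band-limited amplitude at the listed channels by the effect's factor
#' inside its time window, with raised-cosine on/off ramps of at most
#' 0.1 s. Fully reproducible from the noise seed.
#'
#' @param montage data frame `label, x, y` defining the simulated channels
#'   (e.g. a subset of [standard_montage()]).
#' @param events an [event_table()] of cue onsets.
#' @param effects list of [effect_spec()] objects (possibly empty).
#' @param noise a [noise_spec()].
#' @param fs sampling rate (Hz).
#' @param duration_s total duration in seconds; default covers the last
#'   event plus 5 s.
#' @return an [recording()] with the montage attached.
#' @export
simulate_session <- function(montage, events, effects = list(),
                             noise = noise_spec(), fs = 250,
                             duration_s = NULL) {
  montage <- validate_montage(montage)
  stopifnot(inherits(events, "event_table"), inherits(noise, "noise_spec"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  labels <- montage$label
  for (ef in effects) {
    bad <- setdiff(ef$channels, labels)
    if (length(bad))
      stop_ftfa("effect references unknown channel(s): ",
                paste(bad, collapse = ", "), class = "ftfa_channel_error")
    if (ef$band[2] >= fs / 2)
      stop_ftfa("effect band exceeds Nyquist", class = "ftfa_frequency_error")
  }
  need_s <- max(events$sample) / fs + 5
  duration_s <- duration_s %||% need_s
  if (duration_s < need_s)
    stop_ftfa("duration_s does not cover all event windows",
              class = "ftfa_argument_error")
  n <- as.integer(round(duration_s * fs))
  set.seed(derive_seed(noise$seed, "noise"))
  dat <- matrix(0, nrow = length(labels), ncol = n)
  for (ch in seq_along(labels)) {
    x <- numeric(n)
    if (noise$background_rms > 0)
      x <- x + noise$background_rms * pink_noise(n, noise$background_exponent, fs)
    for (bc in noise$band_components)
      if (bc[3] > 0) x <- x + bc[3] * band_noise(n, bc[1], bc[2], fs)
    if (noise$white_rms > 0)
      x <- x + noise$white_rms * rnorm(n)
    dat[ch, ] <- x
  }
  # apply effects: per (channel, band) extract the band-limited part once,
  # then add (factor - 1) * gain(t) * band_part inside each matching trial
  ramp_n <- as.integer(round(0.1 * fs))
  for (ef in effects) {
    ev_idx <- which(events$condition == ef$condition)
    if (!length(ev_idx)) next
    for (chl in ef$channels) {
      ch <- match(chl, labels)
      bp <- bandpass_extract(dat[ch, ], ef$band, fs)
      gain <- numeric(n)
      for (e in ev_idx) {
        i0 <- events$sample[e] + sec_to_samples(ef$window[1], fs)
        i1 <- events$sample[e] + sec_to_samples(ef$window[2], fs) - 1L
        gain <- gain + ramped_window(n, i0, i1, ramp_n)
      }
      dat[ch, ] <- dat[ch, ] + (ef$amplitude_factor - 1) * gain * bp
    }
  }
  recording(dat, fs, channel_labels = labels, montage = montage)
}

#' Null trial-wise TFR data with labels independent of the values
#'
#' Generates i.i.d. positive pixel values (squared standard Gaussians) for
#' every trial, channel, frequency and time, with group labels assigned
#' independently of the data — the type-I-error calibration harness: under
#' this null, the fraction of pixels whose F exceeds the alpha critical
#' value should be close to alpha.
#'
#' @param n_groups number of groups (>= 2).
#' @param trials_per_group trials in each group (>= 1).
#' @param n_channels,n_freqs,n_times tensor dimensions (>= 1).
#' @param seed integer seed.
#' @return list with `tfr` (a `tfr_set`) and `groups` (a `grouped_trials`).
#' @export
generate_null_epochs <- function(n_groups, trials_per_group, n_channels = 1L,
                                 n_freqs = 20L, n_times = 100L, seed = 1L) {
  if (n_groups < 2L)
    stop_ftfa("need at least two groups", class = "ftfa_needs_two_groups_error")
  if (min(trials_per_group, n_channels, n_freqs, n_times) < 1L)
    stop_ftfa("all counts must be >= 1", class = "ftfa_argument_error")
  set.seed(derive_seed(seed, "null"))
  n_trials <- n_groups * trials_per_group
  power <- array(rnorm(n_trials * n_channels * n_freqs * n_times)^2,
                 dim = c(n_trials, n_channels, n_freqs, n_times))
  lev <- paste0("g", seq_len(n_groups))
  labels <- rep(lev, each = trials_per_group)
  tfr <- structure(list(
    power = power, freqs = as.numeric(seq_len(n_freqs)),
    time_axis = as.numeric(seq_len(n_times) - 1L), fs = 1,
    labels = labels, condition_levels = lev,
    channel_labels = paste0("ch", seq_len(n_channels)), montage = NULL,
    baseline_mode = "none", baseline_interval = NULL,
    wavelet = list(n_cycles = NA_real_, output = "power"),
    coi = matrix(FALSE, n_freqs, n_times)),
    class = "tfr_set")
  list(tfr = tfr, groups = group_trials(tfr))
}
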