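#' Extract cue-locked epochs from a continuous recording
#'
#' Cuts one fixed-length trial per event, time-locked to the event sample.
#' The epoch window is half-open `[tmin_s, tmax_s)`: each trial has exactly
#' `round((tmax_s - tmin_s) * fs)` samples, so a -2..4 s window at 250 Hz
#' yields 1500 samples per trial. Trial `t`, channel `c`, sample `k` equals
#' the recording sample at `event_t + round(tmin_s * fs) + k` (k = 0-based
#' offset within the trial).
#'
#' @param rec an [recording()] object.
#' @param events an [event_table()].
#' @param tmin_s,tmax_s epoch window in seconds relative to the event;
#'   `tmax_s > tmin_s` required.
#' @return an object of class `epoch_set` with fields `data` (trials x
#'   channels x samples, microvolts), `fs`, `tmin_s`, `tmax_s`, `labels`
#'   (per-trial condition), `time_axis` (seconds relative to the cue),
#'   `channel_labels`, `montage`, and `condition_levels`.
#' @export
epoch_extract <- function(rec, events, tmin_s, tmax_s) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_table"))
  if (!(tmax_s > tmin_s))
    stop_ftfa("invalid epoch window: tmax_s must exceed tmin_s",
              class = "ftfa_invalid_window_error")
  fs <- rec$fs
  n_t <- as.integer(round((tmax_s - tmin_s) * fs))
  if (n_t < 1L)
    stop_ftfa("invalid epoch window: empty after rounding to samples",
              class = "ftfa_invalid_window_error")
  start_off <- as.integer(round(tmin_s * fs))
  ns <- n_samples(rec)
  starts <- events$sample + start_off
  bad <- which(starts < 1L | (starts + n_t - 1L) > ns)
  if (length(bad))
    stop_ftfa(sprintf(
      "epoch window out of recording bounds for event %d (sample %d, condition %s)",
      bad[1], events$sample[bad[1]], events$condition[bad[1]]),
      class = "ftfa_out_of_bounds_error")
  n_trials <- nrow(events)
  n_ch <- nrow(rec$data)
  dat <- array(NA_real_, dim = c(n_trials, n_ch, n_t))
  for (i in seq_len(n_trials)) {
    idx <- starts[i]:(starts[i] + n_t - 1L)
    dat[i, , ] <- rec$data[, idx, drop = FALSE]
  }
  structure(list(
    data = dat, fs = fs, tmin_s = tmin_s, tmax_s = tmax_s,
    labels = events$condition,
    time_axis = tmin_s + (seq_len(n_t) - 1L) / fs,
    channel_labels = rec$channel_labels,
    montage = rec$montage,
    condition_levels = condition_levels(events)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$tmin_s, x$tmax_s))
  cat("  trials per condition:\n")
  print(table(factor(x$labels, levels = x$condition_levels)))
  invisible(x)
}

#' Group trial indices by condition
#'
#' Partitions the trials of an epoch set (or any labelled trial container)
#' into per-condition index lists — the "groups" entering the one-way ANOVA.
#' Every trial belongs to exactly one group and group sizes sum to the trial
#' count.
#'
#' @param epochs an `epoch_set` (or `tfr_set`) with per-trial `labels` and
#'   `condition_levels`.
#' @return a named list of integer trial-index vectors, class
#'   `grouped_trials`.
#' @export
group_trials <- function(epochs) {
  labels <- epochs$labels
  lev <- epochs$condition_levels %||% sort(unique(labels))
  if (length(labels) < 1L)
    stop_ftfa("no trials to group", class = "ftfa_argument_error")
  bad <- setdiff(labels, lev)
  if (length(bad))
    stop_ftfa("trial label(s) outside declared set: ",
              paste(unique(bad), collapse = ", "), class = "ftfa_label_error")
  groups <- lapply(lev, function(l) which(labels == l))
  names(groups) <- lev
  groups <- groups[vapply(groups, length, 1L) > 0L]
  structure(groups, class = "grouped_trials")
}

#' @export
print.grouped_trials <- function(x, ...) {
  cat("<grouped_trials>", paste(sprintf("%s: n=%d", names(x),
                                        vapply(x, length, 1L)),
                                collapse = ", "), "\n")
  invisible(x)
}
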