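#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording: an amplitude matrix (channels x
#' samples, microvolts), the sampling rate, channel labels (10-20 system
#' names), and optionally a 2-D scalp montage. Input data are assumed to be
#' acquisition-filtered already (e.g. band-pass and notch applied by the
#' amplifier); the package does not re-filter.
#'
#' @param data numeric matrix, channels x samples (microvolts). All values
#'   must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names, one per
#'   row of `data`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param montage optional data frame with columns `label`, `x`, `y` giving
#'   2-D head-circle coordinates; must contain one position per channel
#'   label when supplied.
#' @return an object of class `eeg_recording`.
#' @seealso [epoch_extract()], [read_edf()], [standard_montage()]
#' @export
recording <- function(data, fs, channel_labels = NULL, montage = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_ftfa("sampling rate must be a single positive number", class = "ftfa_argument_error")
  if (!all(is.finite(data)))
    stop_ftfa("recording contains non-finite samples", class = "ftfa_argument_error")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop_ftfa("need one channel label per data row", class = "ftfa_argument_error")
  if (anyDuplicated(channel_labels))
    stop_ftfa("channel labels must be unique", class = "ftfa_argument_error")
  if (!is.null(montage)) {
    montage <- validate_montage(montage)
    missing <- setdiff(channel_labels, montage$label)
    if (length(missing))
      stop_ftfa("montage lacks positions for channel(s): ",
                paste(missing, collapse = ", "), class = "ftfa_montage_error")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

validate_montage <- function(montage) {
  montage <- as.data.frame(montage)
  req <- c("label", "x", "y")
  if (!all(req %in% names(montage)))
    stop_ftfa("montage needs columns label, x, y", class = "ftfa_montage_error")
  montage$label <- as.character(montage$label)
  if (anyDuplicated(montage$label))
    stop_ftfa("duplicate labels in montage", class = "ftfa_montage_error")
  if (!all(is.finite(montage$x)) || !all(is.finite(montage$y)))
    stop_ftfa("montage coordinates must be finite", class = "ftfa_montage_error")
  montage[, req]
}

#' Event table: cue onsets and condition labels
#'
#' Events mark cue onsets in the continuous recording by 1-based sample
#' index together with a condition label drawn from a declared finite set.
#' Sample indices (rather than seconds) avoid rounding ambiguity.
#'
#' @param sample integer vector of strictly increasing 1-based sample
#'   indices.
#' @param condition vector of condition labels, same length as `sample`.
#' @param levels declared condition set; defaults to the sorted unique
#'   labels present.
#' @return an object of class `event_table` (a data frame with columns
#'   `sample` and `condition`, plus a `levels` attribute).
#' @export
event_table <- function(sample, condition, levels = NULL) {
  sample <- as.integer(sample)
  condition <- as.character(condition)
  if (length(sample) != length(condition) || length(sample) < 1L)
    stop_ftfa("sample and condition must be non-empty and equal length",
              class = "ftfa_argument_error")
  if (any(diff(sample) <= 0))
    stop_ftfa("event sample indices must be strictly increasing",
              class = "ftfa_argument_error")
  if (any(sample < 1L))
    stop_ftfa("event sample indices must be >= 1", class = "ftfa_argument_error")
  if (is.null(levels)) levels <- sort(unique(condition))
  levels <- as.character(levels)
  bad <- setdiff(condition, levels)
  if (length(bad))
    stop_ftfa("condition label(s) outside declared set: ",
              paste(unique(bad), collapse = ", "), class = "ftfa_label_error")
  structure(data.frame(sample = sample, condition = condition,
                       stringsAsFactors = FALSE),
            levels = levels, class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, conditions: %s\n", nrow(x),
              paste(attr(x, "levels"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

condition_levels <- function(events) attr(events, "levels")
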