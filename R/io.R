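#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, per-channel physical scaling chosen from the data range. The
#' recording length is padded with zeros to a whole number of records; the
#' true sample count is stored in the header's reserved field so
#' [read_edf()] restores the exact length.
#'
#' @param rec an [recording()] (requires an integer sampling rate).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs))
    stop_ftfa("EDF export requires an integer sampling rate",
              class = "ftfa_io_error")
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  spr <- as.integer(fs)                 # samples per record (1 s records)
  n_rec <- as.integer(ceiling(n / spr))
  pad <- n_rec * spr - n
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad_field <- function(x, w) {
    x <- substr(as.character(x), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  num_field <- function(x, w) pad_field(formatC(x, format = "g", digits = 7), w)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste(s, collapse = ""), con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X", 80))
  wr(pad_field("Startdate 01-JAN-2000 X X X", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (ns + 1), 8))
  wr(pad_field(paste0("FTFA_NS=", n), 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field(1, 8))
  wr(pad_field(ns, 4))
  wr(vapply(rec$channel_labels, pad_field, "", w = 16))
  wr(vapply(rep("", ns), pad_field, "", w = 80))
  wr(vapply(rep("uV", ns), pad_field, "", w = 8))
  wr(vapply(pmin_, num_field, "", w = 8))
  wr(vapply(pmax_, num_field, "", w = 8))
  wr(vapply(rep(dmin, ns), pad_field, "", w = 8))
  wr(vapply(rep(dmax, ns), pad_field, "", w = 8))
  wr(vapply(rep("", ns), pad_field, "", w = 80))
  wr(vapply(rep(spr, ns), pad_field, "", w = 8))
  wr(vapply(rep("", ns), pad_field, "", w = 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dat <- cbind(rec$data, matrix(0, ns, pad))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((dat[ch, idx] - pmin_[ch]) * scale[ch] + dmin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Minimal European Data Format reader: parses the ASCII header (channel
#' labels, physical/digital scaling, record layout) and the 16-bit data
#' records, returning physical units. Handles files written by
#' [write_edf()] and plain continuous EDF from other tools.
#'
#' @param path EDF file path.
#' @param montage optional montage to attach (data frame `label, x, y`).
#' @return an [recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  if (!file.exists(path))
    stop_ftfa("EDF file not found: ", path, class = "ftfa_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                          # version
  rd(80); rd(80); rd(8); rd(8)   # patient, recording, date, time
  rd(8)                          # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L)
    stop_ftfa("corrupt EDF header in ", path, class = "ftfa_io_error")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  for (i in seq_len(ns)) rd(80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(ns)) rd(32)  # reserved
  dat <- matrix(NA_real_, ns, n_rec * spr[1])
  if (length(unique(spr)) != 1L)
    stop_ftfa("EDF files with per-channel sampling rates are not supported",
              class = "ftfa_io_error")
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[ch])
        stop_ftfa("truncated EDF data in ", path, class = "ftfa_io_error")
      dat[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  fs <- spr[1] / rec_dur
  true_n <- if (grepl("^FTFA_NS=", reserved))
    as.integer(sub("^FTFA_NS=", "", reserved)) else ncol(dat)
  recording(dat[, seq_len(true_n), drop = FALSE], fs,
            channel_labels = labels, montage = montage)
}

#' Read / write an event CSV
#'
#' Plain CSV with header columns `sample` (1-based sample index) and
#' `condition`.
#'
#' @param path CSV path.
#' @param levels optional declared condition set (defaults to labels
#'   present).
#' @return [read_events_csv()] returns an [event_table()];
#'   [write_events_csv()] returns `path` invisibly.
#' @export
read_events_csv <- function(path, levels = NULL) {
  if (!file.exists(path))
    stop_ftfa("events file not found: ", path, class = "ftfa_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop_ftfa("events CSV needs columns sample, condition (", path, ")",
              class = "ftfa_io_error")
  event_table(df$sample, df$condition, levels = levels)
}

#' @rdname read_events_csv
#' @param events an [event_table()].
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events)[, c("sample", "condition")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a montage CSV (`label, x, y`)
#'
#' @param path CSV path with header columns `label`, `x`, `y` (head-circle
#'   coordinates, unitless).
#' @return data frame with columns `label`, `x`, `y`.
#' @export
read_montage_csv <- function(path) {
  if (!file.exists(path))
    stop_ftfa("montage file not found: ", path, class = "ftfa_io_error")
  validate_montage(read.csv(path, stringsAsFactors = FALSE))
}

#' Built-in standard 10-20 scalp montage
#'
#' Schematic 2-D head-circle positions (nose up, radius 1) for the extended
#' 10-20 electrode set, sufficient for the usual 22-channel motor-imagery
#' montages (Fz, FC/C/CP rows, Pz, POz, ...).
#'
#' @param channels optional character vector to subset (order preserved).
#' @return data frame `label, x, y`.
#' @export
standard_montage <- function(channels = NULL) {
  path <- system.file("extdata", "montage_1020.csv", package = "ftfa",
                      mustWork = TRUE)
  m <- read_montage_csv(path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, m$label)
    if (length(missing))
      stop_ftfa("unknown channel(s): ", paste(missing, collapse = ", "),
                class = "ftfa_montage_error")
    m <- m[match(channels, m$label), ]
    rownames(m) <- NULL
  }
  m
}

#' Persist / load analysis containers
#'
#' Serializes TFR sets, F-maps, significance masks and epoch sets to a
#' native container (RDS) carrying provenance attributes: package version,
#' creation time-free config hash, and free-form metadata. Round trips are
#' bit-identical: arrays and metadata are restored exactly.
#'
#' @param x object to store (`tfr_set`, `ftf_map`, `epoch_set`, or any list).
#' @param path output path (conventionally `.rds`).
#' @param provenance optional named list stored alongside (e.g. the
#'   analysis config).
#' @return `path` invisibly for [save_container()]; the stored object (with
#'   attribute `provenance`) for [load_container()].
#' @export
save_container <- function(x, path, provenance = NULL) {
  attr(x, "provenance") <- c(
    list(package = "ftfa", version = as.character(packageVersion("ftfa"))),
    provenance)
  saveRDS(x, path, version = 3)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  if (!file.exists(path))
    stop_ftfa("container not found: ", path, class = "ftfa_io_error")
  readRDS(path)
}

#' Write ground-truth metadata of a synthetic session as JSON
#'
#' Stores the effect specifications, noise model, seed and paradigm
#' parameters of a simulated session so test harnesses can score recovery
#' against the injected truth.
#'
#' @param path output JSON path.
#' @param events the [event_table()] used.
#' @param effects list of [effect_spec()]s.
#' @param noise the [noise_spec()].
#' @param fs sampling rate (Hz).
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(path, events, effects, noise, fs) {
  gt <- list(
    fs = fs,
    conditions = condition_levels(events),
    n_events = nrow(events),
    events = as.data.frame(events),
    effects = lapply(effects, unclass),
    noise = unclass(noise))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
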