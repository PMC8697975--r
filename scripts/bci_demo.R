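#!/usr/bin/env Rscript

# Optional demo: FTF analysis of a real motor-imagery recording.
#
# This script is NOT run by the test suite (it needs a download). It
# documents the route from the public four-class motor-imagery benchmark
# (BCI Competition IV dataset 2a, http://www.bbci.de/competition/iv:
# 22-channel EEG, 250 Hz, 4 imagined movements x 72 trials per session)
# to the package's input formats.
#
# The competition distributes GDF files. Convert one training session to
# EDF + events CSV first, e.g. with python-mne:
#
#   import mne, pandas as pd
#   raw = mne.io.read_raw_gdf("A01T.gdf", preload=True)
#   raw.pick(picks="eeg")
#   mne.export.export_raw("A01T.edf", raw, fmt="edf")
#   ev, ids = mne.events_from_annotations(raw)
#   cue = {ids[k]: lab for k, lab in
#          [("769", "left"), ("770", "right"), ("771", "foot"), ("772", "tongue")]
#          if k in ids}
#   rows = [(s + 1, cue[c]) for s, _, c in ev if c in cue]   # 1-based samples
#   pd.DataFrame(rows, columns=["sample", "condition"]).to_csv(
#       "A01T_events.csv", index=False)
#
# Then run this script:
#
#   Rscript scripts/bci_demo.R A01T.edf A01T_events.csv out_dir

suppressPackageStartupMessages(library(ftfa))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 3) {
  cat("usage: Rscript scripts/bci_demo.R <recording.edf> <events.csv> <out_dir>\n")
  quit(status = 2)
}

cfg <- ftf_config(
  input = list(edf = args[1], events = args[2]),
  epoch_window = c(-2, 4), baseline = c(-2, 0), baseline_mode = "ratio",
  freqs = 1:100, n_cycles = 7, alpha = 0.01, correction = "none",
  bands = list(list(f_lo = 17, f_hi = 27,
                    windows = list(c(0.5, 1.5), c(1.5, 2.5), c(2.5, 3.5))),
               list(f_lo = 9, f_hi = 15,
                    windows = list(c(0.5, 1.5), c(1.5, 2.5), c(2.5, 3.5)))),
  out_dir = args[3], render = TRUE)

res <- run_pipeline(cfg)
cat("\nPer-channel mean F in 8-42 Hz, 0.5-3.5 s:\n")
fsel <- res$ftf$freqs >= 8 & res$ftf$freqs <= 42
tsel <- res$ftf$time_axis >= 0.5 & res$ftf$time_axis < 3.5
m <- apply(res$ftf$f_values[, fsel, tsel, drop = FALSE], 1, mean)
print(round(sort(setNames(m, res$ftf$channel_labels), decreasing = TRUE), 2))
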