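# ftfa: F-value time-frequency analysis of multichannel EEG

`ftfa` finds the time-frequency features of EEG that *differ between
experimental conditions*. Classic trial-averaged time-frequency analysis
shows, per condition, where band power rises or falls relative to baseline
(event-related synchronization/desynchronization, ERS/ERD), but leaves the
analyst eyeballing several maps to spot condition differences. `ftfa`
replaces that visual comparison with a statistic: at **every** (channel,
frequency, time) pixel of the trial-wise wavelet power maps it computes the
one-way ANOVA F-value across conditions, producing an *F-map* in which high
values mark features that change a lot between conditions and little within
them — exactly the features that discriminate, e.g., different imagined
movements in motor-imagery experiments.

It is aimed at EEG/MEG researchers and BCI developers who have cue-locked
multi-condition recordings and want a mass-univariate, assumption-light
screening of discriminative time-frequency structure.

## The statistic

For K conditions with n_i trials each (N = Σ n_i), let Y_ij be the
baseline-normalized wavelet power of trial j of condition i at one fixed
(channel, frequency f, time t) pixel. With group means Ȳ_i and grand mean
Ȳ:

    between-group variance = Σ_i n_i (Ȳ_i − Ȳ)² / (K − 1)
    within-group variance  = Σ_i Σ_j (Y_ij − Ȳ_i)² / (N − K)

    F_{f,t} = between-group variance / within-group variance

computed independently at every pixel. Under the null of equal condition
means, F_{f,t} follows an F distribution with (K − 1, N − K) degrees of
freedom; for the canonical layout of 4 conditions × 72 trials that is
(3, 284), with upper 1% critical value 3.851286. Pixels above the critical
value are flagged by `significance_mask()` (optionally with Bonferroni or
Benjamini-Hochberg correction for the mass-univariate multiplicity).

Upstream of the statistic the package provides cue-locked epoching, complex
Morlet wavelet power (unit-energy kernels, default 7 cycles), per-frequency
baseline ratio normalization, condition-wise mean TFRs, band-limited scalp
topographies, minimal EDF and CSV I/O, and a synthetic session generator
with known ERD/ERS ground truth.

## Worked example

Simulate a four-condition motor-imagery session (6 runs × 12 trials per
condition) with a known ERD — amplitude factor 0.5, i.e. band power × 0.25
— at C4 for *left* and C3 for *right* in the 8–13 Hz mu band, 0.5–3 s after
the cue, then recover it:

```r
library(ftfa)

events  <- generate_paradigm(6, 12, c("left", "right", "foot", "tongue"), seed = 42)
montage <- standard_montage(c("C3", "Cz", "C4"))
effects <- list(
  effect_spec("left",  "C4", band = c(8, 13), window = c(0.5, 3), amplitude_factor = 0.5),
  effect_spec("right", "C3", band = c(8, 13), window = c(0.5, 3), amplitude_factor = 0.5))
rec    <- simulate_session(montage, events, effects, noise_spec(seed = 42))
epochs <- epoch_extract(rec, events, -2, 4)
tfr    <- baseline_normalize(tfr_compute(epochs, freqs = 1:30), interval = c(-2, 0))
map    <- ftf_map(tfr, group_trials(epochs))
map
#> <ftf_map> 3 channel(s) x 30 freqs x 1500 times, df = (3, 284)
#>   groups: foot=72, left=72, right=72, tongue=72

critical_f(0.01, map$df_between, map$df_within)
#> [1] 3.851286
mask <- significance_mask(map, alpha = 0.01)
mean(mask$mask)            # fraction of significant pixels
#> [1] 0.062

band_topography(map, 8, 13, windows = list(c(0.5, 3)))[[1]]
#> <topography> band 8-13 Hz, window [0.5, 3) s, 3 channel(s)
#>    C3    Cz    C4
#> 8.255 1.287 8.460
```

The mu-band topography shows mean F well above the 3.85 threshold at the
two channels carrying condition-specific ERD, and near-null values at Cz,
which carries none. `plot(map, channel = "C4")` draws the F-map (time on
x, frequency on y, cue at the red line); `plot_channel_grid(map)` draws all
channels on a shared scale.

A command-line driver with `run`, `simulate`, `tfr`, `ftf`, `topo` and
`render` subcommands ships in `inst/cli/ftfa`
(`Rscript $(Rscript -e 'cat(system.file("cli","ftfa",package="ftfa"))') run --config cfg.yaml`).
Real recordings enter through `read_edf()` plus a `sample,condition` events
CSV; `scripts/bci_demo.R` documents that route end to end.

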