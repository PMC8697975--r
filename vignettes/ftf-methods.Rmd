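---
title: "F-value time-frequency maps: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{F-value time-frequency maps: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftfa)
```

## The problem and the model

Cue-locked EEG experiments with several conditions (e.g. four imagined
movements) produce, per trial, a time-frequency power map per channel.
Condition-specific sensorimotor responses appear as event-related
desynchronization (ERD, band-power decrease) or synchronization (ERS,
increase) relative to the pre-cue baseline. Trial-averaged maps show these
responses one condition at a time; the discriminative question — *where in
time and frequency do the conditions differ?* — is answered here by a
mass-univariate one-way ANOVA.

At a fixed channel, frequency $f$ and time $t$, the per-trial
baseline-normalized power values $Y_{ij}$ ($i$ = condition, $j$ = trial)
are treated as $K$ independent groups, and

$$F_{f,t} = \frac{\sum_i n_i(\bar Y_i - \bar Y)^2/(K-1)}
                 {\sum_i \sum_j (Y_{ij} - \bar Y_i)^2/(N-K)}$$

is evaluated independently at every pixel (`ftf_map()`). Under the per-pixel
null of equal condition means and the usual ANOVA assumptions the statistic
is $F_{K-1,\,N-K}$ distributed; with $K = 4$ conditions of $n_i = 72$
trials, df $= (3, 284)$ and the upper 1% critical value is
`critical_f(0.01, 3, 284)` $= 3.8513$. The map is descriptive as much as
inferential: its value is that condition-dependent structure stands out at
a glance, on a common scale, across channels.

Assumptions worth keeping in mind: single-trial wavelet power is roughly
exponentially distributed, not Gaussian, so the per-pixel F-test is only
asymptotically calibrated — at $n_i = 72$ we measure a mildly conservative
type-I rate (about 0.009 at nominal 0.01, see the null-calibration test);
independence across trials is assumed; independence across *pixels* is
certainly false (wavelet smoothing correlates neighbours), which matters
for any family-wise interpretation (below) but not for the per-pixel value.

## Pipeline and tunable parameters

1. **Epoching** (`epoch_extract()`). Half-open window $[t_{min}, t_{max})$
   in seconds relative to the cue; default $[-2, 4)$ s, which at 250 Hz
   gives exactly 1500 samples. Events are 1-based sample indices (R
   convention). Acquisition filtering is assumed done; the package never
   re-filters analysis data.
2. **Wavelet power** (`tfr_compute()`). Complex Morlet kernels —
   Gaussian-windowed complex exponentials with $\sigma_t = n_c/(2\pi f)$ —
   normalized to unit energy, sampled over $\pm 5\sigma_t$ (odd length).
   Default `n_cycles` $n_c = 7$, a common compromise between temporal and
   spectral resolution for sensorimotor rhythms; it is a plain argument,
   and may be given per analysis. Power is $|W|^2$ by default; a
   `magnitude` switch gives $|W|$ for users who prefer amplitude
   envelopes. The frequency grid defaults to 1–100 Hz in 1 Hz steps.
3. **Baseline normalization** (`baseline_normalize()`). Per trial, channel
   and frequency, power is divided by its mean over the baseline interval
   (default $[-2, 0)$ s, the pre-cue period); `percent` and `dB` modes are
   also provided. The F-statistic is location/scale invariant, so the
   choice mostly affects interpretability of the TFR panels, not the F-map
   — but see the bias note below.
4. **F-map, threshold, topography**. `significance_mask()` applies the
   single fixed threshold by default (`correction = "none"`), reproducing
   the classical presentation; Bonferroni and Benjamini-Hochberg options
   acknowledge that $100 \times 1500$ pixels per channel inflate
   family-wise error badly. `band_topography()` averages F inclusively
   over integer-Hz band edges (17–27 Hz on the 1 Hz grid averages 11
   rows) and half-open time windows. `average_maps()` averages aligned
   maps (e.g. across subjects); a mean of F-values is *not* F-distributed,
   so on averaged maps the critical line is annotation, not inference.

## Numerical choices

* **Convolution and edges.** The CWT is a same-length, zero-padded FFT
  convolution. At 1 Hz with 7 cycles the kernel ($\pm 5\sigma_t \approx
  11.1$ s) is longer than a 6 s epoch; this is permitted by construction,
  and the affected samples are flagged by a cone-of-influence mask
  (`coi_mask()`, $\pm 5\sigma_t$ per frequency) stored on every TFR so
  users can blank unreliable edges. FFT lengths are padded to highly
  composite sizes throughout (including the noise generator), since R's
  mixed-radix FFT degrades severely on lengths with large prime factors.
* **Degenerate pixels.** If the within-group variance is 0 with a positive
  between-group variance, $F = \infty$ (always significant); if all trials
  are identical, $F = 0$. Both conventions are documented and tested.
* **Degenerate baselines** (zero mean power at any trial/channel/frequency)
  are an error rather than silently producing `Inf`/`NaN` maps.
* **Ratio-normalization bias.** Dividing by a *noisy* baseline estimate
  inflates expected normalized power by roughly $1 + \mathrm{CV}^2(\hat\mu)$
  (Jensen): with a 2 s baseline this is a few percent at 10 Hz but tens of
  percent at 5 Hz and below, and cone-of-influence attenuation of a
  baseline that touches the epoch edge adds to it. This cancels in the
  F-map only insofar as it is common to all conditions (it is, under equal
  designs); for TFR interpretation at low frequencies prefer longer
  baselines or wider epochs.

## The synthetic generator: what it emulates and what it does not

`generate_paradigm()` reproduces the session structure of a standard
four-class motor-imagery protocol: runs of randomized condition order,
uniform trial spacing (default 8 s; a 2 s fixation-cross period precedes
each cue), 6 runs × 12 trials/condition × 4 conditions = 288 trials, 72
per condition. `simulate_session()` builds per-channel background as
$1/f^{\beta}$ noise ($\beta = 1$) plus narrow-band alpha (10 Hz, 2 Hz BW,
4 µV RMS) and beta (20 Hz, 4 Hz BW, 2 µV RMS) components and a 1.5 µV
white floor, 8 µV RMS broadband — values chosen once as representative of
resting scalp EEG spectra. `effect_spec()` injects ERD/ERS by rescaling
the band-limited *amplitude* within a trial window (raised-cosine ramps
≤ 0.1 s), so power scales by the squared factor; an amplitude factor 0.5
is a 75% band-power ERD, verified in the tests against an independent
band-pass-power oracle.

The generator deliberately omits: volume conduction and correlated
channels, artifacts (EOG/EMG), non-stationary background, inter-subject
variability, and any phase-locked (evoked) component. Passing tests
therefore demonstrate that the pipeline recovers known band-limited
power effects under realistic spectra and trial counts — not that it is
robust to artifacts or leakage between nearby channels.

`generate_null_epochs()` produces i.i.d. squared-Gaussian pixel values
with labels independent of the data, the calibration harness for the
type-I rate.

## Validation design and problem sizes

The test suite validates each stage against an independent route:
epoch index arithmetic by hand-computed fixtures; kernel properties by
closed forms and FFT; `f_value()` against `anova(lm(...))` on 1000 random
layouts plus the $F = t^2$ identity for $K = 2$; `critical_f()` against
numerical inversion of the regularized incomplete beta function;
`ftf_map()` against the scalar per-pixel statistic; the EDF writer against
an independent Python reader; ERD injection against band-pass power.
Null calibration uses $4 \times 72$ trials and 10,000 pixels (five
20 × 100 maps), where the binomial band around the nominal 0.01 is
[0.006, 0.015]. End-to-end effect recovery runs the full pipeline at 4
channels × 40 frequencies × 1500 times × 288 trials — large enough that
injected effects must survive wavelet smearing and baseline noise, small
enough to run in about a minute; at these sizes the significance mask
covers well over half of the injected pixels and mean F inside injected
regions exceeds outside by > 5×, while an effect-free channel stays at a
null-level rate.

## Known limitations

* Per-pixel inference ignores the strong spatial/spectral/temporal
  correlation of wavelet maps; cluster-based permutation inference is out
  of scope, and the provided corrections are conservative alternatives.
* Only the omnibus F is computed; *which* conditions differ requires
  post-hoc contrasts that the package does not provide.
* Whether to feed the ANOVA baseline-normalized or raw power is a genuine
  modelling choice; normalized power is the default (it removes per-trial
  broadband gain differences), and raw power remains available by simply
  skipping `baseline_normalize()`.
* The EDF layer is minimal (16-bit continuous EDF, equal sampling rates
  across channels); EDF+ annotations and GDF are not parsed.
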