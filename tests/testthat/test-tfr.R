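test_that("Morlet kernels have unit energy, odd length, and the closed-form SD", {
  for (f in c(2, 10, 37, 90)) {
    k <- morlet_kernel(f, fs = 250)
    expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-12)
    expect_true(length(k) %% 2 == 1)
  }
  k10 <- morlet_kernel(10, fs = 250, n_cycles = 7)
  expect_equal(attr(k10, "sigma_t"), 7 / (2 * pi * 10), tolerance = 1e-12)
})

test_that("kernel spectrum peaks at the bin nearest its center frequency", {
  fs <- 250
  k <- morlet_kernel(10, fs = fs, n_cycles = 7)
  spec <- Mod(fft(as.complex(k)))
  half <- floor(length(k) / 2)
  fbin <- (0:half) * fs / length(k)
  expect_equal(fbin[which.max(spec[1:(half + 1)])], fbin[which.min(abs(fbin - 10))])
})

test_that("frequencies at or above Nyquist are rejected", {
  expect_error(morlet_kernel(125, fs = 250), class = "ftfa_frequency_error")
  expect_error(morlet_kernel(-3, fs = 250), class = "ftfa_frequency_error")
  expect_error(cwt_power(rnorm(100), numeric(0), fs = 250),
               class = "ftfa_argument_error")
})

test_that("cwt_power has one row per frequency, is non-negative, and nulls on zero input", {
  x <- rnorm(1500)
  p <- cwt_power(x, 1:100, fs = 250)
  expect_equal(dim(p), c(100, 1500))
  expect_true(all(p >= 0))
  expect_true(all(cwt_power(numeric(200), c(5, 10), fs = 100) == 0))
})

test_that("a pure sinusoid concentrates power at its own frequency", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq(0, 6, by = 1 / fs))
  p <- cwt_power(x, 1:40, fs = fs)
  interior <- seq(fs, length(x) - fs)   # >= 1 s from either edge
  peak <- apply(p[, interior], 2, which.max)
  expect_true(all(peak == 10))
})

test_that("power is quadratic in signal amplitude", {
  set.seed(21)
  x <- rnorm(600)
  p1 <- cwt_power(x, c(5, 12, 30), fs = 100)
  p3 <- cwt_power(3 * x, c(5, 12, 30), fs = 100)
  expect_equal(p3, 9 * p1, tolerance = 1e-9)
})

test_that("baseline normalization implements ratio, percent and dB per definition", {
  # power constant over time: ratio 1, percent 0, dB 0 everywhere
  const <- make_tfr_set(array(2, dim = c(1, 1, 2, 10)), fs = 10,
                        time_axis = seq(-0.5, 0.4, by = 0.1))
  expect_true(all(baseline_normalize(const, c(-0.5, 0), "ratio")$power == 1))
  expect_true(all(baseline_normalize(const, c(-0.5, 0), "percent")$power == 0))
  expect_true(all(baseline_normalize(const, c(-0.5, 0), "dB")$power == 0))

  # baseline mean 2, post-cue value 3 -> percent +50
  pw <- array(2, dim = c(1, 1, 1, 10))
  pw[1, 1, 1, 6:10] <- 3
  tf <- make_tfr_set(pw, fs = 10, time_axis = seq(-0.5, 0.4, by = 0.1))
  out <- baseline_normalize(tf, c(-0.5, 0), "percent")
  expect_equal(as.numeric(out$power[1, 1, 1, 6:10]), rep(50, 5))
  expect_equal(out$baseline_mode, "percent")
  expect_equal(out$baseline_interval, c(-0.5, 0))
})

test_that("degenerate baselines and bad intervals raise typed errors", {
  tf <- make_tfr_set(array(1, dim = c(1, 1, 1, 10)), fs = 10,
                     time_axis = seq(-0.5, 0.4, by = 0.1))
  expect_error(baseline_normalize(tf, c(-3, -2)), class = "ftfa_interval_error")
  expect_error(baseline_normalize(tf, c(0.2, 0.1)), class = "ftfa_interval_error")
  tf0 <- make_tfr_set(array(0, dim = c(1, 1, 1, 10)), fs = 10,
                      time_axis = seq(-0.5, 0.4, by = 0.1))
  expect_error(baseline_normalize(tf0, c(-0.5, 0)),
               class = "ftfa_degenerate_baseline_error")
})

test_that("ratio normalization is invariant to rescaling the raw power", {
  set.seed(31)
  pw <- array(rexp(2 * 1 * 3 * 20), dim = c(2, 1, 3, 20))
  ta <- seq(-1, 0.9, by = 0.1)
  a <- baseline_normalize(make_tfr_set(pw, fs = 10, time_axis = ta), c(-1, 0))
  b <- baseline_normalize(make_tfr_set(7.3 * pw, fs = 10, time_axis = ta), c(-1, 0))
  expect_equal(a$power, b$power, tolerance = 1e-12)
})

test_that("a stationary signal has time-averaged ratio power 1 off the epoch edges", {
  # a pure sinusoid has constant wavelet power at every analysis frequency
  # (complex kernel: no beating), so after ratio normalization the interior
  # of the epoch sits at 1 at all frequencies, on- and off-resonance
  fs <- 100
  t <- (0:(fs * 60 - 1)) / fs
  rec <- recording(matrix(20 * sin(2 * pi * 11.3 * t + 0.7), nrow = 1), fs)
  ev <- event_table(c(1200, 2400, 3600), rep("a", 3))
  ep <- epoch_extract(rec, ev, -4, 4)
  freqs <- c(5, 10, 11, 20, 30)
  tfr <- baseline_normalize(tfr_compute(ep, freqs = freqs), c(-2, 0))
  keep <- !coi_mask(freqs, length(tfr$time_axis), fs)
  for (k in seq_along(freqs)) {
    avg <- mean(tfr$power[, 1, k, keep[k, ]])
    expect_equal(avg, 1, tolerance = 0.05)
  }
})

test_that("condition-wise averaging is the exact arithmetic mean", {
  pw <- array(0, dim = c(3, 2, 2, 4))
  pw[1, , , ] <- 2; pw[2, , , ] <- 4; pw[3, , , ] <- 9
  tf <- make_tfr_set(pw, labels = c("a", "a", "b"))
  m <- average_tfr_by_condition(tf, make_groups(a = 1:2, b = 3L))
  expect_true(all(m$a == 3))            # (2 + 4) / 2
  expect_true(all(m$b == 9))            # single-trial group: identity
  expect_error(average_tfr_by_condition(tf, make_groups(a = integer(0))),
               class = "ftfa_empty_group_error")
  expect_error(average_tfr_by_condition(tf, make_groups(a = c(1L, 9L))),
               class = "ftfa_index_error")
})
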