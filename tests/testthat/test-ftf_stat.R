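test_that("degrees of freedom are (K-1, N-K)", {
  expect_equal(unname(group_dof(c(72, 72, 72, 72))), c(3L, 284L))
  expect_equal(unname(group_dof(c(2, 2))), c(1L, 2L))
  expect_error(group_dof(5), class = "ftfa_needs_two_groups_error")
  expect_error(group_dof(c(1, 1)), class = "ftfa_insufficient_replication_error")
})

test_that("between- and within-group variances match hand-worked values", {
  expect_equal(between_group_variance(list(c(5, 5), c(5, 5))), 0)
  # means 0 and 2, grand mean 1: (2*1 + 2*1) / (2 - 1)
  expect_equal(between_group_variance(list(c(0, 0), c(2, 2))), 4)
  # singleton groups 1 and 3: (1 + 1) / 1
  expect_equal(between_group_variance(list(1, 3)), 2)

  expect_equal(within_group_variance(list(c(3, 3), c(8, 8))), 0)
  # deviations +/-1 in both groups: (1+1+1+1) / (4 - 2)
  expect_equal(within_group_variance(list(c(0, 2), c(1, 3))), 2)
  expect_error(within_group_variance(list(1, 3)),
               class = "ftfa_insufficient_replication_error")
})

test_that("f_value matches the ANOVA oracle and honours degenerate conventions", {
  expect_equal(f_value(list(c(1, 2, 3), c(1, 3, 2))), 0)   # equal means
  s <- list(c(0, 0, 1, 1), c(2, 2, 3, 3))
  expect_equal(f_value(s), 24)
  expect_equal(f_value(s), oracle_anova_f(s), tolerance = 1e-12)
  expect_identical(f_value(list(c(1, 1), c(2, 2))), Inf)   # within 0, between > 0
  expect_identical(f_value(list(c(5, 5), c(5, 5))), 0)     # all identical: 0/0 -> 0
})

test_that("f_value agrees with the linear-model oracle on random grouped data", {
  set.seed(101)
  for (rep in 1:200) {
    K <- sample(2:6, 1)
    sizes <- sample(2:30, K, replace = TRUE)
    samples <- lapply(sizes, function(n) rnorm(n, mean = runif(1, -2, 2)))
    expect_equal(f_value(samples), oracle_anova_f(samples),
                 tolerance = 1e-9)
  }
})

test_that("with two groups F equals the squared pooled-variance t statistic", {
  set.seed(102)
  for (rep in 1:50) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
    tt <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f_value(list(a, b)), unname(tt^2), tolerance = 1e-9)
  }
})

test_that("F is invariant under affine rescaling of the samples", {
  set.seed(103)
  samples <- lapply(1:4, function(i) rnorm(10, mean = i))
  f0 <- f_value(samples)
  for (ab in list(c(3, 0), c(0.2, 5), c(17, -40))) {
    scaled <- lapply(samples, function(y) ab[1] * y + ab[2])
    expect_equal(f_value(scaled), f0, tolerance = 1e-9)
  }
})

test_that("ftf_map equals the per-pixel scalar F, pixel by pixel", {
  set.seed(104)
  tf <- make_tfr_set(array(rexp(9 * 2 * 3 * 4), dim = c(9, 2, 3, 4)),
                     labels = rep(c("a", "b", "c"), each = 3))
  g <- group_trials(tf)
  m <- ftf_map(tf, g)
  expect_equal(dim(m$f_values), c(2, 3, 4))
  expect_equal(m$df_between, 2L)
  expect_equal(m$df_within, 6L)
  for (ch in 1:2) for (fr in 1:3) for (ti in 1:4) {
    pix <- lapply(g, function(idx) tf$power[idx, ch, fr, ti])
    expect_equal(m$f_values[ch, fr, ti], f_value(pix), tolerance = 1e-9)
  }
})

test_that("bit-identical trials give an all-zero map under the 0/0 convention", {
  tf <- make_tfr_set(array(rep(1:24, each = 8), dim = c(8, 2, 3, 4)),
                     labels = rep(c("a", "b"), each = 4))
  m <- ftf_map(tf, group_trials(tf))
  expect_true(all(m$f_values == 0))
})

test_that("planted single-pixel effect is the global argmax", {
  # offset +10 for one group at exactly one pixel of i.i.d. noise
  set.seed(106)
  pw <- array(rnorm(40 * 1 * 6 * 8), dim = c(40, 1, 6, 8))
  labels <- rep(c("a", "b"), each = 20)
  pw[labels == "b", 1, 4, 5] <- pw[labels == "b", 1, 4, 5] + 10
  tf <- make_tfr_set(pw, labels = labels)
  m <- ftf_map(tf, group_trials(tf))
  idx <- arrayInd(which.max(m$f_values), dim(m$f_values))
  expect_equal(as.numeric(idx), c(1, 4, 5))
  expect_error(ftf_map(tf, make_groups(a = 1:20, b = c(21:39, 99L))),
               class = "ftfa_index_error")
})

test_that("critical_f inverts the upper tail of the F distribution", {
  expect_equal(critical_f(0.01, 3, 284), 3.851286, tolerance = 1e-4)
  expect_equal(critical_f(0.05, 1, 10), 4.9646, tolerance = 1e-3)
  expect_lt(critical_f(0.05, 3, 284), critical_f(0.01, 3, 284))
  # agreement with the incomplete-beta inversion oracle over a grid
  for (alpha in c(0.1, 0.05, 0.01, 0.001))
    for (df in list(c(1, 5), c(3, 284), c(2, 40), c(6, 12)))
      expect_equal(critical_f(alpha, df[1], df[2]),
                   oracle_critical_f(alpha, df[1], df[2]), tolerance = 1e-6)
  expect_error(critical_f(1.5, 3, 10), class = "ftfa_argument_error")
  expect_error(critical_f(0.05, 0, 10), class = "ftfa_argument_error")
})

test_that("significance masks honour the correction modes", {
  f <- array(0, dim = c(1, 10, 10))
  map <- structure(list(f_values = f, df_between = 3L, df_within = 284L,
                        group_sizes = c(a = 72, b = 72, c = 72, d = 72),
                        freqs = 1:10, time_axis = 1:10,
                        channel_labels = "ch1", montage = NULL,
                        baseline_mode = "ratio", coi = NULL),
                   class = "ftf_map")
  for (corr in c("none", "bonferroni", "bh-fdr"))
    expect_false(any(significance_mask(map, 0.01, corr)$mask))

  map$f_values[1, 5, 5] <- 5.0
  msk <- significance_mask(map, 0.01, "none")
  expect_true(msk$mask[1, 5, 5])                       # 5.0 > 3.851286
  expect_equal(sum(msk$mask), 1L)
  expect_equal(msk$threshold, critical_f(0.01, 3, 284))

  bon <- significance_mask(map, 0.01, "bonferroni")
  expect_equal(bon$threshold, critical_f(0.01 / 100, 3, 284))

  # BH mask is a subset of the uncorrected mask
  set.seed(107)
  map$f_values <- array(rf(100, 3, 284), dim = c(1, 10, 10))
  bh <- significance_mask(map, 0.05, "bh-fdr")
  un <- significance_mask(map, 0.05, "none")
  expect_true(all(!bh$mask | un$mask))
  expect_error(significance_mask(map, 0.05, "holm"))
})

test_that("map averaging is the element-wise mean and checks axes", {
  set.seed(108)
  tf <- make_tfr_set(array(rexp(8 * 1 * 3 * 4), dim = c(8, 1, 3, 4)),
                     labels = rep(c("a", "b"), each = 4))
  m <- ftf_map(tf, group_trials(tf))
  expect_equal(average_maps(list(m))$f_values, m$f_values)
  m2 <- m; m2$f_values[] <- 4
  m3 <- m; m3$f_values[] <- 2
  avg <- average_maps(list(m2, m3))
  expect_true(all(avg$f_values == 3))
  expect_equal(avg$averaged_n, 2L)
  m4 <- m; m4$freqs <- m$freqs + 1
  expect_error(average_maps(list(m, m4)), class = "ftfa_axis_mismatch_error")
})

test_that("band topographies average inclusive bands over time windows", {
  # F-value = its own frequency, so a band mean is the mean of the bin labels
  freqs <- 1:100
  f <- array(rep(freqs, times = 20), dim = c(1, 100, 20))
  mont <- standard_montage("C3")
  map <- structure(list(f_values = f, df_between = 3L, df_within = 284L,
                        group_sizes = c(a = 72, b = 72, c = 72, d = 72),
                        freqs = freqs, time_axis = seq(0, 1.9, by = 0.1),
                        channel_labels = "C3", montage = mont,
                        baseline_mode = "ratio", coi = NULL),
                   class = "ftf_map")
  hi <- band_topography(map, 17, 27, list(c(0, 1)))[[1]]
  expect_equal(unname(hi$channel_values), mean(17:27))   # 11 inclusive rows
  lo <- band_topography(map, 9, 15, list(c(0, 1)))[[1]]
  expect_equal(unname(lo$channel_values), mean(9:15))    # 7 inclusive rows

  # uniform map: every channel value equals the constant in every window
  map$f_values[] <- 4.2
  tp <- band_topography(map, 9, 15, list(c(0, 0.5), c(0.5, 1), c(1, 1.5)))
  expect_equal(length(tp), 3L)
  for (w in tp) expect_equal(unname(w$channel_values), 4.2)

  expect_error(band_topography(map, 150, 180, list(c(0, 1))),
               class = "ftfa_empty_selection_error")
  expect_error(band_topography(map, 9, 15, list(c(5, 6))),
               class = "ftfa_empty_selection_error")
})
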