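test_that("epoching uses the half-open window convention", {
  # -2..4 s at 250 Hz gives exactly 1500 samples per trial
  rec <- recording(matrix(rnorm(250 * 10), nrow = 1), 250)
  ev <- event_table(c(600, 1200), c("a", "b"))
  ep <- epoch_extract(rec, ev, -2, 4)
  expect_equal(dim(ep$data), c(2, 1, 1500))
  expect_equal(ep$time_axis[1], -2)
  expect_lt(max(ep$time_axis), 4)   # half-open: 4 s excluded
})

test_that("epoch sample values follow exact index arithmetic", {
  # ramp of values 0..99 at 10 Hz; event on the sample holding value 50
  rec <- ramp_recording(100, fs = 10)
  ev <- event_table(51, "a")
  ep <- epoch_extract(rec, ev, -0.2, 0.3)
  expect_equal(as.numeric(ep$data[1, 1, ]), c(48, 49, 50, 51, 52))
})

test_that("invalid and out-of-bounds epoch windows raise typed errors", {
  rec <- ramp_recording(100, fs = 10)
  ev <- event_table(51, "a")
  expect_error(epoch_extract(rec, ev, 0, 0), class = "ftfa_invalid_window_error")
  expect_error(epoch_extract(rec, ev, 2, 1), class = "ftfa_invalid_window_error")
  ev2 <- event_table(c(5, 99), c("a", "b"))
  err <- expect_error(epoch_extract(rec, ev2, -0.1, 0.5),
                      class = "ftfa_out_of_bounds_error")
  expect_match(conditionMessage(err), "event 2")
})

test_that("epoching is translation-equivariant and reconstructs the recording", {
  set.seed(11)
  x <- rnorm(400)
  fs <- 20
  for (shift in c(0L, 7L, 40L)) {
    rec <- recording(matrix(c(rep(0, shift), x), nrow = 1), fs)
    ev <- event_table(c(100, 220) + shift, c("a", "b"))
    ep <- epoch_extract(rec, ev, -1, 2)
    if (shift == 0L) ref <- ep$data
    expect_identical(ep$data, ref)
    # per-trial windows are bit-identical copies of the recording segments
    for (i in 1:2) {
      start <- ev$sample[i] + round(-1 * fs)
      expect_identical(as.numeric(ep$data[i, 1, ]),
                       as.numeric(rec$data[1, start:(start + 59)]))
    }
  }
})

test_that("group_trials partitions trials exactly by condition", {
  rec <- recording(matrix(rnorm(3000), nrow = 1), 100)
  ev <- event_table(c(500, 1000, 1500), c("A", "B", "A"))
  ep <- epoch_extract(rec, ev, -0.5, 0.5)
  g <- group_trials(ep)
  expect_equal(g$A, c(1L, 3L))
  expect_equal(g$B, 2L)
  expect_equal(sum(lengths(g)), 3L)

  # all trials one condition: a single group holding every index
  ev1 <- event_table(c(500, 1000, 1500), rep("A", 3))
  g1 <- group_trials(epoch_extract(rec, ev1, -0.5, 0.5))
  expect_equal(length(g1), 1L)
  expect_equal(g1$A, 1:3)

  # label outside the declared set is rejected
  ep_bad <- ep
  ep_bad$labels[2] <- "Z"
  expect_error(group_trials(ep_bad), class = "ftfa_label_error")
})

test_that("the full paradigm yields four groups of 72 trials", {
  ev <- generate_paradigm(6, 12, c("left", "right", "foot", "tongue"),
                          seed = 5)
  rec <- recording(matrix(0, nrow = 1, ncol = max(ev$sample) + 1100), 250)
  ep <- epoch_extract(rec, ev, -2, 4)
  g <- group_trials(ep)
  expect_equal(sort(names(g)), c("foot", "left", "right", "tongue"))
  expect_true(all(lengths(g) == 72L))
})

test_that("recording and event-table invariants are enforced", {
  expect_error(recording(matrix(c(1, NA), nrow = 1), 10),
               class = "ftfa_argument_error")
  expect_error(recording(matrix(1:4, 2), 0), class = "ftfa_argument_error")
  expect_error(recording(matrix(1:4, 2), 10, channel_labels = c("a", "a")),
               class = "ftfa_argument_error")
  expect_error(event_table(c(10, 10), c("a", "b")),
               class = "ftfa_argument_error")
  expect_error(event_table(10, "x", levels = c("a", "b")),
               class = "ftfa_label_error")
})
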