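test_that("short/long classification follows the distance rule and permutes with channels", {
  lay <- make_layout(n_long = 5, n_short = 3, long_sep_mm = 30,
                     short_sep_mm = 8, short_threshold_mm = 15)
  expect_identical(is_short(lay), channel_distance(lay) < 15)
  expect_equal(sum(is_short(lay)), 3)
  expect_equal(unname(channel_distance(lay)[1]), 30)

  perm <- sample(seq_len(nrow(lay$channels)))
  lay_p <- probe_layout(lay$source_pos, lay$detector_pos,
                        lay$channels[perm, ], lay$short_threshold_mm)
  expect_identical(is_short(lay_p), is_short(lay)[perm])

  # a channel exactly at the threshold is long (strict <)
  lay_t <- probe_layout(matrix(c(0, 0, 0), 1), matrix(c(15, 0, 0), 1),
                        cbind(1, 1))
  expect_false(is_short(lay_t))
})

test_that("layout construction validates indices and geometry", {
  src <- matrix(rnorm(9), 3)
  det <- matrix(rnorm(6), 2)
  expect_error(probe_layout(src, det, cbind(4, 1)), "source index")
  expect_error(probe_layout(src, det, cbind(1, 3)), "detector index")
  expect_error(probe_layout(src, det, matrix(numeric(0), ncol = 2)),
               "at least one channel")
  expect_error(probe_layout(src[, 1:2], det, cbind(1, 1)), "3-D")
})

test_that("default session schedule reproduces the 15-session / 75-repetition protocol", {
  sch <- session_schedule()
  expect_equal(nrow(sch), 15)
  expect_equal(sum(sch$repetitions), 75)
  s7 <- sch[sch$session == 7, ]
  expect_equal(s7$repetitions, 5)
  expect_equal(s7$block_duration_min, 5)
  expect_equal(sch$repetitions[sch$session <= 5], rep(3, 5))
  expect_equal(sch$block_duration_min[sch$session >= 11], rep(3, 5))
})

test_that("session schedule handles custom bands and rejects bad ones", {
  one <- session_schedule(data.frame(from = 1, to = 1, repetitions = 1,
                                     block_duration_min = 2))
  expect_equal(nrow(one), 1)
  expect_equal(sum(one$repetitions), 1)
  expect_error(session_schedule(data.frame(from = 1, to = 3, repetitions = 0,
                                           block_duration_min = 2)),
               "positive")
  expect_error(session_schedule(data.frame(from = c(1, 2), to = c(2, 3),
                                           repetitions = 1,
                                           block_duration_min = 2)),
               "overlap")
})

test_that("a recording declares its duration from samples and rate", {
  lay <- make_layout(n_long = 2, n_short = 0)
  rec <- recording(array(1, c(2, 2, 1500)), 5, "intensity", lay)
  expect_equal(diff(range(rec$timestamps)), (1500 - 1) / 5)
  expect_equal(length(rec$timestamps) / rec$sample_rate, 300)
})

test_that("recording construction enforces its invariants", {
  lay <- make_layout(n_long = 2, n_short = 0)
  dat <- array(1, c(2, 2, 50))
  dat[1, 1, 3] <- -1
  expect_error(recording(dat, 5, "intensity", lay), "strictly positive")
  expect_error(recording(array(1, c(3, 2, 50)), 5, "intensity", lay),
               "does not match the layout")
  # jitter beyond 1% of the sample interval
  ts <- (0:49) / 5
  ts[10] <- ts[10] + 0.1
  expect_error(recording(array(1, c(2, 2, 50)), 5, "intensity", lay,
                         timestamps = ts), "non-uniform")
  # stage transitions only run forward
  odr <- recording(array(0, c(2, 2, 50)), 5, "optical_density", lay)
  expect_error(nirskill:::set_stage(odr, odr$data, "intensity"),
               "not allowed")
})

test_that("csv bundle round trip is the identity on the container", {
  lay <- make_layout(n_long = 10, n_short = 0)
  set.seed(7)
  stim <- stim_design(c(10, 40, 80), c(20, 20, 15), rest_duration = 10)
  dat <- array(exp(rnorm(10 * 2 * 600, 0, 0.1)), c(10, 2, 600))
  rec <- recording(dat, 5, "intensity", lay, stim = stim)
  p <- file.path(tempfile("bundle"))
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$data, rec$data)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$stage, rec$stage)
  expect_equal(back$wavelengths, rec$wavelengths)
  expect_equal(back$layout$channels, rec$layout$channels)
  expect_equal(back$layout$source_pos, rec$layout$source_pos,
               ignore_attr = TRUE)
  expect_equal(length(back$stim$block_onsets), 3)
  expect_equal(back$stim$block_durations, stim$block_durations)
  expect_equal(back$timestamps, rec$timestamps)
})

test_that("concentration-stage round trip preserves chromophore labels", {
  lay <- make_layout(n_long = 3, n_short = 1)
  rec <- recording(array(rnorm(4 * 2 * 100), c(4, 2, 100)), 5,
                   "concentration", lay)
  p <- tempfile("conc")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$chromophores, c("HbO", "HbR"))
  expect_null(back$wavelengths)
  expect_equal(back$data, rec$data)
})

test_that("a written wide montage recovers its short-channel count by the distance rule", {
  lay <- make_layout(n_long = 40, n_short = 8)
  rec <- recording(array(1, c(48, 2, 20)), 5, "intensity", lay)
  p <- tempfile("wide")
  write_recording(rec, p)
  expect_equal(sum(is_short(read_recording(p)$layout)), 8)
})

test_that("degenerate and unsupported I/O fails loudly", {
  lay <- make_layout(n_long = 2, n_short = 0)
  rec <- recording(array(1, c(2, 2, 10)), 5, "intensity", lay)
  rec$data <- rec$data[0, , , drop = FALSE]   # corrupted: no channels
  expect_error(write_recording(rec, tempfile()), "no channels")
  rec2 <- recording(array(1, c(2, 2, 10)), 5, "intensity", lay)
  expect_error(write_recording(rec2, tempfile(), format = "snirf"), "HDF5")
  expect_error(read_recording(tempfile(), format = "snirf"), "HDF5")
  p <- tempfile("nolayout")
  write_recording(rec2, p)
  unlink(file.path(p, "layout.json"))
  expect_error(read_recording(p), "no layout")
})
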