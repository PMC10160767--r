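test_that("the same seed reproduces a simulation bit for bit", {
  lay <- make_layout(n_long = 3, n_short = 2)
  st <- test_stim(2)
  truth <- simulation_truth(lay, seed = 5)
  a <- simulate_hemodynamics(truth, st, stim_duration(st), fs = 5)
  b <- simulate_hemodynamics(truth, st, stim_duration(st), fs = 5)
  expect_identical(a$data, b$data)
  c <- simulate_hemodynamics(simulation_truth(lay, seed = 6), st,
                             stim_duration(st), fs = 5)
  expect_false(identical(a$data, c$data))
})

test_that("null task amplitude leaves only the shared nuisance structure", {
  # amplitude 0, gain 1, no noise/drift: a long channel must equal a short
  # channel sample for sample (both carry superficial + physio only)
  lay <- make_layout(n_long = 2, n_short = 1)
  st <- test_stim(2)
  truth <- quiet_truth(lay, hrf_amplitude = 0, superficial_sd = 0.4,
                       physio = default_physio(), seed = 3)
  rec <- simulate_hemodynamics(truth, st, stim_duration(st), fs = 5)
  short_i <- which(is_short(rec$layout))
  long_i <- which(!is_short(rec$layout))
  expect_equal(rec$data[long_i[1], 1, ], rec$data[short_i, 1, ],
               tolerance = 1e-12)
})

test_that("the noiseless task component equals the closed-form convolution", {
  lay <- make_layout(n_long = 2, n_short = 1)
  st <- test_stim(3)
  dur <- stim_duration(st)
  truth <- quiet_truth(lay, hrf_amplitude = c(1, 2.5), seed = 1)
  rec <- simulate_hemodynamics(truth, st, dur, fs = 5)
  oracle <- task_response_truth(st, dur, fs = 5)
  expect_equal(rec$data[1, 1, ], oracle, tolerance = 1e-10)
  expect_equal(rec$data[2, 1, ], 2.5 * oracle, tolerance = 1e-10)
  # HbR is -1/3 of the HbO task component by default
  expect_equal(rec$data[1, 2, ], -oracle / 3, tolerance = 1e-10)
  # block-averaged response peak: within 5% of the closed-form peak
  expect_lt(abs(max(rec$data[1, 1, ]) - max(oracle)) / max(oracle), 0.05)
})

test_that("stimulus blocks outside the simulated duration are rejected", {
  lay <- make_layout(n_long = 1, n_short = 1)
  st <- stim_design(50, 100, rest_duration = 10)
  expect_error(simulate_hemodynamics(quiet_truth(lay), st, duration = 100),
               "beyond the simulation duration")
})

test_that("forward MBLL to intensity is exact and linear", {
  lay <- make_layout(n_long = 2, n_short = 1)
  # zero concentration gives constant baseline intensity
  conc0 <- recording(array(0, c(3, 2, 40)), 5, "concentration", lay)
  int0 <- to_intensity(conc0, baseline_od = 0.3)
  expect_equal(as.vector(int0$data), rep(10^-0.3, 3 * 2 * 40))

  # doubling HbO with HbR fixed doubles the HbO-attributable OD component
  ext <- default_extinction()
  d_cm <- channel_distance(lay)[1] / 10
  conc1 <- conc0; conc1$data[1, 1, ] <- 1      # 1 uM HbO
  conc2 <- conc0; conc2$data[1, 1, ] <- 2
  od1 <- -log10(to_intensity(conc1)$data[1, , 1])
  od2 <- -log10(to_intensity(conc2)$data[1, , 1])
  expect_equal(od2, 2 * od1, tolerance = 1e-12)
  expect_equal(od1, d_cm * ext$eps[, "HbO"] * 1e-3, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("intensity -> OD -> concentration recovers simulated hemodynamics", {
  # the OD reference is the temporal mean, so recovery is exact up to a
  # per-channel constant; compare centered series
  lay <- make_layout(n_long = 3, n_short = 1)
  st <- test_stim(2)
  truth <- simulation_truth(lay, motion_spike_rate = 0, motion_shift_rate = 0,
                            seed = 9)
  conc <- simulate_hemodynamics(truth, st, stim_duration(st), fs = 5)
  back <- od_to_concentration(intensity_to_od(to_intensity(conc)))
  center <- function(a) sweep(a, 1:2, rowMeans(a, dims = 2))
  expect_equal(center(back$data), center(conc$data), tolerance = 1e-9)
})

test_that("behavioral trials decay to their asymptotes and improve", {
  bt <- behavioral_truth("good", seed = 2, t0 = 500, t_inf = 100, tau = 8,
                         noise_sd_time = 0, noise_sd_penalty = 0,
                         noise_sd_dev = 0)
  tr <- simulate_trials(bt, 200)
  expect_lt(abs(tr$completion_time[200] - 100), 1e-6)
  expect_true(all(diff(tr$completion_time) <= 0))

  tr_g <- simulate_trials(behavioral_truth("good", seed = 1), 75)
  expect_lt(mean(tail(tr_g$completion_time, 3)),
            mean(head(tr_g$completion_time, 3)))
  expect_gt(mean(tail(tr_g$score, 3)), mean(head(tr_g$score, 3)))
})

test_that("default cohorts reproduce the published day-1 completion time", {
  # Monte-Carlo over 100 cohorts of 21 trainees (12 good / 9 weak)
  day1 <- vapply(1:100, function(c) {
    mean(vapply(1:21, function(s) {
      bt <- behavioral_truth(if (s <= 12) "good" else "weak",
                             seed = c * 1000 + s)
      mean(simulate_trials(bt, 3)$completion_time)
    }, numeric(1)))
  }, numeric(1))
  se <- sd(day1) / sqrt(length(day1))
  expect_lt(abs(mean(day1) - 483.22), 2 * se + 1e-9)
})

test_that("a written study bundle is deterministic and structured per protocol", {
  cfg <- study_config(n_subjects = 2, n_good = 1,
                      layout = make_layout(n_long = 4, n_short = 2),
                      roles = list(prefrontal = 1:2, sensorimotor = 3:4,
                                   null = integer(0)),
                      task_block_s = 20, rest_s = 20)
  d1 <- tempfile("study1"); d2 <- tempfile("study2")
  b1 <- simulate_study(cfg, seed = 11, out_dir = d1)
  b2 <- simulate_study(cfg, seed = 11, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))

  # 15 training sessions + 1 retention session per subject
  expect_equal(length(b1$subjects[[1]]$sessions), 16)
  expect_true(dir.exists(file.path(d1, "P01", "session-16")))
  tr <- utils::read.csv(file.path(d1, "trials.csv"))
  expect_equal(sum(tr$session <= 15) / 2, 75)

  # designated channels are elevated on day 15 in the ground truth
  for (sub in b1$subjects) {
    a1 <- sub$amplitudes[["1"]]
    a15 <- sub$amplitudes[["15"]]
    expect_true(all(a15[cfg$roles$sensorimotor] >
                      a1[cfg$roles$sensorimotor]))
  }
})
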