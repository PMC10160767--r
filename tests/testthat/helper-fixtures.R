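# Shared fixtures: everything is generated in code at test time.

# a noiseless truth: task response only (no nuisance, no artifacts)
quiet_truth <- function(layout, ...) {
  args <- list(layout = layout, superficial_sd = 0, noise_sd = 0,
               physio = data.frame(label = "none", freq = 0.3, amp = 0),
               drift_slope = 0, motion_spike_rate = 0, motion_shift_rate = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_truth, args)
}

# standard desk-scale stimulus: onset spacing beyond the 62 s basis span
test_stim <- function(n_blocks = 4, task_s = 25, rest_s = 45) {
  stim_design(rest_s + (seq_len(n_blocks) - 1) * (task_s + rest_s), task_s,
              rest_duration = rest_s)
}

stim_duration <- function(stim, tail_s = 70) {
  max(stim$block_onsets + stim$block_durations) + tail_s
}

# random positive intensity recording
random_intensity <- function(n_ch = 3, n = 400, fs = 5, seed = 1,
                             stim = NULL) {
  set.seed(seed)
  lay <- make_layout(n_long = n_ch, n_short = 0)
  data <- array(exp(stats::rnorm(n_ch * 2 * n, 0, 0.05)), c(n_ch, 2, n))
  recording(data, fs, "intensity", lay, stim = stim)
}

# an hrf_estimates skeleton with a prescribed HRF curve per channel
manual_estimates <- function(hrf_list, fs = 5, t_min = -2, t_max = 60,
                             meta = list()) {
  time <- seq(t_min, t_max, by = 1 / fs)
  nch <- length(hrf_list)
  hrf <- array(0, c(nch, 1, length(time)),
               dimnames = list(sprintf("S%dD%d", seq_len(nch), seq_len(nch)),
                               "HbO", NULL))
  for (i in seq_len(nch)) hrf[i, 1, ] <- hrf_list[[i]]
  structure(list(channels = dimnames(hrf)[[1]], chromophores = "HbO",
                 time = time, hrf = hrf,
                 beta = array(0, c(nch, 1, 1)),
                 rss = matrix(1, nch, 1), residual_variance = matrix(1, nch, 1),
                 dof = matrix(10, nch, 1), meta = meta),
            class = "hrf_estimates")
}

# small null study configuration for calibration runs
null_study_config <- function(n_subjects = 5) {
  study_config(n_subjects = n_subjects, n_good = 3,
               layout = make_layout(n_long = 4, n_short = 2),
               roles = list(prefrontal = integer(0),
                            sensorimotor = integer(0), null = 1:4),
               amp_prefrontal = c(day1 = 0, day15 = 0),
               amp_sensorimotor = c(day1 = 0, day15 = 0),
               good_day15_boost = 0, amp_subject_sd = 0, amp_day_sd = 0,
               sessions = 1L, include_retention = FALSE,
               task_block_s = 25, rest_s = 45)
}

# desk-scale effect-structure study for power runs
power_study_config <- function() {
  study_config(n_subjects = 21, n_good = 12,
               layout = make_layout(n_long = 10, n_short = 2),
               roles = list(prefrontal = integer(0), sensorimotor = 1:3,
                            null = 4:10),
               sessions = c(1L, 15L), include_retention = FALSE,
               task_block_s = 25, rest_s = 45)
}
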