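# Forward model for synthetic fNIRS studies. Every generator is a pure
# function of its seed (the global RNG state is saved and restored), so
# recovery-based tests have exact ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Canonical double-gamma hemodynamic response
#'
#' Ground-truth HRF kernel: a positive gamma lobe peaking at `peak_time`
#' minus a later undershoot lobe, normalized to unit peak. This is
#' deliberately *not* the Gaussian estimation basis, so recovery tests carry
#' a realistic model mismatch.
#'
#' @param t time since onset, seconds (response is zero for `t < 0`).
#' @param peak_time mode of the positive lobe, seconds (default 6).
#' @param undershoot_time mode of the undershoot lobe, seconds (default 16).
#' @param undershoot_ratio undershoot amplitude relative to the peak
#'   (default 1/6).
#' @return numeric vector of HRF values, unit peak.
#' @export
canonical_hrf <- function(t, peak_time = 6, undershoot_time = 16,
                          undershoot_ratio = 1 / 6) {
  g1 <- stats::dgamma(t, shape = peak_time + 1, rate = 1)
  g2 <- stats::dgamma(t, shape = undershoot_time + 1, rate = 1)
  h <- g1 / max(g1) - undershoot_ratio * g2 / max(g2)
  h[t < 0] <- 0
  h / max(h)
}

#' Default physiological oscillation components
#'
#' Cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.10 Hz)
#' sinusoids with typical micromolar amplitudes. The Mayer component sits at
#' the bandpass edge on purpose, stressing the filter design.
#'
#' @return data frame with columns `label`, `freq` (Hz), `amp` (uM).
#' @export
default_physio <- function() {
  data.frame(label = c("cardiac", "respiration", "mayer"),
             freq = c(1.1, 0.25, 0.10),
             amp = c(0.15, 0.08, 0.10))
}

#' Ground truth for one hemodynamic simulation
#'
#' Collects everything the forward model needs: per-channel task amplitudes,
#' the superficial (scalp) process shared between short and long channels,
#' physiological oscillations, drift, motion artifacts and measurement noise.
#' The seed fully determines every generated sample.
#'
#' @param layout a [probe_layout()]; amplitudes/gains are recycled to the
#'   long-channel count.
#' @param hrf_amplitude HbO task response amplitude per long channel, uM.
#' @param hrf_peak_time canonical HRF peak time, seconds.
#' @param hbr_ratio HbR task amplitude = `-hbr_ratio` x HbO amplitude
#'   (default 1/3, the typical empirical ratio).
#' @param superficial_gain unitless coupling of each long channel to the
#'   shared superficial process.
#' @param superficial_sd standard deviation of the superficial process, uM.
#' @param physio data frame of `(freq, amp)` sinusoid components; phases are
#'   drawn from the seed and shared across channels (systemic origin).
#' @param drift_slope slow linear drift, uM/s (recycled per channel).
#' @param motion_spike_rate,motion_shift_rate expected artifact counts per
#'   minute.
#' @param motion_spike_mag,motion_shift_mag artifact magnitudes, uM.
#' @param noise_sd white measurement noise SD, uM.
#' @param adaptation_tau sustained-block adaptation time constant, seconds;
#'   the neural drive during a block decays as `exp(-t_in_block/tau)`
#'   (`Inf` = fully sustained drive, the default).
#' @param hbr_nuisance_scale scale of the independent HbR nuisance processes
#'   relative to the HbO ones.
#' @param seed integer seed.
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(layout, hrf_amplitude = 1, hrf_peak_time = 6,
                             hbr_ratio = 1 / 3, superficial_gain = 1,
                             superficial_sd = 0.4, physio = default_physio(),
                             drift_slope = 2e-4,
                             motion_spike_rate = 0.2, motion_shift_rate = 0.05,
                             motion_spike_mag = 5, motion_shift_mag = 3,
                             noise_sd = 0.05, adaptation_tau = Inf,
                             hbr_nuisance_scale = 0.5, seed = 1) {
  stopifnot(inherits(layout, "probe_layout"))
  n_long <- sum(!is_short(layout))
  amp <- rep_len(hrf_amplitude, n_long)
  gain <- rep_len(superficial_gain, n_long)
  drift <- rep_len(drift_slope, n_long)
  if (any(!is.finite(amp))) stop("amplitudes must be finite")
  if (any(physio$freq <= 0)) stop("physiological frequencies must be positive")
  structure(list(layout = layout, hrf_amplitude = amp,
                 hrf_peak_time = hrf_peak_time, hbr_ratio = hbr_ratio,
                 superficial_gain = gain, superficial_sd = superficial_sd,
                 physio = physio, drift_slope = drift,
                 motion_spike_rate = motion_spike_rate,
                 motion_shift_rate = motion_shift_rate,
                 motion_spike_mag = motion_spike_mag,
                 motion_shift_mag = motion_shift_mag,
                 noise_sd = noise_sd, adaptation_tau = adaptation_tau,
                 hbr_nuisance_scale = hbr_nuisance_scale,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# smooth band-limited random process: random-phase sinusoid bank, 1/sqrt(f)
# amplitudes over ~0.004-0.09 Hz, normalized to unit SD
slow_process <- function(t) {
  freqs <- exp(seq(log(0.004), log(0.09), length.out = 12))
  amps <- 1 / sqrt(freqs)
  ph <- stats::runif(length(freqs), 0, 2 * pi)
  x <- drop(cos(outer(t, 2 * pi * freqs) + rep(ph, each = length(t))) %*% amps)
  x / stats::sd(x)
}

# Task drive convolved with the canonical HRF, evaluated at the sample grid.
# The kernel is normalized to unit sum, so a sustained block plateaus at the
# channel's `hrf_amplitude` (uM) - that is the amplitude convention.
convolve_drive <- function(drive, fs, peak_time) {
  th <- seq(0, 40, by = 1 / fs)
  h <- canonical_hrf(th, peak_time = peak_time)
  h <- h / sum(h)
  n <- length(drive)
  nh <- length(h)
  y <- stats::filter(c(numeric(nh - 1), drive), h, method = "convolution",
                     sides = 1)
  as.numeric(y[nh - 1 + seq_len(n)])
}

# boxcar (with optional within-block adaptation) on the sample grid
stim_drive <- function(stim, t, adaptation_tau) {
  u <- numeric(length(t))
  for (b in seq_along(stim$block_onsets)) {
    on <- stim$block_onsets[b]
    idx <- which(t >= on & t < on + stim$block_durations[b])
    if (!length(idx)) next
    u[idx] <- if (is.finite(adaptation_tau))
      exp(-(t[idx] - on) / adaptation_tau) else 1
  }
  u
}

#' Simulate block-locked hemodynamics
#'
#' Forward model of the assumed signal decomposition. Long-channel HbO is
#' `amplitude x (canonical HRF convolved with the block drive) +
#' gain x superficial + physiological oscillations + drift + white noise`;
#' short channels carry the superficial, physiological and noise terms only
#' (no task response). HbR carries `-hbr_ratio` times the task component
#' plus independent nuisance draws (its own superficial/physiological
#' processes, shared between long and short channels, scaled by
#' `hbr_nuisance_scale`). Motion artifacts - Gaussian-shaped spikes of 0.5 s
#' width and step baseline shifts - hit all channels with channel-specific
#' random scaling. The returned recording embeds short and long channels
#' (concentration stage, uM) with the stimulus attached.
#'
#' @param truth a [simulation_truth()].
#' @param stim a [stim_design()].
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz (default 5).
#' @return a concentration-stage [recording()].
#' @export
simulate_hemodynamics <- function(truth, stim, duration, fs = 5) {
  stopifnot(inherits(truth, "simulation_truth"), inherits(stim, "stim_design"))
  if (any(stim$block_onsets + stim$block_durations > duration))
    stop("stimulus blocks extend beyond the simulation duration")
  if (any(truth$physio$freq >= fs / 2))
    stop("physiological frequencies must lie below the Nyquist frequency")
  layout <- truth$layout
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  short <- is_short(layout)
  long_idx <- which(!short)
  short_idx <- which(short)
  nch <- n_channels(layout)

  with_seed(truth$seed, {
    sup_hbo <- slow_process(t) * truth$superficial_sd
    sup_hbr <- slow_process(t) * truth$superficial_sd * truth$hbr_nuisance_scale
    ph_hbo <- stats::runif(nrow(truth$physio), 0, 2 * pi)
    ph_hbr <- stats::runif(nrow(truth$physio), 0, 2 * pi)
    physio_of <- function(ph, scale) {
      drop(cos(outer(t, 2 * pi * truth$physio$freq) +
                 rep(ph, each = n)) %*% (truth$physio$amp * scale))
    }
    phys_hbo <- physio_of(ph_hbo, 1)
    phys_hbr <- physio_of(ph_hbr, truth$hbr_nuisance_scale)

    drive <- stim_drive(stim, t, truth$adaptation_tau)
    resp <- convolve_drive(drive, fs, truth$hrf_peak_time)

    # motion events shared in time, channel-specific multiplier
    dur_min <- duration / 60
    n_spike <- stats::rpois(1, truth$motion_spike_rate * dur_min)
    n_shift <- stats::rpois(1, truth$motion_shift_rate * dur_min)
    spikes <- if (n_spike) data.frame(time = stats::runif(n_spike, 0, duration),
                                      mag = truth$motion_spike_mag *
                                        stats::rnorm(n_spike, 1, 0.2)) else NULL
    shifts <- if (n_shift) data.frame(time = stats::runif(n_shift, 0, duration),
                                      mag = truth$motion_shift_mag *
                                        stats::rnorm(n_shift, 1, 0.2)) else NULL
    motion_series <- numeric(n)
    if (!is.null(spikes)) for (k in seq_len(nrow(spikes)))
      motion_series <- motion_series +
        spikes$mag[k] * exp(-(t - spikes$time[k])^2 / (2 * 0.25^2))
    if (!is.null(shifts)) for (k in seq_len(nrow(shifts)))
      motion_series <- motion_series + shifts$mag[k] * (t >= shifts$time[k])
    motion_mult <- stats::rnorm(nch, 1, 0.3)

    data <- array(0, dim = c(nch, 2, n))
    for (j in seq_along(long_idx)) {
      i <- long_idx[j]
      task <- truth$hrf_amplitude[j] * resp
      data[i, 1, ] <- task +
        truth$superficial_gain[j] * sup_hbo + phys_hbo +
        truth$drift_slope[j] * t +
        stats::rnorm(n, 0, truth$noise_sd)
      data[i, 2, ] <- -truth$hbr_ratio * task +
        truth$superficial_gain[j] * sup_hbr + phys_hbr +
        stats::rnorm(n, 0, truth$noise_sd * truth$hbr_nuisance_scale)
    }
    for (i in short_idx) {
      data[i, 1, ] <- sup_hbo + phys_hbo + stats::rnorm(n, 0, truth$noise_sd)
      data[i, 2, ] <- sup_hbr + phys_hbr +
        stats::rnorm(n, 0, truth$noise_sd * truth$hbr_nuisance_scale)
    }
    for (i in seq_len(nch)) {
      data[i, 1, ] <- data[i, 1, ] + motion_mult[i] * motion_series
      data[i, 2, ] <- data[i, 2, ] - 0.3 * motion_mult[i] * motion_series
    }
    recording(data, fs, "concentration", layout, stim = stim)
  })
}

#' Convolved task-response truth
#'
#' The generator's noiseless task component for unit amplitude: the canonical
#' HRF convolved with the block drive, on the recording grid. Used as the
#' closed-form oracle in recovery tests.
#'
#' @param stim a [stim_design()].
#' @param duration,fs as in [simulate_hemodynamics()].
#' @param peak_time,adaptation_tau forward-model parameters.
#' @return numeric vector of length `duration * fs`.
#' @export
task_response_truth <- function(stim, duration, fs = 5, peak_time = 6,
                                adaptation_tau = Inf) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  convolve_drive(stim_drive(stim, t, adaptation_tau), fs, peak_time)
}

#' Forward modified Beer-Lambert model: concentrations to intensity
#'
#' Inverse of the preprocessing chain, so it can be tested end to end:
#' concentration changes (uM) are mapped to optical-density changes through
#' the same 2x2 extinction system (distances in cm, identical partial
#' pathlength factors), then to intensity `I = I0 * 10^(-dOD)`.
#'
#' @param conc a concentration-stage [recording()].
#' @param baseline_od constant baseline optical density added to the
#'   modelled changes (sets the mean light level; default 0, i.e. `I0 = 1`).
#' @param ext an [extinction_table()].
#' @param cfg a [preprocess_config()] (partial pathlength factors).
#' @return an intensity-stage [recording()].
#' @export
to_intensity <- function(conc, baseline_od = 0, ext = default_extinction(),
                         cfg = preprocess_config()) {
  stopifnot(inherits(conc, "nirs_recording"))
  if (conc$stage != "concentration")
    stop("expected a concentration-stage recording")
  dist_cm <- channel_distance(conc$layout) / 10
  nd <- dim(conc$data)
  out <- array(0, dim = nd)
  for (i in seq_len(nd[1])) {
    M <- mbll_matrix(dist_cm[i], ext, cfg$ppf)
    if (kappa(M) >= 1e4) stop("singular extinction matrix")
    dod <- M %*% (conc$data[i, , ] / 1000)   # uM -> mM
    out[i, , ] <- 10^(-(dod + baseline_od))
  }
  recording(out, conc$sample_rate, "intensity", conc$layout,
            wavelengths = ext$wavelengths, stim = conc$stim,
            timestamps = conc$timestamps)
}

#' Ground truth for one trainee's behavioral learning curve
#'
#' Completion time and penalty decay exponentially with repetition toward a
#' subject-specific asymptote. Subject-level parameters are drawn from
#' class-specific populations ("good" and "weak" learners); the population
#' means are calibrated so that a default cohort reproduces the published
#' day-1 and final-day (time, deviation, score) summaries jointly.
#'
#' @param class `"good"` or `"weak"`.
#' @param seed integer seed for the subject-level draws.
#' @param ... named overrides of any drawn parameter (`t0`, `t_inf`, `tau`,
#'   `penalty0`, `penalty_inf`, `penalty_tau`, `dev0`, `dev_inf`, `dev_tau`,
#'   `noise_sd_time`, `noise_sd_penalty`, `noise_sd_dev`).
#' @return an object of class `behavioral_truth`.
#' @export
behavioral_truth <- function(class = c("good", "weak"), seed = 1, ...) {
  class <- match.arg(class)
  over <- list(...)
  p <- with_seed(seed, {
    good <- class == "good"
    list(
      t0 = max(250, stats::rnorm(1, 524, 95)),
      t_inf = max(60, stats::rnorm(1, if (good) 95 else 120,
                                   if (good) 15 else 18)),
      tau = max(2, stats::rlnorm(1, log(if (good) 9 else 16),
                                 if (good) 0.7 else 0.35)),
      penalty0 = max(5, stats::rnorm(1, 92, 25)),
      penalty_inf = max(5, stats::rnorm(1, if (good) 40 else 55,
                                        if (good) 10 else 12)),
      penalty_tau = 40,
      dev0 = max(0.2, stats::rnorm(1, 1.47, 0.8)),
      dev_inf = max(0.05, stats::rnorm(1, if (good) 0.45 else 0.75,
                                       if (good) 0.2 else 0.25)),
      dev_tau = 25,
      noise_sd_time = 25, noise_sd_penalty = 12, noise_sd_dev = 0.5)
  })
  p[names(over)] <- over
  p$t_inf <- min(p$t_inf, p$t0 - 50)       # asymptote below the start
  p$penalty_inf <- min(p$penalty_inf, p$penalty0)
  if (p$tau <= 0) stop("tau must be positive")
  p$class <- class
  p$seed <- as.integer(seed)
  structure(p, class = "behavioral_truth")
}

exp_curve <- function(r, start, asymptote, tau) {
  asymptote + (start - asymptote) * exp(-(r - 1) / tau)
}

#' Simulate a trainee's trial log
#'
#' One row per repetition: completion time, target deviation, penalty and the
#' resulting performance score (via [score_trial()]). Times are floored at a
#' positive minimum; penalties and deviations at zero.
#'
#' @param truth a [behavioral_truth()].
#' @param n_reps number of repetitions (default 75).
#' @param scoring a [score_config()].
#' @param seed seed for the trial-level noise (defaults to `truth$seed + 1`).
#' @return data frame with columns `repetition`, `completion_time`,
#'   `deviation_mm`, `penalty`, `score`.
#' @export
simulate_trials <- function(truth, n_reps = 75, scoring = score_config(),
                            seed = truth$seed + 1) {
  stopifnot(inherits(truth, "behavioral_truth"), n_reps >= 1)
  with_seed(seed, {
    r <- seq_len(n_reps)
    time <- pmax(30, exp_curve(r, truth$t0, truth$t_inf, truth$tau) +
                   stats::rnorm(n_reps, 0, truth$noise_sd_time))
    dev <- pmax(0, exp_curve(r, truth$dev0, truth$dev_inf, truth$dev_tau) +
                  stats::rnorm(n_reps, 0, truth$noise_sd_dev))
    pen <- pmax(0, exp_curve(r, truth$penalty0, truth$penalty_inf,
                             truth$penalty_tau) +
                  stats::rnorm(n_reps, 0, truth$noise_sd_penalty))
    data.frame(repetition = r, completion_time = time, deviation_mm = dev,
               penalty = pen, score = score_trial(time, pen, scoring))
  })
}
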