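#' Study configuration
#'
#' The stated world of a synthetic training study: 21 trainees (12 good / 9
#' weak learners), 15 training sessions on the banded schedule (3 reps x
#' 10 min, 5 x 5 min, 7 x 3 min; 75 repetitions) plus one retention session,
#' 2-min rest blocks, 5 Hz dual-wavelength acquisition on a 16-long /
#' 8-short-channel montage. Task amplitudes are assigned by channel role:
#' prefrontal channels are active throughout training, sensorimotor channels
#' start near-silent and are elevated by the final day (the effect structure
#' the day-15 vs day-1 contrast must detect), and the remaining channels are
#' null. `task_block_s`/`rest_s` exist so desk-scale test runs can shorten
#' blocks without touching the protocol's session/repetition structure.
#'
#' @param n_subjects cohort size (default 21).
#' @param n_good number of good learners (default 12).
#' @param layout a [probe_layout()].
#' @param roles list of long-channel index vectors: `prefrontal`,
#'   `sensorimotor`, `null`.
#' @param amp_prefrontal HbO amplitude (uM) of prefrontal channels,
#'   `c(day1, day15)`.
#' @param amp_sensorimotor HbO amplitude of sensorimotor channels,
#'   `c(day1, day15)`; the day-15 elevation is the generator's default
#'   effect size.
#' @param good_day15_boost extra day-15 sensorimotor amplitude for good
#'   learners (uM).
#' @param amp_subject_sd between-subject SD of channel amplitudes (uM).
#' @param amp_day_sd between-subject SD of the day-15 minus day-1 amplitude
#'   difference (uM).
#' @param schedule a [session_schedule()] data frame.
#' @param sessions sessions to simulate (default all in the schedule).
#' @param include_retention add a retention session 4 weeks after training.
#' @param retention_reps,retention_block_min retention session structure.
#' @param task_block_s override of every practice-block duration, seconds
#'   (default `NULL` = use the schedule's block durations).
#' @param rest_s rest-block duration, seconds (default 120).
#' @param fs sampling rate, Hz.
#' @param scoring a [score_config()].
#' @param lc_params an [lc_cusum_params()].
#' @param retention_time_factor,retention_penalty_factor mild skill decay at
#'   the retention session (multipliers on the asymptotic time/penalty).
#' @param ... overrides passed to [simulation_truth()] (noise, superficial,
#'   physiology, motion, ...).
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_subjects = 21, n_good = 12,
                         layout = make_layout(),
                         roles = list(prefrontal = 1:6, sensorimotor = 7:12,
                                      null = 13:16),
                         amp_prefrontal = c(day1 = 0.5, day15 = 0.5),
                         amp_sensorimotor = c(day1 = 0.1, day15 = 0.5),
                         good_day15_boost = 0.15,
                         amp_subject_sd = 0.12, amp_day_sd = 0.05,
                         schedule = session_schedule(),
                         sessions = NULL,
                         include_retention = TRUE,
                         retention_reps = 3, retention_block_min = 3,
                         task_block_s = NULL, rest_s = 120, fs = 5,
                         scoring = score_config(),
                         lc_params = lc_cusum_params(),
                         retention_time_factor = 1.10,
                         retention_penalty_factor = 1.20,
                         ...) {
  stopifnot(n_good <= n_subjects)
  n_long <- sum(!is_short(layout))
  if (max(unlist(roles)) > n_long) stop("channel roles exceed the montage")
  if (is.null(sessions)) sessions <- schedule$session
  if (!all(sessions %in% schedule$session))
    stop("requested sessions missing from the schedule")
  structure(list(n_subjects = n_subjects, n_good = n_good, layout = layout,
                 roles = roles, amp_prefrontal = amp_prefrontal,
                 amp_sensorimotor = amp_sensorimotor,
                 good_day15_boost = good_day15_boost,
                 amp_subject_sd = amp_subject_sd, amp_day_sd = amp_day_sd,
                 schedule = schedule, sessions = sessions,
                 include_retention = include_retention,
                 retention_reps = retention_reps,
                 retention_block_min = retention_block_min,
                 task_block_s = task_block_s, rest_s = rest_s, fs = fs,
                 scoring = scoring, lc_params = lc_params,
                 retention_time_factor = retention_time_factor,
                 retention_penalty_factor = retention_penalty_factor,
                 truth_args = list(...)),
            class = "study_config")
}

#' A small, fast demonstration configuration
#'
#' Four subjects, sessions 1/8/15, shortened practice (25 s) and rest (20 s)
#' blocks, a 6-long / 2-short montage - small enough for examples and smoke
#' tests while exercising every pipeline stage.
#'
#' @param ... overrides forwarded to [study_config()].
#' @return a `study_config`.
#' @export
demo_config <- function(...) {
  args <- list(n_subjects = 4, n_good = 2,
               layout = make_layout(n_long = 6, n_short = 2),
               roles = list(prefrontal = 1:2, sensorimotor = 3:4, null = 5:6),
               sessions = c(1L, 8L, 15L),
               include_retention = TRUE,
               task_block_s = 25, rest_s = 45)
  over <- list(...)
  args[names(over)] <- over
  do.call(study_config, args)
}

# fold any number of integers into one seed strictly below 2^31
derive_seed <- function(...) {
  s <- 0
  for (x in c(...)) s <- (s * 1000003 + as.double(x)) %% 2146483647
  as.integer(s)
}

# session stimulus design under a config
session_stim <- function(config, session_row) {
  reps <- session_row$repetitions
  block_s <- if (!is.null(config$task_block_s)) config$task_block_s else
    session_row$block_duration_min * 60
  rest <- config$rest_s
  onsets <- rest + (seq_len(reps) - 1) * (block_s + rest)
  stim_design(onsets, block_s, rest_duration = rest)
}

session_duration <- function(config, session_row) {
  st <- session_stim(config, session_row)
  max(st$block_onsets + st$block_durations) + config$rest_s
}

# per-subject, per-session channel amplitude vector (HbO, uM)
subject_amplitudes <- function(config, session, base_jitter, day_jitter,
                               good) {
  n_long <- sum(!is_short(config$layout))
  frac <- (min(session, 15) - 1) / 14        # retention holds day-15 levels
  amp <- numeric(n_long)
  amp[config$roles$prefrontal] <-
    config$amp_prefrontal[1] + frac * diff(config$amp_prefrontal)
  boost <- if (good) config$good_day15_boost else 0
  amp[config$roles$sensorimotor] <-
    config$amp_sensorimotor[1] +
    frac * (diff(config$amp_sensorimotor) + boost)
  pmax(0, amp + base_jitter + frac * day_jitter)
}

#' Simulate a full training study
#'
#' Generates, per subject: a behavioral trial log over all sessions (plus
#' retention) and one intensity-stage recording per requested session, whose
#' underlying concentration ground truth follows the configured channel-role
#' amplitude structure. Every random draw descends from `seed`, so the same
#' seed reproduces the study bit for bit. With `out_dir` the study is written
#' to disk as a bundle (per-subject/per-session csv_bundle recordings,
#' `trials.csv`, `truth.json`); otherwise it is returned in memory.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return invisibly, the study bundle: list with `subjects` (each holding
#'   `class`, `trials`, `amplitudes`, and `sessions` - recordings when in
#'   memory, bundle paths when written), `truth`, and `config`.
#' @export
simulate_study <- function(config = study_config(), seed = 1,
                           out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  sched <- config$schedule
  classes <- rep(c("good", "weak"),
                 c(config$n_good, config$n_subjects - config$n_good))
  n_long <- sum(!is_short(config$layout))
  sessions_all <- if (config$include_retention)
    c(config$sessions, 16L) else config$sessions

  subjects <- vector("list", config$n_subjects)
  truth_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("P%02d", s)
    sseed <- derive_seed(seed, s)
    good <- classes[s] == "good"
    btruth <- behavioral_truth(classes[s], seed = sseed)
    jit <- with_seed(sseed + 500L, list(
      base = stats::rnorm(n_long, 0, config$amp_subject_sd),
      day = stats::rnorm(n_long, 0, config$amp_day_sd)))

    # behavioral log across the full protocol
    all_tr <- simulate_trials(btruth, n_reps = sum(sched$repetitions),
                              scoring = config$scoring, seed = sseed + 1L)
    all_tr$session <- rep(sched$session, sched$repetitions)
    if (config$include_retention) {
      ret <- with_seed(sseed + 2L, {
        time <- pmax(30, btruth$t_inf * config$retention_time_factor +
                       stats::rnorm(config$retention_reps, 0,
                                    btruth$noise_sd_time))
        pen <- pmax(0, btruth$penalty_inf * config$retention_penalty_factor +
                      stats::rnorm(config$retention_reps, 0,
                                   btruth$noise_sd_penalty))
        dev <- pmax(0, btruth$dev_inf * 1.3 +
                      stats::rnorm(config$retention_reps, 0,
                                   btruth$noise_sd_dev))
        data.frame(repetition = max(all_tr$repetition) +
                     seq_len(config$retention_reps),
                   completion_time = time, deviation_mm = dev, penalty = pen,
                   score = score_trial(time, pen, config$scoring),
                   session = 16L)
      })
      all_tr <- rbind(all_tr, ret)
    }
    all_tr <- cbind(subject = sid, all_tr)

    recs <- list()
    amps <- list()
    for (sess in sessions_all) {
      row <- if (sess == 16L)
        data.frame(session = 16L, repetitions = config$retention_reps,
                   block_duration_min = config$retention_block_min) else
        sched[sched$session == sess, ]
      stim <- session_stim(config, row)
      dur <- session_duration(config, row)
      amp <- subject_amplitudes(config, sess, jit$base, jit$day, good)
      amps[[as.character(sess)]] <- amp
      truth_args <- c(list(layout = config$layout, hrf_amplitude = amp,
                           seed = derive_seed(seed, s, sess)),
                      config$truth_args)
      struth <- do.call(simulation_truth, truth_args)
      conc <- simulate_hemodynamics(struth, stim, duration = dur,
                                    fs = config$fs)
      rec <- to_intensity(conc)
      if (is.null(out_dir)) {
        recs[[as.character(sess)]] <- rec
      } else {
        p <- file.path(out_dir, sid, sprintf("session-%02d", sess))
        write_recording(rec, p)
        recs[[as.character(sess)]] <- p
      }
    }
    subjects[[s]] <- list(id = sid, class = classes[s], trials = all_tr,
                          behavioral_truth = unclass(btruth),
                          amplitudes = amps, sessions = recs)
    truth_rows[[s]] <- list(id = sid, class = classes[s],
                            behavioral = unclass(btruth),
                            amplitudes = amps)
  }

  truth <- list(seed = seed,
                elevated_channels = config$roles$sensorimotor,
                roles = config$roles,
                classes = stats::setNames(classes,
                                          vapply(subjects, `[[`, "",  "id")),
                subjects = truth_rows)
  bundle <- list(subjects = subjects, truth = truth, config = config)
  if (!is.null(out_dir)) {
    trials <- do.call(rbind, lapply(subjects, `[[`, "trials"))
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    bundle$path <- out_dir
  }
  invisible(bundle)
}

#' Windowed activation effects for selected sessions of a study
#'
#' Runs each subject's session recording through the preprocessing chain and
#' the Gaussian-basis GLM (with short-separation regression) and extracts the
#' windowed HbO effect per long channel.
#'
#' @param bundle a [simulate_study()] result (in-memory or written).
#' @param sessions session indices to analyze.
#' @param cfg a [preprocess_config()].
#' @param ext an [extinction_table()].
#' @param basis an [basis_set()] (defaults to the standard -2..60 s set at
#'   the study's sampling rate).
#' @param ss_mode short-separation mode for [fit_glm()].
#' @param chromophores chromophores to fit (`"HbO"` by default; HbR is
#'   carried through the pipeline but group statistics use HbO).
#' @param window,baseline windows for [window_effect()].
#' @return list, one element per session, each a `[subject x channel]`
#'   effect matrix (uM).
#' @export
study_effects <- function(bundle, sessions, cfg = preprocess_config(),
                          ext = default_extinction(), basis = NULL,
                          ss_mode = "nearest", chromophores = "HbO",
                          window = c(0, 20), baseline = c(-2, 0)) {
  fs <- bundle$config$fs
  if (is.null(basis)) basis <- basis_set(fs = fs)
  out <- list()
  for (sess in sessions) {
    eff <- NULL
    des <- NULL   # the design is shared by all subjects of a session
    for (sub in bundle$subjects) {
      rec <- sub$sessions[[as.character(sess)]]
      if (is.character(rec)) rec <- read_recording(rec)
      if (is.null(rec)) stop("session ", sess, " missing for ", sub$id)
      conc <- preprocess(rec, cfg, ext)$recording
      if (is.null(des))
        des <- build_design(conc$stim, basis, fs, dim(conc$data)[3])
      est <- fit_glm(conc, des, ss_mode = ss_mode,
                     chromophores = chromophores,
                     meta = list(subject = sub$id, day = sess))
      e <- window_effect(est, window, baseline)[, 1]
      eff <- rbind(eff, e)
      rownames(eff)[nrow(eff)] <- sub$id
    }
    out[[as.character(sess)]] <- eff
  }
  out
}
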