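#' Multichannel fNIRS recording container
#'
#' One container shape is shared by all pipeline stages: a 3-way array
#' `[channel x band x time]` where *band* is the two wavelengths (760, 850 nm)
#' for the `intensity` and `optical_density` stages and the two chromophores
#' (HbO, HbR, micromolar) for the `concentration` stage. Stage transitions are
#' only allowed in the order intensity -> optical_density -> concentration.
#'
#' @param data numeric array `[channel x band x time]`.
#' @param sample_rate sampling rate in Hz.
#' @param stage one of `"intensity"`, `"optical_density"`, `"concentration"`.
#' @param layout a [probe_layout()] with one entry per data channel.
#' @param wavelengths numeric, nm; required for intensity/OD stages
#'   (default `c(760, 850)`).
#' @param chromophores character; required for the concentration stage
#'   (default `c("HbO", "HbR")`).
#' @param stim optional [stim_design()] attached to the recording.
#' @param timestamps optional time vector in seconds; defaults to a uniform
#'   grid `(0:(n-1))/sample_rate`. Must be strictly increasing and uniform to
#'   within 1% jitter (silent resampling would hide acquisition faults).
#' @return an object of class `nirs_recording`.
#' @export
recording <- function(data, sample_rate, stage, layout,
                      wavelengths = NULL, chromophores = NULL,
                      stim = NULL, timestamps = NULL) {
  stage <- match.arg(stage, c("intensity", "optical_density", "concentration"))
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3-way array [channel x band x time]")
  if (!inherits(layout, "probe_layout"))
    stop("no layout: a probe_layout is required")
  nd <- dim(data)
  if (nd[1] != n_channels(layout))
    stop("data channel dimension does not match the layout")
  if (nd[2] != 2)
    stop("exactly two bands (wavelengths or chromophores) are expected")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be positive (Hz)")
  if (stage == "concentration") {
    if (is.null(chromophores)) chromophores <- c("HbO", "HbR")
    wavelengths <- NULL
  } else {
    if (is.null(wavelengths)) wavelengths <- c(760, 850)
    chromophores <- NULL
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(nd[3]) - 1) / sample_rate
  } else {
    if (length(timestamps) != nd[3])
      stop("timestamps length must equal the time dimension of the data")
    dt <- diff(timestamps)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (nd[3] > 1 && max(abs(dt - 1 / sample_rate)) > 0.01 / sample_rate)
      stop("non-uniform sampling: timestamp jitter exceeds 1% of the sample interval")
  }
  if (stage == "intensity" && any(data <= 0))
    stop("intensity values must be strictly positive")
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stim_design"))
    t_end <- timestamps[length(timestamps)]
    if (any(stim$block_onsets + stim$block_durations > t_end + 1 / sample_rate))
      stop("stimulus blocks extend beyond the recording end time")
  }
  structure(
    list(data = data, sample_rate = sample_rate, stage = stage,
         timestamps = timestamps, wavelengths = wavelengths,
         chromophores = chromophores, layout = layout, stim = stim),
    class = "nirs_recording")
}

stage_rank <- c(intensity = 1L, optical_density = 2L, concentration = 3L)

#' Internal: replace data / advance the processing stage of a recording.
#' Enforces the intensity -> optical_density -> concentration ordering.
#' @noRd
set_stage <- function(rec, data, stage, chromophores = NULL) {
  if (stage_rank[[stage]] < stage_rank[[rec$stage]])
    stop(sprintf("stage transition %s -> %s is not allowed", rec$stage, stage))
  recording(data, rec$sample_rate, stage, rec$layout,
            wavelengths = if (stage != "concentration") rec$wavelengths,
            chromophores = chromophores,
            stim = rec$stim, timestamps = rec$timestamps)
}

#' @export
print.nirs_recording <- function(x, ...) {
  nd <- dim(x$data)
  bands <- if (x$stage == "concentration")
    paste(x$chromophores, collapse = "/") else
    paste0(x$wavelengths, "nm", collapse = "/")
  cat(sprintf("nirs_recording [%s]: %d channels x %s x %d samples @ %g Hz (%.1f s)\n",
              x$stage, nd[1], bands, nd[3], x$sample_rate, nd[3] / x$sample_rate))
  if (!is.null(x$stim))
    cat(sprintf("  stim: %d blocks\n", length(x$stim$block_onsets)))
  invisible(x)
}

#' Block-design stimulus timing
#'
#' Task practice blocks alternate with rest blocks (2 min by default, matching
#' the resting periods separating task repetitions in a training session).
#'
#' @param block_onsets block start times, seconds from recording start;
#'   strictly increasing.
#' @param block_durations block durations in seconds (recycled if scalar).
#' @param block_labels optional condition names (default `"task"`).
#' @param rest_duration duration of the rest blocks separating tasks,
#'   seconds (default 120).
#' @return an object of class `stim_design`.
#' @export
stim_design <- function(block_onsets, block_durations, block_labels = NULL,
                        rest_duration = 120) {
  n <- length(block_onsets)
  block_durations <- rep_len(as.numeric(block_durations), n)
  if (n < 1) stop("at least one block is required")
  if (any(diff(block_onsets) <= 0))
    stop("block onsets must be strictly increasing")
  if (any(block_durations <= 0)) stop("block durations must be positive")
  if (n > 1 && any(block_onsets[-1] < (block_onsets + block_durations)[-n]))
    stop("blocks must not overlap")
  if (is.null(block_labels)) block_labels <- rep("task", n)
  structure(list(block_onsets = as.numeric(block_onsets),
                 block_durations = block_durations,
                 block_labels = as.character(block_labels),
                 rest_duration = rest_duration),
            class = "stim_design")
}

#' Training session schedule
#'
#' Expands a banded schedule configuration into one row per session. The
#' default reproduces the 15-session / 75-repetition protocol: three
#' repetitions per session with 10-min practice blocks for sessions 1-5, five
#' repetitions with 5-min blocks for sessions 6-10, and seven repetitions with
#' 3-min blocks for sessions 11-15 (practice blocks shorten as trainees speed
#' up).
#'
#' @param config a data frame with columns `from`, `to`, `repetitions`,
#'   `block_duration_min` describing session bands; see [default_schedule()].
#' @return a data frame with columns `session`, `repetitions`,
#'   `block_duration_min`.
#' @export
session_schedule <- function(config = default_schedule()) {
  stopifnot(is.data.frame(config),
            all(c("from", "to", "repetitions", "block_duration_min") %in%
                  names(config)))
  if (any(config$repetitions <= 0))
    stop("repetition counts must be positive")
  if (any(config$block_duration_min <= 0))
    stop("block durations must be positive")
  out <- do.call(rbind, lapply(seq_len(nrow(config)), function(i) {
    data.frame(session = config$from[i]:config$to[i],
               repetitions = config$repetitions[i],
               block_duration_min = config$block_duration_min[i])
  }))
  if (any(duplicated(out$session))) stop("schedule bands overlap")
  out[order(out$session), , drop = FALSE]
}

#' Default 15-session training schedule bands
#'
#' @return a data frame of session bands suitable for [session_schedule()].
#' @export
default_schedule <- function() {
  data.frame(from = c(1L, 6L, 11L),
             to = c(5L, 10L, 15L),
             repetitions = c(3L, 5L, 7L),
             block_duration_min = c(10, 5, 3))
}
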