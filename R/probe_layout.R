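#' Probe montage geometry
#'
#' A `probe_layout` describes an fNIRS optode montage: 3-D source and detector
#' positions (millimetres) and the measured channels as ordered
#' (source, detector) index pairs. A channel is classified as a
#' *short-separation* channel when its source-detector Euclidean distance is
#' below `short_threshold_mm`; short channels sample only scalp/extracerebral
#' hemodynamics and are used as nuisance regressors in the GLM.
#'
#' @param source_pos numeric matrix (n_sources x 3) of source coordinates, mm.
#' @param detector_pos numeric matrix (n_detectors x 3) of detector
#'   coordinates, mm.
#' @param channels integer matrix (n_channels x 2) of 1-based
#'   (source, detector) index pairs.
#' @param short_threshold_mm channels closer than this are short-separation
#'   channels (default 15 mm).
#' @return an object of class `probe_layout`.
#' @seealso [make_layout()] for a ready-made synthetic montage.
#' @export
probe_layout <- function(source_pos, detector_pos, channels,
                         short_threshold_mm = 15) {
  source_pos <- as.matrix(source_pos)
  detector_pos <- as.matrix(detector_pos)
  storage.mode(source_pos) <- "double"
  storage.mode(detector_pos) <- "double"
  if (ncol(source_pos) != 3 || ncol(detector_pos) != 3)
    stop("optode positions must be 3-D (n x 3 matrices, mm)")
  channels <- as.matrix(channels)
  if (ncol(channels) != 2)
    stop("`channels` must be a two-column (source, detector) index matrix")
  if (nrow(channels) < 1)
    stop("montage must contain at least one channel")
  if (any(channels != round(channels)) || any(channels < 1))
    stop("channel indices must be positive integers")
  if (any(channels[, 1] > nrow(source_pos)))
    stop("channel source index out of range of the source position list")
  if (any(channels[, 2] > nrow(detector_pos)))
    stop("channel detector index out of range of the detector position list")
  if (!is.numeric(short_threshold_mm) || short_threshold_mm <= 0)
    stop("`short_threshold_mm` must be a positive number")
  structure(
    list(source_pos = source_pos,
         detector_pos = detector_pos,
         channels = matrix(as.integer(channels), ncol = 2,
                           dimnames = list(NULL, c("source", "detector"))),
         short_threshold_mm = short_threshold_mm),
    class = "probe_layout")
}

#' Source-detector distance of every channel
#'
#' @param layout a [probe_layout()].
#' @return numeric vector of Euclidean distances in mm, one per channel.
#' @export
channel_distance <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  s <- layout$source_pos[layout$channels[, 1], , drop = FALSE]
  d <- layout$detector_pos[layout$channels[, 2], , drop = FALSE]
  sqrt(rowSums((s - d)^2))
}

#' Short-separation classification
#'
#' Pure function of geometry: a channel is short iff its source-detector
#' distance is strictly below the layout's `short_threshold_mm`.
#'
#' @param layout a [probe_layout()].
#' @return logical vector, one flag per channel.
#' @export
is_short <- function(layout) {
  channel_distance(layout) < layout$short_threshold_mm
}

#' @export
print.probe_layout <- function(x, ...) {
  sh <- is_short(x)
  cat(sprintf(
    "probe_layout: %d sources, %d detectors, %d channels (%d short < %g mm)\n",
    nrow(x$source_pos), nrow(x$detector_pos), nrow(x$channels),
    sum(sh), x$short_threshold_mm))
  invisible(x)
}

#' Channel identifiers
#'
#' @param layout a [probe_layout()].
#' @return character vector `"S<i>D<j>"`, one per channel.
#' @export
channel_id <- function(layout) {
  sprintf("S%dD%d", layout$channels[, 1], layout$channels[, 2])
}

n_channels <- function(layout) nrow(layout$channels)

#' Channel midpoints (mm), used e.g. to pick the nearest short channel.
#' @noRd
channel_midpoint <- function(layout) {
  s <- layout$source_pos[layout$channels[, 1], , drop = FALSE]
  d <- layout$detector_pos[layout$channels[, 2], , drop = FALSE]
  (s + d) / 2
}

#' Build a synthetic linear montage
#'
#' Lays sources along a line 40 mm apart; each source gets one long-separation
#' detector at `long_sep_mm` and the first `n_short` sources additionally get
#' a short-separation detector at `short_sep_mm` (~8 mm is the optimum
#' scalp-sampling distance in adults). The default mirrors a 16-source /
#' 16-detector cap with 8 short-distance detectors.
#'
#' @param n_long number of long channels (= sources).
#' @param n_short number of short channels.
#' @param long_sep_mm long source-detector separation (default 30 mm; the
#'   montage's long distance is not a measured quantity here, 30 mm is the
#'   conventional adult value).
#' @param short_sep_mm short source-detector separation (default 8 mm).
#' @param short_threshold_mm classification threshold (default 15 mm).
#' @return a [probe_layout()] whose first `n_long` channels are long and last
#'   `n_short` channels are short.
#' @export
make_layout <- function(n_long = 16, n_short = 8, long_sep_mm = 30,
                        short_sep_mm = 8, short_threshold_mm = 15) {
  stopifnot(n_long >= 1, n_short >= 0, n_short <= n_long)
  x0 <- (seq_len(n_long) - 1) * 40
  source_pos <- cbind(x0, 0, 0)
  det_long <- cbind(x0 + long_sep_mm, 0, 0)
  det_short <- if (n_short > 0)
    cbind(x0[seq_len(n_short)] + short_sep_mm, 0, 0) else
    matrix(numeric(0), ncol = 3)
  detector_pos <- rbind(det_long, det_short)
  ch_long <- cbind(seq_len(n_long), seq_len(n_long))
  ch_short <- if (n_short > 0)
    cbind(seq_len(n_short), n_long + seq_len(n_short)) else
    matrix(integer(0), ncol = 2)
  probe_layout(source_pos, detector_pos, rbind(ch_long, ch_short),
               short_threshold_mm = short_threshold_mm)
}
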