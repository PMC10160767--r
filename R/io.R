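#' Write a recording to disk
#'
#' The on-disk dialect is a *CSV bundle*: a directory holding `data.csv`
#' (time x channel-band matrix), `layout.json`, `meta.json` and, when a
#' stimulus design is attached, `stim.json`. The bundle is lossless for data,
#' layout and stimulus timing and needs no binary tooling. `format = "snirf"`
#' is declared for interoperability but requires an HDF5 interface that is not
#' available to this installation and therefore raises an error.
#'
#' @param rec a [recording()].
#' @param path directory to create/populate.
#' @param format `"csv_bundle"` (default) or `"snirf"` (unsupported here).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv_bundle", "snirf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "nirs_recording"))
  if (format == "snirf")
    stop("SNIRF I/O requires an HDF5 interface, which is not available in ",
         "this installation; use format = \"csv_bundle\"")
  if (dim(rec$data)[1] < 1) stop("refusing to write a recording with no channels")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)

  bands <- band_labels(rec)
  ids <- channel_id(rec$layout)
  nd <- dim(rec$data)
  # time x (channel*band) matrix, channel-major column order S1D1_760, S1D1_850, ...
  flat <- matrix(aperm(rec$data, c(3, 2, 1)), nrow = nd[3])
  colnames(flat) <- as.vector(t(outer(ids, bands, paste, sep = "_")))
  df <- data.frame(time = rec$timestamps, flat, check.names = FALSE)
  utils::write.csv(df, file.path(path, "data.csv"), row.names = FALSE)

  lay <- rec$layout
  jsonlite::write_json(
    list(source_pos = lay$source_pos, detector_pos = lay$detector_pos,
         channels = lay$channels, short_threshold_mm = lay$short_threshold_mm),
    file.path(path, "layout.json"), digits = NA, auto_unbox = TRUE)

  jsonlite::write_json(
    list(stage = rec$stage, sample_rate = rec$sample_rate,
         wavelengths = rec$wavelengths, chromophores = rec$chromophores,
         format_version = 1L),
    file.path(path, "meta.json"), digits = NA, auto_unbox = TRUE, null = "null")

  if (!is.null(rec$stim)) {
    jsonlite::write_json(
      list(block_onsets = rec$stim$block_onsets,
           block_durations = rec$stim$block_durations,
           block_labels = rec$stim$block_labels,
           rest_duration = rec$stim$rest_duration),
      file.path(path, "stim.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]; `read_recording(write_recording(x))`
#' is the identity on the container up to floating-point representation.
#'
#' @param path bundle directory.
#' @param format `"csv_bundle"` (default) or `"snirf"` (unsupported here).
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("csv_bundle", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    stop("SNIRF I/O requires an HDF5 interface, which is not available in ",
         "this installation; use format = \"csv_bundle\"")
  if (!dir.exists(path)) stop("bundle directory does not exist: ", path)
  lay_path <- file.path(path, "layout.json")
  if (!file.exists(lay_path))
    stop("no layout: ", lay_path, " is missing")
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  lj <- jsonlite::read_json(lay_path, simplifyVector = TRUE)
  layout <- probe_layout(lj$source_pos, lj$detector_pos, lj$channels,
                         short_threshold_mm = lj$short_threshold_mm)
  df <- utils::read.csv(file.path(path, "data.csv"), check.names = FALSE)
  ts <- df$time
  flat <- as.matrix(df[, -1, drop = FALSE])
  n <- nrow(flat)
  nch <- n_channels(layout)
  data <- aperm(array(flat, dim = c(n, 2, nch)), c(3, 2, 1))
  stim <- NULL
  stim_path <- file.path(path, "stim.json")
  if (file.exists(stim_path)) {
    sj <- jsonlite::read_json(stim_path, simplifyVector = TRUE)
    stim <- stim_design(sj$block_onsets, sj$block_durations, sj$block_labels,
                        rest_duration = sj$rest_duration)
  }
  recording(data, sample_rate = meta$sample_rate, stage = meta$stage,
            layout = layout,
            wavelengths = meta$wavelengths, chromophores = meta$chromophores,
            stim = stim, timestamps = ts)
}

band_labels <- function(rec) {
  if (rec$stage == "concentration") rec$chromophores else
    as.character(rec$wavelengths)
}
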