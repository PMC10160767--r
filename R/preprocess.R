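#' Extinction coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' acquisition wavelengths, in cm^-1 mM^-1. The values are the widely used
#' compiled spectra (Gratzer/Kollias compilation, as distributed with common
#' fNIRS toolboxes). The specific table sets the micromolar scaling of the
#' output, so it is explicit and swappable.
#'
#' @param wavelengths wavelengths (nm) the table covers.
#' @param eps 2x2 matrix, rows = wavelengths, columns = c("HbO", "HbR"),
#'   cm^-1 mM^-1.
#' @param source citation string.
#' @return an object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths, eps, source = "") {
  eps <- as.matrix(eps)
  stopifnot(length(wavelengths) == 2, all(dim(eps) == c(2, 2)))
  if (kappa(eps) >= 1e4)
    stop("extinction matrix is numerically singular (condition number >= 1e4)")
  dimnames(eps) <- list(as.character(wavelengths), c("HbO", "HbR"))
  structure(list(wavelengths = as.numeric(wavelengths), eps = eps,
                 source = source),
            class = "extinction_table")
}

#' @rdname extinction_table
#' @export
default_extinction <- function() {
  extinction_table(
    c(760, 850),
    matrix(c(1.4866, 3.8437,
             2.5264, 1.7986), nrow = 2, byrow = TRUE),
    source = paste("Gratzer W.B. / Kollias N. compiled hemoglobin spectra",
                   "(cm^-1 mM^-1), as distributed with common fNIRS toolboxes"))
}

#' Preprocessing configuration
#'
#' All tunable constants of the preprocessing chain. Defaults follow the
#' standard recipe: bandpass in the neurovascular coupling band
#' (0.01-0.1 Hz), partial pathlength factors 1.0/1.0 so that concentrations
#' come out in micromolar, and the hybrid spline + Savitzky-Golay motion
#' correction with its published defaults (1 s detection window, 0.4 OD
#' amplitude threshold, 5x moving-SD threshold, 10 s smoothing frame, cubic
#' polynomial).
#'
#' @param band_low,band_high bandpass edges, Hz.
#' @param filter_order Butterworth prototype order.
#' @param ppf partial pathlength factors for the two wavelengths.
#' @param sg_frame_s Savitzky-Golay frame length, seconds.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param motion_window_s moving-window length for motion detection, seconds.
#' @param motion_amp_threshold window amplitude-range threshold, OD units.
#' @param motion_std_threshold multiple of the median moving SD above which a
#'   window is flagged.
#' @param min_spline_s flagged segments shorter than this are replaced by the
#'   local baseline rather than spline-detrended (too few samples for a
#'   stable spline fit).
#' @param od_reference reference for optical density, `"mean"` (default) or
#'   `"first"` sample.
#' @param short_threshold_mm short-channel classification threshold, mm.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.01, band_high = 0.1,
                              filter_order = 3, ppf = c(1, 1),
                              sg_frame_s = 10, sg_polyorder = 3,
                              motion_window_s = 1,
                              motion_amp_threshold = 0.4,
                              motion_std_threshold = 5,
                              min_spline_s = 3,
                              od_reference = c("mean", "first"),
                              short_threshold_mm = 15) {
  od_reference <- match.arg(od_reference)
  if (!(0 < band_low && band_low < band_high))
    stop("require 0 < band_low < band_high")
  stopifnot(length(ppf) == 2, all(ppf > 0))
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order, ppf = ppf,
                 sg_frame_s = sg_frame_s, sg_polyorder = sg_polyorder,
                 motion_window_s = motion_window_s,
                 motion_amp_threshold = motion_amp_threshold,
                 motion_std_threshold = motion_std_threshold,
                 min_spline_s = min_spline_s,
                 od_reference = od_reference,
                 short_threshold_mm = short_threshold_mm),
            class = "preprocess_config")
}

#' Convert light intensity to optical density
#'
#' `OD(t) = -log10(I(t) / I_ref)` per channel and wavelength, where the
#' reference is the channel's temporal mean (or its first sample when the
#' configuration says so). With the mean reference the OD series is
#' zero-mean-ish by construction.
#'
#' @param rec an intensity-stage [recording()].
#' @param cfg a [preprocess_config()].
#' @return an optical-density-stage recording.
#' @export
intensity_to_od <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (rec$stage != "intensity") stop("expected an intensity-stage recording")
  bad <- which(rec$data <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf("nonpositive intensity in channel %s (%g nm) at sample %d",
                 channel_id(rec$layout)[b[1]], rec$wavelengths[b[2]], b[3]))
  }
  od <- rec$data
  nd <- dim(od)
  for (i in seq_len(nd[1])) for (w in seq_len(nd[2])) {
    x <- od[i, w, ]
    ref <- if (cfg$od_reference == "mean") mean(x) else x[1]
    od[i, w, ] <- -log10(x / ref)
  }
  set_stage(rec, od, "optical_density")
}

# moving-window motion detection on one series; returns logical flags
detect_motion_flags <- function(x, fs, cfg) {
  w <- max(3L, round(cfg$motion_window_s * fs))
  n <- length(x)
  if (n <= w) return(rep(FALSE, n))
  E <- stats::embed(x, w)                      # (n-w+1) x w windows
  Ed <- as.data.frame(E)
  rng <- do.call(pmax, Ed) - do.call(pmin, Ed)
  mu <- rowMeans(E)
  sdv <- sqrt(pmax(rowMeans(E^2) - mu^2, 0))
  sd_ref <- stats::median(sdv)
  hit <- (rng > cfg$motion_amp_threshold) |
    (sd_ref > 0 & sdv > cfg$motion_std_threshold * sd_ref)
  flag <- rep(FALSE, n)
  if (any(hit)) {
    # window i of embed() spans samples (i + w - 1) down to i
    for (i in which(hit)) flag[i:(i + w - 1)] <- TRUE
  }
  flag
}

# correct one series given motion flags: spline/baseline removal inside each
# flagged segment plus step re-anchoring of the signal that follows
correct_segments <- function(x, flag, fs, cfg) {
  n <- length(x)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bw <- max(3L, round(2 * fs))                 # 2 s baseline windows
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    pre_idx <- seq(max(1, i0 - bw), i0 - 1)
    pre_idx <- pre_idx[pre_idx >= 1 & pre_idx < i0]
    post_idx <- seq(i1 + 1, min(n, i1 + bw))
    post_idx <- post_idx[post_idx > i1 & post_idx <= n]
    seg <- x[i0:i1]
    len <- length(seg)
    pre <- if (length(pre_idx)) mean(x[pre_idx]) else
      if (length(post_idx)) mean(x[post_idx]) else mean(seg)
    post <- if (length(post_idx)) mean(x[post_idx]) else pre
    if (len >= round(cfg$min_spline_s * fs)) {
      fit <- stats::smooth.spline(seq_len(len), seg, spar = 0.6)
      resid <- seg - stats::predict(fit, seq_len(len))$y
    } else {
      resid <- numeric(len)                    # too short for a stable spline
    }
    x[i0:i1] <- pre + resid
    d <- post - pre                            # remove any persistent shift
    if (i1 < n) x[(i1 + 1):n] <- x[(i1 + 1):n] - d
  }
  x
}

#' Motion artifact correction (hybrid spline + Savitzky-Golay)
#'
#' Two-phase correction on optical-density data. Phase 1 flags motion epochs
#' where the moving-window amplitude range or the moving SD exceeds its
#' threshold, removes the artifact trajectory inside each flagged segment
#' (smoothing-spline detrending, or plain local-baseline replacement for
#' segments too short to support a spline) and re-anchors the subsequent
#' signal so baseline shifts do not persist. Phase 2 applies Savitzky-Golay
#' smoothing to the whole series, which suppresses residual spike-band
#' content. The returned mask marks the motion-flagged samples; the SG
#' smoothing additionally touches every sample (by design of the method).
#'
#' @param rec an optical-density-stage [recording()].
#' @param cfg a [preprocess_config()].
#' @return list with elements `recording` (corrected, same stage) and
#'   `artifact_mask` (logical `[channel x time]`, flags pooled over
#'   wavelengths since head motion affects both).
#' @export
correct_motion_sg <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (rec$stage != "optical_density")
    stop("expected an optical-density-stage recording")
  nd <- dim(rec$data)
  fs <- rec$sample_rate
  frame <- round(cfg$sg_frame_s * fs)
  if (frame %% 2 == 0) frame <- frame + 1
  if (frame >= nd[3])
    stop("Savitzky-Golay frame length must be shorter than the series")
  out <- rec$data
  mask <- matrix(FALSE, nd[1], nd[3])
  for (i in seq_len(nd[1])) {
    flag <- detect_motion_flags(out[i, 1, ], fs, cfg) |
      detect_motion_flags(out[i, 2, ], fs, cfg)
    mask[i, ] <- flag
    for (w in 1:2) {
      x <- out[i, w, ]
      if (any(flag)) x <- correct_segments(x, flag, fs, cfg)
      out[i, w, ] <- sgolay_smooth(x, frame, cfg$sg_polyorder)
    }
  }
  list(recording = set_stage(rec, out, rec$stage), artifact_mask = mask)
}

#' Zero-phase Butterworth bandpass
#'
#' Forward-backward (zero-phase) IIR bandpass in the neurovascular coupling
#' band. Padding uses odd reflection long enough for the low-frequency edge
#' transient (3 periods of `band_low`), so short series are handled
#' gracefully. The stage is unchanged.
#'
#' @param rec a [recording()] at any stage.
#' @param cfg a [preprocess_config()].
#' @return the filtered recording.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  fs <- rec$sample_rate
  if (cfg$band_high >= fs / 2)
    stop("band_high must be below the Nyquist frequency")
  ba <- butter_bandpass(cfg$band_low, cfg$band_high, fs, cfg$filter_order)
  padlen <- round(3 * fs / cfg$band_low)
  out <- rec$data
  nd <- dim(out)
  for (i in seq_len(nd[1])) for (w in seq_len(nd[2]))
    out[i, w, ] <- filtfilt_ba(ba$b, ba$a, out[i, w, ], padlen = padlen)
  set_stage(rec, out, rec$stage, chromophores = rec$chromophores)
}

# channel-wise 2x2 MBLL system matrix: dOD = M %*% c(HbO, HbR) [mM]
mbll_matrix <- function(dist_cm, ext, ppf) {
  ext$eps * (dist_cm * ppf)   # rows scale by wavelength-specific d * ppf
}

#' Optical density to chromophore concentrations (modified Beer-Lambert law)
#'
#' Per channel and sample, solves the 2x2 system
#' `dOD(lambda) = d * ppf(lambda) * (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR)`
#' for the oxy/deoxyhemoglobin concentration changes. Distances enter in cm;
#' with extinction coefficients in cm^-1 mM^-1 and partial pathlength factors
#' of 1.0/1.0 the output is in micromolar.
#'
#' @param rec an optical-density-stage [recording()].
#' @param ext an [extinction_table()].
#' @param cfg a [preprocess_config()] (supplies the partial pathlength
#'   factors).
#' @return a concentration-stage recording (HbO, HbR in uM).
#' @export
od_to_concentration <- function(rec, ext = default_extinction(),
                                cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(ext, "extinction_table"))
  if (rec$stage != "optical_density")
    stop("expected an optical-density-stage recording")
  if (!isTRUE(all.equal(sort(rec$wavelengths), sort(ext$wavelengths))))
    stop("extinction table does not cover the recording's wavelengths")
  dist_cm <- channel_distance(rec$layout) / 10
  if (any(!is.finite(dist_cm)) || any(dist_cm <= 0))
    stop("missing or invalid channel distances")
  nd <- dim(rec$data)
  out <- array(0, dim = c(nd[1], 2, nd[3]))
  ord <- match(rec$wavelengths, ext$wavelengths)
  for (i in seq_len(nd[1])) {
    M <- mbll_matrix(dist_cm[i], ext, cfg$ppf)[ord, , drop = FALSE]
    if (kappa(M) >= 1e4) stop("singular MBLL system for channel ",
                              channel_id(rec$layout)[i])
    out[i, , ] <- solve(M, rec$data[i, , ]) * 1000  # mM -> uM
  }
  set_stage(rec, out, "concentration", chromophores = c("HbO", "HbR"))
}

#' Full preprocessing chain
#'
#' Runs, in the published order: intensity -> optical density -> motion
#' correction (hybrid spline + Savitzky-Golay) -> zero-phase bandpass
#' (0.01-0.1 Hz) -> modified Beer-Lambert law.
#'
#' @param rec an intensity-stage [recording()].
#' @param cfg a [preprocess_config()].
#' @param ext an [extinction_table()].
#' @return list with `recording` (concentration stage, uM) and
#'   `artifact_mask` (logical `[channel x time]`).
#' @export
preprocess <- function(rec, cfg = preprocess_config(),
                       ext = default_extinction()) {
  od <- intensity_to_od(rec, cfg)
  mc <- correct_motion_sg(od, cfg)
  filt <- bandpass(mc$recording, cfg)
  conc <- od_to_concentration(filt, ext, cfg)
  list(recording = conc, artifact_mask = mc$artifact_mask)
}
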