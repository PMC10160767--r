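#' Gaussian basis set for HRF estimation
#'
#' A consecutive sequence of Gaussian basis functions with standard deviation
#' `sigma` and means separated by `spacing` over the peri-onset time range
#' `[t_min, t_max]`. With the defaults (-2 to 60 s, 0.5 s spacing, 0.5 s
#' sigma) the set holds `(60 - (-2))/0.5 + 1 = 125` bases. Each basis has
#' unit peak amplitude so that its coefficient is in the units of the data
#' (micromolar).
#'
#' @param t_min,t_max peri-onset time range, seconds.
#' @param spacing separation of the Gaussian means, seconds.
#' @param sigma standard deviation of each Gaussian, seconds.
#' @param fs sampling rate the basis is evaluated at, Hz.
#' @return an object of class `hrf_basis` with the reconstruction grid
#'   `time` (`t_min` to `t_max` at `1/fs`) and matrix `B`
#'   (`length(time) x n_basis`).
#' @export
basis_set <- function(t_min = -2, t_max = 60, spacing = 0.5, sigma = 0.5,
                      fs = 5) {
  stopifnot(t_max > t_min, spacing > 0, sigma > 0, fs > 0)
  centers <- seq(t_min, t_max, by = spacing)
  time <- seq(t_min, t_max, by = 1 / fs)
  B <- exp(-outer(time, centers, `-`)^2 / (2 * sigma^2))
  structure(list(t_min = t_min, t_max = t_max, spacing = spacing,
                 sigma = sigma, fs = fs, centers = centers, time = time,
                 B = B),
            class = "hrf_basis")
}

#' Build the GLM design matrix
#'
#' Column `k` of the task block is the Gaussian basis `k` time-locked to every
#' stimulus onset (shifted copies summed; bases extending past the sampled
#' range are truncated, never wrapped). Drift columns are appended after the
#' task block: a constant, a linear term and - with the default `"dct"` drift
#' model - a discrete-cosine set spanning frequencies up to `dct_cutoff_hz`.
#' The cosine set covers the band the zero-phase high-pass filter empties
#' (including its transition band), so the task coefficients are identified
#' from frequencies the filter passes cleanly; without it, regressing
#' filtered data on unfiltered task regressors biases HRF amplitudes
#' noticeably downward. Column order is stable: `task 1..n_basis`,
#' `intercept`, `linear`, then the cosines.
#'
#' @param stim a [stim_design()].
#' @param basis an [basis_set()].
#' @param fs sampling rate, Hz.
#' @param n_samples number of samples in the fitted series.
#' @param drift `"dct"` (constant + linear + low-frequency cosines, default)
#'   or `"linear"` (constant + linear only).
#' @param dct_cutoff_hz highest cosine frequency of the `"dct"` drift model
#'   (default 0.015 Hz, 1.5x the standard 0.01 Hz high-pass edge).
#' @return an object of class `glm_design` with the matrix `X` and column
#'   bookkeeping (`task_cols`, `drift_cols`).
#' @export
build_design <- function(stim, basis = basis_set(fs = fs), fs, n_samples,
                         drift = c("dct", "linear"), dct_cutoff_hz = 0.015) {
  drift <- match.arg(drift)
  stopifnot(inherits(stim, "stim_design"), inherits(basis, "hrf_basis"))
  t <- (seq_len(n_samples) - 1) / fs
  if (any(stim$block_onsets < t[1] - basis$t_max) ||
      any(stim$block_onsets > t[n_samples]))
    stop("stimulus onsets must lie within the sampled interval")
  nb <- length(basis$centers)
  X <- matrix(0, n_samples, nb)
  lo <- basis$t_min - 4 * basis$sigma
  hi <- basis$t_max + 4 * basis$sigma
  for (onset in stim$block_onsets) {
    tau <- t - onset
    idx <- which(tau >= lo & tau <= hi)
    if (!length(idx)) next
    X[idx, ] <- X[idx, ] +
      exp(-outer(tau[idx], basis$centers, `-`)^2 / (2 * basis$sigma^2))
  }
  lin <- (t - mean(t)) / (max(t) - min(t))
  D <- cbind(intercept = rep(1, n_samples), linear = lin)
  if (drift == "dct") {
    K <- floor(2 * (n_samples / fs) * dct_cutoff_hz)
    if (K > 0) {
      dct <- vapply(seq_len(K), function(k)
        cos(pi * k * (2 * seq_len(n_samples) - 1) / (2 * n_samples)),
        numeric(n_samples))
      colnames(dct) <- sprintf("dct_%02d", seq_len(K))
      D <- cbind(D, dct)
    }
  }
  X <- cbind(X, D)
  colnames(X)[seq_len(nb)] <- sprintf("basis_%03d", seq_len(nb))
  structure(list(X = X, basis = basis, fs = fs, n_samples = n_samples,
                 onsets = stim$block_onsets,
                 task_cols = seq_len(nb),
                 drift_cols = nb + seq_len(ncol(D))),
            class = "glm_design")
}

# pick, for each long channel, the nuisance short-channel column(s)
select_short <- function(layout, ss_mode, Ylong, Yshort) {
  long_idx <- which(!is_short(layout))
  short_idx <- which(is_short(layout))
  if (ss_mode == "none") return(rep(list(integer(0)), length(long_idx)))
  if (!length(short_idx))
    stop("short-separation regression requested but the montage has no short channels")
  mid <- channel_midpoint(layout)
  lapply(seq_along(long_idx), function(i) {
    switch(ss_mode,
      nearest = {
        d <- sqrt(colSums((t(mid[short_idx, , drop = FALSE]) -
                             mid[long_idx[i], ])^2))
        which.min(d)
      },
      max_correlation = which.max(abs(stats::cor(Ylong[, i], Yshort))),
      all = seq_along(short_idx))
  })
}

#' Fit the HRF GLM with short-separation regression
#'
#' For each long channel and chromophore the channel time series is regressed,
#' by ordinary least squares, on the Gaussian-basis task regressors, the drift
#' terms and the selected short-separation channel series of the same
#' chromophore (which removes signal changes arising in the extracerebral
#' layer). The solve uses a QR decomposition; with the base design shared
#' across channels, the short-channel column is folded in exactly via the
#' Frisch-Waugh partialling identity, so every channel's coefficients equal
#' the full normal-equations solution.
#'
#' @param conc a concentration-stage [recording()].
#' @param design a [build_design()] result for the recording's stimulus.
#' @param ss_mode how to choose the short-channel regressor per long channel:
#'   `"nearest"` (Euclidean, default), `"max_correlation"`, `"all"` (all short
#'   channels enter), or `"none"` (no short-separation regression).
#' @param chromophores chromophores to fit (default both).
#' @param meta optional list carried on the result (e.g. subject, day).
#' @return an object of class `hrf_estimates`: reconstructed HRFs
#'   (`hrf[channel, chromophore, time]` on the basis grid), basis coefficients
#'   `beta`, nuisance coefficients, residual variance, residual sum of
#'   squares and degrees of freedom.
#' @export
fit_glm <- function(conc, design, ss_mode = c("nearest", "max_correlation",
                                              "all", "none"),
                    chromophores = c("HbO", "HbR"), meta = list()) {
  ss_mode <- match.arg(ss_mode)
  stopifnot(inherits(conc, "nirs_recording"), inherits(design, "glm_design"))
  if (conc$stage != "concentration")
    stop("expected a concentration-stage recording")
  n <- dim(conc$data)[3]
  if (n != design$n_samples) stop("design and recording lengths differ")
  X0 <- design$X
  p0 <- ncol(X0)
  qr0 <- qr(X0)
  if (qr0$rank < p0) {
    cond <- tryCatch(kappa(X0), error = function(e) Inf)
    stop(sprintf("design matrix is rank deficient (condition number %.3g)",
                 cond))
  }
  layout <- conc$layout
  long_idx <- which(!is_short(layout))
  short_idx <- which(is_short(layout))
  nb <- length(design$task_cols)
  B <- design$basis$B
  nt <- nrow(B)
  nlong <- length(long_idx)
  chrom_all <- conc$chromophores
  chromophores <- match.arg(chromophores, chrom_all, several.ok = TRUE)

  hrf <- array(NA_real_, c(nlong, length(chromophores), nt),
               dimnames = list(channel_id(layout)[long_idx], chromophores, NULL))
  beta <- array(NA_real_, c(nlong, length(chromophores), nb),
                dimnames = list(channel_id(layout)[long_idx], chromophores, NULL))
  nuis <- vector("list", length(chromophores))
  names(nuis) <- chromophores
  rss <- matrix(NA_real_, nlong, length(chromophores),
                dimnames = list(channel_id(layout)[long_idx], chromophores))
  dof <- rss
  ss_used <- vector("list", length(chromophores))
  names(ss_used) <- chromophores

  for (ci in seq_along(chromophores)) {
    c_band <- match(chromophores[ci], chrom_all)
    Ylong <- t(conc$data[long_idx, c_band, , drop = FALSE][, 1, ])
    if (nlong == 1) Ylong <- matrix(conc$data[long_idx, c_band, ], ncol = 1)
    Yshort <- if (length(short_idx))
      matrix(t(conc$data[short_idx, c_band, , drop = FALSE][, 1, ]),
             nrow = n) else matrix(numeric(0), nrow = n, ncol = 0)
    sel <- select_short(layout, ss_mode, Ylong, Yshort)
    ss_used[[ci]] <- sel
    beta0_y <- qr.coef(qr0, Ylong)
    R_y <- qr.resid(qr0, Ylong)
    if (ncol(Yshort)) {
      beta0_s <- qr.coef(qr0, Yshort)
      R_s <- qr.resid(qr0, Yshort)
    }
    nuis_ci <- vector("list", nlong)
    for (i in seq_len(nlong)) {
      k <- sel[[i]]
      if (length(k)) {
        Z <- R_s[, k, drop = FALSE]
        G <- crossprod(Z)
        if (kappa(G) >= 1e10)
          stop("short-channel regressors are collinear with the design")
        gam <- solve(G, crossprod(Z, R_y[, i]))
        bi <- beta0_y[, i] - beta0_s[, k, drop = FALSE] %*% gam
        resid <- R_y[, i] - Z %*% gam
      } else {
        gam <- numeric(0)
        bi <- beta0_y[, i]
        resid <- R_y[, i]
      }
      p <- p0 + length(k)
      beta[i, ci, ] <- bi[design$task_cols]
      hrf[i, ci, ] <- B %*% bi[design$task_cols]
      rss[i, ci] <- sum(resid^2)
      dof[i, ci] <- n - p
      nuis_ci[[i]] <- c(stats::setNames(bi[design$drift_cols],
                                        colnames(design$X)[design$drift_cols]),
                        stats::setNames(as.numeric(gam),
                                        if (length(k))
                                          paste0("ss_",
                                                 channel_id(layout)[short_idx][k])))
    }
    nuis[[ci]] <- nuis_ci
  }
  if (any(dof <= 0, na.rm = TRUE))
    stop("non-positive residual degrees of freedom: series too short for the design")
  structure(
    list(channels = channel_id(layout)[long_idx],
         chromophores = chromophores,
         time = design$basis$time,
         hrf = hrf, beta = beta, nuisance_betas = nuis,
         rss = rss, residual_variance = rss / dof, dof = dof,
         ss_mode = ss_mode, ss_used = ss_used,
         n_samples = n, meta = meta),
    class = "hrf_estimates")
}

#' @export
print.hrf_estimates <- function(x, ...) {
  cat(sprintf("hrf_estimates: %d channels x %s, grid %g..%g s (%d points)\n",
              length(x$channels), paste(x$chromophores, collapse = "/"),
              min(x$time), max(x$time), length(x$time)))
  if (length(x$meta)) {
    m <- x$meta[!vapply(x$meta, is.null, logical(1))]
    if (length(m)) cat("  meta:", paste(names(m), unlist(m), sep = "=",
                                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average HRF estimates across fits
#'
#' Pointwise mean of the reconstructed HRFs (and basis coefficients) per
#' channel within each group, e.g. the averaged HRF for repetitions performed
#' on each day of training. Grouping keys are taken from each estimate's
#' `meta` (`subject` and `day`).
#'
#' @param estimates list of [fit_glm()] results sharing the basis grid.
#' @param group_by `"subject_day"` (default) or `"subject"`.
#' @return named list of averaged `hrf_estimates`, one per group, each
#'   carrying the per-group `n` in its `meta`.
#' @export
average_hrf <- function(estimates, group_by = c("subject_day", "subject")) {
  group_by <- match.arg(group_by)
  if (!length(estimates)) stop("empty group: no estimates to average")
  if (inherits(estimates, "hrf_estimates")) estimates <- list(estimates)
  keys <- vapply(estimates, function(e) {
    s <- e$meta$subject %||% "?"
    if (group_by == "subject") as.character(s) else
      paste(s, e$meta$day %||% "?", sep = "|")
  }, character(1))
  tmpl <- estimates[[1]]
  for (e in estimates)
    if (!isTRUE(all.equal(e$time, tmpl$time)))
      stop("all estimates must share the basis grid")
  out <- lapply(split(seq_along(estimates), keys), function(ii) {
    g <- estimates[ii]
    avg <- g[[1]]
    avg$hrf <- Reduce(`+`, lapply(g, `[[`, "hrf")) / length(g)
    avg$beta <- Reduce(`+`, lapply(g, `[[`, "beta")) / length(g)
    avg$rss <- Reduce(`+`, lapply(g, `[[`, "rss")) / length(g)
    avg$residual_variance <-
      Reduce(`+`, lapply(g, `[[`, "residual_variance")) / length(g)
    avg$dof <- do.call(pmin, lapply(g, `[[`, "dof"))
    avg$meta$n <- length(g)
    avg
  })
  out[unique(keys)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed HRF effect
#'
#' The mean of the estimated HRF over the analysis window (first 20 s after
#' onset by default) minus its mean over the pre-onset baseline window; this
#' windowed HbO change is the unit of all channel-level statistics.
#'
#' @param est an `hrf_estimates` object.
#' @param window analysis window, seconds (default `c(0, 20)`).
#' @param baseline baseline window, seconds (default `c(-2, 0)`).
#' @return numeric matrix `[channel x chromophore]` of windowed effects (uM).
#' @export
window_effect <- function(est, window = c(0, 20), baseline = c(-2, 0)) {
  stopifnot(inherits(est, "hrf_estimates"))
  iw <- est$time >= window[1] & est$time <= window[2]
  # half-open baseline so the onset sample is not counted in both windows
  ib <- est$time >= baseline[1] & est$time < baseline[2]
  if (!any(iw) || !any(ib))
    stop("empty window after discretization on the basis grid")
  eff <- apply(est$hrf[, , iw, drop = FALSE], c(1, 2), mean) -
    apply(est$hrf[, , ib, drop = FALSE], c(1, 2), mean)
  dimnames(eff) <- list(est$channels, est$chromophores)
  eff
}
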