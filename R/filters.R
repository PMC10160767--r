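# Minimal IIR/FIR filtering machinery. No signal-processing package is
# available to this installation, so the Butterworth design (bilinear
# transform of the analog prototype), the forward-backward zero-phase
# application and the Savitzky-Golay least-squares smoother are implemented
# here and validated against closed-form oracles in the tests.

# polynomial coefficients (descending powers of z, i.e. b0, b1, ...) from roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# evaluate H(z) = sum(b_j z^-j) / sum(a_j z^-j)
freqz_ba <- function(b, a, w) {
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(b * zz^(-(seq_along(b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(-(seq_along(a) - 1))), complex(1))
  num / den
}

#' Butterworth bandpass design
#'
#' Bilinear-transform digital Butterworth bandpass filter. An order-`order`
#' lowpass prototype yields a `2*order`-pole bandpass; gain is normalized to
#' unity at the geometric band centre.
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 3).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @keywords internal
butter_bandpass <- function(low, high, fs, order = 3) {
  if (!(0 < low && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p <- complex(real = -sin(theta), imaginary = cos(theta))  # analog prototype
  w1 <- 2 * fs * tan(pi * low / fs)                         # prewarped edges
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  pbp <- unlist(lapply(p, function(pp) {                    # lowpass -> bandpass
    b2 <- pp * bw / 2
    disc <- sqrt(b2^2 - w0^2)
    c(b2 + disc, b2 - disc)
  }))
  fs2 <- 2 * fs
  pd <- (fs2 + pbp) / (fs2 - pbp)                           # bilinear transform
  zd <- c(rep(1 + 0i, order), rep(-1 + 0i, order))          # zeros at s = 0, inf
  b <- Re(poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  wc <- 2 * atan(w0 / fs2)                                  # digital band centre
  g <- abs(freqz_ba(b, a, wc))
  list(b = b / g, a = a)
}

# one-pass IIR difference equation via stats::filter (convolution FIR part,
# then the recursive part); zero initial conditions
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v[-seq_len(nb - 1)])
  if (length(a) > 1)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

# zero-phase forward-backward filtering with odd (point-reflected) extension
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(a), length(b)) - 1)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xx <- c(pre, x, post)
  } else xx <- x
  y <- iir_filter(b, a, xx)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# Savitzky-Golay smoothing coefficients (0th derivative) for an odd frame
sgolay_coef <- function(frame, polyorder) {
  if (frame %% 2 == 0) stop("Savitzky-Golay frame length must be odd")
  if (polyorder >= frame) stop("polyorder must be smaller than the frame length")
  m <- (frame - 1) / 2
  A <- outer(-m:m, 0:polyorder, `^`)
  # first row of (A'A)^{-1} A' = least-squares value at the window centre
  solve(crossprod(A), t(A))[1, ]
}

# apply SG smoothing with mirror padding at the edges
sgolay_smooth <- function(x, frame, polyorder) {
  n <- length(x)
  if (frame >= n) stop("Savitzky-Golay frame length must be shorter than the series")
  h <- sgolay_coef(frame, polyorder)
  m <- (frame - 1) / 2
  xx <- c(x[(m + 1):2], x, x[(n - 1):(n - m)])
  y <- stats::filter(xx, rev(h), method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + n)])
}
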