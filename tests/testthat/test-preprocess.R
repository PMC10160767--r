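test_that("optical density conversion matches its definition and inverts", {
  lay <- make_layout(n_long = 2, n_short = 0)
  # constant intensity -> identically zero OD
  recc <- recording(array(2, c(2, 2, 100)), 5, "intensity", lay)
  expect_equal(as.vector(intensity_to_od(recc)$data), rep(0, 2 * 2 * 100))

  # a sample at mean(I) * 10^-0.5 has OD 0.5 there; solve the dip value v
  # so that v = mean(x) * 10^-0.5 holds self-consistently
  n <- 100
  k <- 10^-0.5
  v <- (n - 1) / n * k / (1 - k / n)
  x <- rep(1, n)
  x[50] <- v
  dat <- array(0, c(2, 2, n))
  for (i in 1:2) for (w in 1:2) dat[i, w, ] <- x
  od <- intensity_to_od(recording(dat, 5, "intensity", lay))
  expect_equal(od$data[1, 1, 50], 0.5, tolerance = 1e-12)

  # exp10(-OD) * mean(I) reconstructs the series
  set.seed(1)
  rec <- random_intensity(n_ch = 3, n = 300)
  od <- intensity_to_od(rec)
  for (i in 1:3) for (w in 1:2) {
    back <- 10^(-od$data[i, w, ]) * mean(rec$data[i, w, ])
    expect_equal(back, rec$data[i, w, ], tolerance = 1e-12)
  }
})

test_that("nonpositive intensities are reported with channel and sample", {
  lay <- make_layout(n_long = 2, n_short = 0)
  dat <- array(1, c(2, 2, 60))
  dat[2, 1, 17] <- 0
  expect_error(recording(dat, 5, "intensity", lay), "strictly positive")
  r <- recording(array(1, c(2, 2, 60)), 5, "intensity", lay)
  r$data[2, 1, 17] <- -0.1
  expect_error(intensity_to_od(r), "S2D2.*sample 17")
})

test_that("motion correction is a near no-op on clean data", {
  lay <- make_layout(n_long = 1, n_short = 0)
  fs <- 5
  t <- (0:1499) / fs
  x <- 0.01 * sin(2 * pi * 0.05 * t)          # in-band, artifact-free
  dat <- array(rep(x, each = 2), c(1, 2, 1500))
  od <- recording(dat, fs, "optical_density", lay)
  out <- correct_motion_sg(od)
  expect_false(any(out$artifact_mask))
  # interior samples only: the mirror padding leaves a small edge transient
  interior <- 60:1440
  expect_lt(max(abs(out$recording$data[1, 1, interior] - x[interior])),
            0.05 * 0.01)
})

test_that("injected spikes are suppressed below 20% of their magnitude", {
  lay <- make_layout(n_long = 1, n_short = 0)
  fs <- 5
  set.seed(42)
  n <- 1500
  t <- (0:(n - 1)) / fs
  base <- 0.004 * sin(2 * pi * 0.04 * t) + rnorm(n, 0, 5e-4)
  spike_mag <- 5 * sd(base)
  spike <- spike_mag * exp(-(t - 150)^2 / (2 * 0.25^2))   # 0.5 s wide
  dat <- array(0, c(1, 2, n))
  dat[1, 1, ] <- base + spike
  dat[1, 2, ] <- base + spike
  od <- recording(dat, fs, "optical_density", lay)
  out <- correct_motion_sg(od)
  i0 <- which.max(spike)
  expect_true(any(out$artifact_mask[1, (i0 - 3):(i0 + 3)]))
  resid_amp <- abs(out$recording$data[1, 1, i0] - base[i0])
  expect_lt(resid_amp, 0.2 * spike_mag)
})

test_that("step baseline shifts are re-anchored", {
  lay <- make_layout(n_long = 1, n_short = 0)
  fs <- 5
  set.seed(43)
  n <- 2000
  t <- (0:(n - 1)) / fs
  base <- rnorm(n, 0, 0.002)
  shift <- 0.1
  x <- base + shift * (t >= 200)
  dat <- array(0, c(1, 2, n))
  dat[1, 1, ] <- x
  dat[1, 2, ] <- x
  out <- correct_motion_sg(recording(dat, fs, "optical_density", lay))
  y <- out$recording$data[1, 1, ]
  pre <- mean(y[t > 150 & t < 195])
  post <- mean(y[t > 205 & t < 250])
  expect_lt(abs(post - pre), 0.1 * shift)
})

test_that("the bandpass keeps the neurovascular band and is zero phase", {
  lay <- make_layout(n_long = 1, n_short = 0)
  fs <- 5
  t <- (0:2999) / fs                           # 600 s
  mk <- function(x) recording(array(rep(x, each = 2), c(1, 2, length(x))),
                              fs, "optical_density", lay)
  rms <- function(x) sqrt(mean(x^2))
  inb <- sin(2 * pi * 0.05 * t)
  outb <- sin(2 * pi * 0.5 * t)
  y_in <- bandpass(mk(inb))$data[1, 1, ]
  y_out <- bandpass(mk(outb))$data[1, 1, ]
  expect_gte(rms(y_in) / rms(inb), 0.9)
  expect_lte(rms(y_out) / rms(outb), 0.1)
  expect_lt(max(abs(bandpass(mk(rep(1, 3000)))$data[1, 1, ])), 1e-3)
  cc <- ccf(y_in, inb, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass(mk(inb), preprocess_config(band_high = 3)),
               "Nyquist")
})

test_that("MBLL inversion is exact, linear and separates chromophores", {
  lay <- make_layout(n_long = 2, n_short = 1)
  ext <- default_extinction()
  cfg <- preprocess_config()
  n <- 50
  hbo <- 1.0; hbr <- -0.3                      # uM
  dists <- channel_distance(lay) / 10
  dat <- array(0, c(3, 2, n))
  for (i in 1:3) {
    M <- ext$eps * (dists[i] * cfg$ppf)
    dat[i, , ] <- (M %*% c(hbo, hbr)) / 1000
  }
  od <- recording(dat, 5, "optical_density", lay)
  conc <- od_to_concentration(od, ext, cfg)
  expect_equal(as.vector(conc$data[, 1, ]), rep(hbo, 3 * n),
               tolerance = 1e-9)
  expect_equal(as.vector(conc$data[, 2, ]), rep(hbr, 3 * n),
               tolerance = 1e-9)

  # zero OD -> zero concentrations; doubling OD doubles concentrations
  od0 <- recording(array(0, c(3, 2, 5)), 5, "optical_density", lay)
  expect_true(all(od_to_concentration(od0, ext, cfg)$data == 0))
  od2 <- od; od2$data <- 2 * od$data
  expect_equal(od_to_concentration(od2, ext, cfg)$data, 2 * conc$data,
               tolerance = 1e-12)

  # a pure-HbO forward signal yields no HbR after inversion
  datO <- array(0, c(3, 2, n))
  for (i in 1:3) {
    M <- ext$eps * (dists[i] * cfg$ppf)
    datO[i, , ] <- (M %*% c(0.8, 0)) / 1000
  }
  concO <- od_to_concentration(recording(datO, 5, "optical_density", lay),
                               ext, cfg)
  expect_lt(max(abs(concO$data[, 2, ])), 1e-9)
})

test_that("the chain after motion correction is linear", {
  lay <- make_layout(n_long = 2, n_short = 1)
  fs <- 5
  set.seed(8)
  t <- (0:999) / fs
  dat <- array(0, c(3, 2, 1000))
  for (i in 1:3) for (w in 1:2)
    dat[i, w, ] <- 0.002 * sin(2 * pi * 0.03 * t + i + w) +
      rnorm(1000, 0, 2e-4)
  od <- recording(dat, fs, "optical_density", lay)
  run <- function(r) {
    step <- correct_motion_sg(r)
    expect_false(any(step$artifact_mask))
    od_to_concentration(bandpass(step$recording))$data
  }
  od2 <- od; od2$data <- 2 * od$data
  expect_equal(run(od2), 2 * run(od), tolerance = 1e-9)
})
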