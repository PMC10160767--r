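test_that("the default basis set has 125 unit-peak Gaussians", {
  bs <- basis_set(fs = 5)
  expect_equal(length(bs$centers), (60 - (-2)) / 0.5 + 1)
  expect_equal(ncol(bs$B), 125)
  # unit peak as functions; the 0.2 s sampling grid sits within 0.1 s of
  # every center, so the sampled maxima stay above exp(-0.1^2/(2*0.5^2))
  expect_true(all(apply(bs$B, 2, max) <= 1 + 1e-12))
  expect_true(all(apply(bs$B, 2, max) >= exp(-0.01 / 0.5) - 1e-12))
})

test_that("design columns time-lock to onsets and superpose", {
  fs <- 5
  bs <- basis_set(fs = fs)
  n <- 600
  k6 <- which(abs(bs$centers - 6) < 1e-9)
  one <- build_design(stim_design(0.0001, 20, rest_duration = 10), bs, fs, n)
  expect_equal(which.max(one$X[, k6]), round(6 * fs) + 1, tolerance = 1)
  expect_equal(length(one$task_cols), 125)

  sa <- stim_design(10, 20, rest_duration = 10)
  sb <- stim_design(60, 20, rest_duration = 10)
  sab <- stim_design(c(10, 60), 20, rest_duration = 10)
  Xa <- build_design(sa, bs, fs, n)$X
  Xb <- build_design(sb, bs, fs, n)$X
  Xab <- build_design(sab, bs, fs, n)$X
  tc <- seq_len(125)
  expect_equal(Xab[, tc], Xa[, tc] + Xb[, tc], tolerance = 1e-12)

  expect_error(build_design(stim_design(200, 20, rest_duration = 10), bs, fs,
                            n = 300), "within the sampled interval")
})

test_that("noiseless OLS recovers the generating coefficients exactly", {
  fs <- 5
  lay <- make_layout(n_long = 2, n_short = 1)
  st <- test_stim(2)
  n <- round(stim_duration(st) * fs)
  des <- build_design(st, basis_set(fs = fs), fs, n)
  set.seed(21)
  p <- ncol(des$X)
  b1 <- rnorm(p, 0, 0.3)
  b2 <- rnorm(p, 0, 0.3)
  ss <- as.numeric(arima.sim(list(ar = 0.95), n)) * 0.05
  g <- c(0.8, 1.3)
  dat <- array(0, c(3, 2, n))
  dat[1, 1, ] <- des$X %*% b1 + g[1] * ss
  dat[2, 1, ] <- des$X %*% b2 + g[2] * ss
  dat[3, 1, ] <- ss
  conc <- recording(dat, fs, "concentration", lay)
  est <- fit_glm(conc, des, ss_mode = "nearest", chromophores = "HbO")
  expect_equal(as.numeric(est$beta[1, 1, ]), b1[des$task_cols],
               tolerance = 1e-8)
  expect_equal(as.numeric(est$beta[2, 1, ]), b2[des$task_cols],
               tolerance = 1e-8)
  expect_equal(unname(est$nuisance_betas$HbO[[1]]["ss_S1D3"]), g[1],
               tolerance = 1e-8)
  # hrf = basis %*% beta exactly
  expect_equal(as.numeric(est$hrf[1, 1, ]),
               as.numeric(des$basis$B %*% est$beta[1, 1, ]),
               tolerance = 1e-12)
})

test_that("fit_glm equals brute-force normal equations on random instances", {
  fs <- 5
  lay <- make_layout(n_long = 1, n_short = 1)
  small <- basis_set(t_min = 0, t_max = 3.5, spacing = 0.5, sigma = 0.5,
                     fs = fs)
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 200
    st <- stim_design(sort(runif(3, 1, 25)) + c(0, 4, 8), 2,
                      rest_duration = 5)
    des <- build_design(st, small, fs, n, drift = "linear")
    y <- rnorm(n)
    ss <- rnorm(n)
    dat <- array(0, c(2, 2, n))
    dat[1, 1, ] <- y
    dat[2, 1, ] <- ss
    conc <- recording(dat, fs, "concentration", lay)
    est <- fit_glm(conc, des, ss_mode = "nearest", chromophores = "HbO")
    Xfull <- cbind(des$X, ss)
    bf <- solve(crossprod(Xfull), crossprod(Xfull, y))
    expect_equal(as.numeric(est$beta[1, 1, ]),
                 as.numeric(bf[des$task_cols]), tolerance = 1e-8)
    # residuals orthogonal to every design column
    resid <- y - Xfull %*% bf
    expect_lt(max(abs(crossprod(Xfull, resid))) / n, 1e-8)
    expect_equal(est$rss[1, 1], sum(resid^2), tolerance = 1e-8)
    expect_equal(est$dof[1, 1], n - ncol(Xfull))
  }
})

test_that("adding a short-channel regressor never increases the residual SS", {
  fs <- 5
  lay <- make_layout(n_long = 3, n_short = 2)
  st <- test_stim(2)
  truth <- simulation_truth(lay, seed = 31)
  conc <- simulate_hemodynamics(truth, st, stim_duration(st), fs)
  des <- build_design(st, basis_set(fs = fs), fs, dim(conc$data)[3])
  r_none <- fit_glm(conc, des, ss_mode = "none")$rss
  for (mode in c("nearest", "max_correlation", "all")) {
    r_ss <- fit_glm(conc, des, ss_mode = mode)$rss
    expect_true(all(r_ss <= r_none + 1e-10))
  }
})

test_that("short-separation regression suppresses superficial leakage", {
  # pooled over replicate simulations: the superficial process is shared
  # within one simulation, so a single draw is too noisy to threshold on
  fs <- 5
  lay <- make_layout(n_long = 6, n_short = 2)
  st <- test_stim(4)
  des <- build_design(st, basis_set(fs = fs),
                      fs, round(stim_duration(st) * fs))
  e_ss <- e_none <- numeric(0)
  for (r in 1:4) {
    truth <- simulation_truth(lay, hrf_amplitude = 0, seed = 16 + r)
    conc <- simulate_hemodynamics(truth, st, stim_duration(st), fs)
    pp <- preprocess(to_intensity(conc))
    e_ss <- c(e_ss, window_effect(fit_glm(pp$recording, des,
                                          ss_mode = "nearest",
                                          chromophores = "HbO"))[, 1])
    e_none <- c(e_none, window_effect(fit_glm(pp$recording, des,
                                              ss_mode = "none",
                                              chromophores = "HbO"))[, 1])
  }
  expect_gt(mean(abs(e_none)) / mean(abs(e_ss)), 5)
})

test_that("rank-deficient designs are rejected with a condition report", {
  fs <- 5
  lay <- make_layout(n_long = 1, n_short = 0)
  st <- test_stim(1)
  n <- 400
  des <- build_design(st, basis_set(fs = fs), fs, n)
  des$X[, 2] <- des$X[, 1]
  conc <- recording(array(rnorm(2 * n), c(1, 2, n)), fs, "concentration", lay)
  expect_error(fit_glm(conc, des, ss_mode = "none"), "rank deficient")
})

test_that("averaging HRF estimates groups and converges", {
  time <- seq(-2, 60, by = 0.2)
  truth_h <- canonical_hrf(time)
  # single estimate averages to itself
  e1 <- manual_estimates(list(truth_h), meta = list(subject = "a", day = 1))
  avg1 <- average_hrf(list(e1))
  expect_equal(avg1[[1]]$hrf, e1$hrf)
  expect_equal(avg1[[1]]$meta$n, 1)
  # h and -h cancel
  e2 <- manual_estimates(list(-truth_h), meta = list(subject = "a", day = 1))
  expect_equal(max(abs(average_hrf(list(e1, e2))[[1]]$hrf)), 0)
  # grouping by subject_day splits days, by subject pools them
  e3 <- manual_estimates(list(truth_h), meta = list(subject = "a", day = 2))
  expect_equal(length(average_hrf(list(e1, e2, e3))), 2)
  expect_equal(length(average_hrf(list(e1, e2, e3), group_by = "subject")), 1)
  expect_error(average_hrf(list()), "empty group")

  # 50 noisy replicates: the average is closer to truth than typical singles
  set.seed(5)
  noisy <- lapply(1:50, function(i)
    manual_estimates(list(truth_h + rnorm(length(time), 0, 0.3)),
                     meta = list(subject = "s", day = 1)))
  avg <- average_hrf(noisy)[[1]]
  rmse <- function(h) sqrt(mean((h - truth_h)^2))
  single_rmse <- vapply(noisy, function(e) rmse(e$hrf[1, 1, ]), numeric(1))
  expect_lt(rmse(avg$hrf[1, 1, ]), median(single_rmse))
})

test_that("windowed effects reduce the HRF as specified", {
  time <- seq(-2, 60, by = 0.2)
  z <- manual_estimates(list(rep(0, length(time))))
  expect_equal(unname(window_effect(z)[1, 1]), 0)
  stepfn <- ifelse(time >= 0 & time <= 20, 1, 0)
  s <- manual_estimates(list(stepfn))
  expect_equal(unname(window_effect(s)[1, 1]), 1)
  expect_error(window_effect(s, window = c(100, 101)), "empty window")

  # noiseless pipeline effect equals the windowed mean of the convolved truth
  fs <- 5
  lay <- make_layout(n_long = 1, n_short = 1)
  st <- test_stim(3)
  dur <- stim_duration(st)
  truth <- quiet_truth(lay, hrf_amplitude = 1, seed = 1)
  conc <- simulate_hemodynamics(truth, st, dur, fs)
  des <- build_design(st, basis_set(fs = fs), fs, dim(conc$data)[3])
  est <- fit_glm(conc, des, ss_mode = "none", chromophores = "HbO")
  tr <- task_response_truth(st, dur, fs)
  t <- (seq_len(length(tr)) - 1) / fs
  on <- st$block_onsets[1]
  oracle <- mean(tr[t >= on & t <= on + 20]) -
    mean(tr[t >= on - 2 & t <= on])
  expect_equal(unname(window_effect(est)[1, 1]), oracle, tolerance = 0.02)
})
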