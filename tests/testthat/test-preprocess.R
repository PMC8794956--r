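test_that("decimation preserves the passband and kills aliases", {
  fs1 <- 1000
  t1 <- seq(0, 10, by = 1 / fs1)
  d50 <- decimate_signal(sin(2 * pi * 50 * t1), fs1, 4)
  expect_equal(attr(d50, "fs"), 250)
  expect_equal(length(d50), ceiling(length(t1) / 4))
  interior <- 300:2000
  expect_equal(sd(d50[interior]) * sqrt(2), 1, tolerance = 0.01)

  d200 <- decimate_signal(sin(2 * pi * 200 * t1), fs1, 4)
  expect_lt(max(abs(d200[interior])), 0.01)

  dc <- decimate_signal(rep(3, 4000), fs1, 4)
  expect_equal(as.numeric(dc), rep(3, 1000), tolerance = 1e-6)

  expect_message(decimate_signal(1:10, 250, 1), "already at target rate")
})

test_that("EEG band-pass is zero-phase with the stated band edges", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  y <- bandpass_eeg(sin(2 * pi * 10 * t) + 100, fs)
  idx <- 2000:8000
  fit <- lm(y[idx] ~ sin(2 * pi * 10 * t[idx]) + cos(2 * pi * 10 * t[idx]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  phase <- atan2(coef(fit)[2], coef(fit)[1])
  expect_gte(amp, 0.99)
  expect_lt(abs(phase), 0.01)

  expect_lt(abs(mean(bandpass_eeg(rep(100, 10000), fs))), 1)

  drift <- bandpass_eeg(sin(2 * pi * 0.2 * t), fs)
  expect_lt(max(abs(drift[idx])), 10^(-20 / 20))

  expect_error(bandpass_eeg(rnorm(10), fs), "too short")
})

test_that("band-passed broadband signal has zero cross-correlation lag", {
  x <- withr::with_seed(1, rnorm(5000))
  y <- bandpass_eeg(x)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("channel exclusion applies the 30 kOhm boundary and manual flags", {
  meta <- tibble::tibble(
    name = c("M2", "V1", "E3", "E4"), site = c("M2", "V1", "other", "other"),
    impedance_kohm = c(10, 29.9, 30, 30.1), manual_exclude = FALSE)
  out <- exclude_channels(meta)
  expect_equal(out$kept, c(TRUE, TRUE, TRUE, FALSE))  # exactly 30 is kept

  meta$impedance_kohm <- c(10, 12, 14, 16)
  meta$manual_exclude <- c(FALSE, FALSE, TRUE, FALSE)
  expect_equal(exclude_channels(meta)$kept, c(TRUE, TRUE, FALSE, TRUE))

  empty <- meta[0, ]
  expect_equal(nrow(exclude_channels(empty)), 0)

  meta$impedance_kohm[1] <- 45
  expect_error(exclude_channels(meta), "M2")
})

test_that("artifact windows follow the hard-limit / 6-sigma rule", {
  fs <- 250
  x <- withr::with_seed(2, rnorm(fs * 120, sd = 30))
  m0 <- detect_artifact_windows(x, fs)
  expect_lt(mean(m0$masked), 0.02)   # P(|N(0,sigma)| > 6 sigma) is ~1e-9/sample

  x_spike <- x
  x_spike[fs * 30 + 5] <- 1500       # window 8 (seconds 28-32)
  m1 <- detect_artifact_windows(x_spike, fs)
  expect_true(m1$masked[8])
  expect_equal(sum(m1$masked) - sum(m0$masked), 1)

  x_small <- x
  x_small[fs * 50 + 5] <- 5 * attr(m0, "sigma")
  m2 <- detect_artifact_windows(x_small, fs)
  expect_false(m2$masked[13])

  expect_error(detect_artifact_windows(rep(900, fs * 8), fs), "channel dropped")
})

test_that("raising the sigma multiple never masks more windows", {
  fs <- 250
  x <- withr::with_seed(3, rnorm(fs * 200, sd = 30))
  x[sample.int(length(x), 40)] <- x[sample.int(length(x), 40)] + 250
  masked <- vapply(c(3, 4, 5, 6, 8), function(k) {
    sum(detect_artifact_windows(x, fs, sigma_multiple = k)$masked)
  }, numeric(1))
  expect_true(all(diff(masked) <= 0))
})

test_that("sigma estimation excludes rail samples and high-EMG seconds", {
  fs <- 250
  x <- withr::with_seed(4, rnorm(fs * 100, sd = 30))
  clean_sigma <- attr(detect_artifact_windows(x, fs), "sigma")
  x2 <- x
  x2[1:(10 * fs)] <- x2[1:(10 * fs)] * 20          # contaminated first 10 s
  high <- c(rep(TRUE, 10), rep(FALSE, 90))
  sig_excl <- attr(detect_artifact_windows(x2, fs, high_emg = high), "sigma")
  expect_equal(sig_excl, clean_sigma, tolerance = 0.05)
  sig_incl <- attr(detect_artifact_windows(x2, fs), "sigma")
  expect_gt(sig_incl, 2 * clean_sigma)
})

test_that("mean re-referencing conserves a zero per-sample sum", {
  x <- withr::with_seed(5, matrix(rnorm(3000), ncol = 3))
  y <- mean_rereference(x)
  expect_lt(max(abs(rowSums(y))), 1e-9 * max(abs(x)))

  two <- cbind(a = x[, 1], b = x[, 1])
  expect_true(all(abs(mean_rereference(two)) < 1e-12))

  pm <- cbind(x[, 1], -x[, 1])
  expect_equal(mean_rereference(pm), pm)

  expect_warning(mean_rereference(x[, 1, drop = FALSE]), "single|one")
})

test_that("preprocessing a recording yields masks, sigma and tone threshold", {
  prep <- mini_individual()$induction
  expect_true(prep$preprocessed)
  expect_named(prep$sigma, c("M2", "V1"))
  expect_s3_class(prep$emg_tone$mask, "tbl_df")
  expect_true(all(prep$mask$masked %in% c(TRUE, FALSE)))
  iv <- mask_intervals(prep$mask)
  expect_equal(nrow(iv), sum(prep$mask$masked))
})
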