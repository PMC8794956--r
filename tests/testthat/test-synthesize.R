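const_traj <- function(state, total_s = 120) {
  tibble::tibble(time_s = seq(0, total_s, by = 0.25),
                 x = ifelse(state == 1, 1, -1), state = as.integer(state))
}

flat_templates <- function(level = 100) {
  t <- make_spectral_templates(1)
  t$power$awake[] <- level
  t$power$anesthetized[] <- level
  t
}

# Independent spectral oracle: smoothed periodogram via stats::spec.pgram.
welch_band <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 31,
                          taper = 0, plot = FALSE, detrend = TRUE)
  mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

test_that("flat template synthesizes white noise", {
  eeg <- synthesize_eeg(const_traj(0), flat_templates(), seed = 1,
                        modulation_sd = 0, rough_sd = 0)[[1]]$eeg
  p_low <- welch_band(eeg[, 1], 250, 5, 40)
  p_high <- welch_band(eeg[, 1], 250, 60, 110)
  expect_equal(p_low / p_high, 1, tolerance = 0.15)
})

test_that("state templates set the delta-band contrast", {
  tm <- make_spectral_templates(3, band_sigma = 0)
  awake <- synthesize_eeg(const_traj(0, 60), tm, seed = 2,
                          modulation_sd = 0, rough_sd = 0)[[1]]$eeg[, 1]
  anes <- synthesize_eeg(const_traj(1, 60), tm, seed = 2,
                         modulation_sd = 0, rough_sd = 0)[[1]]$eeg[, 1]
  f <- tm$freq
  band <- f >= 0.5 & f <= 4
  tpl_ratio <- mean(tm$power$anesthetized[band, "M2"]) /
    mean(tm$power$awake[band, "M2"])
  obs_ratio <- welch_band(anes, 250, 0.5, 4) / welch_band(awake, 250, 0.5, 4)
  expect_equal(obs_ratio / tpl_ratio, 1, tolerance = 0.2)
})

test_that("EEG synthesis is bit-identical per seed", {
  tm <- make_spectral_templates(1)
  a <- synthesize_eeg(const_traj(0), tm, seed = 5)[[1]]$eeg
  b <- synthesize_eeg(const_traj(0), tm, seed = 5)[[1]]$eeg
  expect_identical(a, b)
})

test_that("EMG bursts follow the awake-bout Poisson process", {
  # Fully awake, 2 bursts/min, 10 min: expect ~20 bursts; Poisson 99%
  # interval of a mean-20 count is roughly [9, 32].
  segs <- synthesize_emg(const_traj(0, 600), seed = 8)
  n_bursts <- nrow(attr(segs, "bursts"))
  expect_gte(n_bursts, qpois(0.005, 20))
  expect_lte(n_bursts, qpois(0.995, 20))

  quiet <- synthesize_emg(const_traj(1, 600), seed = 9)
  expect_equal(nrow(attr(quiet, "bursts")), 0)
  rms <- emg_rms_series(quiet[[1]]$emg)
  # unimodal: dispersion of log RMS is tiny
  expect_lt(sd(log10(rms$rms)), 0.05)
})

test_that("burst amplitude sets the high/low RMS mode ratio", {
  segs <- synthesize_emg(const_traj(0, 1200), seed = 10,
                         burst_rate_per_min = 6, burst_amp = 8)
  lr <- log10(emg_rms_series(segs[[1]]$emg)$rms)
  d <- density(lr, bw = 0.05)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- peaks[d$y[peaks] > 0.05 * max(d$y)]
  expect_gte(length(peaks), 2)
  ratio <- 10^(max(d$x[peaks]) - min(d$x[peaks]))
  expect_gt(ratio, 8 * 0.75)
  expect_lt(ratio, 8 * 1.25)
})

test_that("artifact injection is sparse, marked, and above the hard limit", {
  co <- generate_cohort(n_individuals = 1, seed = 31, spans = mini_spans,
                        artifact_rate_per_min = 0)
  rec0 <- co[[1]]
  expect_equal(nrow(rec0$artifacts), 0)
  rec1 <- inject_artifacts(rec0, rate_per_min = 0, amplitude = 1500, seed = 1)
  expect_identical(rec1$segments[[1]]$eeg, rec0$segments[[1]]$eeg)

  rec2 <- inject_artifacts(rec0, rate_per_min = 0.5, amplitude = 1500, seed = 2)
  expect_gt(nrow(rec2$artifacts), 0)
  fs <- rec2$fs
  for (r in seq_len(nrow(rec2$artifacts))) {
    seg <- rec2$segments[[1]]
    i0 <- round((rec2$artifacts$time_s[r] - seg$start_s) * fs) + 1
    ch <- match(rec2$artifacts$channel[r], colnames(seg$eeg))
    peak <- max(abs(seg$eeg[i0:(i0 + 5), ch]))
    expect_gt(peak, 700)
  }
})

test_that("injected artifacts are recovered by window detection", {
  # Round trip across synthesis -> preprocessing: >= 95% of 4-s windows
  # containing an injected >= 1000 uV transient must be masked.
  co <- generate_cohort(n_individuals = 1, seed = 33, spans = mini_spans,
                        artifact_rate_per_min = 0)
  rec <- inject_artifacts(co[[2]], rate_per_min = 1, amplitude = 1500, seed = 3)
  prep <- preprocess_recording(rec)
  hits <- vapply(seq_len(nrow(rec$artifacts)), function(r) {
    t <- rec$artifacts$time_s[r]
    any(prep$mask$masked & t >= prep$mask$start_s & t < prep$mask$start_s + 4)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohorts are reproducible and correctly sized", {
  c1 <- generate_cohort(n_individuals = 2, seed = 77, spans = mini_spans)
  c2 <- generate_cohort(n_individuals = 2, seed = 77, spans = mini_spans)
  expect_equal(length(c1), 4)
  expect_identical(c1[[1]]$segments[[1]]$eeg, c2[[1]]$segments[[1]]$eeg)
  expect_identical(c1[[4]]$segments[[2]]$emg, c2[[4]]$segments[[2]]$emg)
  arms <- vapply(c1, function(r) r$arm, "")
  expect_equal(arms, c("induction", "emergence", "induction", "emergence"))
})
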