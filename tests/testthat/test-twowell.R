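short_schedule <- function(total_s = 600, conc = 0.6) {
  s <- tibble::tibble(time_s = 0, conc = conc)
  attr(s, "total_s") <- total_s
  attr(s, "final_step_s") <- 0
  attr(s, "arm") <- "induction"
  s
}

test_that("noiseless particle stays in the awake well", {
  cfg <- two_well_config(noise_amplitude = 0)
  traj <- simulate_two_well(cfg, short_schedule(), seed = 1)
  expect_true(all(traj$state == 0))
  expect_true(all(abs(traj$x + 1) < 1e-6))
})

test_that("symmetric wells give 0.5 occupancy on long runs", {
  # High noise for fast mixing; 4000 s >> dwell time at D = 0.15.
  cfg <- two_well_config(noise_amplitude = 0.15)
  occ <- vapply(1:4, function(s) {
    traj <- simulate_two_well(cfg, short_schedule(4000), seed = s)
    occupancy(traj, 0, 4000)
  }, numeric(1))
  expect_equal(mean(occ), 0.5, tolerance = 0.08)
})

test_that("simulated escape times match the Kramers estimate", {
  d <- 0.08
  et <- escape_times(200, a = 1, b = 1, D = d, dt = 0.01, seed = 3)
  expect_gte(length(et), 200)
  ratio <- mean(et) * kramers_rate(1, 1, d)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("trajectories are deterministic in (config, seed) and reject bad dt", {
  cfg <- two_well_config(noise_amplitude = 0.05)
  t1 <- simulate_two_well(cfg, short_schedule(), seed = 9)
  t2 <- simulate_two_well(cfg, short_schedule(), seed = 9)
  expect_identical(t1$x, t2$x)
  t3 <- simulate_two_well(cfg, short_schedule(), seed = 10)
  expect_false(identical(t1$x, t3$x))
  expect_error(two_well_config(a = -1))
  expect_error(
    simulate_two_well(two_well_config(dt = 1), short_schedule(), seed = 1),
    "dt too large")
})

test_that("occupancy handles trivial and degenerate inputs", {
  traj <- tibble::tibble(time_s = 0:99, x = 1, state = 1L)
  expect_equal(occupancy(traj, 0, 100), 1)
  traj$state <- rep(c(0L, 1L), 50)
  expect_equal(occupancy(traj, 0, 100), 0.5)
  expect_error(occupancy(traj, 50, 50), "empty interval")
  expect_error(occupancy(traj, 200, 300), "outside the trajectory")
})

test_that("noise_for_relaxation inverts the Kramers relation", {
  d <- noise_for_relaxation(2400)
  expect_equal(1 / (2 * kramers_rate(D = d)), 2400, tolerance = 1e-9)
  expect_error(noise_for_relaxation(0.1), "too fast")
})

test_that("arm memory produces hysteresis that decays over the final step", {
  # Expected anesthetized fraction: emergence enters the symmetric step from
  # the anesthetized side, induction from the awake side; the gap shrinks.
  cfg <- two_well_config(noise_amplitude = noise_for_relaxation(40 * 60))
  ind <- simulate_state_mixture(cfg, make_exposure_timeline("induction"),
                                seed = 21, n_modules = 48)
  eme <- simulate_state_mixture(cfg, make_exposure_timeline("emergence"),
                                seed = 22, n_modules = 48)
  frac_mean <- function(tr, onset, lo, hi) {
    sel <- tr$time_s >= onset + lo * 60 & tr$time_s < onset + hi * 60
    mean(tr$frac[sel])
  }
  gap_early <- frac_mean(eme, 7200, 30, 50) - frac_mean(ind, 1800, 30, 50)
  gap_late <- frac_mean(eme, 7200, 110, 130) - frac_mean(ind, 1800, 110, 130)
  expect_gt(gap_early, 0)
  expect_lt(gap_late, gap_early)
})

test_that("state mixtures are deterministic and bounded", {
  cfg <- two_well_config(noise_amplitude = 0.08)
  m1 <- simulate_state_mixture(cfg, short_schedule(600), seed = 4, n_modules = 8)
  m2 <- simulate_state_mixture(cfg, short_schedule(600), seed = 4, n_modules = 8)
  expect_identical(m1$frac, m2$frac)
  expect_true(all(m1$frac >= 0 & m1$frac <= 1))
  expect_identical(m1$state, as.integer(m1$frac >= 0.5))
})
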