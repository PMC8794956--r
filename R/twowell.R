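#' Configure the double-well state-switching model
#'
#' The latent arousal state is modeled as Brownian motion of a particle in a
#' quartic double-well potential
#' \deqn{V(x) = \frac{a}{4}x^4 - \frac{b}{2}x^2 + c(t)\,x,}
#' with the negative-`x` well identified with the awake state and the
#' positive-`x` well with the anesthetized state. The tilt follows the
#' anesthetic concentration, \eqn{c(t) = -k\,(\mathrm{conc}(t) -
#' \mathrm{conc}_{ref})}, so concentrations above `reference_conc` deepen the
#' anesthetized well and concentrations below it deepen the awake well; at
#' `reference_conc` (default 0.6\%, the EC50-equivalent) the potential is
#' symmetric. The well depths set state occupancy and the noise amplitude `D`
#' sets how often the particle hops the barrier \eqn{\Delta V = b^2/(4a)}.
#'
#' @param a,b Quartic and quadratic potential coefficients (unitless, > 0).
#' @param tilt_gain Tilt per percent isoflurane (`k`, >= 0).
#' @param reference_conc Concentration (percent) at which the wells are
#'   symmetric.
#' @param noise_amplitude Diffusion constant `D` (unitless, >= 0).
#' @param dt Integration step in seconds.
#' @return A list of class `ni_sim_config`.
#' @seealso [simulate_two_well()], [kramers_rate()], [noise_for_relaxation()]
#' @export
two_well_config <- function(a = 1, b = 1, tilt_gain = 1, reference_conc = 0.6,
                            noise_amplitude = 0.0358, dt = 0.01) {
  stopifnot_scalar_number(a, "a", 0, strict_min = TRUE)
  stopifnot_scalar_number(b, "b", 0, strict_min = TRUE)
  stopifnot_scalar_number(tilt_gain, "tilt_gain", 0)
  stopifnot_scalar_number(reference_conc, "reference_conc", 0)
  stopifnot_scalar_number(noise_amplitude, "noise_amplitude", 0)
  stopifnot_scalar_number(dt, "dt", 0, strict_min = TRUE)
  structure(
    list(a = a, b = b, tilt_gain = tilt_gain, reference_conc = reference_conc,
         noise_amplitude = noise_amplitude, dt = dt),
    class = "ni_sim_config"
  )
}

#' Simulate a latent state trajectory over an exposure schedule
#'
#' Integrates the overdamped Langevin equation with the Euler--Maruyama
#' scheme, \eqn{x \leftarrow x - V'(x)\,dt + \sqrt{2 D\, dt}\; \mathcal{N}(0,1)},
#' over the full concentration schedule. The binary state is the sign of `x`
#' (positive = anesthetized); exact zeros keep the previous state.
#'
#' @param config An [two_well_config()] object.
#' @param schedule A schedule from [make_exposure_timeline()].
#' @param seed Integer seed; identical seed + config gives an identical
#'   trajectory.
#' @param x0 Initial condition: `"awake"` (awake-well minimum, the default:
#'   both paradigms begin in oxygen), `"anesthetized"`, `"random"` (either
#'   minimum with equal probability), or a number.
#' @param thin Keep every `thin`-th integration step in the output (the
#'   default records the path every 0.25 s; behavioral dwell times are
#'   minutes, so nothing of interest lives below that).
#' @return A tibble of class `ni_trajectory` with columns `time_s`, `x`,
#'   `state` (0 awake / 1 anesthetized) and attributes `dt` (output spacing)
#'   and `config`.
#' @export
simulate_two_well <- function(config, schedule, seed, x0 = "awake", thin = 25L) {
  stopifnot(inherits(config, "ni_sim_config"))
  validate_schedule(schedule)
  # Stability guard: the deterministic map x -> x - V'(x) dt must not overshoot
  # for |x| up to ~2x the well positions, i.e. dt * max|V''| well below 2.
  xm <- 2 * sqrt(config$b / config$a) + 2
  if (config$dt * (3 * config$a * xm^2 + config$b) > 2)
    stop("dt too large for stability with the stated potential coefficients", call. = FALSE)

  x_min <- sqrt(config$b / config$a)
  x_start <- if (is.numeric(x0)) {
    x0
  } else {
    switch(match.arg(x0, c("awake", "anesthetized", "random")),
      awake = -x_min,
      anesthetized = x_min,
      random = withr::with_seed(child_seed(seed, 7), sample(c(-1, 1), 1)) * x_min
    )
  }

  tilt <- -config$tilt_gain * (schedule$conc - config$reference_conc)
  path <- withr::with_seed(seed,
    ni_simulate_path(config$a, config$b, config$noise_amplitude, config$dt,
                     schedule$time_s, tilt, attr(schedule, "total_s"),
                     x_start, as.integer(thin))
  )
  out <- tibble::new_tibble(path, class = "ni_trajectory")
  attr(out, "dt") <- config$dt * thin
  attr(out, "config") <- config
  attr(out, "schedule") <- schedule
  out
}

#' Fraction of time spent in the anesthetized state
#'
#' @param traj A trajectory from [simulate_two_well()].
#' @param start_s,end_s Half-open interval `[start_s, end_s)` in seconds.
#' @return Fraction of samples with state 1, in `[0, 1]`.
#' @export
occupancy <- function(traj, start_s, end_s) {
  if (end_s <= start_s) stop("empty interval: end_s must exceed start_s", call. = FALSE)
  keep <- in_interval(traj$time_s, start_s, end_s)
  if (!any(keep)) stop("interval lies outside the trajectory", call. = FALSE)
  mean(traj$state[keep])
}

#' Kramers escape rate for the symmetric double well
#'
#' Closed-form small-noise estimate of the rate at which the particle escapes
#' one well over the barrier,
#' \deqn{r = \frac{\sqrt{V''(x_{min})\,|V''(x_{bar})|}}{2\pi}
#'        \exp(-\Delta V / D),}
#' with \eqn{\Delta V = b^2/(4a)}. Used as an independent oracle for the
#' simulator.
#'
#' @inheritParams two_well_config
#' @param D Noise amplitude.
#' @return Escape rate in 1/s (time unit of `dt`).
#' @export
kramers_rate <- function(a = 1, b = 1, D = 0.0358) {
  sqrt(2 * b * b) / (2 * pi) * exp(-(b^2 / (4 * a)) / D)
}

#' Noise amplitude for a target occupancy relaxation time
#'
#' In the symmetric well the occupancy imbalance decays with rate twice the
#' Kramers escape rate; this inverts that relation to find the `D` giving a
#' requested relaxation time constant.
#'
#' @inheritParams kramers_rate
#' @param relaxation_s Target time constant in seconds.
#' @export
noise_for_relaxation <- function(relaxation_s, a = 1, b = 1) {
  stopifnot_scalar_number(relaxation_s, "relaxation_s", 0, strict_min = TRUE)
  r <- 1 / (2 * relaxation_s)
  pref <- sqrt(2 * b * b) / (2 * pi)
  if (r >= pref) stop("relaxation target too fast for this barrier", call. = FALSE)
  (b^2 / (4 * a)) / log(pref / r)
}

#' Simulate the anesthetized fraction over an ensemble of two-well modules
#'
#' Runs `n_modules` independent two-well particles with identical
#' configuration, schedule and initial condition, and returns the fraction of
#' them in the anesthetized state over time. This is the cortical-ensemble
#' reading of the same energy landscape: each module switches stochastically
#' with the single-particle statistics (so the memory of the initial
#' condition decays with the same relaxation time), while the recorded EEG
#' reflects their aggregate, which tracks the expected occupancy with
#' `~1/sqrt(n_modules)` fluctuations instead of all-or-nothing bouts.
#'
#' @inheritParams simulate_two_well
#' @param n_modules Number of independent modules (default 48; 1 recovers the
#'   single-particle trajectory).
#' @return A tibble of class `ni_trajectory` with columns `time_s`, `frac`
#'   (anesthetized fraction) and `state` (majority state).
#' @export
simulate_state_mixture <- function(config, schedule, seed, n_modules = 48,
                                   x0 = "awake", thin = 25L) {
  acc <- NULL
  for (j in seq_len(n_modules)) {
    tr <- simulate_two_well(config, schedule, seed = child_seed(seed, 31 * j),
                            x0 = x0, thin = thin)
    acc <- if (is.null(acc)) tr$state else acc + tr$state
    if (j == 1) times <- tr$time_s
  }
  out <- tibble::new_tibble(
    list(time_s = times, frac = acc / n_modules,
         state = as.integer(acc / n_modules >= 0.5)),
    class = "ni_trajectory")
  attr(out, "dt") <- config$dt * thin
  attr(out, "config") <- config
  attr(out, "schedule") <- schedule
  out
}

#' Simulated first-passage escape times
#'
#' Draws first-passage times from one well minimum to the other in the
#' symmetric well; their mean is compared against `1 / kramers_rate()` in the
#' package's tests.
#'
#' @inheritParams kramers_rate
#' @param n Number of escapes to simulate.
#' @param dt Integration step (s).
#' @param seed Integer seed.
#' @param t_max Abort threshold per escape (s).
#' @return Numeric vector of `n` escape times (s).
#' @export
escape_times <- function(n, a = 1, b = 1, D = 0.1, dt = 0.01, seed = 1,
                         t_max = 1e6) {
  x_min <- sqrt(b / a)
  withr::with_seed(seed,
    ni_first_passage(a, b, D, dt, -x_min, x_min, as.integer(n), t_max))
}
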