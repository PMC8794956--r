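#' Generate one synthetic recording
#'
#' Simulates a latent two-well state trajectory over the requested exposure
#' paradigm and synthesizes the two EEG channels (M2, V1) plus an EMG channel
#' at 250 Hz, with ground-truth state labels and (optionally) injected
#' large-amplitude artifacts. Both paradigms start in oxygen, so the particle
#' starts in the awake well unless `x0` overrides it.
#'
#' @param individual Individual identifier (integer).
#' @param arm `"induction"` or `"emergence"`.
#' @param config A [two_well_config()].
#' @param templates The individual's [make_spectral_templates()].
#' @param seed Integer seed; all randomness below derives from it.
#' @param spans_min `NULL` for the full recording, or a list of
#'   `c(start, end)` intervals in minutes (multiples of 4 s) to synthesize --
#'   trajectory simulation always covers the full schedule so state memory is
#'   correct, only signal synthesis is restricted.
#' @param x0 Initial condition passed to [simulate_state_mixture()].
#' @param n_modules Independent two-well modules averaged into the spectral
#'   drive (see [simulate_state_mixture()]); 1 gives the raw single-particle
#'   trajectory.
#' @param artifact_rate_per_min,artifact_amplitude Artifact injection
#'   parameters (rate 0 disables).
#' @param emg_args List of overrides for [synthesize_emg()].
#' @param modulation_sd,rough_sd Per-window spectral modulation (dB), see
#'   [synthesize_eeg()].
#' @return An object of class `ni_recording`: list with `individual`, `arm`,
#'   `schedule`, `fs`, `segments` (each `list(start_s, eeg, emg)`), `channels`
#'   metadata tibble, ground-truth `state` tibble, `artifacts` table and the
#'   seeds used.
#' @export
generate_recording <- function(individual, arm, config, templates, seed,
                               spans_min = NULL, x0 = "awake",
                               artifact_rate_per_min = 0.1,
                               artifact_amplitude = 1500,
                               emg_args = list(), modulation_sd = 4.5,
                               rough_sd = 3.2, n_modules = 48) {
  schedule <- make_exposure_timeline(arm)
  traj <- simulate_state_mixture(config, schedule, seed = child_seed(seed, 1),
                                 n_modules = n_modules, x0 = x0)
  spans_s <- if (is.null(spans_min)) NULL else lapply(spans_min, function(sp) sp * 60)

  eeg_segs <- synthesize_eeg(traj, templates, seed = child_seed(seed, 2),
                             spans_s = spans_s, modulation_sd = modulation_sd,
                             rough_sd = rough_sd)
  emg_segs <- do.call(synthesize_emg,
                      c(list(traj = traj, seed = child_seed(seed, 3),
                             spans_s = spans_s), emg_args))

  segments <- purrr::map2(eeg_segs, emg_segs, function(e, m)
    list(start_s = e$start_s, eeg = e$eeg, emg = m$emg))

  rec <- structure(list(
    individual = individual,
    arm = arm,
    schedule = schedule,
    fs = 250,
    segments = segments,
    channels = tibble::tibble(
      name = c("M2", "V1", "EMG1"),
      site = c("M2", "V1", "EMG"),
      impedance_kohm = c(12, 15, 8),
      manual_exclude = FALSE),
    state = tibble::tibble(time_s = traj$time_s, frac = traj$frac,
                           state = traj$state),
    bursts = attr(emg_segs, "bursts"),
    artifacts = tibble::tibble(time_s = numeric(), channel = character()),
    seed = seed
  ), class = "ni_recording")

  if (artifact_rate_per_min > 0)
    rec <- inject_artifacts(rec, artifact_rate_per_min, artifact_amplitude,
                            seed = child_seed(seed, 4))
  rec
}

#' @export
print.ni_recording <- function(x, ...) {
  n_s <- sum(purrr::map_dbl(x$segments, ~ nrow(.x$eeg))) / x$fs
  cat(sprintf("<ni_recording> individual %s, %s arm: %d segment(s), %.0f s at %d Hz, %d artifact(s)\n",
              x$individual, x$arm, length(x$segments), n_s, x$fs,
              nrow(x$artifacts)))
  invisible(x)
}

# Analysis spans (minutes, absolute recording time) covering the classifier
# training windows (minutes 10-30 of each 0.6% step) and the test window
# (minutes 30-130 of the final 0.6% step) of each paradigm.
analysis_spans <- function(arm) {
  switch(arm,
    induction = list(c(40, 160)),
    emergence = list(c(40, 60), c(130, 250)))
}

#' Generate a paired induction/emergence cohort
#'
#' Generates `n_individuals` pairs of recordings. Each individual has its own
#' spectral templates (log-normal band gains) and its own noise amplitude
#' (+/-20\% jitter around the value implied by `relaxation_target_min`), so
#' interindividual spread in downstream classifier accuracy arises naturally.
#' The barrier is fixed at `a = b = 1` (height 0.25) and the noise amplitude
#' is chosen so the initial-condition memory of the final 0.6\% step decays
#' with the requested time constant; the tilt gain makes oxygen strongly
#' awake-tilted and 1.2\% strongly anesthetized-tilted, so the two arms enter
#' the final (symmetric) step from opposite wells. That construction *is* the
#' generated hysteresis: early in the final step the arms differ in state
#' occupancy and the difference decays toward zero.
#'
#' With `exchangeable = TRUE` the tilt gain is zero (wells symmetric under
#' every concentration), initial states are randomized, and relaxation is
#' fast, so induction- and emergence-labeled recordings are statistically
#' exchangeable and any downstream classifier must sit at chance.
#'
#' @param n_individuals Number of individuals (default 6).
#' @param relaxation_target_min Occupancy relaxation time constant (minutes)
#'   of the final-step memory (default 40).
#' @param seed Integer master seed; two cohorts with the same seed are
#'   identical.
#' @param spans `"analysis"` (default; synthesize only the training + test
#'   spans), `"full"`, or a list with elements `induction` / `emergence` of
#'   span lists in minutes.
#' @param exchangeable Generate an arm-exchangeable (null) cohort.
#' @param ... Passed to [generate_recording()].
#' @return A list of class `ni_cohort` of `2 * n_individuals` recordings
#'   (induction then emergence per individual), with a `manifest` attribute
#'   recording seeds and per-individual parameters.
#' @export
generate_cohort <- function(n_individuals = 6, relaxation_target_min = 40,
                            seed = 1, spans = "analysis",
                            exchangeable = FALSE, ...) {
  stopifnot(n_individuals >= 1)
  if (exchangeable && missing(relaxation_target_min)) relaxation_target_min <- 2
  # Individual variability: +/-20% jitter on the relaxation time (realized
  # through D), so every individual's memory timescale stays near the target.
  jit <- withr::with_seed(child_seed(seed, 99),
                          runif(n_individuals, 0.8, 1.2))
  span_list <- function(arm) {
    if (identical(spans, "full")) NULL
    else if (identical(spans, "analysis")) analysis_spans(arm)
    else spans[[arm]]
  }
  recs <- list()
  manifest <- list()
  for (i in seq_len(n_individuals)) {
    cfg <- two_well_config(a = 1, b = 1,
                           tilt_gain = if (exchangeable) 0 else 1,
                           noise_amplitude = noise_for_relaxation(
                             relaxation_target_min * 60 * jit[i]))
    tmpl <- make_spectral_templates(seed = child_seed(seed, 1000 + i))
    for (arm in c("induction", "emergence")) {
      rec <- generate_recording(
        individual = i, arm = arm, config = cfg, templates = tmpl,
        seed = child_seed(seed, 2000 + 2 * i + (arm == "emergence")),
        spans_min = span_list(arm),
        x0 = if (exchangeable) "random" else "awake", ...)
      recs[[length(recs) + 1]] <- rec
    }
    manifest[[i]] <- list(individual = i, noise_amplitude = cfg$noise_amplitude,
                          templates_seed = child_seed(seed, 1000 + i))
  }
  structure(recs, class = "ni_cohort",
            manifest = list(seed = seed, n_individuals = n_individuals,
                            relaxation_target_min = relaxation_target_min,
                            exchangeable = exchangeable,
                            individuals = manifest))
}

#' @export
print.ni_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<ni_cohort> %d individuals x 2 arms (seed %s, relaxation %g min%s)\n",
              m$n_individuals, m$seed, m$relaxation_target_min,
              if (m$exchangeable) ", exchangeable" else ""))
  invisible(x)
}
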