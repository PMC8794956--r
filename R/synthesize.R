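#' Synthesize EEG channels from a latent state trajectory
#'
#' Generates colored-noise EEG whose power spectrum tracks the latent state:
#' each 4-s synthesis block draws random-phase Fourier amplitudes proportional
#' to the square root of the active state's template power, and consecutive
#' blocks are joined with short raised-cosine cross-fades so state switches
#' never produce clicks. On top of the state template, every block receives an
#' independent smooth log-spectral modulation (a low-order cosine series in
#' frequency) emulating the within-state spectral wandering of real EEG at
#' anesthetic steady state.
#'
#' @param traj A trajectory from [simulate_two_well()].
#' @param templates Templates from [make_spectral_templates()].
#' @param seed Integer seed; identical inputs give a bit-identical signal.
#' @param spans_s List of `c(start, end)` intervals (seconds) to synthesize;
#'   `NULL` synthesizes the whole trajectory as one span.
#' @param fs Sample rate (Hz), 250 by default.
#' @param modulation_sd Per-bin standard deviation (dB) of the smooth
#'   log-spectral modulation; 0 disables it.
#' @param n_basis Number of cosine basis functions carrying the modulation.
#' @param rough_sd Per-bin standard deviation (dB) of an additional
#'   independent (bin-wise) log-spectral jitter per window. Together with
#'   `modulation_sd` this sets how much window-to-window spectral
#'   variability rides on top of the state templates; the defaults are the
#'   generator calibration placing the 50-PC variance share at 70--78\%.
#' @return A list of segments, each `list(start_s, eeg)` with `eeg` an
#'   `n x 2` matrix (columns M2, V1, in uV).
#' @export
synthesize_eeg <- function(traj, templates, seed, spans_s = NULL, fs = 250,
                           modulation_sd = 4.5, n_basis = 24, rough_sd = 3.2) {
  stopifnot(inherits(templates, "ni_templates"))
  if (is.null(spans_s)) spans_s <- list(c(0, max(traj$time_s)))
  frac_at <- traj_frac_fun(traj)
  withr::with_seed(seed, {
    lapply(spans_s, function(sp) {
      list(start_s = sp[1],
           eeg = synth_span(sp, frac_at, templates, fs, modulation_sd,
                            n_basis, rough_sd))
    })
  })
}

# Anesthetized-fraction lookup: mixture trajectories carry `frac`, plain
# single-particle trajectories a binary `state`.
traj_frac_fun <- function(traj) {
  y <- if (!is.null(traj[["frac"]])) traj[["frac"]] else traj[["state"]]
  stats::approxfun(traj$time_s, y, method = "constant", rule = 2, f = 0)
}

# One contiguous span: overlap-add of independently synthesized blocks.
# The block spectrum interpolates geometrically (linearly in dB) between the
# awake and anesthetized templates according to the anesthetized fraction.
synth_span <- function(span, frac_at, templates, fs, modulation_sd, n_basis,
                       rough_sd = 0) {
  hop_s <- 4
  hop <- hop_s * fs                      # 1000 samples at 250 Hz
  ov <- 64L                              # ~0.25 s raised-cosine cross-fade
  L <- hop + ov
  n <- round((span[2] - span[1]) * fs)
  n_blocks <- ceiling(n / hop)
  f_fft <- (0:(L / 2)) * fs / L
  df <- fs / L
  ramp_up <- sin(0.5 * pi * (1:ov) / ov)^2
  basis <- cos(pi * outer(templates$freq / max(templates$freq), seq_len(n_basis)))
  sd_coef <- if (n_basis > 0) modulation_sd * sqrt(2 / n_basis) else 0
  log_ratio <- log(templates$power$anesthetized / templates$power$awake)

  out <- matrix(0, n + L, 2)
  for (i in seq_len(n_blocks)) {
    t0 <- span[1] + (i - 1) * hop_s
    phi <- frac_at(t0 + hop_s / 2)
    pw <- templates$power$awake * exp(phi * log_ratio)
    block <- matrix(0, L, 2)
    for (ch in 1:2) {
      p <- pw[, ch]
      if (sd_coef > 0)
        p <- p * 10^((basis %*% rnorm(n_basis, 0, sd_coef)) / 10)
      if (rough_sd > 0)
        p <- p * 10^(rnorm(length(p), 0, rough_sd) / 10)
      p_fft <- approx(templates$freq, p, xout = f_fft, rule = 2)$y
      amp <- sqrt(2 * p_fft * df)
      phase <- runif(L / 2 - 1, 0, 2 * pi)
      z <- complex(modulus = c(0, amp[2:(L / 2)] * L / 2, 0),
                   argument = c(0, phase, 0))
      z <- c(z, Conj(rev(z[2:(L / 2)])))
      block[, ch] <- Re(fft(z, inverse = TRUE)) / L
    }
    w <- rep(1, L)
    if (i > 1) w[1:ov] <- ramp_up
    w[(L - ov + 1):L] <- rev(ramp_up)
    idx <- ((i - 1) * hop + 1):((i - 1) * hop + L)
    out[idx, ] <- out[idx, ] + block * w
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("M2", "V1")
  out
}

#' Synthesize an EMG channel from a latent state trajectory
#'
#' Produces low-amplitude baseline noise everywhere, with Poisson-distributed
#' movement bursts of elevated RMS confined to awake-state bouts (movement and
#' EMG tone are tightly coupled in mice, which is what the downstream high-EMG
#' rejection rule exploits). Over a recording that visits both states the 1-s
#' log-RMS distribution is therefore bimodal.
#'
#' @inheritParams synthesize_eeg
#' @param baseline_rms Baseline noise RMS (uV).
#' @param burst_rate_per_min Poisson rate of movement bursts during awake
#'   bouts.
#' @param burst_amp RMS ratio of burst seconds to baseline (default 8).
#' @param burst_mean_s Mean burst duration (gamma-distributed, shape 2).
#' @return List of segments `list(start_s, emg)`; the burst onset/offset
#'   table is attached as attribute `bursts`.
#' @export
synthesize_emg <- function(traj, seed, spans_s = NULL, fs = 250,
                           baseline_rms = 5, burst_rate_per_min = 2,
                           burst_amp = 8, burst_mean_s = 1.5) {
  if (is.null(spans_s)) spans_s <- list(c(0, max(traj$time_s)))
  frac_at <- traj_frac_fun(traj)
  burst_sd <- baseline_rms * sqrt(max(burst_amp^2 - 1, 0))
  all_bursts <- list()
  segs <- withr::with_seed(seed, lapply(spans_s, function(sp) {
    n <- round((sp[2] - sp[1]) * fs)
    x <- rnorm(n, 0, baseline_rms)
    # Inhomogeneous Poisson burst process: the rate scales with the awake
    # fraction, so a fully anesthetized stretch has no bursts at all.
    sec_t <- sp[1] + seq(0, by = 1, length.out = floor(n / fs))
    p_awake <- 1 - frac_at(sec_t + 0.5)
    nb_sec <- rpois(length(sec_t), burst_rate_per_min / 60 * p_awake)
    bursts <- NULL
    for (j in which(nb_sec > 0)) {
      on <- sec_t[j] + sort(runif(nb_sec[j]))
      dur <- stats::rgamma(nb_sec[j], shape = 2, scale = burst_mean_s / 2)
      off <- pmin(on + dur, sp[2])
      bursts <- rbind(bursts, cbind(on, off))
      for (k in seq_along(on)) {
        i0 <- max(1L, round((on[k] - sp[1]) * fs) + 1L)
        i1 <- min(n, round((off[k] - sp[1]) * fs))
        if (i1 >= i0) x[i0:i1] <- x[i0:i1] + rnorm(i1 - i0 + 1, 0, burst_sd)
      }
    }
    all_bursts[[length(all_bursts) + 1]] <<- bursts
    list(start_s = sp[1], emg = x)
  }))
  bursts <- do.call(rbind, all_bursts)
  attr(segs, "bursts") <- if (is.null(bursts)) {
    tibble::tibble(onset_s = numeric(), offset_s = numeric())
  } else {
    tibble::tibble(onset_s = bursts[, 1], offset_s = bursts[, 2])
  }
  segs
}

#' Inject large-amplitude artifacts into a synthetic recording
#'
#' Adds sparse decaying-exponential transients to one EEG channel at a time,
#' at Poisson-distributed times, and records their ground-truth locations so
#' tests can verify that artifact-window detection recovers them.
#'
#' @param rec A recording from [generate_recording()].
#' @param rate_per_min Mean artifact rate.
#' @param amplitude Peak amplitude (uV, > 0); at the 1500 uV default every
#'   transient exceeds the +/-700 uV hard rejection limit.
#' @param seed Integer seed.
#' @return The recording with transients added and the artifact table
#'   (columns `time_s`, `channel`) appended to `rec$artifacts`.
#' @export
inject_artifacts <- function(rec, rate_per_min, amplitude = 1500, seed = 1) {
  stopifnot(inherits(rec, "ni_recording"))
  stopifnot_scalar_number(amplitude, "amplitude", 0, strict_min = TRUE)
  if (rate_per_min == 0) return(rec)
  fs <- rec$fs
  pulse_n <- round(0.25 * fs)
  pulse <- exp(-(0:(pulse_n - 1)) / (0.06 * fs))
  events <- withr::with_seed(seed, {
    purrr::map(seq_along(rec$segments), function(si) {
      seg <- rec$segments[[si]]
      n <- nrow(seg$eeg)
      len_min <- n / fs / 60
      ne <- rpois(1, rate_per_min * len_min)
      if (ne == 0) return(NULL)
      at <- sort(sample.int(n - pulse_n, ne))
      ch <- sample(1:2, ne, replace = TRUE)
      sgn <- sample(c(-1, 1), ne, replace = TRUE)
      tibble::tibble(segment = si, sample = at, channel = colnames(seg$eeg)[ch],
                     ch_idx = ch, sign = sgn)
    })
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events)) {
    for (r in seq_len(nrow(events))) {
      si <- events$segment[r]
      idx <- events$sample[r]:(events$sample[r] + pulse_n - 1)
      rec$segments[[si]]$eeg[idx, events$ch_idx[r]] <-
        rec$segments[[si]]$eeg[idx, events$ch_idx[r]] +
        events$sign[r] * amplitude * pulse
    }
  }
  new_art <- if (nrow(events)) {
    tibble::tibble(
      time_s = purrr::map2_dbl(events$segment, events$sample,
                               ~ rec$segments[[.x]]$start_s + (.y - 1) / fs),
      channel = events$channel)
  } else {
    tibble::tibble(time_s = numeric(), channel = character())
  }
  rec$artifacts <- dplyr::bind_rows(rec$artifacts, new_art)
  rec
}
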