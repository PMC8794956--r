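#' High-pass filter EMG at 15 Hz
#'
#' Zero-phase 6th-order Butterworth high-pass, removing movement/respiration
#' baseline and most ECG energy before RMS tone estimation.
#'
#' @param x Numeric EMG signal at 250 Hz.
#' @param fs Sample rate.
#' @return Filtered signal.
#' @export
highpass_emg <- function(x, fs = 250) {
  if (length(x) < 9 * 6)
    stop("series too short to high-pass filter", call. = FALSE)
  hp <- signal::butter(6, 15 / (fs / 2), type = "high")
  filt_zerophase(hp, x)
}

#' Per-second RMS of an EMG signal
#'
#' Root-mean-square over non-overlapping 1-s periods; a trailing partial
#' second is dropped.
#'
#' @param x Numeric signal.
#' @param fs Sample rate.
#' @param start_s Time of the first sample (s).
#' @return Tibble with columns `time_s` (period start) and `rms` (uV).
#' @export
emg_rms_series <- function(x, fs = 250, start_s = 0) {
  n_sec <- floor(length(x) / fs)
  if (n_sec < 1) stop("need at least one full second of signal", call. = FALSE)
  m <- matrix(x[seq_len(n_sec * fs)], nrow = fs)
  tibble::tibble(time_s = start_s + seq_len(n_sec) - 1,
                 rms = sqrt(colMeans(m^2)))
}

#' Threshold high EMG tone by the CDF-slope rule
#'
#' Movement epochs make the 1-s log-RMS distribution bimodal: a tight main
#' mode of quiet muscle plus a high-amplitude movement mode. The rule
#' estimates a kernel-smoothed cumulative distribution of the centered
#' log10 RMS on a uniform grid and, scanning upward from the distribution's
#' main mode, takes the first grid point where the CDF slope (the smoothed
#' density) drops below 1 as the high-tone threshold. Centering the log RMS
#' makes the rule invariant to multiplying the EMG signal by any positive
#' constant; the natural log10 spread is retained because the slope-below-1
#' criterion is only meaningful when the quiet mode is tight on that scale.
#' If the slope never reaches 1 anywhere, no movement mode is resolvable and
#' an all-false mask is returned with a warning.
#'
#' @param rms Tibble from [emg_rms_series()] (>= 300 values recommended for a
#'   stable estimate).
#' @param n_grid Grid size for the smoothed CDF (default 512).
#' @return List of class `ni_emg_tone`: `mask` (tibble `time_s`, `high`),
#'   `threshold` (on the centered log10 scale), `threshold_rms` (back on the
#'   uV scale), and the `slope` curve tibble.
#' @export
high_tone_threshold <- function(rms, n_grid = 512) {
  stopifnot(all(c("time_s", "rms") %in% names(rms)))
  if (nrow(rms) < 300)
    warning("fewer than 300 RMS values; threshold may be unstable")
  lr <- log10(pmax(rms$rms, .Machine$double.eps))
  center <- median(lr)
  z <- lr - center
  if (sd(z) < 1e-12) {
    warning("degenerate (constant) RMS series; no high-tone periods flagged")
    return(structure(list(
      mask = tibble::tibble(time_s = rms$time_s, high = FALSE),
      threshold = Inf, threshold_rms = Inf,
      slope = tibble::tibble(z = numeric(), slope = numeric())),
      class = "ni_emg_tone"))
  }
  bw <- stats::bw.nrd0(z)
  grid <- seq(min(z) - 3 * bw, max(z) + 3 * bw, length.out = n_grid)
  # Gaussian-kernel smoothed empirical CDF; its derivative is the density.
  slope <- vapply(grid, function(g) mean(dnorm((g - z) / bw)) / bw, numeric(1))
  mode_i <- which.max(slope)
  if (slope[mode_i] <= 1) {
    warning("CDF slope never exceeds 1; no movement mode resolvable, no high-tone periods flagged")
    thr <- Inf
  } else {
    after <- which(slope < 1 & seq_along(slope) > mode_i)
    thr <- if (length(after)) grid[after[1]] else Inf
  }
  structure(list(
    mask = tibble::tibble(time_s = rms$time_s, high = z > thr),
    threshold = thr,
    threshold_rms = 10^(thr + center),
    slope = tibble::tibble(z = grid, slope = slope)),
    class = "ni_emg_tone")
}

#' @export
print.ni_emg_tone <- function(x, ...) {
  cat(sprintf("<ni_emg_tone> threshold %.3g uV RMS; %d / %d seconds high tone\n",
              x$threshold_rms, sum(x$mask$high), nrow(x$mask)))
  invisible(x)
}
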