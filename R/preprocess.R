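# Zero-phase filtering with odd-reflection end padding, which suppresses the
# start/end transients of plain forward-backward filtering.
filt_zerophase <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, 300)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

#' Decimate a signal to 250 Hz
#'
#' Anti-aliases with an 8th-order zero-phase Butterworth low-pass (cutoff at
#' 0.8 x the new Nyquist frequency) and keeps every `factor`-th sample, the
#' standard conditioning step for 1 kHz acquisitions before spectral analysis.
#'
#' @param x Numeric signal.
#' @param fs_in Input sample rate (Hz).
#' @param factor Integer decimation factor; `fs_in / factor` must be 250 by
#'   pipeline convention but any factor >= 1 is accepted here.
#' @return Numeric vector of length `ceiling(length(x) / factor)` with
#'   attribute `fs` = `fs_in / factor`.
#' @export
decimate_signal <- function(x, fs_in = 1000, factor = 4) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) {
    message("signal already at target rate; returning unchanged")
    return(structure(x, fs = fs_in))
  }
  fs_out <- fs_in / factor
  lp <- signal::butter(8, (0.8 * fs_out / 2) / (fs_in / 2), type = "low")
  y <- filt_zerophase(lp, x)[seq(1, length(x), by = factor)]
  structure(y, fs = fs_out)
}

#' Band-pass filter EEG between 1 and 120 Hz
#'
#' Zero-phase (forward--backward) 6th-order Butterworth band-pass, applied as
#' a cascade of the 1-Hz high-pass and 120-Hz low-pass sections; the squared
#' magnitude response doubles the effective attenuation and cancels the phase,
#' so the output has no lag relative to the input.
#'
#' @param x Numeric signal at 250 Hz.
#' @param fs Sample rate (must be 250).
#' @return Filtered signal.
#' @export
bandpass_eeg <- function(x, fs = 250) {
  if (length(x) < 9 * 6)  # forward-backward 6th order needs padding room
    stop("series too short to band-pass filter", call. = FALSE)
  hp <- signal::butter(6, 1 / (fs / 2), type = "high")
  lp <- signal::butter(6, 120 / (fs / 2), type = "low")
  filt_zerophase(lp, filt_zerophase(hp, x))
}

#' Exclude channels by impedance and manual flag
#'
#' Channels whose measured impedance exceeds 30 kOhm (strictly greater;
#' exactly 30 is kept) or that carry a manual exclusion flag are dropped.
#' Losing either analysis channel (M2 or V1) is fatal downstream, so that
#' condition raises an error rather than a silent exclusion.
#'
#' @param meta Tibble with columns `name`, `site`, `impedance_kohm`,
#'   `manual_exclude`.
#' @param threshold_kohm Exclusion threshold (default 30).
#' @return `meta` with an added logical column `kept`.
#' @export
exclude_channels <- function(meta, threshold_kohm = 30) {
  if (nrow(meta) == 0) return(dplyr::mutate(meta, kept = logical(0)))
  out <- dplyr::mutate(meta,
    kept = .data$impedance_kohm <= threshold_kohm & !.data$manual_exclude)
  bad <- dplyr::filter(out, .data$site %in% c("M2", "V1"), !.data$kept)
  if (nrow(bad) > 0)
    stop("analysis channel(s) excluded: ", paste(bad$name, collapse = ", "),
         "; both M2 and V1 are required", call. = FALSE)
  out
}

#' Detect artifactual 4-s windows in one channel
#'
#' Implements the two-stage amplitude rule: the channel's noise scale `sigma`
#' is the standard deviation of all samples, excluding samples beyond the
#' +/-`hard_limit` rail and samples inside high-EMG seconds (both of which
#' would inflate it); a 4-s window is then masked if any of its samples
#' exceeds `sigma_multiple * sigma` or the hard limit (strictly greater in
#' both cases -- a sample at exactly the threshold is kept).
#'
#' @param x Numeric signal (one channel) at `fs` Hz.
#' @param fs Sample rate.
#' @param high_emg Optional logical vector, one element per second of `x`,
#'   `TRUE` for high-EMG-tone seconds to exclude from the sigma estimate.
#' @param hard_limit Hard amplitude limit in uV (default 700).
#' @param sigma_multiple Multiplier on sigma (default 6).
#' @param window_s Window length in seconds (default 4, the spectral grid).
#' @param start_s Time of the first sample (used only for reporting).
#' @return Tibble of class `ni_artifact_mask` with columns `window`,
#'   `start_s`, `masked`; attributes `sigma` and `n_masked`.
#' @export
detect_artifact_windows <- function(x, fs = 250, high_emg = NULL,
                                    hard_limit = 700, sigma_multiple = 6,
                                    window_s = 4, start_s = 0) {
  stopifnot_scalar_number(hard_limit, "hard_limit", 0, strict_min = TRUE)
  stopifnot_scalar_number(sigma_multiple, "sigma_multiple", 0, strict_min = TRUE)
  keep <- abs(x) <= hard_limit
  if (!is.null(high_emg)) {
    sec <- pmin(floor((seq_along(x) - 1) / fs) + 1, length(high_emg))
    keep <- keep & !high_emg[sec]
  }
  if (!any(keep))
    stop("all samples excluded from sigma estimation; channel dropped", call. = FALSE)
  sigma <- sd(x[keep])
  thr <- min(sigma_multiple * sigma, hard_limit)
  n_win <- floor(length(x) / (window_s * fs))
  wlen <- window_s * fs
  masked <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    any(abs(seg) > thr)
  }, logical(1))
  out <- tibble::new_tibble(
    list(window = seq_len(n_win),
         start_s = start_s + (seq_len(n_win) - 1) * window_s,
         masked = masked),
    class = "ni_artifact_mask")
  attr(out, "sigma") <- sigma
  attr(out, "n_masked") <- sum(masked)
  out
}

#' Mean re-reference a set of channels
#'
#' Subtracts the across-channel mean from every retained channel at each
#' sample, removing common-mode signal; the per-sample sum of the output is
#' zero by construction. With a single channel this is a no-op (warning).
#'
#' @param channels Numeric matrix, samples x channels.
#' @return Matrix of the same shape.
#' @export
mean_rereference <- function(channels) {
  channels <- as.matrix(channels)
  if (ncol(channels) < 2) {
    warning("only one retained channel; mean re-referencing skipped")
    return(channels)
  }
  channels - rowMeans(channels)
}

#' Preprocess a recording
#'
#' Runs the signal-conditioning chain on a synthetic or imported recording:
#' band-pass filter both EEG channels (1--120 Hz, zero phase), high-pass and
#' threshold the EMG to find high-tone seconds, detect artifactual 4-s
#' windows per channel with the hard-limit / 6-sigma rule, and mean
#' re-reference the retained EEG channels. Channel exclusion by impedance is
#' applied first; the two analysis channels must survive it.
#'
#' @param rec An `ni_recording`.
#' @param hard_limit,sigma_multiple Artifact parameters, see
#'   [detect_artifact_windows()].
#' @param impedance_threshold Channel exclusion threshold (kOhm).
#' @return The recording with filtered `segments`, per-segment-window
#'   `mask` tibble (a window is masked if either EEG channel flags it),
#'   `emg_tone` (see [high_tone_threshold()]) and `sigma` per channel.
#' @export
preprocess_recording <- function(rec, hard_limit = 700, sigma_multiple = 6,
                                 impedance_threshold = 30) {
  stopifnot(inherits(rec, "ni_recording"))
  rec$channels <- exclude_channels(rec$channels, impedance_threshold)

  # EMG tone over all segments jointly (one threshold per recording).
  rms_all <- purrr::map(rec$segments, function(seg) {
    emg_rms_series(highpass_emg(seg$emg, rec$fs), fs = rec$fs,
                   start_s = seg$start_s)
  })
  tone <- high_tone_threshold(dplyr::bind_rows(rms_all))
  rec$emg_tone <- tone

  sigmas <- c(M2 = NA_real_, V1 = NA_real_)
  masks <- list()
  for (si in seq_along(rec$segments)) {
    seg <- rec$segments[[si]]
    filt <- apply(seg$eeg, 2, bandpass_eeg, fs = rec$fs)
    n_sec <- floor(nrow(filt) / rec$fs)
    tone_seg <- tone$mask$high[match(seg$start_s + seq_len(n_sec) - 1,
                                     tone$mask$time_s)]
    tone_seg[is.na(tone_seg)] <- FALSE
    ch_masks <- lapply(1:2, function(ch)
      detect_artifact_windows(filt[, ch], fs = rec$fs, high_emg = tone_seg,
                              hard_limit = hard_limit,
                              sigma_multiple = sigma_multiple,
                              start_s = seg$start_s))
    sigmas <- rbind(sigmas, vapply(ch_masks, attr, numeric(1), "sigma"))
    masks[[si]] <- tibble::tibble(
      segment = si,
      window = ch_masks[[1]]$window,
      start_s = ch_masks[[1]]$start_s,
      masked = ch_masks[[1]]$masked | ch_masks[[2]]$masked)
    rec$segments[[si]]$eeg <- mean_rereference(filt)
  }
  rec$mask <- dplyr::bind_rows(masks)
  rec$sigma <- colMeans(sigmas[-1, , drop = FALSE])
  names(rec$sigma) <- c("M2", "V1")
  rec$preprocessed <- TRUE
  rec
}

#' Export an artifact mask as an interval table
#'
#' @param mask The `mask` tibble of a preprocessed recording.
#' @return Tibble with `start_s`, `end_s` for each masked window, suitable
#'   for CSV export.
#' @export
mask_intervals <- function(mask) {
  dplyr::transmute(dplyr::filter(mask, .data$masked),
                   start_s = .data$start_s, end_s = .data$start_s + 4)
}
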