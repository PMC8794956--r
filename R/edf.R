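# Minimal EDF (European Data Format) export/import for the optional
# real-data path: 16-bit integer encoding, 1-s data records, contiguous
# signals. Covers the subset of EDF/EDF+ this pipeline needs (uV-scaled
# polygraphic channels with one sample rate per channel).

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec A single-segment `ni_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ni_recording"))
  if (length(rec$segments) != 1)
    stop("EDF export requires a contiguous (single-segment) recording", call. = FALSE)
  seg <- rec$segments[[1]]
  sig <- cbind(seg$eeg, EMG1 = seg$emg)
  fs <- rec$fs
  n_rec <- floor(nrow(sig) / fs)
  ns <- ncol(sig)
  phys_max <- pmax(apply(abs(sig), 2, max) * 1.0001, 1)
  dig_max <- 32767                       # symmetric range so gain = 1/scale

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000 X X X arm:", rec$arm), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    edf_pad(colnames(sig), 16), edf_pad(rep("", ns), 80),
    edf_pad(rep("uV", ns), 8),
    edf_pad(formatC(-phys_max, format = "g", digits = 6), 8),
    edf_pad(formatC(phys_max, format = "g", digits = 6), 8),
    edf_pad(rep(-dig_max, ns), 8), edf_pad(rep(dig_max, ns), 8),
    edf_pad(rep("", ns), 80), edf_pad(rep(fs, ns), 8),
    edf_pad(rep("", ns), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(round(sig[idx, s] * scale[s])), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param channel_map Named character vector mapping pipeline roles to EDF
#'   channel labels, e.g. `c(M2 = "M2", V1 = "V1", EMG = "EMG1")`. Unmapped
#'   channels in the file are ignored with a notice.
#' @param arm Exposure arm label (`"induction"`/`"emergence"`); read from the
#'   recording-identification field when present.
#' @return An `ni_recording` (unpreprocessed). Signals acquired above 250 Hz
#'   are decimated by [preprocess_recording()].
#' @export
read_edf <- function(path, channel_map = c(M2 = "M2", V1 = "V1", EMG = "EMG1"),
                     arm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("corrupt EDF header: bad version field", call. = FALSE)
  rd(80)                                  # patient id
  rec_id <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, dur, ns)) || ns < 1 ||
      hdr_bytes != 256 * (1 + ns))
    stop("corrupt EDF header: inconsistent sizes", call. = FALSE)
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16), ""))
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8)); phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8)); dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)

  miss <- setdiff(unname(channel_map), labels)
  if (length(miss))
    stop("mapped channel(s) absent from EDF: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(labels, channel_map)
  if (length(extra))
    message("ignoring unmapped EDF channel(s): ", paste(extra, collapse = ", "))

  raw <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, integer(), n = spr[s], size = 2, endian = "little")
      raw[[s]][((r - 1) * spr[s] + 1):(r * spr[s])] <- v
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(seq_len(ns), function(s)
    phys_min[s] + (raw[[s]] - dig_min[s]) * gain[s])
  names(sig) <- labels

  fs <- spr[match(channel_map[["M2"]], labels)] / dur
  if (is.null(arm))
    arm <- if (grepl("arm: emergence", rec_id)) "emergence" else "induction"
  structure(list(
    individual = NA_integer_, arm = arm,
    schedule = make_exposure_timeline(arm), fs = fs,
    segments = list(list(
      start_s = 0,
      eeg = cbind(M2 = sig[[channel_map[["M2"]]]],
                  V1 = sig[[channel_map[["V1"]]]]),
      emg = sig[[channel_map[["EMG"]]]])),
    channels = tibble::tibble(
      name = unname(channel_map), site = c("M2", "V1", "EMG"),
      impedance_kohm = 0, manual_exclude = FALSE),
    state = NULL,
    artifacts = tibble::tibble(time_s = numeric(), channel = character()),
    seed = NA_integer_), class = "ni_recording")
}
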