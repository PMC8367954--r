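# Minimal European Data Format (EDF) codec: continuous recordings, 16-bit
# samples, identical sampling rate across channels. Covers the interchange
# needs of this package (round-tripping simulated recordings); not a general
# EDF+ implementation (no annotations, no discontinuous records).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one data record per second (a final shorter record is
#' dropped, so durations are truncated to whole seconds). The artifact mask
#' is not representable in plain EDF and is written alongside as
#' `<path>.mask` (0/1 text, one line per sample) when any sample is masked.
#'
#' @param rec an [eeg_recording()]; `srate` must be a whole number.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$srate
  if (srate != round(srate)) stop("EDF writer requires an integer srate")
  spr <- as.integer(srate)                     # samples per 1 s record
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
  ns <- n_channels(rec)
  keep <- seq_len(n_rec * spr)
  data <- rec$data[, keep, drop = FALSE]

  phys_min <- floor(min(data)); phys_max <- ceiling(max(data))
  if (phys_min == phys_max) phys_max <- phys_min + 1
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- round((data - phys_min) * scale) + dig_min

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(rec$channel_ids, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    # record layout: all samples of channel 1, then channel 2, ...
    writeBin(as.integer(t(digital[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  if (any(rec$artifact_mask))
    writeLines(as.character(as.integer(rec$artifact_mask[keep])),
               paste0(path, ".mask"))
  invisible(path)
}

#' Read an EDF recording written by [write_edf()] (or any continuous
#' 16-bit EDF with a uniform sampling rate)
#'
#' @param path file path; a sibling `<path>.mask` file, if present, is read
#'   as the artifact mask.
#' @return An [eeg_recording()] with `reference = "raw"`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8 + 80 + 80 + 8 + 8)                       # version/ids/date/time
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                 # transducer
  for (i in seq_len(ns)) rd(8)                  # phys dim
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                 # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("format error: per-channel sampling rates unsupported")
  srate <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  out <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                     signed = TRUE, endian = "little")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    out[, idx] <- t(matrix(block, nrow = spr[1])[, seq_len(ns)])
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- (out - dig_min) * scale + phys_min
  mask_path <- paste0(path, ".mask")
  mask <- if (file.exists(mask_path)) {
    as.logical(as.integer(readLines(mask_path)))
  } else NULL
  eeg_recording(out, srate = srate, channel_ids = labels,
                artifact_mask = mask, reference = "raw")
}
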