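#' Band-pass and notch filter a recording
#'
#' Channel-wise Butterworth band-pass (default 1-40 Hz, order 4) plus a
#' band-stop notch (default 50 Hz, order 2, +-2 Hz), both applied
#' forward-backward (`signal::filtfilt`) so microstate boundaries are not
#' shifted by filter latency. The artifact mask is untouched: filtering never
#' removes samples.
#'
#' @param rec an [eeg_recording()].
#' @param band_low_hz,band_high_hz band-pass edges (Hz).
#' @param notch_hz notch center frequency (Hz), or `NULL`/`NA` to disable.
#' @param order band-pass Butterworth order (doubled by the zero-phase pass).
#' @param notch_halfwidth_hz half width of the notch stop band (Hz).
#' @return Filtered [eeg_recording()].
#' @export
bandpass_notch <- function(rec, band_low_hz = 1, band_high_hz = 40,
                           notch_hz = 50, order = 4L,
                           notch_halfwidth_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz && band_high_hz < nyq))
    stop("need 0 < band_low < band_high < srate/2")
  bp <- signal::butter(order, c(band_low_hz, band_high_hz) / nyq, type = "pass")
  use_notch <- !is.null(notch_hz) && !is.na(notch_hz)
  if (use_notch) {
    if (notch_hz >= nyq) stop("notch frequency violates Nyquist")
    ns <- signal::butter(2L, c(notch_hz - notch_halfwidth_hz,
                               notch_hz + notch_halfwidth_hz) / nyq,
                         type = "stop")
  }
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[i, ])
    if (use_notch) x <- signal::filtfilt(ns, x)
    out[i, ] <- x
  }
  eeg_recording(out, rec$srate, rec$channel_ids, rec$artifact_mask,
                reference = rec$reference)
}

#' Down-sample a recording
#'
#' Polyphase anti-aliased resampling at the rational ratio
#' `target_srate / srate`: zero-insertion upsampling by p, a zero-phase FIR
#' anti-alias low-pass (applied forward-backward, so tones keep their phase
#' and amplitude), then decimation by q. The output has `floor(n * ratio)`
#' samples.
#' The artifact mask is resampled conservatively: a target sample is masked
#' if any source sample in its half-open source window was masked.
#'
#' @param rec an [eeg_recording()].
#' @param target_srate target sampling rate (Hz), `<= rec$srate`.
#' @return Resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_srate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_srate) || target_srate <= 0)
    stop("`target_srate` must be positive")
  if (target_srate > rec$srate)
    stop("`target_srate` must not exceed the source rate")
  if (target_srate == rec$srate) return(rec)
  frac <- rational_ratio(target_srate, rec$srate)
  p <- frac[1]; q <- frac[2]
  n_in <- n_samples(rec)
  n_out <- floor(n_in * p / q)
  h <- signal::fir1(20L * max(p, q), 1 / max(p, q))
  out <- matrix(0, n_channels(rec), n_out)
  for (i in seq_len(nrow(out))) {
    x <- rec$data[i, ]
    up <- if (p > 1) {
      u <- numeric(n_in * p)
      u[seq(1L, length(u), p)] <- x
      u
    } else x
    y <- signal::filtfilt(h, up) * p
    y <- y[seq(1L, length(y), q)]
    out[i, ] <- y[seq_len(n_out)]
  }
  # target sample j (0-based) covers source window [j*q/p, (j+1)*q/p)
  mask <- vapply(seq_len(n_out) - 1L, function(j) {
    lo <- floor(j * q / p) + 1L
    hi <- min(ceiling((j + 1) * q / p), n_in)
    any(rec$artifact_mask[lo:hi])
  }, logical(1))
  eeg_recording(out, target_srate, rec$channel_ids, mask,
                reference = rec$reference)
}

# smallest integer p/q with p/q == a/b (rates are rational in practice)
rational_ratio <- function(a, b, scale = 1000L) {
  p <- round(a * scale); q <- round(b * scale)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Recompute the average reference
#'
#' Subtracts the instantaneous mean across channels from every sample so each
#' column sums to zero. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return Average-referenced [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- sweep(rec$data, 2L, colMeans(rec$data))
  eeg_recording(out, rec$srate, rec$channel_ids, rec$artifact_mask,
                reference = "average")
}

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the potentials across all
#' electrodes at time t (population formula, divisor C): the instantaneous
#' strength of the scalp field. High-GFP time points carry the highest
#' topographic signal-to-noise ratio.
#'
#' @param rec an average-referenced [eeg_recording()].
#' @return Object of class `gfp_series`: list with `values` (per sample,
#'   microvolts) and `peak_indices` (empty until [detect_gfp_peaks()]).
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference != "average")
    stop("GFP requires an average-referenced recording; call rereference_average() first")
  C <- n_channels(rec)
  mu <- colMeans(rec$data)
  values <- sqrt(colSums(sweep(rec$data, 2L, mu)^2) / C)
  structure(list(values = values, peak_indices = integer(0)),
            class = "gfp_series")
}

#' Detect GFP peaks
#'
#' Marks strict interior local maxima of the GFP curve
#' (`values[i-1] < values[i] > values[i+1]`; equal-valued plateaus yield no
#' peak). Peaks on artifact-masked samples, or immediately adjacent to a
#' masked sample, are discarded so no clustering input touches artifact
#' boundaries.
#'
#' @param gfp a `gfp_series` from [compute_gfp()].
#' @param mask logical artifact mask, same length as `gfp$values` (or `NULL`).
#' @return The `gfp_series` with `peak_indices` filled (1-based indices).
#' @export
detect_gfp_peaks <- function(gfp, mask = NULL) {
  stopifnot(inherits(gfp, "gfp_series"))
  v <- gfp$values
  n <- length(v)
  if (n < 3L) stop("series too short for peak detection (need >= 3 samples)")
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("mask length must equal series length")
  i <- 2:(n - 1L)
  is_peak <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  idx <- i[is_peak]
  idx <- idx[!(mask[idx] | mask[idx - 1L] | mask[idx + 1L])]
  gfp$peak_indices <- idx
  gfp
}

#' Extract topographies at GFP peaks
#'
#' Convenience for the clustering stage: the channels x peaks matrix of maps
#' at the detected GFP peaks, together with their GFP values.
#'
#' @param rec average-referenced [eeg_recording()].
#' @param gfp `gfp_series` with peaks detected.
#' @return list with `maps` (channels x n_peaks) and `gfp` (n_peaks).
#' @export
peak_maps <- function(rec, gfp) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(gfp, "gfp_series"))
  if (!length(gfp$peak_indices)) stop("no GFP peaks detected")
  list(maps = rec$data[, gfp$peak_indices, drop = FALSE],
       gfp = gfp$values[gfp$peak_indices])
}
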