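#' Back-fit templates to a recording
#'
#' Winner-takes-all labeling: every sample gets the template with the highest
#' absolute spatial correlation, provided that correlation exceeds
#' `corr_threshold` (default 0.5, read strictly: corr must be `> 0.5`).
#' Samples below the floor, and artifact-masked samples, stay unlabeled
#' (`NA`). Ties in the argmax are broken toward the lowest template index.
#'
#' @param rec an average-referenced [eeg_recording()] whose channel count
#'   matches the templates.
#' @param templates a [template_set()].
#' @param corr_threshold labeling floor on the absolute correlation.
#' @param ignore_polarity compare with absolute correlation (default TRUE;
#'   the microstate convention).
#' @return Object of class `segmentation`: `labels` (integer per sample, NA =
#'   unlabeled), `corr` (best absolute correlation per sample), `gfp`,
#'   `mask`, `srate`, `k`, `map_labels`.
#' @export
backfit <- function(rec, templates, corr_threshold = 0.5,
                    ignore_polarity = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(templates, "template_set"))
  if (rec$reference != "average")
    stop("back-fitting requires an average-referenced recording")
  if (nrow(templates$maps) != n_channels(rec))
    stop("channel count mismatch between recording and templates")
  n <- n_samples(rec)
  X <- sweep(rec$data, 2L, colMeans(rec$data))
  nrm <- sqrt(colSums(X^2))
  gfp <- nrm / sqrt(n_channels(rec))
  ok <- nrm > 0
  cr <- matrix(0, templates$k, n)
  cr[, ok] <- crossprod(templates$maps, sweep(X[, ok, drop = FALSE],
                                              2L, nrm[ok], "/"))
  if (ignore_polarity) cr <- abs(cr)
  lab <- max.col(t(cr), ties.method = "first")
  best <- cr[cbind(lab, seq_len(n))]
  lab[best <= corr_threshold | rec$artifact_mask | !ok] <- NA_integer_
  structure(list(labels = lab, corr = best, gfp = gfp,
                 mask = rec$artifact_mask, srate = rec$srate,
                 k = templates$k, map_labels = templates$labels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples @ %g Hz, k = %d, %.1f%% labeled\n",
              length(x$labels), x$srate, x$k, 100 * mean(!is.na(x$labels))))
  invisible(x)
}

#' Extract runs (maximal constant-label stretches)
#'
#' A run is a maximal stretch of consecutive samples carrying the same label;
#' unlabeled samples and artifact-mask boundaries terminate runs. Intervals
#' are half-open `[start, end)` in 0-based samples.
#'
#' @param seg a `segmentation` from [backfit()].
#' @return data frame of class `run_list`: `label` (integer map index),
#'   `start`, `end` (half-open, 0-based samples), `duration_ms`.
#' @export
extract_runs <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  lab <- seg$labels
  n <- length(lab)
  code <- ifelse(is.na(lab), 0L, lab)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L
  out <- data.frame(label = r$values[keep], start = starts[keep],
                    end = ends[keep])
  out$duration_ms <- (out$end - out$start) / seg$srate * 1000
  class(out) <- c("run_list", class(out))
  out
}

#' The four microstate temporal parameters
#'
#' Per map m over one recording:
#' \itemize{
#'   \item GEV: `sum over samples labeled m of gfp^2 * corr^2`, divided by
#'     the `gfp^2` sum over all unmasked samples (labeled or not) — the
#'     GFP-weighted fraction of total signal variance the map explains.
#'   \item mean duration: average run length of m, in ms.
#'   \item time coverage: percent of unmasked samples labeled m.
#'   \item occurrence: runs of m per second of unmasked time.
#' }
#'
#' @param seg a `segmentation`.
#' @param runs its `run_list`; computed if missing.
#' @param subject_id identifier stored in the output.
#' @return data frame, one row per map: `subject_id`, `map`, `gev`,
#'   `mean_duration_ms`, `coverage_pct`, `occurrence_per_s`.
#' @export
temporal_parameters <- function(seg, runs = NULL, subject_id = "s1") {
  stopifnot(inherits(seg, "segmentation"))
  if (is.null(runs)) runs <- extract_runs(seg)
  unmasked <- !seg$mask
  n_un <- sum(unmasked)
  if (n_un == 0L) stop("no unmasked samples")
  if (!any(!is.na(seg$labels))) stop("segmentation has no labeled samples")
  denom <- sum(seg$gfp[unmasked]^2)
  secs <- n_un / seg$srate
  out <- lapply(seq_len(seg$k), function(m) {
    sel <- !is.na(seg$labels) & seg$labels == m
    gev <- if (denom > 0) sum(seg$gfp[sel]^2 * seg$corr[sel]^2) / denom else 0
    rm_ <- runs[runs$label == m, , drop = FALSE]
    data.frame(subject_id = subject_id, map = seg$map_labels[m],
               gev = gev,
               mean_duration_ms = if (nrow(rm_)) mean(rm_$duration_ms) else 0,
               coverage_pct = 100 * sum(sel) / n_un,
               occurrence_per_s = nrow(rm_) / secs)
  })
  do.call(rbind, out)
}
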