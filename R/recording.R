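#' Construct an EEG recording
#'
#' Container for a multichannel voltage matrix plus the metadata the
#' microstate pipeline needs: sampling rate, channel identifiers, a boolean
#' artifact mask (TRUE = sample excluded from analysis) and the reference
#' state. All downstream operations use 0-based sample time only through
#' `srate`; intervals are half-open.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel names; defaults to
#'   `ch01..chNN`.
#' @param artifact_mask logical per sample, TRUE where the signal is
#'   artifactual and must be ignored; defaults to all FALSE.
#' @param reference `"raw"` or `"average"`. With `"average"` every column
#'   must sum to zero within tolerance.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channel_ids = NULL,
                          artifact_mask = NULL, reference = c("raw", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("recording needs >= 2 channels and >= 2 samples")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a single positive number")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("`channel_ids` length must equal channel count")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(data))
  artifact_mask <- as.logical(artifact_mask)
  if (length(artifact_mask) != ncol(data))
    stop("`artifact_mask` length must equal sample count")
  if (anyNA(artifact_mask)) stop("`artifact_mask` must not contain NA")
  if (reference == "average") {
    colsums <- colSums(data)
    tol <- 1e-6 * max(1, max(abs(data)))
    if (any(abs(colsums) > tol * nrow(data)))
      stop("reference = 'average' but columns do not sum to zero")
  }
  dimnames(data) <- NULL               # channel ids live in channel_ids
  structure(
    list(data = data, srate = as.numeric(srate),
         channel_ids = as.character(channel_ids),
         artifact_mask = artifact_mask, reference = reference),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference, %.1f%% masked\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              x$reference, 100 * mean(x$artifact_mask)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Construct a template set
#'
#' A set of K microstate template topographies. Each map is stored mean-zero
#' (average-reference convention) and unit L2 norm; polarity is arbitrary
#' because all comparisons use absolute spatial correlation.
#'
#' @param maps numeric matrix, channels x K.
#' @param labels character labels, one per map (default `M1..MK`; group-level
#'   sets are conventionally relabeled A..E via [assign_canonical_labels()]).
#' @param level provenance: `"subject"`, `"group"` or `"cohort"`.
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL,
                         level = c("subject", "group", "cohort")) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  if (nrow(maps) < 2L) stop("maps need >= 2 channels")
  k <- ncol(maps)
  if (k < 1L) stop("need at least one map")
  # normalize: mean-zero, unit norm
  maps <- sweep(maps, 2L, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm == 0)) stop("zero-variance map in template set")
  maps <- sweep(maps, 2L, nrm, "/")
  if (is.null(labels)) labels <- sprintf("M%d", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k) stop("one label per map required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  colnames(maps) <- labels
  structure(list(maps = maps, labels = labels, level = level, k = k),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> k = %d (%s), %d channels: %s\n",
              x$k, x$level, nrow(x$maps), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Two formats are supported. `"delimited_matrix"` is a comma-separated text
#' file whose first row holds channel ids (one column per channel, one row
#' per sample); an optional column named `artifact` (0/1) becomes the
#' artifact mask. `"edf"` is the European Data Format (continuous, 16-bit),
#' read by the package's minimal EDF codec.
#'
#' @param path file path.
#' @param format `"delimited_matrix"` or `"edf"`.
#' @param srate sampling rate in Hz; required for `delimited_matrix`
#'   (the text format carries no timing), ignored for EDF.
#' @return An [eeg_recording()] with `reference = "raw"`.
#' @export
read_recording <- function(path, format = c("delimited_matrix", "edf"),
                           srate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "edf") return(read_edf(path))
  if (is.null(srate)) stop("`srate` is required for delimited_matrix input")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  if (ncol(raw) != length(header))
    stop("format error: header/body column mismatch")
  mask_col <- which(names(raw) == "artifact")
  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(raw)))
  bad <- which(apply(num, 1L, anyNA))
  if (length(bad))
    stop("format error: non-numeric cell in data row ", bad[1])
  if (length(mask_col)) {
    mask <- num[, mask_col] != 0
    num <- num[, -mask_col, drop = FALSE]
  } else {
    mask <- rep(FALSE, nrow(num))
  }
  eeg_recording(t(num), srate = srate, channel_ids = colnames(num),
                artifact_mask = mask, reference = "raw")
}

#' Write an EEG recording as delimited text
#'
#' Inverse of [read_recording()]'s `delimited_matrix` format: one column per
#' channel, one row per sample, plus an `artifact` 0/1 column when any sample
#' is masked. Full double precision is preserved.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_ids
  if (any(rec$artifact_mask)) df$artifact <- as.integer(rec$artifact_mask)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a temporal-parameter table
#'
#' One row per subject x map with the four temporal parameters. Re-reading
#' with [read_params_table()] reproduces the values exactly.
#'
#' @param params a data frame as returned by [temporal_parameters()] /
#'   cohort pipelines: columns `subject_id`, `map`, `gev`,
#'   `mean_duration_ms`, `coverage_pct`, `occurrence_per_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_table <- function(params, path) {
  cols <- c("subject_id", "map", "gev", "mean_duration_ms",
            "coverage_pct", "occurrence_per_s")
  if (is.null(params) || !is.data.frame(params) || nrow(params) == 0L)
    stop("`params` must be a non-empty data frame")
  if (!all(cols %in% names(params)))
    stop("missing columns: ", paste(setdiff(cols, names(params)), collapse = ", "))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  df <- params[, cols]
  for (nm in cols[3:6])
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temporal-parameter table written by [write_params_table()]
#' @param path file path.
#' @return data frame with one row per subject x map.
#' @export
read_params_table <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character", map = "character"))
  num_cols <- c("gev", "mean_duration_ms", "coverage_pct", "occurrence_per_s")
  for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Read a clinical score table
#'
#' Delimited text with a header; requires `subject_id` and `group` columns
#' (`group` in ASD/TD), accepts `sex`, `age_years` and any number of score
#' columns (ADOS/MSEL/CBCL or others such as PEP3 — unknown columns are kept
#' as scores). Empty cells become NA, never zero.
#'
#' @param path file path.
#' @return data frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  if (!"group" %in% names(df))
    stop("format error: missing `group` column")
  if (!"subject_id" %in% names(df))
    stop("format error: missing `subject_id` column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("format error: duplicate subject_id '",
         df$subject_id[anyDuplicated(df$subject_id)], "'")
  if (anyNA(df$group)) stop("format error: missing group value")
  if (!all(df$group %in% c("ASD", "TD")))
    stop("format error: group values must be ASD or TD, got '",
         setdiff(unique(df$group), c("ASD", "TD"))[1], "'")
  if ("age_years" %in% names(df) && any(df$age_years <= 0, na.rm = TRUE))
    stop("format error: non-positive age")
  class(df) <- c("clinical_table", class(df))
  df
}

#' Score columns of a clinical table
#'
#' Everything that is not identity metadata (`subject_id`, `group`, `sex`)
#' counts as a score; `age_years` is included so age correlations run through
#' the same machinery as clinical scores.
#' @param clinical a clinical table.
#' @return character vector of score column names.
#' @export
clinical_score_columns <- function(clinical) {
  setdiff(names(clinical), c("subject_id", "group", "sex"))
}
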