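#' Group comparison of all temporal parameters with FDR control
#'
#' One comparison per map x parameter (5 maps x 4 parameters = 20 by
#' default): an unpaired test chosen by [normality_gate()] (Welch t if both
#' samples look Gaussian, Mann-Whitney otherwise), with Benjamini-Hochberg
#' FDR across the whole block.
#'
#' @param params_a,params_b long parameter tables (as from
#'   [temporal_parameters()], stacked over subjects): columns `subject_id`,
#'   `map`, `gev`, `mean_duration_ms`, `coverage_pct`, `occurrence_per_s`.
#' @param var_equal pooled t-test if TRUE; default Welch.
#' @param q_threshold FDR level for the `significant` flag.
#' @return data frame: `map`, `parameter`, `test`, `statistic`, `mean_a`,
#'   `mean_b`, `p`, `q`, `significant`.
#' @export
compare_groups_fdr <- function(params_a, params_b, var_equal = FALSE,
                               q_threshold = 0.05) {
  par_cols <- c("gev", "mean_duration_ms", "coverage_pct", "occurrence_per_s")
  for (df in list(params_a, params_b)) {
    miss <- setdiff(c("subject_id", "map", par_cols), names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  }
  if (length(unique(params_a$subject_id)) < 2L ||
      length(unique(params_b$subject_id)) < 2L)
    stop("need >= 2 subjects per group")
  maps <- sort(unique(c(params_a$map, params_b$map)))
  rows <- list()
  for (m in maps) for (pc in par_cols) {
    va <- params_a[params_a$map == m, pc]
    vb <- params_b[params_b$map == m, pc]
    test <- suppressWarnings(normality_gate(va, vb))
    if (test == "t") {
      tt <- stats::t.test(va, vb, var.equal = var_equal)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      map = m, parameter = pc, test = test, statistic = stat,
      mean_a = mean(va, na.rm = TRUE), mean_b = mean(vb, na.rm = TRUE), p = p)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out
}

#' Welch t-test from printed summary statistics
#'
#' Reconstructs the unequal-variance t-test from (mean, SD, N) summaries —
#' how published group tables are re-checked when raw data are unavailable.
#' `t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p.
#'
#' @param mean_a,sd_a,n_a first group's summary (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b second group's summary.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t_from_moments <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a < 0 || sd_b < 0) stop("sd must be >= 0")
  if (n_a < 2 || n_b < 2) stop("n must be >= 2")
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) stop("undefined: both groups constant and equal")
    return(list(t = sign(mean_a - mean_b) * Inf, df = n_a + n_b - 2, p = 0))
  }
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Correlate temporal parameters with clinical scores
#'
#' For each map x parameter x score: Pearson if both variables pass the
#' normality gate, Spearman otherwise (both two-tailed), with pairwise
#' deletion of missing values and a floor of `min_pairs` complete pairs.
#' Benjamini-Hochberg FDR is applied within each clinical instrument block
#' (scores sharing a prefix before the first underscore or space, e.g. all
#' ADOS scores together), mirroring correction "per evaluation instrument".
#'
#' @param params long parameter table (one group's subjects).
#' @param clinical a clinical table ([read_clinical_table()]), matched on
#'   `subject_id`.
#' @param score_set score columns to use; default every column from
#'   [clinical_score_columns()].
#' @param min_pairs minimal complete pairs per correlation (default 8).
#' @param q_threshold FDR level.
#' @return data frame: `map`, `parameter`, `score`, `block`, `method`, `n`,
#'   `r`, `p`, `q`, `significant`. Skipped combinations (too few pairs, zero
#'   variance) are reported via warnings, not rows.
#' @export
correlate_clinical <- function(params, clinical, score_set = NULL,
                               min_pairs = 8L, q_threshold = 0.05) {
  if (is.null(score_set)) score_set <- clinical_score_columns(clinical)
  par_cols <- c("gev", "mean_duration_ms", "coverage_pct", "occurrence_per_s")
  maps <- sort(unique(params$map))
  rows <- list(); skipped <- 0L
  for (sc in score_set) {
    block <- sub("[_ .].*$", "", sc)
    for (m in maps) for (pc in par_cols) {
      sub_p <- params[params$map == m, c("subject_id", pc)]
      merged <- merge(sub_p, clinical[, c("subject_id", sc)], by = "subject_id")
      x <- merged[[pc]]; y <- merged[[sc]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < min_pairs || stats::sd(x) == 0 || stats::sd(y) == 0) {
        skipped <- skipped + 1L; next
      }
      method <- if (suppressWarnings(normality_gate(x, y)) == "t")
        "pearson" else "spearman"
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = method, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        map = m, parameter = pc, score = sc, block = block, method = method,
        n = length(x), r = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (skipped) warning(skipped, " correlation(s) skipped (too few pairs or zero variance)")
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (b in unique(out$block))
    out$q[out$block == b] <- stats::p.adjust(out$p[out$block == b], "BH")
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Bootstrap subsampling power curve
#'
#' For each candidate sample size n, draws `reps` bootstrap resamples (with
#' replacement by default) of size n from each group's per-subject values,
#' runs a two-tailed unpaired t-test at `alpha` on each pair, and reports the
#' fraction significant: the likelihood of detecting the group difference at
#' that sample size.
#'
#' @param values_a,values_b per-subject values for the two groups.
#' @param n_min,n_max,step sample-size grid (defaults 3..47 step 1).
#' @param reps resamples per n (default 500).
#' @param alpha test level (default 0.05).
#' @param with_replacement bootstrap (TRUE, default) or subsampling without
#'   replacement (needs n <= group size).
#' @param var_equal pooled t-test if TRUE; default Welch.
#' @param seed optional RNG seed.
#' @return data frame: `n`, `likelihood`.
#' @export
bootstrap_power_curve <- function(values_a, values_b, n_min = 3L, n_max = 47L,
                                  step = 1L, reps = 500L, alpha = 0.05,
                                  with_replacement = TRUE, var_equal = FALSE,
                                  seed = NULL) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (reps < 1L) stop("reps must be >= 1")
  if (n_min < 2L) stop("n_min must be >= 2")
  ns <- seq.int(n_min, n_max, by = step)
  if (!with_replacement && max(ns) > min(length(values_a), length(values_b)))
    stop("without replacement, n_max cannot exceed the group sizes")
  if (!is.null(seed)) set.seed(seed)
  lik <- vapply(ns, function(n) {
    hits <- 0L
    for (r in seq_len(reps)) {
      xa <- sample(values_a, n, replace = with_replacement)
      xb <- sample(values_b, n, replace = with_replacement)
      p <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal)$p.value,
                    error = function(e) 1)
      if (!is.na(p) && p < alpha) hits <- hits + 1L
    }
    hits / reps
  }, 0)
  data.frame(n = ns, likelihood = lik)
}

#' Monte-Carlo detection rate from printed moments
#'
#' Draws `reps` replicate pairs of Gaussian samples of size n per group from
#' the two (mean, sd) summaries, tests each pair with a two-tailed unpaired
#' t-test at `alpha`, and returns the percentage significant. This is the
#' moments-only counterpart of [bootstrap_power_curve()] for re-checking
#' published subsampling claims without raw data.
#'
#' @param mean_a,sd_a,mean_b,sd_b group summaries.
#' @param n per-group sample size of each replicate.
#' @param reps number of replicates (default 2000).
#' @param alpha test level.
#' @param var_equal pooled t-test if TRUE; default Welch.
#' @param seed optional RNG seed.
#' @return Detection rate in percent (0..100).
#' @export
detection_rate_from_moments <- function(mean_a, sd_a, mean_b, sd_b, n,
                                        reps = 2000L, alpha = 0.05,
                                        var_equal = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (r in seq_len(reps)) {
    xa <- stats::rnorm(n, mean_a, sd_a)
    xb <- stats::rnorm(n, mean_b, sd_b)
    if (stats::t.test(xa, xb, var.equal = var_equal)$p.value < alpha)
      hits <- hits + 1L
  }
  100 * hits / reps
}

#' Reference cohort summary statistics
#'
#' Published (mean, SD, N) summaries for a cohort of 66 toddlers and
#' preschoolers with ASD and 47 typically developing peers:
#' `"temporal"` — the four temporal parameters of the five microstate
#' classes per group; `"clinical"` — age, ADOS severity, MSEL developmental
#' quotients and CBCL DSM-scale T-scores per group. These printed summaries
#' drive the moment-based re-checks ([welch_t_from_moments()],
#' [detection_rate_from_moments()]) and calibrate the cohort simulator.
#'
#' @param which `"temporal"` or `"clinical"`.
#' @return data frame with columns `parameter` (and `map` for temporal),
#'   `group`, `mean`, `sd`, `n`.
#' @export
cohort_reference_moments <- function(which = c("temporal", "clinical")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("cohort_", which, "_moments.csv"),
                      package = "microstatr", mustWork = TRUE)
  utils::read.csv(path)
}
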