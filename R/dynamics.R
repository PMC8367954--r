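#' Count microstate transitions
#'
#' Counts `C[i, j]` over consecutive pairs of runs (state i followed by state
#' j) that are adjacent in labeled time: a transition is counted only when
#' the gap between the two runs (unlabeled or masked samples) is at most
#' `bridge` samples (default 0 — a transition across an excluded stretch is
#' unobserved, not evidence). The diagonal is structurally zero; rle-style
#' runs cannot self-transition.
#'
#' @param runs a `run_list` from [extract_runs()] (ordered by time).
#' @param k number of states (>= max label present).
#' @param bridge maximal tolerated gap in samples (needs the segmentation's
#'   sample unit; default 0).
#' @return k x k integer count matrix.
#' @export
transition_counts <- function(runs, k, bridge = 0L) {
  stopifnot(is.data.frame(runs))
  if (nrow(runs) && max(runs$label) > k)
    stop("k smaller than the largest label present")
  cnt <- matrix(0L, k, k)
  if (nrow(runs) >= 2L) {
    for (r in seq_len(nrow(runs) - 1L)) {
      gap <- runs$start[r + 1L] - runs$end[r]
      if (gap <= bridge)
        cnt[runs$label[r], runs$label[r + 1L]] <-
          cnt[runs$label[r], runs$label[r + 1L]] + 1L
    }
  }
  cnt
}

#' Observed, expected and normalized transition probabilities
#'
#' Observed row-stochastic probabilities `P[i, j] = C[i, j] / sum_j C[i, j]`
#' are compared with the probabilities expected if transitions reflected only
#' how often each state occurs: `E[i, j] = c[j] / sum(c[m != i])`, the
#' destination's occurrence proportion renormalized without the source state
#' (self-transitions are structurally excluded). The normalized matrix
#' `R = P / E` equals 1 everywhere under a memoryless sequence, so deviations
#' from 1 isolate genuine syntax.
#'
#' @param counts k x k transition count matrix from [transition_counts()].
#' @param coverage nonnegative per-state occupancy proportions (any scale;
#'   e.g. `coverage_pct` from [temporal_parameters()], or occurrence rates if
#'   preferred as the base measure).
#' @return Object of class `transition_result`: `observed`, `expected`,
#'   `normalized` (k x k, NA rows where a state never leaves),
#'   `n_transitions`.
#' @export
observed_vs_expected <- function(counts, coverage) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (ncol(counts) != k) stop("counts must be square")
  if (length(coverage) != k) stop("one coverage value per state required")
  if (any(coverage < 0) || sum(coverage) <= 0)
    stop("coverage must be nonnegative with positive sum")
  observed <- expected <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    row_n <- sum(counts[i, -i])
    if (row_n > 0) {
      observed[i, -i] <- counts[i, -i] / row_n
      observed[i, i] <- 0
    }
    denom <- sum(coverage[-i])
    if (denom > 0) {
      expected[i, -i] <- coverage[-i] / denom
      expected[i, i] <- 0
    }
  }
  normalized <- ifelse(!is.na(expected) & expected > 0,
                       observed / expected, NA_real_)
  diag(normalized) <- 0
  structure(list(observed = observed, expected = expected,
                 normalized = normalized, n_transitions = sum(counts)),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition_result> k = %d, %d transitions\n",
              nrow(x$observed), x$n_transitions))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Compare transition syntax between two groups
#'
#' Per directed edge (i -> j, i != j): unpaired t-test on the subjects'
#' normalized transition probabilities, with Benjamini-Hochberg FDR over all
#' K(K-1) edges. The t-test is used unconditionally for transitions (no
#' normality gate), matching common practice for occurrence-normalized
#' syntax comparisons.
#'
#' @param group_a,group_b lists of `transition_result`s (one per subject).
#' @param map_labels optional state names for the output table.
#' @param var_equal pooled-variance t-test if TRUE; default Welch.
#' @param q_threshold FDR significance level (default 0.05).
#' @return data frame: `from`, `to`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `q`, `significant`. Edges missing in every subject are dropped with a
#'   warning.
#' @export
compare_transitions <- function(group_a, group_b, map_labels = NULL,
                                var_equal = FALSE, q_threshold = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 subjects per group")
  k <- nrow(group_a[[1]]$normalized)
  if (is.null(map_labels)) map_labels <- as.character(seq_len(k))
  edge_vals <- function(group, i, j)
    vapply(group, function(tr) tr$normalized[i, j], 0)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    va <- edge_vals(group_a, i, j); vb <- edge_vals(group_b, i, j)
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L) { dropped <- dropped + 1L; next }
    tt <- stats::t.test(va, vb, var.equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      from = map_labels[i], to = map_labels[j],
      mean_a = mean(va), mean_b = mean(vb),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }
  if (dropped) warning(dropped, " edge(s) excluded: too few observations")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out
}

#' Per-subject transition analysis from a segmentation
#'
#' Convenience wrapper: runs -> counts -> observed/expected/normalized, with
#' the subject's own time-coverage proportions as the base measure (or
#' occurrence rates via `base = "occurrence"`).
#'
#' @param seg a `segmentation`.
#' @param base `"coverage"` (default) or `"occurrence"`.
#' @param bridge see [transition_counts()].
#' @return A `transition_result`.
#' @export
subject_transitions <- function(seg, base = c("coverage", "occurrence"),
                                bridge = 0L) {
  base <- match.arg(base)
  runs <- extract_runs(seg)
  cnt <- transition_counts(runs, seg$k, bridge = bridge)
  pars <- temporal_parameters(seg, runs)
  w <- if (base == "coverage") pars$coverage_pct else pars$occurrence_per_s
  observed_vs_expected(cnt, w)
}
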