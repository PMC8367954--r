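#' Two-stage microstate pipeline over a set of recordings
#'
#' The standard sequence: per subject, GFP computation, peak detection and
#' polarity-invariant k-means on the peak maps; then pooling of all
#' subject-level templates into a group clustering; then back-fitting the
#' group templates to every recording and extracting the four temporal
#' parameters and the transition syntax.
#'
#' @param recordings named list of average-referenced [eeg_recording()]s.
#' @param k number of microstate classes for both stages (default 5). Set
#'   `select_k = TRUE` to instead scan `k_range` with [select_optimal_k()]
#'   at the group stage.
#' @param subject_k maps retained per subject before pooling (default `k`).
#' @param n_restarts k-means restarts (default 20).
#' @param corr_threshold back-fitting floor (default 0.5).
#' @param select_k scan for the optimal group-level k (slower).
#' @param k_range candidate k values when `select_k = TRUE`.
#' @param seed RNG seed for the clustering restarts.
#' @param positions optional sensor layout for canonical A..E labeling of
#'   the group templates.
#' @return list: `group_solution` (`cluster_solution`), `params` (long
#'   per-subject x map parameter table), `segmentations`, `transitions`
#'   (per-subject `transition_result`s), `subject_solutions`.
#' @export
run_pipeline <- function(recordings, k = 5L, subject_k = k,
                         n_restarts = 20L, corr_threshold = 0.5,
                         select_k = FALSE, k_range = 2:8, seed = NULL,
                         positions = NULL) {
  stopifnot(length(recordings) >= 2L)
  if (is.null(names(recordings)))
    names(recordings) <- sprintf("s%03d", seq_along(recordings))
  if (!is.null(seed)) set.seed(seed)

  subject_solutions <- lapply(recordings, function(rec) {
    gfp <- detect_gfp_peaks(compute_gfp(rec), rec$artifact_mask)
    pm <- peak_maps(rec, gfp)
    modified_kmeans(pm$maps, subject_k, gfp = pm$gfp,
                    n_restarts = n_restarts)
  })
  if (select_k) {
    pool <- do.call(cbind, lapply(subject_solutions,
                                  function(s) s$templates$maps))
    sel <- select_optimal_k(pool, k_range = k_range, n_restarts = n_restarts)
    group_solution <- sel$solution
    group_solution$criteria <- sel
  } else {
    group_solution <- group_templates(subject_solutions, k,
                                      n_restarts = n_restarts)
  }
  templates <- group_solution$templates
  if (!is.null(positions))
    templates <- assign_canonical_labels(templates, positions)
  group_solution$templates <- templates

  segmentations <- lapply(recordings, backfit, templates = templates,
                          corr_threshold = corr_threshold)
  params <- do.call(rbind, lapply(names(segmentations), function(id)
    temporal_parameters(segmentations[[id]], subject_id = id)))
  transitions <- lapply(segmentations, subject_transitions)
  list(group_solution = group_solution, params = params,
       segmentations = segmentations, transitions = transitions,
       subject_solutions = subject_solutions)
}
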