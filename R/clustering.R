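#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels after mean-centering both maps. With
#' `ignore_polarity = TRUE` (the microstate convention: oscillatory
#' generators flip sign) the absolute value is returned.
#'
#' @param u,v numeric vectors, one value per channel (equal length >= 2).
#' @param ignore_polarity take `abs()` of the correlation (default TRUE).
#' @return Correlation in `[-1, 1]` (`[0, 1]` when polarity is ignored).
#' @export
spatial_corr <- function(u, v, ignore_polarity = TRUE) {
  if (length(u) != length(v) || length(u) < 2L)
    stop("maps must have equal length >= 2")
  u <- u - mean(u); v <- v - mean(v)
  su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
  if (su == 0 || sv == 0)
    stop("undefined correlation: zero-variance map")
  r <- sum(u * v) / (su * sv)
  if (ignore_polarity) abs(r) else r
}

# center columns and scale to unit L2 norm; errors on zero-variance columns
center_unit <- function(m, what = "map") {
  m <- sweep(m, 2L, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("zero-variance ", what)
  sweep(m, 2L, nrm, "/")
}

# |corr| matrix between unit-norm mean-zero columns of a (C x k) and b (C x n)
abs_corr_matrix <- function(a, b) abs(crossprod(a, b))

#' Polarity-invariant modified k-means
#'
#' Clusters topographies ignoring polarity: maps are assigned to the template
#' with maximal absolute spatial correlation, and each template is updated as
#' the dominant eigenvector (first principal component) of its assigned maps
#' — the polarity-invariant centroid. Iterations stop when the global
#' explained variance (GEV) changes by less than `tol`; the best of
#' `n_restarts` random initializations by GEV is returned.
#'
#' GEV weights every map by its squared GFP:
#' `gev = sum(gfp^2 * corr^2) / sum(gfp^2)`; maps enter the clustering itself
#' unweighted (one peak, one vote).
#'
#' @param maps channels x n matrix of topographies (e.g. [peak_maps()]).
#' @param k number of clusters (`2 <= k <= n`; `k = 1` is allowed and yields
#'   the dominant eigenvector of the whole set).
#' @param gfp optional GFP value per map; defaults to each map's spatial
#'   standard deviation.
#' @param n_restarts random restarts (default 50).
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on GEV change.
#' @param seed optional RNG seed; restart initializations are drawn from the
#'   stream this seed starts, so results are reproducible given
#'   `(seed, n_restarts)`.
#' @param level provenance tag for the returned [template_set()].
#' @return Object of class `cluster_solution`: `templates` ([template_set()]),
#'   `gev_total`, `assignments` (cluster index per map), `corr` (absolute
#'   correlation of each map with its template), `k`.
#' @export
modified_kmeans <- function(maps, k, gfp = NULL, n_restarts = 50L,
                            max_iter = 100L, tol = 1e-7, seed = NULL,
                            level = "subject") {
  maps <- as.matrix(maps)
  n <- ncol(maps); C <- nrow(maps)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds number of maps (", n, ")")
  Mc <- sweep(maps, 2L, colMeans(maps))        # centered raw maps
  Mn <- center_unit(maps)                      # unit-norm for correlations
  if (is.null(gfp)) gfp <- sqrt(colSums(Mc^2) / C)
  w <- gfp^2
  sw <- sum(w)
  if (!is.null(seed)) set.seed(seed)

  pc1 <- function(X) {                         # dominant left singular vector
    if (ncol(X) == 1L) return(X[, 1] / sqrt(sum(X[, 1]^2)))
    u <- svd(X, nu = 1L, nv = 0L)$u[, 1]
    u / sqrt(sum(u^2))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    Tm <- Mn[, sample.int(n, k), drop = FALSE]
    gev_prev <- -Inf
    for (it in seq_len(max_iter)) {
      cr <- abs_corr_matrix(Tm, Mn)            # k x n
      assign <- max.col(t(cr), ties.method = "first")
      best_corr <- cr[cbind(assign, seq_len(n))]
      # refill empty clusters from the worst-fitting map
      for (j in which(tabulate(assign, k) == 0L)) {
        worst <- which.min(best_corr)
        assign[worst] <- j
        best_corr[worst] <- 1
        Tm[, j] <- Mn[, worst]
      }
      for (j in seq_len(k))
        Tm[, j] <- pc1(Mc[, assign == j, drop = FALSE])
      cr <- abs_corr_matrix(Tm, Mn)
      best_corr <- cr[cbind(assign, seq_len(n))]
      gev <- sum(w * best_corr^2) / sw
      if (gev - gev_prev < tol) break
      gev_prev <- gev
    }
    if (is.null(best) || gev > best$gev_total)
      best <- list(templates = Tm, gev_total = gev,
                   assignments = assign, corr = best_corr)
  }
  structure(
    list(templates = template_set(best$templates, level = level),
         gev_total = best$gev_total, assignments = best$assignments,
         corr = best$corr, k = k, criteria = NULL),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, GEV = %.3f, %d maps clustered\n",
              x$k, x$gev_total, length(x$assignments)))
  invisible(x)
}

#' Select the number of microstate classes by a criterion ensemble
#'
#' Fits [modified_kmeans()] for every k in `k_range` and scores each solution
#' with five cluster-validity criteria — Krzanowski-Lai, the
#' cross-validation criterion, mean silhouette width on the
#' `1 - |spatial correlation|` distance, Davies-Bouldin, and a GEV-elbow —
#' then takes the meta-criterion: the median of the per-criterion optimal k
#' values, ties broken downward. This ensemble stands in for the
#' multi-criterion meta-criteria used by microstate toolboxes.
#'
#' @inheritParams modified_kmeans
#' @param k_range candidate cluster numbers (default 2:10).
#' @param criteria_subsample cap on maps entering the pairwise-distance
#'   criteria (silhouette); larger sets are subsampled evenly.
#' @return list with `k` (the selected k*), `criteria_optima` (named optimal
#'   k per criterion), `scores` (per-k table), and `solution` (the
#'   `cluster_solution` refit at k*).
#' @export
select_optimal_k <- function(maps, k_range = 2:10, gfp = NULL,
                             n_restarts = 20L, max_iter = 100L, tol = 1e-7,
                             seed = NULL, criteria_subsample = 300L) {
  maps <- as.matrix(maps)
  n <- ncol(maps); C <- nrow(maps)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || min(k_range) < 2L) stop("k_range must start at >= 2")
  if (max(k_range) + 1L > n)
    stop("k_range does not fit the number of maps")
  Mn <- center_unit(maps)
  # degenerate data: every map identical up to sign/scale
  if (all(abs_corr_matrix(Mn[, 1, drop = FALSE], Mn) > 1 - 1e-10)) {
    warning("all maps identical up to polarity; returning min(k_range)")
    sol <- modified_kmeans(maps, min(k_range), gfp = gfp, n_restarts = 1L,
                           max_iter = max_iter, tol = tol, seed = seed)
    return(list(k = min(k_range), criteria_optima = NULL, scores = NULL,
                solution = sol))
  }
  if (!is.null(seed)) set.seed(seed)
  ks <- (min(k_range) - 1L):(max(k_range) + 1L)   # pad for KL / elbow
  fits <- lapply(ks, function(k)
    modified_kmeans(maps, k, gfp = gfp, n_restarts = n_restarts,
                    max_iter = max_iter, tol = tol))
  names(fits) <- ks

  W <- vapply(fits, function(f) sum(1 - f$corr^2), 0)
  gev <- vapply(fits, function(f) f$gev_total, 0)
  sub <- if (n > criteria_subsample)
    unique(round(seq(1L, n, length.out = criteria_subsample))) else seq_len(n)
  dsub <- stats::as.dist(1 - abs_corr_matrix(Mn[, sub, drop = FALSE],
                                             Mn[, sub, drop = FALSE]))
  in_range <- as.character(k_range)

  sil <- db <- cv <- stats::setNames(rep(NA_real_, length(k_range)), in_range)
  for (kc in in_range) {
    f <- fits[[kc]]; k <- f$k
    a <- f$assignments[sub]
    if (length(unique(a)) >= 2L)
      sil[kc] <- mean(cluster::silhouette(a, dsub)[, "sil_width"])
    Tn <- f$templates$maps
    s <- vapply(seq_len(k), function(j) {
      m <- f$assignments == j
      if (!any(m)) 0 else mean(1 - f$corr[m])
    }, 0)
    Mt <- 1 - abs_corr_matrix(Tn, Tn)
    rat <- outer(s, s, "+") / pmax(Mt, 1e-12)
    diag(rat) <- -Inf
    db[kc] <- mean(apply(rat, 1L, max))
    if (C - 1L - k > 0)
      cv[kc] <- (W[kc] / (n * (C - 1))) * ((C - 1) / (C - 1 - k))^2
  }
  # Krzanowski-Lai on the padded W sequence
  diffs <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks[-1])
    diffs[as.character(k)] <- (k - 1)^(2 / C) * W[as.character(k - 1)] -
      k^(2 / C) * W[as.character(k)]
  kl <- stats::setNames(rep(NA_real_, length(k_range)), in_range)
  for (k in k_range) {
    d1 <- diffs[as.character(k)]; d2 <- diffs[as.character(k + 1)]
    if (!is.na(d1) && !is.na(d2) && abs(d2) > 1e-15)
      kl[as.character(k)] <- abs(d1) / abs(d2)
  }
  # GEV elbow: largest drop in marginal GEV gain
  elbow <- stats::setNames(rep(NA_real_, length(k_range)), in_range)
  for (k in k_range) {
    g1 <- gev[as.character(k)] - gev[as.character(k - 1)]
    g2 <- gev[as.character(k + 1)] - gev[as.character(k)]
    elbow[as.character(k)] <- g1 - g2
  }
  pick <- function(x, maximize) {
    if (all(is.na(x))) return(NA_integer_)
    k_range[if (maximize) which.max(x) else which.min(x)]
  }
  optima <- c(krzanowski_lai = pick(kl, TRUE),
              cross_validation = pick(cv, FALSE),
              silhouette = pick(sil, TRUE),
              davies_bouldin = pick(db, FALSE),
              gev_elbow = pick(elbow, TRUE))
  optima <- optima[!is.na(optima)]
  k_star <- floor(stats::median(optima))            # ties broken downward
  k_star <- min(max(k_star, min(k_range)), max(k_range))
  scores <- data.frame(k = k_range,
                       gev_total = gev[in_range], dispersion = W[in_range],
                       krzanowski_lai = kl, cross_validation = cv,
                       silhouette = sil, davies_bouldin = db,
                       gev_elbow = elbow, row.names = NULL)
  list(k = k_star, criteria_optima = optima, scores = scores,
       solution = fits[[as.character(k_star)]])
}

#' Pool subject template sets into group templates
#'
#' Second-stage clustering: every subject contributes its subject-level maps
#' (one vote per map, GFP-normalized by construction since templates are
#' unit-norm) to a pooled polarity-invariant k-means.
#'
#' @param subject_sets list of [template_set()]s (or `cluster_solution`s).
#' @param k number of group classes.
#' @inheritParams modified_kmeans
#' @return A `cluster_solution` whose `templates` have `level = "group"`.
#' @export
group_templates <- function(subject_sets, k, n_restarts = 50L,
                            max_iter = 100L, tol = 1e-7, seed = NULL) {
  if (length(subject_sets) < 2L) stop("need >= 2 subjects")
  sets <- lapply(subject_sets, function(s)
    if (inherits(s, "cluster_solution")) s$templates else s)
  C <- vapply(sets, function(s) nrow(s$maps), 0L)
  if (length(unique(C)) != 1L)
    stop("heterogeneous channel counts across subjects")
  pool <- do.call(cbind, lapply(sets, function(s) s$maps))
  modified_kmeans(pool, k, n_restarts = n_restarts, max_iter = max_iter,
                  tol = tol, seed = seed, level = "group")
}

# all permutations of 1..k as a matrix (k! rows); k capped upstream
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Optimally match two template sets
#'
#' One-to-one pairing of the maps of two equally sized template sets that
#' maximizes the total absolute spatial correlation, solved exactly by
#' enumeration (K <= 8). Used to compare group solutions (e.g. ASD vs TD
#' templates) and to attach canonical labels.
#'
#' @param set_a,set_b [template_set()]s with equal k and channel count.
#' @return data frame with columns `label_a`, `label_b`, `corr` (one row per
#'   pair, ordered as `set_a`), plus attribute `total` (sum of correlations).
#' @export
match_templates <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "template_set"), inherits(set_b, "template_set"))
  if (set_a$k != set_b$k) stop("template sets must have equal k")
  if (nrow(set_a$maps) != nrow(set_b$maps))
    stop("template sets must share the channel count")
  k <- set_a$k
  if (k > 8L) stop("exact matching supported for k <= 8")
  cr <- abs_corr_matrix(set_a$maps, set_b$maps)
  perms <- permutations_of(k)
  totals <- vapply(seq_len(nrow(perms)), function(r)
    sum(cr[cbind(seq_len(k), perms[r, ])]), 0)
  best <- perms[which.max(totals), ]
  out <- data.frame(label_a = set_a$labels,
                    label_b = set_b$labels[best],
                    corr = cr[cbind(seq_len(k), best)])
  attr(out, "total") <- max(totals)
  out
}

#' Canonical microstate topographies for a sensor layout
#'
#' Idealized versions of the five classes reported across the resting-state
#' literature, expressed on an arbitrary layout via sensor positions:
#' A (right-frontal/left-posterior diagonal), B (left-frontal/right-posterior
#' diagonal), C (anterior-posterior), D (fronto-central), E (parieto-central).
#' Purely cosmetic: used only to attach A-E labels to group solutions.
#'
#' @param positions n_channels x 3 matrix of unit sensor positions
#'   (x = right, y = anterior, z = superior), e.g. [fibonacci_layout()].
#' @param k how many of the five to return (<= 5).
#' @return A [template_set()] labeled `A`..`E`.
#' @export
canonical_templates <- function(positions, k = 5L) {
  stopifnot(ncol(positions) == 3L, k >= 1L, k <= 5L)
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  maps <- cbind(A = y - x, B = y + x, C = y,
                D = z + 0.4 * y, E = z - 0.8 * y)
  template_set(maps[, seq_len(k), drop = FALSE],
               labels = c("A", "B", "C", "D", "E")[seq_len(k)],
               level = "cohort")
}

#' Relabel a template set by canonical class
#'
#' Matches the set against [canonical_templates()] on the given layout and
#' renames each map with the canonical label it pairs with. Numerics are
#' untouched; only labels change.
#'
#' @param set a [template_set()] with k <= 5.
#' @param positions sensor positions as in [canonical_templates()].
#' @return The relabeled [template_set()].
#' @export
assign_canonical_labels <- function(set, positions) {
  stopifnot(inherits(set, "template_set"))
  canon <- canonical_templates(positions, k = set$k)
  m <- match_templates(set, canon)
  template_set(set$maps, labels = m$label_b, level = set$level)
}
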