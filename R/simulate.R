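#' Fibonacci-spiral sensor layout
#'
#' n approximately equidistant unit-sphere points on a spherical cap
#' covering the top of the head (down to just below the equator), standing
#' in for a high-density EEG montage without real electrode coordinate
#' files. Axes: x = right, y = anterior, z = superior.
#'
#' @param n number of sensors.
#' @param z_min lower edge of the cap (default -0.15).
#' @return n x 3 matrix of unit positions.
#' @export
fibonacci_layout <- function(n, z_min = -0.15) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- 1 - i * (1 - z_min) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1L) * golden
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate ground-truth template topographies
#'
#' k smooth, mean-zero, unit-norm maps built from randomly placed and
#' oriented dipoles inside a unit-sphere head, sampled at a
#' [fibonacci_layout()] montage. Candidate maps are redrawn until every pair
#' satisfies `|spatial correlation| < max_corr`.
#'
#' @param n_channels montage size (default 110).
#' @param k number of maps (default 5; labeled A..E).
#' @param seed RNG seed (same seed, same maps).
#' @param max_corr pairwise separation bound (default 0.7).
#' @param orthogonalize Gram-Schmidt the maps to exact zero mutual
#'   correlation (default FALSE).
#' @param n_dipoles dipoles per map (default 2).
#' @param max_tries redraw budget per map before erroring.
#' @return A [template_set()] (`level = "cohort"`) with attribute
#'   `"positions"` (the sensor layout).
#' @export
make_templates <- function(n_channels = 110L, k = 5L, seed = NULL,
                           max_corr = 0.7, orthogonalize = FALSE,
                           n_dipoles = 2L, max_tries = 500L) {
  if (k > n_channels) stop("k cannot exceed the channel count")
  if (!is.null(seed)) set.seed(seed)
  pos <- fibonacci_layout(n_channels)
  draw_map <- function() {
    v <- numeric(n_channels)
    for (d in seq_len(n_dipoles)) {
      p <- stats::runif(3, -1, 1)
      p <- p / max(1, sqrt(sum(p^2)) / 0.6)       # keep inside radius 0.6
      m <- stats::rnorm(3); m <- m / sqrt(sum(m^2))
      diff <- sweep(pos, 2L, p)
      dist3 <- rowSums(diff^2)^1.5
      v <- v + as.vector(diff %*% m) / pmax(dist3, 1e-3)
    }
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  maps <- matrix(0, n_channels, k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- draw_map()
      if (j == 1L ||
          all(abs(crossprod(maps[, seq_len(j - 1L), drop = FALSE], cand)) < max_corr)) {
        maps[, j] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not find ", k, " maps with pairwise |corr| < ", max_corr)
  }
  if (orthogonalize) {
    for (j in seq_len(k)) {
      v <- maps[, j]
      if (j > 1L)
        v <- v - maps[, seq_len(j - 1L), drop = FALSE] %*%
          crossprod(maps[, seq_len(j - 1L), drop = FALSE], v)
      maps[, j] <- v / sqrt(sum(v^2))
    }
  }
  out <- template_set(maps, labels = LETTERS[seq_len(k)], level = "cohort")
  attr(out, "positions") <- pos
  out
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a published toddler ASD/TD
#' cohort: 110-channel average-referenced recordings at 125 Hz, 300 s per
#' subject, five microstate classes whose baseline (TD) mean durations and
#' relative entry rates follow the published TD group means, group sizes
#' 66/47, and an "ASD" effect on map B (duration x 72.48/68.86, entry rate
#' x 2.398/2.092 — the published group-mean ratios). Clinical couplings tie
#' selected scores linearly to true temporal parameters so correlation
#' analyses have known truth.
#'
#' @param n_channels,srate,duration_s,k_true recording geometry.
#' @param mean_duration_ms baseline per-map mean run duration (ms).
#' @param entry_weights baseline relative rate of entering each map.
#' @param duration_shape gamma shape of run durations (default 2: positive,
#'   right-skewed).
#' @param subject_cv_duration,subject_cv_weight between-subject lognormal
#'   coefficients of variation of per-map durations / entry weights.
#' @param template_jitter sd of per-subject topography noise added to the
#'   cohort templates (before renormalization).
#' @param carrier_freq_hz oscillation carrying each topography (alpha-range
#'   default 10 Hz; its sign alternation exercises polarity invariance).
#' @param carrier_floor minimum carrier magnitude (0..1). The carrier is
#'   `sign(sin) * (floor + (1 - floor) * |sin|)`: the topography reverses
#'   polarity every half-cycle but never vanishes, mimicking the residual
#'   broadband field that keeps real topographies identifiable through
#'   oscillation nulls. At 0 the carrier is a pure sinusoid and every zero
#'   crossing drops below the back-fitting floor, fragmenting runs.
#' @param snr template-to-noise amplitude ratio (mean GFP of the clean
#'   signal over mean GFP of the spatially correlated noise).
#' @param artifact_fraction fraction of samples masked in contiguous blocks.
#' @param n_asd,n_td group sizes.
#' @param effect_map,effect_duration_ratio,effect_occurrence_ratio the group
#'   effect injected into the ASD group.
#' @param clinical_couplings list of `list(score=, map=, parameter=, r=)`
#'   target correlations between a clinical score and a true parameter.
#' @param seed master RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 110L, srate = 125, duration_s = 300,
                       k_true = 5L,
                       mean_duration_ms = c(A = 71.91, B = 68.86, C = 83.87,
                                            D = 69.30, E = 69.57),
                       entry_weights = c(A = 2.503, B = 2.092, C = 3.111,
                                         D = 1.976, E = 2.090),
                       duration_shape = 2,
                       subject_cv_duration = 0.06,
                       subject_cv_weight = 0.18,
                       template_jitter = 0.3,
                       carrier_freq_hz = 10,
                       carrier_floor = 0.4,
                       snr = 3,
                       artifact_fraction = 0.1,
                       n_asd = 66L, n_td = 47L,
                       effect_map = "B",
                       effect_duration_ratio = 72.48 / 68.86,
                       effect_occurrence_ratio = 2.398 / 2.092,
                       clinical_couplings = list(
                         list(score = "CBCL_AffP_T", map = "B",
                              parameter = "coverage_pct", r = 0.40),
                         list(score = "MSEL_FM_DQ", map = "D",
                              parameter = "coverage_pct", r = -0.40),
                         list(score = "ADOS_SA_SS", map = "E",
                              parameter = "mean_duration_ms", r = -0.35)),
                       seed = 1L) {
  stopifnot(length(mean_duration_ms) == k_true,
            length(entry_weights) == k_true,
            all(mean_duration_ms > 0), all(entry_weights > 0),
            snr > 0, carrier_floor >= 0, carrier_floor < 1,
            artifact_fraction >= 0, artifact_fraction < 1,
            duration_s > 0, srate > 0)
  structure(as.list(environment()), class = "sim_config")
}

# contiguous artifact blocks totaling ~frac of n samples
artifact_blocks <- function(n, frac, srate) {
  mask <- rep(FALSE, n)
  if (frac <= 0) return(mask)
  target <- round(frac * n)
  guard <- 0L
  while (sum(mask) < target && guard < 1000L) {
    guard <- guard + 1L
    len <- min(round(stats::runif(1, 0.5, 2.5) * srate),
               target - sum(mask) + round(0.1 * srate))
    start <- sample.int(n - len + 1L, 1L)
    mask[start:(start + len - 1L)] <- TRUE
  }
  mask
}

# semi-Markov label sequence: gamma run durations, next state ~ weights
# (self-transitions excluded)
semi_markov_labels <- function(n, dur_samples, weights, shape) {
  k <- length(dur_samples)
  lab <- integer(n)
  pos <- 1L
  state <- sample.int(k, 1L, prob = weights)
  while (pos <= n) {
    len <- max(1L, round(stats::rgamma(1, shape = shape,
                                       scale = dur_samples[state] / shape)))
    end <- min(pos + len - 1L, n)
    lab[pos:end] <- state
    pos <- end + 1L
    w <- weights; w[state] <- 0
    state <- sample.int(k, 1L, prob = w)
  }
  lab
}

#' Simulate one subject's recording with ground truth
#'
#' A semi-Markov microstate sequence (gamma run durations, entry-weight
#' transition structure) drives the clean signal
#' `template[L(t)] * sin(2 pi f t + phase(run))`; spatially correlated
#' Gaussian noise is added at the configured SNR and contiguous artifact
#' blocks are masked. The ground truth carries the exact label sequence, the
#' temporal parameters recomputed from it (with the clean signal's GFP as
#' GEV weights), and the generator's expected transition matrix.
#'
#' @param cfg a [sim_config()].
#' @param templates a [template_set()] with `cfg$k_true` maps (e.g.
#'   [make_templates()]).
#' @param group `"ASD"` (receives the effect spec) or `"TD"`.
#' @param subject_id identifier for the outputs.
#' @param seed per-subject RNG seed.
#' @return list: `recording` (average-referenced [eeg_recording()]),
#'   `truth` (list: `labels`, `params`, `expected_transitions`,
#'   `subject_templates`).
#' @export
simulate_subject <- function(cfg, templates, group = c("TD", "ASD"),
                             subject_id = "s1", seed = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(cfg, "sim_config"), inherits(templates, "template_set"),
            templates$k == cfg$k_true)
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$k_true
  n <- round(cfg$duration_s * cfg$srate)
  C <- nrow(templates$maps)

  dur <- cfg$mean_duration_ms * exp(stats::rnorm(k, 0, cfg$subject_cv_duration))
  wts <- cfg$entry_weights * exp(stats::rnorm(k, 0, cfg$subject_cv_weight))
  if (group == "ASD") {
    i <- match(cfg$effect_map, templates$labels)
    dur[i] <- dur[i] * cfg$effect_duration_ratio
    wts[i] <- wts[i] * cfg$effect_occurrence_ratio
  }
  # per-subject topography variant of the cohort templates
  subj_maps <- templates$maps +
    cfg$template_jitter * matrix(stats::rnorm(C * k), C, k) / sqrt(C)
  subj_maps <- center_unit(subj_maps)

  lab <- semi_markov_labels(n, dur * cfg$srate / 1000, wts, cfg$duration_shape)
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  clean <- matrix(0, C, n)
  tvec <- seq_len(n) / cfg$srate
  for (j in seq_along(r$values)) {
    idx <- starts[j]:ends[j]
    s <- sin(2 * pi * cfg$carrier_freq_hz * tvec[idx] +
               stats::runif(1, 0, 2 * pi))
    carrier <- sign(s) * (cfg$carrier_floor + (1 - cfg$carrier_floor) * abs(s))
    clean[, idx] <- subj_maps[, r$values[j]] %o% carrier
  }
  # spatially correlated noise: exp(-distance) covariance on the layout
  pos <- attr(templates, "positions")
  if (is.null(pos)) pos <- fibonacci_layout(C)
  D <- as.matrix(stats::dist(pos))
  L <- chol(exp(-D / 0.5) + 1e-8 * diag(C))
  noise <- t(L) %*% matrix(stats::rnorm(C * n), C, n)
  noise <- sweep(noise, 2L, colMeans(noise))
  gfp_of <- function(m) sqrt(colSums(sweep(m, 2L, colMeans(m))^2) / C)
  scale <- mean(gfp_of(clean)) / (cfg$snr * mean(gfp_of(noise)))
  data <- clean + scale * noise
  data <- sweep(data, 2L, colMeans(data))
  mask <- artifact_blocks(n, cfg$artifact_fraction, cfg$srate)
  rec <- eeg_recording(data, cfg$srate, artifact_mask = mask,
                       reference = "average")

  # exact ground truth from the generated sequence and the clean signal
  seg_true <- structure(
    list(labels = ifelse(mask, NA_integer_, lab), corr = rep(1, n),
         gfp = gfp_of(clean), mask = mask, srate = cfg$srate, k = k,
         map_labels = templates$labels),
    class = "segmentation")
  params <- temporal_parameters(seg_true, subject_id = subject_id)
  etp <- matrix(0, k, k)
  for (i in seq_len(k)) etp[i, -i] <- wts[-i] / sum(wts[-i])
  list(recording = rec,
       truth = list(labels = lab, params = params,
                    expected_transitions = etp,
                    subject_templates = template_set(subj_maps,
                                                     templates$labels)))
}

#' Simulate a two-group cohort with known ground truth
#'
#' Generates cohort templates (unless supplied), simulates every subject
#' ([simulate_subject()]; the ASD group receives the configured map-B
#' effect), and builds a clinical table whose score distributions follow the
#' published per-group summaries ([cohort_reference_moments()]) with the
#' configured linear couplings to true temporal parameters and realistic
#' missingness (scores assessed in only part of each group).
#'
#' @param cfg a [sim_config()].
#' @param templates optional [template_set()]; generated from `cfg$seed`
#'   when missing.
#' @return list: `recordings` (named list of [eeg_recording()]s), `truth`
#'   (per-subject ground-truth list), `clinical` (clinical table),
#'   `templates`, `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config(), templates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(templates))
    templates <- make_templates(cfg$n_channels, cfg$k_true,
                                seed = cfg$seed)
  ids <- c(sprintf("asd%03d", seq_len(cfg$n_asd)),
           sprintf("td%03d", seq_len(cfg$n_td)))
  groups <- c(rep("ASD", cfg$n_asd), rep("TD", cfg$n_td))
  subj_seeds <- sample.int(.Machine$integer.max, length(ids))
  recordings <- truth <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    s <- simulate_subject(cfg, templates, groups[i], ids[i], subj_seeds[i])
    recordings[[i]] <- s$recording
    truth[[i]] <- s$truth
  }
  true_params <- do.call(rbind, lapply(truth, `[[`, "params"))
  clinical <- simulate_clinical(ids, groups, true_params, cfg)
  list(recordings = recordings, truth = truth, clinical = clinical,
       templates = templates, cfg = cfg)
}

# clinical scores from published per-group moments + configured couplings
simulate_clinical <- function(ids, groups, true_params, cfg) {
  ref <- cohort_reference_moments("clinical")
  n <- length(ids)
  out <- data.frame(subject_id = ids, group = groups,
                    sex = ifelse(stats::runif(n) < 0.2, "F", "M"))
  coupled <- vapply(cfg$clinical_couplings, `[[`, "", "score")
  for (sc in unique(ref$parameter)) {
    vals <- rep(NA_real_, n)
    for (g in c("ASD", "TD")) {
      row <- ref[ref$parameter == sc & ref$group == g, ]
      gi <- which(groups == g)
      # assessed-fraction missingness mirrors the published Ns
      n_group_ref <- ref$n[ref$parameter == "age_years" & ref$group == g]
      frac <- min(1, row$n / n_group_ref)
      assessed <- gi[stats::runif(length(gi)) < frac]
      z <- stats::rnorm(length(assessed))
      ci <- match(sc, coupled)
      if (!is.na(ci) && row$sd > 0) {
        cp <- cfg$clinical_couplings[[ci]]
        pv <- true_params[true_params$map == cp$map,
                          c("subject_id", cp$parameter)]
        x <- pv[match(ids[assessed], pv$subject_id), cp$parameter]
        zx <- (x - mean(x)) / max(stats::sd(x), 1e-12)
        z <- cp$r * zx + sqrt(1 - cp$r^2) * z
      }
      vals[assessed] <- row$mean + row$sd * z
    }
    out[[sc]] <- vals
  }
  class(out) <- c("clinical_table", class(out))
  out
}
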