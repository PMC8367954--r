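# fixed samples shared with an external reference implementation of the
# omnibus normality test (values frozen from scipy.stats.normaltest)
dp_gauss <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.302180,
  0.127840, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792, 0.066031,
  1.127241, 0.467509, -0.859292, 0.368751, -0.958883, 0.878450, -0.049926,
  -0.184862, -0.680930, 1.222541, -0.154529, -0.428328, -0.352134, 0.532309,
  0.365444, 0.412733, 0.430821, 2.141648, -0.406415, -0.512243, -0.813773,
  0.615979, 1.128972, -0.113947, -0.840156, -0.824481, 0.650593, 0.743254,
  0.543154, -0.665510, 0.232161, 0.116686, 0.218689, 0.871429, 0.223596,
  0.678914, 0.067579, 0.289119, 0.631288, -1.457156, -0.319671, -0.470373,
  -0.638878, -0.275142, 1.494941, -0.865831, 0.968278)
dp_expo <- c(1.507809, 5.309883, 2.106660, 1.644866, 1.043491, 0.592524,
  0.044454, 0.956603, 0.621383, 1.507961, 2.028002, 0.332069, 0.049751,
  0.924822, 2.553419, 0.821072, 2.130943, 0.753015, 1.313994, 0.288783,
  0.134417, 0.142481, 0.117682, 0.054673, 1.716593, 0.448615, 0.386131,
  0.934959, 0.187267, 1.918292, 1.291956, 0.329242, 0.200592, 0.531020,
  0.304831, 0.075739, 0.503560, 2.251879, 1.008850, 3.082411, 2.046432,
  1.117892, 1.850600, 0.726931, 1.067849, 0.380219, 0.219054, 2.144917,
  0.140303, 0.187899, 0.310242, 0.967499, 0.413839, 0.684483, 2.159779,
  1.541720, 1.171247, 0.170950, 1.189421, 0.454478)

test_that("the omnibus normality test matches the reference implementation", {
  g <- dagostino_pearson(dp_gauss)
  expect_equal(g$statistic, 0.1186617104, tolerance = 1e-8)
  expect_equal(g$p.value, 0.9423949213, tolerance = 1e-8)
  e <- dagostino_pearson(dp_expo)
  expect_equal(e$statistic, 37.2120723764, tolerance = 1e-8)
  expect_equal(e$p.value, 8.3e-9, tolerance = 1e-2)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(2, 20)), "zero-variance")
})

test_that("the normality gate picks the right test family", {
  expect_equal(normality_gate(dp_gauss, dp_gauss + 1), "t")
  expect_equal(normality_gate(dp_gauss, dp_expo), "mann_whitney")
  expect_equal(normality_gate(dp_expo, dp_expo), "mann_whitney")
  expect_warning(res <- normality_gate(rnorm(5), rnorm(20)), "n < 8")
  expect_equal(res, "mann_whitney")
})

test_that("moment-based Welch tests agree exactly with raw-data t-tests", {
  eq <- welch_t_from_moments(5, 1, 10, 5, 2, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  set.seed(41)
  for (r in 1:10) {
    a <- rnorm(3 + r); b <- rnorm(5 + r, 0.8)
    ref <- t.test(a, b)
    got <- welch_t_from_moments(mean(a), sd(a), length(a),
                                mean(b), sd(b), length(b))
    expect_equal(got$t, unname(ref$statistic))
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value)
  }
  expect_error(welch_t_from_moments(1, 0, 5, 1, 0, 5), "undefined")
  expect_error(welch_t_from_moments(1, 1, 1, 2, 1, 5), "n must be")
})

# long-format parameter table with Gaussian values at given per-map moments
moments_table <- function(ref, group, n, prefix) {
  rows <- list()
  for (m in unique(ref$map)) {
    df <- data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)), map = m)
    for (p in unique(ref$parameter)) {
      r <- ref[ref$map == m & ref$parameter == p & ref$group == group, ]
      df[[p]] <- rnorm(n, r$mean, r$sd)
    }
    rows[[m]] <- df
  }
  do.call(rbind, rows)
}

test_that("group comparison gates tests, applies FDR, and has power for the
           published map-B effect sizes", {
  ref <- cohort_reference_moments("temporal")
  set.seed(42)
  hits3 <- 0; hits4 <- 0; reps <- 40
  for (r in seq_len(reps)) {
    a <- moments_table(ref, "ASD", 66, "a")
    b <- moments_table(ref, "TD", 47, "b")
    cmp <- suppressWarnings(compare_groups_fdr(a, b))
    expect_equal(nrow(cmp), 20L)
    bsig <- cmp$significant[cmp$map == "B"]
    bnon <- cmp$parameter[cmp$map == "B"] != "gev"
    hits3 <- hits3 + all(bsig[bnon])
    hits4 <- hits4 + all(bsig)
  }
  # duration/coverage/occurrence (d ~ 0.85) survive FDR almost always;
  # adding the weaker GEV effect (d ~ 0.63) still succeeds in a majority
  expect_gte(hits3 / reps, 0.90)
  expect_gt(hits4 / reps, 0.5)

  # identical groups: no FDR-significant comparisons at a fixed seed
  set.seed(7)
  a0 <- moments_table(ref, "TD", 40, "a")
  b0 <- moments_table(ref, "TD", 40, "b")
  cmp0 <- suppressWarnings(compare_groups_fdr(a0, b0))
  expect_false(any(cmp0$significant))
  expect_error(compare_groups_fdr(a0[, 1:3], b0), "missing columns")
})

test_that("clinical correlations gate method, block FDR, and skip degenerates", {
  set.seed(43)
  n <- 40
  par <- data.frame(subject_id = sprintf("s%02d", 1:n), map = "B",
                    gev = rnorm(n, 0.1, 0.03),
                    mean_duration_ms = rnorm(n, 72, 5),
                    coverage_pct = rnorm(n, 20, 4),
                    occurrence_per_s = rnorm(n, 2.4, 0.35))
  clin <- data.frame(subject_id = par$subject_id, group = "ASD", sex = "M",
                     CBCL_AffP_T = 2 * par$coverage_pct + rnorm(n, 0, 1),
                     CBCL_AnxP_T = rnorm(n, 55, 8),
                     MSEL_total_DQ = rnorm(n, 75, 20),
                     flat_score = 7)
  res <- suppressWarnings(
    correlate_clinical(par, clin, min_pairs = 8))
  hit <- res[res$score == "CBCL_AffP_T" & res$parameter == "coverage_pct", ]
  expect_gt(hit$r, 0.8)
  expect_lt(hit$p, 0.01)
  expect_equal(hit$method, "pearson")
  expect_false("flat_score" %in% res$score)      # zero variance skipped
  # FDR blocks follow the instrument prefix
  expect_setequal(unique(res$block), c("CBCL", "MSEL"))
  ind <- res[res$score == "MSEL_total_DQ", ]
  expect_true(all(abs(ind$r) < 0.5))
  # missing values: pairwise deletion with the min-pairs floor
  clin2 <- clin; clin2$MSEL_total_DQ[1:35] <- NA
  expect_warning(res2 <- correlate_clinical(par, clin2), "skipped")
  expect_false("MSEL_total_DQ" %in% res2$score)
})

test_that("bootstrap power curves calibrate at the null and rise with n", {
  set.seed(44)
  x <- rnorm(47); y <- rnorm(47)
  null_curve <- bootstrap_power_curve(x, x, n_min = 10, n_max = 40, step = 15,
                                      reps = 400, seed = 1)
  expect_true(all(abs(null_curve$likelihood - 0.05) < 0.04))
  eff <- bootstrap_power_curve(x, y + 0.8, n_min = 5, n_max = 45, step = 5,
                               reps = 300, seed = 2)
  # non-decreasing up to Monte-Carlo error
  expect_lt(max(c(0, -diff(eff$likelihood))), 0.05)
  expect_gt(eff$likelihood[nrow(eff)], eff$likelihood[1])
  expect_error(bootstrap_power_curve(x, y, reps = 0), "reps")
  expect_error(bootstrap_power_curve(x, y, n_max = 60,
                                     with_replacement = FALSE),
               "without replacement")
})

test_that("Benjamini-Hochberg agrees with the step-up definition", {
  # independent step-up implementation
  bh_stepup <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    crit <- ord[which(p[ord] <= q * seq_len(m) / m)]
    reject <- rep(FALSE, m)
    if (length(crit)) {
      kmax <- max(which(p[ord] <= q * seq_len(m) / m))
      reject[ord[seq_len(kmax)]] <- TRUE
    }
    reject
  }
  set.seed(45)
  grid <- seq(0.005, 1, by = 0.05)
  for (m in 1:4) {                                # exhaustive small vectors
    combos <- as.matrix(expand.grid(rep(list(grid), m)))
    combos <- combos[sample(nrow(combos), min(200, nrow(combos))), , drop = FALSE]
    for (i in seq_len(nrow(combos))) {
      p <- combos[i, ]
      expect_equal(p.adjust(p, "BH") <= 0.05, bh_stepup(p, 0.05),
                   ignore_attr = TRUE)
    }
  }
})

test_that("detection rates from printed moments approximate analytic power", {
  # large-n, large-effect sanity: detection approaches the closed-form power
  rate <- detection_rate_from_moments(1, 1, 0, 1, n = 30, reps = 1500, seed = 3)
  analytic <- 100 * power.t.test(n = 30, delta = 1, sd = 1)$power
  expect_lt(abs(rate - analytic), 5)
  null_rate <- detection_rate_from_moments(0, 1, 0, 1, n = 30, reps = 1500,
                                           seed = 4)
  expect_lt(abs(null_rate - 5), 3)
})
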