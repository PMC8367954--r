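test_that("back-fitting is polarity/scale invariant and floor-gated", {
  q <- orthonormal_maps(30, 3, seed = 21)
  tpl <- template_set(q)
  w <- orthonormal_maps(30, 4, seed = 21)[, 4]   # orthogonal to q's span
  samples <- cbind(q[, 2] * -3,                          # template 2, flipped
                   0.4 * q[, 1] + sqrt(1 - 0.16) * w,    # best corr 0.4
                   0.5 * q[, 1] + sqrt(0.75) * w,        # exactly at floor
                   0.8 * q[, 3] + 0.6 * w,               # corr 0.8
                   q[, 1])
  rec <- eeg_recording(samples, 125, reference = "average")
  seg <- backfit(rec, tpl)
  expect_equal(seg$labels[1], 2L)
  expect_equal(seg$corr[1], 1, tolerance = 1e-10)
  expect_true(is.na(seg$labels[2]))              # 0.4 < threshold
  expect_true(is.na(seg$labels[3]))              # 0.5 is not > 0.5 (strict)
  expect_equal(seg$labels[4], 3L)
  expect_equal(seg$corr[4], 0.8, tolerance = 1e-10)
  # masked samples are unlabeled even at perfect correlation
  rec$artifact_mask[5] <- TRUE
  expect_true(is.na(backfit(rec, tpl)$labels[5]))
  expect_error(backfit(eeg_recording(samples, 125, reference = "average"),
                       template_set(orthonormal_maps(10, 3))),
               "channel count")
})

test_that("noiseless synthetic sequences are relabeled perfectly", {
  cfg <- sim_config(n_channels = 40, duration_s = 20, snr = 1e6,
                    template_jitter = 0, artifact_fraction = 0, seed = 4)
  tpl <- make_templates(40, 5, seed = 4)
  sim <- simulate_subject(cfg, tpl, "TD", seed = 9)
  seg <- backfit(sim$recording, tpl)
  expect_equal(seg$labels, sim$truth$labels)
})

test_that("run extraction respects unlabeled gaps and mask boundaries", {
  seg <- make_segmentation(c(1, 1, 2, 2, 2, NA, 1), k = 2)
  runs <- extract_runs(seg)
  expect_equal(runs$label, c(1L, 2L, 1L))
  expect_equal(runs$end - runs$start, c(2L, 3L, 1L))
  expect_equal(runs$start, c(0L, 2L, 6L))        # 0-based half-open
  expect_equal(runs$duration_ms, c(16, 24, 8))   # at 125 Hz
  expect_equal(nrow(extract_runs(make_segmentation(c(NA, NA, NA), k = 2))), 0L)
  alt <- extract_runs(make_segmentation(c(1, 2, 1, 2), k = 2))
  expect_equal(nrow(alt), 4L)
  expect_true(all(alt$end - alt$start == 1L))
})

test_that("temporal parameters match definitions and the brute-force oracle", {
  # 1 s at 125 Hz, three runs of map A totaling 25 samples
  lab <- rep(NA_integer_, 125)
  lab[1:10] <- 1L; lab[31:40] <- 1L; lab[61:65] <- 1L
  lab[80:124] <- 2L
  seg <- make_segmentation(lab, k = 2)
  tp <- temporal_parameters(seg)
  a <- tp[tp$map == "A", ]
  expect_equal(a$occurrence_per_s, 3)
  expect_equal(a$coverage_pct, 20)
  expect_equal(a$mean_duration_ms, mean(c(10, 10, 5)) / 125 * 1000)

  # single-template noiseless recording: GEV 1, coverage 100
  one <- make_segmentation(rep(1L, 50), k = 3, corr = rep(1, 50))
  tp1 <- temporal_parameters(one)
  expect_equal(tp1$gev, c(1, 0, 0))
  expect_equal(tp1$coverage_pct, c(100, 0, 0))
  expect_equal(tp1$occurrence_per_s[2:3], c(0, 0))   # occurrence 0 iff coverage 0

  # random segmentation vs an independent recomputation from raw labels
  set.seed(23)
  n <- 400
  lab <- sample(c(NA, 1:3), n, TRUE)
  mask <- runif(n) < 0.15
  lab[mask] <- NA
  gfp <- runif(n); corr <- runif(n, 0.5, 1)
  seg <- make_segmentation(lab, k = 3, gfp = gfp, corr = corr, mask = mask)
  tp <- temporal_parameters(seg)
  unm <- which(!mask)
  for (m in 1:3) {
    sel <- which(!is.na(lab) & lab == m)
    expect_equal(tp$gev[m], sum(gfp[sel]^2 * corr[sel]^2) / sum(gfp[unm]^2))
    expect_equal(tp$coverage_pct[m], 100 * length(sel) / length(unm))
    runs_m <- 0; durs <- c(); cur <- 0
    for (i in seq_len(n + 1)) {                  # brute-force run scan
      if (i <= n && !is.na(lab[i]) && lab[i] == m) cur <- cur + 1
      else { if (cur > 0) { runs_m <- runs_m + 1; durs <- c(durs, cur) }; cur <- 0 }
    }
    expect_equal(tp$occurrence_per_s[m], runs_m / (length(unm) / 125))
    expect_equal(tp$mean_duration_ms[m], mean(durs) / 125 * 1000)
  }
  # invariants: coverage closes to 100 exactly; GEV sums below 1
  unlabeled_pct <- 100 * sum(is.na(lab[unm])) / length(unm)
  expect_equal(sum(tp$coverage_pct) + unlabeled_pct, 100)
  expect_lte(sum(tp$gev), 1)
  expect_error(temporal_parameters(make_segmentation(c(1, 1), k = 1,
                                                     mask = c(TRUE, TRUE))),
               "unmasked")
})

test_that("occurrence x duration reproduces coverage for equal run lengths", {
  lab <- rep(c(1L, NA), times = c(10, 10))
  lab <- rep(lab, 5)                             # 5 runs of 10 in 100 samples
  seg <- make_segmentation(lab, k = 1, srate = 100)
  tp <- temporal_parameters(seg)
  expect_equal(tp$occurrence_per_s * tp$mean_duration_ms / 1000,
               tp$coverage_pct / 100)
})
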