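test_that("spatial correlation honors polarity convention and errors cleanly", {
  set.seed(2)
  u <- rnorm(20)
  expect_equal(spatial_corr(u, u), 1)
  expect_equal(spatial_corr(u, -u), 1)                      # polarity ignored
  expect_equal(spatial_corr(u, -u, ignore_polarity = FALSE), -1)
  # orthogonalized mean-zero pair correlates at 0 to machine precision
  q <- orthonormal_maps(30, 2, seed = 4)
  expect_lt(abs(spatial_corr(q[, 1], q[, 2])), 1e-12)
  expect_error(spatial_corr(u, rep(1, 20)), "zero-variance")
  expect_error(spatial_corr(u, rnorm(5)), "equal length")
})

test_that("modified k-means recovers sign-flipped templates exactly", {
  q <- orthonormal_maps(40, 2, seed = 5)
  signs <- rep(c(1, -1), 15)
  maps <- cbind(q[, rep(1, 30)] * rep(signs, each = 40),
                q[, rep(2, 30)] * rep(signs, each = 40))
  sol <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  cr <- abs(crossprod(sol$templates$maps, q))
  expect_equal(apply(cr, 2, max), c(1, 1), tolerance = 1e-10)
  expect_equal(sol$gev_total, 1, tolerance = 1e-10)
  expect_error(modified_kmeans(maps, 100), "exceeds")
})

test_that("k = 1 GEV equals the brute-force GFP-weighted oracle", {
  set.seed(6)
  maps <- matrix(rnorm(25 * 40), 25)
  sol <- modified_kmeans(maps, 1, n_restarts = 1, seed = 2)
  # independent oracle: center, per-map gfp and correlation to the template
  tmpl <- sol$templates$maps[, 1]
  num <- den <- 0
  for (i in seq_len(ncol(maps))) {
    m <- maps[, i] - mean(maps[, i])
    gfp <- sqrt(mean(m^2))
    r <- sum(m * tmpl) / sqrt(sum(m^2) * sum(tmpl^2))
    num <- num + gfp^2 * r^2
    den <- den + gfp^2
  }
  expect_equal(sol$gev_total, num / den, tolerance = 1e-12)
})

test_that("noisy multi-template data is recovered above 0.95 correlation", {
  set.seed(8)
  q <- orthonormal_maps(50, 3, seed = 9)
  idx <- rep(1:3, length.out = 60)
  maps <- q[, idx] * rep(sample(c(-1, 1), 60, TRUE), each = 50) +
    0.1 * matrix(rnorm(50 * 60), 50)
  sol <- modified_kmeans(maps, 3, n_restarts = 10, seed = 3)
  cr <- abs(crossprod(sol$templates$maps, q))
  expect_true(all(apply(cr, 2, max) > 0.95))
})

test_that("GEV grows with k and hits 1 when k covers all distinct maps", {
  set.seed(10)
  q <- orthonormal_maps(30, 4, seed = 11)
  maps <- q[, rep(1:4, each = 10)] * rep(sign(rnorm(40)), each = 30)
  gevs <- vapply(1:4, function(k)
    modified_kmeans(maps, k, n_restarts = 8, seed = k)$gev_total, 0)
  expect_true(all(diff(gevs) > -1e-9))
  expect_equal(gevs[4], 1, tolerance = 1e-9)
  # templates are invariant (up to sign/order) under input sign flips
  flipped <- maps * rep(sample(c(-1, 1), 40, TRUE), each = 30)
  s1 <- modified_kmeans(maps, 4, n_restarts = 8, seed = 5)
  s2 <- modified_kmeans(flipped, 4, n_restarts = 8, seed = 6)
  m <- match_templates(s1$templates, s2$templates)
  expect_equal(m$corr, rep(1, 4), tolerance = 1e-9)
})

test_that("the criterion ensemble finds the generating cluster number", {
  set.seed(5)
  tpl <- make_templates(60, 5, seed = 7)
  n <- 300
  idx <- sample(1:5, n, replace = TRUE)
  noisy <- function(k_use) {
    i <- idx; i[i > k_use] <- sample(1:k_use, sum(i > k_use), TRUE)
    tpl$maps[, i] * rep(sample(c(-1, 1), n, TRUE), each = 60) +
      0.25 * matrix(rnorm(60 * n), 60) / sqrt(60)
  }
  sel5 <- select_optimal_k(noisy(5), k_range = 2:8, n_restarts = 8, seed = 3)
  expect_equal(sel5$k, 5L)
  sel2 <- select_optimal_k(noisy(2), k_range = 2:8, n_restarts = 8, seed = 3)
  expect_equal(sel2$k, 2L)
  # degenerate: one template only, up to sign
  one <- tpl$maps[, rep(1, 40)] * rep(c(1, -1), each = 60, length.out = 40 * 60)
  expect_warning(sel1 <- select_optimal_k(one, k_range = 2:4, n_restarts = 2),
                 "identical")
  expect_equal(sel1$k, 2L)
})

test_that("group clustering pools subject templates faithfully", {
  q <- orthonormal_maps(40, 3, seed = 13)
  subj <- template_set(q)
  sol <- group_templates(list(subj, subj, subj), 3, n_restarts = 5, seed = 1)
  m <- match_templates(sol$templates, subj)
  expect_equal(m$corr, rep(1, 3), tolerance = 1e-9)
  other <- template_set(orthonormal_maps(20, 3, seed = 14))
  expect_error(group_templates(list(subj, other), 3), "channel counts")
  expect_error(group_templates(list(subj), 3), ">= 2 subjects")

  # 20 synthetic subjects around one truth: recovery above 0.95 per map
  set.seed(15)
  truth <- make_templates(60, 5, seed = 16)
  subs <- lapply(1:20, function(i) {
    m <- truth$maps + 0.25 * matrix(rnorm(60 * 5), 60) / sqrt(60)
    template_set(m * rep(sample(c(-1, 1), 5, TRUE), each = 60))
  })
  gsol <- group_templates(subs, 5, n_restarts = 10, seed = 2)
  mm <- match_templates(gsol$templates, truth)
  expect_true(all(mm$corr > 0.95))
})

test_that("template matching solves the assignment exactly", {
  set.seed(17)
  a <- template_set(orthonormal_maps(30, 5, seed = 18))
  perm <- c(3, 5, 1, 2, 4)
  b <- template_set(a$maps[, perm] * rep(c(-1, 1, -1, 1, 1), each = 30))
  m <- match_templates(a, b)
  expect_equal(m$corr, rep(1, 5), tolerance = 1e-10)
  expect_equal(match(m$label_b, b$labels), order(perm))
  # independent random sets correlate weakly on average
  r <- template_set(matrix(rnorm(30 * 5), 30))
  expect_lt(mean(match_templates(a, r)$corr), 0.9)
  # k = 1 reduces to a single absolute correlation
  a1 <- template_set(a$maps[, 1, drop = FALSE])
  b1 <- template_set(-a$maps[, 1, drop = FALSE] + 0.01 * rnorm(30))
  m1 <- match_templates(a1, b1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$corr, spatial_corr(a1$maps[, 1], b1$maps[, 1]))
  expect_error(match_templates(a, a1), "equal k")
})

test_that("canonical labeling is cosmetic and deterministic", {
  pos <- fibonacci_layout(64)
  canon <- canonical_templates(pos)
  expect_equal(canon$labels, c("A", "B", "C", "D", "E"))
  relab <- assign_canonical_labels(canon, pos)
  expect_equal(relab$labels, canon$labels)      # fixed point
  expect_equal(unname(relab$maps), unname(canon$maps))
})
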