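#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness z (D'Agostino 1970) and kurtosis
#' z (Anscombe & Glynn 1983) into `K2 = z1^2 + z2^2`, referred to a
#' chi-squared distribution with 2 df. Valid for n >= 8 (below that the
#' kurtosis approximation breaks down and the function refuses).
#'
#' @param x numeric sample (NAs dropped), n >= 8.
#' @return list: `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample")
  b1 <- mean((x - m)^3) / m2^1.5          # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2            # sample kurtosis g2 (not excess)

  # skewness: D'Agostino (1970) normalizing transformation
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Choose between t-test and Mann-Whitney by normality
#'
#' Returns `"t"` only if both samples pass the D'Agostino-Pearson omnibus
#' test at `alpha` (default 0.05). Samples smaller than 8 cannot be tested
#' and fall back to `"mann_whitney"` with a warning.
#'
#' @param sample_a,sample_b numeric samples (NAs dropped).
#' @param alpha normality significance level.
#' @return `"t"` or `"mann_whitney"`.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 8L || length(sample_b) < 8L) {
    warning("n < 8: normality untestable, falling back to Mann-Whitney")
    return("mann_whitney")
  }
  pa <- dagostino_pearson(sample_a)$p.value
  pb <- dagostino_pearson(sample_b)$p.value
  if (pa >= alpha && pb >= alpha) "t" else "mann_whitney"
}
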