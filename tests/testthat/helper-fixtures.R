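# shared fixture builders (everything generated in code, nothing stored)

# multichannel recording carrying one sinusoid on every channel
sine_recording <- function(freq, srate = 1000, duration = 4, channels = 3,
                           amp = 1, phase = 0) {
  t <- (seq_len(srate * duration) - 1) / srate   # sample i at t = (i-1)/fs
  x <- amp * sin(2 * pi * freq * t + phase)
  data <- t(vapply(seq_len(channels), function(i) x * i, t))
  eeg_recording(data, srate)
}

# RMS over the central half of a series (keeps filter edge effects out)
central_rms <- function(x) {
  n <- length(x)
  idx <- floor(n / 4):ceiling(3 * n / 4)
  sqrt(mean(x[idx]^2))
}

# hand-built segmentation object for backfit-independent tests
make_segmentation <- function(labels, k = max(labels, na.rm = TRUE),
                              srate = 125, gfp = NULL, corr = NULL,
                              mask = NULL) {
  n <- length(labels)
  structure(
    list(labels = as.integer(labels),
         corr = if (is.null(corr)) rep(0.9, n) else corr,
         gfp = if (is.null(gfp)) rep(1, n) else gfp,
         mask = if (is.null(mask)) rep(FALSE, n) else mask,
         srate = srate, k = as.integer(k),
         map_labels = LETTERS[seq_len(k)]),
    class = "segmentation")
}

# transition_result with a given normalized matrix (for group comparisons)
make_transition_result <- function(normalized) {
  k <- nrow(normalized)
  structure(list(observed = normalized, expected = matrix(1 / (k - 1), k, k),
                 normalized = normalized, n_transitions = 100L),
            class = "transition_result")
}

# small orthonormal mean-zero map basis (channels x k), via QR of random maps
orthonormal_maps <- function(channels, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(channels * (k + 1)), channels)
  m <- sweep(m, 2, colMeans(m))
  q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
  q <- sweep(q, 2, colMeans(q))          # re-center (QR can reintroduce mean)
  sweep(q, 2, sqrt(colSums(q^2)), "/")
}
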