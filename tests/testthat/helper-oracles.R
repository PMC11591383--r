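# Independent oracles and small fixtures, kept deliberately naive: direct
# evaluation of definitions, loop-based re-implementations, and tiny
# generated datasets. Nothing here calls the code paths it checks.

make_sine <- function(freq, sr, dur = 1, amp = 0.8, phase = 0) {
  audio_segment(amp * sin(2 * pi * freq * (0:(round(dur * sr) - 1)) / sr +
                            phase), sr)
}

# O(N^2) DFT of one windowed frame: X(k) = sum_n x(n) w(n) e^{-2pi i k n/N}.
naive_dft_frame <- function(x, w) {
  n <- length(x)
  k <- 0:(n - 1)
  ek <- exp(-2i * pi * outer(k, k) / n)
  as.vector(ek %*% (x * w))
}

# Direct per-bin constant-Q evaluation with the package's truncation
# policy (kernel cut to the signal length, renormalized by the actual
# kernel length, signal zero-padded past its end).
naive_cqt_bin <- function(x, sr, cfg, k, frame_start) {
  fk <- cfg$f_min * 2^((k - 1) / cfg$bins_per_octave)
  nk <- ceiling(sr * cfg$q / fk)
  nk_eff <- min(nk, length(x))
  n <- 0:(nk_eff - 1)
  w_full <- if (nk == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(nk - 1)) / (nk - 1))
  xs <- numeric(nk_eff)
  idx <- frame_start + n + 1
  inside <- idx <= length(x)
  xs[inside] <- x[idx[inside]]
  abs(sum(xs * w_full[seq_len(nk_eff)] *
            exp(-2i * pi * cfg$q * n / nk))) / nk_eff
}

# Loop-based bilinear resize with half-pixel centers (independent of the
# package's weight-matrix formulation).
naive_bilinear <- function(m, out_r, out_c) {
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      sy <- min(max((i - 0.5) * nrow(m) / out_r + 0.5, 1), nrow(m))
      sx <- min(max((j - 0.5) * ncol(m) / out_c + 0.5, 1), ncol(m))
      y0 <- min(floor(sy), nrow(m) - (nrow(m) > 1)); y0 <- max(y0, 1)
      x0 <- min(floor(sx), ncol(m) - (ncol(m) > 1)); x0 <- max(x0, 1)
      y1 <- min(y0 + 1, nrow(m)); x1 <- min(x0 + 1, ncol(m))
      wy <- sy - y0; wx <- sx - x0
      out[i, j] <- (1 - wy) * ((1 - wx) * m[y0, x0] + wx * m[y0, x1]) +
        wy * ((1 - wx) * m[y1, x0] + wx * m[y1, x1])
    }
  }
  out
}

# Seeded Gaussian blob dataset: 2 informative dimensions separating three
# classes, plus pure-noise dimensions.
make_blobs <- function(n_per_class = 20, noise_dims = 8, sep = 4,
                       seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(c) {
    cbind(rnorm(n_per_class, centers[c, 1]),
          rnorm(n_per_class, centers[c, 2]),
          matrix(rnorm(n_per_class * noise_dims), n_per_class))
  }))
  colnames(X) <- c("inf_1", "inf_2", paste0("noise_", seq_len(noise_dims)))
  list(X = X, y = rep(c("a", "b", "c"), each = n_per_class))
}

# Tiny separable 100x100x3 images: each class lights up a different
# region, plus seeded pixel noise.
tiny_images <- function(n_per_class = 6, seed = 1, noise = 0.05) {
  set.seed(seed)
  classes <- c("foraging", "other", "rumination")
  rows <- list(1:30, 36:65, 71:100)
  images <- list()
  labels <- character(0)
  for (ci in 1:3) {
    for (i in seq_len(n_per_class)) {
      im <- array(runif(100 * 100 * 3) * noise, c(100, 100, 3))
      im[rows[[ci]], , ci] <- im[rows[[ci]], , ci] + 0.8
      images[[length(images) + 1L]] <- pmin(im, 1)
      labels <- c(labels, classes[ci])
    }
  }
  list(images = images, labels = labels)
}

# Envelope-threshold event counter: moving-average smoothed |x|,
# thresholded at a fraction of the peak; sub-event gaps shorter than
# `merge_gap` are closed before counting runs, so one noisy burst counts
# once.
count_envelope_peaks <- function(x, sr, win = 0.01, thresh_frac = 0.3,
                                 merge_gap = 0.05) {
  k <- max(1, round(win * sr))
  env <- stats::filter(abs(x), rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  above <- env > thresh_frac * max(env)
  r <- rle(as.vector(above))
  gap <- max(1, round(merge_gap * sr))
  short_gap <- !r$values & r$lengths < gap
  inner <- which(short_gap & seq_along(r$values) > 1 &
                   seq_along(r$values) < length(r$values))
  r$values[inner] <- TRUE
  merged <- inverse.rle(r)
  sum(diff(c(FALSE, merged)) == 1)
}

# Small labelled synthetic corpus (in memory).
small_corpus <- function(n_per_class = 8, seed = 11, sr = 16000) {
  generate_corpus_segments(corpus_spec(n_per_class = n_per_class,
                                       sample_rate = sr, seed = seed))
}
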