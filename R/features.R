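# Hand-crafted acoustic features: 34 short-term descriptors per frame
# (time-domain, spectral, cepstral and chroma), their first-order deltas,
# and the per-segment mean of both blocks, giving the 68-dimensional
# acoustic feature vector. Framing defaults to 50 ms windows with a 25 ms
# hop. A train-fitted standardizer (z-scoring with population standard
# deviations) is provided for the classifier stages.

base_feature_names <- function() {
  c("zcr", "energy", "energy_entropy", "spectral_centroid",
    "spectral_spread", "spectral_entropy", "spectral_flux",
    "spectral_rolloff", paste0("mfcc_", 1:13), paste0("chroma_", 1:12),
    "chroma_std")
}

#' Acoustic feature names in their fixed order
#'
#' 34 base short-term features (zero-crossing rate, energy, energy
#' entropy, spectral centroid/spread/entropy/flux/roll-off, 13 MFCCs,
#' 12 chroma energies plus their standard deviation) optionally followed
#' by their first-order delta counterparts (`delta_*`), 68 names in all.
#' Downstream feature-selection masks reference these names, never
#' positional indices.
#'
#' @param include_deltas Include the 34 `delta_*` names (default `TRUE`).
#' @return Character vector of length 34 or 68.
#' @export
acoustic_feature_names <- function(include_deltas = TRUE) {
  base <- base_feature_names()
  if (include_deltas) c(base, paste0("delta_", base)) else base
}

dct2_matrix <- function(m) {
  k <- 0:(m - 1L)
  d <- sqrt(2 / m) * cos(pi * outer(k, (0:(m - 1L)) + 0.5) / m)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Short-term acoustic features per frame
#'
#' Frames the segment (50 ms window, 25 ms hop by default) and computes the
#' 34 base features per frame:
#' zero-crossing rate (sign changes / (L-1)); energy (mean square); energy
#' entropy (Shannon entropy over 10 sub-block energy fractions); spectral
#' centroid and spread (mean and standard deviation of normalized
#' frequency under the magnitude spectrum); spectral entropy (entropy of
#' the normalized power spectrum); spectral flux (squared difference of
#' successive L2-normalized magnitude spectra, 0 at the first frame);
#' spectral roll-off (smallest normalized frequency holding 90% of the
#' spectral energy); 13 MFCCs (40-filter mel bank on the frame power
#' spectrum, log with a 1e-10 floor, DCT-II, coefficients 1-13 excluding
#' the DC term); 12 chroma energy fractions (power folded onto semitone
#' pitch classes, A440 reference) and their population standard deviation.
#'
#' @param segment An [audio_segment()] holding at least one frame.
#' @param frame_length,hop Frame and hop in samples; defaults are 50 ms
#'   and 25 ms at the segment's sample rate.
#' @return A `"feature_frames"` object: `values` (frames x 34 matrix with
#'   column names) plus the framing used.
#' @export
short_term_features <- function(segment, frame_length = NULL, hop = NULL) {
  stopifnot(inherits(segment, "audio_segment"))
  sr <- segment$sample_rate
  frame_length <- as.integer(frame_length %||% round(0.05 * sr))
  hop <- as.integer(hop %||% round(0.025 * sr))
  if (frame_length < 2L) {
    stop_foldear("frame_length must be at least 2 samples",
                 "foldear_bad_frame")
  }
  fs <- frame_signal(segment, frame_length, hop)
  frames <- fs$frames
  if (nrow(frames) == 0L) {
    stop_foldear("segment shorter than one frame", "foldear_short_signal")
  }
  L <- frame_length
  nt <- nrow(frames)

  zcr <- rowSums(frames[, -L, drop = FALSE] * frames[, -1L, drop = FALSE]
                 < 0) / (L - 1L)
  energy <- rowMeans(frames^2)

  # energy entropy over 10 equal sub-blocks (remainder samples dropped)
  bl <- L %/% 10L
  sub_idx <- rep(1:10, each = bl)
  sq <- frames[, seq_len(10L * bl), drop = FALSE]^2
  sub_e <- sq %*% outer(sub_idx, 1:10, `==`)
  tot_e <- rowSums(sub_e)
  frac <- sub_e / ifelse(tot_e > 0, tot_e, 1)
  energy_entropy <- apply(frac, 1, entropy_bits)
  energy_entropy[tot_e == 0] <- 0

  nb <- L %/% 2L + 1L
  S <- abs(stats::mvfft(t(frames)))[seq_len(nb), , drop = FALSE]  # nb x nt
  P <- S^2
  fn <- (0:(nb - 1L)) / (nb - 1L)
  sumS <- colSums(S)
  safeS <- ifelse(sumS > 0, sumS, 1)
  centroid <- colSums(fn * S) / safeS
  spread <- sqrt(colSums((fn - rep(centroid, each = nb))^2 * S) / safeS)
  centroid[sumS == 0] <- 0
  spread[sumS == 0] <- 0

  sumP <- colSums(P)
  prob <- P / rep(ifelse(sumP > 0, sumP, 1), each = nb)
  spectral_entropy <- apply(prob, 2, entropy_bits)
  spectral_entropy[sumP == 0] <- 0

  norms <- sqrt(colSums(S^2))
  Sn <- S / rep(ifelse(norms > 0, norms, 1), each = nb)
  flux <- c(0, colSums((Sn[, -1L, drop = FALSE] -
                        Sn[, -nt, drop = FALSE])^2))
  if (nt == 1L) flux <- 0

  rolloff <- vapply(seq_len(nt), function(t) {
    if (sumP[t] <= 0) return(0)
    cs <- cumsum(P[, t])
    (which(cs >= 0.9 * sumP[t])[1] - 1L) / (nb - 1L)
  }, numeric(1))

  fb <- mel_filterbank(40L, L, sr, 0, sr / 2)
  log_fe <- log(pmax(fb %*% P, 1e-10))
  dct <- dct2_matrix(40L)
  mfcc <- t(dct[2:14, , drop = FALSE] %*% log_fe)      # nt x 13

  f_hz <- (0:(nb - 1L)) * sr / L
  audible <- f_hz > 0
  pc <- (round(12 * log2(f_hz[audible] / 440)) %% 12) + 1L
  fold <- outer(pc, 1:12, `==`)
  chroma_e <- t(P[audible, , drop = FALSE]) %*% fold   # nt x 12
  chroma_tot <- rowSums(chroma_e)
  chroma <- chroma_e / ifelse(chroma_tot > 0, chroma_tot, 1)
  chroma_std <- apply(chroma, 1, function(v) sqrt(mean((v - mean(v))^2)))

  values <- cbind(zcr, energy, energy_entropy, centroid, spread,
                  spectral_entropy, flux, rolloff, mfcc, chroma, chroma_std)
  colnames(values) <- base_feature_names()
  structure(list(values = values, frame_length = frame_length, hop = hop),
            class = "feature_frames")
}

#' 68-dimensional acoustic feature vector of a segment
#'
#' Computes the per-frame base features, their first-order deltas
#' (`delta_t = f_t - f_(t-1)`, zero at the first frame) and averages both
#' blocks over frames, giving a named vector of length 68 in the order of
#' [acoustic_feature_names()].
#'
#' @inheritParams short_term_features
#' @return Named numeric vector of length 68.
#' @export
segment_features <- function(segment, frame_length = NULL, hop = NULL) {
  stf <- short_term_features(segment, frame_length, hop)
  base <- stf$values
  delta <- rbind(0, diff(base))
  v <- c(colMeans(base), colMeans(delta))
  names(v) <- acoustic_feature_names()
  v
}

#' Acoustic feature matrix of a corpus
#'
#' @param segments List of [audio_segment()]s.
#' @inheritParams short_term_features
#' @return `n x 68` matrix, one row per segment, with feature column names
#'   and row names taken from the segments' `source_id`s.
#' @export
acoustic_feature_matrix <- function(segments, frame_length = NULL,
                                    hop = NULL) {
  X <- t(vapply(segments, segment_features, numeric(68),
                frame_length = frame_length, hop = hop))
  rownames(X) <- vapply(seq_along(segments), function(i) {
    segments[[i]]$source_id %||% sprintf("segment_%03d", i)
  }, character(1))
  X
}

#' Train-fitted feature standardization
#'
#' `fit_standardizer()` learns column means and population standard
#' deviations (divisor `n`) from training rows only; zero-variance columns
#' get scale 1, so they map to all zeros. `apply_standardizer()` applies a
#' fitted standardizer to any matrix with the same columns.
#'
#' @param X Numeric matrix with at least 2 rows.
#' @return `fit_standardizer`: an object of class `"standardizer"`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    stop_foldear("need at least 2 rows to fit a standardizer",
                 "foldear_bad_standardizer")
  }
  means <- colMeans(X)
  scales <- sqrt(colMeans(sweep(X, 2, means)^2))
  scales[scales == 0] <- 1
  structure(list(means = means, scales = scales, fitted = TRUE),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param S A fitted `"standardizer"`.
#' @export
apply_standardizer <- function(S, X) {
  if (!inherits(S, "standardizer") || !isTRUE(S$fitted)) {
    stop_foldear("standardizer has not been fitted", "foldear_unfitted")
  }
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(S$means))
  sweep(sweep(X, 2, S$means), 2, S$scales, `/`)
}
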