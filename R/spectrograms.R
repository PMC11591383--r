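# Time-frequency transforms: short-time Fourier, constant-Q and mel
# spectrograms. The STFT and mel transforms ride on stats::mvfft; the
# constant-Q transform is evaluated directly from its definition
# (windowed complex kernels per geometrically spaced bin) through a cached
# kernel matrix, which is exact and fast enough for 1-3 s segments.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Spectrogram transform configurations
#'
#' `stft_config()` holds the short-time Fourier analysis parameters
#' (window length `n`, default 2048 samples; hop, default `n/4`).
#' `cqt_config()` holds the constant-Q parameters: total bin count
#' (default 200), bins per octave (default 32, hence a 6.25-octave span),
#' lowest bin frequency (default 22.05 Hz) and the quality factor
#' `q = 1/(2^(1/bins_per_octave) - 1)` unless overridden.
#' `mel_config()` holds the mel-spectrogram parameters (128 triangular
#' filters over the full band by default).
#'
#' @param n STFT window length in samples (>= 2).
#' @param hop Hop between frames in samples (>= 1).
#' @param window Window identifier; only `"hann"` is provided.
#' @return A config list of the corresponding class.
#' @export
stft_config <- function(n = 2048L, hop = NULL, window = "hann") {
  stopifnot(is_count(n), n >= 2)
  hop <- as.integer(hop %||% (n %/% 4L))
  stopifnot(is_count(hop))
  structure(list(n = as.integer(n), hop = hop, window = window),
            class = "stft_config")
}

#' @rdname stft_config
#' @param n_bins Total constant-Q bin count.
#' @param bins_per_octave Bins per octave.
#' @param f_min Lowest bin center frequency (Hz).
#' @param q Quality factor override; `NULL` uses the constant-Q value.
#' @export
cqt_config <- function(n_bins = 200L, bins_per_octave = 32L, f_min = 22.05,
                       hop = 512L, q = NULL, window = "hann") {
  stopifnot(is_count(n_bins), is_count(bins_per_octave), f_min > 0,
            is_count(hop))
  q <- q %||% (1 / (2^(1 / bins_per_octave) - 1))
  structure(list(n_bins = as.integer(n_bins),
                 bins_per_octave = as.integer(bins_per_octave),
                 f_min = f_min, q = q, hop = as.integer(hop),
                 window = window),
            class = "cqt_config")
}

#' @rdname stft_config
#' @param n_mels Number of mel filters.
#' @param f_mel_min,f_mel_max Filterbank frequency range in Hz; `f_mel_max
#'   = NULL` uses the Nyquist frequency of the analyzed segment.
#' @export
mel_config <- function(n_mels = 128L, n = 2048L, hop = NULL,
                       f_mel_min = 0, f_mel_max = NULL, window = "hann") {
  stopifnot(is_count(n_mels))
  base <- stft_config(n = n, hop = hop, window = window)
  structure(c(base, list(n_mels = as.integer(n_mels), f_mel_min = f_mel_min,
                         f_mel_max = f_mel_max)),
            class = "mel_config")
}

#' Octave span of a constant-Q configuration
#'
#' `n_bins / bins_per_octave`; 6.25 octaves at the defaults.
#'
#' @param config A [cqt_config()].
#' @return Octave span (numeric scalar).
#' @export
cqt_octave_span <- function(config = cqt_config()) {
  config$n_bins / config$bins_per_octave
}

#' Center frequencies of constant-Q bins
#'
#' `f_k = f_min * 2^(k / bins_per_octave)` for `k = 0 .. n_bins - 1`.
#'
#' @param config A [cqt_config()].
#' @return Numeric vector of length `n_bins`, strictly increasing.
#' @export
cqt_bin_frequencies <- function(config = cqt_config()) {
  config$f_min * 2^((seq_len(config$n_bins) - 1L) / config$bins_per_octave)
}

new_spectrogram <- function(values, bin_frequencies, frame_times, kind) {
  structure(list(values = values, bin_frequencies = bin_frequencies,
                 frame_times = frame_times, kind = kind),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram:%s> %d bins x %d frames, %.1f-%.1f Hz\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$bin_frequencies), max(x$bin_frequencies)))
  invisible(x)
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed frames of length `n` every `hop` samples; one-sided
#' magnitude spectrum, so the result has `n/2 + 1` frequency rows. Column
#' `t` is computed from the frame starting at sample `(t-1) * hop`.
#'
#' @param segment An [audio_segment()] at least `config$n` samples long.
#' @param config An [stft_config()].
#' @return A `"spectrogram"`: `values` (bins x frames, non-negative),
#'   `bin_frequencies` (Hz), `frame_times` (s, frame starts), `kind`.
#' @export
stft <- function(segment, config = stft_config()) {
  stopifnot(inherits(segment, "audio_segment"))
  n <- config$n
  if (length(segment$samples) < n) {
    stop_foldear(sprintf(
      "signal (%d samples) shorter than the STFT window (%d); zero-pad upstream",
      length(segment$samples), n), "foldear_short_signal")
  }
  fs <- frame_signal(segment, n, config$hop)
  w <- hann_window(n)
  windowed <- t(fs$frames) * w                     # n x frames
  spec <- stats::mvfft(windowed)
  nb <- n %/% 2L + 1L
  mag <- abs(spec[seq_len(nb), , drop = FALSE])
  new_spectrogram(mag,
                  bin_frequencies = (0:(nb - 1L)) * segment$sample_rate / n,
                  frame_times = fs$origin_offsets / segment$sample_rate,
                  kind = "stft")
}

# Per-bin complex kernels (full length N_k = ceil(sr * Q / f_k)), cached per
# (sample rate, config). Memory is bounded by sum_k N_k ~ sr * Q / f_min * 2.1.
cqt_kernel_cache <- new.env(parent = emptyenv())

cqt_kernels <- function(config, sample_rate) {
  key <- paste(sample_rate, config$n_bins, config$bins_per_octave,
               config$f_min, config$q, config$window, sep = "|")
  if (!is.null(cqt_kernel_cache[[key]])) return(cqt_kernel_cache[[key]])
  fk <- cqt_bin_frequencies(config)
  kernels <- lapply(seq_along(fk), function(k) {
    nk <- ceiling(sample_rate * config$q / fk[k])
    n <- 0:(nk - 1L)
    hann_window(nk) * exp(-2i * pi * config$q * n / nk)
  })
  out <- list(kernels = kernels,
              nk = vapply(kernels, length, integer(1)), fk = fk)
  cqt_kernel_cache[[key]] <- out
  out
}

#' Constant-Q magnitude spectrogram
#'
#' Direct evaluation of the constant-Q definition: bin `k` at frame `t` is
#' `(1/N_k) |sum_n x(n + t*hop) w_{N_k}(n) exp(-i 2 pi Q n / N_k)|` with
#' `N_k = ceil(sample_rate * Q / f_k)` and Hann kernel windows. Kernels
#' longer than the segment are truncated to the available signal (keeping
#' their original window shape) and renormalized by the actual kernel
#' length; the signal is zero-padded past its end so every frame is
#' defined. Frames start every `hop` samples while inside the signal.
#'
#' @param segment An [audio_segment()].
#' @param config A [cqt_config()]; the highest bin must respect the
#'   Nyquist frequency.
#' @return A `"spectrogram"` with `n_bins` rows.
#' @export
cqt <- function(segment, config = cqt_config()) {
  stopifnot(inherits(segment, "audio_segment"))
  sr <- segment$sample_rate
  fk <- cqt_bin_frequencies(config)
  over <- which(fk > sr / 2)
  if (length(over)) {
    stop_foldear(sprintf(
      "CQT bin %d (%.2f Hz) exceeds the Nyquist frequency %.2f Hz",
      over[1], fk[over[1]], sr / 2), "foldear_nyquist")
  }
  ker <- cqt_kernels(config, sr)
  x <- segment$samples
  len <- length(x)
  nk_eff <- pmin(ker$nk, len)
  L <- max(nk_eff)
  n_frames <- len %/% config$hop
  if (n_frames < 1L) n_frames <- 1L
  starts <- (seq_len(n_frames) - 1L) * config$hop
  xpad <- c(x, numeric(L))
  frames <- matrix(xpad[outer(starts, seq_len(L), `+`)], nrow = n_frames)
  K <- config$n_bins
  kre <- matrix(0, L, K)
  kim <- matrix(0, L, K)
  for (k in seq_len(K)) {
    kk <- ker$kernels[[k]][seq_len(nk_eff[k])]
    kre[seq_len(nk_eff[k]), k] <- Re(kk)
    kim[seq_len(nk_eff[k]), k] <- Im(kk)
  }
  re <- frames %*% kre
  im <- frames %*% kim
  mag <- t(sqrt(re^2 + im^2)) / nk_eff                  # K x frames
  new_spectrogram(mag, bin_frequencies = fk,
                  frame_times = starts / sr, kind = "cqt")
}

#' Hertz to mel conversion
#'
#' `mel(f) = 2595 * log10(1 + f / 700)`.
#'
#' @param f Frequency in Hz (>= 0), vectorized.
#' @return Mel value(s).
#' @export
mel_scale <- function(f) {
  if (any(f < 0)) stop_foldear("negative frequency", "foldear_bad_frequency")
  2595 * log10(1 + f / 700)
}

mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' `n_filters` unit-peak triangular filters with centers uniformly spaced
#' in mel units between `mel_scale(f_min)` and `mel_scale(f_max)`, sampled
#' at the one-sided FFT bin frequencies of an `n_fft`-point transform.
#'
#' @param n_filters Number of filters.
#' @param n_fft FFT length whose one-sided bins are weighted.
#' @param sample_rate Sample rate in Hz.
#' @param f_min,f_max Filterbank range in Hz.
#' @return Matrix `n_filters x (n_fft/2 + 1)` of non-negative weights.
#' @export
mel_filterbank <- function(n_filters, n_fft, sample_rate, f_min = 0,
                           f_max = sample_rate / 2) {
  stopifnot(f_min < f_max, f_max <= sample_rate / 2)
  nb <- n_fft %/% 2L + 1L
  f_bins <- (0:(nb - 1L)) * sample_rate / n_fft
  edges <- mel_to_hz(seq(mel_scale(f_min), mel_scale(f_max),
                         length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, nb)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; mid <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (f_bins - lo) / max(mid - lo, .Machine$double.eps)
    down <- (hi - f_bins) / max(hi - mid, .Machine$double.eps)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel magnitude spectrogram
#'
#' STFT magnitude pooled through the triangular mel filterbank:
#' `values = filterbank %*% stft_magnitude`.
#'
#' @param segment An [audio_segment()] at least `config$n` samples long.
#' @param config A [mel_config()].
#' @return A `"spectrogram"` with `n_mels` rows; `bin_frequencies` are the
#'   filter center frequencies.
#' @export
mel_spectrogram <- function(segment, config = mel_config()) {
  f_max <- config$f_mel_max %||% (segment$sample_rate / 2)
  base <- stft(segment, stft_config(config$n, config$hop, config$window))
  fb <- mel_filterbank(config$n_mels, config$n, segment$sample_rate,
                       config$f_mel_min, f_max)
  edges <- mel_to_hz(seq(mel_scale(config$f_mel_min), mel_scale(f_max),
                         length.out = config$n_mels + 2L))
  new_spectrogram(fb %*% base$values,
                  bin_frequencies = edges[2:(config$n_mels + 1L)],
                  frame_times = base$frame_times, kind = "mel")
}
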