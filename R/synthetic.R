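# Synthetic sheepfold audio. The generator emulates the spectro-temporal
# structure the classifier relies on: foraging as a fast regular train of
# broadband chewing transients, rumination as a slower train of longer
# lower-band bursts, and an "other" class mixing harmonic bleats,
# broadband coughs, soft panting and ambient-noise-only clips, all over a
# pink (1/f) barn background at a controllable signal-to-noise ratio.
# Everything is seeded and deterministic, file by file.

#' Event model of one behavior class
#'
#' Foraging: band-passed noise bursts at 3-4 events/s, 40-80 ms,
#' 1-6 kHz. Rumination: 1-1.5 events/s, 80-150 ms, 0.4-3 kHz. Other: a
#' mixture of bleat (harmonic stack, f0 200-500 Hz, 5 harmonics, slow
#' vibrato), cough (one loud broadband burst), pant (~2 events/s soft
#' broadband bursts) and noise-only clips with weights 0.4/0.2/0.2/0.2.
#'
#' @param class `"foraging"`, `"rumination"` or `"other"`.
#' @param rate Optional fixed event rate (events/s) overriding the
#'   class's sampled range.
#' @return An object of class `"event_model"`.
#' @export
event_model <- function(class = behavior_classes(), rate = NULL) {
  class <- match.arg(class)
  m <- switch(class,
    foraging = list(rate_range = c(3, 4), dur_range = c(0.040, 0.080),
                    band = c(1000, 6000)),
    rumination = list(rate_range = c(1, 1.5), dur_range = c(0.080, 0.150),
                      band = c(400, 3000)),
    other = list(mixture = c(bleat = 0.4, cough = 0.2, pant = 0.2,
                             noise = 0.2),
                 f0_range = c(200, 500), n_harmonics = 5L,
                 pant_rate = 2, pant_dur = c(0.030, 0.060),
                 cough_dur = c(0.100, 0.200)))
  m$class <- class
  if (!is.null(rate)) m$rate_range <- c(rate, rate)
  structure(m, class = "event_model")
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  k_fold <- pmin(k, n - k)          # symmetric bin distances
  scale <- 1 / sqrt(pmax(k_fold, 1))
  Re(stats::fft(W * scale, inverse = TRUE) / n)
}

# Band-limited noise burst with a Hann envelope (FFT-domain band mask).
noise_burst <- function(n, sample_rate, band) {
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) / n * sample_rate
  f_fold <- pmin(f, sample_rate - f)
  W[f_fold < band[1] | f_fold > band[2]] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  x * hann_window(n)
}

# Jittered periodic burst train; returns the summed event track.
burst_train <- function(n, sample_rate, rate, dur_range, band, amp_range) {
  x <- numeric(n)
  period <- sample_rate / rate
  n_events <- floor(n / period)
  for (i in seq_len(n_events)) {
    center <- (i - 0.5) * period + runif(1, -0.2, 0.2) * period
    nd <- round(runif(1, dur_range[1], dur_range[2]) * sample_rate)
    start <- max(1L, round(center - nd / 2))
    stop_at <- min(n, start + nd - 1L)
    if (stop_at <= start) next
    burst <- noise_burst(stop_at - start + 1L, sample_rate, band)
    x[start:stop_at] <- x[start:stop_at] +
      runif(1, amp_range[1], amp_range[2]) * burst
  }
  x
}

bleat_event <- function(n, sample_rate, f0_range, n_harmonics) {
  dur <- runif(1, 0.5, min(1, n / sample_rate))
  nd <- round(dur * sample_rate)
  start <- if (nd < n) sample.int(n - nd, 1L) else 1L
  f0 <- runif(1, f0_range[1], f0_range[2])
  vib_rate <- runif(1, 3, 5)
  t <- (seq_len(nd) - 1L) / sample_rate
  f_inst <- f0 * (1 + 0.02 * sin(2 * pi * vib_rate * t))
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  tone <- numeric(nd)
  for (h in seq_len(n_harmonics)) tone <- tone + sin(h * phase) / h
  x <- numeric(n)
  x[start:(start + nd - 1L)] <- tone * hann_window(nd)
  x / max(abs(x))
}

other_event_track <- function(n, sample_rate, model) {
  kind <- sample(names(model$mixture), 1L, prob = model$mixture)
  nyq_band <- function(b) c(b[1], min(b[2], sample_rate / 2 * 0.95))
  switch(kind,
    bleat = bleat_event(n, sample_rate, model$f0_range, model$n_harmonics),
    cough = {
      nd <- round(runif(1, model$cough_dur[1], model$cough_dur[2]) *
                    sample_rate)
      start <- sample.int(max(1L, n - nd), 1L)
      x <- numeric(n)
      stop_at <- min(n, start + nd - 1L)
      x[start:stop_at] <- noise_burst(stop_at - start + 1L, sample_rate,
                                      nyq_band(c(200, 7000)))
      x
    },
    pant = burst_train(n, sample_rate, model$pant_rate, model$pant_dur,
                       nyq_band(c(500, 4000)), c(0.2, 0.4)),
    noise = numeric(n))
}

#' Generate one synthetic behavior segment
#'
#' Deterministic given the seed. Events are placed by a jittered periodic
#' process at the class event rate; the background is pink noise scaled
#' `snr_db` decibels below the event RMS; the sum is peak-normalized to
#' 0.9.
#'
#' @param model An [event_model()] or a class name.
#' @param duration Segment length in seconds (>= 0.5).
#' @param sample_rate Hz; the class band must respect Nyquist.
#' @param snr_db Event-to-background ratio in dB.
#' @param seed Seed; the same seed gives bit-identical samples.
#' @param return_components Attach the pre-normalization event and
#'   background tracks as attribute `"components"` (for diagnostics).
#' @return A labelled [audio_segment()].
#' @export
generate_segment <- function(model, duration, sample_rate = 48000,
                             snr_db = 10, seed = 1L,
                             return_components = FALSE) {
  if (is.character(model)) model <- event_model(model)
  stopifnot(inherits(model, "event_model"))
  if (duration < 0.5) {
    stop_foldear("duration must be at least 0.5 s", "foldear_bad_duration")
  }
  if (!is.null(model$band) && model$band[2] > sample_rate / 2) {
    stop_foldear(sprintf("event band [%g, %g] Hz exceeds Nyquist %g Hz",
                         model$band[1], model$band[2], sample_rate / 2),
                 "foldear_nyquist")
  }
  n <- round(duration * sample_rate)
  with_seed(seed, {
    events <- if (model$class %in% c("foraging", "rumination")) {
      rate <- runif(1, model$rate_range[1], model$rate_range[2])
      burst_train(n, sample_rate, rate, model$dur_range, model$band,
                  c(0.7, 1))
    } else {
      other_event_track(n, sample_rate, model)
    }
    bg <- pink_noise(n)
    ev_rms <- sqrt(mean(events^2))
    bg_rms <- sqrt(mean(bg^2))
    gain <- if (ev_rms > 0) ev_rms * 10^(-snr_db / 20) / bg_rms else
      0.05 / bg_rms
    bg <- bg * gain
    x <- events + bg
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak * 0.9
    seg <- audio_segment(x, sample_rate, label = model$class)
    if (return_components) {
      attr(seg, "components") <- list(events = events, background = bg)
    }
    seg
  })
}

#' Corpus generation settings
#'
#' @param n_per_class Segments per class.
#' @param duration_range Segment length range in seconds.
#' @param sample_rate Hz.
#' @param snr_db Event-to-background SNR in dB.
#' @param seed Master seed; per-file seeds are derived from it.
#' @return A list of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_per_class = 60L, duration_range = c(1, 3),
                        sample_rate = 48000, snr_db = 10, seed = 7L) {
  stopifnot(is_count(n_per_class), length(duration_range) == 2L,
            duration_range[1] >= 0.5, is.finite(snr_db))
  structure(list(n_per_class = as.integer(n_per_class),
                 duration_range = duration_range,
                 sample_rate = sample_rate, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

corpus_file_plan <- function(spec) {
  plan <- expand.grid(i = seq_len(spec$n_per_class),
                      class = behavior_classes(),
                      stringsAsFactors = FALSE)[, c("class", "i")]
  plan <- plan[order(plan$class, plan$i), ]
  plan$path <- sprintf("%s_%03d.wav", plan$class, plan$i)
  plan$seed <- vapply(seq_len(nrow(plan)), function(r) {
    child_seed(spec$seed,
               match(plan$class[r], behavior_classes()) * 100000L + plan$i[r])
  }, integer(1))
  plan
}

generate_plan_segment <- function(spec, class, file_seed, source_id) {
  duration <- with_seed(file_seed,
                        runif(1, spec$duration_range[1],
                              spec$duration_range[2]))
  seg <- generate_segment(class, duration, spec$sample_rate, spec$snr_db,
                          seed = child_seed(file_seed, 1))
  seg$source_id <- source_id
  seg
}

#' Generate a labelled synthetic corpus on disk
#'
#' Writes `n_per_class` 16-bit WAV files per class plus `labels.csv` and a
#' `spec.json` provenance file. Per-file seeds derive from the master
#' seed, so any file is reproducible in isolation and two runs of the
#' same spec produce byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [corpus_spec()].
#' @return `out_dir`, invisibly.
#' @export
generate_corpus <- function(out_dir, spec = corpus_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- corpus_file_plan(spec)
  for (r in seq_len(nrow(plan))) {
    seg <- generate_plan_segment(spec, plan$class[r], plan$seed[r],
                                 plan$path[r])
    write_wav(seg, file.path(out_dir, plan$path[r]))
  }
  write_label_table(data.frame(path = plan$path, label = plan$class),
                    file.path(out_dir, "labels.csv"))
  writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "spec.json"))
  invisible(out_dir)
}

#' Generate the corpus in memory
#'
#' Same segments as [generate_corpus()] (including the 16-bit PCM
#' quantization a disk round-trip applies), without touching the
#' filesystem.
#'
#' @param spec A [corpus_spec()].
#' @return List of labelled [audio_segment()]s in label-table order.
#' @export
generate_corpus_segments <- function(spec = corpus_spec()) {
  plan <- corpus_file_plan(spec)
  lapply(seq_len(nrow(plan)), function(r) {
    seg <- generate_plan_segment(spec, plan$class[r], plan$seed[r],
                                 plan$path[r])
    seg$samples <- pmin(32767, round(pmin(1, pmax(-1, seg$samples)) *
                                       32768)) / 32768
    seg
  })
}
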