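# WAV input/output, framing and energy-based segmentation.
#
# The recorder hardware writes mono RIFF WAV files; annotation cuts long
# recordings into short behavior segments using an energy threshold and a
# minimum duration. Both steps are reproduced here. No R audio package is
# required: the RIFF container (PCM 16-bit and IEEE float 32-bit) is parsed
# directly.

#' Construct an audio segment
#'
#' The basic unit handled by the pipeline: a mono, finite, `[-1, 1]`-valued
#' sample sequence with its sample rate and an optional behavior label.
#'
#' @param samples Numeric vector of amplitudes (dimensionless, nominally in
#'   `[-1, 1]`).
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param label Optional behavior tag, one of `"foraging"`, `"rumination"`,
#'   `"other"`.
#' @param source_id Optional provenance string (e.g. the source file name).
#' @return An object of class `"audio_segment"`.
#' @export
audio_segment <- function(samples, sample_rate, label = NULL,
                          source_id = NULL) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_foldear("sample_rate must be a positive finite scalar",
                 "foldear_bad_segment")
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop_foldear("audio segment has zero samples", "foldear_empty_audio")
  }
  if (!all(is.finite(samples))) {
    stop_foldear("audio samples must all be finite", "foldear_bad_segment")
  }
  if (!is.null(label)) {
    label <- match.arg(label, behavior_classes())
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 label = label, source_id = source_id),
            class = "audio_segment")
}

#' Behavior class labels in their fixed order
#'
#' The class order used everywhere in the package (alphabetical):
#' foraging, other, rumination.
#'
#' @return Character vector of length 3.
#' @export
behavior_classes <- function() c("foraging", "other", "rumination")

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %g Hz (%.3f s)%s%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a WAV file as a mono audio segment
#'
#' Parses the RIFF container directly. PCM 8/16/24/32-bit integer and IEEE
#' 32/64-bit float payloads are supported; multi-channel audio is averaged
#' to mono; integer samples are scaled to `[-1, 1]` by the full-scale value
#' of the encoding (e.g. 32768 for 16-bit). No resampling is performed.
#'
#' @param path Path to a WAV file.
#' @param label,source_id Optional label and provenance attached to the
#'   result; `source_id` defaults to the file name.
#' @return An [audio_segment()].
#' @export
read_wav <- function(path, label = NULL, source_id = NULL) {
  if (!file.exists(path)) {
    stop_foldear(paste0("no such file: ", path), "foldear_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_foldear(paste0("not a RIFF/WAVE file: ", path), "foldear_not_wav")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    hd <- read_chunk_header(con)
    if (is.null(hd)) break
    if (identical(hd$id, "fmt ")) {
      body <- readBin(con, raw(), n = hd$size)
      fmt <- list(
        format = readBin(body[1:2], integer(), size = 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(body[3:4], integer(), size = 2L, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(body[5:8], integer(), size = 4L,
                              endian = "little"),
        bits = readBin(body[15:16], integer(), size = 2L, signed = FALSE,
                       endian = "little"))
    } else if (identical(hd$id, "data")) {
      data_raw <- readBin(con, raw(), n = hd$size)
    } else {
      readBin(con, raw(), n = hd$size + (hd$size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_foldear(paste0("missing fmt/data chunk in ", path), "foldear_not_wav")
  }
  if (length(data_raw) == 0L) {
    stop_foldear(paste0("zero-length audio in ", path), "foldear_empty_audio")
  }
  x <- decode_wav_payload(data_raw, fmt)
  if (fmt$channels > 1L) {
    x <- matrix(x, nrow = fmt$channels)
    x <- colMeans(x)
  }
  audio_segment(x, fmt$sample_rate, label = label,
                source_id = source_id %||% basename(path))
}

decode_wav_payload <- function(data_raw, fmt) {
  if (fmt$format == 1L) {  # integer PCM
    if (fmt$bits == 16L) {
      readBin(data_raw, integer(), n = length(data_raw) %/% 2L, size = 2L,
              signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 8L) {
      (readBin(data_raw, integer(), n = length(data_raw), size = 1L,
               signed = FALSE) - 128) / 128
    } else if (fmt$bits == 24L) {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw), nrow = 3L)[, seq_len(n), drop = FALSE]
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(data_raw, integer(), n = length(data_raw) %/% 4L, size = 4L,
              endian = "little") / 2147483648
    } else {
      stop_foldear(sprintf("unsupported PCM bit depth %d", fmt$bits),
                   "foldear_not_wav")
    }
  } else if (fmt$format == 3L) {  # IEEE float
    size <- fmt$bits %/% 8L
    readBin(data_raw, numeric(), n = length(data_raw) %/% size, size = size,
            endian = "little")
  } else {
    stop_foldear(sprintf("unsupported WAV format code %d", fmt$format),
                 "foldear_not_wav")
  }
}

#' Write an audio segment to a WAV file
#'
#' @param segment An [audio_segment()] (or bare numeric vector, in which case
#'   `sample_rate` must be given).
#' @param path Output path.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @param sample_rate Required when `segment` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path, bit_depth = c("pcm16", "float32"),
                      sample_rate = NULL) {
  bit_depth <- match.arg(bit_depth)
  if (!inherits(segment, "audio_segment")) {
    segment <- audio_segment(segment, sample_rate)
  }
  x <- pmin(1, pmax(-1, segment$samples))
  sr <- as.integer(round(segment$sample_rate))
  if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    # symmetric 32768 scaling (clamped at +32767) so read/write round-trips
    # within half an LSB
    payload <- writeBin(as.integer(pmin(32767, round(x * 32768))), raw(),
                        size = 2L, endian = "little")
  } else {
    fmt_code <- 3L; bits <- 32L
    payload <- writeBin(segment$samples, raw(), size = 4L, endian = "little")
  }
  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4L,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(as.integer(sr * block_align), con, size = 4L, endian = "little")
  writeBin(block_align, con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4L, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' Slice a signal into fixed-length frames
#'
#' Frames are contiguous slices of length `frame_length` starting every `hop`
#' samples; the trailing partial frame is dropped (no padding), so
#' `num_frames = floor((n - frame_length) / hop) + 1` when the signal holds at
#' least one frame and 0 otherwise.
#'
#' @param segment An [audio_segment()].
#' @param frame_length,hop Frame length and hop in samples (both >= 1).
#' @return A list of class `"frame_set"` with `frames`
#'   (`num_frames x frame_length` matrix), `frame_length`, `hop`, and
#'   `origin_offsets` (0-based start sample of each frame).
#' @export
frame_signal <- function(segment, frame_length, hop) {
  stopifnot(inherits(segment, "audio_segment"),
            is_count(frame_length), is_count(hop))
  x <- segment$samples
  n <- length(x)
  if (n < frame_length) {
    return(structure(list(frames = matrix(numeric(0), nrow = 0,
                                          ncol = frame_length),
                          frame_length = frame_length, hop = hop,
                          origin_offsets = integer(0)),
                     class = "frame_set"))
  }
  num_frames <- (n - frame_length) %/% hop + 1L
  offsets <- (seq_len(num_frames) - 1L) * hop
  idx <- outer(offsets, seq_len(frame_length), `+`)
  frames <- matrix(x[idx], nrow = num_frames)
  structure(list(frames = frames, frame_length = as.integer(frame_length),
                 hop = as.integer(hop), origin_offsets = as.integer(offsets)),
            class = "frame_set")
}

#' Cut a recording into high-energy segments
#'
#' Reproduces the annotation-time segmentation: frames are scanned for
#' mean-square energy at or above `energy_threshold`; maximal runs of such
#' frames lasting at least `min_duration` seconds are cut back out of the
#' source as sample ranges (first frame start to last frame end).
#'
#' @param segment An [audio_segment()].
#' @param energy_threshold Mean-square amplitude threshold (> 0).
#' @param min_duration Minimum kept duration in seconds (> 0).
#' @param frame_length,hop Scan frame and hop in samples.
#' @return List of [audio_segment()]s (possibly empty), in temporal order.
#' @export
segment_by_energy <- function(segment, energy_threshold, min_duration,
                              frame_length = 2048L, hop = 512L) {
  stopifnot(inherits(segment, "audio_segment"),
            energy_threshold > 0, min_duration > 0)
  fs <- frame_signal(segment, frame_length, hop)
  if (nrow(fs$frames) == 0L) return(list())
  energy <- rowMeans(fs$frames^2)
  active <- energy >= energy_threshold
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    a <- fs$origin_offsets[starts[i]] + 1L
    b <- fs$origin_offsets[ends[i]] + frame_length
    b <- min(b, length(segment$samples))
    if ((b - a + 1L) / segment$sample_rate >= min_duration) {
      out[[length(out) + 1L]] <-
        audio_segment(segment$samples[a:b], segment$sample_rate,
                      label = segment$label,
                      source_id = sprintf("%s[%d:%d]",
                                          segment$source_id %||% "segment",
                                          a, b))
    }
  }
  out
}

#' Read / write a label table
#'
#' The label table is a headered CSV with columns `path` and `label`
#' (`label` in `foraging`, `rumination`, `other`).
#'
#' @param path CSV file path.
#' @return `read_label_table`: a data.frame with columns `path`, `label`.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(tab))) {
    stop_foldear("label table must have columns path,label",
                 "foldear_bad_labels")
  }
  bad <- setdiff(unique(tab$label), behavior_classes())
  if (length(bad)) {
    stop_foldear(paste0("unknown labels: ", paste(bad, collapse = ", ")),
                 "foldear_bad_labels")
  }
  tab[, c("path", "label")]
}

#' @rdname read_label_table
#' @param table Data.frame with columns `path`, `label`.
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(table[, c("path", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a directory of labelled WAV segments
#'
#' @param dir Directory containing WAV files and a label table.
#' @param labels Name of the label CSV inside `dir`.
#' @return List of labelled [audio_segment()]s in label-table order.
#' @export
read_corpus <- function(dir, labels = "labels.csv") {
  tab <- read_label_table(file.path(dir, labels))
  lapply(seq_len(nrow(tab)), function(i) {
    read_wav(file.path(dir, tab$path[i]), label = tab$label[i],
             source_id = tab$path[i])
  })
}
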