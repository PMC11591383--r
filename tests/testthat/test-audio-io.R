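# WAV round trips, framing arithmetic, and energy-based segmentation.

write_raw_wav <- function(path, ints, sr, channels = 1L) {
  payload <- writeBin(as.integer(ints), raw(), size = 2L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4L,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4L, endian = "little")
  writeBin(c(1L, channels), con, size = 2L, endian = "little")
  writeBin(as.integer(c(sr, sr * 2L * channels)), con, size = 4L,
           endian = "little")
  writeBin(c(2L * channels, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con)
  path
}

test_that("PCM16 write/read round-trips within one LSB", {
  seg <- make_sine(440, 48000, dur = 1)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(seg, p)
  back <- read_wav(p)
  expect_s3_class(back, "audio_segment")
  expect_equal(length(back$samples), 48000)
  expect_equal(back$sample_rate, 48000)
  expect_lt(max(abs(back$samples - seg$samples)), 1 / 32768)
})

test_that("float32 write/read is exact at float precision", {
  x <- runif(1000, -1, 1)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_segment(x, 16000), p, bit_depth = "float32")
  expect_equal(read_wav(p)$samples, x, tolerance = 1e-7)
})

test_that("stereo input with identical channels averages to either channel", {
  x <- as.integer(round(sin(2 * pi * 100 * (0:999) / 8000) * 20000))
  p <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(p, as.vector(rbind(x, x)), 8000, channels = 2L)
  seg <- read_wav(p)
  expect_equal(seg$samples, x / 32768, tolerance = 1e-12)
})

test_that("full-scale PCM16 square wave decodes by the 32768 scaling", {
  ints <- rep(c(-32768L, 32767L), 50)
  p <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(p, ints, 16000)
  seg <- read_wav(p)
  expect_equal(sort(unique(round(seg$samples, 6))),
               c(-1, 32767 / 32768), tolerance = 1e-4)
})

test_that("I/O failures raise distinct error classes", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")),
               class = "foldear_missing_file")
  p <- withr::local_tempfile(fileext = ".wav")
  writeBin(charToRaw("this is not audio at all, just text"), p)
  expect_error(read_wav(p), class = "foldear_not_wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_raw_wav(p2, integer(0), 8000)
  expect_error(read_wav(p2), class = "foldear_empty_audio")
})

test_that("frame counts follow floor((n - frame)/hop) + 1 with no padding", {
  seg <- audio_segment(rnorm(48000), 48000)
  expect_equal(nrow(frame_signal(seg, 2048, 512)$frames), 90)
  one <- frame_signal(audio_segment(seg$samples[1:2048], 48000), 2048, 512)
  expect_equal(nrow(one$frames), 1)
  expect_equal(as.vector(one$frames[1, ]), seg$samples[1:2048])
  short <- frame_signal(audio_segment(rnorm(100), 48000), 2048, 512)
  expect_equal(nrow(short$frames), 0)
})

test_that("frames are exact contiguous slices at the stated offsets", {
  set.seed(3)
  x <- rnorm(4000)
  fs <- frame_signal(audio_segment(x, 16000), 400, 160)
  for (i in seq_len(nrow(fs$frames))) {
    expect_identical(as.vector(fs$frames[i, ]),
                     x[(160 * (i - 1) + 1):(160 * (i - 1) + 400)])
  }
  expect_true(all(diff(fs$origin_offsets) == 160))
})

test_that("hop = frame_length re-tiles the prefix of the signal", {
  set.seed(4)
  x <- rnorm(5000)
  fs <- frame_signal(audio_segment(x, 8000), 512, 512)
  expect_identical(as.vector(t(fs$frames)), x[1:(512 * nrow(fs$frames))])
})

test_that("silence yields no segments and a loud tone yields one", {
  silent <- audio_segment(numeric(5 * 8000) + 0, 8000)
  expect_length(segment_by_energy(silent, 1e-6, 0.5, 1024, 256), 0)
  tone <- make_sine(200, 8000, dur = 4, amp = 0.9)
  segs <- segment_by_energy(tone, 0.1, 0.5, 1024, 256)
  expect_length(segs, 1)
  expect_gt(length(segs[[1]]$samples) / 8000, 3.8)
})

test_that("burst boundaries match a brute-force frame-energy scan", {
  set.seed(5)
  sr <- 8000
  x <- numeric(5 * sr)
  b1 <- sr + seq_len(sr)          # 1 s burst at t = 1
  b2 <- 3 * sr + seq_len(sr)      # 1 s burst at t = 3
  x[b1] <- rnorm(sr, sd = 0.3)
  x[b2] <- rnorm(sr, sd = 0.3)
  seg <- audio_segment(x, sr)
  frame <- 512L; hop <- 128L
  segs <- segment_by_energy(seg, 0.001, 0.5, frame, hop)
  expect_length(segs, 2)
  # oracle: scan frame energies directly
  n_frames <- (length(x) - frame) %/% hop + 1
  e <- vapply(seq_len(n_frames), function(i) {
    mean(x[((i - 1) * hop + 1):((i - 1) * hop + frame)]^2)
  }, numeric(1))
  runs <- rle(e >= 0.001)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  active <- which(runs$values)
  for (j in seq_along(active)) {
    a_expect <- (starts[active[j]] - 1) * hop + 1
    got <- as.integer(sub(".*\\[(\\d+):(\\d+)\\]", "\\1",
                          segs[[j]]$source_id))
    expect_lt(abs(got - a_expect), hop + 1)
  }
  # segments are disjoint, ordered, and no longer than the source
  expect_lt(sum(vapply(segs, function(s) length(s$samples), numeric(1))),
            length(x) + 1)
})

test_that("label tables round-trip and reject unknown labels", {
  tab <- data.frame(path = c("a.wav", "b.wav"),
                    label = c("foraging", "other"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_label_table(tab, p)
  expect_equal(read_label_table(p), tab)
  bad <- data.frame(path = "a.wav", label = "grazing")
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_label_table(p2), class = "foldear_bad_labels")
})
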