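# Rendering spectrograms as fixed-size 100 x 100 x 3 color images for the
# CNN: dB scaling, an 80 dB dynamic-range clip, min-max normalization, a
# fixed 256-entry color lookup table, and bilinear resizing with
# half-pixel-centered sampling. Every step is pinned so images are
# bit-reproducible across installs.

#' Fixed 256-entry color lookup table
#'
#' A perceptually ordered dark-to-bright ramp (black through purple, red
#' and orange to near-white), generated by piecewise-linear interpolation
#' of fixed RGB anchors so it is identical on every platform.
#'
#' @return A `256 x 3` matrix of RGB values in `[0, 1]`; row `i` is the
#'   color for normalized intensity `(i - 1)/255`.
#' @export
spectro_colormap <- function() {
  anchors_at <- c(0, 0.15, 0.35, 0.55, 0.75, 0.90, 1)
  anchors <- rbind(c(0.00, 0.00, 0.015),
                   c(0.22, 0.05, 0.30),
                   c(0.55, 0.10, 0.40),
                   c(0.85, 0.25, 0.25),
                   c(0.98, 0.55, 0.10),
                   c(1.00, 0.85, 0.25),
                   c(1.00, 1.00, 0.90))
  u <- (0:255) / 255
  lut <- vapply(1:3, function(ch) {
    stats::approx(anchors_at, anchors[, ch], xout = u)$y
  }, numeric(256))
  dimnames(lut) <- list(NULL, c("r", "g", "b"))
  lut
}

# Weight matrix mapping `n_in` samples to `n_out` by bilinear interpolation
# with half-pixel-centered coordinates (output center i - 0.5 maps to input
# coordinate (i - 0.5) * n_in / n_out, clamped to the valid range). Equals
# the identity when n_in == n_out.
bilinear_weights <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  lo <- pmin(floor(src), n_in - ifelse(n_in > 1L, 1L, 0L))
  lo <- pmax(lo, 1L)
  hi <- pmin(lo + 1L, n_in)
  w <- src - lo
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), lo)] <- 1 - w
  m[cbind(seq_len(n_out), hi)] <- m[cbind(seq_len(n_out), hi)] + w
  m
}

#' Bilinearly resize a matrix
#'
#' Half-pixel-centered separable bilinear interpolation; resizing to the
#' input size is the identity.
#'
#' @param m Numeric matrix.
#' @param out_rows,out_cols Output dimensions.
#' @return `out_rows x out_cols` matrix.
#' @export
bilinear_resize <- function(m, out_rows, out_cols) {
  wr <- bilinear_weights(nrow(m), out_rows)
  wc <- bilinear_weights(ncol(m), out_cols)
  wr %*% m %*% t(wc)
}

#' Render a spectrogram as a 100 x 100 x 3 image
#'
#' The CNN input representation: magnitudes go to dB
#' (`20 log10(v + 1e-10)`), are clipped to the top 80 dB, min-max
#' normalized to `[0, 1]`, mapped through [spectro_colormap()] and
#' bilinearly resized to 100 x 100 per channel. Rows are flipped so low
#' frequencies sit at the bottom of the image. A constant spectrogram
#' (max == min after dB) maps to the last lookup-table entry. Because of
#' the dB + min-max chain the image is invariant to positive gain applied
#' to the input audio.
#'
#' @param spec A `"spectrogram"`.
#' @param size Output side length in pixels (default 100).
#' @return A `"spectrogram_image"`: `size x size x 3` array in `[0, 1]`
#'   with attributes `kind` and `source_id`.
#' @export
render_image <- function(spec, size = 100L) {
  stopifnot(inherits(spec, "spectrogram"), length(spec$values) > 0)
  db <- 20 * log10(spec$values + 1e-10)
  mx <- max(db)
  db <- pmax(db, mx - 80)
  mn <- min(db)
  u <- if (mx > mn) (db - mn) / (mx - mn) else array(1, dim(db))
  idx <- matrix(as.integer(round(u * 255)) + 1L, nrow(db))
  lut <- spectro_colormap()
  flip <- rev(seq_len(nrow(idx)))
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    col_plane <- matrix(lut[idx, ch], nrow(idx))[flip, , drop = FALSE]
    img[, , ch] <- bilinear_resize(col_plane, size, size)
  }
  structure(img, class = "spectrogram_image", kind = spec$kind)
}

#' Compute the rendered CNN input image for one segment
#'
#' Convenience wrapper chaining the chosen transform ([stft()], [cqt()] or
#' [mel_spectrogram()]) and [render_image()].
#'
#' @param segment An [audio_segment()].
#' @param kind `"stft"`, `"cqt"` or `"mel"`.
#' @param config Optional transform config; defaults per transform.
#' @return A `"spectrogram_image"`.
#' @export
spectrogram_image <- function(segment, kind = c("stft", "cqt", "mel"),
                              config = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
                 stft = stft(segment, config %||% stft_config()),
                 cqt = cqt(segment, config %||% cqt_config()),
                 mel = mel_spectrogram(segment, config %||% mel_config()))
  img <- render_image(spec)
  attr(img, "source_id") <- segment$source_id
  img
}
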