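# Multi-scale color contrast: per-pixel squared differences against the
# 5 x 5 neighborhood in each RGB channel, computed on every level of a
# Gaussian pyramid and summed at base resolution. Salient structures of
# different sizes respond at different levels.

#' Color contrast map at a single scale
#'
#' For each pixel `P` and each RGB channel (values scaled to `[0, 1]`), sums
#' `(v(P) - v(q))^2` over the `contrast_neighborhood` window around `P`
#' (excluding `P` itself, whose term is zero anyway), with reflective
#' borders; the three channel maps are added.
#'
#' @param frame `height x width x 3` RGB array (0..255 or already in
#'   `[0, 1]` — values above 1 are assumed 8-bit and divided by 255).
#' @param params an [operator_params()].
#' @return matrix of non-negative contrast values.
#' @export
contrast_map_at_scale <- function(frame, params = operator_params()) {
  params <- as_operator_params(params)
  w <- params$contrast_neighborhood
  if (nrow(frame) < w || ncol(frame) < w)
    stop("frame smaller than the contrast neighborhood (", w, ")")
  r <- (w - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  scale <- if (max(frame) > 1) 255 else 1
  # direct shift-and-add of squared differences: exact zero on flat regions
  # (the algebraically equivalent n v^2 - 2 v S1 + S2 form leaves rounding
  # residue there)
  for (c in 1:3) {
    v <- frame[, , c] / scale
    p <- pad_reflect(v, r)
    for (dy in (-r):r) {
      for (dx in (-r):r) {
        if (dy == 0 && dx == 0) next
        q <- p[(r + 1 + dy):(r + nr + dy), (r + 1 + dx):(r + nc + dx)]
        out <- out + (v - q)^2
      }
    }
  }
  out
}

#' Multi-scale color contrast map
#'
#' Builds a Gaussian pyramid (binomial 5-tap smoothing, factor-2
#' downsampling; level 1 is the original frame), computes
#' [contrast_map_at_scale()] at every level, upsamples each level map back to
#' base resolution by bilinear interpolation, and sums them.
#'
#' @param frame `height x width x 3` RGB array (0..255).
#' @param params an [operator_params()]; `pyramid_levels` sets the number of
#'   levels.
#' @return a `SaliencyMap` (tag `"MSCM"`).
#' @export
multiscale_contrast <- function(frame, params = operator_params()) {
  params <- as_operator_params(params)
  w <- params$contrast_neighborhood
  nr <- nrow(frame); nc <- ncol(frame)
  min_dim <- min(nr, nc) / 2^(params$pyramid_levels - 1)
  if (min_dim < w)
    stop("parameter error: frame ", nr, "x", nc, " too small for ",
         params$pyramid_levels, " pyramid levels with a ", w, "x", w,
         " neighborhood")
  level <- frame
  total <- matrix(0, nr, nc)
  for (l in seq_len(params$pyramid_levels)) {
    cm <- contrast_map_at_scale(level, params)
    total <- total + bilinear_resize(cm, nr, nc)
    if (l < params$pyramid_levels) level <- pyramid_down(level)
  }
  saliency_map(total, "MSCM")
}

# One pyramid reduction: binomial [1 4 6 4 1]/16 smoothing per channel,
# then keep every other row/column (odd indices).
pyramid_down <- function(frame) {
  k <- c(1, 4, 6, 4, 1) / 16
  rows <- seq(1, nrow(frame), by = 2)
  cols <- seq(1, ncol(frame), by = 2)
  out <- array(0, c(length(rows), length(cols), 3))
  for (c in 1:3) {
    sm <- conv_sep1d(conv_sep1d(frame[, , c], k, "row"), k, "col")
    out[, , c] <- sm[rows, cols]
  }
  out
}
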