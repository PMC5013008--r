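# Texture saliency: entropy-directed segmentation of "injurious" (richly
# textured) tissue. High local gray-level entropy marks lesioned regions;
# the thresholded entropy image is cleaned by morphological closing and hole
# filling, and the frame-level score is the injurious area fraction.

#' Local histogram entropy map
#'
#' For every pixel, the gray values in its `entropy_window` neighborhood
#' (reflective borders) are binned into `gray_levels` equal-width bins over
#' `[0, 1]`, and the Shannon entropy `-sum p_k log2 p_k` of the bin
#' frequencies is computed (with `0 log 0 := 0`). The result is divided by
#' `log2(gray_levels)` so that values lie in `[0, 1]` and the segmentation
#' threshold `tau` is scale-free.
#'
#' @param gray grayscale matrix with values in `[0, 1]`.
#' @param params an [operator_params()].
#' @return matrix of normalized entropies in `[0, 1]`.
#' @export
local_entropy <- function(gray, params = operator_params()) {
  params <- as_operator_params(params)
  if (any(gray < 0) || any(gray > 1)) stop("gray values must lie in [0, 1]")
  w <- params$entropy_window
  g <- params$gray_levels
  r <- (w - 1L) %/% 2L
  nr <- nrow(gray); nc <- ncol(gray)
  bins <- pmin(floor(gray * g), g - 1L)  # integer bin 0..g-1
  p <- pad_reflect(bins, r)
  npix <- nr * nc
  counts <- matrix(0L, npix, g)
  idx <- seq_len(npix)
  for (dy in (-r):r) {
    for (dx in (-r):r) {
      b <- as.vector(p[(r + 1 + dy):(r + nr + dy),
                       (r + 1 + dx):(r + nc + dx)])
      ij <- cbind(idx, b + 1L)
      counts[ij] <- counts[ij] + 1L
    }
  }
  n <- w * w
  # H = log2(n) - (1/n) * sum c log2 c, exact for integer counts
  ent <- log2(n) - rowSums(xlog2x(counts)) / n
  ent <- pmax(ent, 0)  # clamp fp residue of the constant-window case
  matrix(ent / log2(g), nr, nc)
}

#' Texture saliency of a frame
#'
#' Pipeline: (1) normalized local entropy of the luminance image; (2) binary
#' mask `entropy >= tau`; (3) morphological closing with a disk of radius
#' `closing_radius`; (4) hole filling; (5) the texture-saliency map keeps the
#' luminance of masked (injurious) pixels and zeroes the rest. The scalar
#' `injurious_fraction` — masked area over frame area — is the frame-level
#' texture score used downstream.
#'
#' @param frame `height x width x 3` RGB array (0..255).
#' @param params an [operator_params()].
#' @return list with `map` (a `SaliencyMap`, tag `"TS"`), `mask` (0/1
#'   matrix), and `injurious_fraction` (scalar in `[0, 1]`).
#' @export
texture_saliency <- function(frame, params = operator_params()) {
  params <- as_operator_params(params)
  gray <- to_grayscale(frame)
  ent <- local_entropy(gray, params)
  mask <- matrix(as.numeric(ent >= params$tau), nrow(ent), ncol(ent))
  mask <- clean_mask(mask, params$closing_radius)
  list(map = saliency_map(gray * mask, "TS"),
       mask = mask,
       injurious_fraction = mean(mask))
}

# Morphological closing (disk structuring element) followed by hole filling.
clean_mask <- function(mask, closing_radius) {
  if (!any(mask > 0)) return(mask)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(mask, brush)
  }
  mask <- EBImage::fillHull(mask)
  matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
}
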