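# Shared numerical helpers: reflective padding, separable convolution,
# bilinear resizing. All saliency operators use reflective (symmetric,
# edge-including) borders so that flat regions stay flat at the image edge.

#' Reflectively pad a matrix
#'
#' Pads `m` by `r` pixels on every side using symmetric reflection that
#' includes the edge pixel (`b a | a b c ... `), the convention used by all
#' window-based operators in the package. Requires `r <= dim(m)`.
#'
#' @param m numeric matrix.
#' @param r non-negative pad width in pixels.
#' @return matrix of dimension `dim(m) + 2 * r`.
#' @keywords internal
pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc)
    stop("reflective pad width ", r, " exceeds image dimensions ",
         nr, "x", nc)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# 1-D convolution of every row/column of a matrix with an odd-length kernel,
# reflective borders. Used for Gaussian smoothing and finite differencing.
conv_sep1d <- function(m, kernel, along = c("row", "col")) {
  along <- match.arg(along)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0) return(m * kernel)
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (k in seq_along(kernel)) {
    off <- k - 1L - r
    if (along == "row") {
      # kernel slides along x (columns)
      out <- out + kernel[k] * p[(r + 1):(r + nr), (r + 1 + off):(r + nc + off)]
    } else {
      out <- out + kernel[k] * p[(r + 1 + off):(r + nr + off), (r + 1):(r + nc)]
    }
  }
  out
}

# Normalized 1-D Gaussian kernel truncated at 3*sigma.
gaussian_kernel1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with reflective borders.
gaussian_smooth <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  conv_sep1d(conv_sep1d(m, k, "row"), k, "col")
}

#' Bilinear resize of a matrix
#'
#' Area-style coordinate mapping (pixel centers at `i - 0.5`), clamped at the
#' borders; the same convention is used for pyramid-level upsampling.
#'
#' @param m numeric matrix.
#' @param nr,nc target dimensions.
#' @return `nr` by `nc` matrix.
#' @keywords internal
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  if (sr == nr && sc == nc) return(m)
  map_axis <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1L); lo <- pmax(lo, 1L)
    list(lo = as.integer(lo), w = src - lo)
  }
  ry <- map_axis(nr, sr)
  rx <- map_axis(nc, sc)
  top <- m[ry$lo, , drop = FALSE] * (1 - ry$w) +
    m[pmin(ry$lo + 1L, sr), , drop = FALSE] * ry$w
  top[, rx$lo, drop = FALSE] * rep(1 - rx$w, each = nr) +
    top[, pmin(rx$lo + 1L, sc), drop = FALSE] * rep(rx$w, each = nr)
}

# x * log2(x) with the 0 * log 0 := 0 convention, elementwise.
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
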