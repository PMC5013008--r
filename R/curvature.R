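# Curvature saliency: magnitude of the second-derivative tensor of the
# Gaussian-smoothed luminance image. Being built from second derivatives in
# all axis combinations it is approximately rotation invariant, which suits
# endoscopic footage captured at arbitrary orientations.

#' Curvature saliency map
#'
#' The luminance image is smoothed with a Gaussian of scale `sigma` (kernel
#' truncated at `3 sigma`, reflective borders) giving `g`; the four second
#' derivatives `g_xx`, `g_yy`, `g_xy`, `g_yx` are taken by central finite
#' differences (also reflective at the borders), and the map is
#' `sqrt(g_xy^2 + g_xx^2 + g_yx^2 + g_yy^2)`. The mixed derivatives coincide
#' analytically but are computed independently (x-then-y and y-then-x),
#' preserving the four-term form.
#'
#' @param gray grayscale matrix with values in `[0, 1]`.
#' @param params an [operator_params()]; `sigma` sets the smoothing scale.
#' @return a `SaliencyMap` (tag `"CM"`).
#' @export
curvature_map <- function(gray, params = operator_params()) {
  params <- as_operator_params(params)
  if (any(gray < 0) || any(gray > 1)) stop("gray values must lie in [0, 1]")
  g <- gaussian_smooth(gray, params$sigma)
  d <- c(-0.5, 0, 0.5)  # central difference; x = columns, y = rows
  gx <- conv_sep1d(g, d, "row")
  gy <- conv_sep1d(g, d, "col")
  gxx <- conv_sep1d(gx, d, "row")
  gyy <- conv_sep1d(gy, d, "col")
  gxy <- conv_sep1d(gx, d, "col")
  gyx <- conv_sep1d(gy, d, "row")
  saliency_map(sqrt(gxy^2 + gxx^2 + gyx^2 + gyy^2), "CM")
}
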