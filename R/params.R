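#' Saliency operator parameters
#'
#' One bundle of tunable parameters shared by the four saliency operators.
#' Defaults follow common practice for 8-bit endoscopic video:
#'
#' \describe{
#'   \item{block_size, search_radius}{motion estimation: exhaustive
#'     block-matching with `block_size` x `block_size` blocks over integer
#'     displacements within `± search_radius` pixels (defaults 16 and 8).}
#'   \item{entropy_window, gray_levels}{texture: local-histogram entropy over
#'     an odd `entropy_window` neighborhood with `gray_levels` histogram bins
#'     (defaults 15 and 256). Entropy is normalized by `log2(gray_levels)`,
#'     so the attainable maximum is `log2(entropy_window^2) /
#'     log2(gray_levels)`; the window must be large enough for the
#'     segmentation threshold `tau` to be attainable with headroom — 15^2 =
#'     225 samples give a ceiling of 0.977 at 256 levels, whereas an 11
#'     window caps at 0.86, leaving richly textured tissue hovering at the
#'     0.8 threshold.}
#'   \item{tau}{entropy threshold in (0, 1) separating injurious
#'     (high-texture) tissue from background; default 0.8.}
#'   \item{closing_radius}{disk radius (pixels) of the morphological closing
#'     applied to the thresholded texture mask; default 5.}
#'   \item{contrast_neighborhood}{odd window for the color-contrast operator;
#'     default 5 (a 5 x 5 neighborhood).}
#'   \item{pyramid_levels}{number of Gaussian-pyramid levels summed by the
#'     multi-scale contrast map; default 3.}
#'   \item{sigma}{Gaussian scale (pixels) of the pre-smoothing in the
#'     curvature map; default 1.5.}
#' }
#'
#' @param block_size,search_radius,entropy_window,tau,closing_radius,gray_levels,contrast_neighborhood,pyramid_levels,sigma
#'   see Details.
#' @return an object of class `OperatorParams`.
#' @export
operator_params <- function(block_size = 16L, search_radius = 8L,
                            entropy_window = 15L, tau = 0.8,
                            closing_radius = 5L, gray_levels = 256L,
                            contrast_neighborhood = 5L, pyramid_levels = 3L,
                            sigma = 1.5) {
  p <- list(block_size = as.integer(block_size),
            search_radius = as.integer(search_radius),
            entropy_window = as.integer(entropy_window),
            tau = tau,
            closing_radius = as.integer(closing_radius),
            gray_levels = as.integer(gray_levels),
            contrast_neighborhood = as.integer(contrast_neighborhood),
            pyramid_levels = as.integer(pyramid_levels),
            sigma = sigma)
  if (p$block_size < 1 || p$search_radius < 0)
    stop("block_size must be >= 1 and search_radius >= 0")
  if (p$entropy_window < 3 || p$entropy_window %% 2 == 0)
    stop("entropy_window must be odd and >= 3")
  if (p$contrast_neighborhood < 3 || p$contrast_neighborhood %% 2 == 0)
    stop("contrast_neighborhood must be odd and >= 3")
  if (p$tau <= 0 || p$tau >= 1) stop("tau must lie in (0, 1)")
  if (p$gray_levels < 2) stop("gray_levels must be >= 2")
  if (p$closing_radius < 0) stop("closing_radius must be >= 0")
  if (p$pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (p$sigma <= 0) stop("sigma must be positive")
  structure(p, class = "OperatorParams")
}

# Merge a plain list of overrides (e.g. from a YAML config) into defaults.
as_operator_params <- function(x = NULL) {
  if (inherits(x, "OperatorParams")) return(x)
  if (is.null(x)) return(operator_params())
  known <- names(formals(operator_params))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0)
    stop("unknown operator parameter(s): ", paste(bad, collapse = ", "))
  do.call(operator_params, x)
}

MODEL_TAGS <- c("MS", "TS", "MSCM", "CM")
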