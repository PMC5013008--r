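# Keyframe selection from the attention curve: either every frame above the
# mean attention value, or the per-shot maxima for a requested number of
# keyframes (NKF).

#' Construct a keyframe set
#'
#' @param indices strictly increasing 0-based frame indices.
#' @param mode `"threshold"` or `"nkf"`.
#' @param threshold_used mean-attention threshold, for threshold mode.
#' @param nkf_used requested keyframe count, for nkf mode.
#' @return an object of class `KeyframeSet`.
#' @export
keyframe_set <- function(indices, mode = c("threshold", "nkf"),
                         threshold_used = NULL, nkf_used = NULL) {
  mode <- match.arg(mode)
  indices <- as.integer(indices)
  if (length(indices) > 1 && any(diff(indices) <= 0))
    stop("keyframe indices must be strictly increasing")
  if (length(indices) > 0 && any(indices < 0))
    stop("keyframe indices must be non-negative (0-based)")
  structure(list(indices = indices, mode = mode,
                 threshold_used = threshold_used, nkf_used = nkf_used),
            class = "KeyframeSet")
}

#' @export
print.KeyframeSet <- function(x, ...) {
  extra <- if (x$mode == "threshold")
    sprintf(" (threshold %.4f)", x$threshold_used)
  else sprintf(" (nkf %d)", x$nkf_used)
  cat(sprintf("KeyframeSet [%s]%s: %s\n", x$mode, extra,
              paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Extract keyframes by mean-attention thresholding
#'
#' The threshold is the arithmetic mean of the attention curve; every frame
#' whose attention value is strictly greater than the mean becomes a
#' keyframe. A constant curve therefore yields no keyframes.
#'
#' @param curve an `AttentionCurve` or numeric vector.
#' @return a [keyframe_set()] in threshold mode with `threshold_used`
#'   recorded.
#' @export
extract_by_threshold <- function(curve) {
  v <- curve_values(curve)
  thr <- mean(v)
  keyframe_set(which(v > thr) - 1L, mode = "threshold", threshold_used = thr)
}

#' Extract keyframes as per-shot attention maxima
#'
#' The sequence is partitioned into `nkf` contiguous shots of near-equal
#' length (the first `n mod nkf` shots are one frame longer); within each
#' shot the frame with the highest attention value is the keyframe, ties
#' going to the earliest frame. When `nkf > n` every frame is its own shot,
#' so exactly `min(nkf, n)` keyframes are returned.
#'
#' @param curve an `AttentionCurve` or numeric vector.
#' @param nkf requested number of keyframes (`>= 1`).
#' @return a [keyframe_set()] in nkf mode.
#' @export
extract_by_nkf <- function(curve, nkf) {
  v <- curve_values(curve)
  if (length(nkf) != 1 || is.na(nkf) || nkf < 1 || nkf != round(nkf))
    stop("parameter error: nkf must be a positive integer")
  n <- length(v)
  bounds <- shot_bounds(n, as.integer(nkf))
  idx <- vapply(seq_len(nrow(bounds)), function(s) {
    seg <- v[bounds[s, 1]:bounds[s, 2]]
    bounds[s, 1] + which.max(seg) - 1L  # which.max: earliest tie
  }, integer(1))
  keyframe_set(idx - 1L, mode = "nkf", nkf_used = as.integer(nkf))
}

# 1-based inclusive [start, end] bounds of min(nkf, n) contiguous shots;
# the first n %% nkf shots get the extra frame.
shot_bounds <- function(n, nkf) {
  k <- min(nkf, n)
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, ends[-k] + 1L), end = as.integer(ends))
}

curve_values <- function(curve) {
  v <- if (inherits(curve, "AttentionCurve")) curve$values else curve
  if (length(v) == 0) stop("input error: empty attention curve")
  v
}
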