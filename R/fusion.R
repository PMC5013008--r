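# Fusion: collapse per-pixel saliency maps to per-frame scores, normalize
# each model's score vector to [0, 1], and combine the models by weighted
# linear fusion into the attention curve.

#' Frame-level score of a saliency map
#'
#' The mean of the strictly positive map values (0 for an identically zero
#' map). Zeros are excluded because a map is sparse by construction — most
#' of a frame carries no saliency — and averaging them in would make the
#' score depend on frame area rather than salient content. For the texture
#' model the frame score is `injurious_fraction`, taken directly from
#' [texture_saliency()], not from this function.
#'
#' @param map a `SaliencyMap` or a plain non-negative matrix.
#' @return scalar `>= 0`.
#' @export
frame_score <- function(map) {
  v <- if (inherits(map, "SaliencyMap")) map$values else map
  if (any(v < 0) || any(!is.finite(v)))
    stop("saliency map must be finite and non-negative")
  pos <- v[v > 0]
  if (length(pos) == 0) 0 else mean(pos)
}

#' Normalize raw per-frame scores to [0, 1]
#'
#' Divides by the maximum score. Unlike min–max scaling this preserves
#' zeros — a frame with no saliency keeps score 0 — and the ratio structure
#' between frames. An all-zero vector stays all-zero (a static video is a
#' legitimate input, not an error).
#'
#' @param raw numeric vector of non-negative finite scores, one per frame.
#' @param model_tag model label attached to the result.
#' @return an object of class `ScoreVector` with fields `model_tag` and
#'   `scores` in `[0, 1]`.
#' @export
normalize_scores <- function(raw, model_tag = "MS") {
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("contract violation: raw scores must be finite and non-negative")
  m <- max(raw)
  scores <- if (m == 0) raw else raw / m
  structure(list(model_tag = match.arg(model_tag, MODEL_TAGS),
                 scores = scores),
            class = "ScoreVector")
}

#' Weighted linear fusion of per-model score vectors
#'
#' Weights are normalized to sum 1 before use, so the fused curve is a
#' convex combination of the per-model scores and stays in `[0, 1]`. With
#' equal weights the fusion degenerates to the arithmetic mean; models can
#' be ablated by giving them weight 0.
#'
#' @param vectors list of `ScoreVector`s of equal length with distinct
#'   model tags.
#' @param weights named non-negative numeric vector, one entry per model tag
#'   present in `vectors` (extra names allowed); at least one weight of a
#'   supplied vector must be positive. Default: equal weights.
#' @return an object of class `AttentionCurve` with field `values`.
#' @export
fuse_scores <- function(vectors, weights = NULL) {
  if (length(vectors) == 0) stop("input error: no score vectors to fuse")
  tags <- vapply(vectors, function(v) v$model_tag, character(1))
  if (anyDuplicated(tags)) stop("input error: duplicate model tags")
  n <- length(vectors[[1]]$scores)
  lens <- vapply(vectors, function(v) length(v$scores), integer(1))
  if (any(lens != n)) stop("input error: score vectors differ in length")
  if (is.null(weights)) weights <- setNames(rep(1, length(tags)), tags)
  if (any(!tags %in% names(weights)))
    stop("input error: missing fusion weight for model(s): ",
         paste(setdiff(tags, names(weights)), collapse = ", "))
  w <- weights[tags]
  if (any(w < 0)) stop("fusion weights must be non-negative")
  if (sum(w) == 0) stop("input error: all fusion weights are zero")
  w <- w / sum(w)
  fused <- rep(0, n)
  for (i in seq_along(vectors)) fused <- fused + w[i] * vectors[[i]]$scores
  attention_curve(fused)
}

#' Construct an attention curve
#'
#' @param values numeric vector of per-frame fused scores in `[0, 1]`.
#' @return an object of class `AttentionCurve`.
#' @export
attention_curve <- function(values) {
  if (length(values) < 1) stop("input error: empty attention curve")
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("attention values must lie in [0, 1]")
  structure(list(values = pmin(pmax(values, 0), 1)), class = "AttentionCurve")
}

#' @export
print.AttentionCurve <- function(x, ...) {
  cat(sprintf("AttentionCurve: %d frames, mean %.4f, max %.4f\n",
              length(x$values), mean(x$values), max(x$values)))
  invisible(x)
}
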