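# Motion saliency: exhaustive block-matching motion estimation followed by
# per-pixel displacement magnitude. Fast hysteroscope pans produce large
# magnitudes, slow dwells over areas of interest produce small ones.

#' Estimate a per-pixel motion field by block matching
#'
#' The current frame is partitioned into `block_size` blocks (ragged at the
#' right/bottom edges). For each block, every integer displacement
#' `(dx, dy)` with `|dx|, |dy| <= search_radius` is scored by the sum of
#' absolute differences (SAD) against the previous frame, which is
#' reflectively padded so displaced blocks remain defined at the borders.
#' All pixels of a block share the winning displacement. Ties are broken by
#' smallest displacement magnitude, then smallest `dy`, then smallest `dx`,
#' so a static scene yields an exactly zero field.
#'
#' Displacements follow the convention `cur(x, y) ~ prev(x - dx, y - dy)`:
#' content that moved right/down between frames has positive `dx`/`dy`.
#' `x` indexes columns and `y` rows.
#'
#' @param prev,cur grayscale matrices of identical dimensions (values in
#'   `[0, 1]`).
#' @param params an [operator_params()].
#' @return an object of class `MotionField` with matrices `dx` and `dy`.
#' @export
estimate_motion_field <- function(prev, cur, params = operator_params()) {
  params <- as_operator_params(params)
  if (!identical(dim(prev), dim(cur)))
    stop("input error: prev and cur frames differ in dimensions")
  nr <- nrow(cur); nc <- ncol(cur)
  b <- params$block_size
  r <- params$search_radius

  # candidate displacements in tie-break order: magnitude, then dy, then dx
  cand <- expand.grid(dy = (-r):r, dx = (-r):r)
  cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dy, cand$dx), ]

  pp <- pad_reflect(prev, max(r, 1L))
  pr <- max(r, 1L)
  block_row <- rep(ceiling(seq_len(nr) / b), times = nc)
  block_col <- rep(ceiling(seq_len(nc) / b), each = nr)
  nbr <- ceiling(nr / b); nbc <- ceiling(nc / b)
  block_id <- block_row + (block_col - 1L) * nbr

  sad <- matrix(NA_real_, nbr * nbc, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    dy <- cand$dy[k]; dx <- cand$dx[k]
    shifted <- pp[(pr + 1 - dy):(pr + nr - dy),
                  (pr + 1 - dx):(pr + nc - dx), drop = FALSE]
    d <- abs(cur - shifted)
    sad[, k] <- rowsum(as.vector(d), block_id)[, 1]
  }
  # first candidate (in tie-break order) within a hair of the minimum: SADs
  # that are mathematically tied can differ by summation rounding, which
  # must not override the tie-break
  tol <- 1e-9
  best <- apply(sad, 1, function(s) which.max(s <= min(s) + tol))

  dx_block <- cand$dx[best]; dy_block <- cand$dy[best]
  field_dx <- matrix(dx_block[block_id], nr, nc)
  field_dy <- matrix(dy_block[block_id], nr, nc)
  structure(list(dx = field_dx, dy = field_dy), class = "MotionField")
}

#' Motion saliency map
#'
#' Per-pixel motion magnitude `sqrt(dx^2 + dy^2)` of a [estimate_motion_field()]
#' result, before any normalization.
#'
#' @param field a `MotionField`.
#' @return a `SaliencyMap` (tag `"MS"`).
#' @export
motion_saliency <- function(field) {
  stopifnot(inherits(field, "MotionField"))
  saliency_map(sqrt(field$dx^2 + field$dy^2), "MS")
}

#' Construct a saliency map
#'
#' @param values non-negative finite matrix.
#' @param model_tag one of `"MS"`, `"TS"`, `"MSCM"`, `"CM"`.
#' @return an object of class `SaliencyMap`.
#' @export
saliency_map <- function(values, model_tag) {
  model_tag <- match.arg(model_tag, MODEL_TAGS)
  if (any(!is.finite(values)) || any(values < 0))
    stop("saliency values must be finite and non-negative")
  structure(list(values = values, model_tag = model_tag),
            class = "SaliencyMap")
}

#' @export
print.SaliencyMap <- function(x, ...) {
  cat(sprintf("SaliencyMap [%s]: %dx%d, range [%.4g, %.4g]\n", x$model_tag,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
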