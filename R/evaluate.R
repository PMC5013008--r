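# Evaluation against gynecologist-style ground truth: tolerance-window
# one-to-one matching of extracted to annotated keyframes, with accuracy
# (percent of ground-truth frames recovered), precision, recall, and
# F-measure. Accuracy and recall coincide by construction (both tp/|truth|);
# accuracy is reported on the 0-100 scale.

#' Match extracted keyframes against ground truth
#'
#' Greedy one-to-one matching: ground-truth indices are processed in
#' increasing order; each is matched to the earliest still-unmatched
#' extracted index within `± tolerance` frames. With tolerance 0 this
#' reduces to set intersection. Because both index sets are sorted and the
#' matching windows are intervals, this greedy scheme attains the optimal
#' (maximum) one-to-one assignment — a nearest-neighbour rule would not
#' (e.g. truth \{2, 3\} vs extracted \{1, 2\} at tolerance 1 strands one
#' match). Equivalence with brute-force optimal assignment is asserted in
#' the test suite. Only the counts enter the metrics, so which in-window
#' frame is paired does not affect any reported number.
#'
#' @param extracted a `KeyframeSet` or integer vector of 0-based indices.
#' @param truth a `GroundTruth` or integer vector of 0-based indices.
#' @param tolerance non-negative matching window in frames (default 0).
#' @return list of class `EvalResult`: `true_positives`, `false_positives`,
#'   `false_negatives`, `accuracy` (percent), `precision`, `recall`,
#'   `f_measure`, `tolerance`.
#' @export
match_keyframes <- function(extracted, truth, tolerance = 0) {
  if (length(tolerance) != 1 || tolerance < 0)
    stop("parameter error: tolerance must be a non-negative scalar")
  ext <- sort(unique(as.integer(
    if (inherits(extracted, "KeyframeSet")) extracted$indices else extracted)))
  tru <- sort(unique(as.integer(
    if (inherits(truth, "GroundTruth")) truth$keyframe_indices else truth)))
  matched <- logical(length(ext))
  tp <- 0L
  for (t in tru) {
    cand <- which(!matched & abs(ext - t) <= tolerance)
    if (length(cand) > 0) {
      matched[cand[1]] <- TRUE   # earliest in window: optimal for intervals
      tp <- tp + 1L
    }
  }
  fp <- sum(!matched)
  fn <- length(tru) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- if (length(tru) == 0) 0 else 100 * tp / length(tru)
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, accuracy = accuracy,
                 precision = precision, recall = recall, f_measure = f,
                 tolerance = tolerance),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf(
    "EvalResult (tolerance %g): tp=%d fp=%d fn=%d | accuracy %.1f%% P=%.3f R=%.3f F=%.3f\n",
    x$tolerance, x$true_positives, x$false_positives, x$false_negatives,
    x$accuracy, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Ablation table over saliency-model subsets
#'
#' Re-runs the summarization pipeline on the same frame sequence once per
#' model subset (models outside the subset get fusion weight 0) and tabulates
#' extracted keyframe count, attention-curve threshold, accuracy, and
#' F-measure against the ground truth — the machine-readable analogue of a
#' per-model performance table.
#'
#' Per-model raw scores are computed once and reused across subsets, so the
#' table is cheap even for many rows.
#'
#' @param seq a `FrameSequence`.
#' @param truth a `GroundTruth`.
#' @param model_subsets list of character vectors of model tags (subsets of
#'   `c("MS", "TS", "MSCM", "CM")`); names, if any, label the rows.
#' @param params an [operator_params()].
#' @param mode extraction rule, `"threshold"` (default, the evaluation
#'   protocol) or `"nkf"`.
#' @param nkf keyframe count for nkf mode.
#' @param tolerance matching tolerance in frames.
#' @return data frame with one row per subset: `models`, `n_extracted`,
#'   `threshold`, `accuracy`, `f_measure`.
#' @export
ablation_report <- function(seq, truth, model_subsets,
                            params = operator_params(),
                            mode = c("threshold", "nkf"), nkf = NULL,
                            tolerance = 0) {
  mode <- match.arg(mode)
  if (length(model_subsets) == 0)
    stop("parameter error: no model subsets given")
  for (s in model_subsets) {
    if (length(s) == 0) stop("parameter error: empty model subset")
    if (!all(s %in% MODEL_TAGS))
      stop("unknown model tag(s): ",
           paste(setdiff(s, MODEL_TAGS), collapse = ", "))
  }
  raw <- saliency_scores(seq, params)   # all four models, once
  rows <- lapply(model_subsets, function(s) {
    s <- unique(s)
    vectors <- lapply(s, function(tag) normalize_scores(raw[[tag]], tag))
    curve <- fuse_scores(vectors)
    keys <- if (mode == "threshold") extract_by_threshold(curve)
            else extract_by_nkf(curve, nkf)
    ev <- match_keyframes(keys, truth, tolerance)
    data.frame(models = paste(sort(s), collapse = "+"),
               n_extracted = length(keys$indices),
               threshold = keys$threshold_used %||% NA_real_,
               accuracy = ev$accuracy,
               f_measure = ev$f_measure,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(model_subsets))) rownames(out) <- names(model_subsets)
  out
}
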