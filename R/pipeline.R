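# Pipeline orchestration: run the four saliency models over a frame
# sequence, fuse the per-frame scores into the attention curve, extract
# keyframes, and (optionally) write curve CSV, keyframe PNGs, and a
# provenance manifest.

#' Raw per-frame saliency scores for all four models
#'
#' Sequential frame loop computing, for each frame: motion saliency against
#' the previous frame (the first frame has no predecessor and gets a zero
#' field), texture saliency, multi-scale contrast, and curvature. Per-pixel
#' maps are collapsed with [frame_score()] (mean of positive values), except
#' texture, whose frame score is the injurious area fraction.
#'
#' @param seq a `FrameSequence`.
#' @param params an [operator_params()].
#' @param models character vector of model tags to compute (default all
#'   four); omitted models are returned as zero score vectors.
#' @return named list of numeric vectors `MS`, `TS`, `MSCM`, `CM`, one raw
#'   (unnormalized) score per frame.
#' @export
saliency_scores <- function(seq, params = operator_params(),
                            models = MODEL_TAGS) {
  stopifnot(inherits(seq, "FrameSequence"))
  params <- as_operator_params(params)
  models <- match.arg(models, MODEL_TAGS, several.ok = TRUE)
  n <- length(seq$frames)
  raw <- setNames(rep(list(rep(0, n)), length(MODEL_TAGS)), MODEL_TAGS)
  prev_gray <- NULL
  for (i in seq_len(n)) {
    frame <- seq$frames[[i]]
    gray <- to_grayscale(frame)
    if ("MS" %in% models) {
      ms <- if (is.null(prev_gray)) {
        saliency_map(matrix(0, nrow(gray), ncol(gray)), "MS")
      } else {
        motion_saliency(estimate_motion_field(prev_gray, gray, params))
      }
      raw$MS[i] <- frame_score(ms)
    }
    if ("TS" %in% models) {
      raw$TS[i] <- texture_saliency(frame, params)$injurious_fraction
    }
    if ("MSCM" %in% models) {
      raw$MSCM[i] <- frame_score(multiscale_contrast(frame, params))
    }
    if ("CM" %in% models) {
      raw$CM[i] <- frame_score(curvature_map(gray, params))
    }
    prev_gray <- gray
  }
  raw
}

#' Attention curve of a frame sequence
#'
#' Convenience wrapper: [saliency_scores()], [normalize_scores()] per model,
#' then [fuse_scores()] with the given weights. Models with weight 0 are
#' skipped entirely.
#'
#' @param seq a `FrameSequence`.
#' @param params an [operator_params()].
#' @param weights named non-negative fusion weights over
#'   `c("MS", "TS", "MSCM", "CM")`; default equal weights on all four.
#' @return list with `curve` (an `AttentionCurve`) and `scores` (data frame
#'   of per-model normalized scores).
#' @export
attention_scores <- function(seq, params = operator_params(),
                             weights = NULL) {
  if (is.null(weights)) weights <- setNames(rep(1, 4), MODEL_TAGS)
  if (!all(names(weights) %in% MODEL_TAGS))
    stop("unknown model tag(s) in weights: ",
         paste(setdiff(names(weights), MODEL_TAGS), collapse = ", "))
  if (any(weights < 0)) stop("fusion weights must be non-negative")
  active <- names(weights)[weights > 0]
  if (length(active) == 0)
    stop("validation error: all fusion weights are zero")
  raw <- saliency_scores(seq, params, models = active)
  vectors <- lapply(active, function(tag) normalize_scores(raw[[tag]], tag))
  curve <- fuse_scores(vectors, weights)
  norm <- as.data.frame(lapply(setNames(nm = MODEL_TAGS), function(tag) {
    if (tag %in% active) normalize_scores(raw[[tag]], tag)$scores
    else rep(NA_real_, length(seq$frames))
  }))
  list(curve = curve, scores = norm)
}

#' Run the full summarization pipeline
#'
#' Executes read (or synthesis) → per-frame saliency → score normalization →
#' weighted fusion → keyframe extraction → output writing, from a single
#' config. The config is a nested list (see [read_config()] for the on-disk
#' YAML/JSON form) with entries:
#'
#' \describe{
#'   \item{input}{path to a frame directory, a `FrameSequence`, or `NULL`
#'     when `synthetic` is given.}
#'   \item{synthetic}{a [synthetic_spec()] or a list of its arguments.}
#'   \item{models}{list of [operator_params()] overrides.}
#'   \item{weights}{named fusion weights (default equal on all four).}
#'   \item{mode}{`"threshold"` or `"nkf"` (default `"threshold"`).}
#'   \item{nkf}{keyframe count for nkf mode.}
#'   \item{outdir}{output directory; if `NULL`, nothing is written.
#'     Written artifacts: `attention_curve.csv` (per-frame model and fused
#'     scores), `keyframes/` (PNG per keyframe plus `keyframes.json`
#'     manifest), `keyframes.txt` (one 0-based index per line, the
#'     annotation format), and `manifest.json` (all effective parameters).}
#' }
#'
#' @param config nested list as described above.
#' @return list of class `SummarizeResult`: `keys` (a `KeyframeSet`),
#'   `curve` (an `AttentionCurve`), `scores` (per-model normalized scores),
#'   `truth` (planted `GroundTruth` for synthetic input, else `NULL`), and
#'   `manifest` (effective parameters; written as JSON when `outdir` is
#'   set).
#' @export
run_summarize <- function(config) {
  cfg <- validate_config(config)
  seq <- cfg$seq
  truth <- cfg$truth
  att <- attention_scores(seq, cfg$params, cfg$weights)
  keys <- if (cfg$mode == "threshold") extract_by_threshold(att$curve)
          else extract_by_nkf(att$curve, cfg$nkf)

  manifest <- list(
    source = seq$source_id, n_frames = length(seq$frames),
    frame_dims = as.integer(frame_dims(seq)),
    params = unclass(cfg$params), weights = as.list(cfg$weights),
    mode = cfg$mode, nkf = cfg$nkf,
    threshold_used = keys$threshold_used,
    keyframes = keys$indices)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    curve_df <- data.frame(frame_index = seq_along(att$curve$values) - 1L,
                           att$scores, fused = att$curve$values)
    write.csv(curve_df, file.path(cfg$outdir, "attention_curve.csv"),
              row.names = FALSE)
    write_keyframes(seq, keys, file.path(cfg$outdir, "keyframes"))
    writeLines(as.character(keys$indices),
               file.path(cfg$outdir, "keyframes.txt"))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(keys = keys, curve = att$curve, scores = att$scores,
                 truth = truth, manifest = manifest, seq = seq),
            class = "SummarizeResult")
}

#' Read a pipeline config file
#'
#' YAML (`.yml`/`.yaml`) or JSON, mirroring the list accepted by
#' [run_summarize()].
#'
#' @param path config file.
#' @return nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("input error: no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# Validate the whole config before any computation; resolve input frames.
validate_config <- function(config) {
  stopifnot(is.list(config))
  params <- as_operator_params(config$models)
  weights <- config$weights
  if (is.null(weights)) weights <- setNames(rep(1, 4), MODEL_TAGS)
  weights <- unlist(weights)
  if (!all(names(weights) %in% MODEL_TAGS))
    stop("unknown model tag(s) in weights")
  if (any(weights < 0) || sum(weights) == 0)
    stop("validation error: fusion weights must be non-negative with at ",
         "least one positive")
  mode <- config$mode %||% "threshold"
  mode <- match.arg(mode, c("threshold", "nkf"))
  nkf <- config$nkf
  if (mode == "nkf") {
    if (is.null(nkf) || nkf < 1) stop("validation error: nkf mode needs nkf >= 1")
    nkf <- as.integer(nkf)
  }
  truth <- NULL
  if (!is.null(config$synthetic)) {
    spec <- if (inherits(config$synthetic, "SyntheticSpec")) config$synthetic
            else do.call(synthetic_spec, config$synthetic)
    gen <- synth_generate(spec)
    seq <- gen$seq; truth <- gen$truth
  } else if (inherits(config$input, "FrameSequence")) {
    seq <- config$input
  } else if (is.character(config$input)) {
    seq <- read_frames(config$input, frame_rate = config$frame_rate %||% 30)
  } else {
    stop("validation error: config needs either 'input' or 'synthetic'")
  }
  if (!is.null(config$ground_truth)) {
    truth <- if (inherits(config$ground_truth, "GroundTruth")) config$ground_truth
             else read_ground_truth(config$ground_truth, length(seq$frames))
  }
  list(seq = seq, truth = truth, params = params, weights = weights,
       mode = mode, nkf = nkf, outdir = config$outdir)
}
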