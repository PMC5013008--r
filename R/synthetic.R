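# Synthetic diagnostic-hysteroscopy video generator. Emulates the
# statistical structure that drives the saliency pipeline — not photoreal
# tissue: a pinkish low-contrast textured canvas viewed through a moving
# circular endoscopic field with dark vignette; the camera alternates fast
# pans (unimportant) with slow dwells centered on high-entropy "lesion"
# patches (important); a fraction of non-dwell frames is contaminated by
# specular glare blobs and blur. Ground truth is the middle frame of each
# dwell.

#' Specify a synthetic DH video
#'
#' Defaults are a scaled-down analogue of a clinical recording (30 fps,
#' minutes long): 90 frames of 64 x 64 with three dwell events of 12 frames
#' each, pans at 6 px/frame versus dwells at 1 px/frame, 30% of pan frames
#' glare-contaminated, and lesions textured with full-range noise of
#' amplitude 0.8.
#'
#' @param n_frames total frame count.
#' @param height,width frame size in pixels.
#' @param n_events number of diagnostically important dwell segments (may be
#'   0).
#' @param dwell_length frames per dwell segment.
#' @param pan_speed_fast,pan_speed_slow camera speed in pixels/frame during
#'   pans and dwells. Fast pans should stay within the motion search radius
#'   to be measurable.
#' @param glare_fraction fraction of non-dwell frames overlaid with
#'   saturated glare blobs and blur, in `[0, 1]`.
#' @param lesion_entropy_boost amplitude (in `[0, 1]` gray units) of the
#'   uniform full-range noise inside lesion patches that raises their local
#'   entropy above the background texture.
#' @param lesion_radius lesion patch radius in pixels. The default (26 for
#'   the 64-pixel default frame) roughly fills the endoscopic field stop, as
#'   when the hysteroscope dwells close to the uterine wall; any off-center
#'   view then strictly loses visible lesion area to the dark surround.
#' @param frame_rate nominal frames/second, recorded in the sequence.
#' @param seed RNG seed making the video reproducible.
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_frames = 90L, height = 64L, width = 64L,
                           n_events = 3L, dwell_length = 12L,
                           pan_speed_fast = 6, pan_speed_slow = 1,
                           glare_fraction = 0.3, lesion_entropy_boost = 0.8,
                           lesion_radius = 26L, frame_rate = 30,
                           seed = 1L) {
  spec <- list(n_frames = as.integer(n_frames), height = as.integer(height),
               width = as.integer(width), n_events = as.integer(n_events),
               dwell_length = as.integer(dwell_length),
               pan_speed_fast = pan_speed_fast,
               pan_speed_slow = pan_speed_slow,
               glare_fraction = glare_fraction,
               lesion_entropy_boost = lesion_entropy_boost,
               lesion_radius = as.integer(lesion_radius),
               frame_rate = frame_rate, seed = as.integer(seed))
  if (spec$n_frames < 1 || spec$height < 8 || spec$width < 8)
    stop("parameter error: counts must be positive (frames >= 1, dims >= 8)")
  if (spec$n_events < 0 || (spec$n_events > 0 && spec$dwell_length < 1))
    stop("parameter error: n_events >= 0 and dwell_length >= 1 required")
  if (spec$n_events * spec$dwell_length > spec$n_frames)
    stop("parameter error: n_events * dwell_length exceeds n_frames")
  if (spec$glare_fraction < 0 || spec$glare_fraction > 1)
    stop("parameter error: glare_fraction must lie in [0, 1]")
  if (spec$lesion_entropy_boost < 0 || spec$lesion_entropy_boost > 1)
    stop("parameter error: lesion_entropy_boost must lie in [0, 1]")
  if (spec$pan_speed_fast <= 0 || spec$pan_speed_slow < 0)
    stop("parameter error: pan speeds must be positive/non-negative")
  structure(spec, class = "SyntheticSpec")
}

#' Per-frame segment table of a synthetic video
#'
#' Deterministic companion of [synth_generate()]: labels every frame
#' `dwell`, `fast_pan`, or `contaminated` (a glare-overlaid pan frame) and
#' reports the dwell boundaries, without rendering any pixels.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `frames` (data frame: `index` 0-based, `label`,
#'   `segment`) and `dwells` (data frame: `event`, `start`, `end`,
#'   `gt_index`, all 0-based inclusive).
#' @export
synth_describe <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  plan <- synth_plan(spec)
  plan[c("frames", "dwells")]
}

#' Generate a synthetic DH video with planted ground truth
#'
#' Renders the video described by `spec` (see [synthetic_spec()]), bit-
#' identically for a fixed spec and seed. Returns the frame sequence and the
#' ground truth (one index per dwell event: the middle frame of the dwell).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `seq` (a `FrameSequence`), `truth` (a `GroundTruth`),
#'   and `segments` (the [synth_describe()] table).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  plan <- synth_plan(spec)
  set.seed(spec$seed + 1L)   # plan consumed the seed stream from spec$seed

  h <- spec$height; w <- spec$width
  canvas <- synth_canvas(spec, plan)
  vignette <- synth_vignette(h, w)

  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    cy <- plan$path[i, 1]; cx <- plan$path[i, 2]
    r0 <- round(cy) - h %/% 2L
    c0 <- round(cx) - w %/% 2L
    win <- canvas[r0:(r0 + h - 1L), c0:(c0 + w - 1L), , drop = FALSE]
    if (plan$frames$label[i] != "dwell") {
      # fast pans are motion-blurred at ~30 fps; dwell views are sharp
      blur <- spec$pan_speed_fast / 3
      for (c in 1:3) win[, , c] <- gaussian_smooth(win[, , c], blur)
    }
    if (plan$frames$label[i] == "contaminated") win <- synth_glare(win)
    for (c in 1:3) win[, , c] <- win[, , c] * vignette
    fr <- round(pmin(pmax(win, 0), 1) * 255)
    storage.mode(fr) <- "integer"
    frames[[i]] <- fr
  }
  seq <- frame_sequence(frames, frame_rate = spec$frame_rate,
                        source_id = sprintf("synthetic(seed=%d)", spec$seed))
  truth <- ground_truth(plan$dwells$gt_index, spec$n_frames)
  list(seq = seq, truth = truth, segments = plan[c("frames", "dwells")])
}

# ---- internals -------------------------------------------------------------

# Camera schedule, path, glare assignment, and dwell table. Consumes RNG
# from set.seed(spec$seed) so that describe() and generate() agree.
synth_plan <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_frames; ev <- spec$n_events; dl <- spec$dwell_length

  # schedule: pan / dwell / pan / ... / dwell / pan, pans near-equal
  labels <- rep("fast_pan", n)
  segment <- integer(n)
  dwell_starts <- integer(0)
  if (ev > 0) {
    pan_total <- n - ev * dl
    pan_sizes <- rep(pan_total %/% (ev + 1L), ev + 1L)
    extra <- pan_total %% (ev + 1L)
    if (extra > 0) pan_sizes[seq_len(extra)] <- pan_sizes[seq_len(extra)] + 1L
    pos <- 1L
    for (e in seq_len(ev)) {
      pos <- pos + pan_sizes[e]
      dwell_starts <- c(dwell_starts, pos)
      labels[pos:(pos + dl - 1L)] <- "dwell"
      segment[pos:(pos + dl - 1L)] <- e
      pos <- pos + dl
    }
  }

  # camera path: fast random-direction walk on pans, slow jitter on dwells;
  # reflected inside the canvas working area
  ch <- synth_canvas_dims(spec)
  margin <- c(spec$height, spec$width) %/% 2 + 2L
  lo <- margin + 1; hi <- c(ch[1], ch[2]) - margin
  pos <- c(mean(c(lo[1], hi[1])), mean(c(lo[2], hi[2])))
  theta <- runif(1, 0, 2 * pi)
  path <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    speed <- if (labels[i] == "dwell") spec$pan_speed_slow else spec$pan_speed_fast
    if (labels[i] != "dwell" && runif(1) < 0.15)
      theta <- theta + rnorm(1, 0, 0.8)   # occasional direction change
    if (labels[i] == "dwell") theta <- theta + rnorm(1, 0, 1.5)
    step <- speed * c(sin(theta), cos(theta))
    pos <- pos + step
    # reflect off the working-area walls
    for (a in 1:2) {
      if (pos[a] < lo[a]) { pos[a] <- 2 * lo[a] - pos[a]; theta <- -theta }
      if (pos[a] > hi[a]) { pos[a] <- 2 * hi[a] - pos[a]; theta <- -theta }
    }
    path[i, ] <- pos
  }

  # glare on a fixed fraction of non-dwell frames
  pan_idx <- which(labels == "fast_pan")
  n_glare <- round(spec$glare_fraction * length(pan_idx))
  if (n_glare > 0) {
    glare_idx <- sort(sample(pan_idx, n_glare))
    labels[glare_idx] <- "contaminated"
  }

  dwells <- if (ev > 0) {
    data.frame(event = seq_len(ev),
               start = dwell_starts - 1L,
               end = dwell_starts + dl - 2L,
               gt_index = dwell_starts - 1L + (dl - 1L) %/% 2L)
  } else {
    data.frame(event = integer(0), start = integer(0), end = integer(0),
               gt_index = integer(0))
  }
  # lesion centers: mean camera position during each dwell
  lesions <- if (ev > 0) {
    t(vapply(seq_len(ev), function(e) {
      colMeans(path[segment == e, , drop = FALSE])
    }, numeric(2)))
  } else matrix(0, 0, 2)

  list(frames = data.frame(index = seq_len(n) - 1L, label = labels,
                           segment = segment, stringsAsFactors = FALSE),
       dwells = dwells, path = path, lesions = lesions)
}

synth_canvas_dims <- function(spec) {
  c(max(4L * spec$height, 256L), max(4L * spec$width, 256L))
}

# Pinkish band-limited tissue texture with high-entropy lesion patches.
synth_canvas <- function(spec, plan) {
  ch <- synth_canvas_dims(spec)
  base <- c(0.80, 0.45, 0.50)  # endometrial pink
  noise <- gaussian_smooth(matrix(runif(prod(ch), -1, 1), ch[1], ch[2]), 2)
  noise <- noise / max(abs(noise), 1e-12)
  canvas <- array(0, c(ch, 3))
  for (c in 1:3) canvas[, , c] <- pmin(pmax(base[c] + 0.10 * noise, 0), 1)

  if (nrow(plan$lesions) > 0) {
    yy <- matrix(seq_len(ch[1]), ch[1], ch[2])
    xx <- matrix(seq_len(ch[2]), ch[1], ch[2], byrow = TRUE)
    for (e in seq_len(nrow(plan$lesions))) {
      cy <- plan$lesions[e, 1]; cx <- plan$lesions[e, 2]
      inside <- (yy - cy)^2 + (xx - cx)^2 <= spec$lesion_radius^2
      npx <- sum(inside)
      if (npx == 0) next
      # brightness speckle shared across channels: the luminance histogram
      # inside the lesion becomes near-uniform over the boost range, raising
      # local entropy; independent per-channel noise would mix into a
      # bell-shaped (lower-entropy) luma distribution instead
      u <- runif(npx)
      for (c in 1:3) {
        v <- canvas[, , c]
        v[inside] <- pmin(pmax(
          (1 - spec$lesion_entropy_boost) * v[inside] +
            spec$lesion_entropy_boost * u, 0), 1)
        canvas[, , c] <- v
      }
    }
  }
  canvas
}

# Circular endoscopic field of view with soft dark vignette.
synth_vignette <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # field stop safely inside the frame: the dark surround, not the frame
  # border, is what clips off-center structures
  rad <- 0.42 * min(h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  # steep falloff: windows straddling the rim see a near-bimodal histogram
  # (low entropy), as with a real endoscopic field stop
  v <- 1 / (1 + exp((d - rad) / 0.8))
  0.05 + 0.95 * v
}

# Fig-1a-style contamination: saturated specular blobs composited over the
# frame, then whole-frame defocus blur. The blur blooms the blob rims and
# washes out the tissue texture, as over-exposed endoscopic frames do.
synth_glare <- function(win) {
  h <- nrow(win); w <- ncol(win)
  n_blobs <- sample(2:4, 1)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 0.2 * h, 0.8 * h); cx <- runif(1, 0.2 * w, 0.8 * w)
    rad <- runif(1, 0.08, 0.18) * min(h, w)
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    g <- 1 / (1 + exp((d - rad) / 0.8))  # clipped-sensor core
    for (c in 1:3) win[, , c] <- win[, , c] * (1 - g) + g
  }
  for (c in 1:3) win[, , c] <- gaussian_smooth(win[, , c], 2)
  pmin(win, 1)
}
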