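# Frame-sequence I/O. A FrameSequence is the unit of summarization: an
# ordered list of 8-bit RGB frames of identical size, as produced by a
# hysteroscope recording split into still images.

#' Construct a frame sequence
#'
#' @param frames list of `height x width x 3` numeric arrays with integer
#'   values in 0..255, all of identical dimensions.
#' @param frame_rate frames per second (informational only; default 30, the
#'   typical DH recording rate).
#' @param source_id free-text identifier of the source video.
#' @return an object of class `FrameSequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 30, source_id = "") {
  if (!is.list(frames) || length(frames) < 1)
    stop("a FrameSequence needs at least one frame")
  dims <- dim(frames[[1]])
  if (length(dims) != 3 || dims[3] != 3)
    stop("frames must be height x width x 3 RGB arrays")
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (is.null(d) || length(d) != 3 || any(d != dims))
      stop("frame ", i - 1, " has dimensions ", paste(d, collapse = "x"),
           ", expected ", paste(dims, collapse = "x"))
    v <- frames[[i]]
    if (any(v < 0) || any(v > 255) || any(v != round(v)))
      stop("frame ", i - 1, " has pixel values outside integer range 0..255")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, source_id = source_id),
    class = "FrameSequence")
}

#' @export
length.FrameSequence <- function(x) length(x$frames)

#' @export
print.FrameSequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("FrameSequence: %d frames of %dx%d RGB, %g fps%s\n",
              length(x$frames), d[1], d[2], x$frame_rate,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Dimensions of a frame sequence
#'
#' @param seq a `FrameSequence`.
#' @return integer vector `c(height, width)` of one frame.
#' @export
frame_dims <- function(seq) {
  stopifnot(inherits(seq, "FrameSequence"))
  dim(seq$frames[[1]])[1:2]
}

#' Read an ordered frame sequence from a directory of images
#'
#' Reads every raster image in `path` in lexicographic filename order, the
#' deterministic stand-in for container frame order. PNG and TIFF are
#' supported; video containers must be split into stills beforehand (e.g.
#' with ffmpeg), since no codec bindings are assumed.
#'
#' @param path directory containing the frame images.
#' @param frame_rate frames per second recorded in the returned sequence.
#' @param pattern filename regular expression (default: PNG/TIFF extensions).
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, frame_rate = 30,
                        pattern = "\\.(png|tif|tiff)$") {
  if (!dir.exists(path))
    stop("input error: not a readable directory: ", path)
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0)
    stop("input error: no frame images found under ", path)
  frames <- lapply(files, read_rgb_image)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: mixed frame dimensions under ", path)
  frame_sequence(frames, frame_rate = frame_rate, source_id = path)
}

# Read one image file as an 8-bit RGB array (grayscale replicated, alpha
# dropped).
read_rgb_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read ", file)
      tiff::readTIFF(file)
    },
    stop("input error: unsupported image format: ", file))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Convert an 8-bit RGB frame to luminance
#'
#' ITU-R BT.601 luma weights, the standard for video-derived stills:
#' `(0.299 R + 0.587 G + 0.114 B) / 255`.
#'
#' @param frame `height x width x 3` array with values in 0..255.
#' @return luminance matrix with values in `[0, 1]`.
#' @export
to_grayscale <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  (0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]) / 255
}

#' Construct a ground-truth annotation
#'
#' @param keyframe_indices 0-based frame indices judged diagnostically
#'   important (sorted and deduplicated).
#' @param n_frames sequence length the indices must respect, or `NULL` to
#'   skip validation.
#' @return an object of class `GroundTruth` with fields `keyframe_indices`
#'   and `total_keyframes`.
#' @export
ground_truth <- function(keyframe_indices, n_frames = NULL) {
  idx <- sort(unique(as.integer(keyframe_indices)))
  if (length(idx) > 0 && any(idx < 0))
    stop("ground-truth indices must be non-negative (0-based)")
  if (!is.null(n_frames) && length(idx) > 0 && any(idx >= n_frames))
    stop("validation error: ground-truth indices out of range (>= ",
         n_frames, "): ", paste(idx[idx >= n_frames], collapse = ", "))
  structure(list(keyframe_indices = idx, total_keyframes = length(idx)),
            class = "GroundTruth")
}

#' Read a ground-truth annotation file
#'
#' Accepts either plain text with one 0-based frame index per line or a JSON
#' array of indices. Indices are deduplicated, sorted, and validated against
#' the sequence length.
#'
#' @param path annotation file.
#' @param n_frames number of frames in the annotated sequence.
#' @return a [ground_truth()].
#' @export
read_ground_truth <- function(path, n_frames) {
  if (!file.exists(path)) stop("input error: no such annotation file: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  if (length(txt) == 0) return(ground_truth(integer(0), n_frames))
  idx <- if (grepl("^\\[", txt[1])) {
    as.integer(jsonlite::fromJSON(paste(txt, collapse = "\n")))
  } else {
    v <- suppressWarnings(as.integer(txt))
    if (any(is.na(v)))
      stop("input error: non-integer annotation lines in ", path)
    v
  }
  ground_truth(idx, n_frames)
}

#' Write selected keyframes as PNG files
#'
#' Each keyframe is written as `frame_NNNNNN.png` (zero-padded 0-based frame
#' index) under `outdir`; a manifest mapping index to filename is returned
#' and written as `keyframes.json`.
#'
#' @param seq a `FrameSequence`.
#' @param keys a `KeyframeSet` or an integer vector of 0-based frame indices.
#' @param outdir output directory (created if missing).
#' @return invisibly, a data frame with columns `index` and `file`.
#' @export
write_keyframes <- function(seq, keys, outdir) {
  stopifnot(inherits(seq, "FrameSequence"))
  idx <- if (inherits(keys, "KeyframeSet")) keys$indices else as.integer(keys)
  n <- length(seq$frames)
  if (length(idx) > 0 && (any(idx < 0) || any(idx >= n)))
    stop("keyframe indices out of range for a ", n, "-frame sequence: ",
         paste(idx[idx < 0 | idx >= n], collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("I/O error: cannot create ", outdir)
  files <- sprintf("frame_%06d.png", idx)
  for (i in seq_along(idx)) {
    png::writePNG(seq$frames[[idx[i] + 1L]] / 255,
                  file.path(outdir, files[i]))
  }
  manifest <- data.frame(index = idx, file = files,
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "keyframes.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Write a frame sequence as a directory of PNG files
#'
#' @param seq a `FrameSequence`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_frames <- function(seq, outdir) {
  stopifnot(inherits(seq, "FrameSequence"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("I/O error: cannot create ", outdir)
  paths <- file.path(outdir,
                     sprintf("frame_%06d.png", seq_along(seq$frames) - 1L))
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}
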