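# Independent brute-force oracles used to pin down the saliency operators
# and the extraction/evaluation rules. These deliberately share nothing with
# the package implementation beyond the stated contracts (reflective
# borders, bin rule, tie-break order).

# symmetric (edge-including) mirror index into 1..n
reflect_idx <- function(i, n) {
  # period-2n sawtooth: ... 2 1 1 2 ... n n n-1 ...
  j <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

oracle_entropy <- function(gray, window, gray_levels) {
  r <- (window - 1) %/% 2
  nr <- nrow(gray); nc <- ncol(gray)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- numeric(0)
      for (dy in (-r):r) {
        for (dx in (-r):r) {
          vals <- c(vals, gray[reflect_idx(i + dy, nr), reflect_idx(j + dx, nc)])
        }
      }
      b <- pmin(floor(vals * gray_levels), gray_levels - 1)
      p <- table(b) / length(b)
      out[i, j] <- -sum(p * log2(p)) / log2(gray_levels)
    }
  }
  out
}

oracle_contrast <- function(frame, window) {
  r <- (window - 1) %/% 2
  nr <- nrow(frame); nc <- ncol(frame)
  scale <- if (max(frame) > 1) 255 else 1
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (ch in 1:3) {
        v <- frame[i, j, ch] / scale
        for (dy in (-r):r) {
          for (dx in (-r):r) {
            if (dy == 0 && dx == 0) next
            q <- frame[reflect_idx(i + dy, nr), reflect_idx(j + dx, nc), ch] / scale
            acc <- acc + (v - q)^2
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Exhaustive SAD block search; returns per-pixel dx, dy matrices.
oracle_block_match <- function(prev, cur, block, radius) {
  nr <- nrow(cur); nc <- ncol(cur)
  fdx <- matrix(0L, nr, nc); fdy <- matrix(0L, nr, nc)
  prev_at <- function(i, j) prev[reflect_idx(i, nr), reflect_idx(j, nc)]
  for (bi in seq(1, nr, by = block)) {
    for (bj in seq(1, nc, by = block)) {
      rows <- bi:min(bi + block - 1, nr)
      cols <- bj:min(bj + block - 1, nc)
      best <- NULL
      for (dy in (-radius):radius) {
        for (dx in (-radius):radius) {
          sad <- 0
          for (i in rows) for (j in cols)
            sad <- sad + abs(cur[i, j] - prev_at(i - dy, j - dx))
          key <- c(sad, dx^2 + dy^2, dy, dx)
          if (is.null(best) || lex_less(key, best$key))
            best <- list(key = key, dx = dx, dy = dy)
        }
      }
      fdx[rows, cols] <- as.integer(best$dx)
      fdy[rows, cols] <- as.integer(best$dy)
    }
  }
  list(dx = fdx, dy = fdy)
}

lex_less <- function(a, b, tol = 1e-9) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - tol) return(TRUE)
    if (a[k] > b[k] + tol) return(FALSE)
  }
  FALSE
}

# nested-loop recomputation of the NKF rule
oracle_nkf <- function(values, nkf) {
  n <- length(values)
  k <- min(nkf, n)
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0) sizes[1:extra] <- sizes[1:extra] + 1
  out <- integer(0); pos <- 1
  for (s in sizes) {
    best <- pos
    for (t in pos:(pos + s - 1)) if (values[t] > values[best]) best <- t
    out <- c(out, as.integer(best) - 1L)  # 0-based
    pos <- pos + s
  }
  out
}

# brute-force maximum one-to-one matching size within +/- tolerance
oracle_optimal_matching <- function(ext, tru, tol) {
  ext <- sort(unique(ext)); tru <- sort(unique(tru))
  recurse <- function(ti, used) {
    if (ti > length(tru)) return(0L)
    best <- recurse(ti + 1L, used)  # leave tru[ti] unmatched
    for (e in seq_along(ext)) {
      if (!used[e] && abs(ext[e] - tru[ti]) <= tol) {
        used[e] <- TRUE
        best <- max(best, 1L + recurse(ti + 1L, used))
        used[e] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(length(ext)))
}

# deterministic random RGB frame (integer 0..255)
random_frame <- function(nr, nc) {
  arr <- array(sample(0:255, nr * nc * 3, replace = TRUE), c(nr, nc, 3))
  storage.mode(arr) <- "integer"
  arr
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  arr <- round(img[, , 1:3, drop = FALSE] * 255)
  storage.mode(arr) <- "integer"
  arr
}

MODEL_TAGS_FOR_TEST <- c("MS", "TS", "MSCM", "CM")
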