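# The four saliency operators against independent brute-force oracles and
# their analytic special cases.

test_that("block-matching motion field matches the exhaustive SAD oracle", {
  set.seed(101)
  for (rep in 1:12) {
    nr <- sample(6:15, 1); nc <- sample(6:15, 1)
    prev <- matrix(sample(0:255, nr * nc, TRUE) / 255, nr, nc)
    cur <- matrix(sample(0:255, nr * nc, TRUE) / 255, nr, nc)
    b <- sample(c(3, 4, 5), 1); r <- sample(2:4, 1)
    p <- operator_params(block_size = b, search_radius = r)
    field <- estimate_motion_field(prev, cur, p)
    orc <- oracle_block_match(prev, cur, b, r)
    expect_identical(field$dx, orc$dx)
    expect_identical(field$dy, orc$dy)
  }
})

test_that("motion field recovers a known periodic translation of (3, 4)", {
  set.seed(5)
  n <- 32
  prev <- matrix(sample(0:255, n * n, TRUE) / 255, n, n)
  # cur(x, y) = prev(x - 3, y - 4), periodic wrap
  cur <- prev[((seq_len(n) - 1 - 4) %% n) + 1, ((seq_len(n) - 1 - 3) %% n) + 1]
  p <- operator_params(block_size = 8, search_radius = 8)
  field <- estimate_motion_field(prev, cur, p)
  # interior blocks (source region untouched by wrap seam or padding)
  interior_r <- 9:24; interior_c <- 9:24
  expect_true(all(field$dx[interior_r, interior_c] == 3))
  expect_true(all(field$dy[interior_r, interior_c] == 4))
  ms <- motion_saliency(field)
  expect_true(all(ms$values[interior_r, interior_c] == 5))
})

test_that("motion degenerates correctly: identical and constant frames", {
  g <- matrix(runif(100), 10, 10)
  f <- estimate_motion_field(g, g, operator_params(block_size = 4, search_radius = 3))
  expect_true(all(f$dx == 0) && all(f$dy == 0))
  cst <- matrix(0.5, 12, 12)
  f2 <- estimate_motion_field(cst, cst, operator_params(block_size = 4, search_radius = 3))
  expect_true(all(f2$dx == 0) && all(f2$dy == 0))  # tie-break: zero magnitude
  expect_error(estimate_motion_field(matrix(0, 4, 4), matrix(0, 5, 5)),
               "differ in dimensions")
})

test_that("motion saliency is displacement magnitude and dx/dy symmetric", {
  f <- structure(list(dx = matrix(3, 2, 2), dy = matrix(4, 2, 2)),
                 class = "MotionField")
  expect_equal(motion_saliency(f)$values, matrix(5, 2, 2))
  fs <- structure(list(dx = f$dy, dy = f$dx), class = "MotionField")
  expect_equal(motion_saliency(fs)$values, motion_saliency(f)$values)
})

test_that("local entropy matches the per-pixel histogram oracle exactly", {
  set.seed(202)
  for (rep in 1:10) {
    nr <- sample(5:15, 1); nc <- sample(5:15, 1)
    gray <- matrix(sample(0:255, nr * nc, TRUE) / 255, nr, nc)
    w <- sample(c(3, 5, 7), 1)
    gl <- sample(c(8, 64, 256), 1)
    p <- operator_params(entropy_window = w, gray_levels = gl)
    expect_equal(local_entropy(gray, p), oracle_entropy(gray, w, gl),
                 tolerance = 1e-12)
  }
})

test_that("entropy analytic cases: constant frame and two-level checkerboard", {
  p <- operator_params(entropy_window = 11, gray_levels = 256)
  expect_equal(local_entropy(matrix(0.37, 20, 20), p), matrix(0, 20, 20))
  # checkerboard of two gray levels: a near-even two-bin histogram; with an
  # 11x11 window the split is 61/60, entropy a hair under 1 bit = 1/8 after
  # normalization by log2(256)
  cb <- matrix(rep_len(c(0.3, 0.7), 21 * 21), 21, 21)
  ent <- local_entropy(cb, p)
  h_exact <- -(61 / 121) * log2(61 / 121) - (60 / 121) * log2(60 / 121)
  expect_equal(ent[11, 11], h_exact / 8, tolerance = 1e-12)
  expect_lt(abs(ent[11, 11] - 1 / 8), 1e-4)
})

test_that("texture saliency segments a noisy disk and fills mask holes", {
  # frame: flat pink except a disk of full-range noise
  set.seed(33)
  n <- 48
  arr <- array(0, c(n, n, 3))
  base <- c(0.8, 0.45, 0.5)
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disk <- (yy - 24)^2 + (xx - 24)^2 <= 14^2
  u <- runif(sum(disk))
  for (c in 1:3) {
    ch <- matrix(base[c], n, n)
    ch[disk] <- u
    arr[, , c] <- ch
  }
  frame <- round(arr * 255); storage.mode(frame) <- "integer"
  ts <- texture_saliency(frame, operator_params())
  # mask concentrates on the disk: high recall inside an eroded disk core,
  # nothing outside the dilated disk
  core <- (yy - 24)^2 + (xx - 24)^2 <= 6^2
  outside <- (yy - 24)^2 + (xx - 24)^2 > 22^2
  expect_gt(mean(ts$mask[core]), 0.95)
  expect_lt(mean(ts$mask[outside]), 0.05)
  expect_equal(ts$injurious_fraction, mean(ts$mask))
  # TS map equals luminance under the mask, zero elsewhere
  gray <- to_grayscale(frame)
  expect_equal(ts$map$values, gray * ts$mask)

  # constant frame: empty mask, zero fraction
  flat <- array(128L, c(32, 32, 3))
  ts0 <- texture_saliency(flat, operator_params())
  expect_equal(ts0$injurious_fraction, 0)
  expect_true(all(ts0$map$values == 0))
})

test_that("mask cleanup fills a ring into a disk", {
  n <- 31
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  d2 <- (yy - 16)^2 + (xx - 16)^2
  ring <- matrix(as.numeric(d2 <= 12^2 & d2 >= 8^2), n, n)
  filled <- keysal:::clean_mask(ring, closing_radius = 2)
  inner <- d2 <= 6^2
  expect_true(all(filled[inner] == 1))
})

test_that("single-scale contrast matches the nested-loop oracle", {
  set.seed(303)
  for (rep in 1:10) {
    nr <- sample(5:15, 1); nc <- sample(5:15, 1)
    frame <- random_frame(nr, nc)
    w <- sample(c(3, 5), 1)
    p <- operator_params(contrast_neighborhood = w)
    expect_equal(contrast_map_at_scale(frame, p), oracle_contrast(frame, w),
                 tolerance = 1e-10)
  }
})

test_that("contrast analytic cases: constant image and single white pixel", {
  p <- operator_params()
  flat <- array(77L, c(9, 9, 3))
  expect_equal(contrast_map_at_scale(flat, p), matrix(0, 9, 9))
  one <- array(0L, c(9, 9, 3)); one[5, 5, ] <- 255L
  cm <- contrast_map_at_scale(one, p)
  expect_equal(cm[5, 5], 72)  # 3 channels x 24 neighbors x 1^2
})

test_that("multi-scale contrast composes pyramid levels correctly", {
  set.seed(404)
  frame <- random_frame(16, 16)
  p1 <- operator_params(pyramid_levels = 1)
  expect_equal(multiscale_contrast(frame, p1)$values,
               contrast_map_at_scale(frame, p1))
  # two-level case against an independently composed reference
  p2 <- operator_params(pyramid_levels = 2)
  lvl2 <- keysal:::pyramid_down(frame)
  ref <- contrast_map_at_scale(frame, p1) +
    keysal:::bilinear_resize(oracle_contrast(lvl2, 5), 16, 16)
  expect_equal(multiscale_contrast(frame, p2)$values, ref, tolerance = 1e-10)
  # constant frame stays zero at any depth
  flat <- array(100L, c(32, 32, 3))
  expect_true(all(multiscale_contrast(flat, operator_params())$values == 0))
  # too-small frame for the requested pyramid
  expect_error(multiscale_contrast(random_frame(8, 8), operator_params()),
               "too small")
})

test_that("curvature map vanishes on flat and linear images", {
  p <- operator_params()
  expect_equal(curvature_map(matrix(0.4, 16, 16), p)$values,
               matrix(0, 16, 16))
  ramp <- outer(seq(0, 0.5, length.out = 20), seq(0, 0.4, length.out = 20), "+")
  cm <- curvature_map(ramp, p)$values
  # second derivatives of a plane vanish away from the reflected border
  expect_lt(max(cm[8:13, 8:13]), 1e-10)
})

test_that("curvature map commutes with 90-degree rotation on a smooth blob", {
  n <- 33
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  blob <- exp(-((yy - 14)^2 + (xx - 19)^2) / (2 * 4^2))  # off-center
  p <- operator_params(sigma = 1.5)
  m_rot <- curvature_map(rot90cw(blob), p)$values
  rot_m <- rot90cw(curvature_map(blob, p)$values)
  interior <- 5:(n - 4)
  a <- m_rot[interior, interior]; b <- rot_m[interior, interior]
  expect_lt(max(abs(a - b)) / max(abs(b)), 0.05)
})

test_that("all operators produce finite non-negative maps on random input", {
  set.seed(505)
  p <- operator_params(block_size = 4, search_radius = 2, entropy_window = 5,
                       pyramid_levels = 2, contrast_neighborhood = 3)
  for (rep in 1:5) {
    f1 <- random_frame(12, 12); f2 <- random_frame(12, 12)
    g1 <- to_grayscale(f1); g2 <- to_grayscale(f2)
    maps <- list(
      motion_saliency(estimate_motion_field(g1, g2, p))$values,
      local_entropy(g2, p),
      texture_saliency(f2, p)$map$values,
      multiscale_contrast(f2, p)$values,
      curvature_map(g2, p)$values)
    for (m in maps) {
      expect_true(all(is.finite(m)))
      expect_true(all(m >= 0))
    }
  }
})
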