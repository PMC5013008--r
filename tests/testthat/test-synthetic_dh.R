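# The synthetic DH-video generator: construction contract, determinism, and
# the statistical structure the saliency operators are meant to recover.

test_that("generator honors the construction contract", {
  spec <- synthetic_spec(n_frames = 60, n_events = 3, dwell_length = 10,
                         seed = 7)
  gen <- synth_generate(spec)
  expect_length(gen$seq$frames, 60)
  expect_identical(frame_dims(gen$seq), c(64L, 64L))
  expect_identical(gen$truth$total_keyframes, 3L)
  d <- gen$segments$dwells
  expect_identical(nrow(d), 3L)
  # one ground-truth index inside each dwell window
  for (e in 1:3) {
    expect_gte(gen$truth$keyframe_indices[e], d$start[e])
    expect_lte(gen$truth$keyframe_indices[e], d$end[e])
    expect_identical(d$gt_index[e], d$start[e] + (10L - 1L) %/% 2L)
  }
})

test_that("generation is bit-identical for a fixed spec and seed", {
  spec <- synthetic_spec(n_frames = 20, n_events = 2, dwell_length = 5,
                         seed = 123)
  a <- synth_generate(spec)
  b <- synth_generate(spec)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth$keyframe_indices, b$truth$keyframe_indices)
  c <- synth_generate(synthetic_spec(n_frames = 20, n_events = 2,
                                     dwell_length = 5, seed = 124))
  expect_false(identical(a$seq$frames, c$seq$frames))
})

test_that("segment description matches the generated video", {
  spec <- synthetic_spec(n_frames = 60, n_events = 3, dwell_length = 10,
                         seed = 7)
  seg <- synth_describe(spec)
  expect_identical(sum(seg$frames$label == "dwell"), 30L)
  expect_identical(seg$frames$label,
                   synth_generate(spec)$segments$frames$label)

  no_glare <- synthetic_spec(n_frames = 30, n_events = 2, dwell_length = 5,
                             glare_fraction = 0, seed = 1)
  expect_identical(sum(synth_describe(no_glare)$frames$label == "contaminated"), 0L)

  tiny <- synthetic_spec(n_frames = 1, n_events = 1, dwell_length = 1,
                         seed = 1)
  expect_identical(synth_describe(tiny)$frames$label, "dwell")
})

test_that("degenerate and invalid specs are handled", {
  none <- synth_generate(synthetic_spec(n_frames = 12, n_events = 0, seed = 2))
  expect_identical(none$truth$total_keyframes, 0L)
  expect_length(none$seq$frames, 12)
  expect_error(synthetic_spec(n_frames = 20, n_events = 3, dwell_length = 10),
               "exceeds n_frames")
  expect_error(synthetic_spec(glare_fraction = 1.5), "glare_fraction")
})

test_that("planted structure is recoverable: motion, entropy, and texture", {
  spec <- synthetic_spec(seed = 11)
  gen <- synth_generate(spec)
  lab <- gen$segments$frames$label
  p <- operator_params()

  # camera-path displacement: slower inside dwells than on pans
  raw <- saliency_scores(gen$seq, p, models = c("MS", "TS"))
  ms_dwell <- mean(raw$MS[lab == "dwell"])
  ms_pan <- mean(raw$MS[lab != "dwell"][-1])  # first frame has no motion
  expect_lt(ms_dwell, ms_pan)

  # texture: injurious fraction higher on lesion (dwell) frames
  expect_gt(mean(raw$TS[lab == "dwell"]), mean(raw$TS[lab != "dwell"]))

  # entropy inside the lesion exceeds the background on a dwell frame
  gt1 <- gen$truth$keyframe_indices[1] + 1L
  gray <- to_grayscale(gen$seq$frames[[gt1]])
  ent <- local_entropy(gray, p)
  h <- nrow(ent); w <- ncol(ent)
  center <- ent[(h %/% 2 - 8):(h %/% 2 + 8), (w %/% 2 - 8):(w %/% 2 + 8)]
  # background reference: a pan frame far from any lesion, same ring of the
  # visible field
  pan_far <- which(lab == "fast_pan")[1]
  ent_pan <- local_entropy(to_grayscale(gen$seq$frames[[pan_far]]), p)
  center_pan <- ent_pan[(h %/% 2 - 8):(h %/% 2 + 8), (w %/% 2 - 8):(w %/% 2 + 8)]
  expect_gt(mean(center), mean(center_pan))
})
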