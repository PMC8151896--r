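test_that("zero-amplitude spec yields a constant standing pose with zero acceleration", {
  spec <- activity_spec("still", period = 1, joint_amplitude = c(l_thigh = 0),
                        noise_sd = 0, duration = 120, seed = 5)
  seg <- generate_activity(spec)
  for (b in c("pelvis", "l_thigh", "head")) {
    r <- bone_rot(seg, b)
    expect_equal(max(abs(sweep(r, 2L, r[1L, ]))), 0)
    expect_equal(max(abs(bone_acc(seg, b))), 0)
  }
})

test_that("phase-coupled bones with zero offset and zero noise move identically", {
  spec <- activity_spec("twin", period = 1,
                        joint_amplitude = c(l_thigh = 25, r_thigh = 25),
                        phase_coupling = list(c("l_thigh", "r_thigh", 0)),
                        noise_sd = 0, duration = 200, seed = 2)
  seg <- generate_activity(spec)
  expect_equal(unname(bone_rot(seg, "l_thigh")), unname(bone_rot(seg, "r_thigh")),
               tolerance = 1e-12)
})

test_that("generation is deterministic in the seed and emits valid rotations", {
  spec <- example_activity_specs(300)$trunk
  spec$seed <- 77L
  a <- generate_activity(spec)
  b <- generate_activity(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (bn in c("spine1", "head", "l_foot")) {
    expect_true(all(rot_valid(bone_rot(a, bn), tol = 1e-9)))
  }
})

test_that("corpus bookkeeping: repeats, labels and segment seeds", {
  specs <- example_activity_specs(150)
  corpus <- generate_corpus(specs, repeats = c(walk = 5, arms = 2, trunk = 1), seed = 3)
  segs <- segments_summary(corpus)
  expect_equal(nrow(segs), 8L)
  expect_equal(sum(segs$activity == "walk"), 5L)
  expect_equal(sum(segs$activity == "arms"), 2L)
  # repeats of the same activity differ (different derived seeds)
  w1 <- corpus[corpus$segment_id == "walk_01", ]
  w2 <- corpus[corpus$segment_id == "walk_02", ]
  expect_gt(max(abs(bone_rot(w1, "l_thigh") - bone_rot(w2, "l_thigh"))), 1e-4)
  # full determinism of the corpus
  corpus2 <- generate_corpus(specs, repeats = c(walk = 5, arms = 2, trunk = 1), seed = 3)
  expect_identical(as.data.frame(corpus), as.data.frame(corpus2))
})

test_that("reference generation guards its minimum length and is reproducible", {
  spec <- example_activity_specs(600)$walk
  expect_error(generate_reference(spec, 200), "300")
  r1 <- generate_reference(spec, 400, seed = 9)
  r2 <- generate_reference(spec, 400, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 400L)
})

test_that("reference and corpus realizations of one activity share their marginals", {
  spec <- example_activity_specs(10000)$walk
  corpus_seg <- normalize_frames(generate_activity({s <- spec; s$seed <- 11L; s}))
  ref_seg <- normalize_frames(generate_activity({s <- spec; s$seed <- 429L; s}))
  fc <- extract_features(corpus_seg)
  fr <- extract_features(ref_seg)
  keep <- apply(fc, 2L, stats::sd) > 1e-9 & apply(fr, 2L, stats::sd) > 1e-9
  pooled <- rbind(fc[, keep], fr[, keep])
  edges <- t(vapply(seq_len(ncol(pooled)), function(i)
    seq(min(pooled[, i]), max(pooled[, i]), length.out = 21L), numeric(21L)))
  P <- fit_histogram(fr[, keep], bin_edges = edges)
  Q <- fit_histogram(fc[, keep], bin_edges = edges)
  expect_lt(kl_distance(P, Q), 0.05)
})

test_that("coupled bone pairs carry more mutual information than independent pairs", {
  spec <- activity_spec("mi", period = NULL,
                        joint_amplitude = c(l_thigh = 20, r_thigh = 20, head = 20),
                        phase_coupling = list(c("l_thigh", "r_thigh", 0.4)),
                        noise_sd = 5, duration = 5000, seed = 31)
  seg <- normalize_frames(generate_activity(spec))
  a1 <- rotation_to_axis_angle(bone_rot(seg, "l_thigh"))[, 1L]
  a2 <- rotation_to_axis_angle(bone_rot(seg, "r_thigh"))[, 1L]
  a3 <- rotation_to_axis_angle(bone_rot(seg, "head"))[, 2L]
  expect_gt(binned_mi(a1, a2), binned_mi(a1, a3))
})
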