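test_that("feature extraction has the right shape and content", {
  seg <- normalize_frames(generate_activity(example_activity_specs(120)$walk))
  f6 <- extract_features(seg, bones = c("l_thigh", "r_thigh", "l_shank",
                                        "r_shank", "head", "spine1"))
  expect_equal(dim(f6), c(120L, 36L))
  f_all <- extract_features(seg)
  expect_equal(ncol(f_all), 6L * 20L)  # all non-root bones

  # static standing frame: rest-pose orientations (identity) and zero accel
  still <- normalize_frames(generate_activity(
    activity_spec("still", period = 1, joint_amplitude = c(l_thigh = 0),
                  noise_sd = 0, duration = 60, seed = 1)))
  expect_equal(max(abs(extract_features(still))), 0)

  # features recover the constructed joint angle of a driven bone: the
  # l_thigh rotates about the skeleton's x axis by the spec amplitude
  aa <- rotation_to_axis_angle(bone_rot(seg, "l_thigh"))
  expect_equal(f_all[, "l_thigh.aa1"], aa[, 1L])
  expect_gt(max(abs(aa[, 1L])), 20 * pi / 180)  # reaches most of the 30 deg amplitude

  # unnormalized frames (moving root) are rejected
  heading <- activity_spec("turn", period = 1,
                           joint_amplitude = c(pelvis = 20, l_thigh = 20),
                           noise_sd = 0, duration = 60, seed = 2)
  expect_error(extract_features(generate_activity(heading)), "normalized")
})

test_that("unit splitting drops remainders and counts windows exactly", {
  sk <- default_skeleton()
  specs <- example_activity_specs(500)
  long <- generate_activity(specs$walk, segment_id = "long")
  short <- generate_activity({s <- specs$arms; s$duration <- 300L; s}, segment_id = "short")
  tiny <- generate_activity({s <- specs$trunk; s$duration <- 49L; s}, segment_id = "tiny")
  data <- normalize_frames(mocapselect:::new_motion_tbl(
    dplyr::bind_rows(long, short, tiny), sk))
  units <- split_into_units(data, selection_config())
  expect_equal(sum(units$segment_id == "long"), 10L)
  expect_equal(sum(units$segment_id == "short"), 6L)
  expect_equal(sum(units$segment_id == "tiny"), 0L)
  expect_equal(nrow(units), 16L)
  expect_true(all(units$length == 50L))
  # a 120-frame segment yields 2 units starting at frames 1 and 51
  u120 <- split_into_units(normalize_frames(generate_activity(
    {s <- specs$walk; s$duration <- 120L; s})), selection_config())
  expect_equal(u120$start, c(1L, 51L))
})

test_that("unit cosine similarity hits its closed-form anchors", {
  set.seed(5)
  u <- matrix(stats::rnorm(50 * 12), 50, 12)
  expect_equal(unit_similarity(u, u), 1)
  expect_equal(unit_similarity(u, -u), -1)
  # frame-wise orthogonal by construction: disjoint nonzero channels
  v <- cbind(matrix(0, 50, 6), u[, 1:6])
  w <- cbind(u[, 7:12], matrix(0, 50, 6))
  expect_equal(unit_similarity(v, w), 0)
  expect_error(unit_similarity(u, u[1:10, ]), "equal")
  u0 <- u; u0[1, ] <- 0
  expect_warning(sim <- unit_similarity(u0, u), "zero-norm")
  expect_equal(sim, mean(c(0, rowSums(mocapselect:::unit_row_normalize(u[-1, ], warn = FALSE) *
                                        mocapselect:::unit_row_normalize(u[-1, ], warn = FALSE)))))
})

test_that("similarity screening keeps same-activity units and enforces the run floor", {
  corpus <- normalize_frames(small_corpus(seed = 1))
  ref <- normalize_frames(walk_reference(seed = 99))
  cfg <- selection_config()
  cu <- split_into_units(corpus, cfg)
  ru <- split_into_units(ref, cfg)
  sel <- select_similar(cu, ru, cfg)
  segs <- segments_summary(corpus)
  walk_ids <- segs$segment_id[segs$activity == "walk"]
  # every selected piece lies in a walk segment and all walk frames survive
  expect_true(all(sel$segment_id %in% walk_ids))
  expect_equal(sum(sel$length), sum(segs$n_frames[segs$activity == "walk"]))

  # cross-activity frame similarity is genuinely low
  eta <- attr(sel, "eta_max")
  arm_units <- cu$segment_id %in% segs$segment_id[segs$activity != "walk"]
  expect_lt(max(eta[arm_units]), 0.5)

  # threshold floor -1 keeps everything, runs become whole segments
  cfg_all <- selection_config(similarity_threshold = -1)
  sel_all <- select_similar(cu, ru, cfg_all)
  expect_equal(sum(sel_all$length), sum(segs$n_frames %/% 50L * 50L))

  # runs shorter than min_run_length are discarded: 250 contiguous frames < 300
  cfg250 <- selection_config()
  cu250 <- split_into_units(normalize_frames(generate_activity(
    {s <- example_activity_specs(250)$walk; s$seed <- 5L; s})), cfg250)
  expect_error(select_similar(cu250, ru, cfg250), "min_run_length|no similar")
})

test_that("histograms are normalized, smoothed and anchored to closed forms", {
  set.seed(11)
  x <- matrix(stats::runif(20000), ncol = 1L)
  h <- fit_histogram(x, n_bins = 20L)
  expect_equal(rowSums(h$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(h$prob - 0.05) < 0.005))

  # all mass in one bin
  h1 <- fit_histogram(matrix(rep(0.5, 100)), bin_edges = matrix(seq(0, 1, 0.05), 1L))
  expect_gt(max(h1$prob), 0.999)
  expect_lt(sort(h1$prob, decreasing = TRUE)[2L], 1e-6)

  expect_warning(fit_histogram(matrix(rep(2, 50))), "constant")
})

test_that("KL divergence matches the hand-computed two-bin case and is asymmetric", {
  edges <- matrix(c(0, 0.5, 1), 1L)
  P <- fit_histogram(matrix(c(rep(0.25, 50), rep(0.75, 50))), bin_edges = edges)
  Q <- fit_histogram(matrix(c(rep(0.25, 25), rep(0.75, 75))), bin_edges = edges)
  # 0.5 ln(0.5/0.25) + 0.5 ln(0.5/0.75) = 0.143841...
  expect_equal(kl_distance(P, P), 0, tolerance = 1e-9)
  expect_equal(kl_distance(P, Q), 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-4)
  expect_equal(kl_distance(P, Q), 0.1438, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(kl_distance(P, Q), kl_distance(Q, P))))
  expect_error(kl_distance(P, fit_histogram(matrix(stats::runif(100)), n_bins = 20L)),
               "edges")
})

test_that("entropy and data-amount terms hit their closed forms", {
  uni <- structure(list(edges = matrix(seq(0, 1, 0.05), 1L),
                        prob = matrix(rep(0.05, 20L), 1L), n = 100L),
                   class = "feature_histogram")
  expect_equal(entropy_term(uni), log(20))
  point <- fit_histogram(matrix(rep(0.5, 1000)), bin_edges = matrix(seq(0, 1, 0.05), 1L))
  expect_lt(entropy_term(point), 1e-4)
  set.seed(3)
  h <- fit_histogram(matrix(stats::rnorm(500)), n_bins = 20L)
  expect_gte(entropy_term(h), 0)
  expect_lte(entropy_term(h), log(20))

  sel100 <- tibble::tibble(segment_id = "s", start = 1L, length = 100L)
  expect_equal(data_amount(sel100), log(100))
  sel2 <- tibble::tibble(segment_id = c("a", "b"), start = 1L, length = c(300L, 700L))
  expect_equal(data_amount(sel2), log(1000))
})

test_that("the selection objective decomposes as alpha*H - beta*KL - gamma*logN", {
  ref <- normalize_frames(walk_reference(seed = 7, n_frames = 600))
  cfg <- selection_config()
  feats <- extract_features(ref)
  keep_edges <- t(vapply(seq_len(ncol(feats)), function(i) {
    rng <- range(feats[, i]); if (rng[1] == rng[2]) rng <- rng + c(-1e-9, 1e-9)
    seq(rng[1], rng[2], length.out = 21L)
  }, numeric(21L)))
  ref_hist <- fit_histogram(feats, bin_edges = keep_edges, epsilon = cfg$epsilon)
  whole <- mocapselect:::new_selection(
    tibble::tibble(segment_id = ref$segment_id[1L], start = 1L, length = nrow(ref)), cfg)
  obj <- fds_objective(whole, ref, ref_hist, cfg)
  # selection = reference itself: KL term vanishes
  expect_equal(obj, entropy_term(ref_hist) - log(nrow(ref)), tolerance = 1e-9)

  # with alpha = beta = 0, duplicating content only pays the size penalty
  cfg0 <- selection_config(alpha = 0, beta = 0, gamma = 1)
  sk <- default_skeleton()
  twin <- normalize_frames(mocapselect:::new_motion_tbl(dplyr::bind_rows(
    generate_activity({s <- example_activity_specs(400)$walk; s$seed <- 3L; s}, segment_id = "c1"),
    generate_activity({s <- example_activity_specs(400)$walk; s$seed <- 3L; s}, segment_id = "c2")), sk))
  one <- mocapselect:::new_selection(tibble::tibble(segment_id = "c1", start = 1L, length = 400L), cfg0)
  two <- mocapselect:::new_selection(tibble::tibble(segment_id = c("c1", "c2"),
                                                    start = 1L, length = 400L), cfg0)
  o1 <- fds_objective(one, twin, ref_hist, cfg0)
  o2 <- fds_objective(two, twin, ref_hist, cfg0)
  expect_equal(o1 - o2, log(800) - log(400), tolerance = 1e-9)
})

test_that("greedy pruning removes off-distribution pieces first and traces monotonically", {
  corpus <- normalize_frames(small_corpus(seed = 21, duration = 400,
                                          repeats = c(walk = 2, arms = 1, trunk = 0)))
  ref <- normalize_frames(walk_reference(seed = 50, n_frames = 400, duration = 400))
  cfg <- selection_config()
  segs <- segments_summary(corpus)
  candidate <- mocapselect:::new_selection(
    tibble::tibble(segment_id = segs$segment_id, start = 1L, length = segs$n_frames), cfg)
  feats_ref <- extract_features(ref)
  feats_all <- extract_features(selected_frames(candidate, corpus))
  pooled <- rbind(feats_all, feats_ref)
  edges <- t(vapply(seq_len(ncol(pooled)), function(i) {
    rng <- range(pooled[, i]); if (rng[1] == rng[2]) rng <- rng + c(-1e-9, 1e-9)
    seq(rng[1], rng[2], length.out = 21L)
  }, numeric(21L)))
  ref_hist <- fit_histogram(feats_ref, bin_edges = edges, epsilon = cfg$epsilon)

  pruned <- greedy_prune(candidate, corpus, ref_hist, cfg)
  tr <- attr(pruned, "trace")
  expect_true(all(diff(tr$objective) > -1e-12))
  # the off-distribution (arms) piece goes first
  expect_equal(tr$removed_segment[2L], "arms_01")

  # a single piece cannot be pruned below the floor
  single <- candidate[1L, ]
  expect_equal(nrow(greedy_prune(single, corpus, ref_hist, cfg)), 1L)
})

test_that("greedy pruning matches the exhaustive subset oracle on small candidates", {
  agree <- 0L
  n_fix <- 8L
  for (s in seq_len(n_fix)) {
    corpus <- normalize_frames(small_corpus(seed = 100 + s, duration = 350,
                                            repeats = c(walk = 3, arms = 1, trunk = 1)))
    ref <- normalize_frames(walk_reference(seed = 300 + s, n_frames = 350, duration = 350))
    cfg <- selection_config()
    segs <- segments_summary(corpus)
    candidate <- mocapselect:::new_selection(
      tibble::tibble(segment_id = segs$segment_id, start = 1L, length = segs$n_frames), cfg)
    feats_ref <- extract_features(ref)
    pooled <- rbind(extract_features(selected_frames(candidate, corpus)), feats_ref)
    edges <- t(vapply(seq_len(ncol(pooled)), function(i) {
      rng <- range(pooled[, i]); if (rng[1] == rng[2]) rng <- rng + c(-1e-9, 1e-9)
      seq(rng[1], rng[2], length.out = 21L)
    }, numeric(21L)))
    ref_hist <- fit_histogram(feats_ref, bin_edges = edges, epsilon = cfg$epsilon)
    g <- greedy_prune(candidate, corpus, ref_hist, cfg)
    e <- exhaustive_prune(candidate, corpus, ref_hist, cfg)
    g_obj <- attr(g, "trace")$objective[nrow(attr(g, "trace"))]
    if (isTRUE(all.equal(sort(paste(g$segment_id, g$start)),
                         sort(paste(e$segment_id, e$start))))) agree <- agree + 1L
    expect_lte(g_obj, attr(e, "objective") + 1e-9)
  }
  expect_gte(agree, ceiling(0.75 * n_fix))
})

test_that("the full selection pipeline recovers the reference activity and shrinks monotonically", {
  corpus <- small_corpus(seed = 17)
  ref <- walk_reference(seed = 23)
  sel <- suppressMessages(select_training_data(corpus, ref))
  sizes <- attr(sel, "sizes")
  expect_lte(sizes["selected"], sizes["similar"])
  expect_lte(sizes["similar"], sizes["corpus"])
  lab <- segments_summary(corpus)
  sel_act <- lab$activity[match(sel$segment_id, lab$segment_id)]
  expect_gte(sum(sel$length[sel_act == "walk"]) / sum(sel$length), 0.9)

  # determinism
  sel2 <- suppressMessages(select_training_data(corpus, ref))
  expect_identical(tidy(sel), tidy(sel2))

  expect_error(suppressMessages(select_training_data(corpus[0, ], ref)), "empty")
})
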