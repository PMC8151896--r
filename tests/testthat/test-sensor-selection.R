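test_that("MIC behaves on functional, independent and degenerate pairs", {
  set.seed(1)
  x <- stats::runif(200)
  expect_gte(mic(x, x), 0.99)
  expect_gte(mic(x, 2 * x - 1), 0.99)    # linear map, noiseless
  y <- sin(2 * pi * x)                   # nonlinear functional relationship
  expect_gt(mic(x, y), 0.8)

  for (i in 1:5) {
    a <- stats::runif(500); b <- stats::runif(500)
    v <- mic(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lt(v, 0.35)
    expect_identical(mic(a, b), mic(b, a))
  }

  expect_warning(v0 <- mic(rep(1, 100), stats::runif(100)), "constant")
  expect_equal(v0, 0)
  expect_error(mic(stats::runif(30), stats::runif(29)), "length")
  expect_error(mic(stats::runif(10), stats::runif(10)), "20")
})

test_that("the dynamic-programming search is bounded by the exhaustive oracle", {
  set.seed(8)
  cfg_ex <- mic_config(estimator = "exhaustive_small")
  for (i in 1:5) {
    x <- stats::runif(24)
    y <- if (i %% 2) x + stats::rnorm(24, sd = 0.2) else stats::runif(24)
    dp <- mic(x, y)
    ex <- mic(x, y, cfg_ex)
    expect_lte(dp, ex + 1e-9)
  }
})

test_that("independent noise cannot increase MIC (data-processing sanity)", {
  set.seed(14)
  x <- stats::runif(400)
  y <- sin(2 * pi * x)
  clean <- mic(x, y)
  noisy <- vapply(1:20, function(i) mic(x, y + stats::rnorm(400, sd = 0.5)), 0)
  expect_lt(stats::median(noisy), clean)
})

test_that("relevance reflects coupling and respects its bounds", {
  spec <- activity_spec("rel", period = NULL,
                        joint_amplitude = c(l_thigh = 20, r_thigh = 20, head = 20),
                        phase_coupling = list(c("l_thigh", "r_thigh", 0.3)),
                        noise_sd = 2, duration = 1200, seed = 4)
  seg <- normalize_frames(generate_activity(spec))
  r_self <- relevance("l_thigh", "l_thigh", seg, max_frames = 400)
  f <- extract_features(seg, "l_thigh")
  n_var <- sum(apply(f[seq(1, nrow(f), length.out = 400), ], 2L, stats::sd) > 0)
  expect_gte(r_self, n_var * 0.99)  # each varying feature matches itself
  expect_lte(r_self, 36)
  r_coupled <- relevance("l_thigh", "r_thigh", seg, max_frames = 400)
  r_indep <- relevance("l_thigh", "head", seg, max_frames = 400)
  expect_gt(r_coupled, r_indep)
})

test_that("group scores match hand arithmetic on a printed 3-sensor toy matrix", {
  rel <- matrix(c(4, 2, 1,
                  2, 5, 3,
                  1, 3, 6), 3, 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # |S| = |C| = 1: the single entry
  expect_equal(group_relevance_T("a", "c", rel), 1)
  # hand-summed: S = {a, b}, C = {c}: (1 + 3) / (2 * 1) = 2
  expect_equal(group_relevance_T(c("a", "b"), "c", rel), 2)
  # R over {a, b}: (4 + 2 + 2 + 5) / 4 = 3.25 (self-pairs included as printed)
  expect_equal(group_redundancy_R(c("a", "b"), rel), 3.25)
  expect_equal(phi(c("a", "b"), "c", rel), 2 - 3.25)
  expect_equal(group_redundancy_R("a", rel), 4)
  # constant matrix: T = r and phi = 0
  relc <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(group_relevance_T(c("a", "b"), "c", relc), 2)
  expect_equal(phi(c("a", "b"), "c", relc), 0)
  # empty C
  expect_equal(group_relevance_T(c("a", "b", "c"), character(0), rel), 0)
})

test_that("a duplicated sensor raises redundancy and lowers phi", {
  # "dup" carries exactly the channels of "a": relevance pattern identical
  rel <- matrix(c(4, 1, 1, 4,
                  1, 5, 2, 1,
                  1, 2, 6, 1,
                  4, 1, 1, 4), 4, 4, byrow = TRUE,
                dimnames = list(c("a", "b", "c", "dup"), c("a", "b", "c", "dup")))
  R_dup <- group_redundancy_R(c("a", "dup"), rel)
  R_ind <- group_redundancy_R(c("a", "b"), rel)
  expect_gt(R_dup, R_ind)
  expect_lt(phi(c("a", "dup"), c("b", "c"), rel), phi(c("a", "b"), c("c", "dup"), rel))
})

test_that("greedy placement forces the root, finds the hub and traces phi", {
  hs <- hub_activity_spec()
  hs$seed <- 21L
  seg <- normalize_frames(generate_activity(hs))
  bones <- c("pelvis", "spine4", "head", "l_hand", "r_hand", "l_foot", "r_foot")
  rel <- relevance_matrix(seg, bones = bones, max_frames = 500)
  g <- greedy_select(NULL, k = 4, rel = rel, root = "pelvis")
  expect_equal(g$selected[1L], "pelvis")
  expect_equal(g$selected[2L], "spine4")  # the hub drives five followers
  expect_equal(nrow(g$trace), 3L)
  expect_true(all(c("T", "R", "phi") %in% names(g$trace)))

  # k spanning the whole candidate set: C empty, phi = -R
  g_all <- greedy_select(NULL, k = length(bones), rel = rel, root = "pelvis")
  expect_setequal(g_all$selected, bones)
  last <- g_all$trace[nrow(g_all$trace), ]
  expect_equal(last$phi, -group_redundancy_R(bones, rel))

  expect_error(greedy_select(NULL, k = 1, rel = rel), "between")
  expect_error(greedy_select(NULL, k = 99, rel = rel), "between")
})

test_that("exhaustive placement enumerates exactly and agrees with greedy when greedy is optimal", {
  rel <- matrix(c(0, 0, 0, 0,
                  0, 6, 1, 1,
                  0, 1, 5, 4,
                  0, 1, 4, 5), 4, 4, byrow = TRUE,
                dimnames = list(c("pelvis", "a", "b", "c"), c("pelvis", "a", "b", "c")))
  ex <- exhaustive_select(NULL, k = 2, rel = rel, root = "pelvis")
  # k = 2: pick the placement maximizing phi({root, x}, rest)
  cand_phi <- vapply(c("a", "b", "c"), function(x)
    phi(c("pelvis", x), setdiff(c("a", "b", "c"), x), rel), 0)
  expect_equal(setdiff(ex$selected, "pelvis"), names(which.max(cand_phi)))
  expect_equal(choose(3, 1), 3)  # the enumeration size for this case
  g <- greedy_select(NULL, k = 3, rel = rel, root = "pelvis")
  e3 <- exhaustive_select(NULL, k = 3, rel = rel, root = "pelvis")
  expect_equal(glance(g)$phi, glance(e3)$phi, tolerance = 1e-12)
  rel_big <- diag(21)
  dimnames(rel_big) <- list(c("pelvis", paste0("b", 1:20)),
                            c("pelvis", paste0("b", 1:20)))
  expect_error(exhaustive_select(NULL, k = 11, rel = rel_big), "budget")
})
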