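test_that("sensor-to-bone calibration recovers the mounting rotation", {
  expect_equal(calibrate_sensor(diag(3), diag(3)), diag(3))

  set.seed(41)
  for (i in 1:10) {
    r <- random_rotation()
    expect_equal(calibrate_sensor(r, r), diag(3), tolerance = 1e-12)
    # round trip: worn sensor with known mounting rotation recovers it
    sbr <- random_rotation()
    bone <- r %*% sbr
    expect_equal(calibrate_sensor(r, bone), sbr, tolerance = 1e-12)
    expect_equal(r %*% calibrate_sensor(r, bone), bone, tolerance = 1e-12)
  }

  bad <- diag(3) * 1.5
  expect_error(calibrate_sensor(bad, diag(3)), "world_sensor")
  expect_error(calibrate_sensor(diag(3), bad), "known_bone")
})

test_that("root normalization maps the root to identity and is idempotent", {
  seg <- generate_activity(example_activity_specs(200)$walk, segment_id = "w")
  nrm <- normalize_frames(seg)
  expect_true(is_normalized(nrm))
  id9 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(nrm)), ncol = 9)
  expect_equal(unname(bone_rot(nrm, "pelvis")), id9, tolerance = 1e-12)
  expect_equal(max(abs(bone_acc(nrm, "pelvis"))), 0, tolerance = 1e-12)
  # idempotent
  nrm2 <- normalize_frames(nrm)
  expect_equal(as.matrix(nrm2[-(1:3)]), as.matrix(nrm[-(1:3)]), tolerance = 1e-12)
})

test_that("degenerate and identity-root frames normalize as expected", {
  sk <- default_skeleton()
  n <- 5L
  r <- as_rot9_test <- matrix(rep(as.numeric(t(axis_angle_to_rotation(c(0.3, -0.2, 0.9)))),
                                  each = n), n, 9L)
  acc <- matrix(rep(c(1, 2, 3), each = n), n, 3L)
  cols <- list(segment_id = rep("d", n), activity = rep("d", n), frame = 1:n)
  for (b in sk$bone) {
    rr <- r; colnames(rr) <- paste0(b, ".R", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
    aa <- acc; colnames(aa) <- paste0(b, ".a", 1:3)
    cols <- c(cols, as.list(as.data.frame(rr)), as.list(as.data.frame(aa)))
  }
  deg <- mocapselect:::new_motion_tbl(tibble::as_tibble(cols), sk)
  nrm <- normalize_frames(deg)
  for (b in sk$bone) {
    expect_equal(unname(bone_rot(nrm, b)),
                 matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9L),
                 tolerance = 1e-12)
    expect_equal(max(abs(bone_acc(nrm, b))), 0, tolerance = 1e-12)
  }

  # identity root: orientations unchanged, accelerations shifted by -a_root
  seg <- generate_activity(example_activity_specs(100)$arms, segment_id = "a")
  idcols <- paste0("pelvis.R", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
  seg[idcols] <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(seg)), ncol = 9)
  nrm <- normalize_frames(seg)
  expect_equal(bone_rot(nrm, "l_forearm"), bone_rot(seg, "l_forearm"), tolerance = 1e-12)
  expect_equal(bone_acc(nrm, "l_forearm"),
               bone_acc(seg, "l_forearm") - bone_acc(seg, "pelvis"), tolerance = 1e-12)
})

test_that("normalization is invariant to a global world-frame rotation", {
  seg <- generate_activity(example_activity_specs(150)$walk, segment_id = "w")
  g <- axis_angle_to_rotation(c(0.4, -1.1, 0.7))
  a <- normalize_frames(seg)
  b <- normalize_frames(rotate_world(seg, g))
  expect_equal(as.matrix(b[-(1:3)]), as.matrix(a[-(1:3)]), tolerance = 1e-9)
})

test_that("angular error matches closed forms and the quaternion oracle", {
  r30 <- axis_angle_to_rotation(c(0, 0, pi / 6))
  expect_equal(angular_error(r30, r30), 0)
  expect_equal(angular_error(diag(3), r30), 30, tolerance = 1e-10)

  set.seed(7)
  for (i in 1:25) {
    r1 <- random_rotation(); r2 <- random_rotation()
    expect_equal(angular_error(r1, r2), quat_angle_deg(r1, r2), tolerance = 1e-6)
    expect_equal(angular_error(r1, r2), angular_error(r2, r1))
  }
  # triangle inequality on sampled triples
  for (i in 1:25) {
    r1 <- random_rotation(); r2 <- random_rotation(); r3 <- random_rotation()
    expect_lte(angular_error(r1, r3),
               angular_error(r1, r2) + angular_error(r2, r3) + 1e-9)
  }
})

test_that("axis-angle conversion round-trips, including near-pi angles", {
  expect_equal(rotation_to_axis_angle(diag(3)), c(0, 0, 0))
  expect_equal(rotation_to_axis_angle(axis_angle_to_rotation(c(pi / 2, 0, 0))),
               c(pi / 2, 0, 0), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:30) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 1e-4, pi - 1e-4)
    expect_equal(rotation_to_axis_angle(axis_angle_to_rotation(v)), v,
                 tolerance = 1e-9)
  }
  # stable branch close to pi
  for (i in 1:10) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * (pi - 1e-6)
    r <- axis_angle_to_rotation(v)
    rt <- axis_angle_to_rotation(rotation_to_axis_angle(r))
    expect_lt(angular_error(rt, r), 1e-4)
  }
})

test_that("rotation validation and polar repair behave", {
  r <- random_rotation()
  expect_true(rot_valid(r))
  noisy <- r + matrix(stats::rnorm(9, sd = 1e-3), 3, 3)
  expect_false(rot_valid(noisy, tol = 1e-6))
  fixed <- rot_project(noisy)
  expect_true(rot_valid(fixed, tol = 1e-9))
  expect_lt(angular_error(fixed, r), 0.5)
})
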