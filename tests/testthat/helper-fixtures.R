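# shared fixtures and independent oracles

random_rotation <- function() {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2)) * stats::runif(1, 0.05, pi - 0.05)
  axis_angle_to_rotation(v)
}

# quaternion oracle for the relative rotation angle (degrees)
rotmat_to_quat <- function(m) {
  tr <- sum(diag(m))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, s / 4, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, s / 4,
           (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, s / 4)
  }
  q / sqrt(sum(q^2))
}

quat_angle_deg <- function(r1, r2) {
  d <- abs(sum(rotmat_to_quat(r1) * rotmat_to_quat(r2)))
  2 * acos(min(d, 1)) * 180 / pi
}

# small mixed-activity corpus used across the selection tests
small_corpus <- function(seed = 1L, duration = 600, repeats = c(walk = 2, arms = 1, trunk = 1)) {
  generate_corpus(example_activity_specs(duration), repeats = repeats, seed = seed)
}

walk_reference <- function(seed = 99L, n_frames = 400, duration = 600) {
  generate_reference(example_activity_specs(duration)$walk, n_frames, seed = seed)
}

# binned mutual information (nats) on a fixed b x b grid: independent oracle
# for the coupling property of the generator
binned_mi <- function(x, y, b = 20L) {
  bx <- cut(x, stats::quantile(x, probs = seq(0, 1, length.out = b + 1L)),
            include.lowest = TRUE, labels = FALSE)
  by <- cut(y, stats::quantile(y, probs = seq(0, 1, length.out = b + 1L)),
            include.lowest = TRUE, labels = FALSE)
  tab <- table(bx, by) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  sum(ifelse(tab > 0, tab * log(tab / outer(px, py)), 0))
}
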