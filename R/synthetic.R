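#' Specify a synthetic activity
#'
#' Describes one activity type for the synthetic motion generator. Each
#' bone's joint angle (about its skeleton axis) follows either a sinusoid
#' (`period` given, in seconds) or a smoothed Ornstein-Uhlenbeck random
#' walk (`period = NULL`), plus smoothed noise of standard deviation
#' `noise_sd` degrees. `joint_amplitude` gives per-bone amplitudes in
#' degrees (sinusoid amplitude, or stationary standard deviation for the
#' aperiodic walk); bones not listed stay at the rest pose.
#' `phase_coupling` is a list of `c(driver, follower, offset)` triples:
#' the follower bone reuses the driver bone's angle waveform shifted by
#' `offset` radians (one period, or one second for aperiodic specs, being
#' 2*pi), so the pair is deterministically coupled up to `noise_sd`; pairs
#' not listed are driven by independent noise streams.
#'
#' @param name activity label
#' @param period cycle length in seconds, or `NULL` for aperiodic dynamics
#' @param joint_amplitude named numeric vector, degrees, names are bone ids
#' @param phase_coupling list of `c(driver, follower, offset_radians)`
#' @param noise_sd per-bone angle noise, degrees
#' @param duration segment length in frames
#' @param seed integer; fixes the full output bitstream
#' @return an `activity_spec` object
#' @export
activity_spec <- function(name, period = NULL, joint_amplitude, phase_coupling = list(),
                          noise_sd = 1, duration = 1000, seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(joint_amplitude), !is.null(names(joint_amplitude)),
            all(joint_amplitude >= 0), noise_sd >= 0, duration >= 1)
  structure(list(name = name, period = period, joint_amplitude = joint_amplitude,
                 phase_coupling = phase_coupling, noise_sd = noise_sd,
                 duration = as.integer(duration), seed = as.integer(seed)),
            class = "activity_spec")
}

# Band-limited unit-variance noise: a sum of random-phase sinusoids with
# frequencies below fmax and a reddened (1/sqrt(f)) amplitude envelope.
# Strict band limiting matters because bone accelerations are obtained by
# double differencing positions, which amplifies spectral power as omega^4;
# physical joint-angle jitter carries no power near the Nyquist frequency.
smooth_noise <- function(n, fmax = 2, fps = 100) {
  K <- 24L
  f <- stats::runif(K, 0.15, fmax)
  ph <- stats::runif(K, 0, 2 * pi)
  amp <- 1 / sqrt(f)
  tt <- seq_len(n) / fps
  x <- rowSums(sweep(cos(outer(tt, 2 * pi * f) +
                           matrix(ph, n, K, byrow = TRUE)), 2L, amp, `*`))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  x / s
}

# y(t) = x(t - lag), clamped at the edges
shift_series <- function(x, lag) {
  x[pmin(pmax(seq_along(x) - lag, 1L), length(x))]
}

# Per-bone joint-angle series (radians), duration x bones. A follower bone
# reproduces its driver's *measured* angle series (signal plus the driver's
# own noise), lagged by the phase offset and rescaled to its amplitude,
# plus its own independent noise: a coupled pair is one noise hop apart
# while two followers of a common driver are two hops apart.
synth_angles <- function(spec, skeleton) {
  bones <- skeleton$bone
  amp <- setNames(numeric(length(bones)), bones)
  unknown <- setdiff(names(spec$joint_amplitude), bones)
  if (length(unknown)) stop("unknown bone in joint_amplitude: ", paste(unknown, collapse = ", "))
  amp[names(spec$joint_amplitude)] <- spec$joint_amplitude * pi / 180
  n <- spec$duration
  fps <- 100
  period_frames <- if (is.null(spec$period)) fps else spec$period * fps

  # driver bookkeeping: follower -> (driver, lag in frames)
  followers <- list()
  for (pc in spec$phase_coupling) {
    if (length(pc) == 1L && identical(pc, "independent")) next
    stopifnot(length(pc) == 3L)
    if (!(pc[[1L]] %in% bones) || !(pc[[2L]] %in% bones)) {
      stop("unknown bone in phase_coupling: ", pc[[1L]], " / ", pc[[2L]])
    }
    followers[[pc[[2L]]]] <- list(
      driver = pc[[1L]],
      lag = round(as.numeric(pc[[3L]]) / (2 * pi) * period_frames))
  }

  # deterministic golden-ratio phase spread for uncoupled periodic bones
  phase0 <- 2 * pi * ((seq_along(bones) - 1L) * 0.381966) %% (2 * pi)
  names(phase0) <- bones
  seed_of <- function(bone, salt) {
    (spec$seed + salt * match(bone, bones)) %% 2147483647L
  }
  base_wave <- function(b) {
    if (!is.null(spec$period)) {
      sin(2 * pi * seq_len(n) / period_frames + phase0[[b]])
    } else {
      set.seed(seed_of(b, 131071L))
      smooth_noise(n, fmax = 1.5)
    }
  }
  bone_noise <- function(b) {
    if (spec$noise_sd == 0 || amp[[b]] == 0) return(numeric(n))
    set.seed(seed_of(b, 524287L))
    smooth_noise(n) * spec$noise_sd * pi / 180
  }

  angles <- matrix(NA_real_, n, length(bones), dimnames = list(NULL, bones))
  resolve <- function(b, depth = 0L) {
    if (!anyNA(angles[, b])) return(invisible())
    if (depth > length(bones)) stop("phase_coupling has a cycle")
    f <- followers[[b]]
    if (is.null(f)) {
      angles[, b] <<- amp[[b]] * base_wave(b) + bone_noise(b)
    } else {
      resolve(f$driver, depth + 1L)
      driver_series <- angles[, f$driver]
      scale <- if (amp[[f$driver]] > 0) amp[[b]] / amp[[f$driver]] else amp[[b]]
      src <- if (amp[[f$driver]] > 0) driver_series else base_wave(f$driver)
      angles[, b] <<- scale * shift_series(src, f$lag) + bone_noise(b)
    }
  }
  for (b in bones) resolve(b)
  angles
}

#' Generate one synthetic motion segment
#'
#' Converts per-bone joint-angle series into a world-frame motion table:
#' each bone's local rotation is `angle * axis` in axis-angle form,
#' composed down the kinematic chain from the pelvis; bone accelerations
#' are obtained by double differencing joint positions (forward kinematics
#' with the skeleton's offsets) at the frame rate.
#'
#' @param spec an [activity_spec()]
#' @param skeleton a skeleton, see [default_skeleton()]
#' @param segment_id identifier for the emitted segment
#' @param frame_rate frames per second
#' @return a world-frame motion table with one segment
#' @export
generate_activity <- function(spec, skeleton = default_skeleton(),
                              segment_id = spec$name, frame_rate = 100) {
  assert_skeleton(skeleton)
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  angles <- synth_angles(spec, skeleton)
  n <- nrow(angles)
  bones <- skeleton$bone
  topo <- skeleton_topo(skeleton)
  root <- skeleton_root(skeleton)

  rots <- list()  # world orientation per bone, n x 9
  pos <- list()   # joint position per bone, n x 3
  for (b in topo) {
    i <- match(b, bones)
    axis <- c(skeleton$axis_x[i], skeleton$axis_y[i], skeleton$axis_z[i])
    local <- axis_angle_to_rotation(outer(angles[, b], axis))
    par <- skeleton$parent[i]
    off <- c(skeleton$offset_x[i], skeleton$offset_y[i], skeleton$offset_z[i])
    if (is.na(par)) {
      rots[[b]] <- local
      pos[[b]] <- matrix(rep(off, each = n), n, 3L)
    } else {
      rots[[b]] <- rot9_compose(rots[[par]], local)
      pos[[b]] <- pos[[par]] + rot9_apply(rots[[par]], matrix(rep(off, each = n), n, 3L))
    }
  }

  fps2 <- frame_rate^2
  accel <- lapply(pos, function(p) {
    a <- matrix(0, n, 3L)
    if (n >= 3L) {
      core <- (p[1:(n - 2L), , drop = FALSE] - 2 * p[2:(n - 1L), , drop = FALSE] +
                 p[3:n, , drop = FALSE]) * fps2
      a[2:(n - 1L), ] <- core
      a[1L, ] <- core[1L, ]           # replicate ends
      a[n, ] <- core[n - 2L, ]
    }
    a
  })

  cols <- list(segment_id = rep(segment_id, n), activity = rep(spec$name, n),
               frame = seq_len(n))
  for (b in bones) {
    r <- rots[[b]]; colnames(r) <- rot_cols(b)
    a <- accel[[b]]; colnames(a) <- acc_cols(b)
    cols <- c(cols, as.list(as.data.frame(r)), as.list(as.data.frame(a)))
  }
  new_motion_tbl(tibble::as_tibble(cols), skeleton, frame_rate = frame_rate)
}

#' Generate a labeled multi-activity corpus
#'
#' Emulates an accumulated, possibly imbalanced motion dataset: each
#' activity spec is instantiated `repeats[[name]]` times with segment
#' seeds derived deterministically from the corpus seed, so any subset of
#' the corpus is reproducible on its own.
#'
#' @param specs list of [activity_spec()]s
#' @param repeats named integer vector or list, segments per activity
#'   (default 1 each)
#' @param skeleton a skeleton
#' @param seed corpus seed
#' @return a motion table containing all segments
#' @export
generate_corpus <- function(specs, repeats = NULL, skeleton = default_skeleton(),
                            seed = 1L) {
  stopifnot(length(specs) >= 1L)
  parts <- list()
  counter <- 0L
  for (spec in specs) {
    n_rep <- if (is.null(repeats)) 1L else as.integer(repeats[[spec$name]])
    if (is.na(n_rep)) n_rep <- 1L
    for (r in seq_len(n_rep)) {
      counter <- counter + 1L
      s <- spec
      s$seed <- as.integer((seed + 7919L * counter) %% 2147483647L)
      parts[[counter]] <- generate_activity(
        s, skeleton, segment_id = sprintf("%s_%02d", spec$name, r))
    }
  }
  out <- dplyr::bind_rows(parts)
  new_motion_tbl(out, skeleton)
}

#' Generate a small reference sample
#'
#' A short single-activity dataset standing in for reference data recorded
#' in the target scenario, drawn from the same generator family as the
#' corpus but with a fresh seed. At least 300 frames (one model sequence
#' length) are required.
#'
#' @param spec an [activity_spec()]
#' @param n_frames reference length in frames (>= 300)
#' @param seed reference seed
#' @param skeleton a skeleton
#' @return a motion table with one segment labeled `ref_<activity>`
#' @export
generate_reference <- function(spec, n_frames = 1000, seed = 99L,
                               skeleton = default_skeleton()) {
  if (n_frames < 300) stop("reference must be at least 300 frames (one model sequence)")
  s <- spec
  s$duration <- as.integer(n_frames)
  s$seed <- as.integer(seed)
  generate_activity(s, skeleton, segment_id = paste0("ref_", spec$name))
}
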