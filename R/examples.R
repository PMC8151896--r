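#' Ready-made activity specifications
#'
#' A small family of synthetic activities used throughout the examples and
#' the package's own experiments. The three activities move largely
#' disjoint bone sets with distinct dynamics, so their per-frame features
#' are close to orthogonal (frame-wise cosine well below 0.5 across
#' activities) while two realizations of the same activity stay highly
#' similar:
#'
#' * `walk`: periodic (1 s cycle) anti-phase thigh/shank swings with
#'   contralateral arm swing;
#' * `arms`: faster (0.8 s) bilateral arm and forearm swings;
#' * `trunk`: slow aperiodic spine/neck/head sway.
#'
#' @param duration frames per segment
#' @param noise_sd per-bone angle noise, degrees
#' @return a named list of [activity_spec()]s
#' @export
#' @examples
#' corpus <- generate_corpus(example_activity_specs(600),
#'                           repeats = c(walk = 2, arms = 1, trunk = 1), seed = 1)
example_activity_specs <- function(duration = 900, noise_sd = 1.5) {
  list(
    walk = activity_spec("walk", period = 1,
      joint_amplitude = c(l_thigh = 30, r_thigh = 30, l_shank = 25, r_shank = 25,
                          l_upper_arm = 15, r_upper_arm = 15, pelvis = 6),
      phase_coupling = list(c("l_thigh", "pelvis", pi / 2),
                            c("l_thigh", "r_thigh", pi),
                            c("l_thigh", "l_shank", 0.5),
                            c("r_thigh", "r_shank", 0.5),
                            c("l_thigh", "r_upper_arm", 0),
                            c("r_thigh", "l_upper_arm", 0)),
      noise_sd = noise_sd, duration = duration),
    arms = activity_spec("arms", period = 0.8,
      joint_amplitude = c(l_upper_arm = 45, r_upper_arm = 45,
                          l_forearm = 35, r_forearm = 35,
                          l_hand = 15, r_hand = 15),
      phase_coupling = list(c("l_upper_arm", "r_upper_arm", 0),
                            c("l_upper_arm", "l_forearm", 0.8),
                            c("r_upper_arm", "r_forearm", 0.8)),
      noise_sd = noise_sd, duration = duration),
    trunk = activity_spec("trunk", period = NULL,
      joint_amplitude = c(spine1 = 12, spine2 = 10, spine3 = 8,
                          neck = 10, head = 12),
      phase_coupling = list(c("spine1", "spine2", 0.2),
                            c("spine2", "spine3", 0.2)),
      noise_sd = noise_sd, duration = duration)
  )
}

#' Hub-coupled activity specification
#'
#' An aperiodic activity in which one "hub" bone perfectly drives five
#' followers (each follower is the hub's waveform plus its own independent
#' noise) while the remaining listed bones move independently. Every
#' hub-follower pair is one noise hop apart but follower pairs are two
#' hops apart, so the hub carries strictly the most information about the
#' rest of the body -- the structure the greedy placement search should
#' discover.
#'
#' The default bones respect the kinematic chain: the hub is a leaf with
#' no descendants and the followers are leaf bones on distinct chains, so
#' no mover inherits another mover's rotation by composition. Extra
#' independent movers can be added, but note that an independent bone
#' that is an ancestor of a follower feeds its own signal into that
#' follower's measurements.
#'
#' @param hub the driver bone
#' @param followers five bones coupled to the hub
#' @param independents bones driven by independent streams
#' @param duration frames
#' @param noise_sd angle noise, degrees; sets the one-hop vs two-hop
#'   information gap between hub-follower and follower-follower pairs
#' @return an [activity_spec()]
#' @export
hub_activity_spec <- function(hub = "spine4",
                              followers = c("head", "l_hand", "r_hand",
                                            "l_foot", "r_foot"),
                              independents = character(0),
                              duration = 1500, noise_sd = 6) {
  stopifnot(length(followers) == 5L)
  amp <- setNames(rep(20, 1L + length(followers) + length(independents)),
                  c(hub, followers, independents))
  coupling <- lapply(seq_along(followers),
                     function(i) c(hub, followers[i], 0))
  activity_spec("hub", period = NULL, joint_amplitude = amp,
                phase_coupling = coupling, noise_sd = noise_sd,
                duration = duration)
}

#' Random contiguous selection baseline
#'
#' Draws contiguous pieces of `piece_length` frames uniformly from the
#' corpus segments (without overlap) until `n_frames` frames are covered:
#' the size-matched random baseline against which an algorithmic selection
#' is compared.
#'
#' @param corpus a motion table
#' @param n_frames total frames to select
#' @param piece_length length of each random piece
#' @param seed RNG seed
#' @return a `motion_selection`
#' @export
random_selection <- function(corpus, n_frames, piece_length = 300L, seed = 1L) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  segs <- segments_summary(corpus)
  segs <- segs[segs$n_frames >= piece_length, ]
  if (!nrow(segs)) stop("no segment is long enough for a random piece")
  taken <- list()
  pieces <- list()
  total <- 0L
  guard <- 0L
  while (total < n_frames && guard < 1000L) {
    guard <- guard + 1L
    i <- sample.int(nrow(segs), 1L)
    start <- sample.int(segs$n_frames[i] - piece_length + 1L, 1L)
    key <- segs$segment_id[i]
    iv <- c(start, start + piece_length - 1L)
    overlaps <- any(vapply(taken[[key]] %||% list(), function(x)
      iv[1L] <= x[2L] && x[1L] <= iv[2L], TRUE))
    if (overlaps) next
    taken[[key]] <- c(taken[[key]] %||% list(), list(iv))
    pieces[[length(pieces) + 1L]] <- tibble::tibble(
      segment_id = key, start = start, length = piece_length)
    total <- total + piece_length
  }
  new_selection(dplyr::arrange(dplyr::bind_rows(pieces), .data$segment_id,
                               .data$start),
                selection_config(min_run_length = piece_length))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive pruning oracle
#'
#' Enumerates every non-empty subset of the candidate pieces that keeps at
#' least `min_run_length` frames and returns the subset maximizing the
#' selection objective: the brute-force counterpart of [greedy_prune()],
#' practical only for small candidate sets.
#'
#' @inheritParams greedy_prune
#' @param max_pieces refuse enumeration beyond this many pieces
#' @return a `motion_selection` with the optimum objective as attribute
#'   `objective`
#' @export
exhaustive_prune <- function(candidate, data, ref_hist,
                             config = selection_config(), max_pieces = 16L) {
  candidate <- dplyr::arrange(tibble::as_tibble(candidate), .data$segment_id,
                              .data$start)
  k <- nrow(candidate)
  if (k > max_pieces) stop("too many pieces for exhaustive enumeration: ", k)
  piece_counts <- vector("list", k)
  for (i in seq_len(k)) {
    feats <- extract_features(selected_frames(candidate[i, ], data), config$bones)
    piece_counts[[i]] <- histogram_counts(feats, ref_hist$edges)
  }
  best <- NULL; best_obj <- -Inf
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    frames <- sum(candidate$length[idx])
    if (frames < config$min_run_length) next
    counts <- Reduce(`+`, piece_counts[idx])
    obj <- obj_from_counts(counts, frames, ref_hist$prob, config)
    if (obj > best_obj + 1e-12) { best_obj <- obj; best <- idx }
  }
  if (is.null(best)) stop("no subset satisfies the minimum frame floor")
  out <- new_selection(candidate[best, ], config)
  attr(out, "objective") <- best_obj
  out
}
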