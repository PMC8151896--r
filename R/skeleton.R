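#' The 21-placement motion-capture skeleton
#'
#' Returns the candidate sensor placements used throughout the package: a
#' kinematic tree of 21 body segments (pelvis root, three spine segments,
#' neck, head, and left/right shoulders, upper arms, forearms, hands,
#' thighs, shanks, feet). Each bone carries its parent, a fixed offset
#' vector (metres, in the parent frame, used for forward kinematics when
#' synthesizing accelerations) and a unit axis about which its synthetic
#' joint angle rotates.
#'
#' @return A tibble with columns `bone`, `parent` (`NA` for the root),
#'   `offset_x/y/z` (m) and `axis_x/y/z` (unit vector).
#' @export
#' @examples
#' sk <- default_skeleton()
#' nrow(sk)        # 21
#' skeleton_root(sk)
default_skeleton <- function() {
  # offsets are approximate adult segment vectors (m), enough for plausible
  # double-differenced accelerations; axes are the dominant anatomical
  # rotation axes (x = mediolateral flexion axis, z = vertical)
  def <- list(
    #      bone          parent        offset             axis
    list("pelvis",       NA,           c(0, 0, 1.00),     c(0, 0, 1)),
    list("spine1",       "pelvis",     c(0, 0, 0.10),     c(1, 0, 0)),
    list("spine2",       "spine1",     c(0, 0, 0.12),     c(1, 0, 0)),
    list("spine3",       "spine2",     c(0, 0, 0.12),     c(0, 0, 1)),
    list("neck",         "spine3",     c(0, 0, 0.10),     c(1, 0, 0)),
    list("head",         "neck",       c(0, 0, 0.12),     c(0, 1, 0)),
    list("l_shoulder",   "spine3",     c(-0.10, 0, 0.05), c(0, 1, 0)),
    list("r_shoulder",   "spine3",     c(0.10, 0, 0.05),  c(0, 1, 0)),
    list("l_upper_arm",  "l_shoulder", c(-0.12, 0, 0),    c(1, 0, 0)),
    list("r_upper_arm",  "r_shoulder", c(0.12, 0, 0),     c(1, 0, 0)),
    list("l_forearm",    "l_upper_arm", c(-0.28, 0, 0),   c(0, 1, 0)),
    list("r_forearm",    "r_upper_arm", c(0.28, 0, 0),    c(0, 1, 0)),
    list("l_hand",       "l_forearm",  c(-0.25, 0, 0),    c(1, 0, 0)),
    list("r_hand",       "r_forearm",  c(0.25, 0, 0),     c(1, 0, 0)),
    list("l_thigh",      "pelvis",     c(-0.09, 0, 0),    c(1, 0, 0)),
    list("r_thigh",      "pelvis",     c(0.09, 0, 0),     c(1, 0, 0)),
    list("l_shank",      "l_thigh",    c(0, 0, -0.42),    c(1, 0, 0)),
    list("r_shank",      "r_thigh",    c(0, 0, -0.42),    c(1, 0, 0)),
    list("l_foot",       "l_shank",    c(0, 0, -0.41),    c(1, 0, 0)),
    list("r_foot",       "r_shank",    c(0, 0, -0.41),    c(1, 0, 0)),
    list("spine4",       "spine3",     c(0, 0, 0.08),     c(0, 0, 1))
  )
  sk <- tibble::tibble(
    bone   = vapply(def, `[[`, "", 1L),
    parent = vapply(def, function(d) ifelse(is.na(d[[2L]]), NA_character_, d[[2L]]), ""),
    offset_x = vapply(def, function(d) d[[3L]][1L], 0),
    offset_y = vapply(def, function(d) d[[3L]][2L], 0),
    offset_z = vapply(def, function(d) d[[3L]][3L], 0),
    axis_x = vapply(def, function(d) d[[4L]][1L], 0),
    axis_y = vapply(def, function(d) d[[4L]][2L], 0),
    axis_z = vapply(def, function(d) d[[4L]][3L], 0)
  )
  # keep the canonical ordering: pelvis first, then tree order
  sk <- sk[order(match(sk$bone, skeleton_order())), ]
  class(sk) <- c("skeleton", class(sk))
  sk
}

skeleton_order <- function() {
  c("pelvis", "spine1", "spine2", "spine3", "spine4", "neck", "head",
    "l_shoulder", "r_shoulder", "l_upper_arm", "r_upper_arm",
    "l_forearm", "r_forearm", "l_hand", "r_hand",
    "l_thigh", "r_thigh", "l_shank", "r_shank", "l_foot", "r_foot")
}

#' @rdname default_skeleton
#' @param skeleton a skeleton tibble from [default_skeleton()]
#' @export
skeleton_root <- function(skeleton) {
  skeleton$bone[is.na(skeleton$parent)][1L]
}

#' @rdname default_skeleton
#' @export
skeleton_bones <- function(skeleton) skeleton$bone

assert_skeleton <- function(skeleton) {
  stopifnot(is.data.frame(skeleton), all(c("bone", "parent") %in% names(skeleton)))
  if (anyDuplicated(skeleton$bone)) stop("duplicate bone names in skeleton")
  root <- skeleton$bone[is.na(skeleton$parent)]
  if (length(root) != 1L) stop("skeleton must have exactly one root bone")
  known <- skeleton$parent[!is.na(skeleton$parent)]
  if (!all(known %in% skeleton$bone)) stop("skeleton parent refers to unknown bone")
  invisible(skeleton)
}

# bones ordered so every parent precedes its children
skeleton_topo <- function(skeleton) {
  ord <- character(0)
  remaining <- skeleton$bone
  while (length(remaining)) {
    ready <- remaining[is.na(skeleton$parent[match(remaining, skeleton$bone)]) |
                         skeleton$parent[match(remaining, skeleton$bone)] %in% ord]
    if (!length(ready)) stop("skeleton has a cycle")
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}
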