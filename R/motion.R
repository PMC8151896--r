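#' Motion tables
#'
#' The package's core container is a *motion table*: a tibble with one row
#' per frame, identified by `segment_id`, `activity` and `frame`
#' (consecutive integer timestamps within a segment; frame rate 100 Hz by
#' default), followed by 12 numeric columns per bone -- the world (or
#' root-normalized) orientation as row-major rotation-matrix entries
#' `<bone>.R11 ... <bone>.R33` and the acceleration `<bone>.a1 a2 a3` in
#' m/s^2. The skeleton travels along as an attribute.
#'
#' @name motion_tbl
NULL

META_COLS <- c("segment_id", "activity", "frame")

new_motion_tbl <- function(df, skeleton, frame_rate = 100, normalized = FALSE) {
  df <- tibble::as_tibble(df)
  attr(df, "skeleton") <- skeleton
  attr(df, "frame_rate") <- frame_rate
  attr(df, "normalized") <- normalized
  class(df) <- unique(c("motion_tbl", class(df)))
  df
}

#' @describeIn motion_tbl The skeleton attached to a motion table.
#' @param data a motion table
#' @export
motion_skeleton <- function(data) attr(data, "skeleton", exact = TRUE)

#' @describeIn motion_tbl Frame rate in Hz (default 100).
#' @export
motion_frame_rate <- function(data) {
  fr <- attr(data, "frame_rate", exact = TRUE)
  if (is.null(fr)) 100 else fr
}

#' @describeIn motion_tbl Has the table been root-normalized?
#' @export
is_normalized <- function(data) isTRUE(attr(data, "normalized", exact = TRUE))

motion_bones <- function(data) {
  sk <- motion_skeleton(data)
  if (!is.null(sk)) return(sk$bone)
  unique(sub("\\.(R[1-3][1-3]|a[1-3])$", "", grep("\\.R11$", names(data), value = TRUE)))
}

rot_cols <- function(bone) paste0(bone, ".R", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
acc_cols <- function(bone) paste0(bone, ".a", 1:3)

#' @describeIn motion_tbl The n x 9 row-major orientation block of one bone.
#' @param bone a bone id
#' @export
bone_rot <- function(data, bone) {
  cols <- rot_cols(bone)
  if (!all(cols %in% names(data))) stop("no orientation columns for bone '", bone, "'")
  as.matrix(data[cols])
}

#' @describeIn motion_tbl The n x 3 acceleration block of one bone.
#' @export
bone_acc <- function(data, bone) {
  cols <- acc_cols(bone)
  if (!all(cols %in% names(data))) stop("no acceleration columns for bone '", bone, "'")
  as.matrix(data[cols])
}

assert_motion_tbl <- function(data) {
  if (!all(META_COLS %in% names(data))) {
    stop("motion table must have columns ", paste(META_COLS, collapse = ", "))
  }
  bones <- motion_bones(data)
  missing <- bones[!vapply(bones, function(b) all(rot_cols(b) %in% names(data)), TRUE)]
  if (length(missing)) stop("missing orientation columns for: ", paste(missing, collapse = ", "))
  invisible(data)
}

#' Root-bone normalization of motion frames
#'
#' Expresses every bone's kinematics relative to the root bone (pelvis):
#' orientations become `t(R_root) %*% R_bone` and accelerations
#' `t(R_root) %*% (a_bone - a_root)`. After normalization the root's
#' orientation is the identity and its acceleration the zero vector, so
#' downstream features are invariant to the subject's heading and to any
#' global world-frame rotation. The operation is idempotent.
#'
#' @param data a motion table in world coordinates
#' @return the normalized motion table (attribute `normalized` set)
#' @export
normalize_frames <- function(data) {
  assert_motion_tbl(data)
  sk <- motion_skeleton(data)
  root <- if (!is.null(sk)) skeleton_root(sk) else "pelvis"
  if (!all(rot_cols(root) %in% names(data))) {
    stop("motion table has no measurement for the root bone '", root, "'")
  }
  rootR <- bone_rot(data, root)            # W<-Root
  rootRt <- rot9_transpose(rootR)          # Root<-W
  rootA <- bone_acc(data, root)
  out <- data
  for (b in motion_bones(data)) {
    out[rot_cols(b)] <- rot9_compose(rootRt, bone_rot(data, b))
    out[acc_cols(b)] <- rot9_apply(rootRt, bone_acc(data, b) - rootA)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' @describeIn normalize_frames Apply a fixed world-frame rotation `g`
#'   (3x3) to every orientation and acceleration -- a change of world
#'   coordinates. Root normalization is invariant under this map.
#' @param g a 3x3 rotation applied on the world side
#' @export
rotate_world <- function(data, g) {
  assert_rotation(g, "g")
  g9 <- as_rot9(g)
  out <- data
  for (b in motion_bones(data)) {
    out[rot_cols(b)] <- rot9_compose(g9[rep(1L, nrow(data)), , drop = FALSE],
                                     bone_rot(data, b))
    out[acc_cols(b)] <- rot9_apply(g9, bone_acc(data, b))
  }
  out
}

#' Summarize a motion table
#'
#' @param object a motion table
#' @param ... unused
#' @return a tibble with one row per segment: id, activity, frame count.
#' @export
segments_summary <- function(object, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$segment_id,
                                   .data$activity),
                   n_frames = dplyr::n(), .groups = "drop")
}

#' @export
print.motion_tbl <- function(x, ...) {
  segs <- segments_summary(x)
  cat(sprintf("<motion_tbl: %d frames, %d segments, %d bones, %g Hz%s>\n",
              nrow(x), nrow(segs), length(motion_bones(x)), motion_frame_rate(x),
              if (is_normalized(x)) ", root-normalized" else ""))
  NextMethod()
}
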