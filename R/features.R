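#' Per-frame motion features
#'
#' The feature vector of a root-normalized frame, for a given set of
#' bones, is the concatenation of each bone's orientation in axis-angle
#' form (3 components, radians) and its normalized acceleration (3
#' components, m/s^2): 6 features per bone. These features drive both the
#' training-data selection (cosine screening, histograms) and the MIC
#' relevance estimates.
#'
#' @param data a root-normalized motion table
#' @param bones character vector of bone ids; default: every non-root bone
#' @return an n_frames x (6 * length(bones)) numeric matrix with named
#'   columns `<bone>.aa1..3` and `<bone>.ac1..3`
#' @export
extract_features <- function(data, bones = NULL) {
  assert_motion_tbl(data)
  sk <- motion_skeleton(data)
  root <- if (!is.null(sk)) skeleton_root(sk) else "pelvis"
  if (!is_normalized(data)) {
    # accept tables whose root is already the identity, reject others
    rr <- bone_rot(data, root)
    idm <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(rr))
    if (max(abs(rr - idm)) > 1e-6) {
      stop("frames are not root-normalized; call normalize_frames() first")
    }
  }
  if (is.null(bones)) bones <- setdiff(motion_bones(data), root)
  unknown <- setdiff(bones, motion_bones(data))
  if (length(unknown)) stop("unknown bones: ", paste(unknown, collapse = ", "))
  out <- matrix(0, nrow(data), 6L * length(bones))
  nm <- character(6L * length(bones))
  for (j in seq_along(bones)) {
    b <- bones[j]
    aa <- rotation_to_axis_angle(bone_rot(data, b))
    ac <- bone_acc(data, b)
    out[, (6L * (j - 1L) + 1L):(6L * j)] <- cbind(aa, ac)
    nm[(6L * (j - 1L) + 1L):(6L * j)] <- paste0(b, c(".aa1", ".aa2", ".aa3",
                                                     ".ac1", ".ac2", ".ac3"))
  }
  colnames(out) <- nm
  out
}
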