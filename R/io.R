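#' Read and write motion tables as CSV
#'
#' The on-disk layout matches the in-memory one: one row per frame with
#' `segment_id`, `activity`, `frame` metadata followed by 12 numeric
#' columns per bone (9 row-major rotation entries + 3 acceleration
#' entries). Doubles are written in full precision, so a write/read
#' round-trip reproduces every entry. On read, orientation blocks are
#' validated; non-orthonormal matrices are repaired by polar projection
#' with a warning, or rejected when `strict = TRUE`.
#'
#' @param data a motion table
#' @param path file path
#' @param skeleton skeleton to attach on read (default: the package's
#'   21-placement skeleton when the columns match it, otherwise inferred)
#' @param strict reject rather than repair invalid rotations
#' @param normalized mark the loaded table as root-normalized
#' @return `read_motion_csv` returns a motion table;
#'   `write_motion_csv` returns `path` invisibly.
#' @export
write_motion_csv <- function(data, path) {
  assert_motion_tbl(data)
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, TRUE) & !(names(df) %in% "frame")
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path, skeleton = NULL, strict = FALSE,
                            normalized = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(META_COLS %in% names(df))) {
    stop("motion CSV must have columns ", paste(META_COLS, collapse = ", "))
  }
  num_cols <- setdiff(names(df), c("segment_id", "activity"))
  for (cn in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad)) {
      stop("malformed value in column '", cn, "' at data row ", bad[1L])
    }
    df[[cn]] <- as.numeric(df[[cn]])
  }
  bones <- unique(sub("\\.R11$", "", grep("\\.R11$", names(df), value = TRUE)))
  if (is.null(skeleton)) {
    def <- default_skeleton()
    skeleton <- if (setequal(bones, def$bone)) def else NULL
  }
  out <- new_motion_tbl(df, skeleton, normalized = normalized)
  for (b in bones) {
    r9 <- bone_rot(out, b)
    ok <- rot_valid(r9, tol = 1e-6)
    if (!all(ok)) {
      if (strict) {
        stop("non-orthonormal rotation for bone '", b, "' at data row ",
             which(!ok)[1L])
      }
      warning("repairing ", sum(!ok), " non-orthonormal rotations for bone '",
              b, "' by polar projection")
      r9[!ok, ] <- rot_project(r9[!ok, , drop = FALSE])
      out[rot_cols(b)] <- r9
    }
  }
  out
}

#' Import a BVH motion-capture file
#'
#' Reads the skeleton hierarchy and the motion block of a BVH file and
#' converts each joint's Euler channels (degrees, applied in the order
#' listed in its CHANNELS line) to world orientations along the kinematic
#' chain. BVH carries no accelerations; they are derived by double
#' differencing joint world positions at the file's frame rate, which is
#' noisy for real captures and intended for plumbing rather than
#' metrology.
#'
#' @param path BVH file path
#' @param segment_id,activity labels for the imported segment
#' @return a world-frame motion table whose bones are the BVH joints
#' @export
read_bvh <- function(path, segment_id = basename(path), activity = "bvh") {
  txt <- readLines(path, warn = FALSE)
  mot_at <- grep("^\\s*MOTION\\s*$", txt)
  if (!length(mot_at)) stop("not a BVH file: no MOTION block")
  hier <- txt[seq_len(mot_at - 1L)]

  joints <- list(); stack <- character(0); chan_total <- 0L
  i <- 1L
  while (i <= length(hier)) {
    line <- trimws(hier[i])
    if (grepl("^(ROOT|JOINT)\\s+", line)) {
      nm <- sub("^(ROOT|JOINT)\\s+", "", line)
      joints[[nm]] <- list(name = nm,
                           parent = if (length(stack)) stack[length(stack)] else NA_character_,
                           offset = c(0, 0, 0), channels = character(0),
                           chan_from = NA_integer_)
      stack <- c(stack, nm)
    } else if (grepl("^End Site", line)) {
      # consume the { OFFSET } block
      while (i <= length(hier) && !grepl("^\\}", trimws(hier[i + 1L]))) i <- i + 1L
      i <- i + 1L
    } else if (grepl("^OFFSET\\s", line)) {
      v <- as.numeric(strsplit(line, "\\s+")[[1L]][-1L])
      joints[[stack[length(stack)]]]$offset <- v
    } else if (grepl("^CHANNELS\\s", line)) {
      parts <- strsplit(line, "\\s+")[[1L]]
      nch <- as.integer(parts[2L])
      joints[[stack[length(stack)]]]$channels <- parts[3:(2L + nch)]
      joints[[stack[length(stack)]]]$chan_from <- chan_total + 1L
      chan_total <- chan_total + nch
    } else if (grepl("^\\}", line)) {
      stack <- stack[-length(stack)]
    }
    i <- i + 1L
  }

  frames_line <- grep("^\\s*Frames:", txt, value = TRUE)[1L]
  n_frames <- as.integer(sub(".*Frames:\\s*", "", frames_line))
  ft_line <- grep("^\\s*Frame Time:", txt, value = TRUE)[1L]
  frame_time <- as.numeric(sub(".*Frame Time:\\s*", "", ft_line))
  data_from <- grep("^\\s*Frame Time:", txt) + 1L
  vals <- do.call(rbind, lapply(txt[data_from:(data_from + n_frames - 1L)],
                                function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  if (ncol(vals) != chan_total) stop("BVH motion row width does not match channel count")

  axis_rot <- function(axis, deg) {
    th <- deg * pi / 180
    v <- switch(axis, X = cbind(th, 0, 0), Y = cbind(0, th, 0), Z = cbind(0, 0, th))
    axis_angle_to_rotation(v)
  }
  n <- n_frames
  rots <- list(); pos <- list()
  for (nm in names(joints)) {
    j <- joints[[nm]]
    local <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), n, 9L)
    trans <- matrix(rep(j$offset, each = n), n, 3L)
    for (ci in seq_along(j$channels)) {
      ch <- j$channels[ci]
      col <- vals[, j$chan_from + ci - 1L]
      if (grepl("rotation$", ch)) {
        local <- rot9_compose(local, axis_rot(substr(ch, 1L, 1L), col))
      } else if (grepl("position$", ch)) {
        ax <- match(substr(ch, 1L, 1L), c("X", "Y", "Z"))
        trans[, ax] <- trans[, ax] + col - j$offset[ax]
      }
    }
    if (is.na(j$parent)) {
      rots[[nm]] <- local
      pos[[nm]] <- trans
    } else {
      rots[[nm]] <- rot9_compose(rots[[j$parent]], local)
      pos[[nm]] <- pos[[j$parent]] + rot9_apply(rots[[j$parent]], trans)
    }
  }
  fps <- 1 / frame_time
  cols <- list(segment_id = rep(segment_id, n), activity = rep(activity, n),
               frame = seq_len(n))
  for (nm in names(joints)) {
    r <- rots[[nm]]; colnames(r) <- rot_cols(nm)
    p <- pos[[nm]]
    a <- matrix(0, n, 3L)
    if (n >= 3L) {
      core <- (p[1:(n - 2L), , drop = FALSE] - 2 * p[2:(n - 1L), , drop = FALSE] +
                 p[3:n, , drop = FALSE]) * fps^2
      a[2:(n - 1L), ] <- core; a[1L, ] <- core[1L, ]; a[n, ] <- core[n - 2L, ]
    }
    colnames(a) <- acc_cols(nm)
    cols <- c(cols, as.list(as.data.frame(r)), as.list(as.data.frame(a)))
  }
  sk <- tibble::tibble(
    bone = names(joints),
    parent = vapply(joints, function(j) j$parent, ""),
    offset_x = vapply(joints, function(j) j$offset[1L], 0),
    offset_y = vapply(joints, function(j) j$offset[2L], 0),
    offset_z = vapply(joints, function(j) j$offset[3L], 0),
    axis_x = 1, axis_y = 0, axis_z = 0)
  new_motion_tbl(tibble::as_tibble(cols), sk, frame_rate = fps)
}

#' Write and read selection artifacts
#'
#' Selections and sensor groups are serialized as JSON: the selected
#' pieces (or ordered placements), a config echo, and the objective or
#' score trace, so a run can be audited and re-loaded.
#'
#' @param selection a `motion_selection`
#' @param path output path
#' @return `path`, invisibly (writers); the restored object (readers)
#' @export
write_selection_json <- function(selection, path) {
  cfg <- attr(selection, "config")
  obj <- list(pieces = tidy(selection),
              config = unclass(cfg),
              trace = attr(selection, "trace"),
              sizes = as.list(attr(selection, "sizes")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$bones <- if (length(cfg$bones)) unlist(cfg$bones) else NULL
  config <- do.call(selection_config, cfg[!vapply(cfg, is.null, TRUE)])
  new_selection(tibble::as_tibble(obj$pieces), config,
                trace = if (!is.null(obj$trace)) tibble::as_tibble(obj$trace),
                sizes = unlist(obj$sizes))
}

#' @rdname write_selection_json
#' @param group a `sensor_group`
#' @export
write_sensors_json <- function(group, path) {
  obj <- list(selected = group$selected, unselected = group$unselected,
              method = group$method, trace = group$trace,
              relevance = as.data.frame(group$relevance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @export
read_sensors_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel <- as.matrix(obj$relevance)
  rownames(rel) <- colnames(rel)
  new_sensor_group(obj$selected, c(obj$selected, obj$unselected), rel,
                   tibble::as_tibble(obj$trace), obj$method)
}
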