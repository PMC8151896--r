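#' MIC estimator configuration
#'
#' The maximal information coefficient of two series is the maximum, over
#' all grids with `a * b < B = n^exponent` cells, of the binned mutual
#' information normalized by `log2(min(a, b))`. The default
#' `"equipartition_search"` estimator equipartitions one axis and
#' optimizes the other axis' cut points by dynamic programming over a
#' finer candidate equipartition, in both orientations;
#' `"exhaustive_small"` enumerates every consecutive-group partition of
#' both axes (feasible only for short series) and serves as an oracle.
#'
#' @param exponent grid budget exponent, `B = n^exponent`, in (0, 1)
#' @param max_grid_axis cap on the number of cells per axis
#' @param estimator `"equipartition_search"` or `"exhaustive_small"`
#' @param cand_factor candidate row bins per requested row, for the
#'   dynamic-programming search
#' @return a `mic_config` list
#' @export
mic_config <- function(exponent = 0.6, max_grid_axis = 15L,
                       estimator = c("equipartition_search", "exhaustive_small"),
                       cand_factor = 5L) {
  stopifnot(exponent > 0, exponent < 1, max_grid_axis >= 2)
  structure(list(exponent = exponent, max_grid_axis = as.integer(max_grid_axis),
                 estimator = match.arg(estimator),
                 cand_factor = as.integer(cand_factor)),
            class = "mic_config")
}

#' Maximal information coefficient
#'
#' @param x,y numeric series of equal length (n >= 20)
#' @param config a [mic_config()]
#' @param warn warn on constant input (which yields 0)
#' @return a number in \[0, 1\]
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(200)
#' mic(x, x)            # noiseless functional relationship: close to 1
#' mic(x, runif(200))   # independent: small
mic <- function(x, y, config = mic_config(), warn = TRUE) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 20L) stop("MIC needs at least 20 observations")
  if (anyNA(x) || anyNA(y)) stop("series contain missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (warn) warning("constant series; MIC is 0")
    return(0)
  }
  if (config$estimator == "exhaustive_small") {
    return(mic_exhaustive(x, y, config))
  }
  mic_cpp(x, y, config$exponent, config$max_grid_axis, config$cand_factor)
}

# Oracle estimator: enumerate all consecutive-group partitions of the sorted
# order of both axes for every admissible (a, b). Cost grows as
# choose(n-1, a-1) * choose(n-1, b-1); refuse clearly infeasible calls.
mic_exhaustive <- function(x, y, config) {
  n <- length(x)
  B <- n^config$exponent
  ordx <- order(x, seq_along(x)); ordy <- order(y, seq_along(y))
  rx <- integer(n); rx[ordx] <- seq_len(n)
  ry <- integer(n); ry[ordy] <- seq_len(n)
  best <- 0
  for (a in 2:max(2L, floor(B / 2))) {
    for (b in 2:max(2L, floor(B / 2))) {
      if (a * b >= B) next
      if (choose(n - 1, a - 1) * choose(n - 1, b - 1) > 2e5) {
        stop("exhaustive MIC enumeration budget exceeded")
      }
      cuts_x <- utils::combn(n - 1L, a - 1L, simplify = FALSE)
      cuts_y <- utils::combn(n - 1L, b - 1L, simplify = FALSE)
      for (cx in cuts_x) {
        bx <- findInterval(rx, c(0L, cx, n), left.open = TRUE)
        for (cy in cuts_y) {
          by <- findInterval(ry, c(0L, cy, n), left.open = TRUE)
          tab <- table(bx, by) / n
          px <- rowSums(tab); py <- colSums(tab)
          mi <- sum(ifelse(tab > 0, tab * log(tab / outer(px, py)), 0))
          val <- mi / log(min(a, b))
          if (val > best) best <- val
        }
      }
    }
  }
  min(max(best, 0), 1)
}

#' Relevance between two sensor placements
#'
#' The sum of the MICs between every feature of one placement and every
#' feature of the other (`s = 6` features per placement: 3 axis-angle + 3
#' acceleration components of the root-normalized data), bounded by `s^2`.
#'
#' @param sensor_x,sensor_y bone ids
#' @param data a root-normalized motion table
#' @param config a [mic_config()]
#' @param max_frames cap on frames used (deterministic stride subsampling)
#' @return a nonnegative number
#' @export
relevance <- function(sensor_x, sensor_y, data, config = mic_config(),
                      max_frames = 10000L) {
  fx <- sensor_features(data, sensor_x, max_frames)
  fy <- sensor_features(data, sensor_y, max_frames)
  s <- ncol(fx)
  total <- 0
  for (i in seq_len(s)) for (j in seq_len(ncol(fy))) {
    total <- total + mic(fx[, i], fy[, j], config, warn = FALSE)
  }
  total
}

sensor_features <- function(data, bone, max_frames) {
  f <- extract_features(data, bones = bone)
  n <- nrow(f)
  if (n > max_frames) {
    idx <- unique(round(seq(1L, n, length.out = max_frames)))
    f <- f[idx, , drop = FALSE]
  }
  f
}

#' Relevance matrix over all placements
#'
#' Computes the symmetric placement-by-placement relevance matrix used by
#' the max-relevance/min-redundancy scores. MIC cost is superlinear in the
#' series length, so frames are subsampled by a deterministic stride down
#' to `max_frames`. The diagonal is the constant `s * MIC(x; x) = s`
#' (each of a placement's `s` features carries maximal information about
#' itself), so the self-pairs inside the redundancy score contribute a
#' fixed `s / |S|` offset that leaves rankings at a given group size
#' unchanged.
#'
#' @param data a root-normalized motion table
#' @param config a [mic_config()]
#' @param bones placements to include (default: the data's full skeleton)
#' @param max_frames frame cap for the MIC estimates
#' @return a named symmetric matrix of relevances
#' @export
relevance_matrix <- function(data, config = mic_config(), bones = NULL,
                             max_frames = 10000L) {
  if (!is_normalized(data)) data <- normalize_frames(data)
  if (is.null(bones)) bones <- motion_bones(data)
  p <- length(bones)
  feats <- lapply(bones, function(b) sensor_features(data, b, max_frames))
  rel <- matrix(0, p, p, dimnames = list(bones, bones))
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        rel[i, i] <- ncol(feats[[i]])
        next
      }
      total <- 0
      fi <- feats[[i]]; fj <- feats[[j]]
      for (a in seq_len(ncol(fi))) for (b in seq_len(ncol(fj))) {
        total <- total + mic(fi[, a], fj[, b], config, warn = FALSE)
      }
      rel[i, j] <- total
      rel[j, i] <- total
    }
  }
  rel
}

#' Group relevance, redundancy and quality scores
#'
#' `group_relevance_T` is the mean relevance between selected placements
#' `S` and unselected placements `C`; `group_redundancy_R` the mean
#' relevance among selected placements (the double sum includes the
#' self-pairs); `phi` their difference, the quantity the greedy placement
#' search maximizes. When every sensor is selected (`C` empty) the
#' relevance term is defined as 0.
#'
#' @param S,C character vectors of placement ids
#' @param rel a relevance matrix from [relevance_matrix()]
#' @return a number
#' @export
group_relevance_T <- function(S, C, rel) {
  if (length(C) == 0L) return(0)
  stopifnot(length(S) >= 1L)
  sum(rel[S, C, drop = FALSE]) / (length(S) * length(C))
}

#' @rdname group_relevance_T
#' @export
group_redundancy_R <- function(S, rel) {
  stopifnot(length(S) >= 1L)
  sum(rel[S, S, drop = FALSE]) / length(S)^2
}

#' @rdname group_relevance_T
#' @export
phi <- function(S, C, rel) {
  group_relevance_T(S, C, rel) - group_redundancy_R(S, rel)
}

new_sensor_group <- function(selected, universe, rel, trace, method) {
  structure(list(selected = selected, unselected = setdiff(universe, selected),
                 relevance = rel, trace = trace, method = method),
            class = "sensor_group")
}

#' @export
print.sensor_group <- function(x, ...) {
  cat(sprintf("<sensor_group (%s): %d of %d placements>\n", x$method,
              length(x$selected), length(x$selected) + length(x$unselected)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  T = %.3f  R = %.3f  Phi = %.3f\n", last$T, last$R, last$phi))
  }
  invisible(x)
}

#' Greedy max-relevance/min-redundancy sensor placement
#'
#' Selects `k` of the candidate placements (the root/pelvis is always
#' forced in and counted): the first data-driven placement is the one with
#' the greatest total relevance to all other placements; every later step
#' adds the candidate maximizing `phi(S + x, C - x)`. Ties break by
#' placement order. The per-step `(T, R, phi)` trace is attached.
#'
#' @param data a motion table (normalized internally if needed), or `NULL`
#'   when `rel` is supplied
#' @param k number of sensors including the root, `2 <= k <= #placements`
#' @param config a [mic_config()]
#' @param bones candidate placements (default: full skeleton)
#' @param rel optional precomputed relevance matrix (skips the MIC pass)
#' @param root root placement id (default from the data's skeleton)
#' @param max_frames frame cap for the MIC estimates
#' @return a `sensor_group` with fields `selected`, `unselected`,
#'   `relevance`, `trace`
#' @export
greedy_select <- function(data, k, config = mic_config(), bones = NULL,
                          rel = NULL, root = NULL, max_frames = 10000L) {
  if (is.null(rel)) {
    if (!is_normalized(data)) data <- normalize_frames(data)
    if (is.null(bones)) bones <- motion_bones(data)
    if (is.null(root)) {
      sk <- motion_skeleton(data)
      root <- if (!is.null(sk)) skeleton_root(sk) else "pelvis"
    }
    rel <- relevance_matrix(data, config, bones, max_frames)
  } else {
    bones <- rownames(rel)
    if (is.null(root)) root <- "pelvis"
  }
  if (!root %in% bones) stop("root placement '", root, "' not among candidates")
  p <- length(bones)
  if (k < 2L || k > p) stop("k must be between 2 and ", p)

  S <- root
  others <- setdiff(bones, root)
  # first data-driven sensor: maximum total relevance to the placements it
  # would have to predict
  tot <- vapply(others, function(x) sum(rel[x, setdiff(bones, c(S, x))]), 0)
  first <- others[which.max(tot)]
  S <- c(S, first)
  trace <- list(step_row(S, bones, rel, first))
  while (length(S) < k) {
    cand <- setdiff(bones, S)
    scores <- vapply(cand, function(x) phi(c(S, x), setdiff(cand, x), rel), 0)
    nxt <- cand[which.max(scores)]  # which.max takes the first = placement order
    S <- c(S, nxt)
    trace[[length(trace) + 1L]] <- step_row(S, bones, rel, nxt)
  }
  new_sensor_group(S, bones, rel, dplyr::bind_rows(trace), "greedy")
}

step_row <- function(S, bones, rel, added) {
  C <- setdiff(bones, S)
  tibble::tibble(step = length(S), added = added,
                 T = group_relevance_T(S, C, rel),
                 R = group_redundancy_R(S, rel),
                 phi = phi(S, C, rel))
}

#' Exhaustive sensor placement (oracle)
#'
#' Enumerates every k-subset containing the root and returns the exact
#' maximizer of `phi`; used to validate the greedy search on small
#' candidate sets. Refuses runs with more than `1e5` subsets.
#'
#' @inheritParams greedy_select
#' @return a `sensor_group` with `method = "exhaustive"`
#' @export
exhaustive_select <- function(data, k, config = mic_config(), bones = NULL,
                              rel = NULL, root = NULL, max_frames = 10000L) {
  if (is.null(rel)) {
    if (!is_normalized(data)) data <- normalize_frames(data)
    if (is.null(bones)) bones <- motion_bones(data)
    if (is.null(root)) {
      sk <- motion_skeleton(data)
      root <- if (!is.null(sk)) skeleton_root(sk) else "pelvis"
    }
    rel <- relevance_matrix(data, config, bones, max_frames)
  } else {
    bones <- rownames(rel)
    if (is.null(root)) root <- "pelvis"
  }
  p <- length(bones)
  if (k < 2L || k > p) stop("k must be between 2 and ", p)
  others <- setdiff(bones, root)
  n_comb <- choose(length(others), k - 1L)
  if (n_comb > 1e5) stop("exhaustive enumeration budget exceeded: ", n_comb, " subsets")
  best <- NULL; best_phi <- -Inf
  combs <- utils::combn(others, k - 1L, simplify = FALSE)
  for (cc in combs) {
    S <- c(root, cc)
    val <- phi(S, setdiff(bones, S), rel)
    if (val > best_phi + 1e-12) { best_phi <- val; best <- S }
  }
  trace <- step_row(best, bones, rel, best[length(best)])
  trace$step <- length(best)
  new_sensor_group(best, bones, rel, trace, "exhaustive")
}
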