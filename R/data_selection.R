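#' Training-data selection configuration
#'
#' Parameters of the two-step IID training-data selection: segments are
#' cut into `unit_length`-frame data units (50 frames = 0.5 s at 100 Hz);
#' units whose maximum frame-wise cosine similarity to any reference unit
#' reaches `similarity_threshold` (0.8) survive the screening; surviving
#' contiguous runs shorter than `min_run_length` frames (300, one model
#' sequence) are dropped; the greedy pruning stage then maximizes
#' `alpha * H(D) - beta * KL(D || Ref) - gamma * log(n_frames)` over
#' 20-bin per-feature histograms with additive smoothing `epsilon`.
#'
#' @param unit_length data-unit length N in frames
#' @param similarity_threshold cosine screening threshold eta0 in (0, 1]
#' @param min_run_length minimum surviving run length L in frames (>= N)
#' @param n_bins histogram bins per feature
#' @param alpha,beta,gamma nonnegative objective weights
#' @param epsilon additive histogram smoothing added to every bin count
#' @param include_reference append the reference data itself to the final
#'   training selection
#' @param bones bones whose features are used; default all non-root bones
#' @return a `selection_config` list
#' @export
selection_config <- function(unit_length = 50L, similarity_threshold = 0.8,
                             min_run_length = 300L, n_bins = 20L,
                             alpha = 1, beta = 1, gamma = 1, epsilon = 1e-6,
                             include_reference = TRUE, bones = NULL) {
  stopifnot(similarity_threshold <= 1, min_run_length >= unit_length,
            alpha >= 0, beta >= 0, gamma >= 0, epsilon > 0, n_bins >= 2)
  structure(list(unit_length = as.integer(unit_length),
                 similarity_threshold = similarity_threshold,
                 min_run_length = as.integer(min_run_length),
                 n_bins = as.integer(n_bins), alpha = alpha, beta = beta,
                 gamma = gamma, epsilon = epsilon,
                 include_reference = include_reference, bones = bones),
            class = "selection_config")
}

#' Split a motion table into fixed-length data units
#'
#' Cuts every segment into non-overlapping consecutive windows of exactly
#' `unit_length` frames; a trailing remainder shorter than a unit is
#' discarded. Each unit carries its feature matrix (frames x features).
#'
#' @param data a root-normalized motion table
#' @param config a [selection_config()]
#' @return a tibble with columns `segment_id`, `start` (1-based frame
#'   offset within the segment), `length`, and list-column `features`
#' @export
split_into_units <- function(data, config = selection_config()) {
  feats <- extract_features(data, config$bones)
  n_unit <- config$unit_length
  df <- tibble::as_tibble(data[META_COLS])
  df$row <- seq_len(nrow(df))
  segs <- split(df, df$segment_id)
  out <- list()
  for (seg in segs) {
    seg <- seg[order(seg$frame), ]
    k <- nrow(seg) %/% n_unit
    if (k == 0L) next
    for (u in seq_len(k)) {
      rows <- seg$row[((u - 1L) * n_unit + 1L):(u * n_unit)]
      out[[length(out) + 1L]] <- tibble::tibble(
        segment_id = seg$segment_id[1L],
        start = (u - 1L) * n_unit + 1L,
        length = n_unit,
        features = list(feats[rows, , drop = FALSE]))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(segment_id = character(), start = integer(),
                          length = integer(), features = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$segment_id, .data$start)
}

# rows normalized to unit length; zero rows become zero vectors (their
# cosine term is 0, a neutral contribution)
unit_row_normalize <- function(m, warn = TRUE) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero) && warn) warning("zero-norm frame feature vector; cosine term set to 0")
  nrm[zero] <- 1
  m / nrm
}

#' Cosine similarity between two data units
#'
#' The mean, over the paired frames of the two units, of the cosine of the
#' angle between their frame feature vectors. A zero-norm frame vector
#' contributes 0 to the mean (with a warning).
#'
#' @param u1,u2 feature matrices of equal dimensions (frames x features)
#' @return a number in \[-1, 1\]
#' @export
unit_similarity <- function(u1, u2) {
  if (!all(dim(u1) == dim(u2))) stop("units must have equal length and feature count")
  mean(rowSums(unit_row_normalize(u1) * unit_row_normalize(u2)))
}

#' Screen corpus units against the reference (similarity filtering)
#'
#' Keeps corpus units whose maximum similarity to any reference unit is at
#' least `similarity_threshold`, merges kept units that are contiguous in
#' their source segment into runs, and discards runs shorter than
#' `min_run_length` frames. The result is the similar dataset, the
#' candidate pool for greedy pruning.
#'
#' @param corpus_units,ref_units unit tibbles from [split_into_units()]
#' @param config a [selection_config()]
#' @return a `motion_selection`: a tibble of `(segment_id, start, length)`
#'   pieces with the per-unit maximum similarities as attribute `eta_max`
#' @export
select_similar <- function(corpus_units, ref_units, config = selection_config()) {
  if (nrow(ref_units) == 0L) stop("reference produced no data units")
  if (nrow(corpus_units) == 0L) stop("corpus produced no data units")
  nfr <- config$unit_length
  ref_flat <- t(vapply(ref_units$features, function(f) as.numeric(unit_row_normalize(f, warn = FALSE)),
                       numeric(nfr * ncol(ref_units$features[[1L]]))))
  cor_flat <- t(vapply(corpus_units$features, function(f) as.numeric(unit_row_normalize(f, warn = FALSE)),
                       numeric(nfr * ncol(corpus_units$features[[1L]]))))
  # sim(u1, u2) = (1/N) sum_i <n1_i, n2_i> = (1/N) * flat dot product
  eta <- (cor_flat %*% t(ref_flat)) / nfr
  eta_max <- apply(eta, 1L, max)
  keep <- eta_max >= config$similarity_threshold
  if (!any(keep)) {
    stop("no corpus data is similar to the reference; consider lowering similarity_threshold")
  }
  kept <- corpus_units[keep, c("segment_id", "start", "length")]
  # merge contiguous kept units into runs
  kept <- dplyr::arrange(kept, .data$segment_id, .data$start)
  runs <- list()
  cur <- NULL
  for (i in seq_len(nrow(kept))) {
    row <- kept[i, ]
    if (!is.null(cur) && row$segment_id == cur$segment_id &&
        row$start == cur$start + cur$length) {
      cur$length <- cur$length + row$length
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- row
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  pieces <- dplyr::bind_rows(runs)
  pieces <- pieces[pieces$length >= config$min_run_length, ]
  if (nrow(pieces) == 0L) {
    stop("no similar run reaches min_run_length; consider lowering similarity_threshold")
  }
  new_selection(pieces, config, eta_max = eta_max)
}

new_selection <- function(pieces, config, trace = NULL, eta_max = NULL, sizes = NULL) {
  pieces <- tibble::as_tibble(pieces)
  attr(pieces, "config") <- config
  attr(pieces, "trace") <- trace
  attr(pieces, "eta_max") <- eta_max
  attr(pieces, "sizes") <- sizes
  class(pieces) <- unique(c("motion_selection", class(pieces)))
  pieces
}

#' @export
print.motion_selection <- function(x, ...) {
  cat(sprintf("<motion_selection: %d pieces, %d frames>\n", nrow(x), sum(x$length)))
  NextMethod()
}

#' Extract the frames covered by a selection
#'
#' @param selection a `motion_selection`
#' @param data the motion table the selection indexes into
#' @return the motion table restricted to the selected frames
#' @export
selected_frames <- function(selection, data) {
  parts <- list()
  for (i in seq_len(nrow(selection))) {
    seg <- data[data$segment_id == selection$segment_id[i], ]
    seg <- seg[order(seg$frame), ]
    parts[[i]] <- seg[selection$start[i]:(selection$start[i] + selection$length[i] - 1L), ]
  }
  out <- dplyr::bind_rows(parts)
  new_motion_tbl(out, motion_skeleton(data), motion_frame_rate(data),
                 normalized = is_normalized(data))
}

#' Per-feature histograms
#'
#' Discretizes each feature into `n_bins` equal-width intervals spanning
#' `bin_edges` (or, if absent, the pooled min/max of the data per
#' feature); every bin receives additive smoothing `epsilon` before
#' normalization so downstream KL terms stay finite.
#'
#' @param x numeric feature matrix (observations x features)
#' @param bin_edges optional n_features x (n_bins + 1) edge matrix
#' @param n_bins bins per feature
#' @param epsilon additive smoothing per bin count
#' @return a `feature_histogram`: list with `edges` and row-stochastic
#'   `prob` (n_features x n_bins)
#' @export
fit_histogram <- function(x, bin_edges = NULL, n_bins = 20L, epsilon = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("histogram needs at least one observation")
  nf <- ncol(x)
  if (is.null(bin_edges)) {
    bin_edges <- t(vapply(seq_len(nf), function(i) {
      rng <- range(x[, i])
      if (rng[1L] == rng[2L]) {
        warning("constant feature ", i, "; widening its bin range by machine epsilon")
        rng <- rng + c(-1, 1) * max(abs(rng[1L]), 1) * 1e-12
      }
      seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    }, numeric(n_bins + 1L)))
  } else {
    bin_edges <- as.matrix(bin_edges)
    stopifnot(nrow(bin_edges) == nf)
    n_bins <- ncol(bin_edges) - 1L
  }
  counts <- histogram_counts(x, bin_edges)
  prob <- (counts + epsilon)
  prob <- prob / rowSums(prob)
  structure(list(edges = bin_edges, prob = prob, n = nrow(x)),
            class = "feature_histogram")
}

# raw per-feature bin counts on fixed edges; values outside the edge range
# are clamped into the boundary bins
histogram_counts <- function(x, bin_edges) {
  nf <- ncol(x)
  n_bins <- ncol(bin_edges) - 1L
  counts <- matrix(0, nf, n_bins)
  for (i in seq_len(nf)) {
    e <- bin_edges[i, ]
    idx <- findInterval(x[, i], e, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > n_bins] <- n_bins
    counts[i, ] <- tabulate(idx, n_bins)
  }
  counts
}

#' KL divergence between feature histograms
#'
#' The mean over features of `sum_x P(x) log(P(x)/Q(x))` (natural log);
#' the histograms' additive smoothing keeps the value finite. Both
#' histograms must share bin edges.
#'
#' @param P,Q `feature_histogram`s on identical edges
#' @return a nonnegative number
#' @export
kl_distance <- function(P, Q) {
  if (!isTRUE(all.equal(P$edges, Q$edges))) stop("histograms have mismatched bin edges")
  mean(rowSums(P$prob * log(P$prob / Q$prob)))
}

#' Mean per-feature Shannon entropy of a histogram
#'
#' `(1/N_f) sum_i sum_x -P_i(x) log P_i(x)` in nats: the information
#' content term of the selection objective.
#'
#' @param P a `feature_histogram`
#' @return a number in \[0, log(n_bins)\]
#' @export
entropy_term <- function(P) {
  mean(rowSums(-P$prob * log(P$prob)))
}

#' Data-amount term of the selection objective
#'
#' The natural log of the total number of selected frames.
#'
#' @param selection a `motion_selection` (or anything with a `length` column)
#' @return `log(sum(length))`
#' @export
data_amount <- function(selection) {
  if (nrow(selection) == 0L) stop("selection is empty")
  log(sum(selection$length))
}

# objective from precomputed counts (fast path shared with greedy_prune)
obj_from_counts <- function(counts, total_frames, ref_prob, config) {
  p <- counts + config$epsilon
  p <- p / rowSums(p)
  H <- mean(rowSums(-p * log(p)))
  KL <- mean(rowSums(p * log(p / ref_prob)))
  config$alpha * H - config$beta * KL - config$gamma * log(total_frames)
}

#' Training-data selection objective
#'
#' `alpha * H(P_D) - beta * KL(P_D || Q_ref) - gamma * log(n_frames)`,
#' with the selection's histogram fitted on the reference histogram's bin
#' edges so the two are comparable.
#'
#' @param selection a `motion_selection`
#' @param data the root-normalized motion table the selection indexes
#' @param ref_hist the reference `feature_histogram`
#' @param config a [selection_config()]
#' @return the objective value (larger is better)
#' @export
fds_objective <- function(selection, data, ref_hist, config = selection_config()) {
  if (nrow(selection) == 0L) stop("selection is empty")
  feats <- extract_features(selected_frames(selection, data), config$bones)
  counts <- histogram_counts(feats, ref_hist$edges)
  obj_from_counts(counts, sum(selection$length), ref_hist$prob, config)
}

#' Greedy pruning of the candidate selection
#'
#' Starting from the full candidate set (the similar dataset), repeatedly
#' deletes the piece whose removal maximizes the objective, as long as the
#' best single deletion strictly improves it and at least
#' `min_run_length` frames remain. Ties break toward the lowest
#' `(segment_id, start)`. The per-iteration objective trace (monotone
#' non-decreasing) is attached to the result.
#'
#' @param candidate a `motion_selection` (the similar dataset)
#' @param data the root-normalized corpus motion table
#' @param ref_hist the reference `feature_histogram`
#' @param config a [selection_config()]
#' @return the pruned `motion_selection` with attribute `trace`
#' @export
greedy_prune <- function(candidate, data, ref_hist, config = selection_config()) {
  stopifnot(nrow(candidate) >= 1L)
  candidate <- dplyr::arrange(tibble::as_tibble(candidate), .data$segment_id, .data$start)
  k <- nrow(candidate)
  # per-piece histogram counts, computed once
  piece_counts <- vector("list", k)
  for (i in seq_len(k)) {
    feats <- extract_features(selected_frames(candidate[i, ], data), config$bones)
    piece_counts[[i]] <- histogram_counts(feats, ref_hist$edges)
  }
  alive <- rep(TRUE, k)
  total_counts <- Reduce(`+`, piece_counts)
  total_frames <- sum(candidate$length)
  cur_obj <- obj_from_counts(total_counts, total_frames, ref_hist$prob, config)
  trace <- list(tibble::tibble(iteration = 0L, removed_segment = NA_character_,
                               removed_start = NA_integer_, objective = cur_obj,
                               n_frames = total_frames))
  it <- 0L
  repeat {
    idx <- which(alive)
    if (length(idx) <= 1L) break
    best <- NULL; best_obj <- -Inf
    for (i in idx) {
      rem_frames <- total_frames - candidate$length[i]
      if (rem_frames < config$min_run_length) next
      obj <- obj_from_counts(total_counts - piece_counts[[i]], rem_frames,
                             ref_hist$prob, config)
      if (obj > best_obj + 1e-12) { best_obj <- obj; best <- i }
    }
    if (is.null(best) || best_obj <= cur_obj + 1e-12) break
    alive[best] <- FALSE
    total_counts <- total_counts - piece_counts[[best]]
    total_frames <- total_frames - candidate$length[best]
    cur_obj <- best_obj
    it <- it + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(
      iteration = it, removed_segment = candidate$segment_id[best],
      removed_start = candidate$start[best], objective = cur_obj,
      n_frames = total_frames)
  }
  new_selection(candidate[alive, ], config, trace = dplyr::bind_rows(trace))
}

#' Select IID training data matching a reference sample
#'
#' The full two-step pipeline: cut the corpus and the reference into data
#' units, screen corpus units by cosine similarity against the reference,
#' then greedily prune the surviving runs to maximize the
#' entropy/KL/data-amount objective. Histogram bin edges are fixed from
#' the pooled per-feature range of the screened data and the reference so
#' that both distributions are binned identically.
#'
#' @param corpus a motion table (world frame or already normalized)
#' @param reference a motion table of target-scenario reference data
#' @param config a [selection_config()]
#' @return a `motion_selection` over the corpus, with attributes `trace`
#'   (greedy objective trace) and `sizes` (frame counts of the corpus, the
#'   similar dataset and the final selection)
#' @export
select_training_data <- function(corpus, reference, config = selection_config()) {
  if (nrow(corpus) == 0L) stop("no similar data: the corpus is empty")
  if (!is_normalized(corpus)) corpus <- normalize_frames(corpus)
  if (!is_normalized(reference)) reference <- normalize_frames(reference)
  corpus_units <- split_into_units(corpus, config)
  ref_units <- split_into_units(reference, config)
  similar <- select_similar(corpus_units, ref_units, config)

  ref_feats <- extract_features(reference, config$bones)
  sim_feats <- extract_features(selected_frames(similar, corpus), config$bones)
  pooled <- rbind(sim_feats, ref_feats)
  edges <- t(vapply(seq_len(ncol(pooled)), function(i) {
    rng <- range(pooled[, i])
    if (rng[1L] == rng[2L]) rng <- rng + c(-1, 1) * max(abs(rng[1L]), 1) * 1e-12
    seq(rng[1L], rng[2L], length.out = config$n_bins + 1L)
  }, numeric(config$n_bins + 1L)))
  ref_hist <- fit_histogram(ref_feats, bin_edges = edges, epsilon = config$epsilon)

  pruned <- greedy_prune(similar, corpus, ref_hist, config)
  sizes <- c(corpus = nrow(corpus), similar = sum(similar$length),
             selected = sum(pruned$length))
  message(sprintf("data selection: corpus %d frames -> similar %d -> selected %d",
                  sizes[1L], sizes[2L], sizes[3L]))
  new_selection(pruned, config, trace = attr(pruned, "trace"),
                eta_max = attr(similar, "eta_max"), sizes = sizes)
}
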