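#' Posture-model configuration
#'
#' Hyperparameters of the bidirectional LSTM posture reconstructor. The
#' model consumes windows of `sequence_length` frames (default 300, i.e.
#' 150 frames of past and future context at 100 Hz) of the selected
#' bones' root-normalized rotation matrices and accelerations, applies
#' dropout to the input layer, runs one LSTM layer in each time direction,
#' and regresses, per frame, the unselected bones' axis-angle orientation
#' and acceleration norm with a linear readout, minimizing mean squared
#' error.
#'
#' @param sequence_length window length in frames (even)
#' @param input_dropout input-layer dropout probability in \[0, 1)
#' @param hidden_units LSTM units per direction
#' @param learning_rate Adam step size
#' @param epochs training epochs
#' @param seed integer seed fixing initialization, dropout and batching
#' @param stride training window stride (default: `sequence_length`,
#'   non-overlapping windows)
#' @return a `model_config` list
#' @export
model_config <- function(sequence_length = 300L, input_dropout = 0.2,
                         hidden_units = 64L, learning_rate = 5e-3,
                         epochs = 50L, seed = 1L, stride = NULL) {
  stopifnot(sequence_length %% 2 == 0, input_dropout >= 0, input_dropout < 1,
            hidden_units >= 1, epochs >= 1)
  structure(list(sequence_length = as.integer(sequence_length),
                 input_dropout = input_dropout,
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 stride = if (is.null(stride)) as.integer(sequence_length)
                          else as.integer(stride)),
            class = "model_config")
}

# per-frame model input (12 per selected bone) and target (4 per unselected)
model_io_frames <- function(data, selected, unselected) {
  x <- matrix(0, nrow(data), 12L * length(selected))
  for (j in seq_along(selected)) {
    b <- selected[j]
    x[, (12L * (j - 1L) + 1L):(12L * j)] <- cbind(bone_rot(data, b), bone_acc(data, b))
  }
  y <- matrix(0, nrow(data), 4L * length(unselected))
  for (j in seq_along(unselected)) {
    b <- unselected[j]
    aa <- rotation_to_axis_angle(bone_rot(data, b))
    an <- sqrt(rowSums(bone_acc(data, b)^2))
    y[, (4L * (j - 1L) + 1L):(4L * j)] <- cbind(aa, an)
  }
  list(x = x, y = y)
}

#' Build training windows from a motion table
#'
#' Slides `sequence_length`-frame windows (stride `config$stride`) over
#' every segment; windows never cross segment boundaries and segments
#' shorter than one window are skipped with a message. The input encodes
#' each selected bone's root-normalized rotation matrix (9 entries) and
#' acceleration (3); the target encodes each unselected bone's axis-angle
#' orientation (3) and acceleration norm (1).
#'
#' @param data a root-normalized motion table
#' @param group a `sensor_group` (or list with `selected`/`unselected`)
#' @param config a [model_config()]
#' @return a list with arrays `x` (windows x frames x 12n), `y`
#'   (windows x frames x 4m) and a `meta` tibble of window origins
#' @export
make_examples <- function(data, group, config = model_config()) {
  if (!is_normalized(data)) stop("frames must be root-normalized")
  selected <- group$selected
  unselected <- group$unselected
  io <- model_io_frames(data, selected, unselected)
  Lw <- config$sequence_length
  meta <- list(); xs <- list(); ys <- list()
  df <- tibble::as_tibble(data[META_COLS]); df$row <- seq_len(nrow(df))
  for (seg in split(df, df$segment_id)) {
    seg <- seg[order(seg$frame), ]
    if (nrow(seg) < Lw) {
      message("skipping segment ", seg$segment_id[1L], ": shorter than one window")
      next
    }
    starts <- seq(1L, nrow(seg) - Lw + 1L, by = config$stride)
    for (s in starts) {
      rows <- seg$row[s:(s + Lw - 1L)]
      xs[[length(xs) + 1L]] <- io$x[rows, , drop = FALSE]
      ys[[length(ys) + 1L]] <- io$y[rows, , drop = FALSE]
      meta[[length(meta) + 1L]] <- tibble::tibble(
        segment_id = seg$segment_id[1L], activity = seg$activity[1L], start = s)
    }
  }
  if (!length(xs)) stop("no segment is long enough for a single window")
  nw <- length(xs)
  x <- array(0, c(nw, Lw, ncol(io$x)))
  y <- array(0, c(nw, Lw, ncol(io$y)))
  for (i in seq_len(nw)) { x[i, , ] <- xs[[i]]; y[i, , ] <- ys[[i]] }
  list(x = x, y = y, meta = dplyr::bind_rows(meta),
       selected = selected, unselected = unselected)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

init_lstm_dir <- function(din, H) {
  # small uniform init; forget-gate bias 1 for stable memory early on
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc)
  b <- rep(0, 4L * H); b[(H + 1L):(2L * H)] <- 1
  list(W = u(din, 4L * H), U = u(H, 4L * H), b = b)
}

# forward pass of one direction over a list of B x din input matrices;
# returns hidden states and the cache needed for backprop
lstm_forward <- function(xt, par, H) {
  Tt <- length(xt); B <- nrow(xt[[1L]])
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tt)
  hs <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    z <- xt[[t]] %*% par$W + h %*% par$U + matrix(par$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    o <- sigmoid(z[, (2L * H + 1L):(3L * H), drop = FALSE])
    g <- tanh(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev, tc = tc,
                       h_prev = h_prev)
    hs[[t]] <- h
  }
  list(h = hs, cache = cache)
}

# backward pass; dh_list holds dL/dh_t; returns parameter grads
lstm_backward <- function(xt, par, H, fwd, dh_list) {
  Tt <- length(xt); B <- nrow(xt[[1L]])
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  dU <- matrix(0, H, 4L * H)
  db <- rep(0, 4L * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    cc <- fwd$cache[[t]]
    dh <- dh_list[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    dW <- dW + crossprod(xt[[t]], dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(par$U)
    dc_next <- dc * cc$f
  }
  list(W = dW, U = dU, b = db)
}

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

adam_init <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(m = zeros, v = zeros)
}

#' Train the bidirectional LSTM posture reconstructor
#'
#' Fits the model by full-batch Adam on the mean squared error of the
#' per-frame output vector, with inverted dropout on the input layer.
#' Inputs and targets are standardized internally (the scales are stored
#' in the model and undone at prediction time). Training is deterministic
#' given `config$seed`.
#'
#' @param examples windows from [make_examples()]
#' @param config a [model_config()]
#' @return a `posture_model` with the fitted weights, the
#'   standardization scales and the per-epoch `loss_history`
#' @export
train_posture_model <- function(examples, config = model_config()) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  x <- examples$x; y <- examples$y
  nw <- dim(x)[1L]; Tt <- dim(x)[2L]; din <- dim(x)[3L]; dout <- dim(y)[3L]
  H <- config$hidden_units

  # inputs: standardized per channel. Targets: centered per channel but
  # scaled per channel *group* (one global scale for all axis-angle
  # channels, one for all acceleration norms), so the squared error
  # weights every radian of every bone equally -- per-channel scaling
  # would starve near-constant bones of gradient and misalign the loss
  # with the angular-error metric.
  xm <- apply(x, 3L, mean); xs <- apply(x, 3L, stats::sd); xs[xs < 1e-8] <- 1
  ym <- apply(y, 3L, mean)
  is_aa <- rep(c(TRUE, TRUE, TRUE, FALSE), dout / 4L)
  sd_aa <- stats::sd(y[, , is_aa, drop = FALSE])
  sd_an <- stats::sd(y[, , !is_aa, drop = FALSE])
  ys <- ifelse(is_aa, max(sd_aa, 1e-8), max(sd_an, 1e-8))
  for (d in seq_len(din)) x[, , d] <- (x[, , d] - xm[d]) / xs[d]
  for (d in seq_len(dout)) y[, , d] <- (y[, , d] - ym[d]) / ys[d]

  # time-major views: list over t of (windows x dim)
  xt0 <- lapply(seq_len(Tt), function(t) matrix(x[, t, ], nw, din))
  yt <- lapply(seq_len(Tt), function(t) matrix(y[, t, ], nw, dout))

  par <- list(fw = init_lstm_dir(din, H), bw = init_lstm_dir(din, H),
              V = matrix(stats::runif(2L * H * dout, -0.08, 0.08), 2L * H, dout),
              c = rep(0, dout))
  st <- list(fw = adam_init(par$fw), bw = adam_init(par$bw),
             out = adam_init(list(V = par$V, c = par$c)))

  loss_hist <- numeric(config$epochs)
  p_drop <- config$input_dropout
  for (epoch in seq_len(config$epochs)) {
    xt <- xt0
    if (p_drop > 0) {
      for (t in seq_len(Tt)) {
        mask <- matrix(stats::rbinom(nw * din, 1L, 1 - p_drop), nw, din) / (1 - p_drop)
        xt[[t]] <- xt0[[t]] * mask
      }
    }
    fwd_f <- lstm_forward(xt, par$fw, H)
    fwd_b <- lstm_forward(rev(xt), par$bw, H)
    hb <- rev(fwd_b$h)  # align backward states with forward time
    dV <- matrix(0, 2L * H, dout); dc_out <- rep(0, dout)
    dh_f <- vector("list", Tt); dh_b_rev <- vector("list", Tt)
    loss <- 0
    denom <- nw * Tt * dout
    for (t in seq_len(Tt)) {
      hcat <- cbind(fwd_f$h[[t]], hb[[t]])
      pred <- hcat %*% par$V + matrix(par$c, nw, dout, byrow = TRUE)
      err <- pred - yt[[t]]
      loss <- loss + sum(err^2)
      derr <- 2 * err / denom
      dV <- dV + crossprod(hcat, derr)
      dc_out <- dc_out + colSums(derr)
      dh <- derr %*% t(par$V)
      dh_f[[t]] <- dh[, 1:H, drop = FALSE]
      dh_b_rev[[Tt - t + 1L]] <- dh[, (H + 1L):(2L * H), drop = FALSE]
    }
    loss_hist[epoch] <- loss / denom
    if (!is.finite(loss_hist[epoch])) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    g_f <- lstm_backward(xt, par$fw, H, fwd_f, dh_f)
    g_b <- lstm_backward(rev(xt), par$bw, H, fwd_b, dh_b_rev)
    up <- adam_step(par$fw, g_f, st$fw, config$learning_rate, epoch)
    par$fw <- up$par; st$fw <- up$state
    up <- adam_step(par$bw, g_b, st$bw, config$learning_rate, epoch)
    par$bw <- up$par; st$bw <- up$state
    up <- adam_step(list(V = par$V, c = par$c), list(V = dV, c = dc_out),
                    st$out, config$learning_rate, epoch)
    par$V <- up$par$V; par$c <- up$par$c; st$out <- up$state
  }
  structure(list(config = config, params = par,
                 selected = examples$selected, unselected = examples$unselected,
                 input_dim = din, output_dim = dout,
                 x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
                 loss_history = loss_hist),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf(paste0("<posture_model: bidirectional LSTM, %d units/direction, ",
                     "%d -> %d, final loss %.4g>\n"),
              x$config$hidden_units, x$input_dim, x$output_dim,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Reconstruct unselected-bone posture from selected-bone measurements
#'
#' Runs the fitted model over each segment of a root-normalized motion
#' table and returns per-frame predictions for every unselected bone:
#' axis-angle orientation, the rotation matrix it converts to, and the
#' predicted acceleration norm (reported but not used in pose assembly).
#' Segments are processed in tiles of the model's `sequence_length` (the
#' last tile is shifted back to fit), so the recurrent state is only ever
#' run at the length it was trained on; shorter segments run as one
#' shorter sequence.
#'
#' @param model a `posture_model`
#' @param data a root-normalized motion table containing the model's
#'   selected bones
#' @return a tibble with one row per frame and unselected bone
#' @export
reconstruct <- function(model, data) {
  if (!is_normalized(data)) stop("frames must be root-normalized")
  io <- model_io_frames(data, model$selected, model$unselected)
  if (ncol(io$x) != model$input_dim) {
    stop("input dimension mismatch: expected ", model$input_dim, ", got ", ncol(io$x))
  }
  H <- model$config$hidden_units
  par <- model$params
  preds <- matrix(0, nrow(data), model$output_dim)
  df <- tibble::as_tibble(data[META_COLS]); df$row <- seq_len(nrow(df))
  Lw <- model$config$sequence_length
  for (seg in split(df, df$segment_id)) {
    seg <- seg[order(seg$frame), ]
    rows <- seg$row
    n_seg <- length(rows)
    starts <- if (n_seg <= Lw) 1L else unique(c(seq(1L, n_seg - Lw + 1L, by = Lw),
                                                n_seg - Lw + 1L))
    for (s in starts) {
      tile <- rows[s:min(s + Lw - 1L, n_seg)]
      xseg <- sweep(sweep(io$x[tile, , drop = FALSE], 2L, model$x_center), 2L,
                    model$x_scale, `/`)
      Tt <- length(tile)
      xt <- lapply(seq_len(Tt), function(t) xseg[t, , drop = FALSE])
      hf <- lstm_forward(xt, par$fw, H)$h
      hbv <- rev(lstm_forward(rev(xt), par$bw, H)$h)
      for (t in seq_len(Tt)) {
        hcat <- cbind(hf[[t]], hbv[[t]])
        preds[tile[t], ] <- hcat %*% par$V + par$c
      }
    }
  }
  preds <- sweep(sweep(preds, 2L, model$y_scale, `*`), 2L, model$y_center, `+`)
  out <- list()
  for (j in seq_along(model$unselected)) {
    b <- model$unselected[j]
    aa <- preds[, (4L * (j - 1L) + 1L):(4L * (j - 1L) + 3L), drop = FALSE]
    r9 <- axis_angle_to_rotation(aa)
    colnames(r9) <- paste0("R", c(11, 12, 13, 21, 22, 23, 31, 32, 33))
    colnames(aa) <- c("aa1", "aa2", "aa3")
    out[[j]] <- tibble::tibble(
      segment_id = data$segment_id, activity = data$activity, frame = data$frame,
      bone = b) |>
      dplyr::bind_cols(tibble::as_tibble(aa), tibble::as_tibble(r9),
                       tibble::tibble(accel_norm = preds[, 4L * j]))
  }
  dplyr::bind_rows(out)
}

#' Evaluate posture-reconstruction error
#'
#' Mean angular error, in degrees, between reconstructed and actual
#' orientations, averaged over frames and bones; per-activity and
#' per-bone breakdowns are attached. With `reduction = "unselected"`
#' (default) the mean runs over the reconstructed bones only; with
#' `reduction = "all"` it runs over the full skeleton, the bones carrying
#' sensors contributing zero error -- the comparable reduction when
#' models with different sensor counts are set side by side, since the
#' averaging set is then fixed.
#'
#' @param model a `posture_model`
#' @param test a root-normalized motion table disjoint from training
#' @param reduction `"unselected"` or `"all"`
#' @return a `posture_eval`: list with `mean_error` (degrees),
#'   `by_activity`, `by_bone`, and the per-frame `errors` tibble
#' @export
evaluate_model <- function(model, test, reduction = c("unselected", "all")) {
  reduction <- match.arg(reduction)
  pred <- reconstruct(model, test)
  errs <- list()
  for (j in seq_along(model$unselected)) {
    b <- model$unselected[j]
    pb <- pred[pred$bone == b, ]
    pb <- pb[order(pb$segment_id, pb$frame), ]
    actual <- test[order(test$segment_id, test$frame), ]
    e <- angular_error(as.matrix(pb[paste0("R", c(11, 12, 13, 21, 22, 23, 31, 32, 33))]),
                       bone_rot(actual, b))
    errs[[j]] <- tibble::tibble(segment_id = actual$segment_id,
                                activity = actual$activity,
                                frame = actual$frame, bone = b, error_deg = e)
  }
  errors <- dplyr::bind_rows(errs)
  n_all <- length(model$selected) + length(model$unselected)
  mean_err <- if (reduction == "all") {
    sum(errors$error_deg) / (nrow(test) * n_all)
  } else {
    mean(errors$error_deg)
  }
  structure(list(
    mean_error = mean_err,
    by_activity = dplyr::summarise(dplyr::group_by(errors, .data$activity),
                                   mean_error = mean(.data$error_deg),
                                   .groups = "drop"),
    by_bone = dplyr::summarise(dplyr::group_by(errors, .data$bone),
                               mean_error = mean(.data$error_deg),
                               .groups = "drop"),
    errors = errors), class = "posture_eval")
}

#' @export
print.posture_eval <- function(x, ...) {
  cat(sprintf("<posture_eval: mean angular error %.2f deg over %d frame-bones>\n",
              x$mean_error, nrow(x$errors)))
  print(x$by_activity)
  invisible(x)
}
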