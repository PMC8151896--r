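#' Tidiers for selection and model objects
#'
#' `tidy()` returns the object's main per-element table: the selected
#' pieces for a `motion_selection`, the per-step `(T, R, phi)` trace for a
#' `sensor_group`, the per-epoch loss for a `posture_model`, and the
#' per-frame errors for a `posture_eval`. `glance()` returns a one-row
#' summary.
#'
#' @param x the object
#' @param ... unused
#' @return a tibble
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.motion_selection <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("segment_id", "start", "length")])
}

#' @rdname tidiers
#' @export
glance.motion_selection <- function(x, ...) {
  sizes <- attr(x, "sizes")
  tr <- attr(x, "trace")
  tibble::tibble(
    n_pieces = nrow(x), n_frames = sum(x$length),
    corpus_frames = if (is.null(sizes)) NA_integer_ else unname(sizes["corpus"]),
    similar_frames = if (is.null(sizes)) NA_integer_ else unname(sizes["similar"]),
    final_objective = if (is.null(tr)) NA_real_ else tr$objective[nrow(tr)])
}

#' @rdname tidiers
#' @export
tidy.sensor_group <- function(x, ...) x$trace

#' @rdname tidiers
#' @export
glance.sensor_group <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(method = x$method, k = length(x$selected),
                 T = last$T, R = last$R, phi = last$phi)
}

#' @rdname tidiers
#' @export
tidy.posture_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidiers
#' @export
glance.posture_model <- function(x, ...) {
  tibble::tibble(hidden_units = x$config$hidden_units,
                 sequence_length = x$config$sequence_length,
                 input_dim = x$input_dim, output_dim = x$output_dim,
                 epochs = x$config$epochs,
                 final_loss = x$loss_history[length(x$loss_history)])
}

#' @rdname tidiers
#' @export
tidy.posture_eval <- function(x, ...) x$errors

#' @rdname tidiers
#' @export
glance.posture_eval <- function(x, ...) {
  tibble::tibble(mean_error = x$mean_error, n = nrow(x$errors))
}

#' Plot methods
#'
#' `autoplot()` draws the natural diagnostic for each result type: the
#' greedy objective trace of a `motion_selection`, the per-step quality
#' scores of a `sensor_group`, the training-loss curve of a
#' `posture_model`, and the per-activity error distribution of a
#' `posture_eval`.
#'
#' @param object the object
#' @param ... unused
#' @return a ggplot
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.motion_selection <- function(object, ...) {
  tr <- attr(object, "trace")
  if (is.null(tr)) stop("selection has no greedy trace to plot")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "greedy deletion", y = "selection objective",
                  title = "Greedy pruning trace")
}

#' @rdname plots
#' @export
autoplot.sensor_group <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, cols = c("T", "R", "phi"),
                            names_to = "score", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sensors selected", y = "score",
                  title = "Relevance (T), redundancy (R) and quality (phi)")
}

#' @rdname plots
#' @export
autoplot.posture_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", title = "Training loss")
}

#' @rdname plots
#' @export
autoplot.posture_eval <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = .data$activity, y = .data$error_deg)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "angular error (deg)",
                  title = "Reconstruction error by activity")
}

#' @rdname plots
#' @param rel a relevance matrix from [relevance_matrix()]
#' @export
plot_relevance <- function(rel, ...) {
  df <- tibble::as_tibble(as.data.frame.table(rel, responseName = "relevance"))
  names(df)[1:2] <- c("from", "to")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$relevance)) +
    ggplot2::geom_tile() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Placement relevance matrix")
}
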