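#' Plot an embedding as a 2-D scatter of its first two dimensions
#'
#' @param object An [embedding()].
#' @param labels Optional cluster or family labels used for color.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding <- function(object, labels = NULL, ...) {
  df <- tidy_embedding(object, labels = labels)
  dims <- setdiff(names(df), c("id", "label"))
  if (length(dims) < 2) {
    abort("need at least 2 dimensions to plot", class = "seqmds_validation_error")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[dims[1]]], .data[[dims[2]]]))
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$label)),
                                 size = 0.8) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal()
}

#' @rdname autoplot.embedding
#' @export
autoplot.mds_fit <- function(object, labels = NULL, ...) {
  autoplot.embedding(object$embedding, labels = labels, ...)
}

#' @rdname autoplot.embedding
#' @export
autoplot.run_manifest <- function(object, ...) {
  autoplot.embedding(object$embedding, labels = unname(object$labels), ...)
}

#' Plot the SMACOF stress trace of a fit
#'
#' Stress is guaranteed nonincreasing across majorization iterations; this
#' plot makes the convergence visible.
#'
#' @param fit An `mds_fit` from [run_smacof()].
#' @return A ggplot object (log-scaled y axis).
#' @export
plot_stress_trace <- function(fit) {
  stopifnot(inherits(fit, "mds_fit"))
  df <- tibble(iteration = seq_along(fit$stress_trace) - 1L,
               stress = fit$stress_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$stress)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "raw stress") +
    ggplot2::theme_minimal()
}
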