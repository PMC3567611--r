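# ggplot2 displays for traces, fits, tree tables and evidence surfaces.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an observer-model trace
#'
#' Subjective probabilities (or expectancies) of every event over trials,
#' with the realised stimuli marked along the bottom.
#'
#' @param object A `p3_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.p3_trace <- function(object, ...) {
  model <- attr(object, "model")
  prefix <- if (identical(model, "SQU")) "E_" else "P_"
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with(prefix),
    names_to = "event_k", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = trial, y = value, colour = event_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      mapping = ggplot2::aes(x = trial, y = min(long$value) - 0.02,
                             shape = factor(event)),
      inherit.aes = FALSE, size = 0.8
    ) +
    ggplot2::labs(
      x = "trial n",
      y = if (identical(model, "SQU")) "expectancy E_k(n)" else "subjective probability P_k(n)",
      colour = NULL, shape = "stimulus",
      title = sprintf("%s observer trace", model)
    ) +
    ggplot2::theme_minimal()
}

#' Plot measured versus fitted amplitudes of a PEB fit
#'
#' @param object A `peb_fit`.
#' @param Y Measured amplitudes (defaults to refitting residuals off
#'   `Yhat`, so pass the design's `Y` for a faithful overlay).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peb_fit <- function(object, Y = NULL, ...) {
  n <- length(object$Yhat)
  L <- length(object$participants)
  df <- tibble::tibble(
    participant = rep(object$participants, each = n / L),
    trial = rep(seq_len(n / L), L),
    fitted = object$Yhat
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = trial, y = fitted)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~participant) +
    ggplot2::labs(x = "trial n", y = "amplitude (uV)",
                  title = "Model-based trial-by-trial amplitude estimates") +
    ggplot2::theme_minimal()
  if (!is.null(Y)) {
    df$measured <- Y
    p <- p + ggplot2::geom_point(data = df, ggplot2::aes(y = measured),
                                 alpha = 0.3, size = 0.4)
  }
  p
}

#' Contour display of grid-search evidence surfaces
#'
#' One panel per optimised parameter pair and iteration, with the running
#' optimum marked.
#'
#' @param object A `dif_search`.
#' @param iteration Which iteration(s) to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dif_search <- function(object, iteration = NULL, ...) {
  surf <- object$surfaces
  if (!is.null(iteration)) surf <- dplyr::filter(surf, iteration %in% !!iteration)
  ggplot2::ggplot(surf, ggplot2::aes(x = value1, y = value2, z = F)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::facet_wrap(iteration ~ pair, scales = "free") +
    ggplot2::labs(x = "first parameter", y = "second parameter",
                  fill = "log evidence",
                  title = "Evidence surfaces of the coordinate grid search") +
    ggplot2::theme_minimal()
}

#' Tree diagram of sequence-conditioned amplitude means
#'
#' Displays pattern means by history order, connecting each pattern to its
#' children in the next order, in the style of sequential-effect tree
#' diagrams.
#'
#' @param tree A tibble from [tree_table()].
#' @return A ggplot object.
#' @export
plot_tree <- function(tree) {
  tree <- dplyr::filter(tree, !is.na(mean))
  ggplot2::ggplot(tree, ggplot2::aes(x = order, y = mean, group = 1)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = pattern), hjust = -0.2, size = 3) +
    ggplot2::geom_segment(
      data = tree_edges(tree),
      ggplot2::aes(x = order_parent, xend = order_child,
                   y = mean_parent, yend = mean_child),
      inherit.aes = FALSE, alpha = 0.5
    ) +
    ggplot2::scale_x_continuous(breaks = sort(unique(tree$order))) +
    ggplot2::labs(x = "history order", y = "mean amplitude (uV)",
                  title = "Sequence-history tree of amplitude means") +
    ggplot2::theme_minimal()
}

tree_edges <- function(tree) {
  purrr::map_dfr(sort(unique(tree$order)), function(o) {
    if (!any(tree$order == o + 1)) return(NULL)
    parents <- dplyr::filter(tree, order == o)
    children <- dplyr::filter(tree, order == o + 1)
    children$parent <- substr(children$pattern, 2, nchar(children$pattern))
    dplyr::inner_join(
      dplyr::transmute(parents, parent = pattern,
                       order_parent = order, mean_parent = mean),
      dplyr::transmute(children, parent, order_child = order,
                       mean_child = mean),
      by = "parent"
    )
  })
}

#' Amplitude responses of the three DIF filters
#'
#' The short-term low-pass, the long-term low-pass frozen at given trials,
#' and the alternation high-pass, over `[0, fs/2]` (log-frequency axis).
#'
#' @param params A [dif_params()].
#' @param n_long Trials at which the long-term filter is frozen.
#' @param fs Stimulus presentation rate (Hz).
#' @param n_points Frequency resolution.
#' @return A ggplot object.
#' @export
plot_amplitude_responses <- function(params = dif_params(), n_long = c(1, 192),
                                     fs = 2 / 3, n_points = 200) {
  f <- exp(seq(log(fs / 2000), log(fs / 2), length.out = n_points))
  parts <- list(
    dplyr::mutate(amplitude_response("short", f, fs, params), filter = "short-term H_S")
  )
  for (n in n_long) {
    parts[[length(parts) + 1]] <- dplyr::mutate(
      amplitude_response("long", f, fs, params, n = n),
      filter = sprintf("long-term H_L (n = %d)", n)
    )
  }
  parts[[length(parts) + 1]] <- dplyr::mutate(
    amplitude_response("alternation", f, fs, params), filter = "alternation H_Delta"
  )
  df <- dplyr::bind_rows(parts)
  ggplot2::ggplot(df, ggplot2::aes(x = f, y = magnitude, colour = filter)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz, log scale)", y = "|H(f)|",
                  title = "Amplitude responses of the DIF filters") +
    ggplot2::theme_minimal()
}
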