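# Broom-style tidiers and ggplot2 helpers for the package's result objects.

#' @rdname fit_var
#' @param x A `var_model`.
#' @param ... Unused.
#' @return `tidy()`: long coefficient tibble (lag, target, source, estimate);
#'   `glance()`: one-row model summary.
#' @export
tidy.var_model <- function(x, ...) {
  p <- dim(x$coefficients)[1]
  n <- dim(x$coefficients)[2]
  grid <- expand.grid(target = seq_len(n), source = seq_len(n), lag = seq_len(p))
  tibble::tibble(
    lag = grid$lag, target = grid$target, source = grid$source,
    estimate = x$coefficients[cbind(grid$lag, grid$target, grid$source)]
  )
}

#' @rdname fit_var
#' @export
glance.var_model <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    n_nodes = dim(x$coefficients)[2],
    n_timepoints = x$n_timepoints,
    schwarz_score = x$schwarz_score,
    spectral_radius = x$spectral_radius
  )
}

#' Tidy a connectivity matrix into an edge list
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return Tibble (source, target, weight, method, directed); for undirected
#'   matrices only the upper triangle is emitted.
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  w <- unclass(x)[, , drop = FALSE]
  n <- nrow(w)
  if (is_directed(x)) {
    grid <- expand.grid(source = seq_len(n), target = seq_len(n))
    grid <- grid[grid$source != grid$target, ]
  } else {
    idx <- combn(n, 2)
    grid <- data.frame(source = idx[1, ], target = idx[2, ])
  }
  tibble::tibble(
    source = grid$source, target = grid$target,
    weight = w[cbind(grid$source, grid$target)],
    method = conn_method(x), directed = is_directed(x)
  )
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  w <- unclass(object)[, , drop = FALSE]
  n <- nrow(w)
  df <- expand.grid(target = seq_len(n), source = seq_len(n))
  df$weight <- w[cbind(df$source, df$target)]
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s connectivity (%s)", conn_method(object),
                      if (is_directed(object)) "directed" else "undirected"),
      x = "target node", y = "source node", fill = "weight"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot intra vs inter ND distributions
#'
#' Violin + box summaries of the ND distributions per estimator, in the style
#' of scan-rescan variability figures: one panel per level.
#'
#' @param nd Long ND tibble from [build_nd_distributions()].
#' @param level Which ND level to show.
#' @return A ggplot object.
#' @export
plot_nd_distributions <- function(nd, level = c("matrix", "global_metric",
                                                "local_metric")) {
  level <- match.arg(level)
  df <- dplyr::filter(nd, .data$level == !!level)
  if (!nrow(df)) abort(sprintf("no ND values at level '%s'", level))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$value,
                                        fill = .data$pair_kind)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(0.8),
                         trim = TRUE, alpha = 0.7) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                          width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = "estimator", y = "normalized difference",
                  fill = "pair kind",
                  title = sprintf("ND distributions (%s level)", level))
  if (level != "matrix") {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$metric))
  }
  p
}

#' Effect sizes of the intra vs inter comparison per contrast
#'
#' @param comparisons Output of [compare_intra_inter()].
#' @param alpha Significance level used for the fill.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(comparisons, alpha = 0.05) {
  df <- comparisons
  df$significant <- df$p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$effect_size,
                                   fill = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimator", y = "ES = median(inter) - median(intra)",
                  fill = sprintf("p < %g", alpha))
}
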