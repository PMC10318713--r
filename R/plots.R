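# ggplot2 visualisations for decoded states, fitted models and selection
# comparisons.

#' Plot movement metrics coloured by decoded state
#'
#' Faceted time series of the three metrics with fixes coloured by the
#' decoded latent state -- the standard diagnostic for judging whether the
#' non-movement state isolates the lambing bout.
#'
#' @param states decoded tibble from [viterbi()] (one animal recommended).
#' @param channels metric columns to show.
#' @return a ggplot object.
#' @export
plot_state_series <- function(states, channels = c("dist", "rt100", "hr")) {
  stopifnot(all(channels %in% names(states)))
  colour_col <- if ("state_label" %in% names(states)) "state_label" else "state"
  long <- tidyr::pivot_longer(states, dplyr::all_of(channels),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp, y = .data$value,
                                     colour = factor(.data[[colour_col]]))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "state") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lamb_hmm <- function(object, ...) {
  tt <- tidy(object)
  grid <- dplyr::group_by(tt, .data$channel)
  grid <- dplyr::reframe(
    grid,
    state = rep(.data$state, each = 200),
    label = rep(.data$label, each = 200),
    x = unlist(purrr::map2(.data$mean, .data$shape, function(m, s)
      seq(1e-6, stats::qgamma(0.995, shape = s, rate = s / m), length.out = 200))),
    dens = unlist(purrr::map2(.data$mean, .data$shape, function(m, s)
      dgamma(seq(1e-6, stats::qgamma(0.995, shape = s, rate = s / m),
                 length.out = 200), shape = s, rate = s / m)))
  )
  lab <- if (all(is.na(grid$label))) "state" else "label"
  grid$grp <- if (lab == "label") grid$label else factor(grid$state)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$dens,
                                     colour = .data$grp)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", colour = "state") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lamb_glmm <- function(object, ...) {
  tt <- tidy(object)
  tt <- tt[tt$term != "(Intercept)", ]
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lamb_selection_comparison <- function(object, ...) {
  labels <- attr(object, "labels") %||% c("a", "b")
  long <- dplyr::bind_rows(
    tibble::tibble(term = object$term, group = labels[1],
                   estimate = object$estimate_a,
                   conf.low = object$conf.low_a, conf.high = object$conf.high_a),
    tibble::tibble(term = object$term, group = labels[2],
                   estimate = object$estimate_b,
                   conf.low = object$conf.low_b, conf.high = object$conf.high_b)
  )
  long <- long[long$term != "(Intercept)", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$term,
                                     colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "selection coefficient (95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
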