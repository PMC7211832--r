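#' Plot an association matrix as a heatmap
#'
#' @param object An `assoc_matrix`.
#' @param order_by_sex Group bats by sex along the axes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_matrix <- function(object, order_by_sex = TRUE, ...) {
  ids <- object$bats$bat_id
  if (order_by_sex) ids <- object$bats$bat_id[order(object$bats$sex, object$bats$bat_id)]
  df <- tidy(object) |>
    dplyr::mutate(bat_1 = factor(.data$bat_1, levels = ids),
                  bat_2 = factor(.data$bat_2, levels = ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bat_1, y = .data$bat_2,
                                   fill = .data$sri)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "SRI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a permutation test's null distribution
#'
#' Histogram of the null statistics with the observed value marked.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$nulls[is.finite(object$nulls)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = object$statistic_name, y = "null count",
                  title = sprintf("%s = %.4g, p %s", object$statistic_name,
                                  object$statistic, object$p_display)) +
    ggplot2::theme_minimal()
}

#' Plot QAP null coefficient distributions
#'
#' One panel per term: null betas with the observed beta marked.
#'
#' @param object A `qap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qap_result <- function(object, ...) {
  nulls <- tibble::as_tibble(object$null_betas) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term", values_to = "beta")
  obs <- object$coefficients
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$beta),
                        colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "beta", y = "null count") +
    ggplot2::theme_minimal()
}

#' Plot the sightings-threshold curve
#'
#' Number of bats observed at least N times, against N — the trade-off between
#' association precision (more sightings per bat) and sample size.
#'
#' @param x A `capture_dataset` or a tibble from [sightings_threshold_curve()].
#' @return A ggplot.
#' @export
plot_sightings_curve <- function(x) {
  curve <- if (inherits(x, "capture_dataset")) sightings_threshold_curve(x) else x
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_min, y = .data$n_bats)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum sightings N", y = "bats observed >= N times") +
    ggplot2::theme_minimal()
}
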