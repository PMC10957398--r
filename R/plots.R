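# --- ggplot2 visualizations ------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a psychometric fit
#'
#' Fraction of rightward choices against signed visual contrast, one curve
#' per auditory condition, with the model's predictions overlaid. With
#' `log_odds_axis = TRUE`, plots empirical log odds against
#' `sign(side) * contrast^gamma`, on which the additive model predicts
#' parallel straight lines.
#'
#' @param object A `psychfit`.
#' @param trials Trial tibble for the empirical points (defaults to model
#'   predictions only).
#' @param log_odds_axis Use the linearized log-odds representation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychfit <- function(object, trials = NULL, log_odds_axis = FALSE,
                              ...) {
  m <- object$model
  gamma <- if ("gamma" %in% names(object$estimates)) {
    object$estimates[["gamma"]]
  } else 1
  grid <- tidyr::crossing(
    signed_contrast = seq(-max(m$contrast_set), max(m$contrast_set),
                          length.out = 101),
    aud_azimuth_deg = m$azimuth_set
  ) |>
    dplyr::mutate(
      vis_contrast_L = pmax(-.data$signed_contrast, 0),
      vis_contrast_R = pmax(.data$signed_contrast, 0)
    )
  grid$p_right <- logistic(log_odds(object, grid))
  grid$x <- sign(grid$signed_contrast) * abs(grid$signed_contrast)^gamma
  xvar <- if (log_odds_axis) "x" else "signed_contrast"
  yvar <- if (log_odds_axis) "log_odds" else "p_right"
  if (log_odds_axis) grid$log_odds <- log(grid$p_right / (1 - grid$p_right))
  pl <- ggplot2::ggplot(grid,
    ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                 color = factor(.data$aud_azimuth_deg))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (log_odds_axis) {
      expression(sign %*% contrast^gamma)
    } else "signed visual contrast",
    y = if (log_odds_axis) "log odds rightward" else "p(rightward)",
    color = "auditory azimuth (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    emp <- empirical_log_odds(trials, gamma = gamma) |>
      dplyr::mutate(
        signed_contrast = .data$vis_contrast_R - .data$vis_contrast_L,
        p_right = .data$nR / (.data$nR + .data$nL),
        x = .data$x_contrast
      )
    pl <- pl + ggplot2::geom_point(data = emp)
  }
  pl
}

#' Plot fitted temporal kernels
#'
#' One panel per kernel, one line per neuron.
#'
#' @param object A `kernel_fit`.
#' @param neurons Optional subset of neuron ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_fit <- function(object, neurons = NULL, ...) {
  k <- object$kernels
  if (!is.null(neurons)) k <- dplyr::filter(k, .data$neuron_id %in% neurons)
  ggplot2::ggplot(k, ggplot2::aes(x = .data$lag_s, y = .data$value,
                                  group = .data$neuron_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~kernel, scales = "free_y") +
    ggplot2::labs(x = "lag (s)", y = "kernel value (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a pulse-timing analysis
#'
#' Change in the fraction of rightward choices against pulse time, with
#' significant windows marked.
#'
#' @param object A `pulse_timing_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pulse_timing_result <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$center_s,
                                  y = .data$delta_frac_right)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "red3"),
                                na.value = "grey80") +
    ggplot2::labs(x = "laser onset relative to stimulus (s)",
                  y = expression(Delta ~ "fraction rightward")) +
    ggplot2::theme_minimal()
}

#' Plot accumulator outcomes as a psychometric curve
#'
#' Fraction of rightward model choices per condition against the signed
#' visual contrast, split by auditory condition.
#'
#' @param object An `accum_outcomes` tibble (with `condition`).
#' @param conditions Condition table mapping labels to stimulus columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accum_outcomes <- function(object, conditions, ...) {
  d <- object |>
    dplyr::filter(.data$choice != "none") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(p_right = mean(.data$choice == "R"), .groups = "drop") |>
    dplyr::left_join(dplyr::select(conditions, "condition", "vis_contrast_L",
                                   "vis_contrast_R", "aud_azimuth_deg"),
                     by = "condition") |>
    dplyr::mutate(signed_contrast = .data$vis_contrast_R - .data$vis_contrast_L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_contrast, y = .data$p_right,
                                  color = factor(.data$aud_azimuth_deg))) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "signed visual contrast", y = "p(rightward)",
                  color = "auditory azimuth (deg)") +
    ggplot2::theme_minimal()
}
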