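# --- broom-style tidiers ---------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychfit`.
#' @param ... Unused.
#' @return Tibble `(term, estimate, fixed)`.
#' @export
tidy.psychfit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    fixed = names(x$estimates) %in% names(x$model$fixed)
  )
}

#' @rdname tidy.psychfit
#' @export
glance.psychfit <- function(x, ...) {
  tibble::tibble(
    family = x$model$family,
    n_params = n_params(x$model),
    n_trials = x$n_trials,
    logLik = x$logLik,
    cv_bits_per_trial = if (is.null(x$cv)) NA_real_ else x$cv$bits_per_trial,
    converged = x$converged
  )
}

#' Tidy a pooled multi-subject fit
#'
#' @param x A `psychfit_pooled`.
#' @param ... Unused.
#' @return Tibble `(term, estimate, sd)` with the across-repeat SD.
#' @export
tidy.psychfit_pooled <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    sd = apply(x$per_repeat, 2, stats::sd)
  )
}

#' Tidy a kernel fit
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return The long kernel tibble `(neuron_id, kernel, lag_s, value)`.
#' @export
tidy.kernel_fit <- function(x, ...) x$kernels

#' @rdname tidy.kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x$errors),
    alpha = x$alpha,
    mean_E_test = mean(x$errors$E_test),
    mean_E_train = mean(x$errors$E_train),
    mean_var_explained = mean(x$errors$var_explained)
  )
}

#' Tidy a shuffle-test result
#'
#' @param x A `shuffle_result`.
#' @param ... Unused.
#' @return One-row tibble `(observed, p, null_mean, null_sd, n_null)`.
#' @export
tidy.shuffle_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, p = x$p,
    null_mean = mean(x$null), null_sd = stats::sd(x$null),
    n_null = length(x$null)
  )
}

#' Tidy an accumulator model
#'
#' @param x An `accumulator_model`.
#' @param ... Unused.
#' @return Tibble `(neuron, weight, constraint)`.
#' @export
tidy.accumulator_model <- function(x, ...) {
  tibble::tibble(
    neuron = seq_along(x$w),
    weight = x$w,
    constraint = if (is.null(x$constraint)) 0 else x$constraint
  )
}

#' @rdname tidy.accumulator_model
#' @export
glance.accumulator_model <- function(x, ...) {
  tibble::tibble(
    n_neurons = length(x$w),
    boundary_upper = x$boundaries[1],
    boundary_lower = x$boundaries[2],
    final_loss = if (is.null(x$loss_history)) NA_real_ else
      utils::tail(x$loss_history, 1)
  )
}
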