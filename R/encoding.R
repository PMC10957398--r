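# --- firing-rate estimation and temporal-kernel encoding models ------------

#' Estimate single-trial firing rates from spike times
#'
#' Bins spikes (default 2 ms) and smooths with a causal half-Gaussian filter
#' (mass only at nonnegative lags, normalized to unit mass, default SD
#' 60 ms), so each spike contributes exactly one spike's worth of rate after
#' its time of occurrence. PSTHs are obtained by averaging the returned
#' single-trial rates across trials.
#'
#' @param spikes Spike tibble `(neuron_id, trial_id, spike_time_s)` or a
#'   `spike_data` object.
#' @param trials Trial tibble (defines the trial set; defaults to the trials
#'   stored in a `spike_data` input).
#' @param bin Bin width (s).
#' @param smooth_sd Half-Gaussian SD (s); 0 disables smoothing.
#' @param t_range Window (s) around stimulus onset.
#' @return A `rate_traces` object: bin-center times `t`, and `rates`, a
#'   named list of `trials x bins` matrices (Hz) per neuron.
#' @export
estimate_rates <- function(spikes, trials = NULL, bin = 0.002,
                           smooth_sd = 0.060, t_range = c(-0.3, 0.8)) {
  if (inherits(spikes, "spike_data")) {
    trials <- trials %||% spikes$trials
    spikes <- spikes$spikes
  }
  if (is.null(trials)) abort("trials must be supplied")
  breaks <- seq(t_range[1], t_range[2], by = bin)
  t_mid <- breaks[-1] - bin / 2
  n_bins <- length(t_mid)
  trial_ids <- trials$trial_id
  n_tr <- length(trial_ids)
  K <- smoothing_matrix(n_bins, bin, smooth_sd)
  sp <- spikes[spikes$spike_time_s >= t_range[1] &
                 spikes$spike_time_s < t_range[2] &
                 spikes$trial_id %in% trial_ids, ]
  sp_by_neuron <- split(sp, sp$neuron_id)
  neuron_ids <- unique(spikes$neuron_id)
  rates <- lapply(setNames(neuron_ids, neuron_ids), function(nid) {
    d <- sp_by_neuron[[nid]]
    M <- matrix(0, n_tr, n_bins, dimnames = list(trial_ids, NULL))
    if (!is.null(d) && nrow(d)) {
      ti <- match(d$trial_id, trial_ids)
      bi <- pmin(pmax(floor((d$spike_time_s - t_range[1]) / bin) + 1, 1), n_bins)
      for (k in seq_along(ti)) M[ti[k], bi[k]] <- M[ti[k], bi[k]] + 1
    }
    (M / bin) %*% K
  })
  structure(list(t = t_mid, rates = rates, trial_ids = trial_ids,
                 bin = bin, smooth_sd = smooth_sd),
            class = "rate_traces")
}

# causal half-Gaussian smoothing as a (bins x bins) linear operator:
# column j receives mass from earlier bins only
smoothing_matrix <- function(n_bins, bin, smooth_sd) {
  if (smooth_sd <= 0) return(diag(n_bins))
  lags <- 0:min(n_bins - 1, ceiling(4 * smooth_sd / bin))
  k <- exp(-(lags * bin)^2 / (2 * smooth_sd^2))
  k <- k / sum(k)
  K <- matrix(0, n_bins, n_bins)
  for (j in seq_along(lags)) {
    idx <- seq_len(n_bins - lags[j])
    K[cbind(idx, idx + lags[j])] <- k[j]
  }
  K
}

#' @export
print.rate_traces <- function(x, ...) {
  cat("<rate_traces>", length(x$rates), "neurons,", length(x$trial_ids),
      "trials,", length(x$t), "bins of", x$bin * 1000, "ms\n")
  invisible(x)
}

#' Trial-averaged PSTH from rate traces
#'
#' @param rates A `rate_traces` object.
#' @param trial_subset Optional trial ids to average over.
#' @return Tibble `(neuron_id, t_s, rate_hz)`.
#' @export
psth <- function(rates, trial_subset = NULL) {
  sel <- if (is.null(trial_subset)) seq_along(rates$trial_ids) else
    match(trial_subset, rates$trial_ids)
  purrr::imap_dfr(rates$rates, function(M, nid) {
    tibble::tibble(neuron_id = nid, t_s = rates$t,
                   rate_hz = colMeans(M[sel, , drop = FALSE]))
  })
}

#' Build the kernel design for the temporal decomposition
#'
#' Lays out the regression design of the kernel decomposition
#' `F_i(t) = B(t) + a_i A(t) + v_i V(t) + a_i v_i N(t) + M(t - tau_i) +
#' c_i D(t - tau_i)`: one regressor column per kernel per lattice bin, with
#' the stimulus-aligned kernels (B, A, V, N) supported on `stim_window` and
#' the movement-aligned kernels (M, D) on `move_window` relative to each
#' trial's movement onset. Intended inputs are audiovisual trials pooled
#' over the high contrasts (40% and 80%); movement models keep only trials
#' with movement onset before 300 ms. The 8-kernel movement variant
#' (`per_condition_movement = TRUE`) gives each of the four audiovisual
#' conditions its own movement and direction kernels.
#'
#' @param trials Trial tibble (rows must match the rate matrices).
#' @param t Time lattice of the rate bins (s, stimulus-aligned).
#' @param include_interaction Include the nonadditive interaction kernel N.
#' @param include_movement Include movement-aligned kernels (requires
#'   `rt_s` as the movement-onset time and `choice`).
#' @param per_condition_movement Use the 8-kernel movement variant.
#' @param stim_window,move_window Kernel support windows (s).
#' @param max_tau Movement-onset cutoff (s) for inclusion.
#' @return A `kernel_design`: design matrix `X` (rows = kept trial x bin),
#'   `row_trial`/`row_bin` indices, column metadata `cols`
#'   `(kernel, lag_s)`, and the kept trial indices.
#' @export
build_design <- function(trials, t, include_interaction = TRUE,
                         include_movement = TRUE,
                         per_condition_movement = FALSE,
                         stim_window = c(-0.05, 0.4),
                         move_window = c(-0.2, 0.7),
                         max_tau = 0.3) {
  bin <- t[2] - t[1]
  a_i <- sign(trials$aud_azimuth_deg)
  v_i <- sign(trials$vis_contrast_R - trials$vis_contrast_L)
  keep <- rep(TRUE, nrow(trials))
  if (include_movement) {
    if (!all(c("rt_s", "choice") %in% names(trials))) {
      abort("movement kernels require rt_s (movement onset) and choice")
    }
    keep <- keep & !is.na(trials$rt_s) & trials$rt_s < max_tau &
      trials$choice %in% c("L", "R")
  }
  trials <- trials[keep, ]
  a_i <- a_i[keep]; v_i <- v_i[keep]
  n_tr <- nrow(trials); n_bins <- length(t)
  stim_lags <- t[t >= stim_window[1] - 1e-9 & t <= stim_window[2] + 1e-9]
  stim_lag_of_bin <- match(round(t, 9), round(stim_lags, 9))
  move_lags <- seq(move_window[1] + bin / 2, move_window[2] - bin / 2, by = bin)
  kernels <- c("B", "A", "V", if (include_interaction) "N")
  if (include_movement) {
    if (per_condition_movement) {
      conds <- paste0("a", a_i, "v", v_i)
      u_conds <- sort(unique(conds))
      if (length(u_conds) < 4 && length(unique(paste(a_i, v_i))) < 4) {
        abort("per-condition movement kernels need all four audiovisual conditions")
      }
      kernels <- c(kernels, paste0("M_", u_conds), paste0("D_", u_conds))
    } else {
      kernels <- c(kernels, "M", "D")
    }
  }
  n_stim_l <- length(stim_lags); n_move_l <- length(move_lags)
  cols <- dplyr::bind_rows(lapply(kernels, function(kn) {
    lags <- if (startsWith(kn, "M") || startsWith(kn, "D")) move_lags else stim_lags
    tibble::tibble(kernel = kn, lag_s = lags)
  }))
  X <- matrix(0, n_tr * n_bins, nrow(cols))
  row_trial <- rep(seq_len(n_tr), each = n_bins)
  row_bin <- rep(seq_len(n_bins), n_tr)
  col0 <- 0
  code_of <- function(kn, i) {
    switch(substr(kn, 1, 1),
           B = 1, A = a_i[i], V = v_i[i], N = a_i[i] * v_i[i],
           M = 1, D = choice_code(trials$choice[i]))
  }
  for (kn in kernels) {
    is_move <- startsWith(kn, "M") || startsWith(kn, "D")
    n_l <- if (is_move) n_move_l else n_stim_l
    cond_sel <- if (grepl("_", kn)) sub("^[MD]_", "", kn) else NULL
    for (i in seq_len(n_tr)) {
      if (!is.null(cond_sel) && paste0("a", a_i[i], "v", v_i[i]) != cond_sel) next
      z <- code_of(kn, i)
      if (is.na(z) || z == 0) next
      if (is_move) {
        lag_idx <- round((t - trials$rt_s[i] - move_lags[1]) / bin) + 1
        ok <- lag_idx >= 1 & lag_idx <= n_l
        rows <- (i - 1) * n_bins + which(ok)
        X[cbind(rows, col0 + lag_idx[ok])] <- z
      } else {
        ok <- !is.na(stim_lag_of_bin)
        rows <- (i - 1) * n_bins + which(ok)
        X[cbind(rows, col0 + stim_lag_of_bin[ok])] <- z
      }
    }
    col0 <- col0 + n_l
  }
  structure(
    list(X = X, row_trial = row_trial, row_bin = row_bin, cols = cols,
         t = t, kept = which(keep), trials = trials),
    class = "kernel_design"
  )
}

#' Fit temporal kernels by ridge regression
#'
#' Solves the kernel decomposition per neuron by ridge regression with a
#' single shared regularization strength (`alpha = 10` by default, on the
#' raw firing-rate scale in Hz), training on a random half of the trials and
#' reporting the cross-validated mean-squared error E between predicted and
#' observed smoothed rates over `error_window` (default 0 to 400 ms) on the
#' held-out trials. With `alpha = 0` a rank-deficient design falls back to a
#' minimum-norm least-squares solution with a warning.
#'
#' @param rates A `rate_traces` object (all neurons are fit against the same
#'   design, so one call fits the whole population).
#' @param design A `kernel_design` from [build_design()].
#' @param alpha Ridge strength.
#' @param train_frac Fraction of trials in the training split.
#' @param error_window Window (s) over which E is computed.
#' @param seed Seed for the train/test split.
#' @return A `kernel_fit`: tidy `kernels` tibble
#'   `(neuron_id, kernel, lag_s, value)`, per-neuron `errors` tibble with
#'   train/test E and variance explained, and the split.
#' @export
fit_kernels <- function(rates, design, alpha = 10, train_frac = 0.5,
                        error_window = c(0, 0.4), seed = NULL) {
  local_seed(seed)
  n_tr <- nrow(design$trials)
  train <- seq_len(n_tr) %in% sample.int(n_tr, round(n_tr * train_frac))
  if (!any(train) || all(train)) abort("degenerate train/test split")
  fit_kernels_split(rates, design, alpha, train, error_window)
}

fit_kernels_split <- function(rates, design, alpha, train, error_window) {
  row_train <- train[design$row_trial]
  Y <- do.call(cbind, lapply(rates$rates, function(M) {
    as.vector(t(M[design$kept, , drop = FALSE]))
  }))
  Xtr <- design$X[row_train, , drop = FALSE]
  Ytr <- Y[row_train, , drop = FALSE]
  XtX <- crossprod(Xtr)
  XtY <- crossprod(Xtr, Ytr)
  p <- ncol(Xtr)
  theta <- if (alpha > 0) {
    solve(XtX + alpha * diag(p), XtY)
  } else {
    qr_x <- qr(Xtr)
    if (qr_x$rank < p) {
      warn("design is rank deficient with alpha = 0; using minimum-norm solution")
      sv <- svd(Xtr)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos] %*% (crossprod(sv$u[, pos], Ytr) / sv$d[pos])
    } else {
      qr.coef(qr_x, Ytr)
    }
  }
  pred <- design$X %*% theta
  in_win <- rates$t[design$row_bin] >= error_window[1] - 1e-9 &
    rates$t[design$row_bin] <= error_window[2] + 1e-9
  err_rows <- function(rows) {
    se <- (Y[rows, , drop = FALSE] - pred[rows, , drop = FALSE])^2
    colMeans(se)
  }
  test_rows <- !row_train & in_win
  train_rows <- row_train & in_win
  E_test <- err_rows(test_rows)
  E_train <- err_rows(train_rows)
  var_test <- apply(Y[test_rows, , drop = FALSE], 2, function(y) mean((y - mean(y))^2))
  neuron_ids <- names(rates$rates)
  kernels <- purrr::map_dfr(seq_along(neuron_ids), function(j) {
    dplyr::mutate(design$cols, neuron_id = neuron_ids[j], value = theta[, j])
  }) |>
    dplyr::select("neuron_id", "kernel", "lag_s", "value")
  errors <- tibble::tibble(
    neuron_id = neuron_ids,
    E_train = unname(E_train), E_test = unname(E_test),
    var_explained = 1 - unname(E_test) / unname(var_test)
  )
  structure(
    list(kernels = kernels, errors = errors, alpha = alpha, train = train,
         error_window = error_window, cols = design$cols),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit>", length(unique(x$kernels$neuron_id)), "neurons; alpha =",
      x$alpha, "; mean test E =", signif(mean(x$errors$E_test), 4), "\n")
  invisible(x)
}

#' Fit the passive (movement-free) kernel model
#'
#' Reduced decomposition `F_i(t) = B(t) + a_i A(t) + v_i V(t) [+ a_i v_i
#' N(t)]` for passive stimulus presentations: no movement kernels and no
#' regularization. Intended for single-contrast multisensory trials.
#'
#' @inheritParams fit_kernels
#' @param trials Trial tibble matched to `rates`.
#' @param include_interaction Keep the interaction kernel N.
#' @param ... Passed to [build_design()].
#' @export
fit_passive_kernels <- function(rates, trials, include_interaction = TRUE,
                                train_frac = 0.5, error_window = c(0, 0.4),
                                seed = NULL, ...) {
  design <- build_design(trials, rates$t,
                         include_interaction = include_interaction,
                         include_movement = FALSE, ...)
  fit_kernels(rates, design, alpha = 0, train_frac = train_frac,
              error_window = error_window, seed = seed)
}

#' Per-neuron kernel amplitude summaries
#'
#' Averages the auditory (A) and visual (V) kernels over a post-stimulus
#' window (default 0–300 ms), signed and absolute, for neurons whose fit
#' explains at least `min_var` of the held-out variance (default 2%).
#' Movement/direction kernel summaries over `move_window` are included when
#' present. The output feeds lateralization and amplitude-correlation
#' analyses.
#'
#' @param fit A `kernel_fit`.
#' @param neurons Optional neuron metadata (joined by `neuron_id`, e.g. for
#'   hemisphere labels).
#' @param window Stimulus-kernel averaging window (s).
#' @param move_window Movement-kernel averaging window (s).
#' @param min_var Minimum test-set variance explained.
#' @return Tibble with per-neuron mean signed/absolute kernel amplitudes.
#' @export
kernel_summaries <- function(fit, neurons = NULL, window = c(0, 0.3),
                             move_window = c(-0.2, 0.4), min_var = 0.02) {
  keep <- fit$errors$neuron_id[fit$errors$var_explained >= min_var]
  avg <- function(kn, win) {
    fit$kernels |>
      dplyr::filter(.data$kernel == kn, .data$lag_s >= win[1] - 1e-9,
                    .data$lag_s <= win[2] + 1e-9) |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise("{kn}_mean" := mean(.data$value),
                       "{kn}_abs_mean" := mean(abs(.data$value)),
                       .groups = "drop")
  }
  out <- avg("A", window) |>
    dplyr::left_join(avg("V", window), by = "neuron_id")
  for (kn in intersect(c("M", "D"), unique(fit$kernels$kernel))) {
    out <- dplyr::left_join(out, avg(kn, move_window), by = "neuron_id")
  }
  out <- dplyr::filter(out, .data$neuron_id %in% keep) |>
    dplyr::left_join(fit$errors, by = "neuron_id")
  if (!is.null(neurons)) {
    out <- dplyr::left_join(out,
      dplyr::select(neurons, dplyr::any_of(c("neuron_id", "hemisphere",
                                             "ap_mm", "ml_mm", "depth_mm"))),
      by = "neuron_id")
  }
  out
}
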