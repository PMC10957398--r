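# --- maximum-likelihood fitting and cross-validated model comparison -------

# Trials are aggregated to stimulus-condition cells (nR, nL) before
# optimization: the Bernoulli likelihood depends on the data only through
# these counts, so fits cost the same for 200 or 200,000 trials.
aggregate_cells <- function(trials) {
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"))
  if (!nrow(tr)) abort("no L/R choice trials to fit")
  tr |>
    dplyr::count(.data$vis_contrast_L, .data$vis_contrast_R,
                 .data$aud_azimuth_deg, .data$choice) |>
    tidyr::pivot_wider(names_from = "choice", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"R" %in% names(d)) d$R <- 0L
      if (!"L" %in% names(d)) d$L <- 0L
      dplyr::rename(d, nR = "R", nL = "L")
    })()
}

cell_nll <- function(free, model, cells, free_names, prep = NULL) {
  names(free) <- free_names
  prep <- prep %||% prep_conditions(model, cells)
  eta <- eval_log_odds(model, prep, free)
  p <- pmin(pmax(logistic(eta), 1e-12), 1 - 1e-12)
  -sum(cells$nR * log(p) + cells$nL * log(1 - p))
}

# analytic NLL gradient for the plain additive / ipsi-contra families
# (the hot path of the shuffle tests); other families fall back to optim's
# numerical differencing
cell_nll_gradient <- function(model, prep, cells) {
  if (!model$family %in% c("additive", "ipsi_contra", "bias_only",
                           "visual_only", "auditory_only")) {
    return(NULL)
  }
  nm_v <- if (model$family == "ipsi_contra") c("vi", "vc", "ai", "ac") else
    c("vR", "vL", "aR", "aL")
  logVR <- ifelse(prep$VR > 0, log(prep$VR), 0)
  logVL <- ifelse(prep$VL > 0, log(prep$VL), 0)
  function(free, model, cells, free_names, prep) {
    names(free) <- free_names
    par <- free
    fx <- unlist(model$fixed)
    par[names(fx)] <- fx
    g <- if ("gamma" %in% names(par)) par[["gamma"]] else 1
    vRg <- prep$VR^g; vLg <- prep$VL^g
    eta <- eval_log_odds(model, prep, par)
    p <- pmin(pmax(logistic(eta), 1e-12), 1 - 1e-12)
    w <- (cells$nR + cells$nL) * p - cells$nR   # dNLL / deta per cell
    has <- function(nm) nm %in% names(par)
    d_eta <- list(b = rep(1, prep$n))
    if (has(nm_v[1])) d_eta[[nm_v[1]]] <- vRg
    if (has(nm_v[2])) d_eta[[nm_v[2]]] <- -vLg
    if (has(nm_v[3])) d_eta[[nm_v[3]]] <- prep$AR
    if (has(nm_v[4])) d_eta[[nm_v[4]]] <- -prep$AL
    if (has("gamma")) {
      vR <- if (has(nm_v[1])) par[[nm_v[1]]] else 0
      vL <- if (has(nm_v[2])) par[[nm_v[2]]] else 0
      d_eta$gamma <- vR * vRg * logVR - vL * vLg * logVL
    }
    vapply(free_names, function(nm) sum(w * d_eta[[nm]]), numeric(1))
  }
}

param_bounds <- function(nms) {
  lower <- ifelse(nms == "gamma", 0.01, -20)
  upper <- ifelse(nms == "gamma", 3, 20)
  list(lower = lower, upper = upper)
}

random_start <- function(nms) {
  s <- stats::rnorm(length(nms), 0, 1)
  names(s) <- nms
  if ("gamma" %in% nms) s["gamma"] <- stats::runif(1, 0.2, 1.5)
  s
}

default_start <- function(nms) {
  s <- rep(0, length(nms))
  names(s) <- nms
  if ("gamma" %in% nms) s["gamma"] <- 0.6
  s
}

#' Fit a psychometric model by maximum likelihood
#'
#' Maximizes the Bernoulli likelihood of the observed left/right choices
#' under the given model family, using a bounded quasi-Newton optimizer
#' (L-BFGS-B) with multiple restarts (`gamma` bounded to `(0.01, 3]`,
#' log-odds parameters to `[-20, 20]`). Parameters listed in the model's
#' `fixed` slot are frozen — e.g. the contrast exponent can be fixed at the
#' value obtained from non-inactivation trials before refitting laser trials.
#' Timeout trials are ignored.
#'
#' @param trials Trial tibble with stimulus columns and `choice` in
#'   `{"L","R","timeout"}`.
#' @param model A [psych_model()]. For the `full` family, any condition cell
#'   absent from `trials` keeps no weight and predicts the bias-only value.
#' @param n_starts Number of optimizer restarts (first start is
#'   deterministic at zero sensitivities, `gamma = 0.6`).
#' @param seed Seed for the random restarts.
#' @return A `psychfit` object: estimates, train log-likelihood (natural
#'   log), trial/cell counts, and a convergence flag. Use [cv_bits_per_trial()]
#'   to attach cross-validated goodness of fit, [generics::tidy()] /
#'   [generics::glance()] to extract tables.
#' @examples
#' cfg <- behavior_sim_config(n_trials = 500, seed = 1)
#' tr <- simulate_choices(gen_trial_schedule(cfg), cfg$true_params, seed = 2)
#' fit <- fit_psych(tr, psych_model("additive"), seed = 3)
#' tidy(fit)
#' @export
fit_psych <- function(trials, model = psych_model("additive"),
                      n_starts = 10, seed = NULL) {
  local_seed(seed)
  cells <- aggregate_cells(trials)
  n_trials <- sum(cells$nR + cells$nL)
  nms_all <- param_names(model)
  if (model$family == "full") {
    # only cells observed in the data carry a weight
    nms_all <- intersect(nms_all, unique(full_cell_label(cells)))
  }
  free_names <- setdiff(nms_all, names(model$fixed))
  if (n_trials < length(free_names)) {
    warn("fewer trials than free parameters; estimates will be unreliable")
  }
  if (model$family == "full" && !length(model$fixed)) {
    # the full-model likelihood separates by cell: the MLE of each cell
    # weight is the empirical log odds, clamped to the parameter bounds
    cells$lab <- full_cell_label(cells)
    w <- pmin(pmax(log(cells$nR / cells$nL), -20), 20)
    w[cells$nR == 0] <- -20
    w[cells$nL == 0] <- 20
    est <- setNames(w, cells$lab)[nms_all]
    p <- pmin(pmax(logistic(est[cells$lab]), 1e-12), 1 - 1e-12)
    ll <- sum(cells$nR * log(p) + cells$nL * log(1 - p))
    return(structure(
      list(model = model, estimates = est, logLik = unname(ll),
           n_trials = n_trials, n_cells = nrow(cells),
           converged = TRUE, fallback_log_odds = bias_fit_b(cells),
           cv = NULL, seed = seed),
      class = "psychfit"
    ))
  }
  bounds <- param_bounds(free_names)
  starts <- c(list(default_start(free_names)),
              replicate(max(0, n_starts - 1), random_start(free_names),
                        simplify = FALSE))
  prep <- prep_conditions(model, cells)
  grad <- cell_nll_gradient(model, prep, cells)
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, cell_nll, gr = grad, model = model, cells = cells,
            free_names = free_names, prep = prep, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) abort("all optimizer starts failed")
  if (!any_conv) warn("optimizer did not report convergence from any start")
  est <- best$par
  names(est) <- free_names
  fx <- unlist(model$fixed)
  est <- c(est, fx[setdiff(names(fx), names(est))])
  # bias-only value used by full-model cells unseen in training
  fb <- if (model$family == "full") {
    bias_fit_b(cells)
  } else NULL
  structure(
    list(model = model, estimates = est, logLik = -best$value,
         n_trials = n_trials, n_cells = nrow(cells),
         converged = any_conv, fallback_log_odds = fb,
         cv = NULL, seed = seed),
    class = "psychfit"
  )
}

# closed-form bias-only MLE on aggregated cells
bias_fit_b <- function(cells) {
  nR <- sum(cells$nR); nL <- sum(cells$nL)
  log((nR + 0.5) / (nL + 0.5))
}

#' @export
print.psychfit <- function(x, ...) {
  cat("<psychfit>", x$model$family, "model,", x$n_trials, "trials\n")
  print(round(x$estimates, 4))
  cat("logLik:", round(x$logLik, 2))
  if (!is.null(x$cv)) cat(" | cv bits/trial:", round(x$cv$bits_per_trial, 4))
  cat("\n")
  invisible(x)
}

#' @export
predict.psychfit <- function(object, newdata, type = c("log_odds", "p_right"),
                             ...) {
  type <- match.arg(type)
  lo <- log_odds(object, newdata)
  if (type == "p_right") logistic(lo) else lo
}

test_log_lik <- function(fit, cells) {
  eta <- log_odds(fit, cells)
  p <- pmin(pmax(logistic(eta), 1e-12), 1 - 1e-12)
  sum(cells$nR * log(p) + cells$nL * log(1 - p))
}

#' Cross-validated bits per trial of a psychometric model
#'
#' Scores a model family by k-fold cross-validation against the bias-only
#' model: the summed held-out log-likelihood difference, divided by
#' \eqn{n \ln 2}, giving the expected number of bits per trial saved in
#' communicating the subject's choice when the stimulus is known. The
#' bias-only reference is refit on every training fold. Folds are stratified
#' by stimulus condition; a fold whose training split lacks both choice
#' classes triggers a refold under a fresh seed (reported via a message).
#'
#' @inheritParams fit_psych
#' @param k Number of folds.
#' @param n_starts Optimizer restarts per fold fit.
#' @param seed Seed controlling fold assignment and restarts.
#' @return A `psychfit` fitted to all trials, with a `cv` component holding
#'   `bits_per_trial`, the per-fold values, `k`, and the seed used.
#' @export
cv_bits_per_trial <- function(trials, model = psych_model("additive"),
                              k = 5, n_starts = 5, seed = NULL) {
  local_seed(seed)
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"))
  n <- nrow(tr)
  if (n < k) abort("fewer choice trials than folds")
  cell_id <- paste(tr$vis_contrast_L, tr$vis_contrast_R, tr$aud_azimuth_deg)
  for (attempt in 1:20) {
    folds <- integer(n)
    for (ix in split(seq_len(n), cell_id)) {
      folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      ch <- tr$choice[folds != f]
      any(ch == "R") && any(ch == "L")
    }, logical(1)))
    if (ok) break
    if (attempt == 20) abort("could not build folds with both classes")
    inform("degenerate fold encountered; refolding with a new draw")
  }
  bias <- psych_model("bias_only")
  diffs <- numeric(k)
  n_test <- integer(k)
  for (f in seq_len(k)) {
    train <- tr[folds != f, ]
    test_cells <- aggregate_cells(tr[folds == f, ])
    fit_m <- fit_psych(train, model, n_starts = n_starts)
    fit_b <- fit_psych(train, bias, n_starts = 1)
    diffs[f] <- test_log_lik(fit_m, test_cells) - test_log_lik(fit_b, test_cells)
    n_test[f] <- sum(test_cells$nR + test_cells$nL)
  }
  fit <- fit_psych(tr, model, n_starts = n_starts)
  fit$cv <- list(
    bits_per_trial = sum(diffs) / (sum(n_test) * log(2)),
    per_fold = diffs / (n_test * log(2)),
    k = k, seed = seed, fold_sizes = n_test
  )
  fit
}

#' Combine subjects by equal-n subsampling before fitting
#'
#' Fits a single psychometric model to data pooled over subjects, after
#' subsampling trials to equalize the contribution of every subject. The
#' subsample-and-fit cycle is repeated and the mean parameter vector (and
#' mean per-condition rightward fraction) over repeats is reported.
#'
#' @inheritParams fit_psych
#' @param n_repeats Number of subsample/fit repeats.
#' @return A `psychfit_pooled` object: mean `estimates`, the per-repeat
#'   estimate matrix, and a per-condition tibble of mean empirical and
#'   predicted rightward fractions.
#' @export
combine_subjects <- function(trials, model = psych_model("additive"),
                             n_repeats = 10, n_starts = 5, seed = NULL) {
  local_seed(seed)
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"))
  counts <- dplyr::count(tr, .data$subject_id)
  empty <- setdiff(unique(trials$subject_id), counts$subject_id)
  if (length(empty)) {
    warn(paste("excluding subject(s) with no choice trials:",
               paste(empty, collapse = ", ")))
  }
  n_min <- min(counts$n)
  est_list <- vector("list", n_repeats)
  cond_list <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sub <- tr |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_sample(n = n_min) |>
      dplyr::ungroup()
    fit <- fit_psych(sub, model, n_starts = n_starts)
    est_list[[r]] <- fit$estimates
    cond_list[[r]] <- aggregate_cells(sub) |>
      dplyr::mutate(
        frac_right = .data$nR / (.data$nR + .data$nL),
        pred_right = logistic(log_odds(fit, dplyr::pick(dplyr::everything())))
      )
  }
  est_mat <- do.call(rbind, est_list)
  by_cond <- dplyr::bind_rows(cond_list) |>
    dplyr::group_by(.data$vis_contrast_L, .data$vis_contrast_R,
                    .data$aud_azimuth_deg) |>
    dplyr::summarise(frac_right = mean(.data$frac_right),
                     pred_right = mean(.data$pred_right),
                     n = sum(.data$nR + .data$nL) / n_repeats,
                     .groups = "drop")
  structure(
    list(model = model, estimates = colMeans(est_mat),
         per_repeat = est_mat, by_condition = by_cond,
         n_per_subject = n_min, n_repeats = n_repeats, seed = seed),
    class = c("psychfit_pooled")
  )
}

#' @export
print.psychfit_pooled <- function(x, ...) {
  cat("<psychfit_pooled>", x$model$family, "model;", x$n_repeats,
      "subsample repeats of", x$n_per_subject, "trials/subject\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Empirical per-condition log odds on the linearized contrast axis
#'
#' Computes `log(nR / nL)` for every stimulus condition, with optional
#' regularization for one-sided cells (one trial added in each direction
#' whenever a cell has zero rightward or zero leftward choices), and a
#' linearized x-coordinate `sign(side) * contrast^gamma` on which the
#' additive model predicts straight lines per auditory condition.
#'
#' @param trials Trial tibble with choices.
#' @param gamma Contrast exponent for the x-axis (e.g. from a fitted model).
#' @param regularize Apply the one-trial-each-way correction to one-sided
#'   cells.
#' @return Tibble with condition columns, `nR`, `nL`, `log_odds`, and
#'   `x_contrast`.
#' @export
empirical_log_odds <- function(trials, gamma = 0.6, regularize = TRUE) {
  cells <- aggregate_cells(trials)
  nR <- cells$nR; nL <- cells$nL
  onesided <- (nR == 0) | (nL == 0)
  if (regularize) {
    nR[onesided] <- nR[onesided] + 1
    nL[onesided] <- nL[onesided] + 1
  }
  cells$log_odds <- log(nR / nL)
  cells$regularized <- onesided & regularize
  cells$x_contrast <- sign(cells$vis_contrast_R - cells$vis_contrast_L) *
    pmax(cells$vis_contrast_R, cells$vis_contrast_L)^gamma
  cells
}

#' Test additivity via equal-and-opposite audiovisual pairs
#'
#' Under the additive law, a conflict condition whose visual term exactly
#' cancels the auditory term (`f(V) = -g(A)`) should yield rightward-choice
#' probability `sigma(b)` — neutral behavior up to the bias. This function
#' finds the conflict conditions closest to cancellation under the fitted
#' parameters and compares predicted and (optionally) empirical rightward
#' fractions with `sigma(b)`.
#'
#' @param fit A `psychfit` from an additive-family fit.
#' @param trials Optional trials for empirical fractions at those conditions.
#' @param tol Maximum |f(V) + g(A)| (log odds) for a pair to count as matched.
#' @return Tibble of matched conditions with predicted `p_right`, the
#'   reference `sigma(b)`, and empirical fractions when trials are given.
#' @export
neutral_pair_test <- function(fit, trials = NULL, tol = 0.2) {
  est <- fit$estimates
  m <- fit$model
  conds <- tidyr::crossing(
    contrast = m$contrast_set,
    vside = c(-1, 1),
    aud_azimuth_deg = setdiff(m$azimuth_set, 0)
  ) |>
    dplyr::mutate(
      vis_contrast_L = ifelse(.data$vside < 0, .data$contrast, 0),
      vis_contrast_R = ifelse(.data$vside > 0, .data$contrast, 0)
    ) |>
    dplyr::select(-"contrast", -"vside") |>
    classify_trials() |>
    dplyr::filter(.data$trial_type == "conflict")
  lo <- log_odds(fit, conds)
  resid <- lo - est[["b"]]   # f(V) + g(A) for additive families
  out <- conds |>
    dplyr::mutate(cancel_residual = abs(resid),
                  p_right_pred = logistic(lo),
                  p_right_neutral = logistic(est[["b"]])) |>
    dplyr::filter(.data$cancel_residual < tol)
  if (!is.null(trials) && nrow(out)) {
    emp <- aggregate_cells(trials) |>
      dplyr::mutate(frac_right = .data$nR / (.data$nR + .data$nL),
                    n = .data$nR + .data$nL) |>
      dplyr::select("vis_contrast_L", "vis_contrast_R", "aud_azimuth_deg",
                    "frac_right", "n")
    out <- dplyr::left_join(out, emp,
      by = c("vis_contrast_L", "vis_contrast_R", "aud_azimuth_deg"))
  }
  out
}

#' Audit the conditional-independence assumption of the stimulus design
#'
#' The additive law is the optimal rule when `p(V, A | S) = p(V | S) p(A | S)`,
#' where `S` is the rewarded side. This audit computes the actual joint
#' stimulus likelihoods implied by the trial frequencies and the reward rule
#' (`p(R | V, A)` is 1 for rightward unisensory/coherent stimuli, 0 for
#' leftward, and 0.5 on conflict and neutral trials, with prior
#' `p(R) = 0.5`), compares them with the product of their marginals, and
#' reports the total-variation distance per side.
#'
#' @param trials Trial tibble (choices not needed); frequencies are taken
#'   from the empirical condition counts.
#' @return A `condition_likelihoods` list: `joint` and `indep` tibbles (rows
#'   `(V, A)` cells by side, each summing to 1 over cells within a side) and
#'   `tv_distance` per side.
#' @export
independence_audit <- function(trials) {
  cond <- classify_trials(trials) |>
    dplyr::count(.data$vis_contrast_L, .data$vis_contrast_R,
                 .data$aud_azimuth_deg, .data$trial_type) |>
    dplyr::mutate(p_va = .data$n / sum(.data$n))
  vside <- sign(cond$vis_contrast_R - cond$vis_contrast_L)
  aside <- sign(cond$aud_azimuth_deg)
  # reward rule: p(R | V, A)
  pR_given <- dplyr::case_when(
    cond$trial_type %in% c("conflict", "neutral") ~ 0.5,
    cond$trial_type == "unisensory_visual" ~ (vside + 1) / 2,
    cond$trial_type == "unisensory_auditory" ~ (aside + 1) / 2,
    cond$trial_type == "coherent" ~ (vside + 1) / 2
  )
  joint <- cond |>
    dplyr::mutate(
      p_given_R = pR_given * .data$p_va / 0.5,
      p_given_L = (1 - pR_given) * .data$p_va / 0.5,
      v_label = ifelse(vside > 0, paste0("R", pmax(.data$vis_contrast_R,
                                                   .data$vis_contrast_L)),
                       ifelse(vside < 0, paste0("L", .data$vis_contrast_L), "0")),
      a_label = paste0("A", .data$aud_azimuth_deg)
    ) |>
    dplyr::mutate(p_given_R = .data$p_given_R / sum(.data$p_given_R),
                  p_given_L = .data$p_given_L / sum(.data$p_given_L))
  indep_side <- function(p_col) {
    pv <- tapply(joint[[p_col]], joint$v_label, sum)
    pa <- tapply(joint[[p_col]], joint$a_label, sum)
    pv[joint$v_label] * pa[joint$a_label]
  }
  indep <- joint |>
    dplyr::mutate(p_given_R = as.numeric(indep_side("p_given_R")),
                  p_given_L = as.numeric(indep_side("p_given_L"))) |>
    dplyr::mutate(p_given_R = .data$p_given_R / sum(.data$p_given_R),
                  p_given_L = .data$p_given_L / sum(.data$p_given_L))
  tv <- c(
    R = 0.5 * sum(abs(joint$p_given_R - indep$p_given_R)),
    L = 0.5 * sum(abs(joint$p_given_L - indep$p_given_L))
  )
  structure(list(joint = joint, indep = indep, tv_distance = tv),
            class = "condition_likelihoods")
}
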