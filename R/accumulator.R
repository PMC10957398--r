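# --- linear integrate-to-bound accumulator over surrogate spike trains ----

#' Generate a surrogate population from a PSTH bank
#'
#' Simulates independent-Poisson spike-count "trials" per stimulus
#' condition, with per-bin intensity given by the condition PSTHs (default
#' 360 trials per condition, as in the accumulator analysis). The target
#' decision variable `y` is the stimulus side (+1 right, −1 left) on
#' unisensory and coherent conditions; on conflict conditions, where there
#' is no correct response, `y` is random with equal probability. On
#' unisensory visual conditions, the side is the visual side; on unisensory
#' auditory, the auditory side.
#'
#' @param bank A `psth_bank` from [gen_psth_bank()].
#' @param n_per_cond Trials per condition.
#' @param seed RNG seed.
#' @return A `surrogate_population`: count array `x` `[neuron, time,
#'   trial]`, `trial_info` tibble (`condition`, `y`), the time lattice, and
#'   the neuron metadata.
#' @export
make_surrogates <- function(bank, n_per_cond = 360, seed = NULL) {
  local_seed(seed)
  n_neur <- dim(bank$rates)[1]
  n_bins <- dim(bank$rates)[2]
  n_cond <- dim(bank$rates)[3]
  conds <- bank$conditions
  vside <- sign(conds$vis_contrast_R - conds$vis_contrast_L)
  aside <- sign(conds$aud_azimuth_deg)
  y_rule <- ifelse(conds$trial_type == "conflict", NA_real_,
                   ifelse(vside != 0, vside, aside))
  n_tot <- n_per_cond * n_cond
  x <- array(0L, c(n_neur, n_bins, n_tot))
  info <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    lam <- bank$rates[, , ci] * bank$bin
    sl <- ((ci - 1) * n_per_cond + 1):(ci * n_per_cond)
    x[, , sl] <- stats::rpois(n_neur * n_bins * n_per_cond, lam)
    y <- if (is.na(y_rule[ci])) {
      sample(c(-1, 1), n_per_cond, replace = TRUE)
    } else {
      rep(y_rule[ci], n_per_cond)
    }
    info[[ci]] <- tibble::tibble(condition = conds$condition[ci], y = y)
  }
  structure(
    list(x = x, trial_info = dplyr::bind_rows(info), t = bank$t,
         bin = bank$bin, neurons = bank$neurons,
         conditions = conds),
    class = "surrogate_population"
  )
}

#' @export
print.surrogate_population <- function(x, ...) {
  d <- dim(x$x)
  cat("<surrogate_population>", d[1], "neurons x", d[2], "bins x", d[3],
      "trials\n")
  invisible(x)
}

#' Construct an accumulator model
#'
#' The decision variable integrates weighted population activity:
#' `d(t) = d(t-1) + w . x(t)`, from the start of the trace (so pre-stimulus
#' activity is integrated, and is penalized toward zero during training).
#' The choice is the sign of `d` at its first crossing of the decision
#' boundaries; the model reaction time is the crossing time.
#'
#' @param w Per-neuron weight vector (time independent).
#' @param boundaries `c(upper, lower)` decision boundaries (training uses
#'   +1/−1; see [fit_boundaries()]).
#' @param bin Time-bin width (s).
#' @param constraint Optional per-neuron sign constraint (+1 = weight >= 0,
#'   −1 = weight <= 0, 0/NA = free), used by the hemisphere-constrained
#'   variant.
#' @return An `accumulator_model`.
#' @export
accumulator_model <- function(w, boundaries = c(1, -1), bin = 0.01,
                              constraint = NULL) {
  stopifnot(boundaries[1] > 0, boundaries[2] < 0)
  structure(list(w = w, boundaries = boundaries, bin = bin,
                 constraint = constraint),
            class = "accumulator_model")
}

#' @export
print.accumulator_model <- function(x, ...) {
  cat("<accumulator_model>", length(x$w), "weights; boundaries",
      paste(signif(x$boundaries, 3), collapse = " / "),
      if (!is.null(x$constraint)) "| sign-constrained" else "", "\n")
  invisible(x)
}

# decision-variable matrix (bins x trials): cumulative sum of w.x(t)
decision_variable <- function(w, x) {
  d <- dim(x)
  drive <- crossprod(matrix(x, d[1], d[2] * d[3]), w)   # (bins*trials)
  apply(matrix(drive, d[2], d[3]), 2, cumsum)
}

#' Run the accumulator on a surrogate population
#'
#' @param model An `accumulator_model`.
#' @param pop A `surrogate_population` (or a count array `[neuron, time,
#'   trial]`).
#' @param t Time lattice (taken from `pop` when available); crossing times
#'   are reported on it.
#' @return An `accum_outcomes` tibble: per trial `choice` (`"R"`, `"L"`, or
#'   `"none"` when no boundary is crossed), `rt_s` (first crossing time),
#'   `condition`, and target `y`.
#' @export
run_accumulator <- function(model, pop, t = NULL) {
  x <- if (inherits(pop, "surrogate_population")) pop$x else pop
  t <- t %||% if (inherits(pop, "surrogate_population")) pop$t else
    seq_len(dim(x)[2]) * model$bin
  D <- decision_variable(model$w, x)
  up <- model$boundaries[1]; lo <- model$boundaries[2]
  n_tr <- ncol(D)
  first_cross <- vapply(seq_len(n_tr), function(i) {
    k <- which(D[, i] >= up | D[, i] <= lo)
    if (!length(k)) NA_integer_ else k[1]
  }, integer(1))
  choice <- ifelse(is.na(first_cross), "none",
                   ifelse(D[cbind(pmax(first_cross, 1),
                                  seq_len(n_tr))] >= up, "R", "L"))
  out <- tibble::tibble(
    trial = seq_len(n_tr),
    choice = choice,
    rt_s = ifelse(is.na(first_cross), NA_real_, t[first_cross])
  )
  if (inherits(pop, "surrogate_population")) {
    out$condition <- pop$trial_info$condition
    out$y <- pop$trial_info$y
  }
  class(out) <- c("accum_outcomes", class(out))
  out
}

#' Accumulator training loss for one trajectory
#'
#' Mean-squared error on the decision variable before stimulus onset (to
#' keep the model undecided before evidence arrives) plus a hinge loss
#' after onset (zero once the decision variable is beyond the unit margin
#' on the correct side):
#' `L = sum_{t<0} d(t)^2 + sum_{t>=0} max(0, 1 - y d(t))`.
#'
#' @param d Decision-variable trajectory (vector over time bins).
#' @param y Target (+1/−1).
#' @param t Time lattice (s) aligning bins to stimulus onset.
#' @return Scalar loss.
#' @export
accumulator_loss <- function(d, y, t) {
  pre <- t < 0
  sum(d[pre]^2) + sum(pmax(0, 1 - y * d[!pre]))
}

#' Train accumulator weights
#'
#' Minimizes the mean per-trial loss of [accumulator_loss()] over the
#' training split by adaptive-moment gradient descent (learning rate 0.01,
#' 300 epochs, standard first/second-moment decay 0.9/0.999), with decision
#' boundaries fixed at +1/−1 during training. Weights are never fit to
#' observed behavior — only to the speed/accuracy targets `y`. An optional
#' per-neuron sign constraint (e.g. left-hemisphere weights nonnegative,
#' right nonpositive) is enforced by projection after every step. The
#' gradient of the piecewise loss is computed analytically.
#'
#' @param pop A `surrogate_population`.
#' @param lr Learning rate.
#' @param epochs Training epochs (full-batch).
#' @param train_frac Fraction of trials in the training split.
#' @param constraint Optional per-neuron sign vector (see
#'   [accumulator_model()]); `"hemisphere"` builds it from the population's
#'   neuron metadata (left = positive, right = negative).
#' @param seed RNG seed (split, initialization).
#' @return An `accumulator_model` with `train_idx`, `test_idx`, and the
#'   loss history attached.
#' @export
train_accumulator <- function(pop, lr = 0.01, epochs = 300, train_frac = 0.7,
                              constraint = NULL, seed = NULL) {
  local_seed(seed)
  d <- dim(pop$x)
  n_neur <- d[1]; n_bins <- d[2]; n_tr <- d[3]
  if (identical(constraint, "hemisphere")) {
    constraint <- ifelse(pop$neurons$hemisphere == "left", 1, -1)
  }
  train_idx <- sort(sample.int(n_tr, round(n_tr * train_frac)))
  test_idx <- setdiff(seq_len(n_tr), train_idx)
  # cumulative counts: C[n, t, i] = sum_{s<=t} x[n, s, i]
  C <- aperm(apply(pop$x[, , train_idx, drop = FALSE], c(1, 3), cumsum),
             c(2, 1, 3))
  Cmat <- matrix(C, n_neur, n_bins * length(train_idx))
  y <- pop$trial_info$y[train_idx]
  pre <- pop$t < 0
  n_train <- length(train_idx)
  w <- stats::rnorm(n_neur, 0, 1e-3)
  project <- function(w) {
    if (is.null(constraint)) return(w)
    w[constraint > 0 & w < 0] <- 0
    w[constraint < 0 & w > 0] <- 0
    w
  }
  w <- project(w)
  m <- v <- numeric(n_neur)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    D <- matrix(crossprod(Cmat, w), n_bins, n_train)  # d(t) per trial
    hinge_active <- (1 - sweep(D, 2, y, "*")) > 0
    G <- matrix(0, n_bins, n_train)
    G[pre, ] <- 2 * D[pre, ]
    post <- !pre
    G[post, ] <- -sweep(hinge_active[post, , drop = FALSE] * 1, 2, y, "*")
    grad <- as.vector(Cmat %*% as.vector(G)) / n_train
    loss <- (sum(D[pre, ]^2) +
               sum(pmax(0, 1 - sweep(D[post, , drop = FALSE], 2, y, "*")))) /
      n_train
    history[ep] <- loss
    if (!is.finite(loss)) abort("non-finite training loss; check inputs")
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mh <- m / (1 - b1^ep); vh <- v / (1 - b2^ep)
    w <- project(w - lr * mh / (sqrt(vh) + eps))
  }
  mdl <- accumulator_model(w, boundaries = c(1, -1), bin = pop$bin,
                           constraint = constraint)
  mdl$train_idx <- train_idx
  mdl$test_idx <- test_idx
  mdl$loss_history <- history
  mdl
}

# analytic gradient of the per-trial loss wrt w (used by tests against
# finite differences)
accumulator_loss_grad <- function(w, x, y, t) {
  Cn <- t(apply(x, 1, cumsum))          # neuron x time cumulative
  if (is.null(dim(Cn))) Cn <- matrix(Cn, nrow = length(w))
  d <- as.vector(crossprod(Cn, w))
  pre <- t < 0
  g <- numeric(length(t))
  g[pre] <- 2 * d[pre]
  g[!pre] <- ifelse(1 - y * d[!pre] > 0, -y, 0)
  as.vector(Cn %*% g)
}

#' Fit decision boundaries to target choice probabilities
#'
#' After training (with boundaries at +1/−1), grid-searches an asymmetric
#' boundary pair minimizing the mean-squared error between the model's
#' per-condition rightward-choice probabilities (held-out trials,
#' no-crossing trials excluded) and target probabilities — e.g. those
#' observed in the subjects.
#'
#' @param model A trained `accumulator_model`.
#' @param pop The `surrogate_population` (held-out trials are used when the
#'   model carries a `test_idx`).
#' @param target Tibble `(condition, p_right)` of target probabilities.
#' @param grid Candidate boundary magnitudes.
#' @return The model with `boundaries` replaced by the best pair and the
#'   achieved `boundary_mse` attached.
#' @export
fit_boundaries <- function(model, pop, target,
                           grid = seq(0.4, 3, by = 0.2)) {
  idx <- model$test_idx %||% seq_len(dim(pop$x)[3])
  sub <- pop$x[, , idx, drop = FALSE]
  conds <- pop$trial_info$condition[idx]
  D <- decision_variable(model$w, sub)
  tgt <- setNames(target$p_right, target$condition)
  best <- NULL
  for (up in grid) for (lo in -grid) {
    first <- apply(D, 2, function(dc) {
      k <- which(dc >= up | dc <= lo)
      if (!length(k)) NA_integer_ else k[1]
    })
    ch <- ifelse(is.na(first), NA_character_,
                 ifelse(D[cbind(pmax(first, 1), seq_along(first))] >= up,
                        "R", "L"))
    pr <- tapply(ch == "R", conds, mean, na.rm = TRUE)
    common <- intersect(names(pr), names(tgt))
    mse <- mean((pr[common] - tgt[common])^2, na.rm = TRUE)
    if (is.null(best) || mse < best$mse) best <- list(up = up, lo = lo,
                                                      mse = mse)
  }
  model$boundaries <- c(best$up, best$lo)
  model$boundary_mse <- best$mse
  model
}

#' Simulate inactivation of a neuron subset
#'
#' Scales the spike counts of selected neurons (e.g. visual-left-preferring
#' cells, or all right-hemisphere cells) by `scale` — default 0.4, a 60%
#' activity reduction — and reruns the already-trained model. Weights are
#' not retrained.
#'
#' @param model A trained `accumulator_model`.
#' @param pop A `surrogate_population`.
#' @param selector Logical per-neuron vector of neurons to suppress.
#' @param scale Multiplicative factor on selected neurons' counts.
#' @return An `accum_outcomes` tibble (see [run_accumulator()]).
#' @export
simulate_inactivation <- function(model, pop, selector, scale = 0.4) {
  stopifnot(length(selector) == dim(pop$x)[1])
  pop2 <- pop
  pop2$x[selector, , ] <- pop2$x[selector, , , drop = FALSE] * scale
  run_accumulator(model, pop2)
}

#' Evaluate accumulator outcomes against additive behavior
#'
#' Converts accumulator outcomes to a trial table, fits the additive
#' psychometric model to the model's choices, and compares the model's
#' per-condition log odds with reference log odds (from a psychometric fit
#' to behavior) by mean-squared error. Significance is assessed against a
#' null distribution obtained by shuffling the stimulus-condition labels of
#' the outcome trials and refitting (`n_shuffle` times): a model whose
#' stimulus code genuinely drives choice beats this null. Also reports the
#' relative median reaction time per stimulus type.
#'
#' @param outcomes An `accum_outcomes` tibble with `condition`.
#' @param conditions Condition tibble (as in a `psth_bank`) mapping
#'   condition labels to stimulus columns.
#' @param reference A `psychfit` (or anything accepted by [log_odds()])
#'   giving reference log odds per condition.
#' @param n_shuffle Null size.
#' @param seed RNG seed.
#' @return An `accum_evaluation`: `mse`, `null`, `p`, the fitted `psychfit`,
#'   per-condition table, and `rel_rt` per stimulus type.
#' @export
evaluate_vs_behavior <- function(outcomes, conditions, reference,
                                 n_shuffle = 100, seed = NULL) {
  local_seed(seed)
  oc <- dplyr::filter(outcomes, .data$choice %in% c("L", "R"))
  frac_none <- 1 - nrow(oc) / nrow(outcomes)
  cond_cols <- dplyr::select(conditions, "condition", "vis_contrast_L",
                             "vis_contrast_R", "aud_azimuth_deg")
  tr <- dplyr::left_join(oc, cond_cols, by = "condition") |>
    classify_trials()
  model <- psych_model("additive",
                       contrast_set = setdiff(unique(c(tr$vis_contrast_L,
                                                       tr$vis_contrast_R)), 0),
                       azimuth_set = unique(tr$aud_azimuth_deg))
  cells <- dplyr::distinct(cond_cols, .data$vis_contrast_L,
                           .data$vis_contrast_R, .data$aud_azimuth_deg)
  ref_lo <- log_odds(reference, cells)
  mse_of <- function(trials) {
    fit <- fit_psych(trials, model, n_starts = 3)
    mean((log_odds(fit, cells) - ref_lo)^2)
  }
  mse <- mse_of(tr)
  fit <- fit_psych(tr, model, n_starts = 5)
  null <- vapply(seq_len(n_shuffle), function(i) {
    shuf <- tr
    ix <- sample.int(nrow(shuf))
    shuf[, c("vis_contrast_L", "vis_contrast_R", "aud_azimuth_deg",
             "AR", "AL", "trial_type")] <-
      shuf[ix, c("vis_contrast_L", "vis_contrast_R", "aud_azimuth_deg",
                 "AR", "AL", "trial_type")]
    mse_of(shuf)
  }, numeric(1))
  p <- (sum(null <= mse) + 1) / (n_shuffle + 1)
  rel_rt <- tr |>
    dplyr::mutate(stimulus_type = sub("_(VL_AR|VR_AL)$", "",
                                      sub("_[0-9]*[LR]$", "", .data$condition))) |>
    dplyr::group_by(.data$stimulus_type) |>
    dplyr::summarise(median_rt = median(.data$rt_s, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(rel_rt = .data$median_rt - mean(.data$median_rt))
  structure(
    list(mse = mse, null = null, p = p, fit = fit, frac_none = frac_none,
         rel_rt = rel_rt,
         by_condition = dplyr::left_join(
           dplyr::count(tr, .data$condition,
                        right = .data$choice == "R") |>
             tidyr::pivot_wider(names_from = "right", values_from = "n",
                                values_fill = 0L),
           cond_cols, by = "condition")),
    class = "accum_evaluation"
  )
}

#' @export
print.accum_evaluation <- function(x, ...) {
  cat("<accum_evaluation> log-odds MSE:", signif(x$mse, 4),
      "| shuffle p =", signif(x$p, 3),
      "| no-crossing fraction:", round(x$frac_none, 3), "\n")
  invisible(x)
}
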