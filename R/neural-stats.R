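# --- population decoding and single-neuron selectivity statistics ----------

# time-averaged rate per trial x neuron over a window
window_features <- function(rates, window) {
  in_w <- rates$t >= window[1] - 1e-9 & rates$t <= window[2] + 1e-9
  if (!any(in_w)) abort("window contains no rate bins")
  do.call(cbind, lapply(rates$rates, function(M) {
    rowMeans(M[, in_w, drop = FALSE])
  }))
}

#' Decode a binary label from population firing rates
#'
#' Linear support-vector-machine decoding of a binary trial label from the
#' time-averaged firing-rate vector in a window, reported as relative
#' accuracy
#' \deqn{(\mathrm{raw} - \mathrm{baseline}) / (1 - \mathrm{baseline}),}
#' where the baseline model has no access to spikes and always predicts the
#' training set's majority class. To make accuracy comparable across
#' populations of different sizes, decoding repeatedly subsamples
#' `n_sub` neurons (`n_repeats` times) and averages the k-fold
#' cross-validated relative accuracy over repeats. Standard windows are
#' 0–300 ms after stimulus onset (stimulus decoding), −130–0 ms before
#' movement onset (upcoming choice), and 150–300 ms after movement onset.
#'
#' @param rates A `rate_traces` object.
#' @param labels Per-trial labels (2 classes; `NA` rows dropped).
#' @param window Time-averaging window (s) on the rate lattice.
#' @param n_sub Neurons per subsample (population must have at least this
#'   many).
#' @param n_repeats Number of neuron subsamples.
#' @param k Cross-validation folds.
#' @param min_per_class Minimum trials per class (standard inclusion
#'   criterion: 25).
#' @param seed RNG seed.
#' @return A `decode_result` list: `relative_accuracy`, `raw_accuracy`,
#'   `baseline_accuracy`, and the configuration.
#' @export
decode_population <- function(rates, labels, window = c(0, 0.3),
                              n_sub = 30, n_repeats = 5, k = 5,
                              min_per_class = 25, seed = NULL) {
  local_seed(seed)
  X <- window_features(rates, window)
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) != 2) abort("labels must have exactly 2 classes")
  if (min(table(y)) < min_per_class) {
    abort(paste("fewer than", min_per_class, "trials in a class"))
  }
  if (ncol(X) < n_sub) abort(paste("fewer than", n_sub, "neurons"))
  n <- nrow(X)
  rep_res <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    cols <- sample.int(ncol(X), n_sub)
    folds <- integer(n)
    for (ix in split(seq_len(n), y)) folds[ix] <- sample(rep_len(seq_len(k),
                                                                 length(ix)))
    fold_res <- purrr::map_dfr(seq_len(k), function(f) {
      tr_ix <- folds != f; te_ix <- folds == f
      Xtr <- X[tr_ix, cols, drop = FALSE]
      keep_col <- apply(Xtr, 2, function(z) stats::sd(z) > 0)
      maj <- names(which.max(table(y[tr_ix])))
      base_acc <- mean(y[te_ix] == maj)
      if (!any(keep_col)) {
        return(tibble::tibble(raw = base_acc, base = base_acc))
      }
      fit <- e1071::svm(Xtr[, keep_col, drop = FALSE], y[tr_ix],
                        kernel = "linear", scale = TRUE)
      pred <- stats::predict(fit, X[te_ix, cols, drop = FALSE][, keep_col,
                                                               drop = FALSE])
      tibble::tibble(raw = mean(pred == y[te_ix]), base = base_acc)
    })
    dplyr::summarise(fold_res, raw = mean(.data$raw), base = mean(.data$base))
  })
  raw <- mean(rep_res$raw); base <- mean(rep_res$base)
  structure(
    list(relative_accuracy = (raw - base) / (1 - base),
         raw_accuracy = raw, baseline_accuracy = base,
         n_neurons = n_sub, n_trials = n, window = window,
         k = k, n_repeats = n_repeats),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result> relative accuracy:", round(x$relative_accuracy, 3),
      "(raw", paste0(round(x$raw_accuracy, 3), ","), "baseline",
      paste0(round(x$baseline_accuracy, 3), ")"), "\n")
  invisible(x)
}

#' Discriminability index (d-prime) between two rate distributions
#'
#' `d' = (mean_1 - mean_2) / ((sd_1 + sd_2) / 2)`: the difference of the
#' mean firing rates in the two trial conditions divided by the mean of
#' their standard deviations. Signed; use the absolute value for population
#' comparisons.
#'
#' @param x1,x2 Per-trial time-averaged rates in the two conditions.
#' @return Signed d-prime (`NaN` when both SDs are 0).
#' @export
dprime <- function(x1, x2) {
  (mean(x1) - mean(x2)) / ((stats::sd(x1) + stats::sd(x2)) / 2)
}

#' Per-neuron d-prime table for a binary condition
#'
#' @param rates A `rate_traces` object.
#' @param split Logical/two-level per-trial vector (`TRUE`/level 1 = group
#'   1); `NA` trials dropped.
#' @param window Averaging window (s): 0–300 ms post-stimulus for stimulus
#'   selectivity; −130–0 ms before movement for choice.
#' @return Tibble `(neuron_id, dprime)`.
#' @export
dprime_by_neuron <- function(rates, split, window = c(0, 0.3)) {
  X <- window_features(rates, window)
  keep <- !is.na(split)
  g <- as.logical(split[keep])
  purrr::imap_dfr(setNames(seq_len(ncol(X)), colnames(X)), function(j, nid) {
    tibble::tibble(neuron_id = nid,
                   dprime = dprime(X[keep, j][g], X[keep, j][!g]))
  })
}

# Mann-Whitney U statistic (pairs where x > y, ties 0.5) and its p value;
# exact for small untied samples, tie-corrected normal approximation
# otherwise
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (nx < 50 && ny < 50 && !ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    tie_tab <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = min(p, 1))
}

#' Combined-conditions choice (or stimulus) probability
#'
#' The fraction of trial pairs with identical stimulus condition but
#' different outcome for which the firing rate on the positive-outcome trial
#' exceeds that on the negative-outcome trial (ties count 0.5). With choices
#' as the outcome this is the combined-conditions choice probability (ccCP);
#' with one stimulus as the outcome and condition labels that include the
#' other stimulus and the choice, it is the combined-conditions stimulus
#' probability (ccSP). Significance is assessed against a null distribution
#' from shuffling outcome labels within condition: the observed statistic is
#' significant at the 0.01 level when it falls below the 0.5th or above the
#' 99.5th percentile of the null.
#'
#' @param values Per-trial scalar responses (e.g. window-averaged rate).
#' @param conditions Per-trial condition labels (pairs formed within).
#' @param outcomes Per-trial outcome, coercible to 2 levels (the higher
#'   level is "positive", e.g. rightward).
#' @param n_shuffle Null size.
#' @param seed RNG seed.
#' @return A `cp_result`: `statistic`, `null`, `significant`, `n_pairs`.
#' @export
combined_conditions_probability <- function(values, conditions, outcomes,
                                            n_shuffle = 1000, seed = NULL) {
  local_seed(seed)
  keep <- !is.na(values) & !is.na(outcomes) & !is.na(conditions)
  values <- values[keep]
  conditions <- conditions[keep]
  pos <- outcomes[keep] == sort(unique(outcomes[keep]))[length(unique(outcomes[keep]))]
  by_cond <- split(seq_along(values), conditions)
  cc_stat <- function(pos_v) {
    n_gt <- 0; n_pairs <- 0
    for (ix in by_cond) {
      p_ix <- ix[pos_v[ix]]; n_ix <- ix[!pos_v[ix]]
      if (!length(p_ix) || !length(n_ix)) next
      r <- rank(c(values[p_ix], values[n_ix]))
      U <- sum(r[seq_along(p_ix)]) - length(p_ix) * (length(p_ix) + 1) / 2
      n_gt <- n_gt + U
      n_pairs <- n_pairs + length(p_ix) * length(n_ix)
    }
    if (n_pairs == 0) return(NA_real_)
    n_gt / n_pairs
  }
  observed <- cc_stat(pos)
  if (is.na(observed)) {
    warn("no condition contains trials of both outcomes; ccCP undefined")
    return(structure(list(statistic = NA_real_, null = numeric(0),
                          significant = NA, n_pairs = 0),
                     class = "cp_result"))
  }
  null <- vapply(seq_len(n_shuffle), function(i) {
    shuf <- pos
    for (ix in by_cond) shuf[ix] <- pos[ix][sample.int(length(ix))]
    cc_stat(shuf)
  }, numeric(1))
  qs <- stats::quantile(null, c(0.005, 0.995), na.rm = TRUE, names = FALSE)
  structure(
    list(statistic = observed, null = null,
         significant = observed < qs[1] | observed > qs[2],
         n_pairs = sum(vapply(by_cond, function(ix) {
           sum(pos[ix]) * sum(!pos[ix])
         }, numeric(1)))),
    class = "cp_result"
  )
}

#' @export
print.cp_result <- function(x, ...) {
  cat("<cp_result> statistic:", round(x$statistic, 3), "over", x$n_pairs,
      "pairs;", if (isTRUE(x$significant)) "significant" else "not significant",
      "at p 0.01 (two-tailed)\n")
  invisible(x)
}

#' Choice-axis projection of population activity over time
#'
#' Projects each timepoint's population vector onto the choice axis — the
#' difference between the mean rightward-choice and leftward-choice
#' population vectors computed 0–100 ms after movement onset — via cosine
#' similarity. Choice vectors are cross-validated per stimulus condition
#' (held-out: computed from all other conditions) and trial counts are
#' balanced across choices before averaging, so stimulus-driven activity
#' cannot masquerade as choice-related.
#'
#' @param rates A `rate_traces` object (stimulus-aligned).
#' @param trials Matched trial tibble with `choice`, `rt_s` (movement
#'   onset), and `trial_type`/condition columns.
#' @param choice_window Window (s) after movement onset defining the choice
#'   vectors.
#' @param seed RNG seed (trial balancing).
#' @return Tibble `(trial_id, t_s, sc, choice, condition)` of cosine
#'   similarities.
#' @export
choice_axis_projection <- function(rates, trials,
                                   choice_window = c(0, 0.1), seed = NULL) {
  local_seed(seed)
  cond <- paste(trials$vis_contrast_L, trials$vis_contrast_R,
                trials$aud_azimuth_deg)
  ok <- trials$choice %in% c("L", "R") & !is.na(trials$rt_s)
  # per-trial population vector averaged over the movement-aligned window
  move_feat <- t(vapply(seq_len(nrow(trials)), function(i) {
    if (!ok[i]) return(rep(NA_real_, length(rates$rates)))
    w <- rates$t >= trials$rt_s[i] + choice_window[1] - 1e-9 &
      rates$t <= trials$rt_s[i] + choice_window[2] + 1e-9
    if (!any(w)) return(rep(NA_real_, length(rates$rates)))
    vapply(rates$rates, function(M) mean(M[i, w]), numeric(1))
  }, numeric(length(rates$rates))))
  out <- vector("list", nrow(trials))
  for (cn in unique(cond)) {
    test_ix <- which(cond == cn & ok)
    if (!length(test_ix)) next
    pool <- which(cond != cn & ok & !is.na(move_feat[, 1]))
    pr <- pool[trials$choice[pool] == "R"]
    pl <- pool[trials$choice[pool] == "L"]
    nb <- min(length(pr), length(pl))
    if (nb < 2) next
    pr <- resample(pr, nb); pl <- resample(pl, nb)
    axis <- colMeans(move_feat[pr, , drop = FALSE]) -
      colMeans(move_feat[pl, , drop = FALSE])
    axis_norm <- sqrt(sum(axis^2))
    if (axis_norm == 0) next
    for (i in test_ix) {
      Xi <- vapply(rates$rates, function(M) M[i, ], numeric(length(rates$t)))
      num <- as.vector(Xi %*% axis)
      den <- sqrt(rowSums(Xi^2)) * axis_norm
      out[[i]] <- tibble::tibble(
        trial_id = trials$trial_id[i], t_s = rates$t,
        sc = ifelse(den > 0, num / den, 0),
        choice = trials$choice[i], condition = cn
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Classify neurons as stimulus On-Off and/or Right-Left responsive
#'
#' Shuffle tests per neuron and modality on unisensory passive responses.
#' On-Off: the difference between the maximum of the PSTH 0–300 ms after
#' stimulus onset and the mean rate 300–0 ms before onset, against a null
#' that swaps each trial's pre- and post-stimulus windows at random; tested
#' separately for left and right stimuli, significant if either falls in
#' the outer percentiles. Right-Left: the maximum absolute difference
#' between the left- and right-stimulus PSTHs 0–300 ms, against a null that
#' shuffles the side labels.
#'
#' @param rates A `rate_traces` object.
#' @param trials Matched trial tibble.
#' @param n_shuffle Null size per test.
#' @param percentile Two-sided significance percentile (default 0.01:
#'   outside the 1st/99th).
#' @param seed RNG seed.
#' @return Tibble `(neuron_id, aud_onoff, vis_onoff, aud_rightleft,
#'   vis_rightleft)` of logical flags.
#' @export
classify_neurons <- function(rates, trials, n_shuffle = 1000,
                             percentile = 0.01, seed = NULL) {
  local_seed(seed)
  t <- rates$t
  pre_ix <- which(t >= -0.3 - 1e-9 & t < 0)
  post_ix <- which(t >= 0 & t <= 0.3 + 1e-9)
  n_use <- min(length(pre_ix), length(post_ix))
  pre_ix <- tail(pre_ix, n_use); post_ix <- head(post_ix, n_use)
  mod_trials <- list(
    aud = list(ix = which(trials$trial_type == "unisensory_auditory"),
               side = sign(trials$aud_azimuth_deg)),
    vis = list(ix = which(trials$trial_type == "unisensory_visual"),
               side = sign(trials$vis_contrast_R - trials$vis_contrast_L))
  )
  purrr::imap_dfr(rates$rates, function(M, nid) {
    row <- list(neuron_id = nid)
    for (mod in names(mod_trials)) {
      ix <- mod_trials[[mod]]$ix
      side <- mod_trials[[mod]]$side[ix]
      if (length(ix) < 4) {
        row[[paste0(mod, "_onoff")]] <- NA
        row[[paste0(mod, "_rightleft")]] <- NA
        next
      }
      Mpre <- M[ix, pre_ix, drop = FALSE]
      Mpost <- M[ix, post_ix, drop = FALSE]
      onoff_stat <- function(pre, post, rows) {
        max(vapply(c(-1, 1), function(s) {
          r <- rows == s
          if (!any(r)) return(-Inf)
          max(colMeans(post[r, , drop = FALSE])) - mean(pre[r, , drop = FALSE])
        }, numeric(1)))
      }
      obs_on <- onoff_stat(Mpre, Mpost, side)
      null_on <- vapply(seq_len(n_shuffle), function(s) {
        swap <- stats::runif(length(ix)) < 0.5
        pre2 <- Mpre; post2 <- Mpost
        pre2[swap, ] <- Mpost[swap, ]; post2[swap, ] <- Mpre[swap, ]
        onoff_stat(pre2, post2, side)
      }, numeric(1))
      rl_stat <- function(rows) {
        if (!any(rows > 0) || !any(rows < 0)) return(NA_real_)
        max(abs(colMeans(Mpost[rows > 0, , drop = FALSE]) -
                  colMeans(Mpost[rows < 0, , drop = FALSE])))
      }
      obs_rl <- rl_stat(side)
      null_rl <- vapply(seq_len(n_shuffle), function(s) {
        rl_stat(side[sample.int(length(side))])
      }, numeric(1))
      sig <- function(obs, null) {
        if (is.na(obs)) return(NA)
        qs <- stats::quantile(null, c(percentile, 1 - percentile),
                              na.rm = TRUE, names = FALSE)
        obs < qs[1] | obs > qs[2]
      }
      row[[paste0(mod, "_onoff")]] <- sig(obs_on, null_on)
      row[[paste0(mod, "_rightleft")]] <- sig(obs_rl, null_rl)
    }
    tibble::as_tibble(row)
  })
}

#' Discrimination time of a single neuron
#'
#' The earliest time at which a neuron's firing statistically distinguishes
#' stimulus presence (On-Off, pre- vs post-stimulus rate, taking the earlier
#' of the left- and right-stimulus results) or stimulus location
#' (Right-Left, left- vs right-stimulus rate), using a sliding window
#' (default 50 ms, stepped by 5 ms) with a Mann-Whitney test at `alpha` and
#' requiring `n_consec` consecutive significant windows. The reported time
#' is the start of the first window of the qualifying run; times beyond
#' `max_time` (300 ms) are discarded as unlikely to be stimulus-driven.
#'
#' @param rates A `rate_traces` object.
#' @param trials Matched trial tibble (unisensory passive trials are used).
#' @param modality `"aud"` or `"vis"`.
#' @param type `"rightleft"` or `"onoff"`.
#' @param window,step Sliding-window width and step (s).
#' @param alpha Per-window significance level.
#' @param n_consec Consecutive significant windows required.
#' @param max_time Latest admissible discrimination time (s).
#' @return Tibble `(neuron_id, modality, type, discrimination_time_s)`
#'   (`NA` when no qualifying run).
#' @export
discrimination_time <- function(rates, trials, modality = c("aud", "vis"),
                                type = c("rightleft", "onoff"),
                                window = 0.050, step = 0.005, alpha = 0.01,
                                n_consec = 3, max_time = 0.3) {
  modality <- match.arg(modality)
  type <- match.arg(type)
  t <- rates$t
  ix <- if (modality == "aud") {
    which(trials$trial_type == "unisensory_auditory")
  } else {
    which(trials$trial_type == "unisensory_visual")
  }
  side <- if (modality == "aud") sign(trials$aud_azimuth_deg[ix]) else
    sign(trials$vis_contrast_R[ix] - trials$vis_contrast_L[ix])
  starts <- seq(0, max_time, by = step)
  pre_ix <- which(t >= -0.3 - 1e-9 & t < 0)
  purrr::imap_dfr(rates$rates, function(M, nid) {
    Msub <- M[ix, , drop = FALSE]
    p_of_start <- function(s0, rows_a, rows_b, vs_pre = FALSE) {
      w <- which(t >= s0 - 1e-9 & t < s0 + window - 1e-9)
      if (!length(w)) return(NA_real_)
      xa <- rowMeans(Msub[rows_a, w, drop = FALSE])
      if (vs_pre) {
        xb <- rowMeans(Msub[rows_a, pre_ix, drop = FALSE])
      } else {
        xb <- rowMeans(Msub[rows_b, w, drop = FALSE])
      }
      mann_whitney(xa, xb)$p
    }
    time_of <- function(pvec) {
      sig <- !is.na(pvec) & pvec < alpha
      run <- 0
      for (j in seq_along(sig)) {
        run <- if (sig[j]) run + 1 else 0
        if (run >= n_consec) {
          t0 <- starts[j - n_consec + 1]
          if (t0 <= max_time) return(t0) else return(NA_real_)
        }
      }
      NA_real_
    }
    dtime <- if (type == "rightleft") {
      if (!any(side > 0) || !any(side < 0)) NA_real_ else {
        p <- vapply(starts, p_of_start, numeric(1),
                    rows_a = which(side > 0), rows_b = which(side < 0))
        time_of(p)
      }
    } else {
      per_side <- vapply(c(-1, 1), function(s) {
        rows <- which(side == s)
        if (!length(rows)) return(NA_real_)
        p <- vapply(starts, p_of_start, numeric(1),
                    rows_a = rows, rows_b = NULL, vs_pre = TRUE)
        time_of(p)
      }, numeric(1))
      if (all(is.na(per_side))) NA_real_ else min(per_side, na.rm = TRUE)
    }
    tibble::tibble(neuron_id = nid, modality = modality, type = type,
                   discrimination_time_s = dtime)
  })
}

#' Post-hoc decoding accuracy at the discrimination time
#'
#' Relative (baseline-corrected) cross-validated linear-SVM accuracy of
#' stimulus side from a single neuron's rate averaged 0–100 ms after its
#' discrimination time.
#'
#' @param rates A `rate_traces` object.
#' @param trials Matched trial tibble.
#' @param times Output of [discrimination_time()].
#' @param k Folds.
#' @param seed RNG seed.
#' @return `times` with a `decode_accuracy` column appended.
#' @export
discrimination_decode <- function(rates, trials, times, k = 5, seed = NULL) {
  local_seed(seed)
  times$decode_accuracy <- vapply(seq_len(nrow(times)), function(r) {
    dtime <- times$discrimination_time_s[r]
    if (is.na(dtime)) return(NA_real_)
    mod <- times$modality[r]
    ix <- if (mod == "aud") which(trials$trial_type == "unisensory_auditory")
      else which(trials$trial_type == "unisensory_visual")
    side <- if (mod == "aud") sign(trials$aud_azimuth_deg[ix]) else
      sign(trials$vis_contrast_R[ix] - trials$vis_contrast_L[ix])
    M <- rates$rates[[times$neuron_id[r]]]
    w <- rates$t >= dtime - 1e-9 & rates$t <= dtime + 0.1 + 1e-9
    x <- rowMeans(M[ix, w, drop = FALSE])
    y <- factor(side)
    folds <- integer(length(x))
    for (g in split(seq_along(x), y)) folds[g] <- sample(rep_len(seq_len(k),
                                                                 length(g)))
    accs <- vapply(seq_len(k), function(f) {
      tr_ix <- folds != f; te_ix <- folds == f
      maj <- names(which.max(table(y[tr_ix])))
      base <- mean(y[te_ix] == maj)
      if (stats::sd(x[tr_ix]) == 0) return(0)
      fit <- e1071::svm(matrix(x[tr_ix]), y[tr_ix], kernel = "linear",
                        scale = TRUE)
      raw <- mean(stats::predict(fit, matrix(x[te_ix])) == y[te_ix])
      (raw - base) / max(1 - base, 1e-9)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  times
}
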