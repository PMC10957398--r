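# --- trial filtering and behavioral summaries ------------------------------

#' Apply the standard trial filters
#'
#' Flags (never deletes) trials excluded from behavioral analyses:
#' \describe{
#'   \item{`session_edge`}{trials before the first, or after the last, run of
#'     three consecutive non-timeout choices in a session (removes inattentive
#'     session edges). A session with no such run is flagged entirely.}
#'   \item{`timeout`}{no threshold crossing within the response window.}
#'   \item{`repeat`}{stimulus repetitions following an incorrect (non-timeout)
#'     choice.}
#'   \item{`rt_undetectable`}{a choice was made but no reaction time could be
#'     extracted from the wheel trace.}
#' }
#' The function is idempotent: re-filtering a filtered table reproduces the
#' same flags.
#'
#' @param trials Trial tibble with `session_id`, `trial_id` (ordering within
#'   session), `choice`, `timeout`, `repeat_flag`, and optionally
#'   `rt_excluded`.
#' @return `trials` with `excluded_flag` (logical) and `excluded_reason`
#'   (`NA` when kept) columns.
#' @export
filter_trials <- function(trials) {
  if (!all(c("session_id", "trial_id") %in% names(trials))) {
    abort("trials must carry session_id and trial_id for session ordering")
  }
  trials |>
    dplyr::group_by(.data$session_id) |>
    dplyr::arrange(.data$trial_id, .by_group = TRUE) |>
    dplyr::group_modify(~ filter_one_session(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$trial_id)
}

filter_one_session <- function(tr) {
  n <- nrow(tr)
  is_to <- tr$timeout | tr$choice %in% "timeout" | is.na(tr$choice)
  ok <- !is_to
  # runs of >= 3 consecutive non-timeout choices
  run3 <- if (n >= 3) which(ok[1:(n - 2)] & ok[2:(n - 1)] & ok[3:n]) else integer(0)
  edge <- rep(TRUE, n)
  if (length(run3)) {
    edge[seq(min(run3), max(run3) + 2)] <- FALSE
  }
  # repeats following an incorrect (non-timeout) choice
  prev_incorrect <- c(FALSE, !is_to[-n] & !is_correct(tr)[-n])
  rep_excl <- tr$repeat_flag & prev_incorrect
  rt_missing <- if ("rt_excluded" %in% names(tr)) {
    !is_to & (tr$rt_excluded %in% TRUE | is.na(tr$rt_s))
  } else {
    rep(FALSE, n)
  }
  reason <- dplyr::case_when(
    edge ~ "session_edge",
    is_to ~ "timeout",
    rep_excl ~ "repeat",
    rt_missing ~ "rt_undetectable",
    TRUE ~ NA_character_
  )
  dplyr::mutate(tr, excluded_flag = !is.na(reason), excluded_reason = reason)
}

# rewarded side is defined on unisensory and coherent trials only
is_correct <- function(tr) {
  vside <- sign(tr$vis_contrast_R - tr$vis_contrast_L)
  aside <- sign(tr$aud_azimuth_deg)
  target <- dplyr::case_when(
    tr$trial_type == "unisensory_visual" ~ vside,
    tr$trial_type == "unisensory_auditory" ~ aside,
    tr$trial_type == "coherent" ~ vside,
    TRUE ~ NA_real_
  )
  code <- choice_code(tr$choice)
  out <- code == target
  out[is.na(out)] <- FALSE   # conflict/neutral: "correct" undefined
  out
}

#' Summarize choices and reaction times by stimulus type
#'
#' Per-subject summary following the session-first aggregation order: the
#' statistic (fraction rewarded; median reaction time) is computed within
#' each session, then averaged over sessions, then over mirrored (left/right)
#' presentations. Relative reaction time subtracts each subject's mean over
#' stimulus types. Cells with no valid trials are missing, not zero.
#'
#' @param trials Filtered trial tibble (rows with `excluded_flag` are
#'   dropped; an unfiltered table is used as is).
#' @return A list of class `behavior_summary` with `by_type` (per subject x
#'   stimulus type: `frac_rewarded`, `median_rt`, `rel_rt`) and
#'   `by_condition` (per signed condition: `n`, `frac_right`).
#' @export
summarize_behavior <- function(trials) {
  tr <- trials
  if ("excluded_flag" %in% names(tr)) tr <- dplyr::filter(tr, !.data$excluded_flag)
  tr <- dplyr::filter(tr, .data$choice %in% c("L", "R"))
  tr$correct <- is_correct(tr)
  tr$side <- dplyr::case_when(
    tr$trial_type %in% c("unisensory_visual", "coherent", "conflict") ~
      sign(tr$vis_contrast_R - tr$vis_contrast_L),
    tr$trial_type == "unisensory_auditory" ~ sign(tr$aud_azimuth_deg),
    TRUE ~ 0
  )
  per_session <- tr |>
    dplyr::group_by(.data$subject_id, .data$session_id, .data$trial_type,
                    .data$side) |>
    dplyr::summarise(
      frac_rewarded = ifelse(.data$trial_type[1] %in%
                               c("conflict", "neutral"), NA_real_,
                             mean(.data$correct)),
      median_rt = median(.data$rt_s, na.rm = TRUE),
      .groups = "drop"
    )
  by_type <- per_session |>
    dplyr::group_by(.data$subject_id, .data$trial_type, .data$side) |>
    dplyr::summarise(dplyr::across(c("frac_rewarded", "median_rt"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::group_by(.data$subject_id, .data$trial_type) |>
    dplyr::summarise(dplyr::across(c("frac_rewarded", "median_rt"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(rel_rt = .data$median_rt - mean(.data$median_rt,
                                                  na.rm = TRUE)) |>
    dplyr::ungroup()
  by_condition <- tr |>
    dplyr::group_by(.data$vis_contrast_L, .data$vis_contrast_R,
                    .data$aud_azimuth_deg) |>
    dplyr::summarise(n = dplyr::n(), frac_right = mean(.data$choice == "R"),
                     .groups = "drop")
  structure(list(by_type = by_type, by_condition = by_condition),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>\n")
  print(x$by_type)
  invisible(x)
}

#' Decode stimulus side from wheel velocity over time
#'
#' For each timepoint, predicts whether the stimulus was on the left or right
#' from the instantaneous wheel velocity, using a class-balanced 2-fold
#' cross-validated nearest-class-mean rule per session, separately for
#' unisensory auditory and unisensory visual trials. Accuracies are averaged
#' session -> subject.
#'
#' @param trials Trial tibble.
#' @param traces Long wheel-trace tibble.
#' @param time_grid Timepoints (s) at which to decode.
#' @param seed RNG seed (class balancing, folds).
#' @return Tibble `(modality, t_s, accuracy)` averaged across subjects.
#' @export
decode_side_from_wheel <- function(trials, traces,
                                   time_grid = seq(0, 0.5, by = 0.025),
                                   seed = NULL) {
  local_seed(seed)
  vel <- traces |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::arrange(.data$t_s, .by_group = TRUE) |>
    dplyr::mutate(v = c(NA_real_, diff(.data$position_deg) / diff(.data$t_s))) |>
    dplyr::ungroup()
  vel_at <- function(ids, tp) {
    vapply(split(vel[vel$trial_id %in% ids, ], vel$trial_id[vel$trial_id %in% ids])[as.character(ids)],
           function(d) {
             k <- which.min(abs(d$t_s - tp))
             d$v[k]
           }, numeric(1))
  }
  out <- list()
  for (mod in c("unisensory_auditory", "unisensory_visual")) {
    per_sess <- list()
    for (sess in unique(trials$session_id)) {
      tr <- trials[trials$session_id == sess & trials$trial_type == mod &
                     trials$choice %in% c("L", "R"), ]
      side <- if (mod == "unisensory_auditory") {
        sign(tr$aud_azimuth_deg)
      } else {
        sign(tr$vis_contrast_R - tr$vis_contrast_L)
      }
      nl <- sum(side < 0); nr <- sum(side > 0)
      if (min(nl, nr) < 2) next
      nb <- min(nl, nr)
      keep <- c(sample(which(side < 0), nb), sample(which(side > 0), nb))
      tr <- tr[keep, ]; side <- side[keep]
      fold <- sample(rep_len(1:2, nrow(tr)))
      acc <- vapply(time_grid, function(tp) {
        v <- vel_at(tr$trial_id, tp)
        correct <- 0; total <- 0
        for (f in 1:2) {
          tr_ix <- fold != f; te_ix <- fold == f
          mR <- mean(v[tr_ix & side > 0], na.rm = TRUE)
          mL <- mean(v[tr_ix & side < 0], na.rm = TRUE)
          if (!is.finite(mR) || !is.finite(mL)) next
          pred <- ifelse(abs(v[te_ix] - mR) < abs(v[te_ix] - mL), 1, -1)
          correct <- correct + sum(pred == side[te_ix], na.rm = TRUE)
          total <- total + sum(!is.na(v[te_ix]))
        }
        if (total == 0) NA_real_ else correct / total
      }, numeric(1))
      subj <- tr$subject_id[1]
      per_sess[[sess]] <- tibble::tibble(modality = mod, subject_id = subj,
                                         t_s = time_grid, accuracy = acc)
    }
    if (length(per_sess)) {
      out[[mod]] <- dplyr::bind_rows(per_sess) |>
        dplyr::group_by(.data$modality, .data$subject_id, .data$t_s) |>
        dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::group_by(.data$modality, .data$t_s) |>
        dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                         .groups = "drop")
    }
  }
  dplyr::bind_rows(out)
}

#' Shuffle test for stimulus-locked wheel movement
#'
#' Tests whether the wheel moves in response to stimuli (e.g. during passive
#' presentation): the observed statistic is the mean over trials of the
#' absolute wheel displacement between stimulus onset and `window_s` later;
#' the null randomizes the onset time within each trial. The movement is
#' significant when the observed value lies in the top 5% of the null.
#'
#' @param traces Long wheel-trace tibble.
#' @param onsets Tibble `(trial_id, onset_s)` of true stimulus onsets.
#' @param n_shuffle Number of shuffles (must be positive).
#' @param window_s Displacement window (s).
#' @param seed RNG seed.
#' @return List with `observed`, `null` (length `n_shuffle`), `p` (rank
#'   based, one-sided), and `significant`.
#' @export
passive_wheel_shuffle_test <- function(traces, onsets, n_shuffle = 1000,
                                       window_s = 0.5, seed = NULL) {
  if (n_shuffle < 1) abort("n_shuffle must be positive")
  local_seed(seed)
  tr_split <- split(traces, traces$trial_id)
  disp <- function(d, t0) {
    p0 <- d$position_deg[which.min(abs(d$t_s - t0))]
    p1 <- d$position_deg[which.min(abs(d$t_s - (t0 + window_s)))]
    abs(p1 - p0)
  }
  ids <- as.character(onsets$trial_id)
  observed <- mean(purrr::map2_dbl(tr_split[ids], onsets$onset_s, disp))
  ranges <- purrr::map(tr_split[ids], function(d) {
    c(min(d$t_s), max(d$t_s) - window_s)
  })
  null <- vapply(seq_len(n_shuffle), function(j) {
    t0s <- purrr::map_dbl(ranges, function(r) stats::runif(1, r[1], r[2]))
    mean(purrr::map2_dbl(tr_split[ids], t0s, disp))
  }, numeric(1))
  p <- (sum(null >= observed) + 1) / (n_shuffle + 1)
  list(observed = observed, null = null, p = p, significant = p < 0.05)
}
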