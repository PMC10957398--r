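# --- wheel traces: generation and choice / reaction-time extraction -------

#' Generate synthetic wheel-position traces
#'
#' Builds one wheel trace per trial consistent with the trial's choice and
#' target reaction time: the wheel holds still (with at least 50 ms of zero
#' velocity immediately before the reaction time), then ramps monotonically
#' past the choice threshold in the choice direction. Timeout trials never
#' cross the threshold within the 1.5 s response window. Optional
#' sub-threshold wiggles (a brief opposite-direction excursion that returns
#' to rest at least 100 ms before the reaction time) exercise the
#' last-zero-crossing rule of [detect_reaction_time()].
#'
#' @param trials Trial tibble with `choice` and `rt_s`.
#' @param sampling_rate Samples per second; the sampling interval must be at
#'   most 10 ms, as the reaction-time definition needs finer resolution.
#' @param threshold_deg Choice threshold in wheel degrees.
#' @param t_range Trace time span (s) relative to stimulus onset; must
#'   include pre-stimulus samples.
#' @param ramp_speed_deg_s Movement velocity of the choice ramp.
#' @param wiggle Inject a sub-threshold pre-RT wiggle on every moving trial.
#' @param seed RNG seed (wiggle phases).
#' @return Long tibble `(trial_id, t_s, position_deg)`.
#' @export
gen_wheel_traces <- function(trials, sampling_rate = 200, threshold_deg = 30,
                             t_range = c(-0.1, 1.6), ramp_speed_deg_s = 200,
                             wiggle = FALSE, seed = NULL) {
  dt <- 1 / sampling_rate
  if (dt > 0.010 + 1e-12) {
    abort("sampling interval must be <= 10 ms for reaction-time extraction")
  }
  bad_rt <- !trials$timeout & !is.na(trials$choice) &
    trials$choice != "timeout" & (is.na(trials$rt_s) | trials$rt_s <= 0)
  if (any(bad_rt)) abort("non-timeout trials need a positive target rt_s")
  local_seed(seed)
  t <- seq(t_range[1], t_range[2], by = dt)
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    pos <- numeric(length(t))
    is_timeout <- isTRUE(tr$timeout) || identical(tr$choice, "timeout") ||
      is.na(tr$choice)
    if (!is_timeout) {
      dir <- ifelse(tr$choice == "R", 1, -1)
      moving <- t > tr$rt_s
      pos[moving] <- dir * pmin((t[moving] - tr$rt_s) * ramp_speed_deg_s,
                                1.5 * threshold_deg)
      if (wiggle && tr$rt_s > 0.35) {
        # opposite-direction half-sine bump ending 100 ms before the RT
        w0 <- tr$rt_s - 0.30
        w1 <- tr$rt_s - 0.10
        in_w <- t >= w0 & t <= w1
        pos[in_w] <- pos[in_w] -
          dir * 0.2 * threshold_deg * sin(pi * (t[in_w] - w0) / (w1 - w0))
      }
    }
    tibble::tibble(trial_id = tr$trial_id, t_s = t, position_deg = pos)
  })
}

#' Detect the choice from a wheel trace
#'
#' The choice is the direction of the first crossing of
#' `|position - position(0)| >= threshold_deg` within the response window;
#' a trace that never crosses is a timeout.
#'
#' @param trace Tibble with `t_s` (strictly increasing, covering the window
#'   and pre-stimulus samples) and `position_deg`.
#' @param threshold_deg Choice threshold in wheel degrees.
#' @param response_window_s Response window (s) after stimulus onset.
#' @return List with `choice` (`"R"`, `"L"`, or `"timeout"`) and
#'   `crossing_time` (s; `NA` on timeout).
#' @export
detect_choice <- function(trace, threshold_deg = 30, response_window_s = 1.5) {
  t <- trace$t_s; pos <- trace$position_deg
  if (max(t) < response_window_s) {
    abort("trace does not cover the response window")
  }
  pre <- which(t <= 0)
  if (!length(pre)) abort("trace has no pre-stimulus samples")
  p0 <- pos[max(pre)]
  in_win <- t > 0 & t <= response_window_s
  dev <- abs(pos - p0)
  hit <- which(in_win & dev >= threshold_deg)
  if (!length(hit)) {
    return(list(choice = "timeout", crossing_time = NA_real_))
  }
  k <- hit[1]
  list(choice = ifelse(pos[k] - p0 > 0, "R", "L"), crossing_time = t[k])
}

#' Extract the reaction time from a wheel trace
#'
#' Implements the movement-onset rule: the reaction time is the last time
#' before the threshold crossing at which the wheel velocity crossed zero
#' after at least `still_s` seconds at zero (or moving opposite to the
#' choice direction), and then exceeded `vel_frac` of the choice threshold
#' per second for at least `move_s` seconds. The trial is excluded (returns
#' `NA` with `excluded = TRUE`) when no such time exists or when movement is
#' already nonzero within `onset_quiet_s` of stimulus onset.
#'
#' Velocity is computed by first differences over the native sampling
#' interval with no smoothing; "at zero" admits |velocity| up to `vel_eps`
#' (deg/s). When several samples tie as the zero-crossing, the latest one is
#' taken (the rule asks for the last such time).
#'
#' @param trace Wheel trace tibble (`t_s`, `position_deg`).
#' @param choice `"R"` or `"L"` from [detect_choice()].
#' @param crossing_time Threshold-crossing time from [detect_choice()].
#' @param threshold_deg Choice threshold (deg).
#' @param still_s,move_s Minimum durations of the still and moving phases.
#' @param vel_frac Post-onset velocity criterion, as a fraction of
#'   `threshold_deg` per second.
#' @param onset_quiet_s Movement within this time of stimulus onset excludes
#'   the trial.
#' @param vel_eps Velocity magnitude (deg/s) still counted as "zero".
#' @return List with `rt_s` (`NA` when excluded) and `excluded` flag.
#' @export
detect_reaction_time <- function(trace, choice, crossing_time,
                                 threshold_deg = 30, still_s = 0.050,
                                 move_s = 0.050, vel_frac = 0.2,
                                 onset_quiet_s = 0.010, vel_eps = 1e-9) {
  if (identical(choice, "timeout")) abort("reaction time undefined on timeouts")
  t <- trace$t_s; pos <- trace$position_deg
  dt <- diff(t)
  v <- c(NA_real_, diff(pos) / dt)           # velocity at sample k over (k-1, k]
  dir <- ifelse(choice == "R", 1, -1)
  s <- v * dir                               # signed toward choice direction
  # exclusion: movement already nonzero right after stimulus onset
  early <- which(t > 0 & t <= onset_quiet_s)
  if (length(early) && any(abs(v[early]) > vel_eps, na.rm = TRUE)) {
    return(list(rt_s = NA_real_, excluded = TRUE))
  }
  v_crit <- vel_frac * threshold_deg
  n <- length(t)
  cand_rt <- NA_real_
  ks <- which(t > 0 & t <= crossing_time & !is.na(s) & s > vel_eps)
  for (k in ks) {
    # still (or opposite) phase covering at least still_s before t[k-1]
    still_ix <- which(t <= t[k - 1] & t > t[k - 1] - still_s - 1e-9)
    still_ix <- still_ix[still_ix >= 2]
    if (!length(still_ix) || t[k - 1] - still_s < t[1]) next
    if (any(s[still_ix] > vel_eps)) next
    # moving phase: velocity above criterion for at least move_s from t[k]
    move_ix <- which(t >= t[k] & t < t[k] + move_s - 1e-9)
    if (max(move_ix) >= n && t[n] < t[k] + move_s - 1e-9) next
    if (all(s[move_ix] >= v_crit - 1e-9)) cand_rt <- t[k - 1]
  }
  list(rt_s = cand_rt, excluded = is.na(cand_rt))
}

#' Extract choices and reaction times for a table of trials
#'
#' Table-level wrapper over [detect_choice()] and [detect_reaction_time()].
#'
#' @param trials Trial tibble.
#' @param traces Long wheel-trace tibble (`trial_id`, `t_s`, `position_deg`).
#' @param threshold_deg,response_window_s See [detect_choice()].
#' @param ... Passed to [detect_reaction_time()].
#' @return `trials` with `choice`, `rt_s`, `timeout`, and `rt_excluded`
#'   columns filled from the traces.
#' @export
extract_behavior <- function(trials, traces, threshold_deg = 30,
                             response_window_s = 1.5, ...) {
  tr_split <- split(traces, traces$trial_id)
  res <- purrr::map(as.character(trials$trial_id), function(id) {
    tra <- tr_split[[id]]
    if (is.null(tra)) return(list(choice = NA_character_, rt = NA_real_,
                                  excl = NA))
    ch <- detect_choice(tra, threshold_deg, response_window_s)
    if (ch$choice == "timeout") {
      return(list(choice = "timeout", rt = NA_real_, excl = FALSE))
    }
    rt <- detect_reaction_time(tra, ch$choice, ch$crossing_time,
                               threshold_deg, ...)
    list(choice = ch$choice, rt = rt$rt_s, excl = rt$excluded)
  })
  dplyr::mutate(trials,
    choice = purrr::map_chr(res, "choice"),
    rt_s = purrr::map_dbl(res, "rt"),
    timeout = .data$choice == "timeout",
    rt_excluded = purrr::map_lgl(res, "excl")
  )
}
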