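# --- shuffle-test inference for optogenetic inactivation -------------------

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test for the table `[[a, b], [c, d]]` with fixed
#' margins: the p value is the sum of probabilities of all tables at most as
#' probable as the observed one. Implemented directly (no external test
#' dependency) so the pulse-timing analysis can call it tens of thousands of
#' times cheaply.
#'
#' @param a,b,c,d Nonnegative integer cell counts (row 1: `a`, `b`; row 2:
#'   `c`, `d`).
#' @return Two-sided p value.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row-1 total
  n2 <- c + d         # row-2 total
  k <- a + c          # column-1 total
  if (m + n2 == 0) return(NA_real_)
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# stimulus side in the sense of the inactivation maps: the visual side on
# any visual-containing trial (including conflict), the auditory side on
# unisensory auditory trials, 0 on neutral
stimulus_side <- function(trials) {
  vside <- sign(trials$vis_contrast_R - trials$vis_contrast_L)
  ifelse(vside != 0, vside, sign(trials$aud_azimuth_deg))
}

# mirror trials so stimuli are effectively leftward (laser ML flips too)
mirror_stimuli_left <- function(trials) {
  mirror_trials(trials, stimulus_side(trials) > 0)
}

#' Shuffle test for the inactivation-induced choice shift at a site
#'
#' Quantifies the change in the fraction of rightward choices when a laser
#' site is inactivated, for one stimulus type. Trials are first mirrored so
#' that stimuli are effectively presented on the left (the visual stimulus on
#' conflict trials), flipping the laser laterality along with them; the site
#' is then identified by its coordinates in this mirrored frame. The observed
#' statistic is the mean, over `n_subsample` subsample iterations that
#' equalize each subject's contribution to laser and control trials, of
#' `frac_right(laser at site) - frac_right(control)`. The null reassigns
#' laser/control labels at random within subject (`n_shuffle_per` shuffles
#' per iteration), and the p value is the two-sided rank of the observed mean
#' in the pooled null.
#'
#' @param trials Trial tibble with laser columns and choices.
#' @param site Length-2 numeric `(ap_mm, ml_mm)` in the mirrored frame.
#' @param stimulus_type One of the five trial types, or `"all"`.
#' @param n_subsample Number of subsample iterations.
#' @param n_shuffle_per Shuffles per iteration (null size is
#'   `n_subsample * n_shuffle_per`).
#' @param seed RNG seed.
#' @return A `shuffle_result` list: `observed`, `null`, `p`, `n_laser`,
#'   `n_control`.
#' @export
shuffle_test_choice_shift <- function(trials, site,
                                      stimulus_type = "unisensory_visual",
                                      n_subsample = 25000, n_shuffle_per = 10,
                                      seed = NULL) {
  if (n_shuffle_per < 1) abort("n_shuffle_per must be positive")
  local_seed(seed)
  tr <- mirror_stimuli_left(trials) |>
    dplyr::filter(.data$choice %in% c("L", "R"))
  if (!identical(stimulus_type, "all")) {
    tr <- dplyr::filter(tr, .data$trial_type == stimulus_type)
  }
  at_site <- tr$laser_on & tr$laser_ap_mm == site[1] & tr$laser_ml_mm == site[2]
  at_site[is.na(at_site)] <- FALSE
  control <- !tr$laser_on
  if (!any(at_site)) abort("site has no laser trials for this stimulus type")
  r <- as.integer(tr$choice == "R")
  subj <- tr$subject_id
  subjects <- unique(subj)
  las_ix <- lapply(subjects, function(s) which(at_site & subj == s))
  ctl_ix <- lapply(subjects, function(s) which(control & subj == s))
  m_per <- pmin(lengths(las_ix), lengths(ctl_ix))
  keep <- m_per > 0
  las_ix <- las_ix[keep]; ctl_ix <- ctl_ix[keep]; m_per <- m_per[keep]
  if (!length(m_per)) abort("no subject contributes both laser and control trials")
  one_delta <- function(shuffle) {
    dl <- 0; dc <- 0; m_tot <- 0
    for (j in seq_along(m_per)) {
      li <- resample(las_ix[[j]], m_per[j])
      ci <- resample(ctl_ix[[j]], m_per[j])
      if (shuffle) {
        pool <- c(li, ci)
        pool <- pool[sample.int(length(pool))]
        li <- pool[seq_len(m_per[j])]
        ci <- pool[-seq_len(m_per[j])]
      }
      dl <- dl + sum(r[li]); dc <- dc + sum(r[ci]); m_tot <- m_tot + m_per[j]
    }
    (dl - dc) / m_tot
  }
  obs <- vapply(seq_len(n_subsample), function(i) one_delta(FALSE), numeric(1))
  null <- vapply(seq_len(n_subsample * n_shuffle_per),
                 function(i) one_delta(TRUE), numeric(1))
  observed <- mean(obs)
  structure(
    list(observed = observed, null = null,
         p = rank_p_two_sided(observed, null),
         n_laser = sum(at_site), n_control = sum(control),
         site = site, stimulus_type = stimulus_type),
    class = "shuffle_result"
  )
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("<shuffle_result> observed:", signif(x$observed, 4),
      "| p =", signif(x$p, 3), "| null size:", length(x$null), "\n")
  invisible(x)
}

# symmetrize control trials (each trial plus its mirror image) so the
# ipsi/contra model applies to data with no inactivated hemisphere
symmetrize_controls <- function(tr) {
  dplyr::bind_rows(tr, mirror_trials(tr, rep(TRUE, nrow(tr))))
}

#' Shuffle test for inactivation-induced psychometric parameter changes
#'
#' Fits the ipsi/contra reparameterized additive model
#' `log p(I)/p(C) = b + vi*Vi^gamma - vc*Vc^gamma + ai*Ai - ac*Ac` to
#' control trials (symmetrized across hemispheres) and to laser trials at
#' the sites of one region (each mirrored so its inactivated hemisphere is
#' the "ipsi" side). The contrast exponent is frozen at the control-fit
#' value. The observed statistic per parameter is the mean, over subsample
#' iterations equalizing subject contributions, of the laser-minus-control
#' parameter difference; the null shuffles laser/control labels.
#'
#' @param trials Trial tibble with `laser_region` (or supply `sites`).
#' @param region Region label selecting laser trials.
#' @param n_subsample Subsample iterations for the observed mean.
#' @param n_shuffle_total Total null points.
#' @param n_starts Optimizer restarts per fit (fits are per-iteration; keep
#'   small).
#' @param seed RNG seed.
#' @return Tibble with one row per parameter (`b`, `vi`, `vc`, `ai`, `ac`):
#'   observed `delta`, rank-based two-sided `p`, and null summary columns.
#' @export
shuffle_test_param_change <- function(trials, region, n_subsample = 2500,
                                      n_shuffle_total = 25000, n_starts = 2,
                                      seed = NULL) {
  local_seed(seed)
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"))
  is_las <- tr$laser_on & tr$laser_region %in% region
  is_ctl <- !tr$laser_on
  tr <- tr[is_las | is_ctl, ]
  is_las <- tr$laser_on
  if (!any(is_las)) abort("region has no laser trials")
  design <- list(contrast_set = setdiff(unique(c(tr$vis_contrast_L,
                                                 tr$vis_contrast_R)), 0),
                 azimuth_set = sort(unique(c(tr$aud_azimuth_deg,
                                             -tr$aud_azimuth_deg))))
  ic0 <- psych_model("ipsi_contra", contrast_set = design$contrast_set,
                     azimuth_set = design$azimuth_set)
  ctl_sym <- symmetrize_controls(tr[!is_las, ])
  fit_ctl_full <- fit_psych(ctl_sym, ic0, n_starts = 5)
  gamma_hat <- fit_ctl_full$estimates[["gamma"]]
  ic <- psych_model("ipsi_contra", contrast_set = design$contrast_set,
                    azimuth_set = design$azimuth_set,
                    fixed = list(gamma = gamma_hat))
  par_names <- c("b", "vi", "vc", "ai", "ac")
  tr_ic <- mirror_to_ipsi(tr)     # laser trials into the ipsi frame
  subj <- tr_ic$subject_id
  subjects <- unique(subj)
  las_ix <- lapply(subjects, function(s) which(is_las & subj == s))
  ctl_ix <- lapply(subjects, function(s) which(!is_las & subj == s))
  m_per <- pmin(lengths(las_ix), lengths(ctl_ix))
  keep <- m_per > 0
  las_ix <- las_ix[keep]; ctl_ix <- ctl_ix[keep]; m_per <- m_per[keep]
  delta_once <- function(shuffle) {
    li <- integer(0); ci <- integer(0)
    for (j in seq_along(m_per)) {
      lj <- resample(las_ix[[j]], m_per[j])
      cj <- resample(ctl_ix[[j]], m_per[j])
      if (shuffle) {
        pool <- c(lj, cj)[sample.int(2 * m_per[j])]
        lj <- pool[seq_len(m_per[j])]; cj <- pool[-seq_len(m_per[j])]
      }
      li <- c(li, lj); ci <- c(ci, cj)
    }
    f_l <- fit_psych(tr_ic[li, ], ic, n_starts = n_starts)
    f_c <- fit_psych(symmetrize_controls(tr_ic[ci, ]), ic,
                     n_starts = n_starts)
    f_l$estimates[par_names] - f_c$estimates[par_names]
  }
  obs <- rowMeans(vapply(seq_len(n_subsample), function(i) delta_once(FALSE),
                         numeric(length(par_names))))
  null <- vapply(seq_len(n_shuffle_total), function(i) delta_once(TRUE),
                 numeric(length(par_names)))
  tibble::tibble(
    parameter = par_names,
    delta = unname(obs),
    p = vapply(seq_along(par_names),
               function(j) rank_p_two_sided(obs[j], null[j, ]), numeric(1)),
    null_mean = rowMeans(null), null_sd = apply(null, 1, sd),
    gamma_frozen = gamma_hat
  )
}

#' Shuffle test for divergent inactivation effects between two regions
#'
#' Tests whether inactivating two regions changes behavior in different
#' ways: for each subsample (equalizing subject contributions and train/test
#' sizes), the ipsi/contra additive model is fit on a training half of each
#' region's laser trials and evaluated on held-out trials of the same region
#' (within-region log likelihood) and of the other region (inter-region).
#' The statistic is the mean per-trial within-minus-inter difference; the
#' null shuffles region labels before the split. When comparing several
#' region pairs, Bonferroni-correct the returned p values.
#'
#' @param trials Trial tibble with `laser_region`.
#' @param regionA,regionB Region labels.
#' @param n_subsample Subsamples for the observed statistic.
#' @param n_shuffle Null points.
#' @param seed RNG seed.
#' @return A `shuffle_result` with the within-minus-inter statistic.
#' @export
region_model_divergence <- function(trials, regionA, regionB,
                                    n_subsample = 100, n_shuffle = 1000,
                                    seed = NULL) {
  local_seed(seed)
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"),
                      .data$laser_on, .data$laser_region %in% c(regionA, regionB))
  if (!nrow(tr)) abort("no laser trials in the requested regions")
  tr <- mirror_to_ipsi(tr)
  lab <- tr$laser_region
  design_contrasts <- setdiff(unique(c(tr$vis_contrast_L, tr$vis_contrast_R)), 0)
  az <- sort(unique(c(tr$aud_azimuth_deg, -tr$aud_azimuth_deg)))
  ic <- psych_model("ipsi_contra", contrast_set = design_contrasts,
                    azimuth_set = az)
  n_eq <- min(table(lab))
  stat_once <- function(shuffle) {
    lab_i <- if (shuffle) lab[sample.int(length(lab))] else lab
    ia <- resample(which(lab_i == regionA), n_eq)
    ib <- resample(which(lab_i == regionB), n_eq)
    ha <- sample.int(n_eq) <= n_eq / 2
    hb <- sample.int(n_eq) <= n_eq / 2
    fa <- fit_psych(tr[ia[ha], ], ic, n_starts = 2)
    fb <- fit_psych(tr[ib[hb], ], ic, n_starts = 2)
    ll <- function(fit, rows) {
      cells <- aggregate_cells(tr[rows, ])
      test_log_lik(fit, cells) / sum(cells$nR + cells$nL)
    }
    within <- (ll(fa, ia[!ha]) + ll(fb, ib[!hb])) / 2
    inter <- (ll(fa, ib[!hb]) + ll(fb, ia[!ha])) / 2
    within - inter
  }
  obs <- mean(vapply(seq_len(n_subsample), function(i) stat_once(FALSE),
                     numeric(1)))
  null <- vapply(seq_len(n_shuffle), function(i) stat_once(TRUE), numeric(1))
  structure(
    list(observed = obs, null = null, p = rank_p_two_sided(obs, null),
         regionA = regionA, regionB = regionB),
    class = "shuffle_result"
  )
}

#' Pulsed-inactivation timing analysis
#'
#' For brief laser pulses delivered at varying times around stimulus onset,
#' computes the change in the fraction of rightward choices as a function of
#' pulse time, in a sliding boxcar window over laser onsets, with a Fisher's
#' exact test per window against control (no-laser) trials. Sessions with
#' fewer than `min_laser_trials` laser trials are excluded. A window is
#' flagged significant when it, or both of its neighbors, passes the
#' significance criterion; windows containing no laser trials get `NA` and
#' are never flagged.
#'
#' @param trials Trial tibble with `laser_onset_s` for laser trials.
#' @param window Boxcar width (s).
#' @param step Window-center step (s).
#' @param alpha Per-window significance criterion.
#' @param min_laser_trials Per-session inclusion threshold.
#' @return A `pulse_timing_result`: tibble with `center_s`, `n_laser`,
#'   `delta_frac_right`, `p`, `significant`.
#' @export
pulse_timing_analysis <- function(trials, window = 0.070, step = 0.010,
                                  alpha = 0.001, min_laser_trials = 75) {
  tr <- dplyr::filter(trials, .data$choice %in% c("L", "R"))
  sess_n <- tr |>
    dplyr::filter(.data$laser_on) |>
    dplyr::count(.data$session_id)
  keep_sess <- sess_n$session_id[sess_n$n >= min_laser_trials]
  tr <- dplyr::filter(tr, .data$session_id %in% keep_sess)
  if (!nrow(tr)) abort("no sessions pass the laser-trial threshold")
  las <- dplyr::filter(tr, .data$laser_on, !is.na(.data$laser_onset_s))
  ctl <- dplyr::filter(tr, !.data$laser_on)
  cr <- sum(ctl$choice == "R"); cl <- sum(ctl$choice == "L")
  centers <- seq(min(las$laser_onset_s), max(las$laser_onset_s), by = step)
  res <- purrr::map_dfr(centers, function(cen) {
    in_w <- abs(las$laser_onset_s - cen) <= window / 2 + 1e-12
    nr <- sum(las$choice[in_w] == "R"); nl <- sum(las$choice[in_w] == "L")
    if (nr + nl == 0) {
      return(tibble::tibble(center_s = cen, n_laser = 0L,
                            delta_frac_right = NA_real_, p = NA_real_))
    }
    tibble::tibble(
      center_s = cen, n_laser = nr + nl,
      delta_frac_right = nr / (nr + nl) - cr / (cr + cl),
      p = fisher_exact_2x2(nr, nl, cr, cl)
    )
  })
  sig <- !is.na(res$p) & res$p < alpha
  nb_prev <- c(FALSE, sig[-nrow(res)])
  nb_next <- c(sig[-1], FALSE)
  res$significant <- !is.na(res$p) & (sig | (nb_prev & nb_next))
  structure(list(windows = res, window = window, alpha = alpha),
            class = "pulse_timing_result")
}

#' @export
print.pulse_timing_result <- function(x, ...) {
  cat("<pulse_timing_result>", nrow(x$windows), "windows of",
      x$window * 1000, "ms;", sum(x$windows$significant), "significant\n")
  invisible(x)
}
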