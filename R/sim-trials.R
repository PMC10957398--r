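# --- synthetic behavioral datasets -----------------------------------------

#' Additive psychometric parameters
#'
#' Convenience constructor for the 6 parameters of the additive parametric
#' model: bias `b` (log odds), contrast exponent `gamma` (> 0), visual
#' sensitivities `vR`, `vL` (log odds per unit contrast^gamma), and auditory
#' sensitivities `aR`, `aL` (log odds). Defaults are in the range typical of
#' well-trained mice on this task.
#'
#' @param b,gamma,vR,vL,aR,aL Parameter values.
#' @return Named numeric vector.
#' @export
additive_params <- function(b = 0, gamma = 0.6, vR = 3, vL = 3,
                            aR = 2, aL = 2) {
  if (gamma <= 0) abort("gamma must be positive")
  c(b = b, gamma = gamma, vR = vR, vL = vL, aR = aR, aL = aL)
}

#' Configuration for a synthetic behavioral session
#'
#' Describes the stimulus design and generative choice/reaction-time model of
#' a synthetic session. Trial types are drawn with probabilities proportional
#' to `type_ratio`, whose default 10/10/5/5/1 (unisensory visual / unisensory
#' auditory / coherent / conflict / neutral) matches the task design. The
#' reaction-time model is generative plumbing: RT = base latency minus an
#' auditory advantage on auditory-containing trials, minus a contrast-
#' dependent speedup, plus Gaussian jitter, truncated positive.
#'
#' @param true_params Generative [additive_params()].
#' @param contrast_set Nonzero visual contrast fractions.
#' @param azimuth_set Auditory azimuths in degrees (must include 0).
#' @param type_ratio Five nonnegative weights over trial types, in the order
#'   unisensory visual, unisensory auditory, coherent, conflict, neutral.
#' @param n_trials Number of trials.
#' @param rt_model List with `base` (s), `aud_advantage` (s), `contrast_slope`
#'   (s per unit max contrast; negative = faster at high contrast) and
#'   `jitter_sd` (s).
#' @param n_sessions,n_subjects Number of session/subject labels to spread
#'   trials over (round-robin blocks).
#' @param seed Seed stored in the config; generators use it by default.
#' @return A `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(true_params = additive_params(),
                                contrast_set = c(0.1, 0.2, 0.4, 0.8),
                                azimuth_set = c(-60, 0, 60),
                                type_ratio = c(10, 10, 5, 5, 1),
                                n_trials = 1000,
                                rt_model = list(base = 0.25,
                                                aud_advantage = 0.022,
                                                contrast_slope = -0.05,
                                                jitter_sd = 0.04),
                                n_sessions = 1, n_subjects = 1,
                                seed = NULL) {
  if (!length(contrast_set)) abort("contrast_set must be non-empty")
  if (length(type_ratio) != 5 || any(type_ratio < 0) || sum(type_ratio) <= 0) {
    abort("type_ratio must be 5 nonnegative weights with positive sum")
  }
  if (rt_model$base <= 0 || rt_model$jitter_sd < 0) {
    abort("rt_model latencies must be positive")
  }
  structure(
    list(true_params = true_params, contrast_set = sort(contrast_set),
         azimuth_set = sort(azimuth_set), type_ratio = type_ratio,
         n_trials = n_trials, rt_model = rt_model,
         n_sessions = n_sessions, n_subjects = n_subjects, seed = seed),
    class = "behavior_sim_config"
  )
}

#' Generate a trial schedule (stimuli only, no choices)
#'
#' Draws `n_trials` stimulus conditions: the trial type from `type_ratio`,
#' contrasts uniformly from the contrast set, and stimulus sides at random.
#' Session and subject labels are assigned in contiguous blocks.
#'
#' @param cfg A [behavior_sim_config()].
#' @param seed Overrides `cfg$seed`.
#' @return Trial tibble with stimulus columns, `trial_type`, empty `choice`,
#'   and laser columns set to "off".
#' @export
gen_trial_schedule <- function(cfg, seed = cfg$seed) {
  stopifnot(cfg$n_trials >= 1)
  local_seed(seed)
  n <- cfg$n_trials
  type <- sample(trial_types, n, replace = TRUE,
                 prob = cfg$type_ratio / sum(cfg$type_ratio))
  contrast <- resample(cfg$contrast_set, n, replace = TRUE)
  vside <- sample(c(-1, 1), n, replace = TRUE)
  aside <- sample(c(-1, 1), n, replace = TRUE)
  az_mag <- resample(setdiff(abs(cfg$azimuth_set), 0), n, replace = TRUE)
  vis_L <- ifelse(type %in% c("unisensory_visual", "coherent", "conflict") &
                    vside < 0, contrast, 0)
  vis_R <- ifelse(type %in% c("unisensory_visual", "coherent", "conflict") &
                    vside > 0, contrast, 0)
  aud <- dplyr::case_when(
    type == "unisensory_auditory" ~ aside * az_mag,
    type == "coherent" ~ vside * az_mag,
    type == "conflict" ~ -vside * az_mag,
    TRUE ~ 0
  )
  sess <- rep(seq_len(cfg$n_sessions), each = ceiling(n / cfg$n_sessions))[1:n]
  subj <- rep(seq_len(cfg$n_subjects), each = ceiling(n / cfg$n_subjects))[1:n]
  tibble::tibble(
    trial_id = seq_len(n),
    session_id = paste0("s", sess),
    subject_id = paste0("m", subj),
    vis_contrast_L = vis_L, vis_contrast_R = vis_R,
    aud_azimuth_deg = aud,
    choice = NA_character_, rt_s = NA_real_,
    timeout = FALSE, repeat_flag = FALSE,
    laser_on = FALSE, laser_ap_mm = NA_real_, laser_ml_mm = NA_real_,
    laser_onset_s = NA_real_
  ) |>
    classify_trials()
}

#' Simulate choices under a psychometric model
#'
#' Draws each trial's choice as Bernoulli with rightward probability
#' `sigma(log odds)` under the given parameters (additive model by default;
#' pass `model` for other families). Sides are coded rightward = positive.
#'
#' @param trials Trial schedule tibble.
#' @param params Named parameter vector (e.g. [additive_params()]).
#' @param seed RNG seed.
#' @param model A [psych_model()]; defaults to the additive family over the
#'   contrasts/azimuths present in `trials`.
#' @return `trials` with `choice` filled in (`"R"`/`"L"`).
#' @export
simulate_choices <- function(trials, params, seed = NULL, model = NULL) {
  params <- unlist(params)
  if ("gamma" %in% names(params) && params[["gamma"]] <= 0) {
    abort("gamma must be positive")
  }
  model <- model %||% psych_model(
    "additive",
    contrast_set = setdiff(unique(c(trials$vis_contrast_L,
                                    trials$vis_contrast_R)), 0),
    azimuth_set = unique(trials$aud_azimuth_deg)
  )
  local_seed(seed)
  p_right <- logistic(log_odds(model, trials, params = params))
  dplyr::mutate(trials,
                choice = ifelse(stats::runif(dplyr::n()) < p_right, "R", "L"),
                timeout = FALSE)
}

#' Simulate reaction times from the generative RT model
#'
#' @param trials Trial tibble with `trial_type` and contrasts.
#' @param rt_model RT model list (see [behavior_sim_config()]).
#' @param seed RNG seed.
#' @return `trials` with `rt_s` filled for non-timeout trials.
#' @export
simulate_rts <- function(trials, rt_model, seed = NULL) {
  local_seed(seed)
  has_aud <- trials$aud_azimuth_deg != 0
  cmax <- pmax(trials$vis_contrast_L, trials$vis_contrast_R)
  mu <- rt_model$base - rt_model$aud_advantage * has_aud +
    rt_model$contrast_slope * cmax
  rt <- mu + stats::rnorm(nrow(trials), 0, rt_model$jitter_sd)
  rt <- pmax(rt, 0.02)  # truncate > 0
  dplyr::mutate(trials, rt_s = ifelse(.data$timeout | is.na(.data$choice),
                                      NA_real_, rt))
}

#' Simulate a complete behavioral dataset
#'
#' Chains [gen_trial_schedule()], [simulate_choices()] and [simulate_rts()].
#'
#' @param cfg A [behavior_sim_config()].
#' @param seed Overrides `cfg$seed`.
#' @return Trial tibble with choices and reaction times.
#' @export
sim_behavior_dataset <- function(cfg, seed = cfg$seed) {
  local_seed(seed)
  gen_trial_schedule(cfg, seed = NULL) |>
    simulate_choices(cfg$true_params, seed = NULL) |>
    simulate_rts(cfg$rt_model, seed = NULL)
}

# --- inactivation datasets -------------------------------------------------

#' Laser site grid for scanning inactivation
#'
#' Builds the table of stereotaxic laser target sites. The default is a
#' synthetic full product grid of the task's AP positions (0, +/-1, +/-2,
#' +/-3, -4 mm) and ML positions (+/-0.6, +/-1.8, +/-3.0, +/-4.2 mm) — 64
#' sites; experimental grids drop some combinations, so supply your own
#' `ap_mm`/`ml_mm` vectors to reproduce a particular layout. Sites are
#' assigned to named regions by their (AP, |ML|) coordinates: visual
#' (-4, 1.8), (-4, 3), (-3, 3); frontal (2, 0.6), (2, 1.8), (3, 0.6);
#' lateral (-4, 4.2), (-2, 4.2); somatosensory (1, 3), (0, 3), (0, 4.2).
#'
#' @param ap_mm,ml_mm Site coordinates; defaults give the synthetic full
#'   grid (all AP x ML combinations).
#' @param regions Named list mapping region name to a 2-column matrix of
#'   (AP, |ML|) coordinates.
#' @return Tibble with `ap_mm`, `ml_mm`, `hemisphere`, `region`.
#' @export
laser_site_grid <- function(ap_mm = NULL, ml_mm = NULL,
                            regions = default_regions()) {
  if (is.null(ap_mm) || is.null(ml_mm)) {
    g <- expand.grid(ap_mm = c(-4, -3, -2, -1, 0, 1, 2, 3),
                     ml_mm = c(-4.2, -3, -1.8, -0.6, 0.6, 1.8, 3, 4.2))
    ap_mm <- g$ap_mm; ml_mm <- g$ml_mm
  }
  sites <- tibble::tibble(ap_mm = ap_mm, ml_mm = ml_mm) |>
    dplyr::mutate(hemisphere = ifelse(ml_mm < 0, "left", "right"),
                  region = "none")
  for (rn in names(regions)) {
    coords <- regions[[rn]]
    for (i in seq_len(nrow(coords))) {
      hit <- sites$ap_mm == coords[i, 1] & abs(sites$ml_mm) == coords[i, 2]
      if (any(sites$region[hit] != "none")) {
        abort("a site may belong to at most one region")
      }
      sites$region[hit] <- rn
    }
  }
  sites
}

default_regions <- function() {
  list(
    visual = rbind(c(-4, 1.8), c(-4, 3), c(-3, 3)),
    frontal = rbind(c(2, 0.6), c(2, 1.8), c(3, 0.6)),
    lateral = rbind(c(-4, 4.2), c(-2, 4.2)),
    somatosensory = rbind(c(1, 3), c(0, 3), c(0, 4.2))
  )
}

#' Configuration for a synthetic inactivation experiment
#'
#' @param site_grid Laser site tibble from [laser_site_grid()].
#' @param laser_fraction Probability that a trial is an inactivation trial
#'   (default 0.75, as in the scanning design).
#' @param region_effects Named list mapping region name to additive deltas on
#'   the ipsi/contra parameters, e.g.
#'   `list(visual = c(vc = -2), frontal = c(vc = -1, ac = -1, b = 0.5))`.
#'   Delta names are among `b`, `vi`, `vc`, `ai`, `ac`.
#' @param seed RNG seed.
#' @return An `inactivation_sim_config` list.
#' @export
inactivation_sim_config <- function(site_grid = laser_site_grid(),
                                    laser_fraction = 0.75,
                                    region_effects = list(),
                                    seed = NULL) {
  if (laser_fraction < 0 || laser_fraction > 1) {
    abort("laser_fraction must be in [0, 1]")
  }
  unknown <- setdiff(names(region_effects), unique(site_grid$region))
  if (length(unknown)) {
    abort(paste("region_effects references unknown region(s):",
                paste(unknown, collapse = ", ")))
  }
  structure(list(site_grid = site_grid, laser_fraction = laser_fraction,
                 region_effects = region_effects, seed = seed),
            class = "inactivation_sim_config")
}

#' Generate a synthetic inactivation dataset
#'
#' Simulates a scanning-inactivation session: each trial is a laser trial
#' with probability `laser_fraction`, targeting a uniformly drawn site from
#' the grid. Choices on non-laser trials follow the base additive parameters;
#' choices on laser trials follow ipsi/contra-reparameterized parameters
#' shifted by the configured region effect (sites in unnamed regions get no
#' shift). "Ipsi" is defined per trial by the hemisphere of the targeted
#' site.
#'
#' @param base_params Base [additive_params()].
#' @param cfg An [inactivation_sim_config()].
#' @param n_trials Number of trials.
#' @param behavior_cfg Optional [behavior_sim_config()] for the stimulus
#'   design (its `true_params` are ignored in favor of `base_params`).
#' @param seed RNG seed.
#' @return Trial tibble with laser columns and choices.
#' @export
gen_inactivation_dataset <- function(base_params, cfg, n_trials = 10000,
                                     behavior_cfg = NULL, seed = cfg$seed) {
  local_seed(seed)
  bcfg <- behavior_cfg %||% behavior_sim_config(n_trials = n_trials)
  bcfg$n_trials <- n_trials
  trials <- gen_trial_schedule(bcfg, seed = NULL)
  n <- nrow(trials)
  laser <- stats::runif(n) < cfg$laser_fraction
  site_ix <- sample.int(nrow(cfg$site_grid), n, replace = TRUE)
  trials$laser_on <- laser
  trials$laser_ap_mm <- ifelse(laser, cfg$site_grid$ap_mm[site_ix], NA_real_)
  trials$laser_ml_mm <- ifelse(laser, cfg$site_grid$ml_mm[site_ix], NA_real_)
  trials$laser_onset_s <- ifelse(laser, 0, NA_real_)
  region <- ifelse(laser, cfg$site_grid$region[site_ix], NA_character_)
  hemi_right <- ifelse(laser, cfg$site_grid$ml_mm[site_ix] >= 0, NA)

  bp <- unlist(base_params)
  # rightward log odds per trial, with laser trials evaluated in the
  # ipsi/contra frame of their site's hemisphere
  eta <- log_odds(psych_model("additive",
                              contrast_set = bcfg$contrast_set,
                              azimuth_set = bcfg$azimuth_set),
                  trials, params = bp)
  ic_model <- psych_model("ipsi_contra", contrast_set = bcfg$contrast_set,
                          azimuth_set = bcfg$azimuth_set)
  for (rn in names(cfg$region_effects)) {
    d <- cfg$region_effects[[rn]]
    dd <- function(nm) if (nm %in% names(d)) d[[nm]] else 0
    for (right_hemi in c(TRUE, FALSE)) {
      idx <- which(laser & region == rn & hemi_right == right_hemi)
      if (!length(idx)) next
      # map base L/R params into the ipsi/contra frame of this hemisphere
      ic <- if (right_hemi) {
        c(b = unname(bp["b"]), gamma = unname(bp["gamma"]),
          vi = unname(bp["vR"]), vc = unname(bp["vL"]),
          ai = unname(bp["aR"]), ac = unname(bp["aL"]))
      } else {
        c(b = unname(bp["b"]), gamma = unname(bp["gamma"]),
          vi = unname(bp["vL"]), vc = unname(bp["vR"]),
          ai = unname(bp["aL"]), ac = unname(bp["aR"]))
      }
      ic[c("b", "vi", "vc", "ai", "ac")] <-
        ic[c("b", "vi", "vc", "ai", "ac")] +
        c(dd("b"), dd("vi"), dd("vc"), dd("ai"), dd("ac"))
      cond <- trials[idx, ]
      if (!right_hemi) cond <- mirror_trials(cond, rep(TRUE, nrow(cond)))
      eta_ic <- log_odds(ic_model, cond, params = ic)
      # eta_ic is the log odds of an ipsilateral choice
      eta[idx] <- if (right_hemi) eta_ic else -eta_ic
    }
  }
  p_right <- logistic(eta)
  trials$choice <- ifelse(stats::runif(n) < p_right, "R", "L")
  trials <- simulate_rts(trials, bcfg$rt_model, seed = NULL)
  trials$laser_region <- region
  trials
}
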