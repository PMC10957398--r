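#' Psychometric model specifications for audiovisual choice
#'
#' Constructs a member of the psychometric model family used to describe
#' two-alternative audiovisual localization choices. All families model the
#' log odds of a rightward choice; the workhorse is the additive parametric
#' model
#' \deqn{\log \frac{p(R)}{p(L)} = b + v_R V_R^\gamma - v_L V_L^\gamma +
#'   a_R A_R - a_L A_L,}
#' where \eqn{V_R, V_L} are the right/left visual contrasts, \eqn{A_R, A_L}
#' are indicators of right/left auditory stimuli, \eqn{b} is a bias, and
#' \eqn{\gamma} a contrast exponent capturing visual saturation. The additive
#' form is the optimal combination rule when the visual and auditory noise
#' are conditionally independent given the stimulus side.
#'
#' Available families:
#' \describe{
#'   \item{`bias_only`}{log odds equal to `b` everywhere (1 parameter).}
#'   \item{`visual_only`}{`b` plus the visual power-law term (4 parameters).}
#'   \item{`auditory_only`}{`b` plus the auditory term (3 parameters).}
#'   \item{`auditory_dominance`}{additive, but the visual term is zeroed on
#'     conflict trials; with `free_acon = TRUE` the auditory weight on
#'     conflict trials is additionally scaled by a free `1 - acon` factor.}
#'   \item{`sensory_bias`}{additive plus multiplicative deflators
#'     `1 - vcon`, `1 - vcoh` (visual) and `1 - acon`, `1 - acoh` (auditory)
#'     on conflict/coherent trials (10 parameters).}
#'   \item{`additive`}{the 6-parameter additive parametric model above.}
#'   \item{`additive_unconstrained`}{`b` plus one free weight per nonzero
#'     signed contrast level and per lateral auditory location — any function
#'     of contrast (11 parameters for a 4-level contrast set).}
#'   \item{`full`}{one weight per (visual condition x auditory condition)
#'     cell, with no additivity constraint (27 parameters for 4 contrast
#'     levels and 3 azimuths).}
#'   \item{`additive_5azimuth`}{additive with a distinct weight per nonzero
#'     azimuth for the extended 5-speaker design (8 parameters).}
#'   \item{`ipsi_contra`}{the additive model reparameterized relative to an
#'     inactivated hemisphere: `b + vi*Vi^gamma - vc*Vc^gamma + ai*Ai -
#'     ac*Ac`, fit to data mirrored so that "ipsilateral" plays the role of
#'     rightward (see [mirror_to_ipsi()]).}
#' }
#'
#' @param family Family name (see Details).
#' @param contrast_set Nonzero visual contrast fractions of the stimulus
#'   design (used to lay out parameters of the unconstrained and full models).
#' @param azimuth_set Auditory azimuths (degrees) of the design.
#' @param fixed Named list of parameters to freeze at given values (e.g.
#'   `list(gamma = 0.6)` when refitting inactivation trials).
#' @param free_acon For `auditory_dominance`: free the conflict-trial
#'   auditory weight instead of fixing it at zero.
#' @return An object of class `psych_model`.
#' @examples
#' m <- psych_model("additive")
#' n_params(m)
#' @export
psych_model <- function(family = c("additive", "bias_only", "visual_only",
                                   "auditory_only", "auditory_dominance",
                                   "sensory_bias", "additive_unconstrained",
                                   "full", "additive_5azimuth", "ipsi_contra"),
                        contrast_set = c(0.1, 0.2, 0.4, 0.8),
                        azimuth_set = c(-60, 0, 60),
                        fixed = list(),
                        free_acon = FALSE) {
  family <- match.arg(family)
  contrast_set <- sort(unique(contrast_set[contrast_set > 0]))
  azimuth_set <- sort(unique(azimuth_set))
  if (family == "additive_5azimuth" &&
      !all(c(-60, -30, 30, 60) %in% azimuth_set)) {
    abort("additive_5azimuth requires azimuths at +/-30 and +/-60 degrees")
  }
  m <- structure(
    list(family = family, contrast_set = contrast_set,
         azimuth_set = azimuth_set, fixed = fixed, free_acon = free_acon),
    class = "psych_model"
  )
  bad <- setdiff(names(fixed), param_names(m))
  if (length(bad)) abort(paste("unknown fixed parameter(s):",
                               paste(bad, collapse = ", ")))
  m
}

#' @export
print.psych_model <- function(x, ...) {
  cat("<psych_model> family:", x$family, "|", n_params(x), "parameters\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

vis_cond_labels <- function(contrast_set) {
  c(paste0("L", rev(contrast_set)), "0", paste0("R", contrast_set))
}

aud_cond_labels <- function(azimuth_set) paste0("A", azimuth_set)

#' Parameter names of a psychometric model
#'
#' @param model A [psych_model()].
#' @return Character vector of parameter names (fixed parameters included).
#' @export
param_names <- function(model) {
  cs <- model$contrast_set
  switch(model$family,
    bias_only = "b",
    visual_only = c("b", "gamma", "vR", "vL"),
    auditory_only = c("b", "aR", "aL"),
    additive = c("b", "gamma", "vR", "vL", "aR", "aL"),
    auditory_dominance = c("b", "gamma", "vR", "vL", "aR", "aL",
                           if (model$free_acon) "acon"),
    sensory_bias = c("b", "gamma", "vR", "vL", "aR", "aL",
                     "vcon", "vcoh", "acon", "acoh"),
    additive_unconstrained = c(
      "b",
      paste0("v_", c(paste0("L", cs), paste0("R", cs))),
      "a_L", "a_R"
    ),
    full = as.vector(outer(vis_cond_labels(cs), aud_cond_labels(model$azimuth_set),
                           function(v, a) paste0("w_", v, "_", a))),
    additive_5azimuth = c("b", "gamma", "vR", "vL",
                          "aR60", "aR30", "aL60", "aL30"),
    ipsi_contra = c("b", "gamma", "vi", "vc", "ai", "ac")
  )
}

#' @rdname param_names
#' @export
n_params <- function(model) length(param_names(model))

# label of the (visual x auditory) cell a condition falls in
full_cell_label <- function(cond) {
  v <- ifelse(cond$vis_contrast_R > 0, paste0("R", cond$vis_contrast_R),
              ifelse(cond$vis_contrast_L > 0, paste0("L", cond$vis_contrast_L),
                     "0"))
  paste0("w_", v, "_A", cond$aud_azimuth_deg)
}

check_design <- function(model, cond) {
  if (!all(cond$aud_azimuth_deg %in% model$azimuth_set)) {
    abort("condition outside design: unknown auditory azimuth")
  }
}

#' Evaluate model log odds for stimulus conditions
#'
#' Computes the log odds of a rightward choice under a psychometric model for
#' each row of a condition table. For the `ipsi_contra` family, "rightward"
#' means ipsilateral to the inactivated hemisphere and `conditions` must be in
#' the mirrored frame produced by [mirror_to_ipsi()].
#'
#' @param model A [psych_model()], or a fitted [fit_psych()] object (in which
#'   case `params` defaults to its estimates).
#' @param conditions Tibble with columns `vis_contrast_L`, `vis_contrast_R`,
#'   `aud_azimuth_deg` (one row per condition or trial).
#' @param params Named vector/list of parameter values covering
#'   [param_names()] (fixed parameters may be omitted).
#' @param fallback Log-odds value used for `full`-model cells that have no
#'   fitted weight (cells unobserved during training); default 0.
#' @return Numeric vector of log odds, one per row of `conditions`.
#' @export
log_odds <- function(model, conditions, params = NULL, fallback = 0) {
  if (inherits(model, "psychfit")) {
    params <- params %||% model$estimates
    fallback <- model$fallback_log_odds %||% fallback
    model <- model$model
  }
  stopifnot(inherits(model, "psych_model"))
  prep <- prep_conditions(model, conditions)
  eval_log_odds(model, prep, unlist(params), fallback = fallback)
}

# precompute the design features once so repeated evaluation (inside the
# optimizer) is pure vector arithmetic
prep_conditions <- function(model, conditions) {
  cond <- classify_trials(conditions)
  check_design(model, cond)
  list(
    n = nrow(cond),
    VR = cond$vis_contrast_R, VL = cond$vis_contrast_L,
    AR = cond$AR, AL = cond$AL,
    az = cond$aud_azimuth_deg,
    Tcon = as.numeric(cond$trial_type == "conflict"),
    Tcoh = as.numeric(cond$trial_type == "coherent"),
    v_label_R = paste0("v_R", cond$vis_contrast_R),
    v_label_L = paste0("v_L", cond$vis_contrast_L),
    full_label = full_cell_label(cond)
  )
}

eval_log_odds <- function(model, prep, params, fallback = 0) {
  missing_par <- setdiff(param_names(model),
                         c(names(params), names(model$fixed)))
  if (model$family != "full" && length(missing_par)) {
    abort(paste("missing parameter(s):", paste(missing_par, collapse = ", ")))
  }
  fx <- unlist(model$fixed)
  params[names(fx)] <- fx
  p <- function(nm) unname(params[nm])
  VR <- prep$VR; VL <- prep$VL; AR <- prep$AR; AL <- prep$AL
  Tcon <- prep$Tcon; Tcoh <- prep$Tcoh
  switch(model$family,
    bias_only = rep(p("b"), prep$n),
    visual_only = p("b") + p("vR") * VR^p("gamma") - p("vL") * VL^p("gamma"),
    auditory_only = p("b") + p("aR") * AR - p("aL") * AL,
    additive = p("b") + p("vR") * VR^p("gamma") - p("vL") * VL^p("gamma") +
      p("aR") * AR - p("aL") * AL,
    auditory_dominance = {
      acon <- if (model$free_acon) p("acon") else 0
      p("b") + (1 - Tcon) * (p("vR") * VR^p("gamma") - p("vL") * VL^p("gamma")) +
        (1 - acon * Tcon) * (p("aR") * AR - p("aL") * AL)
    },
    sensory_bias = p("b") +
      (1 - p("vcon") * Tcon) * (1 - p("vcoh") * Tcoh) *
        (p("vR") * VR^p("gamma") - p("vL") * VL^p("gamma")) +
      (1 - p("acon") * Tcon) * (1 - p("acoh") * Tcoh) *
        (p("aR") * AR - p("aL") * AL),
    additive_unconstrained = {
      vterm <- rep(0, prep$n)
      nz_r <- VR > 0; nz_l <- VL > 0
      vterm[nz_r] <- params[prep$v_label_R[nz_r]]
      vterm[nz_l] <- params[prep$v_label_L[nz_l]]
      p("b") + vterm + p("a_R") * AR + p("a_L") * AL
    },
    full = {
      out <- unname(params[prep$full_label])
      out[is.na(out)] <- fallback
      out
    },
    additive_5azimuth = {
      az <- prep$az
      p("b") + p("vR") * VR^p("gamma") - p("vL") * VL^p("gamma") +
        p("aR60") * (az == 60) + p("aR30") * (az == 30) -
        p("aL60") * (az == -60) - p("aL30") * (az == -30)
    },
    ipsi_contra = p("b") + p("vi") * VR^p("gamma") - p("vc") * VL^p("gamma") +
      p("ai") * AR - p("ac") * AL
  )
}

#' Mirror inactivation trials into the ipsi/contra frame
#'
#' Reflects trials whose laser site is in the left hemisphere (negative ML)
#' so that the inactivated hemisphere is always on the right. In the returned
#' table, right visual/auditory stimuli and rightward choices are ipsilateral
#' to the inactivation. Non-laser trials are passed through unchanged unless
#' `reference_hemisphere` is given.
#'
#' @param trials Trial tibble with `laser_ml_mm` (and optionally `choice`).
#' @param reference_hemisphere Optional `"left"`/`"right"` to mirror all
#'   trials relative to a fixed hemisphere instead of each trial's own site.
#' @return The mirrored trial tibble.
#' @export
mirror_to_ipsi <- function(trials, reference_hemisphere = NULL) {
  flip <- if (is.null(reference_hemisphere)) {
    !is.na(trials$laser_ml_mm) & trials$laser_ml_mm < 0
  } else {
    rep(identical(reference_hemisphere, "left"), nrow(trials))
  }
  mirror_trials(trials, flip)
}

# reflect the given trials left<->right (stimuli, choices, laser ML)
mirror_trials <- function(trials, flip) {
  out <- trials
  vl <- out$vis_contrast_L[flip]
  out$vis_contrast_L[flip] <- out$vis_contrast_R[flip]
  out$vis_contrast_R[flip] <- vl
  out$aud_azimuth_deg[flip] <- -out$aud_azimuth_deg[flip]
  if ("choice" %in% names(out)) {
    ch <- out$choice[flip]
    out$choice[flip] <- ifelse(ch == "R", "L", ifelse(ch == "L", "R", ch))
  }
  if ("laser_ml_mm" %in% names(out)) {
    out$laser_ml_mm[flip] <- -out$laser_ml_mm[flip]
  }
  if ("trial_type" %in% names(out)) out <- classify_trials(out)
  out
}
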