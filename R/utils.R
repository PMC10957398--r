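#' @importFrom rlang .data abort warn inform %||% :=
#' @importFrom stats plogis rbinom rpois rnorm runif median sd var optim
#'   dhyper quantile wilcox.test setNames complete.cases
#' @importFrom utils head tail
NULL

# sequential column references inside tibble() calls
utils::globalVariables("hemisphere")

# seed handling: all stochastic entry points take `seed`; NULL leaves the RNG
# stream untouched so callers can manage reproducibility themselves.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}

logistic <- function(x) stats::plogis(x)

# sample() that never treats a length-1 numeric x as 1:x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Derive stimulus indicator variables and the trial type
#'
#' Adds the binary auditory-side indicators and classifies each trial as
#' unisensory visual, unisensory auditory, multisensory coherent, multisensory
#' conflict, or neutral. The type is a pure function of the contrasts and the
#' auditory azimuth: a trial is coherent when the auditory and visual stimuli
#' are on the same side, conflict when on opposite sides, and neutral when the
#' contrast is zero and the speaker is central.
#'
#' @param trials A trial tibble with columns `vis_contrast_L`, `vis_contrast_R`
#'   (contrast fractions in `[0, 1]`, at most one nonzero) and
#'   `aud_azimuth_deg` (degrees, rightward positive).
#' @return The input tibble with columns `AR`, `AL` (0/1 auditory side
#'   indicators) and `trial_type` added (or overwritten).
#' @export
classify_trials <- function(trials) {
  stopifnot(all(c("vis_contrast_L", "vis_contrast_R", "aud_azimuth_deg") %in%
                  names(trials)))
  if (any(trials$vis_contrast_L * trials$vis_contrast_R > 0)) {
    abort("at most one of vis_contrast_L / vis_contrast_R may be nonzero")
  }
  vs <- sign(trials$vis_contrast_R - trials$vis_contrast_L) # visual side
  as_ <- sign(trials$aud_azimuth_deg)
  type <- dplyr::case_when(
    vs != 0 & as_ == 0 ~ "unisensory_visual",
    vs == 0 & as_ != 0 ~ "unisensory_auditory",
    vs != 0 & as_ == vs ~ "coherent",
    vs != 0 & as_ == -vs ~ "conflict",
    TRUE ~ "neutral"
  )
  dplyr::mutate(trials,
    AR = as.integer(.data$aud_azimuth_deg > 0),
    AL = as.integer(.data$aud_azimuth_deg < 0),
    trial_type = type
  )
}

trial_types <- c("unisensory_visual", "unisensory_auditory",
                 "coherent", "conflict", "neutral")

# choice coded "R"/"L"/"timeout"; numeric code +1/-1 with timeout NA
choice_code <- function(choice) {
  ifelse(choice == "R", 1L, ifelse(choice == "L", -1L, NA_integer_))
}

# rank-based two-sided p for an observed statistic within a null sample;
# never exactly 0 by the (r + 1) / (n + 1) construction
rank_p_two_sided <- function(observed, null) {
  n <- length(null)
  p_hi <- (sum(null >= observed) + 1) / (n + 1)
  p_lo <- (sum(null <= observed) + 1) / (n + 1)
  min(1, 2 * min(p_hi, p_lo))
}
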