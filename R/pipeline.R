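# --- end-to-end reproducible pipeline --------------------------------------

#' Pipeline configuration
#'
#' Assembles every stage configuration and per-stage seed for
#' [run_pipeline()]. The `profile` chooses replication counts: `"full"`
#' uses full-scale replication (large shuffle counts; hours of compute),
#' `"ci"` uses reduced replication suitable for continuous testing.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param n_trials Behavioral trials to simulate.
#' @param n_neurons Neurons to simulate (0 skips the neural and
#'   accumulator stages).
#' @param profile `"ci"` or `"full"`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param behavior,neurons,inactivation Optional stage config overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("avchoice-run-"),
                            n_trials = 5000, n_neurons = 30,
                            profile = c("ci", "full"),
                            seed = 1,
                            behavior = NULL, neurons = NULL,
                            inactivation = NULL) {
  profile <- match.arg(profile)
  reps <- if (profile == "ci") {
    list(n_subsample = 100, n_shuffle_per = 5, cv_folds = 5,
         accum_epochs = 100, n_per_cond = 60, accum_shuffles = 20)
  } else {
    list(n_subsample = 25000, n_shuffle_per = 10, cv_folds = 5,
         accum_epochs = 300, n_per_cond = 360, accum_shuffles = 100)
  }
  seeds <- as.list(seed + seq_len(8) * 101)
  names(seeds) <- c("behavior", "wheel", "inactivation", "spikes",
                    "encoding", "decoding", "accumulator", "evaluation")
  structure(
    list(out_dir = out_dir, profile = profile, reps = reps, seeds = seeds,
         behavior = behavior %||% behavior_sim_config(n_trials = n_trials),
         neurons = neurons %||% neuron_sim_config(n_neurons = n_neurons),
         inactivation = inactivation %||% inactivation_sim_config(
           region_effects = list(visual = c(vc = -2),
                                 frontal = c(vc = -1.2, ac = -1.2, b = 0.6))),
         master_seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Chains synthetic generation, behavior extraction, psychometric fitting,
#' inactivation statistics, neural encoding/decoding, and the accumulator,
#' writing per-stage artifacts (CSV/JSON) and a manifest with seeds and
#' versions to `cfg$out_dir`. Deterministic given the configuration. Any
#' stage failure aborts with a stage-tagged message.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  res <- list()
  # --- behavior ------------------------------------------------------------
  res$trials <- stage("behavior", {
    tr <- sim_behavior_dataset(cfg$behavior, seed = cfg$seeds$behavior)
    tr <- filter_trials(tr)
    write_trials(tr, file.path(cfg$out_dir, "trials.csv"))
    tr
  })
  res$behavior_summary <- stage("behavior_summary", {
    s <- summarize_behavior(res$trials)
    readr::write_csv(s$by_type, file.path(cfg$out_dir, "behavior_by_type.csv"))
    readr::write_csv(s$by_condition,
                     file.path(cfg$out_dir, "behavior_by_condition.csv"))
    s
  })
  res$psych_fit <- stage("psychometrics", {
    fit <- cv_bits_per_trial(res$trials, psych_model("additive"),
                             k = cfg$reps$cv_folds,
                             seed = cfg$seeds$behavior + 1)
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates),
           cv_bits_per_trial = fit$cv$bits_per_trial,
           n_trials = fit$n_trials, seed = fit$cv$seed),
      file.path(cfg$out_dir, "psych_fit.json"), auto_unbox = TRUE, digits = NA)
    fit
  })
  # --- inactivation --------------------------------------------------------
  res$inactivation <- stage("inactivation", {
    tr <- gen_inactivation_dataset(cfg$behavior$true_params,
                                   cfg$inactivation,
                                   n_trials = cfg$behavior$n_trials,
                                   behavior_cfg = cfg$behavior,
                                   seed = cfg$seeds$inactivation)
    write_trials(tr, file.path(cfg$out_dir, "inactivation_trials.csv"))
    shift <- shuffle_test_choice_shift(
      tr, site = c(-4, 1.8), stimulus_type = "unisensory_visual",
      n_subsample = cfg$reps$n_subsample,
      n_shuffle_per = cfg$reps$n_shuffle_per,
      seed = cfg$seeds$inactivation + 1)
    readr::write_csv(tidy(shift),
                     file.path(cfg$out_dir, "choice_shift_visual_site.csv"))
    list(trials = tr, choice_shift = shift)
  })
  if (cfg$neurons$n_neurons == 0) {
    res$manifest <- write_manifest(cfg, res, skipped = c("encoding",
                                                         "decoding",
                                                         "accumulator"))
    return(invisible(res))
  }
  # --- encoding ------------------------------------------------------------
  res$encoding <- stage("encoding", {
    beh_cfg <- cfg$behavior
    beh_cfg$type_ratio <- c(0, 0, 1, 1, 0)   # audiovisual trials
    beh_cfg$contrast_set <- c(0.4, 0.8)
    beh_cfg$n_trials <- min(cfg$behavior$n_trials, 300)
    tr <- sim_behavior_dataset(beh_cfg, seed = cfg$seeds$spikes)
    spk <- gen_population_spikes(tr, cfg$neurons, seed = cfg$seeds$spikes + 1)
    rates <- estimate_rates(spk, bin = 0.01, t_range = c(-0.3, 0.8))
    des_add <- build_design(tr, rates$t, include_interaction = FALSE)
    des_full <- build_design(tr, rates$t, include_interaction = TRUE)
    fit_add <- fit_kernels(rates, des_add, seed = cfg$seeds$encoding)
    fit_full <- fit_kernels(rates, des_full, seed = cfg$seeds$encoding)
    readr::write_csv(fit_add$kernels,
                     file.path(cfg$out_dir, "kernels_additive.csv"))
    jsonlite::write_json(
      list(additive = fit_add$errors, full = fit_full$errors),
      file.path(cfg$out_dir, "kernel_errors.json"), digits = NA)
    list(trials = tr, spikes = spk, rates = rates,
         fit_additive = fit_add, fit_full = fit_full)
  })
  res$decoding <- stage("decoding", {
    tr <- res$encoding$trials
    rates <- res$encoding$rates
    lab <- sign(tr$aud_azimuth_deg)
    dec <- tryCatch(
      decode_population(rates, ifelse(lab == 0, NA, lab),
                        n_sub = min(30, cfg$neurons$n_neurons),
                        min_per_class = 10, seed = cfg$seeds$decoding),
      error = function(e) NULL)
    if (!is.null(dec)) {
      jsonlite::write_json(unclass(dec)[c("relative_accuracy",
                                          "raw_accuracy",
                                          "baseline_accuracy")],
                           file.path(cfg$out_dir, "decode_auditory.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    dec
  })
  # --- accumulator ---------------------------------------------------------
  res$accumulator <- stage("accumulator", {
    bank <- gen_psth_bank(cfg$neurons, seed = cfg$seeds$accumulator)
    write_psth_bank(bank, file.path(cfg$out_dir, "psth_bank.json"))
    pop <- make_surrogates(bank, n_per_cond = cfg$reps$n_per_cond,
                           seed = cfg$seeds$accumulator + 1)
    mdl <- train_accumulator(pop, epochs = cfg$reps$accum_epochs,
                             seed = cfg$seeds$accumulator + 2)
    oc <- run_accumulator(mdl, pop)
    ev <- evaluate_vs_behavior(oc[mdl$test_idx, ], bank$conditions,
                               res$psych_fit,
                               n_shuffle = cfg$reps$accum_shuffles,
                               seed = cfg$seeds$evaluation)
    readr::write_csv(oc, file.path(cfg$out_dir, "accumulator_outcomes.csv"))
    jsonlite::write_json(
      list(weights = mdl$w, boundaries = mdl$boundaries,
           mse = ev$mse, shuffle_p = ev$p),
      file.path(cfg$out_dir, "accumulator_model.json"),
      auto_unbox = TRUE, digits = NA)
    list(bank = bank, model = mdl, outcomes = oc, evaluation = ev)
  })
  res$manifest <- write_manifest(cfg, res)
  invisible(res)
}

write_manifest <- function(cfg, res, skipped = character(0)) {
  manifest <- list(
    package = "avchoice",
    version = as.character(utils::packageVersion("avchoice")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    profile = cfg$profile,
    master_seed = cfg$master_seed,
    seeds = cfg$seeds,
    stages_run = setdiff(c("behavior", "behavior_summary", "psychometrics",
                           "inactivation", "encoding", "decoding",
                           "accumulator"), skipped),
    stages_skipped = skipped,
    artifacts = list.files(cfg$out_dir)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
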