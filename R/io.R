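# --- serialization: trial tables, wheel traces, spikes, PSTH banks ---------

trial_csv_cols <- c("trial_id", "session_id", "subject_id", "vis_contrast_L",
                    "vis_contrast_R", "aud_azimuth_deg", "trial_type",
                    "choice", "rt_s", "timeout", "repeat_flag", "laser_on",
                    "laser_ap_mm", "laser_ml_mm", "laser_onset_s")

#' Read and write trial tables as CSV
#'
#' The on-disk schema is one row per trial with columns `trial_id`,
#' `session_id`, `subject_id`, `vis_contrast_L`, `vis_contrast_R`,
#' `aud_azimuth_deg`, `trial_type`, `choice`, `rt_s`, `timeout`,
#' `repeat_flag`, `laser_on`, `laser_ap_mm`, `laser_ml_mm`,
#' `laser_onset_s`. Extra columns are preserved.
#'
#' @param path File path.
#' @param trials Trial tibble.
#' @return `read_trials()` returns the trial tibble (indicator columns
#'   re-derived); `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("vis_contrast_L", "vis_contrast_R",
                            "aud_azimuth_deg"), names(tr))
  if (length(missing_cols)) {
    abort(paste("trial CSV lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  classify_trials(tr)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  front <- intersect(trial_csv_cols, names(trials))
  readr::write_csv(dplyr::relocate(trials, dplyr::all_of(front)), path)
  invisible(path)
}

#' Read and write wheel traces as CSV
#'
#' Long format: `trial_id`, `t_s`, `position_deg`.
#' @param path File path.
#' @param traces Trace tibble.
#' @export
read_wheel_traces <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(trial_id = readr::col_double()))
}

#' @rdname read_wheel_traces
#' @export
write_wheel_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read and write spike data as a pair of CSV files
#'
#' Spikes: `neuron_id`, `trial_id`, `spike_time_s`. Neuron metadata:
#' `neuron_id`, `hemisphere`, `ap_mm`, `ml_mm`, `depth_mm`, plus any
#' ground-truth columns.
#'
#' @param spike_path,neuron_path File paths.
#' @param x A `spike_data` object.
#' @export
read_spike_data <- function(spike_path, neuron_path) {
  structure(
    list(spikes = readr::read_csv(spike_path, show_col_types = FALSE),
         neurons = readr::read_csv(neuron_path, show_col_types = FALSE),
         trials = NULL, t_range = NULL, cfg = NULL),
    class = "spike_data"
  )
}

#' @rdname read_spike_data
#' @export
write_spike_data <- function(x, spike_path, neuron_path) {
  readr::write_csv(x$spikes, spike_path)
  readr::write_csv(x$neurons, neuron_path)
  invisible(spike_path)
}

#' Read and write a PSTH bank as JSON
#'
#' JSON layout: `t` (bin centers, s), `bin`, `regime`, `conditions` (the
#' condition table), `neurons` (metadata), and `rates` as a map
#' condition -> (neuron x time) rate matrix in Hz.
#'
#' @param path File path.
#' @param bank A `psth_bank`.
#' @export
read_psth_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conds <- tibble::as_tibble(obj$conditions)
  n_cond <- nrow(conds)
  r1 <- obj$rates[[conds$condition[1]]]
  rates <- array(0, c(nrow(r1), ncol(r1), n_cond),
                 dimnames = list(obj$neurons$neuron_id, NULL,
                                 conds$condition))
  for (cn in conds$condition) rates[, , cn] <- obj$rates[[cn]]
  structure(
    list(t = obj$t, conditions = classify_trials(conds), rates = rates,
         neurons = tibble::as_tibble(obj$neurons), bin = obj$bin,
         regime = obj$regime),
    class = "psth_bank"
  )
}

#' @rdname read_psth_bank
#' @export
write_psth_bank <- function(bank, path) {
  rates <- setNames(
    lapply(seq_len(dim(bank$rates)[3]), function(ci) bank$rates[, , ci]),
    dimnames(bank$rates)[[3]]
  )
  obj <- list(
    t = bank$t, bin = bank$bin, regime = bank$regime,
    conditions = dplyr::select(bank$conditions, -dplyr::any_of(c("AR", "AL"))),
    neurons = bank$neurons, rates = rates
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys become configuration entries.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
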