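# --- synthetic spiking populations -----------------------------------------

#' Configuration for a synthetic neural population
#'
#' Describes a population whose firing follows the temporal-kernel forward
#' model: on trial `i`, neuron rates are
#' `max(0, B(t) + a_i A(t) + v_i V(t) + a_i v_i N(t) + M(t - tau_i) +
#' c_i D(t - tau_i))`, where `a_i, v_i, c_i` are the signed auditory side,
#' visual side, and choice of the trial, and `tau_i` the movement onset.
#' Kernels are smooth bumps with per-neuron amplitudes; the visual
#' contribution scales with `(contrast / 0.8)^contrast_exponent` so that
#' weaker contrasts evoke weaker responses.
#'
#' The `trained` regime draws lateralized auditory and visual kernels for
#' the configured fractions of neurons. The `naive` regime zeroes the
#' lateralized kernels (A and V) — stimulus location is not encoded — while
#' keeping a non-lateralized onset response in the baseline kernel, emulating
#' a population before task learning.
#'
#' @param n_neurons Number of neurons.
#' @param baseline_rate_mean,baseline_rate_shape Gamma-distributed baseline
#'   rates (Hz).
#' @param amp Named list of mean absolute kernel peak amplitudes (Hz) for
#'   `A`, `V`, `N`, `M`, `D`, and the non-lateralized onset bump `onset`.
#' @param fraction_selective Named list: fraction of neurons with nonzero
#'   `aud` (A), `vis` (V), `move` (M), `dir` (D) kernels.
#' @param latency Named list of kernel onset latencies (s): auditory before
#'   visual by default (`aud = 0.03`, `vis = 0.075`).
#' @param kernel_width Bump duration (s).
#' @param contrast_exponent Saturating contrast-response exponent.
#' @param regime `"trained"` or `"naive"`.
#' @param seed RNG seed.
#' @return A `neuron_sim_config` list.
#' @export
neuron_sim_config <- function(n_neurons = 60,
                              baseline_rate_mean = 5,
                              baseline_rate_shape = 4,
                              amp = list(A = 6, V = 6, N = 0, M = 8, D = 5,
                                         onset = 3),
                              fraction_selective = list(aud = 0.6, vis = 0.6,
                                                        move = 0.7, dir = 0.5),
                              latency = list(aud = 0.030, vis = 0.075),
                              kernel_width = 0.20,
                              contrast_exponent = 0.6,
                              regime = c("trained", "naive"),
                              seed = NULL) {
  regime <- match.arg(regime)
  if (baseline_rate_mean < 0) abort("baseline rate must be nonnegative")
  structure(
    list(n_neurons = n_neurons, baseline_rate_mean = baseline_rate_mean,
         baseline_rate_shape = baseline_rate_shape, amp = amp,
         fraction_selective = fraction_selective, latency = latency,
         kernel_width = kernel_width, contrast_exponent = contrast_exponent,
         regime = regime, seed = seed),
    class = "neuron_sim_config"
  )
}

# half-sine bump of unit peak on lattice t, starting at `onset`
bump <- function(t, onset, width) {
  x <- (t - onset) / width
  ifelse(x > 0 & x < 1, sin(pi * x), 0)
}

# draw the per-neuron ground-truth kernel parameters
draw_neuron_kernels <- function(cfg) {
  n <- cfg$n_neurons
  sel <- function(frac) stats::runif(n) < frac
  amp_draw <- function(mean_amp) mean_amp * (0.5 + stats::runif(n))
  lat_jit <- function() stats::runif(n, -0.005, 0.005)
  naive <- cfg$regime == "naive"
  tibble::tibble(
    neuron_id = paste0("n", seq_len(n)),
    hemisphere = sample(c("left", "right"), n, replace = TRUE),
    baseline = stats::rgamma(n, shape = cfg$baseline_rate_shape,
                             rate = cfg$baseline_rate_shape /
                               cfg$baseline_rate_mean),
    amp_A = ifelse(sel(cfg$fraction_selective$aud) & !naive,
                   amp_draw(cfg$amp$A) * sample(c(-1, 1), n, TRUE), 0),
    amp_V = ifelse(sel(cfg$fraction_selective$vis) & !naive,
                   amp_draw(cfg$amp$V) * sample(c(-1, 1), n, TRUE), 0),
    amp_N = ifelse(cfg$amp$N > 0 & !naive,
                   amp_draw(cfg$amp$N) * sample(c(-1, 1), n, TRUE), 0),
    amp_M = ifelse(sel(cfg$fraction_selective$move), amp_draw(cfg$amp$M), 0),
    amp_D = ifelse(sel(cfg$fraction_selective$dir),
                   amp_draw(cfg$amp$D) * sample(c(-1, 1), n, TRUE), 0),
    amp_onset = amp_draw(cfg$amp$onset) * (if (naive) 0.5 else 1),
    lat_A = cfg$latency$aud + lat_jit(),
    lat_V = cfg$latency$vis + lat_jit(),
    ap_mm = stats::runif(n, 1.5, 3),
    ml_mm = ifelse(hemisphere == "right", 1, -1) * stats::runif(n, 0.3, 1.5),
    depth_mm = stats::runif(n, 0.2, 1.2)
  )
}

# expected rate matrix (trials x bins) for one neuron under the kernel model
neuron_rate_matrix <- function(nk, trials, t, cfg, movement = TRUE) {
  a_i <- sign(trials$aud_azimuth_deg)
  v_i <- sign(trials$vis_contrast_R - trials$vis_contrast_L)
  cmax <- pmax(trials$vis_contrast_L, trials$vis_contrast_R)
  cgain <- ifelse(cmax > 0, (cmax / 0.8)^cfg$contrast_exponent, 0)
  has_aud <- as.numeric(trials$aud_azimuth_deg != 0 |
                          trials$trial_type == "neutral")
  w <- cfg$kernel_width
  A_t <- bump(t, nk$lat_A, w)
  V_t <- bump(t, nk$lat_V, w)
  onset_t <- bump(t, min(nk$lat_A, nk$lat_V), w)
  n_tr <- nrow(trials)
  R <- matrix(nk$baseline, n_tr, length(t))
  R <- R + outer(has_aud + cgain, onset_t) * nk$amp_onset * 0.5
  R <- R + outer(a_i, A_t) * nk$amp_A
  R <- R + outer(v_i * cgain, V_t) * nk$amp_V
  N_t <- bump(t, nk$lat_V, w)
  R <- R + outer(a_i * v_i * cgain, N_t) * nk$amp_N
  if (movement && "rt_s" %in% names(trials)) {
    c_i <- choice_code(trials$choice)
    tau <- trials$rt_s
    ok <- !is.na(tau) & !is.na(c_i)
    if (any(ok)) {
      dtb <- t[2] - t[1]
      M_shape <- function(x) bump(x, -0.05, 0.25)  # movement-aligned bump
      for (i in which(ok)) {
        x <- t - tau[i]
        R[i, ] <- R[i, ] + nk$amp_M * M_shape(x) +
          c_i[i] * nk$amp_D * M_shape(x)
      }
    }
  }
  pmax(R, 0)
}

#' Generate spike trains for a synthetic population
#'
#' Draws inhomogeneous-Poisson spikes for every neuron and trial from the
#' kernel forward model, on a 1 ms lattice. The ground-truth kernel
#' parameters used to build the rates are stored in the result for recovery
#' tests.
#'
#' @param trials Trial tibble (choices and `rt_s` present if movement
#'   kernels should contribute).
#' @param cfg A [neuron_sim_config()].
#' @param t_range Time span (s) around stimulus onset.
#' @param movement Include movement-aligned kernels (requires choices).
#' @param seed Overrides `cfg$seed`.
#' @return A `spike_data` object: `spikes` tibble
#'   `(neuron_id, trial_id, spike_time_s)`, `neurons` metadata tibble
#'   (hemisphere, coordinates, ground-truth amplitudes), `trials`, and the
#'   generation window.
#' @export
gen_population_spikes <- function(trials, cfg, t_range = c(-0.3, 0.8),
                                  movement = TRUE, seed = cfg$seed) {
  local_seed(seed)
  neurons <- draw_neuron_kernels(cfg)
  dt <- 0.001
  t <- seq(t_range[1] + dt / 2, t_range[2] - dt / 2, by = dt)
  sp <- vector("list", nrow(neurons))
  for (j in seq_len(nrow(neurons))) {
    nk <- neurons[j, ]
    R <- neuron_rate_matrix(nk, trials, t, cfg, movement = movement)
    counts <- matrix(stats::rpois(length(R), R * dt), nrow(R), ncol(R))
    hit <- which(counts > 0, arr.ind = TRUE)
    if (!nrow(hit)) next
    times <- rep(t[hit[, 2]], counts[hit]) +
      stats::runif(sum(counts[hit]), -dt / 2, dt / 2)
    sp[[j]] <- tibble::tibble(
      neuron_id = nk$neuron_id,
      trial_id = rep(trials$trial_id[hit[, 1]], counts[hit]),
      spike_time_s = times
    )
  }
  structure(
    list(spikes = dplyr::bind_rows(sp), neurons = neurons,
         trials = trials, t_range = t_range, cfg = cfg),
    class = "spike_data"
  )
}

#' @export
print.spike_data <- function(x, ...) {
  cat("<spike_data>", nrow(x$neurons), "neurons,",
      nrow(x$trials), "trials,", nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Noise-free expected rates of a synthetic population
#'
#' Evaluates the kernel forward model exactly (no Poisson noise) on a given
#' time lattice, returning the same `rate_traces` container as
#' [estimate_rates()]. Used for kernel-recovery checks where the regression
#' should reproduce the generating kernels to numerical tolerance.
#'
#' @param pop A `spike_data` object (its stored neurons and trials are
#'   used), or a neuron tibble from a previous generation.
#' @param t Time lattice (bin centers, s).
#' @param trials,cfg Required when `pop` is a neuron tibble.
#' @param movement Include movement-aligned kernels.
#' @return A `rate_traces` object of exact rates (Hz).
#' @export
expected_rate_traces <- function(pop, t, trials = NULL, cfg = NULL,
                                 movement = TRUE) {
  if (inherits(pop, "spike_data")) {
    trials <- trials %||% pop$trials
    cfg <- cfg %||% pop$cfg
    neurons <- pop$neurons
  } else {
    neurons <- pop
    if (is.null(trials) || is.null(cfg)) abort("trials and cfg are required")
  }
  rates <- lapply(seq_len(nrow(neurons)), function(j) {
    M <- neuron_rate_matrix(neurons[j, ], trials, t, cfg, movement = movement)
    rownames(M) <- trials$trial_id
    M
  })
  names(rates) <- neurons$neuron_id
  structure(list(t = t, rates = rates, trial_ids = trials$trial_id,
                 bin = t[2] - t[1], smooth_sd = 0),
            class = "rate_traces")
}

#' Build a condition-wise PSTH bank
#'
#' Computes expected firing-rate traces (the noise-free PSTHs of the kernel
#' forward model, movement kernels excluded as under passive presentation)
#' for the standard accumulator condition set: unisensory visual at 10, 20,
#' 40, 80% contrast left and right, unisensory auditory left and right, and
#' coherent and conflict audiovisual pairs at 80% contrast. In the naive
#' regime the lateralized kernels are zero, so left and right PSTHs are
#' equal in expectation.
#'
#' @param cfg A [neuron_sim_config()].
#' @param t_range Window (s) around stimulus onset; must cover
#'   `[-0.1, 0.3]`.
#' @param bin Lattice step (s).
#' @param conditions Optional condition tibble (columns `condition`,
#'   `vis_contrast_L`, `vis_contrast_R`, `aud_azimuth_deg`); defaults to the
#'   standard 14-condition set.
#' @param seed Overrides `cfg$seed` (neuron draw).
#' @return A `psth_bank`: `t`, `conditions`, `rates` array
#'   `[neuron, time, condition]` (Hz), and neuron metadata.
#' @export
gen_psth_bank <- function(cfg, t_range = c(-0.1, 0.3), bin = 0.010,
                          conditions = NULL, seed = cfg$seed) {
  if (t_range[1] > -0.1 + 1e-9 || t_range[2] < 0.3 - 1e-9) {
    abort("PSTH window must cover [-0.1, 0.3] s around stimulus onset")
  }
  local_seed(seed)
  conditions <- conditions %||% accumulator_conditions()
  neurons <- draw_neuron_kernels(cfg)
  t <- seq(t_range[1] + bin / 2, t_range[2] - bin / 2, by = bin)
  cond_tr <- classify_trials(conditions)
  rates <- array(0, c(nrow(neurons), length(t), nrow(conditions)),
                 dimnames = list(neurons$neuron_id, NULL,
                                 conditions$condition))
  for (j in seq_len(nrow(neurons))) {
    rates[j, , ] <- t(neuron_rate_matrix(neurons[j, ], cond_tr, t, cfg,
                                         movement = FALSE))
  }
  structure(
    list(t = t, conditions = cond_tr, rates = rates, neurons = neurons,
         bin = bin, regime = cfg$regime),
    class = "psth_bank"
  )
}

#' Standard accumulator condition set
#'
#' @return Condition tibble: unisensory visual at 10/20/40/80% contrast on
#'   each side, unisensory auditory on each side, and the 80%-contrast
#'   coherent and conflict pairs.
#' @export
accumulator_conditions <- function() {
  vis <- tidyr::crossing(contrast = c(0.1, 0.2, 0.4, 0.8), side = c(-1, 1)) |>
    dplyr::mutate(vis_contrast_L = ifelse(.data$side < 0, .data$contrast, 0),
                  vis_contrast_R = ifelse(.data$side > 0, .data$contrast, 0),
                  aud_azimuth_deg = 0,
                  condition = paste0("vis_", .data$contrast * 100,
                                     ifelse(.data$side > 0, "R", "L")))
  aud <- tibble::tibble(vis_contrast_L = 0, vis_contrast_R = 0,
                        aud_azimuth_deg = c(-60, 60),
                        condition = c("aud_L", "aud_R"))
  coh <- tibble::tibble(vis_contrast_L = c(0.8, 0), vis_contrast_R = c(0, 0.8),
                        aud_azimuth_deg = c(-60, 60),
                        condition = c("coherent_L", "coherent_R"))
  con <- tibble::tibble(vis_contrast_L = c(0.8, 0), vis_contrast_R = c(0, 0.8),
                        aud_azimuth_deg = c(60, -60),
                        condition = c("conflict_VL_AR", "conflict_VR_AL"))
  dplyr::bind_rows(dplyr::select(vis, -"contrast", -"side"), aud, coh, con)
}

#' @export
print.psth_bank <- function(x, ...) {
  cat("<psth_bank>", dim(x$rates)[1], "neurons x", dim(x$rates)[2],
      "bins x", dim(x$rates)[3], "conditions;", x$regime, "regime\n")
  invisible(x)
}
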