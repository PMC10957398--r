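# shared fixtures, generated in code at load time

default_params <- additive_params(b = 0.2, gamma = 0.6, vR = 3, vL = 3,
                                  aR = 2, aL = 2)

sim_trials <- function(n = 2000, params = default_params, seed = 1, ...) {
  cfg <- behavior_sim_config(true_params = params, n_trials = n,
                             seed = seed, ...)
  sim_behavior_dataset(cfg)
}

# small audiovisual-only design for encoding tests
sim_av_trials <- function(n = 100, contrast = 0.8, seed = 1) {
  cfg <- behavior_sim_config(n_trials = n, type_ratio = c(0, 0, 1, 1, 0),
                             contrast_set = contrast, seed = seed)
  sim_behavior_dataset(cfg)
}

# a simple triangular wheel trace: still, then constant-velocity ramp
ramp_trace <- function(rt = 0.2, dir = 1, threshold = 30, speed = 200,
                       dt = 0.005, t_end = 1.6, trial_id = 1) {
  t <- seq(-0.1, t_end, by = dt)
  pos <- dir * pmax(t - rt, 0) * speed
  tibble::tibble(trial_id = trial_id, t_s = t, position_deg = pos)
}
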