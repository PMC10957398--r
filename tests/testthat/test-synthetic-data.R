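test_that("trial schedules follow the type ratio and design", {
  cfg <- behavior_sim_config(n_trials = 31000, seed = 11)
  tr <- gen_trial_schedule(cfg)
  frac <- prop.table(table(factor(tr$trial_type,
                                  levels = c("unisensory_visual",
                                             "unisensory_auditory",
                                             "coherent", "conflict",
                                             "neutral"))))
  expect_equal(unname(as.vector(frac)), c(10, 10, 5, 5, 1) / 31,
               tolerance = 0.01 / min(c(10, 10, 5, 5, 1) / 31))
  expect_true(all(abs(as.vector(frac) - c(10, 10, 5, 5, 1) / 31) < 0.01))
  # at most one contrast nonzero; contrasts from the set; azimuths legal
  expect_true(all(tr$vis_contrast_L * tr$vis_contrast_R == 0))
  expect_true(all(tr$aud_azimuth_deg %in% c(-60, 0, 60)))
  nz <- pmax(tr$vis_contrast_L, tr$vis_contrast_R)
  expect_true(all(nz[nz > 0] %in% cfg$contrast_set))
})

test_that("degenerate type ratio yields a single trial type", {
  cfg <- behavior_sim_config(n_trials = 50, type_ratio = c(1, 0, 0, 0, 0),
                             seed = 2)
  expect_true(all(gen_trial_schedule(cfg)$trial_type == "unisensory_visual"))
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- behavior_sim_config(n_trials = 300, seed = 7)
  expect_identical(sim_behavior_dataset(cfg), sim_behavior_dataset(cfg))
  ncfg <- neuron_sim_config(n_neurons = 3, seed = 7)
  tr <- gen_trial_schedule(cfg)
  expect_identical(gen_population_spikes(tr, ncfg),
                   gen_population_spikes(tr, ncfg))
  expect_identical(gen_psth_bank(ncfg)$rates, gen_psth_bank(ncfg)$rates)
})

test_that("empty contrast set is a configuration error", {
  expect_error(behavior_sim_config(contrast_set = numeric(0)), "contrast_set")
})

test_that("simulated choices follow the closed-form logistic probabilities", {
  # all parameters zero: p(R) = 0.5 everywhere
  tr <- gen_trial_schedule(behavior_sim_config(n_trials = 4000, seed = 3))
  tr0 <- simulate_choices(tr, additive_params(b = 0, vR = 0, vL = 0,
                                              aR = 0, aL = 0), seed = 4)
  expect_equal(mean(tr0$choice == "R"), 0.5, tolerance = 0.03)
  # saturating bias: all rightward
  trb <- simulate_choices(tr, additive_params(b = 19), seed = 4)
  expect_true(all(trb$choice == "R"))
  # closed form at one condition
  cond <- tibble::tibble(vis_contrast_L = 0, vis_contrast_R = 0.8,
                         aud_azimuth_deg = 60)
  eta <- log_odds(psych_model("additive"), cond, params = default_params)
  expect_equal(eta, 0.2 + 3 * 0.8^0.6 + 2)
})

test_that("empirical choice fractions converge to the model probabilities", {
  n <- 1e5
  cfg <- behavior_sim_config(true_params = default_params, n_trials = n,
                             seed = 5)
  tr <- simulate_choices(gen_trial_schedule(cfg), default_params, seed = 6)
  cells <- tr |>
    dplyr::count(vis_contrast_L, vis_contrast_R, aud_azimuth_deg,
                 right = choice == "R") |>
    tidyr::pivot_wider(names_from = right, values_from = n,
                       values_fill = 0L)
  p_hat <- cells$`TRUE` / (cells$`TRUE` + cells$`FALSE`)
  p_true <- plogis(log_odds(psych_model("additive"), cells,
                            params = default_params))
  n_cell <- cells$`TRUE` + cells$`FALSE`
  se <- sqrt(p_true * (1 - p_true) / n_cell)
  expect_true(all(abs(p_hat - p_true) < 3 * se + 1e-9))
})

test_that("spike generation conserves ground truth and Poisson means", {
  cfg <- behavior_sim_config(n_trials = 1000, seed = 8)
  tr <- sim_behavior_dataset(cfg)
  ncfg <- neuron_sim_config(
    n_neurons = 1, baseline_rate_mean = 10, baseline_rate_shape = 1e8,
    amp = list(A = 0, V = 0, N = 0, M = 0, D = 0, onset = 0),
    fraction_selective = list(aud = 0, vis = 0, move = 0, dir = 0),
    seed = 9)
  spk <- gen_population_spikes(tr, ncfg, t_range = c(0, 1), movement = FALSE)
  # stored ground truth equals the parameters used to generate rates
  expect_equal(spk$neurons$baseline, 10, tolerance = 1e-3)
  expect_equal(spk$neurons$amp_A, 0)
  # 10 Hz over 1 s: mean count 10 within sampling error (3 SE)
  mean_count <- nrow(spk$spikes) / nrow(tr)
  expect_equal(mean_count, 10, tolerance = 3 * sqrt(10 / nrow(tr)) / 10)
})

test_that("negative baseline rate is rejected", {
  expect_error(neuron_sim_config(baseline_rate_mean = -1), "nonnegative")
})

test_that("naive-regime visual d-prime is indistinguishable from shuffle", {
  cfg <- behavior_sim_config(n_trials = 400, type_ratio = c(1, 0, 0, 0, 0),
                             contrast_set = 0.8, seed = 10)
  tr <- sim_behavior_dataset(cfg)
  ncfg <- neuron_sim_config(n_neurons = 12, regime = "naive", seed = 11)
  spk <- gen_population_spikes(tr, ncfg, t_range = c(-0.3, 0.5),
                               movement = FALSE)
  rates <- estimate_rates(spk, bin = 0.01, t_range = c(-0.3, 0.5))
  side <- sign(tr$vis_contrast_R - tr$vis_contrast_L)
  dp <- dprime_by_neuron(rates, side > 0)$dprime
  set.seed(12)
  dp_shuf <- replicate(20, {
    mean(abs(dprime_by_neuron(rates, sample(side) > 0)$dprime))
  })
  # observed mean |d'| within the shuffle distribution (no visual code)
  expect_lt(mean(abs(dp)), max(dp_shuf) * 1.2)
  expect_gt(mean(abs(dp)), min(dp_shuf) * 0.8)
})

test_that("inactivation dataset respects the laser configuration", {
  grid <- laser_site_grid()
  expect_equal(nrow(grid), 64)
  expect_equal(sum(grid$region == "visual"), 6)   # 3 coordinates x 2 hemispheres
  # laser_fraction = 0: no laser trials
  cfg0 <- inactivation_sim_config(grid, laser_fraction = 0, seed = 1)
  tr0 <- gen_inactivation_dataset(default_params, cfg0, n_trials = 500)
  expect_false(any(tr0$laser_on))
  # unknown region in effects errors
  expect_error(
    inactivation_sim_config(grid, region_effects = list(nowhere = c(vc = -1))),
    "unknown region")
  # null world: laser and control choice fractions statistically equal
  cfgN <- inactivation_sim_config(grid, seed = 2)
  trN <- gen_inactivation_dataset(default_params, cfgN, n_trials = 8000)
  pL <- mean(trN$choice[trN$laser_on] == "R")
  pC <- mean(trN$choice[!trN$laser_on] == "R")
  se <- sqrt(0.25 / sum(trN$laser_on) + 0.25 / sum(!trN$laser_on))
  expect_lt(abs(pL - pC), 3 * se)
})

test_that("a contralateral visual deficit shifts choices away from the stimulus", {
  grid <- laser_site_grid()
  cfg <- inactivation_sim_config(grid,
                                 region_effects = list(visual = c(vc = -2)),
                                 seed = 3)
  tr <- gen_inactivation_dataset(default_params, cfg, n_trials = 40000)
  # right-hemisphere visual site inactivated, left (contralateral) visual
  # stimulus: the leftward evidence is attenuated, so choices shift toward
  # the ipsilateral (rightward) side — the closed form gives
  # p(R) = sigma(b + ... - vc * Vc^gamma) with vc reduced
  vis_left <- tr$trial_type == "unisensory_visual" & tr$vis_contrast_L > 0
  las <- tr$laser_on & tr$laser_region %in% "visual" & tr$laser_ml_mm > 0
  p_las <- mean(tr$choice[vis_left & las] == "R")
  p_ctl <- mean(tr$choice[vis_left & !tr$laser_on] == "R")
  expect_gt(p_las, p_ctl)
  # the mirror-image check: left-hemisphere inactivation, right stimulus
  vis_right <- tr$trial_type == "unisensory_visual" & tr$vis_contrast_R > 0
  lasL <- tr$laser_on & tr$laser_region %in% "visual" & tr$laser_ml_mm < 0
  expect_lt(mean(tr$choice[vis_right & lasL] == "R"),
            mean(tr$choice[vis_right & !tr$laser_on] == "R"))
})

test_that("PSTH banks cover the required window and encode the regimes", {
  expect_error(gen_psth_bank(neuron_sim_config(seed = 1),
                             t_range = c(0, 0.3)), "cover")
  ncfg_t <- neuron_sim_config(n_neurons = 20, regime = "trained", seed = 4)
  ncfg_n <- neuron_sim_config(n_neurons = 20, regime = "naive", seed = 4)
  bank_t <- gen_psth_bank(ncfg_t)
  bank_n <- gen_psth_bank(ncfg_n)
  # naive: left and right unisensory PSTHs identical in expectation
  expect_equal(bank_n$rates[, , "aud_L"], bank_n$rates[, , "aud_R"])
  expect_false(isTRUE(all.equal(bank_t$rates[, , "aud_L"],
                                bank_t$rates[, , "aud_R"])))
  # trained: auditory L/R divergence precedes visual divergence by the
  # configured latency offset
  diverge_onset <- function(d) bank_t$t[which(d > 1e-6)[1]]
  aud_div <- colMeans(abs(bank_t$rates[, , "aud_R"] -
                            bank_t$rates[, , "aud_L"]))
  vis_div <- colMeans(abs(bank_t$rates[, , "vis_80R"] -
                            bank_t$rates[, , "vis_80L"]))
  lag <- diverge_onset(vis_div) - diverge_onset(aud_div)
  offset <- ncfg_t$latency$vis - ncfg_t$latency$aud
  expect_equal(lag, offset, tolerance = 0.35)   # +/- latency jitter and bin
  # zero-amplitude kernels: flat PSTHs at baseline
  ncfg0 <- neuron_sim_config(
    n_neurons = 2, amp = list(A = 0, V = 0, N = 0, M = 0, D = 0, onset = 0),
    fraction_selective = list(aud = 0, vis = 0, move = 0, dir = 0), seed = 5)
  bank0 <- gen_psth_bank(ncfg0)
  expect_equal(max(apply(bank0$rates, 1, sd)), 0)
})

test_that("an additive fit attains near-Bayes accuracy under conditional independence", {
  # generative world: S uniform; V and A drawn independently given S from
  # discrete likelihood tables; responder probability-matches the posterior
  set.seed(13)
  v_levels <- c(-0.8, -0.2, 0, 0.2, 0.8)
  p_v_R <- c(0.05, 0.15, 0.2, 0.3, 0.3)
  p_v_L <- rev(p_v_R)
  a_levels <- c(-60, 0, 60)
  p_a_R <- c(0.15, 0.25, 0.6)
  p_a_L <- rev(p_a_R)
  n <- 20000
  S <- sample(c(-1, 1), n, replace = TRUE)
  V <- ifelse(S > 0, sample(v_levels, n, TRUE, p_v_R),
              sample(v_levels, n, TRUE, p_v_L))
  A <- ifelse(S > 0, sample(a_levels, n, TRUE, p_a_R),
              sample(a_levels, n, TRUE, p_a_L))
  post <- function(v, a) {
    lv <- log(p_v_R[match(v, v_levels)] / p_v_L[match(v, v_levels)])
    la <- log(p_a_R[match(a, a_levels)] / p_a_L[match(a, a_levels)])
    plogis(lv + la)
  }
  pr <- post(V, A)
  trials <- tibble::tibble(
    trial_id = seq_len(n), session_id = "s1", subject_id = "m1",
    vis_contrast_L = pmax(-V, 0), vis_contrast_R = pmax(V, 0),
    aud_azimuth_deg = A,
    choice = ifelse(runif(n) < pr, "R", "L")
  ) |> classify_trials()
  fit <- fit_psych(trials, psych_model("additive_unconstrained",
                                       contrast_set = c(0.2, 0.8)),
                   seed = 14)
  # Bayes accuracy by enumeration over the (V, A) grid
  grid <- expand.grid(V = v_levels, A = a_levels)
  pva <- 0.5 * (p_v_R[match(grid$V, v_levels)] * p_a_R[match(grid$A, a_levels)] +
                p_v_L[match(grid$V, v_levels)] * p_a_L[match(grid$A, a_levels)])
  post_grid <- post(grid$V, grid$A)
  bayes_acc <- sum(pva * pmax(post_grid, 1 - post_grid))
  cond <- tibble::tibble(vis_contrast_L = pmax(-grid$V, 0),
                         vis_contrast_R = pmax(grid$V, 0),
                         aud_azimuth_deg = grid$A)
  fit_rule_R <- log_odds(fit, cond) > 0
  fit_acc <- sum(pva * ifelse(fit_rule_R, post_grid, 1 - post_grid))
  expect_lt(bayes_acc - fit_acc, 0.01)
})
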