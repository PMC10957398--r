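test_that("model families expose the design parameter counts", {
  expect_equal(n_params(psych_model("bias_only")), 1)
  expect_equal(n_params(psych_model("auditory_only")), 3)
  expect_equal(n_params(psych_model("visual_only")), 4)
  expect_equal(n_params(psych_model("additive")), 6)
  expect_equal(n_params(psych_model("auditory_dominance")), 6)
  expect_equal(n_params(psych_model("auditory_dominance", free_acon = TRUE)), 7)
  expect_equal(n_params(psych_model("sensory_bias")), 10)
  expect_equal(n_params(psych_model("additive_unconstrained")), 11)
  expect_equal(n_params(psych_model("full")), 27)
  expect_equal(n_params(psych_model("additive_5azimuth",
                                    azimuth_set = c(-60, -30, 0, 30, 60))), 8)
  expect_equal(n_params(psych_model("ipsi_contra")), 6)
})

test_that("log odds evaluate family-specific forms", {
  neutral <- tibble::tibble(vis_contrast_L = 0, vis_contrast_R = 0,
                            aud_azimuth_deg = 0)
  conflict <- tibble::tibble(vis_contrast_L = 0.8, vis_contrast_R = 0,
                             aud_azimuth_deg = 60)
  # bias only: constant everywhere
  expect_equal(log_odds(psych_model("bias_only"),
                        dplyr::bind_rows(neutral, conflict),
                        params = c(b = 0.7)),
               c(0.7, 0.7))
  # additive at the neutral condition: just the bias
  expect_equal(log_odds(psych_model("additive"), neutral,
                        params = default_params), 0.2)
  # dominance on a conflict trial: visual term zeroed, auditory term kept
  expect_equal(log_odds(psych_model("auditory_dominance"), conflict,
                        params = default_params),
               0.2 + 2)
  # unknown azimuth errors
  expect_error(log_odds(psych_model("additive"),
                        dplyr::mutate(neutral, aud_azimuth_deg = 45),
                        params = default_params),
               "azimuth")
})

test_that("maximum likelihood recovers generating parameters", {
  tr <- sim_trials(20000, seed = 41)
  fit <- fit_psych(tr, psych_model("additive"), seed = 42)
  est <- fit$estimates
  expect_lt(abs(est[["b"]] - 0.2), 0.1)
  expect_lt(abs(est[["aR"]] - 2), 0.1)
  expect_lt(abs(est[["aL"]] - 2), 0.1)
  expect_lt(abs(est[["vR"]] - 3) / 3, 0.1)
  expect_lt(abs(est[["vL"]] - 3) / 3, 0.1)
  expect_lt(abs(est[["gamma"]] - 0.6) / 0.6, 0.1)
})

test_that("balanced coin-flip data fit to zero bias and sensitivities", {
  tr <- gen_trial_schedule(behavior_sim_config(n_trials = 4000, seed = 43))
  tr$choice <- rep(c("L", "R"), length.out = nrow(tr))
  fit <- fit_psych(tr, psych_model("additive"), seed = 44)
  expect_lt(abs(fit$estimates[["b"]]), 0.15)
  expect_lt(abs(fit$estimates[["aR"]]), 0.25)
  expect_lt(abs(fit$estimates[["vR"]]), 0.4)
})

test_that("the optimizer matches a coarse grid-search oracle", {
  tr <- sim_trials(5000, seed = 45)
  frozen <- list(gamma = 0.6, vR = 3, vL = 3, aL = 2)
  model <- psych_model("additive", fixed = frozen)
  fit <- fit_psych(tr, model, seed = 46)
  # independent oracle: direct per-trial Bernoulli likelihood on a grid
  b_grid <- seq(-0.5, 1, by = 0.05)
  a_grid <- seq(1, 3, by = 0.05)
  r <- tr$choice == "R"
  VR <- tr$vis_contrast_R; VL <- tr$vis_contrast_L
  AR <- as.integer(tr$aud_azimuth_deg > 0); AL <- as.integer(tr$aud_azimuth_deg < 0)
  ll_of <- function(b, aR) {
    eta <- b + 3 * VR^0.6 - 3 * VL^0.6 + aR * AR - 2 * AL
    sum(ifelse(r, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE)))
  }
  ll <- outer(b_grid, a_grid, Vectorize(ll_of))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_lt(abs(fit$estimates[["b"]] - b_grid[best[1]]), 0.05)
  expect_lt(abs(fit$estimates[["aR"]] - a_grid[best[2]]), 0.05)
})

test_that("train log-likelihood respects model nesting", {
  tr <- sim_trials(3000, seed = 47)
  ll <- function(fam) fit_psych(tr, psych_model(fam), seed = 48)$logLik
  ll_bias <- ll("bias_only")
  ll_add <- ll("additive")
  ll_sb <- ll("sensory_bias")
  ll_full <- ll("full")
  tol <- 1e-4 * abs(ll_add)
  expect_gte(ll_add, ll_bias - tol)
  expect_gte(ll_sb, ll_add - tol)
  expect_gte(ll_full, ll_add - tol)
})

test_that("fits are reflection equivariant", {
  tr <- sim_trials(8000, params = additive_params(b = 0.5, vR = 3.5, vL = 2.5,
                                                  aR = 2.2, aL = 1.6),
                   seed = 49)
  fit <- fit_psych(tr, psych_model("additive"), seed = 50)
  mir <- mirror_trials(tr, rep(TRUE, nrow(tr)))
  fit_m <- fit_psych(mir, psych_model("additive"), seed = 50)
  tol <- 0.05
  expect_equal(fit_m$estimates[["b"]], -fit$estimates[["b"]], tolerance = tol)
  expect_equal(fit_m$estimates[["vR"]], fit$estimates[["vL"]], tolerance = tol)
  expect_equal(fit_m$estimates[["vL"]], fit$estimates[["vR"]], tolerance = tol)
  expect_equal(fit_m$estimates[["aR"]], fit$estimates[["aL"]], tolerance = tol)
  expect_equal(fit_m$estimates[["aL"]], fit$estimates[["aR"]], tolerance = tol)
})

test_that("cross-validated bits per trial is zero for bias-only against itself", {
  tr <- sim_trials(1000, seed = 51)
  fit <- cv_bits_per_trial(tr, psych_model("bias_only"), seed = 52)
  expect_lt(abs(fit$cv$bits_per_trial), 0.01)
})

test_that("bits per trial approaches the generative information gain", {
  # enumeration oracle: expected bits/trial of the true model over the
  # condition distribution, relative to the bias-only entropy
  tr <- sim_trials(30000, seed = 53)
  cells <- avchoice:::aggregate_cells(tr)
  p_cond <- (cells$nR + cells$nL) / sum(cells$nR + cells$nL)
  p_true <- plogis(log_odds(psych_model("additive"), cells,
                            params = default_params))
  h <- function(p) -(p * log2(p) + (1 - p) * log2(1 - p))
  p_marg <- sum(p_cond * p_true)
  gain <- h(p_marg) - sum(p_cond * h(p_true))
  fit <- cv_bits_per_trial(tr, psych_model("additive"), seed = 54)
  expect_equal(fit$cv$bits_per_trial, gain, tolerance = 0.05)
})

test_that("model selection ranks the generating family first", {
  set.seed(55)
  seeds <- 1:8
  rank_ok_add <- rank_ok_dom <- logical(length(seeds))
  dom <- psych_model("auditory_dominance")
  add <- psych_model("additive")
  for (i in seq_along(seeds)) {
    sched <- gen_trial_schedule(behavior_sim_config(n_trials = 2000,
                                                    seed = 100 + i))
    tr_a <- simulate_choices(sched, default_params, seed = 200 + i)
    tr_d <- simulate_choices(sched, default_params, seed = 300 + i,
                             model = dom)
    bits <- function(tr, m) cv_bits_per_trial(tr, m, n_starts = 3,
                                              seed = 400 + i)$cv$bits_per_trial
    rank_ok_add[i] <- bits(tr_a, add) >= bits(tr_a, dom)
    rank_ok_dom[i] <- bits(tr_d, dom) >= bits(tr_d, add)
  }
  expect_gte(mean(rank_ok_add), 0.75)
  expect_gte(mean(rank_ok_dom), 0.75)
})

test_that("pooled fits subsample subjects symmetrically", {
  sched <- gen_trial_schedule(behavior_sim_config(n_trials = 4000,
                                                  n_subjects = 2, seed = 56))
  # opposite biases across two equal-n subjects cancel
  p_plus <- additive_params(b = 1)
  p_minus <- additive_params(b = -1)
  tr <- dplyr::bind_rows(
    simulate_choices(sched[sched$subject_id == "m1", ], p_plus, seed = 57),
    simulate_choices(sched[sched$subject_id == "m2", ], p_minus, seed = 58)
  )
  pooled <- combine_subjects(tr, psych_model("additive"), n_repeats = 4,
                             seed = 59)
  expect_lt(abs(pooled$estimates[["b"]]), 0.2)
  expect_equal(nrow(pooled$per_repeat), 4)
})

test_that("empirical log odds handle one-sided cells by regularization", {
  tr <- tibble::tibble(
    trial_id = 1:15, session_id = "s", subject_id = "m",
    vis_contrast_L = 0, vis_contrast_R = rep(c(0.8, 0.4), c(10, 5)),
    aud_azimuth_deg = 0,
    choice = c(rep("R", 8), rep("L", 2), rep("R", 5))
  ) |> classify_trials()
  lo <- empirical_log_odds(tr, gamma = 0.6)
  cell8 <- lo[lo$vis_contrast_R == 0.8, ]
  cell4 <- lo[lo$vis_contrast_R == 0.4, ]
  expect_equal(cell8$log_odds, log(4))       # 8 vs 2
  expect_equal(cell4$log_odds, log(6))       # 5 vs 0 -> (5+1)/(0+1)
  expect_true(cell4$regularized)
  expect_equal(cell8$x_contrast, 0.8^0.6)
})

test_that("equal-and-opposite pairs behave neutrally under additive fits", {
  # equal auditory and visual weights: conflict at the contrast where
  # v * c^gamma = a cancels exactly
  params <- additive_params(b = 0.3, gamma = 1, vR = 2.5, vL = 2.5,
                            aR = 2.5 * 0.8, aL = 2.5 * 0.8)
  cfg <- behavior_sim_config(true_params = params, n_trials = 30000,
                             type_ratio = c(1, 1, 1, 4, 0.2), seed = 60)
  tr <- sim_behavior_dataset(cfg)
  fit <- fit_psych(tr, psych_model("additive"), seed = 61)
  np <- neutral_pair_test(fit, trials = tr, tol = 0.25)
  expect_gt(nrow(np), 0)
  # empirical fraction at matched pairs within 3 SE of sigma(b)
  for (i in seq_len(nrow(np))) {
    se <- sqrt(np$p_right_neutral[i] * (1 - np$p_right_neutral[i]) / np$n[i])
    expect_lt(abs(np$frac_right[i] - np$p_right_neutral[i]),
              3 * se + np$cancel_residual[i] / 4 + 0.02)
  }
  # negative control: dominance-generated data violate the property — at
  # each matched condition the auditory term rules, pushing the fraction
  # far from sigma(b) (conditions must be compared individually; pooling
  # mirror-image pairs would cancel the deviations)
  tr_d <- simulate_choices(gen_trial_schedule(cfg), params, seed = 62,
                           model = psych_model("auditory_dominance"))
  emp_d <- avchoice:::aggregate_cells(tr_d) |>
    dplyr::semi_join(np, by = c("vis_contrast_L", "vis_contrast_R",
                                "aud_azimuth_deg")) |>
    dplyr::mutate(frac = nR / (nR + nL))
  expect_gt(max(abs(emp_d$frac - plogis(0.3))), 0.15)
})

test_that("the independence audit flags the task's dependent design", {
  # a single-modality design is exactly conditionally independent (the
  # visual channel is degenerate), so the distance is 0
  set.seed(63)
  tr_ind <- tibble::tibble(vis_contrast_L = 0, vis_contrast_R = 0,
                           aud_azimuth_deg = sample(c(-60, 60), 2000, TRUE))
  audit_ind <- independence_audit(tr_ind)
  expect_equal(max(audit_ind$tv_distance), 0, tolerance = 1e-12)
  # the 10/10/5/5/1 task design is not independent
  tr_task <- gen_trial_schedule(behavior_sim_config(n_trials = 20000,
                                                    seed = 64))
  audit_task <- independence_audit(tr_task)
  expect_gt(min(audit_task$tv_distance), 0.1)
  # joint and product tables are normalized per side
  for (aud in list(audit_ind, audit_task)) {
    expect_equal(sum(aud$joint$p_given_R), 1)
    expect_equal(sum(aud$joint$p_given_L), 1)
    expect_equal(sum(aud$indep$p_given_R), 1)
    expect_equal(sum(aud$indep$p_given_L), 1)
  }
})

test_that("tidiers and autoplot work on psychometric fits", {
  tr <- sim_trials(1500, seed = 65)
  fit <- cv_bits_per_trial(tr, psych_model("additive"), seed = 66)
  td <- tidy(fit)
  expect_setequal(td$term, c("b", "gamma", "vR", "vL", "aR", "aL"))
  gl <- glance(fit)
  expect_equal(gl$n_params, 6)
  expect_false(is.na(gl$cv_bits_per_trial))
  pl <- ggplot2::autoplot(fit, trials = tr)
  expect_s3_class(pl, "ggplot")
})
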