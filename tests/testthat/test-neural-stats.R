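# build a rate_traces object directly from a matrix list
rates_of <- function(mats, t) {
  structure(list(t = t, rates = mats,
                 trial_ids = seq_len(nrow(mats[[1]])),
                 bin = t[2] - t[1], smooth_sd = 0),
            class = "rate_traces")
}

test_that("population decoding sits at chance and at ceiling where it should", {
  set.seed(111)
  n_tr <- 80; n_neur <- 35
  t <- seq(0.005, 0.3, by = 0.01)
  labels <- rep(c(-1, 1), each = n_tr / 2)
  noise <- lapply(setNames(seq_len(n_neur), paste0("n", seq_len(n_neur))),
                  function(j) matrix(rnorm(n_tr * length(t), 10, 2), n_tr))
  r_noise <- rates_of(noise, t)
  d0 <- decode_population(r_noise, labels, n_sub = 30, min_per_class = 25,
                          seed = 112)
  expect_lt(abs(d0$relative_accuracy), 0.25)
  # linearly separable rates decode perfectly
  sep <- lapply(noise, function(M) M + outer(labels, rep(3, length(t))))
  d1 <- decode_population(rates_of(sep, t), labels, n_sub = 30,
                          min_per_class = 25, seed = 113)
  expect_equal(d1$relative_accuracy, 1)
  # relative accuracy is invariant to per-neuron rescaling
  scaled <- purrr::imap(sep, function(M, nm) M * runif(1, 0.1, 10))
  d2 <- decode_population(rates_of(scaled, t), labels, n_sub = 30,
                          min_per_class = 25, seed = 113)
  expect_equal(d2$relative_accuracy, d1$relative_accuracy)
  # inclusion criteria
  expect_error(decode_population(r_noise, labels, n_sub = 50), "neurons")
  expect_error(decode_population(r_noise, c(rep(-1, 5), rep(1, n_tr - 5)),
                                 min_per_class = 25), "class")
})

test_that("d-prime matches its definition and a sampling oracle", {
  expect_equal(dprime(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(114)
  x1 <- rnorm(2000, 1, 1); x2 <- rnorm(2000, 0, 1)
  expect_equal(dprime(x1, x2), 1, tolerance = 0.1)
  # closed form for unequal SDs: (mu1 - mu2) / ((s1 + s2) / 2)
  y1 <- rnorm(4000, 3, 2); y2 <- rnorm(4000, 1, 4)
  expect_equal(dprime(y1, y2), 2 / 3, tolerance = 0.1)
})

test_that("ccCP matches the brute-force pair enumeration and the U identity", {
  set.seed(115)
  n <- 40
  vals <- c(rnorm(n), rnorm(n) + 0.8)
  conds <- rep(c("c1", "c2"), n)
  outs <- rep(c(-1, 1), each = n)
  brute <- function(values, conditions, pos) {
    n_gt <- 0; n_pair <- 0
    for (i in seq_along(values)) for (j in seq_along(values)) {
      if (!pos[i] || pos[j]) next
      if (conditions[i] != conditions[j]) next
      n_pair <- n_pair + 1
      n_gt <- n_gt + (values[i] > values[j]) + 0.5 * (values[i] == values[j])
    }
    n_gt / n_pair
  }
  res <- combined_conditions_probability(vals, conds, outs, n_shuffle = 50,
                                         seed = 116)
  expect_equal(res$statistic, brute(vals, conds, outs == 1), tolerance = 1e-12)
  # ties count one half
  res_tie <- combined_conditions_probability(rep(1, 10), rep("c", 10),
                                             rep(c(-1, 1), 5),
                                             n_shuffle = 20, seed = 117)
  expect_equal(res_tie$statistic, 0.5)
  # single condition: equals the Mann-Whitney U normalized by pair count
  vals1 <- rnorm(30); outs1 <- sample(c(-1, 1), 30, TRUE)
  res1 <- combined_conditions_probability(vals1, rep("c", 30), outs1,
                                          n_shuffle = 20, seed = 118)
  U <- unname(stats::wilcox.test(vals1[outs1 == 1],
                                 vals1[outs1 == -1])$statistic)
  expect_equal(res1$statistic, U / (sum(outs1 == 1) * sum(outs1 == -1)),
               tolerance = 1e-12)
  # extremes
  hi <- c(rep(0, 10), rep(1, 10))
  res_hi <- combined_conditions_probability(hi, rep("c", 20),
                                            rep(c(-1, 1), each = 10),
                                            n_shuffle = 100, seed = 119)
  expect_equal(res_hi$statistic, 1)
  expect_true(res_hi$significant)
})

test_that("rate-independent outcomes give a non-significant ccCP near one half", {
  set.seed(120)
  vals <- rnorm(120, 10)
  res <- combined_conditions_probability(vals, rep(c("a", "b"), 60),
                                         sample(c(-1, 1), 120, TRUE),
                                         n_shuffle = 300, seed = 121)
  expect_equal(res$statistic, 0.5, tolerance = 0.12)
  expect_false(res$significant)
})

test_that("neuron classification flags the constructed response types", {
  set.seed(122)
  n_side <- 40
  t <- seq(-0.295, 0.395, by = 0.01)
  trials <- tibble::tibble(
    trial_id = seq_len(4 * n_side), session_id = "s", subject_id = "m",
    vis_contrast_L = rep(c(0, 0, 0.8, 0), each = n_side),
    vis_contrast_R = rep(c(0, 0, 0, 0.8), each = n_side),
    aud_azimuth_deg = rep(c(-60, 60, 0, 0), each = n_side)
  ) |> classify_trials()
  n_tr <- nrow(trials)
  base <- function() matrix(rnorm(n_tr * length(t), 10, 1.5), n_tr)
  aud_ix <- trials$trial_type == "unisensory_auditory"
  # sound-onset step, same for both sides
  M_on <- base()
  M_on[aud_ix, t >= 0] <- M_on[aud_ix, t >= 0] + 6
  # lateralized visual response
  M_lat <- base()
  vis_r <- trials$vis_contrast_R > 0
  M_lat[vis_r, t >= 0.05] <- M_lat[vis_r, t >= 0.05] + 6
  M_flat <- base()
  rt <- rates_of(list(on = M_on, lat = M_lat, flat = M_flat), t)
  cls <- classify_neurons(rt, trials, n_shuffle = 300, seed = 123)
  on <- cls[cls$neuron_id == "on", ]
  expect_true(on$aud_onoff)
  expect_false(on$aud_rightleft)
  lat <- cls[cls$neuron_id == "lat", ]
  expect_true(lat$vis_rightleft)
  flat <- cls[cls$neuron_id == "flat", ]
  expect_false(any(unlist(flat[, -1])))
})

test_that("discrimination time localizes a step and respects the cap", {
  set.seed(124)
  n_side <- 35
  t <- seq(-0.295, 0.495, by = 0.005)
  trials <- tibble::tibble(
    trial_id = seq_len(2 * n_side), session_id = "s", subject_id = "m",
    vis_contrast_L = 0, vis_contrast_R = 0,
    aud_azimuth_deg = rep(c(-60, 60), each = n_side)
  ) |> classify_trials()
  right <- trials$aud_azimuth_deg > 0
  mk <- function(onset, snr = 8) {
    M <- matrix(rnorm(nrow(trials) * length(t), 10, 1), nrow(trials))
    M[right, t >= onset] <- M[right, t >= onset] + snr
    M
  }
  rt <- rates_of(list(step100 = mk(0.1), none = mk(2), late = mk(0.35)), t)
  res <- discrimination_time(rt, trials, modality = "aud",
                             type = "rightleft")
  # the reported time is the start of the first significant window, so a
  # high-SNR step is detected up to one window width early
  t_step <- res$discrimination_time_s[res$neuron_id == "step100"]
  expect_lt(abs(t_step - 0.1), 0.055)
  expect_lte(t_step, 0.1)
  expect_true(is.na(res$discrimination_time_s[res$neuron_id == "none"]))
  # a difference starting after 300 ms is rejected by the cap
  expect_true(is.na(res$discrimination_time_s[res$neuron_id == "late"]))
  # post-hoc decoding is near-perfect for the high-SNR step neuron
  dec <- discrimination_decode(rt, trials, res, seed = 125)
  expect_gt(dec$decode_accuracy[dec$neuron_id == "step100"], 0.9)
})

test_that("auditory-leading populations discriminate sound location earlier", {
  set.seed(126)
  cfg <- behavior_sim_config(n_trials = 360, type_ratio = c(1, 1, 0, 0, 0),
                             contrast_set = 0.8, seed = 127)
  tr <- sim_behavior_dataset(cfg)
  lead <- 0.045
  ncfg <- neuron_sim_config(n_neurons = 14, amp = list(A = 14, V = 14, N = 0,
                                                       M = 0, D = 0,
                                                       onset = 2),
                            fraction_selective = list(aud = 1, vis = 1,
                                                      move = 0, dir = 0),
                            latency = list(aud = 0.030, vis = 0.030 + lead),
                            seed = 128)
  spk <- gen_population_spikes(tr, ncfg, t_range = c(-0.3, 0.5),
                               movement = FALSE)
  rates <- estimate_rates(spk, bin = 0.005, t_range = c(-0.3, 0.5))
  t_aud <- discrimination_time(rates, tr, "aud", "rightleft")
  t_vis <- discrimination_time(rates, tr, "vis", "rightleft")
  da <- median(t_aud$discrimination_time_s, na.rm = TRUE)
  dv <- median(t_vis$discrimination_time_s, na.rm = TRUE)
  expect_lt(da, dv)
  expect_equal(dv - da, lead, tolerance = 0.03)
})

test_that("choice-axis projection is 1 on the axis and 0 orthogonal to it", {
  set.seed(129)
  n_side <- 20; n_neur <- 6
  t <- seq(0.005, 0.4, by = 0.01)
  # choices vary within condition so the held-out choice axis is defined
  trials <- tibble::tibble(
    trial_id = seq_len(2 * n_side), session_id = "s", subject_id = "m",
    vis_contrast_L = rep(c(0.8, 0), each = n_side),
    vis_contrast_R = rep(c(0, 0.8), each = n_side),
    aud_azimuth_deg = 0,
    choice = rep(c("L", "R"), n_side),
    rt_s = 0.1
  ) |> classify_trials()
  # population vector exactly mu_R - mu_L on every right trial, and an
  # orthogonal pattern elsewhere
  muR <- c(1, 1, 0, 0, 0, 0); muL <- c(0, 0, 1, 1, 0, 0)
  orth <- c(0, 0, 0, 0, 1, 1)
  mats <- lapply(setNames(seq_len(n_neur), paste0("n", seq_len(n_neur))),
                 function(j) {
    M <- matrix(0, nrow(trials), length(t))
    M[trials$choice == "R", ] <- muR[j]
    M[trials$choice == "L", ] <- muL[j]
    M
  })
  proj <- choice_axis_projection(rates_of(mats, t), trials, seed = 130)
  axis_dir <- muR - muL
  sc_r <- proj$sc[proj$choice == "R"]
  expected_r <- sum(muR * axis_dir) / (sqrt(sum(muR^2)) * sqrt(sum(axis_dir^2)))
  expect_equal(unique(round(sc_r, 9)), round(expected_r, 9))
  # orthogonal population vector projects to zero
  mats_o <- lapply(setNames(seq_len(n_neur), paste0("n", seq_len(n_neur))),
                   function(j) {
    M <- matrix(orth[j], nrow(trials), length(t))
    # keep the choice vectors themselves intact after movement onset
    M[, t >= 0.1] <- ifelse(trials$choice == "R", muR[j], muL[j])
    M
  })
  proj_o <- choice_axis_projection(rates_of(mats_o, t), trials, seed = 131)
  sc_early <- proj_o$sc[proj_o$t_s < 0.1]
  expect_true(all(abs(sc_early) < 1e-9))
})

test_that("a ramping choice signal separates choices before movement onset", {
  set.seed(132)
  n_side <- 30; n_neur <- 8
  t <- seq(-0.095, 0.4, by = 0.01)
  trials <- tibble::tibble(
    trial_id = seq_len(2 * n_side), session_id = "s", subject_id = "m",
    vis_contrast_L = rep(c(0.8, 0), each = n_side),
    vis_contrast_R = rep(c(0, 0.8), each = n_side),
    aud_azimuth_deg = 0,
    choice = rep(c("L", "R"), n_side),
    rt_s = 0.2
  ) |> classify_trials()
  pref <- rep(c(1, -1), length.out = n_neur)   # half prefer right
  mats <- lapply(setNames(seq_len(n_neur), paste0("n", seq_len(n_neur))),
                 function(j) {
    ramp <- pmax(t + 0.05, 0)  # ramp starting 50 ms before... onset at -0.05
    ch <- ifelse(trials$choice == "R", 1, -1)
    10 + outer(ch * pref[j], ramp) * 20 +
      matrix(rnorm(nrow(trials) * length(t), 0, 0.3), nrow(trials))
  })
  proj <- choice_axis_projection(rates_of(mats, t), trials, seed = 133)
  pre_move <- proj$t_s > 0.05 & proj$t_s < 0.2
  mean_r <- mean(proj$sc[proj$choice == "R" & pre_move])
  mean_l <- mean(proj$sc[proj$choice == "L" & pre_move])
  expect_gt(mean_r - mean_l, 0.3)
})
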