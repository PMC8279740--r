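# Binning arithmetic, baseline and soft normalization formulas, the
# sliding-test facilitated/suppressed classifier, peak latencies, firing
# statistics, and heatmap ordering.

test_that("bin grids follow the full-window-inside convention", {
  expect_equal(bin_centers_in <- seq(-0.2, 0.8, by = 0.02),
               local({
                 tr <- generate_trials(1, "EXE", seed = 1)
                 sp <- data.frame(trial_id = 1, spike_time_s = 1)
                 b <- bin_activity(sp, tr[tr$condition == "Go", ][1, ],
                                   window = c(-0.3, 0.9))
                 b$bin_centers
               }))
  expect_length(bin_centers_in, 51)
})

test_that("single spikes and constant Poisson trains bin correctly", {
  tr <- generate_trials(1, "EXE", seed = 2)
  tr <- tr[tr$condition == "Go", ][1, ]
  sp <- data.frame(trial_id = tr$trial_id, spike_time_s = tr$t_go_signal)
  b <- bin_activity(sp, tr, window = c(-0.1, 0.1))
  # only bins whose 200-ms span covers the event time are nonzero
  covers <- abs(b$bin_centers) <= 0.1 + 1e-12
  expect_true(all(b$rate[1, covers] == 5))
  expect_true(all(b$rate[1, !covers] == 0))

  # constant-rate Poisson: every bin's trial-mean near the true rate
  trials <- generate_trials(20, "EXE", seed = 3, objects = "ring")
  set.seed(4)
  sp2 <- do.call(rbind, lapply(trials$trial_id, function(id) {
    n <- rpois(1, 10 * 4)
    data.frame(trial_id = id, spike_time_s = runif(n, 0, 4))
  }))
  b2 <- bin_activity(sp2, trials, alignment = "t_cue_onset",
                     window = c(-0.3, 0.9))
  m <- colMeans(b2$rate)
  se <- apply(b2$rate, 2, sd) / sqrt(nrow(b2$rate))
  expect_true(all(abs(m - 10) < 3 * se + 1e-9))

  expect_error(bin_activity(sp, trials[0, ]), "empty trial set")
  # No-Go trials lack movement onset and are excluded with a warning
  expect_warning(
    bin_activity(sp2, trials, alignment = "t_movement_onset",
                 window = c(-0.2, 0.2)),
    "missing event")
})

test_that("baseline rates follow the 500-ms pre-cue epoch", {
  tr <- generate_trials(1, "EXE", seed = 5)[1, ]
  sp <- data.frame(trial_id = tr$trial_id,
                   spike_time_s = tr$t_cue_onset - c(0.05, 0.15, 0.25, 0.35, 0.45))
  bl <- compute_baseline(sp, tr)
  expect_equal(bl$per_trial$rate, 10)  # 5 spikes in 0.5 s
  bl0 <- compute_baseline(data.frame(trial_id = integer(0),
                                     spike_time_s = numeric(0)), tr)
  expect_equal(bl0$per_trial$rate, 0)

  # planted 12 spk/s homogeneous baseline recovered within 2 SE
  unit <- data.frame(baseline_rate = 12, mod_sign_exe = 0, mod_sign_obs = 0,
                     modulation_depth = 0, onset_event = "t_movement_onset",
                     onset_latency_s = 0, gain_ring = 1, gain_small_cone = 1,
                     gain_big_cone = 1)
  trials <- generate_trials(10, "EXE", seed = 6, objects = "ring")
  sp2 <- do.call(rbind, lapply(seq_len(nrow(trials)), function(j) {
    st <- generate_spike_train(unit, trials[j, ], seed = j)
    if (!length(st)) return(NULL)
    data.frame(trial_id = trials$trial_id[j], spike_time_s = st)
  }))
  bl2 <- compute_baseline(sp2, trials)
  se <- sd(bl2$per_trial$rate) / sqrt(nrow(bl2$per_trial))
  expect_lt(abs(mean(bl2$per_trial$rate) - 12), 2 * se + 0.5)
})

test_that("soft normalization applies the net/(max + 5) formula", {
  centers <- seq(-0.2, 0.8, by = 0.02)
  rate <- matrix(10, 4, length(centers))
  rate[, 26] <- 25   # one bin at 25 spk/s -> net 15 = the absolute max
  b <- fake_binned(rate, centers)
  nrm <- net_soft_normalize(b, baseline = 10,
                            groups = rep("all", 4))
  expect_equal(as.numeric(nrm[1, 26]), 0.75)  # (25-10)/(15+5)
  expect_equal(as.numeric(nrm[1, 1]), 0)      # baseline-level bins are zero
  expect_true(all(abs(nrm) < 1))

  # identically baseline-level activity: all zeros
  nrm0 <- net_soft_normalize(fake_binned(matrix(10, 4, 51), centers), 10,
                             groups = rep("all", 4))
  expect_true(all(nrm0 == 0))

  # low-rate unit: the +5 constant damps the peak to 1/6
  rate2 <- matrix(2, 4, length(centers)); rate2[, 26] <- 3
  nrm2 <- net_soft_normalize(fake_binned(rate2, centers), 2,
                             groups = rep("all", 4))
  expect_equal(as.numeric(nrm2[1, 26]), 1 / 6)
})

test_that("planted facilitation and suppression are labeled with type-I control", {
  labs_fac <- vapply(1:20, function(s) sim_classified_unit(15, s)$label,
                     character(1))
  expect_gte(mean(labs_fac == "facilitated"), 0.9)

  labs_sup <- vapply(1:20, function(s) sim_classified_unit(-8, s)$label,
                     character(1))
  expect_gte(mean(labs_sup == "suppressed"), 0.9)

  labs_null <- vapply(1:50, function(s) sim_classified_unit(0, s)$label,
                      character(1))
  expect_lte(mean(labs_null != "nonsignificant"), 0.10)
})

test_that("flipping the modulation sign swaps the labels exactly", {
  centers <- seq(-0.2, 0.8, by = 0.02)
  n_trials <- 12
  base <- 10
  jitter <- seq(-2, 2, length.out = n_trials)      # deterministic variation
  mod <- outer(rep(1, n_trials), as.numeric(centers >= 0.1 & centers <= 0.5))
  up <- base + (8 + jitter) * mod
  dn <- base - (8 + jitter) * mod
  baseline <- base + jitter * 0.1
  lab_up <- classify_response(fake_binned(up, centers), baseline)
  lab_dn <- classify_response(fake_binned(dn, centers), baseline)
  expect_equal(lab_up$label, "facilitated")
  expect_equal(lab_dn$label, "suppressed")
  expect_identical(lab_up$significant_bin_mask, lab_dn$significant_bin_mask)
})

test_that("peak times take the window maximum, earliest on ties", {
  centers <- seq(-0.2, 0.8, by = 0.02)
  bump <- exp(-0.5 * ((centers - 0.25) / 0.08)^2)
  expect_lt(abs(peak_time(bump, c(0, 0.6), centers) - 0.25), 0.021)
  rising <- centers  # monotone: last bin of the window
  expect_equal(peak_time(rising, c(0, 0.6), centers), 0.6)
  flat <- rep(1, length(centers))  # ties resolve to the earliest bin
  expect_equal(peak_time(flat, c(0.1, 0.5), centers), 0.1)
  expect_error(peak_time(bump, c(5, 6), centers), "no bins")
})

test_that("firing statistics match constructed and Poisson trains", {
  tr <- generate_trials(1, "EXE", seed = 7)[1, ]
  regular <- data.frame(trial_id = tr$trial_id,
                        spike_time_s = seq(0.1, 3, by = 0.05))
  fs <- firing_statistics(regular, tr)
  expect_equal(fs$isi_cv, 0)
  expect_equal(fs$mean_isi, 0.05)

  set.seed(8)
  pois <- data.frame(trial_id = tr$trial_id,
                     spike_time_s = sort(runif(600, 0, 20)))
  fp <- firing_statistics(pois, tr)
  expect_lt(abs(fp$isi_cv - 1), 3 / sqrt(599))

  doublets <- data.frame(trial_id = tr$trial_id,
                         spike_time_s = sort(c(seq(0.1, 3, 0.1),
                                               seq(0.1, 3, 0.1) + 0.005)))
  fd <- firing_statistics(doublets, tr)
  expect_gt(fd$burst_fraction, 0.45)

  # fewer than 2 spikes: ISI fields absent
  one <- data.frame(trial_id = tr$trial_id, spike_time_s = 0.5)
  expect_true(is.na(firing_statistics(one, tr)$isi_cv))
})

test_that("heatmap ordering is by descending net modulation, stable on ties", {
  centers <- seq(-0.2, 0.8, by = 0.02)
  traces <- rbind(rep(-0.2, 51), rep(0.5, 51), rep(0.5, 51))
  ord <- order_heatmap(traces, centers)
  expect_equal(ord, c(2, 3, 1))  # ties keep input order
})
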