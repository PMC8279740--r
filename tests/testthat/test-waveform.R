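# Average-waveform construction: selection/alignment, +/-3 SD rejection,
# interpolation to the 1000-point grid, QC rules, and feature extraction
# against analytic and brute-force oracles.

template_params <- list(trough_to_peak_ms = 0.38, repolarization_ms = 0.20,
                        amplitude = 100)

test_that("snippet selection aligns minima, caps, and is reproducible", {
  sn <- generate_waveform_snippets(template_params, n_spikes = 50,
                                   noise_sd = 3, seed = 2)
  al <- select_and_align_snippets(sn$snippets, sn$sampling_rate,
                                  n_select = 20, seed = 5)
  expect_equal(nrow(al), 20)
  ctr <- attr(al, "align_index")
  # minimum at (or next to, for edge-shifted crops) the center column
  mins <- apply(al, 1, which.min)
  expect_true(all(abs(mins - ctr) <= 1))

  al_all <- select_and_align_snippets(sn$snippets, sn$sampling_rate,
                                      n_select = 1000, seed = 5)
  expect_equal(nrow(al_all), 50)  # capped at availability

  expect_identical(al, select_and_align_snippets(sn$snippets,
                                                 sn$sampling_rate,
                                                 n_select = 20, seed = 5))
  short <- sn$snippets[, 1:30]
  expect_error(select_and_align_snippets(short, sn$sampling_rate),
               "2.5 ms")
})

test_that("the +/-3 SD rule matches a brute-force check and removes artifacts", {
  # homogeneous noiseless snippets: zero SD, nothing removed
  flat <- matrix(rep(sin(seq(0, 3, length.out = 80)), 10), 10, byrow = TRUE)
  expect_equal(reject_outlier_waveforms(flat)$removed_fraction, 0)

  set.seed(7)
  x <- matrix(rnorm(60 * 40), 60, 40)
  res <- reject_outlier_waveforms(x)
  # independent brute-force application of the rule
  mu <- colMeans(x); s <- apply(x, 2, sd)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    all(abs(x[i, ] - mu) <= 3 * s + 1e-12)
  }, logical(1))
  expect_identical(res$kept, keep)

  # one large single-sample artifact is rejected
  sn <- generate_waveform_snippets(template_params, n_spikes = 200,
                                   noise_sd = 2, seed = 3)
  bad <- sn$snippets
  bad[17, 40] <- bad[17, 40] + 500
  al <- select_and_align_snippets(bad, sn$sampling_rate, seed = 1)
  res2 <- reject_outlier_waveforms(al)
  art_row <- which(attr(al, "selected") == 17)
  expect_false(res2$kept[art_row])

  # generator-default noise is band-limited so removal sits near 10%
  sn3 <- generate_waveform_snippets(template_params, n_spikes = 1500,
                                    noise_sd = 5, seed = 4)
  al3 <- select_and_align_snippets(sn3$snippets, sn3$sampling_rate, seed = 1)
  fr <- reject_outlier_waveforms(al3)$removed_fraction
  expect_gt(fr, 0.03)
  expect_lt(fr, 0.25)
})

test_that("interpolation is exact on matched grids and idempotent", {
  # input already on the 1000-point grid with the minimum centered:
  # output equals the pointwise mean
  dt <- 2.5 / 999
  grid <- (0:999) * dt
  y1 <- waveform_template(grid, 0.30, 0.15, t_trough_ms = 499 * dt)
  y2 <- 0.9 * y1
  fs <- 999 / 2.5 * 1e3
  avg <- average_and_interpolate(rbind(y1, y2), fs)
  expect_equal(as.numeric(avg), as.numeric((y1 + y2) / 2), tolerance = 1e-10)

  # single snippet passes through (itself, interpolated)
  avg1 <- average_and_interpolate(rbind(y1), fs)
  expect_equal(as.numeric(avg1), as.numeric(y1), tolerance = 1e-10)

  # idempotence: re-running on its own output changes nothing
  avg2 <- average_and_interpolate(rbind(as.numeric(avg)), fs)
  expect_equal(as.numeric(avg2), as.numeric(avg), tolerance = 1e-9)

  expect_error(average_and_interpolate(rbind(c(y1[-1], NA)), fs),
               "non-finite")
})

test_that("30 kHz and 40 kHz samplings of one template agree after interpolation", {
  make_avg <- function(fs) {
    n <- floor(3e-3 * fs) + 1
    t_ms <- (seq_len(n) - 1) / fs * 1e3
    y <- waveform_template(t_ms, 0.38, 0.20, t_trough_ms = 1.5)
    al <- select_and_align_snippets(rbind(y, y), fs, seed = 1)
    average_and_interpolate(al)
  }
  a30 <- make_avg(30000)
  a40 <- make_avg(40000)
  trough_depth <- abs(min(a30))
  expect_lt(max(abs(as.numeric(a30) - as.numeric(a40))), 0.01 * trough_depth)
})

test_that("QC applies the three exclusion rules in order", {
  dt <- 2.5 / 999
  grid <- (0:999) * dt
  clean <- structure(waveform_template(grid, 0.30, 0.15,
                                       t_trough_ms = 499 * dt),
                     dt_ms = dt, align_index = 500L,
                     class = "average_waveform")
  expect_equal(qc_exclude_unit(clean, 1500), "retained")
  expect_equal(qc_exclude_unit(clean, 800), "excluded_min_spikes")

  # pre-trough positive peak at 25% of the trough depth
  pre <- as.numeric(clean)
  pre[100:120] <- pre[100:120] + 25 * exp(-0.5 * ((100:120 - 110) / 4)^2)
  expect_equal(qc_exclude_unit(structure(pre, dt_ms = dt), 1500),
               "excluded_amplitude_ratio")

  # trough shallower than the subsequent peak
  upside <- as.numeric(clean)
  upside[upside > 0] <- upside[upside > 0] * 3
  expect_equal(qc_exclude_unit(structure(upside, dt_ms = dt), 1500),
               "excluded_amplitude_ratio")

  # two extra bumps strictly between trough and largest post-trough peak
  multi <- as.numeric(waveform_template(grid, 1.0, 0.15,
                                        t_trough_ms = 400 * dt))
  bump <- function(y, at, amp) {
    i <- seq(at - 8, at + 8)
    y[i] <- y[i] + amp * exp(-0.5 * ((i - at) / 3)^2)
    y
  }
  multi <- bump(multi, 500, 12)
  multi <- bump(multi, 600, 12)
  expect_equal(qc_exclude_unit(structure(multi, dt_ms = dt), 1500),
               "excluded_multipeak")
})

test_that("features follow sample arithmetic and the Gaussian-lobe oracle", {
  dt <- 2.5 / 999
  grid <- (0:999) * dt
  # trough at sample 500, peak 152 samples later -> 152 * dt =~ 0.380 ms
  y <- waveform_template(grid, 152 * dt, 0.20, t_trough_ms = 499 * dt)
  f <- compute_features(structure(y, dt_ms = dt))
  expect_equal(f$trough_index, 500)
  expect_equal(f$peak_index, 652)
  expect_equal(f$trough_to_peak_ms, 152 * dt, tolerance = 1e-9)

  # post-peak Gaussian lobe with SD sigma: inflection exactly sigma after
  # the peak, so repolarization_time = sigma (numerical second-difference
  # oracle localizes the same crossing)
  for (sigma in c(0.1, 0.2, 0.35)) {
    ys <- waveform_template(grid, 0.3, sigma, t_trough_ms = 499 * dt)
    fs <- compute_features(structure(ys, dt_ms = dt))
    expect_lt(abs(fs$repolarization_ms - sigma), 2 * dt)
    d2 <- diff(ys, differences = 2)
    pk <- fs$peak_index
    k <- which(d2[-1] >= 0 & d2[-length(d2)] < 0)
    k <- k[k >= pk][1]
    expect_lt(abs((k + 1 - pk) * dt - sigma), 2 * dt)
  }

  # monotone rise to the window end: no local maximum, reported distinctly
  ramp <- structure(seq(-1, 1, length.out = 1000), dt_ms = dt)
  expect_error(compute_features(ramp), "no local maximum")
})

test_that("feature ordering and estimation stability hold at default noise", {
  ests <- t(vapply(1:30, function(s) {
    sn <- generate_waveform_snippets(template_params, n_spikes = 500,
                                     noise_sd = 5, seed = s)
    f <- unit_waveform_features(sn$snippets, sn$sampling_rate,
                                n_spikes_total = 1500, seed = s)
    c(f$trough_to_peak_ms, f$repolarization_ms)
  }, numeric(2)))
  # ordering: trough < peak < inflection, i.e. both intervals positive
  expect_true(all(ests > 0))
  # estimate spread below 10 us (0.01 ms)
  expect_lt(sd(ests[, 1]), 0.010)
  # bias from alignment-jitter smoothing stays below half a raw sample period
  expect_lt(abs(mean(ests[, 1]) - 0.38), 0.5 * 1e3 / 30000)
})

test_that("exclusion bookkeeping reports percentages", {
  status <- rep(c("retained", "excluded_min_spikes"), c(9, 1))
  s <- qc_summary(status)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$percent_excluded, 10)
})
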