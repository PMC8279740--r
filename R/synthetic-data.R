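# Synthetic sessions: trial tables, class-structured waveform snippets, and
# condition-dependent inhomogeneous-Poisson spike trains with a planted
# ground-truth record, so every downstream stage can be tested end to end.

#' Generate a randomized trial table for one task block
#'
#' Emulates the Go/No-Go visuomotor paradigm: fixation onset triggers a cue
#' sound, the target object becomes visible 0.8 s later, and after a variable
#' 0.8-1.2 s delay the sound ceases (Go signal). In Go trials the actor
#' reaches, grasps and pulls the object; in No-Go trials no movement occurs,
#' so movement and pulling timestamps are absent.
#'
#' @param n_per_condition trials per (condition x object) cell.
#' @param task `"EXE"` (monkey acts) or `"OBS"` (experimenter acts).
#' @param seed integer seed; identical seeds give identical tables.
#' @param objects object set presented; defaults to the three grip targets.
#' @param conditions condition set, by default Go and No-Go.
#' @return a `data.frame` with one row per trial (randomized order):
#'   `trial_id`, `task`, `condition`, `object`, the event timestamps
#'   `t_fixation_onset`, `t_cue_onset`, `t_object_presentation`,
#'   `t_go_signal`, `t_movement_onset`, `t_pulling_onset` (seconds from
#'   trial start; `NA` for No-Go movement events) and `correct`.
#' @export
generate_trials <- function(n_per_condition, task = c("EXE", "OBS"), seed = 1L,
                            objects = c("ring", "small_cone", "big_cone"),
                            conditions = c("Go", "NoGo")) {
  stopifnot_scalar_count(n_per_condition, "n_per_condition")
  task <- match.arg(task)
  grid <- expand.grid(condition = conditions, object = objects,
                      rep = seq_len(n_per_condition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  with_seed(seed, {
    ord <- sample.int(n)
    grid <- grid[ord, , drop = FALSE]
    t_fix <- runif(n, 0.5, 1.0)  # leaves the 500-ms pre-cue baseline in-span
    t_cue <- t_fix + 0.05                      # cue sound triggered by fixation
    t_obj <- t_cue + 0.8                       # fixed cue-to-object delay
    t_go <- t_obj + runif(n, 0.8, 1.2)         # variable object-to-Go delay
    go <- grid$condition == "Go"
    t_mov <- ifelse(go, t_go + runif(n, 0.25, 0.45), NA_real_)
    t_pull <- ifelse(go, t_mov + runif(n, 0.35, 0.55), NA_real_)
    data.frame(trial_id = seq_len(n), task = task,
               condition = grid$condition, object = grid$object,
               t_fixation_onset = t_fix, t_cue_onset = t_cue,
               t_object_presentation = t_obj, t_go_signal = t_go,
               t_movement_onset = t_mov, t_pulling_onset = t_pull,
               correct = TRUE, stringsAsFactors = FALSE)
  })
}

#' Default waveform-feature distributions of the three cell classes
#'
#' Class means span the narrow-to-broad spiking continuum; within-class SDs
#' are small enough that class means are separated by at least 8 within-class
#' SDs on both features, and draws are truncated to the observable feature
#' ranges (trough-to-peak 0.13-0.58 ms, repolarization 0.0025-0.43 ms).
#'
#' @return a `data.frame` with one row per class: feature means and SDs (ms)
#'   and the mean trough amplitude (arbitrary units).
#' @export
waveform_class_defaults <- function() {
  data.frame(
    class = 1:3,
    trough_to_peak_mean = c(0.20, 0.34, 0.48),
    trough_to_peak_sd = 0.015,
    repolarization_mean = c(0.05, 0.17, 0.30),
    repolarization_sd = 0.015,
    amplitude_mean = c(90, 100, 110)
  )
}

# truncated-normal draw by rejection (bounds are several SD away at defaults)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate ground-truth unit parameters
#'
#' Draws per-unit waveform parameters from the class-conditional defaults,
#' baseline rates (higher for narrow-spiking classes), task-modulation signs
#' with a mirror-like joint structure (jointly facilitated, jointly
#' suppressed, opposite, single-task, or unmodulated), modulation depths,
#' onset latencies relative to a named alignment event, and per-object gain
#' multipliers for object-selective units.
#'
#' @param n_units number of units.
#' @param seed integer seed.
#' @param areas recording areas sampled uniformly per unit.
#' @param class_probs mixing proportions of the three waveform classes.
#' @param p_object_selective probability that a unit's modulation depends on
#'   object identity.
#' @param feature_ranges truncation bounds, `list(trough_to_peak =, repolarization =)`.
#' @return a `data.frame` (the GroundTruth record), one row per unit.
#' @export
generate_units <- function(n_units, seed = 1L,
                           areas = c("AIP", "F5", "F6"),
                           class_probs = c(0.22, 0.28, 0.50),
                           p_object_selective = 0.5,
                           feature_ranges = list(
                             trough_to_peak = c(0.13, 0.58),
                             repolarization = c(0.0025, 0.43))) {
  stopifnot_scalar_count(n_units, "n_units")
  defs <- waveform_class_defaults()
  with_seed(seed, {
    cls <- sample(defs$class, n_units, replace = TRUE, prob = class_probs)
    ttp <- rep_len(NA_real_, n_units)
    rpz <- rep_len(NA_real_, n_units)
    amp <- rep_len(NA_real_, n_units)
    for (k in defs$class) {
      idx <- which(cls == k)
      if (!length(idx)) next
      ttp[idx] <- rtruncnorm1(length(idx), defs$trough_to_peak_mean[k],
                              defs$trough_to_peak_sd[k],
                              feature_ranges$trough_to_peak[1],
                              feature_ranges$trough_to_peak[2])
      rpz[idx] <- rtruncnorm1(length(idx), defs$repolarization_mean[k],
                              defs$repolarization_sd[k],
                              feature_ranges$repolarization[1],
                              feature_ranges$repolarization[2])
      amp[idx] <- rnorm(length(idx), defs$amplitude_mean[k], 8)
    }
    base_mean <- c(14, 10, 6)[cls]
    baseline <- rgamma(n_units, shape = 4, scale = base_mean / 4)
    # joint EXE/OBS modulation-sign patterns (mirror-like structure)
    patterns <- matrix(c(1, 1,   -1, -1,   1, -1,  -1, 1,
                         1, 0,   -1, 0,    0, 1,    0, 0),
                       ncol = 2, byrow = TRUE)
    p_pat <- c(0.30, 0.10, 0.10, 0.05, 0.15, 0.05, 0.05, 0.20)
    pat <- sample(nrow(patterns), n_units, replace = TRUE, prob = p_pat)
    depth <- runif(n_units, 8, 20)
    onset_event <- sample(c("t_movement_onset", "t_object_presentation"),
                          n_units, replace = TRUE, prob = c(0.65, 0.35))
    latency <- runif(n_units, 0.02, 0.20)
    sel <- runif(n_units) < p_object_selective
    gains <- matrix(1, n_units, 3)
    if (any(sel)) {
      base_gain <- c(1.6, 1.0, 0.5)
      for (i in which(sel)) gains[i, ] <- sample(base_gain)
    }
    data.frame(
      unit_id = sprintf("u%03d", seq_len(n_units)),
      area = sample(areas, n_units, replace = TRUE),
      true_class = cls,
      trough_to_peak_ms = ttp, repolarization_ms = rpz, amplitude = amp,
      baseline_rate = baseline,
      mod_sign_exe = patterns[pat, 1], mod_sign_obs = patterns[pat, 2],
      modulation_depth = depth,
      onset_event = onset_event, onset_latency_s = latency,
      gain_ring = gains[, 1], gain_small_cone = gains[, 2],
      gain_big_cone = gains[, 3],
      stringsAsFactors = FALSE)
  })
}

#' Analytic spike-waveform template
#'
#' Piecewise-smooth biphasic template with direct analytic control of both
#' waveform features: a half-Gaussian descent into the trough, a half-cosine
#' rise from trough to peak whose extrema sit exactly at the trough and peak
#' times, and a Gaussian post-peak decay whose SD equals the repolarization
#' time, so the inflection point (zero of the second derivative) falls
#' exactly one repolarization time after the peak.
#'
#' @param t_ms evaluation times in ms.
#' @param trough_to_peak_ms,repolarization_ms target features (ms).
#' @param amplitude trough depth (positive number; trough value is
#'   `-amplitude`).
#' @param t_trough_ms trough position (ms).
#' @param peak_ratio peak amplitude as a fraction of trough depth (< 1 and
#'   pre-trough activity 0, so a clean template passes the amplitude-ratio QC).
#' @param pre_sd_ms SD of the descent into the trough (ms).
#' @return numeric vector of template values at `t_ms`.
#' @export
waveform_template <- function(t_ms, trough_to_peak_ms, repolarization_ms,
                              amplitude = 100, t_trough_ms = 1.25,
                              peak_ratio = 0.5, pre_sd_ms = 0.15) {
  a_p <- peak_ratio * amplitude
  t_pk <- t_trough_ms + trough_to_peak_ms
  y <- numeric(length(t_ms))
  pre <- t_ms <= t_trough_ms
  y[pre] <- -amplitude * exp(-0.5 * ((t_ms[pre] - t_trough_ms) / pre_sd_ms)^2)
  mid <- t_ms > t_trough_ms & t_ms < t_pk
  y[mid] <- -amplitude + (amplitude + a_p) *
    (1 - cos(pi * (t_ms[mid] - t_trough_ms) / trough_to_peak_ms)) / 2
  post <- t_ms >= t_pk
  y[post] <- a_p * exp(-0.5 * ((t_ms[post] - t_pk) / repolarization_ms)^2)
  y
}

#' Generate noisy waveform snippets for one unit
#'
#' Repeats the unit's analytic template and adds band-limited Gaussian noise
#' (white noise convolved with a one-sample-SD Gaussian kernel, then rescaled
#' to `noise_sd`), emulating filtered extracellular snippets.
#'
#' @param params numeric vector or list with `trough_to_peak_ms`,
#'   `repolarization_ms` and optionally `amplitude`.
#' @param n_spikes number of snippets.
#' @param noise_sd noise SD in the template's amplitude units; must be >= 0.
#' @param seed integer seed.
#' @param sampling_rate sampling rate in Hz.
#' @param duration_ms snippet duration (>= 2.5 ms), trough at the center.
#' @return a list with `snippets` (`n_spikes` x samples matrix),
#'   `sampling_rate`, and `t_ms` (sample times).
#' @export
generate_waveform_snippets <- function(params, n_spikes, noise_sd = 5,
                                       seed = 1L, sampling_rate = 30000,
                                       duration_ms = 3) {
  stopifnot_scalar_count(n_spikes, "n_spikes")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (duration_ms < 2.5) stop("snippet duration must be at least 2.5 ms")
  params <- as.list(params)
  amp <- if (!is.null(params$amplitude)) params$amplitude else 100
  n_samp <- floor(duration_ms * 1e-3 * sampling_rate) + 1L
  t_ms <- (seq_len(n_samp) - 1) / sampling_rate * 1e3
  tmpl <- waveform_template(t_ms, params$trough_to_peak_ms,
                            params$repolarization_ms, amplitude = amp,
                            t_trough_ms = duration_ms / 2)
  snips <- with_seed(seed, {
    if (noise_sd == 0) {
      matrix(rep(tmpl, each = n_spikes), n_spikes, n_samp)
    } else {
      k <- exp(-0.5 * (-3:3)^2); k <- k / sqrt(sum(k^2))  # unit-power kernel
      noise <- matrix(rnorm(n_spikes * (n_samp + 6)), n_spikes)
      sm <- t(apply(noise, 1, function(z) {
        as.numeric(stats::filter(z, k, sides = 2))[4:(n_samp + 3)]
      }))
      matrix(rep(tmpl, each = n_spikes), n_spikes, n_samp) + noise_sd * sm
    }
  })
  list(snippets = snips, sampling_rate = sampling_rate, t_ms = t_ms)
}

#' Instantaneous firing-rate profile of a ground-truth unit in one trial
#'
#' Baseline rate plus epoch-locked modulation: a plateau of the planted depth
#' (object gain applied, sign per task) that rises as a half-Gaussian ramp at
#' the planted latency after the alignment event and falls symmetrically
#' after `duration`. Rates are clipped at zero. Units aligned to movement
#' onset are silent of modulation in No-Go trials, where no movement occurs.
#'
#' @param unit one row of the ground-truth table.
#' @param trial one row of a trial table.
#' @param times evaluation times (s, relative to trial start).
#' @param rise ramp SD (s).
#' @param duration plateau duration (s).
#' @return numeric vector of rates (spk/s) at `times`.
#' @export
rate_profile <- function(unit, trial, times, rise = 0.1, duration = 0.6) {
  s <- if (trial$task == "EXE") unit$mod_sign_exe else unit$mod_sign_obs
  base <- unit$baseline_rate
  t_ev <- trial[[unit$onset_event]]
  if (s == 0 || is.na(t_ev) || unit$modulation_depth == 0)
    return(pmax(rep(base, length(times)), 0))
  gain <- switch(as.character(trial$object),
                 ring = unit$gain_ring,
                 small_cone = unit$gain_small_cone,
                 big_cone = unit$gain_big_cone, 1)
  t_on <- t_ev + unit$onset_latency_s
  t_off <- t_on + duration
  g <- ifelse(times < t_on, exp(-0.5 * ((times - t_on) / rise)^2),
              ifelse(times <= t_off, 1,
                     exp(-0.5 * ((times - t_off) / rise)^2)))
  pmax(base + s * unit$modulation_depth * gain * g, 0)
}

#' Sample a spike train from a unit's rate profile by thinning
#'
#' Exact sampling of the inhomogeneous Poisson process: candidate events are
#' drawn homogeneously at the profile's upper bound and retained with
#' probability rate/bound.
#'
#' @param unit,trial single rows as in [rate_profile()].
#' @param seed integer seed.
#' @param t_end end of the simulated span (s); defaults to 1 s after the last
#'   trial event.
#' @inheritParams rate_profile
#' @return sorted numeric vector of spike times (s, relative to trial start).
#' @export
generate_spike_train <- function(unit, trial, seed = 1L, t_end = NULL,
                                 rise = 0.1, duration = 0.6) {
  if (is.null(t_end)) {
    evs <- unlist(trial[grep("^t_", names(trial))])
    t_end <- max(evs, na.rm = TRUE) + 1
  }
  gmax <- max(unit$gain_ring, unit$gain_small_cone, unit$gain_big_cone)
  rmax <- unit$baseline_rate + abs(unit$modulation_depth) * gmax
  if (rmax <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1, rmax * t_end)
    if (n_cand == 0) {
      numeric(0)
    } else {
      tt <- sort(runif(n_cand, 0, t_end))
      r <- rate_profile(unit, trial, tt, rise = rise, duration = duration)
      if (any(r < 0)) stop("internal error: negative rate after clipping")
      tt[runif(n_cand) < r / rmax]
    }
  })
}

#' Simulate a complete recording session
#'
#' Trial tables for both tasks, spike trains for every unit and trial, one
#' snippet set per unit, and the planted ground truth.
#'
#' @param n_units number of units.
#' @param n_per_condition trials per (condition x object) cell and task.
#' @param seed session seed; all per-unit/per-trial streams derive from it.
#' @param n_snippets waveform snippets per unit.
#' @param noise_sd snippet noise SD (amplitude units).
#' @param ... passed to [generate_units()].
#' @return a list of class `mirrorpop_session`: `trials` (both tasks,
#'   globally unique `trial_id`), `spikes` (`unit_id`, `area`, `trial_id`,
#'   `spike_time_s`), `snippets` (named list per unit), `ground_truth`.
#' @export
simulate_session <- function(n_units = 30, n_per_condition = 10, seed = 1L,
                             n_snippets = 1500, noise_sd = 5, ...) {
  units <- generate_units(n_units, seed = derive_seed(seed, 1), ...)
  tr_exe <- generate_trials(n_per_condition, "EXE", seed = derive_seed(seed, 2))
  tr_obs <- generate_trials(n_per_condition, "OBS", seed = derive_seed(seed, 3))
  tr_obs$trial_id <- tr_obs$trial_id + nrow(tr_exe)
  trials <- rbind(tr_exe, tr_obs)
  spikes <- vector("list", n_units)
  snippets <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    u <- units[i, ]
    st <- lapply(seq_len(nrow(trials)), function(j) {
      s <- generate_spike_train(u, trials[j, ],
                                seed = derive_seed(seed, 10L + i, j))
      if (length(s) == 0) return(NULL)
      data.frame(unit_id = u$unit_id, area = u$area,
                 trial_id = trials$trial_id[j], spike_time_s = s,
                 stringsAsFactors = FALSE)
    })
    spikes[[i]] <- do.call(rbind, st)
    snippets[[i]] <- generate_waveform_snippets(
      list(trough_to_peak_ms = u$trough_to_peak_ms,
           repolarization_ms = u$repolarization_ms, amplitude = u$amplitude),
      n_spikes = n_snippets, noise_sd = noise_sd,
      seed = derive_seed(seed, 5000L + i))
  }
  names(snippets) <- units$unit_id
  out <- list(trials = trials, spikes = do.call(rbind, spikes),
              snippets = snippets, ground_truth = units, seed = seed)
  class(out) <- "mirrorpop_session"
  out
}
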