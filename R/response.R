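# Trial-aligned binning, baseline-referenced soft normalization,
# facilitated/suppressed labeling with the sliding-test + consecutive-bin
# rule, peak latencies, firing statistics, and heatmap ordering.

#' Bin one unit's activity around an alignment event
#'
#' Average firing rate in 200-ms windows advanced by 20 ms; the value is
#' assigned to the window center, and only windows fully inside
#' `window` are used (so a [-0.3, 0.9] s window yields 51 bins centered
#' -0.2..0.8 s). Trials missing the alignment event are excluded with a
#' warning.
#'
#' @param spikes data.frame with `trial_id` and `spike_time_s` for one unit
#'   (times relative to trial start).
#' @param trials trial table (rows define the trial set; trials without
#'   spikes get zero rates).
#' @param alignment name of the event column to align to.
#' @param window analysis span (s, relative to the event).
#' @param bin_width,step bin width and step (s).
#' @return a `binned_activity` object: list with `rate` and `counts`
#'   (trials x bins), `bin_centers`, `bin_width`, `step`, `alignment`, and
#'   the trial metadata columns.
#' @export
bin_activity <- function(spikes, trials, alignment = "t_go_signal",
                         window = c(-0.3, 0.9), bin_width = 0.2,
                         step = 0.02) {
  if (nrow(trials) == 0) stop("empty trial set")
  has_ev <- is.finite(trials[[alignment]])
  if (!all(has_ev)) {
    warning(sprintf("%d trial(s) missing event '%s' excluded",
                    sum(!has_ev), alignment))
    trials <- trials[has_ev, , drop = FALSE]
    if (nrow(trials) == 0) stop("no trial has the alignment event")
  }
  centers <- bin_centers_in(window, bin_width, step)
  nb <- length(centers)
  counts <- matrix(0, nrow(trials), nb)
  sp_by_trial <- split(spikes$spike_time_s, spikes$trial_id)
  for (i in seq_len(nrow(trials))) {
    st <- sp_by_trial[[as.character(trials$trial_id[i])]]
    if (is.null(st) || !length(st)) next
    rel <- sort(st - trials[[alignment]][i])
    hi <- findInterval(centers + bin_width / 2 - 1e-12, rel)
    lo <- findInterval(centers - bin_width / 2 - 1e-12, rel)
    counts[i, ] <- hi - lo
  }
  structure(list(rate = counts / bin_width, counts = counts,
                 bin_centers = centers, bin_width = bin_width, step = step,
                 alignment = alignment, trial_id = trials$trial_id,
                 task = trials$task, condition = trials$condition,
                 object = trials$object),
            class = "binned_activity")
}

#' Baseline firing rate in the pre-cue epoch
#'
#' Per-trial rate in the epoch (default the 500 ms preceding cue-sound
#' onset), with task-specific means computed separately for EXE and OBS.
#'
#' @param spikes,trials as in [bin_activity()].
#' @param epoch epoch relative to the alignment event (s).
#' @param alignment event column (default cue onset).
#' @return list with `per_trial` (data.frame: `trial_id`, `task`, `rate`)
#'   and `mean_by_task` (named vector).
#' @export
compute_baseline <- function(spikes, trials, epoch = c(-0.5, 0),
                             alignment = "t_cue_onset") {
  ok <- is.finite(trials[[alignment]])
  drop <- trials[[alignment]][ok] + epoch[1] < 0
  if (any(drop))
    warning(sprintf("%d trial(s) with baseline epoch before recording start dropped",
                    sum(drop)))
  tr <- trials[ok, , drop = FALSE][!drop, , drop = FALSE]
  sp_by_trial <- split(spikes$spike_time_s, spikes$trial_id)
  rate <- vapply(seq_len(nrow(tr)), function(i) {
    st <- sp_by_trial[[as.character(tr$trial_id[i])]]
    if (is.null(st)) return(0)
    t0 <- tr[[alignment]][i]
    sum(st >= t0 + epoch[1] & st < t0 + epoch[2]) / diff(epoch)
  }, numeric(1))
  per_trial <- data.frame(trial_id = tr$trial_id, task = tr$task, rate = rate)
  list(per_trial = per_trial,
       mean_by_task = tapply(per_trial$rate, per_trial$task, mean))
}

#' Net soft-normalized condition traces
#'
#' Subtracts the baseline from the condition-mean rate at each bin and
#' divides by the absolute maximum of the net activity across all conditions
#' plus 5 spk/s, so traces lie strictly inside (-1, 1) and low-rate units
#' are damped.
#'
#' @param binned a `binned_activity`.
#' @param baseline scalar baseline rate (spk/s) for the matching task.
#' @param groups factor over trials defining the conditions (default the
#'   stored `condition`).
#' @param soft softening constant (spk/s, default 5).
#' @return matrix conditions x bins with attributes `bin_centers` and
#'   `denominator`.
#' @export
net_soft_normalize <- function(binned, baseline, groups = NULL, soft = 5) {
  if (is.null(groups)) groups <- binned$condition
  groups <- factor(groups)
  cond_mean <- do.call(rbind, lapply(levels(groups), function(g) {
    colMeans(binned$rate[groups == g, , drop = FALSE])
  }))
  rownames(cond_mean) <- levels(groups)
  net <- cond_mean - baseline
  denom <- max(abs(net)) + soft
  structure(net / denom, bin_centers = binned$bin_centers,
            denominator = denom, baseline = baseline)
}

#' Classify a unit as facilitated, suppressed, or nonsignificant
#'
#' The sign of the mean net modulation over the analysis span (by default
#' -300..+900 ms around the Go signal) fixes the direction; each bin is then
#' tested against the trialwise baseline with a one-tailed paired t test
#' (p < `alpha`, uncorrected), and the unit is labeled facilitated or
#' suppressed only if at least `min_consec` consecutive bins are significant.
#'
#' @param binned a `binned_activity` around the Go signal.
#' @param baseline_per_trial per-trial baseline rates, in the order of the
#'   trials stored in `binned` (a `compute_baseline()` `per_trial` frame is
#'   matched on `trial_id`).
#' @param alpha per-bin significance level (default 0.05).
#' @param min_consec consecutive-bin requirement (default 5).
#' @return a `response_label`: list with `label`, `sign`,
#'   `significant_bin_mask`, `p_values`, `bin_centers`.
#' @export
classify_response <- function(binned, baseline_per_trial, alpha = 0.05,
                              min_consec = 5L) {
  if (is.data.frame(baseline_per_trial)) {
    m <- match(binned$trial_id, baseline_per_trial$trial_id)
    if (anyNA(m)) stop("baseline missing for some binned trials")
    baseline_per_trial <- baseline_per_trial$rate[m]
  }
  rate <- binned$rate
  if (nrow(rate) < 2) stop("at least 2 trials required")
  net <- sweep(rate, 1, baseline_per_trial)
  sgn <- sign(mean(net))
  if (sgn == 0) {
    mask <- rep(FALSE, ncol(rate))
    pv <- rep(NA_real_, ncol(rate))
  } else {
    alt <- if (sgn > 0) "greater" else "less"
    pv <- vapply(seq_len(ncol(rate)), function(b) {
      d <- net[, b]
      if (sd(d) == 0) return(NA_real_)  # t undefined; bin nonsignificant
      t.test(rate[, b], baseline_per_trial, paired = TRUE,
             alternative = alt)$p.value
    }, numeric(1))
    mask <- !is.na(pv) & pv < alpha
  }
  sig_mask <- runs_at_least(mask, min_consec)
  label <- if (any(sig_mask)) {
    if (sgn > 0) "facilitated" else "suppressed"
  } else "nonsignificant"
  structure(list(label = label,
                 sign = if (label == "nonsignificant") 0L else as.integer(sgn),
                 significant_bin_mask = sig_mask, p_values = pv,
                 bin_centers = binned$bin_centers),
            class = "response_label")
}

#' Peak time of a condition-averaged net trace
#'
#' Time of the trace maximum within the window (object epoch: 100-500 ms
#' after object presentation; Go epoch: 0-600 ms after the Go signal);
#' the earliest bin wins on ties.
#'
#' @param trace numeric vector (a single trace) with bin centers supplied
#'   via `bin_centers` or an attribute.
#' @param window epoch `c(t0, t1)` in s relative to the trace's alignment.
#' @param bin_centers bin centers of `trace`.
#' @return peak time in seconds.
#' @export
peak_time <- function(trace, window, bin_centers = attr(trace, "bin_centers")) {
  if (is.null(bin_centers)) stop("`bin_centers` required")
  inside <- bin_centers >= window[1] - 1e-12 & bin_centers <= window[2] + 1e-12
  if (!any(inside)) stop("no bins inside the window")
  tc <- bin_centers[inside]
  tv <- trace[inside]
  tc[which.max(tv)]
}

#' Baseline and interspike-interval statistics of one unit
#'
#' Baseline rate from the pre-cue epoch; mean ISI, ISI coefficient of
#' variation, and burst fraction (proportion of ISIs below 10 ms, a declared
#' surrogate burst metric) over within-trial ISIs pooled across trials.
#'
#' @param spikes,trials as in [bin_activity()].
#' @param baseline_epoch,baseline_alignment baseline definition.
#' @param burst_threshold_s ISI threshold counting as a burst (default 0.01).
#' @return list with `baseline_rate`, `mean_isi`, `isi_cv`, `burst_fraction`
#'   (ISI fields `NA` with fewer than 2 spikes in every trial).
#' @export
firing_statistics <- function(spikes, trials, baseline_epoch = c(-0.5, 0),
                              baseline_alignment = "t_cue_onset",
                              burst_threshold_s = 0.01) {
  bl <- compute_baseline(spikes, trials, epoch = baseline_epoch,
                         alignment = baseline_alignment)
  isis <- unlist(lapply(split(spikes$spike_time_s, spikes$trial_id),
                        function(st) if (length(st) >= 2) diff(sort(st)) else NULL))
  if (is.null(isis) || length(isis) == 0) {
    mean_isi <- isi_cv <- burst <- NA_real_
  } else {
    mean_isi <- mean(isis)
    isi_cv <- sd(isis) / mean_isi
    burst <- mean(isis < burst_threshold_s)
  }
  list(baseline_rate = mean(bl$per_trial$rate), mean_isi = mean_isi,
       isi_cv = isi_cv, burst_fraction = burst)
}

#' Heatmap row ordering by net modulation magnitude
#'
#' Descending sort of units by their mean net normalized activity within the
#' window; ties preserve input order. EXE and OBS orderings are computed by
#' separate calls on their own trace matrices.
#'
#' @param traces units x bins matrix of net soft-normalized traces.
#' @param bin_centers bin centers (s).
#' @param window span over which the mean modulation is taken.
#' @return integer ordering indices (first = strongest facilitation).
#' @export
order_heatmap <- function(traces, bin_centers, window = c(-0.3, 0.9)) {
  inside <- bin_centers >= window[1] - 1e-12 & bin_centers <= window[2] + 1e-12
  score <- rowMeans(traces[, inside, drop = FALSE])
  order(-score)
}
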