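# Mutual Modulation Depth: per-bin product of a unit's net soft-normalized
# execution and observation activity around movement onset, with a
# first-bins-referenced significance test and class/area summaries.

#' Mutual Modulation Depth time course
#'
#' `MMD_n(t) = EXE_n(t) * OBS_n(t)`, the elementwise product of the net
#' (500 ms before the Go signal) soft-normalized activity of each unit in
#' the two tasks on an identical bin grid (by default 200-ms bins stepped
#' 20 ms over -500..+700 ms around movement onset). Positive values mark
#' congruent modulation in the two tasks (jointly facilitated or jointly
#' suppressed), negative values opposite modulation, and values near zero a
#' lack of modulation in at least one task. The theoretical extremes are
#' +1 and -1, attained only for unit-magnitude normalized activity.
#'
#' @param exe,obs net soft-normalized traces, either vectors or units x
#'   bins matrices on the same grid.
#' @param bin_centers optional grid; taken from attributes when present and
#'   checked for agreement between the two inputs.
#' @return MMD values with the same shape as the inputs, `bin_centers`
#'   attribute carried over.
#' @export
mmd_timecourse <- function(exe, obs, bin_centers = NULL) {
  bc_e <- attr(exe, "bin_centers"); bc_o <- attr(obs, "bin_centers")
  if (!is.null(bc_e) && !is.null(bc_o) &&
      (length(bc_e) != length(bc_o) || any(abs(bc_e - bc_o) > 1e-9)))
    stop("EXE and OBS traces are on different bin grids")
  if (length(exe) != length(obs)) stop("EXE and OBS traces differ in shape")
  out <- unclass(exe) * unclass(obs)
  attr(out, "bin_centers") <- if (!is.null(bin_centers)) bin_centers else bc_e
  out
}

#' Significance mask for an MMD increase during movement
#'
#' The reference for each unit is the mean of its first `n_ref` bins; each
#' bin is compared against the reference with a one-tailed paired t test
#' across units (increase only), and only runs of at least `min_consec`
#' consecutive significant bins are kept.
#'
#' @param mmd units x bins MMD matrix for one group.
#' @param alpha per-bin significance level; default 0.01, with 0.05
#'   available as the more permissive setting.
#' @param n_ref number of leading reference bins (default 5).
#' @param min_consec consecutive-bin requirement (default 5).
#' @return list with `mask` (logical per bin; all-`NA` with a warning for a
#'   single-unit group), `p_values`, `reference` (per-unit reference value).
#' @export
mmd_significance <- function(mmd, alpha = 0.01, n_ref = 5L, min_consec = 5L) {
  mmd <- as.matrix(mmd)
  B <- ncol(mmd)
  ref <- rowMeans(mmd[, seq_len(n_ref), drop = FALSE])
  if (nrow(mmd) < 2) {
    warning("group of fewer than 2 units: significance mask undefined")
    return(list(mask = rep(NA, B), p_values = rep(NA_real_, B),
                reference = ref))
  }
  pv <- vapply(seq_len(B), function(b) {
    d <- mmd[, b] - ref
    if (sd(d) == 0) return(NA_real_)
    t.test(mmd[, b], ref, paired = TRUE, alternative = "greater")$p.value
  }, numeric(1))
  mask <- runs_at_least(!is.na(pv) & pv < alpha, min_consec)
  list(mask = mask, p_values = pv, reference = ref)
}

#' Summarize MMD by cell class and area
#'
#' Mean MMD curves per class, per area, and per (class x area) cell, plus
#' scalar class means +/- SE (across units, of each unit's time-averaged
#' MMD). The factorial class x area comparison itself is left to standard
#' analysis-of-variance routines; this function exports their input
#' (`unit_means`).
#'
#' @param mmd units x bins MMD matrix.
#' @param class,area per-unit labels.
#' @return list with `class_means` (data.frame class/mean/se/n),
#'   `area_means`, `curves_by_class`, `curves_by_area`, `curves_by_group`
#'   (named "class.area"), and `unit_means`.
#' @export
mmd_summary <- function(mmd, class, area) {
  mmd <- as.matrix(mmd)
  unit_mean <- rowMeans(mmd)
  summarize <- function(g) {
    g <- factor(g)
    do.call(rbind, lapply(levels(g), function(lv) {
      v <- unit_mean[g == lv]
      data.frame(group = lv, mean = mean(v),
                 se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
                 n = length(v))
    }))
  }
  curves <- function(g) {
    g <- factor(g)
    out <- lapply(levels(g), function(lv)
      colMeans(mmd[g == lv, , drop = FALSE]))
    names(out) <- levels(g)
    out
  }
  grp <- interaction(class, area, drop = FALSE)
  present <- levels(grp)[levels(grp) %in% as.character(grp)]
  if (length(present) < nlevels(grp))
    warning("empty class x area cells omitted: ",
            paste(setdiff(levels(grp), present), collapse = ", "))
  grp <- factor(as.character(grp), levels = present)
  list(class_means = summarize(class), area_means = summarize(area),
       curves_by_class = curves(class), curves_by_area = curves(area),
       curves_by_group = curves(grp),
       unit_means = data.frame(class = class, area = area,
                               mmd = unit_mean))
}

#' Net soft-normalized traces aligned to movement onset for MMD
#'
#' Convenience builder: bins one unit's Go-trial activity in both tasks
#' around movement onset (-500..+700 ms), subtracts the task-specific
#' baseline taken in the 500 ms before the Go signal (the MMD-specific
#' reference, distinct from the pre-cue baseline), and soft-normalizes EXE
#' and OBS with their own absolute-maximum denominators.
#'
#' @param spikes one unit's spikes (`trial_id`, `spike_time_s`).
#' @param trials full trial table (both tasks).
#' @param window span around movement onset (s).
#' @param bin_width,step binning (s).
#' @param soft softening constant (spk/s).
#' @return list with `exe` and `obs` trace vectors (attributes
#'   `bin_centers`) and the two baselines.
#' @export
mmd_traces <- function(spikes, trials, window = c(-0.5, 0.7),
                       bin_width = 0.2, step = 0.02, soft = 5) {
  go <- trials[trials$condition == "Go", , drop = FALSE]
  one_task <- function(task) {
    tr <- go[go$task == task, , drop = FALSE]
    b <- bin_activity(spikes, tr, alignment = "t_movement_onset",
                      window = window, bin_width = bin_width, step = step)
    bl <- compute_baseline(spikes, tr, epoch = c(-0.5, 0),
                           alignment = "t_go_signal")
    tr_mean <- net_soft_normalize(b, mean(bl$per_trial$rate),
                                  groups = rep("all", nrow(b$rate)),
                                  soft = soft)
    structure(as.numeric(tr_mean[1, ]), bin_centers = b$bin_centers,
              baseline = mean(bl$per_trial$rate))
  }
  exe <- one_task("EXE")
  obs <- one_task("OBS")
  list(exe = exe, obs = obs,
       baseline_exe = attr(exe, "baseline"), baseline_obs = attr(obs, "baseline"))
}
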