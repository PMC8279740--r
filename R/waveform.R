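# Average-waveform construction and feature extraction: snippet selection and
# alignment, pointwise +/-3 SD outlier rejection, spline interpolation to a
# 1000-point / 2.5-ms grid, the three unit-exclusion rules, and the
# trough-to-peak / repolarization-time features.

WAVEFORM_N <- 1000L
WAVEFORM_SPAN_MS <- 2.5

#' Randomly select snippets and align them on their absolute minimum
#'
#' Each selected snippet is windowed to 2.5 ms centered on its absolute
#' minimum. Selection is without replacement; when fewer than `n_select`
#' snippets are available all of them are returned (the min-spike exclusion
#' applies downstream).
#'
#' @param snippets matrix, one snippet per row.
#' @param sampling_rate sampling rate in Hz.
#' @param n_select number of snippets to select (default 1000).
#' @param seed integer seed.
#' @return matrix of aligned snippets (rows) spanning 2.5 ms, with attributes
#'   `sampling_rate` and `align_index` (column of the minimum).
#' @export
select_and_align_snippets <- function(snippets, sampling_rate,
                                      n_select = 1000L, seed = 1L) {
  snippets <- as.matrix(snippets)
  n_samp <- ncol(snippets)
  dur_ms <- (n_samp - 1) / sampling_rate * 1e3
  if (dur_ms < WAVEFORM_SPAN_MS - 1e-9)
    stop(sprintf("snippets span %.3f ms; at least %.1f ms required",
                 dur_ms, WAVEFORM_SPAN_MS))
  half <- floor(WAVEFORM_SPAN_MS / 2 * 1e-3 * sampling_rate)
  n_take <- min(nrow(snippets), n_select)
  idx <- with_seed(seed, sample.int(nrow(snippets), n_take))
  out <- matrix(NA_real_, n_take, 2L * half + 1L)
  for (r in seq_len(n_take)) {
    x <- snippets[idx[r], ]
    i0 <- which.min(x)
    lo <- i0 - half
    hi <- i0 + half
    # shift the crop when the minimum sits too close to an edge
    if (lo < 1) { hi <- hi + (1L - lo); lo <- 1L }
    if (hi > n_samp) { lo <- lo - (hi - n_samp); hi <- n_samp }
    out[r, ] <- x[lo:hi]
  }
  structure(out, sampling_rate = sampling_rate, align_index = half + 1L,
            selected = idx)
}

#' Reject snippets exceeding +/-3 SD from the average at any sample
#'
#' Single pass: the pointwise mean and SD are computed once over all
#' snippets, and a snippet is removed if it exceeds the band at any sample.
#' A zero-SD sample never rejects (no exceedance is possible there).
#'
#' @param aligned matrix of aligned snippets (rows).
#' @param n_sd rejection band half-width in SDs (default 3).
#' @return list with `retained` (matrix), `removed_fraction`, and `kept`
#'   (logical index into the input rows).
#' @export
reject_outlier_waveforms <- function(aligned, n_sd = 3) {
  if (nrow(aligned) < 2) stop("at least 2 snippets required")
  mu <- colMeans(aligned)
  s <- apply(aligned, 2, sd)
  dev <- abs(sweep(aligned, 2, mu))
  lim <- n_sd * s
  keep <- apply(dev, 1, function(d) all(d <= lim + 1e-12))
  if (!any(keep)) stop("all snippets rejected by the +/-3 SD rule")
  ret <- aligned[keep, , drop = FALSE]
  attributes(ret)$sampling_rate <- attr(aligned, "sampling_rate")
  list(retained = ret, removed_fraction = mean(!keep), kept = keep)
}

# spline-resample one snippet to the 1000-point grid, realigned so that its
# absolute minimum sits at the center sample
interp_align_one <- function(x, sampling_rate) {
  n <- length(x)
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1e3
  f <- splinefun(t_ms, x, method = "natural")
  dt <- WAVEFORM_SPAN_MS / (WAVEFORM_N - 1)
  center <- 500L
  grid0 <- t_ms[which.min(x)] + (seq_len(WAVEFORM_N) - center) * dt
  y <- f(grid0)
  # shift until the discrete minimum is the center sample (usually 1 pass)
  for (pass in 1:5) {
    i0 <- which.min(y)
    if (i0 == center) break
    grid0 <- grid0 + (i0 - center) * dt
    y <- f(grid0)
  }
  y
}

#' Average retained snippets on the 1000-point, 2.5-ms grid
#'
#' Cubic-spline interpolation of each snippet to 1000 points over 2.5 ms
#' (whatever the original sampling rate), realignment to the absolute
#' minimum, and pointwise averaging.
#'
#' @param retained matrix of retained aligned snippets, or the list returned
#'   by [reject_outlier_waveforms()].
#' @param sampling_rate sampling rate in Hz (taken from the input's
#'   attributes when present).
#' @return an `average_waveform` object: numeric vector of 1000 samples with
#'   attributes `dt_ms` (2.5/999) and `align_index` (position of the global
#'   minimum).
#' @export
average_and_interpolate <- function(retained, sampling_rate = NULL) {
  if (is.list(retained) && !is.null(retained$retained))
    retained <- retained$retained
  retained <- as.matrix(retained)
  if (is.null(sampling_rate))
    sampling_rate <- attr(retained, "sampling_rate")
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  if (!all(is.finite(retained))) stop("non-finite snippet values")
  interp <- t(apply(retained, 1, interp_align_one,
                    sampling_rate = sampling_rate))
  avg <- colMeans(interp)
  structure(avg, dt_ms = WAVEFORM_SPAN_MS / (WAVEFORM_N - 1),
            align_index = which.min(avg), class = "average_waveform")
}

# strict three-point local maxima, plateaus resolved to the earliest sample
local_maxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Apply the three unit-exclusion rules to an average waveform
#'
#' In order: (1) fewer than 1000 total spikes; (2) very noisy ("multipeak")
#' waveform, i.e. more than one local maximum strictly between the main
#' trough and the largest post-trough peak; (3) a main trough amplitude
#' smaller than the subsequent peak, or a pre-trough peak greater than 20% of
#' the trough depth (likely axonal waveforms). The first failing rule is
#' reported.
#'
#' @param avg an `average_waveform`.
#' @param n_spikes_total total spikes recorded for the unit.
#' @param min_spikes minimum spike count (default 1000).
#' @return one of `"retained"`, `"excluded_min_spikes"`,
#'   `"excluded_multipeak"`, `"excluded_amplitude_ratio"`.
#' @export
qc_exclude_unit <- function(avg, n_spikes_total, min_spikes = 1000L) {
  if (n_spikes_total < min_spikes) return("excluded_min_spikes")
  y <- as.numeric(avg)
  i0 <- which.min(y)
  trough_depth <- abs(y[i0])
  post <- y[(i0 + 1L):length(y)]
  ipk <- i0 + which.max(post)
  inner <- local_maxima(y)
  inner <- inner[inner > i0 & inner < ipk]
  if (length(inner) > 1) return("excluded_multipeak")
  if (trough_depth < y[ipk]) return("excluded_amplitude_ratio")
  if (i0 > 1 && max(y[1:(i0 - 1L)]) > 0.2 * trough_depth)
    return("excluded_amplitude_ratio")
  "retained"
}

#' Extract trough-to-peak duration and repolarization time
#'
#' Trough-to-peak is the interval between the global minimum and the next
#' local maximum. Repolarization time is the interval between that maximum
#' and the subsequent inflection point, located as the first sign change of
#' the central second difference after the peak, refined by linear
#' interpolation of the crossing.
#'
#' @param avg an `average_waveform` (or any numeric vector with a `dt_ms`
#'   attribute; defaults to the 2.5/999 ms grid).
#' @return list with `trough_to_peak_ms`, `repolarization_ms`,
#'   `trough_index`, `peak_index`.
#' @export
compute_features <- function(avg) {
  y <- as.numeric(avg)
  dt <- attr(avg, "dt_ms")
  if (is.null(dt)) dt <- WAVEFORM_SPAN_MS / (length(y) - 1)
  i0 <- which.min(y)
  mx <- local_maxima(y)
  mx <- mx[mx > i0]
  if (!length(mx))
    stop("no local maximum after the trough; waveform not measurable")
  j <- mx[1]
  d2 <- diff(y, differences = 2)            # d2[k] ~ y''(k + 1)
  ks <- seq.int(j, length(d2))              # second-difference index at sample k+1
  vals <- d2[ks]
  pos <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(pos))
    stop("no inflection point after the peak; waveform not measurable")
  k <- pos[1]
  v0 <- vals[k]; v1 <- vals[k + 1]
  frac <- if (v1 > v0) -v0 / (v1 - v0) else 0
  # sample index of the crossing: d2[ks[k]] corresponds to sample ks[k] + 1
  infl <- (ks[k] + 1) + frac
  list(trough_to_peak_ms = (j - i0) * dt,
       repolarization_ms = (infl - j) * dt,
       trough_index = i0, peak_index = j)
}

#' Full waveform pipeline for one unit
#'
#' Select/align, reject outliers, average/interpolate, QC, and extract
#' features.
#'
#' @param snippets matrix of raw snippets (rows).
#' @param sampling_rate Hz.
#' @param n_spikes_total total spikes for the unit; defaults to the number
#'   of snippets.
#' @param n_select,seed as in [select_and_align_snippets()].
#' @return list with `qc_status`, `trough_to_peak_ms`, `repolarization_ms`
#'   (NA unless retained), `avg` (the average waveform), `removed_fraction`.
#' @export
unit_waveform_features <- function(snippets, sampling_rate,
                                   n_spikes_total = nrow(snippets),
                                   n_select = 1000L, seed = 1L) {
  al <- select_and_align_snippets(snippets, sampling_rate,
                                  n_select = n_select, seed = seed)
  rej <- reject_outlier_waveforms(al)
  avg <- average_and_interpolate(rej$retained, sampling_rate)
  status <- qc_exclude_unit(avg, n_spikes_total)
  ttp <- rpz <- NA_real_
  if (status == "retained") {
    ft <- tryCatch(compute_features(avg), error = function(e) NULL)
    if (is.null(ft)) {
      status <- "excluded_multipeak"
    } else {
      ttp <- ft$trough_to_peak_ms
      rpz <- ft$repolarization_ms
    }
  }
  list(qc_status = status, trough_to_peak_ms = ttp, repolarization_ms = rpz,
       avg = avg, removed_fraction = rej$removed_fraction)
}

#' Summarize unit exclusions
#'
#' @param status character vector of per-unit QC statuses.
#' @return list with `n_total`, `n_excluded`, `percent_excluded`, and the
#'   per-criterion counts.
#' @export
qc_summary <- function(status) {
  n <- length(status)
  excl <- status != "retained"
  list(n_total = n, n_excluded = sum(excl),
       percent_excluded = 100 * sum(excl) / n,
       counts = table(factor(status, levels = c(
         "retained", "excluded_min_spikes", "excluded_multipeak",
         "excluded_amplitude_ratio"))))
}
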