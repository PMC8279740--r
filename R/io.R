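# On-disk formats and the pipeline driver. Trials and spikes travel as TSV
# (UTF-8, '.' decimal, seconds); waveform snippets as a little-endian float64
# array with a JSON sidecar. Artifacts are stamped with a config hash and the
# session seed.

TRIALS_COLUMNS <- c("trial_id", "task", "condition", "object",
                    "t_fixation_onset", "t_cue_onset",
                    "t_object_presentation", "t_go_signal",
                    "t_movement_onset", "t_pulling_onset", "correct")
SPIKES_COLUMNS <- c("unit_id", "area", "trial_id", "spike_time_s")

validate_trials <- function(trials, file = "<trials>") {
  miss <- setdiff(TRIALS_COLUMNS, names(trials))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(miss, collapse = ", ")))
  ev <- c("t_fixation_onset", "t_cue_onset", "t_object_presentation",
          "t_go_signal", "t_movement_onset", "t_pulling_onset")
  for (i in seq_len(nrow(trials))) {
    v <- unlist(trials[i, ev])
    v <- v[!is.na(v)]
    if (any(diff(v) <= 0))
      stop(sprintf("%s: line %d: event times not strictly increasing", file, i))
  }
  nogo <- trials$condition == "NoGo"
  bad <- nogo & (!is.na(trials$t_movement_onset) |
                   !is.na(trials$t_pulling_onset))
  if (any(bad))
    stop(sprintf("%s: line %d: No-Go trial has movement/pulling events (column t_movement_onset)",
                 file, which(bad)[1]))
  invisible(trials)
}

#' Read / write the trials table
#'
#' Tab-separated, one row per trial, `NA` for absent No-Go movement events.
#' Reading validates the schema, the strict event ordering, and the No-Go
#' invariant, naming file, line and column on failure.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials` returns the validated data.frame.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.table(trials[, TRIALS_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_trials(tr, file = path)
  tr
}

#' Read / write the spikes table
#'
#' Tab-separated: `unit_id`, `area`, `trial_id`, `spike_time_s` (seconds
#' from trial start).
#'
#' @param spikes a spikes table.
#' @param path file path.
#' @return `read_spikes` returns the data.frame.
#' @export
write_spikes <- function(spikes, path) {
  miss <- setdiff(SPIKES_COLUMNS, names(spikes))
  if (length(miss))
    stop(sprintf("spikes table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  write.table(spikes[, SPIKES_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  sp <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(SPIKES_COLUMNS, names(sp))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  sp
}

#' Read / write a snippet array container
#'
#' Row-major little-endian float64 array (`.bin`) with a JSON sidecar
#' (`.json`) recording `sampling_rate_hz`, `n_snippets` and `n_samples`.
#'
#' @param snippets list with `snippets` matrix and `sampling_rate` (as
#'   produced by [generate_waveform_snippets()]).
#' @param path path of the `.bin` file; the sidecar replaces the extension
#'   with `.json`.
#' @return `read_snippets` returns the same list structure.
#' @export
write_snippets <- function(snippets, path) {
  m <- snippets$snippets
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(sampling_rate_hz = snippets$sampling_rate,
                            n_snippets = nrow(m), n_samples = ncol(m)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snippets
#' @export
read_snippets <- function(path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar))
    stop(sprintf("%s: JSON sidecar %s not found", path, sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_snippets * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop(sprintf("%s: expected %d values, found %d", path, n, length(v)))
  list(snippets = matrix(v, meta$n_snippets, meta$n_samples, byrow = TRUE),
       sampling_rate = meta$sampling_rate_hz)
}

#' Default analysis configuration
#'
#' Every analysis default equals the value used throughout the method chain
#' (bin width 0.2 s stepped 0.02 s; pre-cue baseline -0.5..0 s; sliding test
#' p 0.05 with 5 consecutive bins over -0.3..0.9 s around the Go signal;
#' GMM with 500 replicates and K up to 10; decoding with 65-unit subsamples,
#' 50 iterations, 10 runs, 0.04-s smoothing, preselection p 0.5; MMD over
#' -0.5..0.7 s around movement onset with p 0.01). Overrides passed as
#' `...` are recorded and echoed to the run log.
#'
#' @param ... named overrides of the defaults.
#' @return a `session_config` list; `$overrides` names the changed fields.
#' @export
session_config <- function(...) {
  cfg <- list(
    n_units = 30, n_per_condition = 10, seed = 1L,
    n_snippets = 1500, snippet_noise_sd = 5,
    bin_width = 0.2, step = 0.02,
    baseline_epoch = c(-0.5, 0),
    response_window = c(-0.3, 0.9), response_alpha = 0.05, min_consec = 5,
    soft = 5,
    gmm_replicates = 500, gmm_Kmax = 10,
    decode_window = c(-0.5, 1.0),
    n_subsample = 65, n_iterations = 50, n_runs = 10,
    smoothing_sd = 0.04, preselect_p = 0.5,
    mmd_window = c(-0.5, 0.7), mmd_alpha = 0.01)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg$overrides <- names(ov)
  class(cfg) <- "session_config"
  cfg
}

# stable polynomial hash of the serialized config, for artifact stamping
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "overrides")],
                        auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Stages in dependency order: `simulate` (synthetic session), `features`
#' (average waveforms and QC), `cluster` (cell classes by BIC), `classify`
#' (facilitated/suppressed labels), `decode` (Go/No-Go and object MI time
#' courses), `mmd`, `report` (summary JSON). Artifacts are written as
#' TSV/JSON into `out_dir` and stamped with the config hash and seed; every
#' default override is logged once.
#'
#' @param config a [session_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run; upstream artifacts must already
#'   exist in `out_dir`, otherwise the missing stage is named.
#' @return invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config = session_config(), out_dir,
                         stages = c("simulate", "features", "cluster",
                                    "classify", "decode", "mmd", "report")) {
  all_stages <- c("simulate", "features", "cluster", "classify", "decode",
                  "mmd", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("config_hash=%s seed=%d\n", hash, config$seed), file = logf)
  for (ov in config$overrides)
    logline("override: %s=%s", ov, paste(format(config[[ov]]), collapse = ","))
  res <- list()

  need <- function(stage, file) {
    if (!file.exists(file.path(out_dir, file)))
      stop(sprintf("artifact '%s' missing: run stage '%s' first", file, stage))
  }

  if ("simulate" %in% stages) {
    sess <- simulate_session(config$n_units, config$n_per_condition,
                             seed = config$seed,
                             n_snippets = config$n_snippets,
                             noise_sd = config$snippet_noise_sd)
    write_trials(sess$trials, file.path(out_dir, "trials.tsv"))
    write_spikes(sess$spikes, file.path(out_dir, "spikes.tsv"))
    write.table(sess$ground_truth, file.path(out_dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (uid in names(sess$snippets))
      write_snippets(sess$snippets[[uid]],
                     file.path(out_dir, sprintf("snippets_%s.bin", uid)))
    saveRDS(sess, file.path(out_dir, "session.rds"))
    res$session <- sess
    logline("simulate: %d units, %d trials", config$n_units,
            nrow(sess$trials))
  } else if (any(c("features", "cluster", "classify", "decode", "mmd",
                   "report") %in% stages)) {
    need("simulate", "session.rds")
    res$session <- readRDS(file.path(out_dir, "session.rds"))
  }

  if ("features" %in% stages) {
    sess <- res$session
    feats <- do.call(rbind, lapply(seq_along(sess$snippets), function(i) {
      f <- unit_waveform_features(sess$snippets[[i]]$snippets,
                                  sess$snippets[[i]]$sampling_rate,
                                  n_spikes_total = config$n_snippets,
                                  seed = derive_seed(config$seed, 900L + i))
      data.frame(unit_id = names(sess$snippets)[i],
                 area = sess$ground_truth$area[i],
                 trough_to_peak_ms = f$trough_to_peak_ms,
                 repolarization_ms = f$repolarization_ms,
                 qc_status = f$qc_status, stringsAsFactors = FALSE)
    }))
    write.table(feats, file.path(out_dir, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$features <- feats
    logline("features: %d/%d units retained",
            sum(feats$qc_status == "retained"), nrow(feats))
  } else if (any(c("cluster", "report") %in% stages)) {
    need("features", "features.tsv")
    res$features <- read.delim(file.path(out_dir, "features.tsv"))
  }

  if ("cluster" %in% stages) {
    feats <- res$features
    keep <- feats$qc_status == "retained"
    x <- as.matrix(feats[keep, c("trough_to_peak_ms", "repolarization_ms")])
    model <- select_K_by_bic(x, Kmax = min(config$gmm_Kmax, sum(keep) - 1),
                             seed = derive_seed(config$seed, 21L),
                             n_replicates = config$gmm_replicates)
    classes <- data.frame(unit_id = feats$unit_id[keep],
                          class = model$assignments)
    write.table(cbind(classes, round(model$posteriors, 6)),
                file.path(out_dir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(config_hash = hash, K = model$K,
                              means = model$means, variances = model$variances,
                              weights = model$weights,
                              bic_by_K = as.list(model$bic_by_K)),
                         file.path(out_dir, "model.json"), digits = NA)
    res$model <- model
    res$classes <- classes
    logline("cluster: K=%d selected by BIC", model$K)
  }

  if ("classify" %in% stages) {
    sess <- res$session
    labels <- do.call(rbind, lapply(seq_len(nrow(sess$ground_truth)),
                                    function(i) {
      uid <- sess$ground_truth$unit_id[i]
      sp <- sess$spikes[sess$spikes$unit_id == uid, , drop = FALSE]
      do.call(rbind, lapply(c("EXE", "OBS"), function(task) {
        tr <- sess$trials[sess$trials$task == task, , drop = FALSE]
        bl <- compute_baseline(sp, tr, epoch = config$baseline_epoch)
        b <- bin_activity(sp, tr[tr$condition == "Go", , drop = FALSE],
                          window = config$response_window,
                          bin_width = config$bin_width, step = config$step)
        lab <- classify_response(b, bl$per_trial,
                                 alpha = config$response_alpha,
                                 min_consec = config$min_consec)
        nrm <- net_soft_normalize(b, mean(bl$per_trial$rate),
                                  groups = rep("all", nrow(b$rate)),
                                  soft = config$soft)
        pk_go <- if (lab$label == "facilitated")
          peak_time(nrm[1, ], c(0, 0.6), b$bin_centers) else NA_real_
        data.frame(unit_id = uid, task = task, label = lab$label,
                   sign = lab$sign, peak_time_go = pk_go,
                   stringsAsFactors = FALSE)
      }))
    }))
    write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$labels <- labels
    logline("classify: %d facilitated, %d suppressed of %d unit-tasks",
            sum(labels$label == "facilitated"),
            sum(labels$label == "suppressed"), nrow(labels))
  }

  if ("decode" %in% stages) {
    sess <- res$session
    pop <- population_from_session(sess, task = "EXE",
                                   variable = "condition",
                                   alignment = "t_object_presentation",
                                   window = config$decode_window,
                                   bin_width = config$bin_width,
                                   step = config$step)
    dec <- decode_timecourse(pop,
                             n_subsample = min(config$n_subsample,
                                               length(pop)),
                             n_iterations = config$n_iterations,
                             n_runs = config$n_runs,
                             smoothing_sd = config$smoothing_sd,
                             preselect_p = config$preselect_p,
                             seed = derive_seed(config$seed, 31L))
    onset <- onset_time(dec, n_area = length(pop))
    curves <- data.frame(bin_center_s = dec$bin_centers,
                         mi_mean = dec$mi_mean, mi_sd = dec$mi_sd,
                         significant = dec$significance_mask)
    write.table(curves, file.path(out_dir, "mi_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(config_hash = hash,
                              go_nogo = list(onset_mean = onset$onset_mean,
                                             onset_se = onset$onset_se,
                                             n_iterations = config$n_iterations)),
                         file.path(out_dir, "onsets.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    res$decoding <- dec
    res$onset <- onset
    logline("decode: max MI %.3f bits", max(dec$mi_mean))
  }

  if ("mmd" %in% stages) {
    sess <- res$session
    ids <- sess$ground_truth$unit_id
    tr_list <- lapply(ids, function(uid) {
      sp <- sess$spikes[sess$spikes$unit_id == uid, , drop = FALSE]
      mmd_traces(sp, sess$trials, window = config$mmd_window,
                 bin_width = config$bin_width, step = config$step,
                 soft = config$soft)
    })
    mmd <- do.call(rbind, lapply(tr_list, function(z)
      as.numeric(mmd_timecourse(z$exe, z$obs))))
    rownames(mmd) <- ids
    write.table(data.frame(unit_id = ids, mmd, check.names = FALSE),
                file.path(out_dir, "mmd.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$mmd <- mmd
    logline("mmd: %d units x %d bins", nrow(mmd), ncol(mmd))
  }

  if ("report" %in% stages) {
    summary <- list(config_hash = hash, seed = config$seed,
                    n_units = config$n_units,
                    qc = if (!is.null(res$features))
                      qc_summary(res$features$qc_status)[c("n_total",
                                                           "n_excluded",
                                                           "percent_excluded")]
                    else NULL,
                    K = if (!is.null(res$model)) res$model$K else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    logline("report: summary.json written")
  }
  invisible(res)
}
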