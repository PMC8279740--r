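# Pseudo-population decoding: trial resampling into splits, ANOVA-style
# feature preselection, a Poisson naive Bayes classifier evaluated by
# leave-one-split-out cross-validation, plug-in mutual information of the
# confusion matrix, number-matched subsampling with iteration/run averaging,
# Gaussian smoothing, and onset-latency estimation/comparison.

#' Build a decodable population from a simulated session
#'
#' Bins every unit's activity on a common grid and attaches the per-trial
#' labels of the decoded variable.
#'
#' @param session a `mirrorpop_session`.
#' @param task `"EXE"` or `"OBS"`.
#' @param variable trial column holding the decoded label (`"condition"`
#'   for Go/No-Go, `"object"` for object identity).
#' @param alignment event column to align to.
#' @param window analysis span (s).
#' @param trial_filter optional logical expression over the trial table
#'   (e.g. `condition == "Go"` for object decoding within Go trials).
#' @param bin_width,step binning parameters (s).
#' @return a list of class `decoding_population`: one element per unit with
#'   `counts` (trials x bins) and `label`; attributes `bin_centers`, `step`,
#'   `conditions`, `unit_id`, `area`.
#' @export
population_from_session <- function(session, task = "EXE",
                                    variable = c("condition", "object"),
                                    alignment = "t_object_presentation",
                                    window = c(-0.5, 1.0),
                                    trial_filter = NULL,
                                    bin_width = 0.2, step = 0.02) {
  variable <- match.arg(variable)
  trials <- session$trials[session$trials$task == task, , drop = FALSE]
  if (!is.null(trial_filter)) {
    keep <- eval(trial_filter, trials, parent.frame())
    trials <- trials[keep, , drop = FALSE]
  }
  ids <- session$ground_truth$unit_id
  units <- lapply(ids, function(uid) {
    sp <- session$spikes[session$spikes$unit_id == uid, , drop = FALSE]
    b <- bin_activity(sp, trials, alignment = alignment, window = window,
                      bin_width = bin_width, step = step)
    list(counts = b$counts, label = factor(b[[variable]]))
  })
  structure(units, class = "decoding_population",
            bin_centers = bin_centers_in(window, bin_width, step),
            step = step,
            conditions = levels(factor(trials[[variable]])),
            unit_id = ids, area = session$ground_truth$area)
}

#' Deal trials into pseudo-population splits
#'
#' Each unit's trials are shuffled independently within condition and dealt
#' one per condition into `n_splits` splits, so every split holds exactly
#' one data point (trial) per condition and the population is treated as if
#' recorded simultaneously.
#'
#' @param population a `decoding_population` (or plain list of units with
#'   `counts` and `label`).
#' @param n_splits number of splits; defaults to the smallest per-condition
#'   trial count across units.
#' @param seed integer seed.
#' @return a `pseudo_population`: list with `x` (array units x bins x
#'   conditions x splits), `conditions`, `bin_centers`.
#' @export
make_pseudopopulation <- function(population, n_splits = NULL, seed = 1L) {
  conds <- attr(population, "conditions")
  if (is.null(conds)) conds <- levels(factor(population[[1]]$label))
  U <- length(population)
  B <- ncol(population[[1]]$counts)
  K <- length(conds)
  avail <- vapply(seq_len(U), function(u) {
    min(table(factor(population[[u]]$label, levels = conds)))
  }, numeric(1))
  if (is.null(n_splits)) n_splits <- min(avail)
  stopifnot_scalar_count(n_splits, "n_splits")
  short <- which(avail < n_splits)
  if (length(short))
    stop(sprintf("unit(s) %s have fewer than %d trials in some condition",
                 paste(short, collapse = ", "), n_splits))
  x <- array(NA_real_, c(U, B, K, n_splits))
  with_seed(seed, {
    for (u in seq_len(U)) {
      lab <- factor(population[[u]]$label, levels = conds)
      for (k in seq_len(K)) {
        rows <- which(lab == conds[k])
        rows <- sample(rows)[seq_len(n_splits)]
        x[u, , k, ] <- t(population[[u]]$counts[rows, , drop = FALSE])
      }
    }
  })
  structure(list(x = x, conditions = conds,
                 bin_centers = attr(population, "bin_centers")),
            class = "pseudo_population")
}

#' ANOVA-style feature preselection p-values
#'
#' One-way F test across condition groups for each unit (row), on training
#' data only. Units with p below the threshold are retained; with zero
#' between- and within-group variance the p-value is 1 (no difference), and
#' with zero within- but positive between-group variance it is 0.
#'
#' @param x units x points matrix of training counts (one time bin).
#' @param labels condition factor over the points.
#' @return numeric vector of p-values per unit.
#' @export
preselect_features <- function(x, labels) {
  labels <- factor(labels)
  K <- nlevels(labels)
  n <- length(labels)
  if (n - K < 1) return(rep(0, nrow(x)))  # too few points for a within-group df
  gm <- vapply(levels(labels), function(g) {
    rowMeans(x[, labels == g, drop = FALSE])
  }, numeric(nrow(x)))
  gm <- matrix(gm, nrow = nrow(x))
  counts <- as.numeric(table(labels))
  grand <- rowMeans(x)
  ssb <- as.numeric((sweep(gm, 1, grand))^2 %*% counts)
  ssw <- rowSums((x - gm[, as.integer(labels), drop = FALSE])^2)
  f <- (ssb / (K - 1)) / (ssw / (n - K))
  p <- pf(f, K - 1, n - K, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb == 0] <- 1
  p
}

#' Train a Poisson naive Bayes classifier
#'
#' Class-conditional mean counts per unit (and per bin when given an array),
#' floored at `floor` to keep log-rates finite; class priors are uniform for
#' the balanced splits used throughout.
#'
#' @param x units x points training counts.
#' @param labels condition factor over points.
#' @param floor minimum rate parameter (counts; default 1e-3).
#' @return list with `lambda` (units x classes), `classes`, `floor`.
#' @export
train_poisson_nb <- function(x, labels, floor = 1e-3) {
  labels <- factor(labels)
  lambda <- vapply(levels(labels), function(g) {
    pmax(rowMeans(x[, labels == g, drop = FALSE]), floor)
  }, numeric(nrow(x)))
  lambda <- matrix(lambda, nrow = nrow(x),
                   dimnames = list(NULL, levels(labels)))
  list(lambda = lambda, classes = levels(labels), floor = floor)
}

#' Classify test points with a trained Poisson naive Bayes model
#'
#' Score of class k for a test vector x is `sum_u x_u log(lambda_uk) -
#' lambda_uk` (uniform priors); the argmax wins, ties broken uniformly at
#' random.
#'
#' @param model a [train_poisson_nb()] fit.
#' @param x units x points matrix of test counts.
#' @param mask optional logical unit mask from feature preselection.
#' @return integer vector of predicted class indices.
#' @export
classify_poisson_nb <- function(model, x, mask = NULL) {
  x <- as.matrix(x)
  if (is.null(mask)) mask <- rep(TRUE, nrow(x))
  if (!any(mask)) stop("all units filtered out; review the preselection threshold")
  lam <- model$lambda[mask, , drop = FALSE]
  xt <- x[mask, , drop = FALSE]
  scores <- t(xt) %*% log(lam) -
    matrix(colSums(lam), ncol(xt), ncol(lam), byrow = TRUE)
  max.col(scores, ties.method = "random")
}

#' Plug-in mutual information of a confusion matrix (bits)
#'
#' MI of the joint (actual, predicted) distribution obtained by normalizing
#' the confusion counts, with the convention 0 log 0 = 0.
#'
#' @param confusion K x K matrix of counts (rows = actual).
#' @return mutual information in bits.
#' @export
mi_from_confusion <- function(confusion) {
  m <- as.matrix(confusion)
  if (any(m < 0) || sum(m) == 0) stop("confusion counts must be nonnegative, not all zero")
  p <- m / sum(m)
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

# Leave-one-split-out cross-validation over all bins at once.
# Returns mi (bins) and confusion (bins x K x K).
nb_crossvalidate <- function(pp, preselect_p = 0.5, floor = 1e-3,
                             seed = 1L) {
  x <- pp$x
  U <- dim(x)[1]; B <- dim(x)[2]; K <- dim(x)[3]; S <- dim(x)[4]
  conf <- array(0, c(B, K, K))
  with_seed(seed, {
    for (s in seq_len(S)) {
      tr <- x[, , , -s, drop = FALSE]          # U x B x K x (S-1)
      te <- array(x[, , , s], c(U, B, K))
      lam <- array(NA_real_, c(U, B, K))
      for (k in seq_len(K))
        lam[, , k] <- rowMeans(array(tr[, , k, ], c(U, B, S - 1)), dims = 2)
      # preselection: one-way F across conditions, training data only
      if (S - 1 >= 2 && preselect_p < 1) {
        ng <- S - 1
        grand <- rowMeans(lam, dims = 2)
        ssb <- ng * apply(sweep(lam, 1:2, grand)^2, 1:2, sum)
        ssw <- matrix(0, U, B)
        for (k in seq_len(K)) {
          dev <- array(tr[, , k, ], c(U, B, ng)) -
            array(lam[, , k], c(U, B, ng))
          ssw <- ssw + rowSums(dev^2, dims = 2)
        }
        f <- (ssb / (K - 1)) / (ssw / (K * (ng - 1)))
        p <- pf(f, K - 1, K * (ng - 1), lower.tail = FALSE)
        p[ssw == 0 & ssb > 0] <- 0
        p[ssw == 0 & ssb == 0] <- 1
        mask <- p < preselect_p
      } else {
        mask <- matrix(TRUE, U, B)
      }
      lamf <- pmax(lam, floor)
      loglam <- log(lamf)
      for (cc in seq_len(K)) {
        sc <- matrix(0, B, K)
        for (k in seq_len(K)) {
          contrib <- mask * (array(te[, , cc], c(U, B)) * loglam[, , k] -
                               lamf[, , k])
          sc[, k] <- colSums(contrib)
        }
        pred <- max.col(sc, ties.method = "random")
        for (b in seq_len(B))
          conf[b, cc, pred[b]] <- conf[b, cc, pred[b]] + 1
      }
    }
  })
  mi <- vapply(seq_len(B), function(b) mi_from_confusion(conf[b, , ]),
               numeric(1))
  list(mi = mi, confusion = conf)
}

# shared iteration engine: sample_fun(i) returns the unit indices of
# iteration i; each iteration averages n_runs cross-validation cycles with
# fresh splits and is then Gaussian-smoothed.
decode_engine <- function(population, sample_fun, n_iterations, n_runs,
                          smoothing_sd, preselect_p, n_splits, seed) {
  step <- attr(population, "step")
  centers <- attr(population, "bin_centers")
  K <- length(attr(population, "conditions"))
  if (K < 2) stop("decoding requires at least 2 conditions")
  B <- length(centers)
  mi <- matrix(NA_real_, n_iterations, B)
  for (i in seq_len(n_iterations)) {
    idx <- sample_fun(i)
    sub <- population[idx]
    attributes(sub) <- attributes(population)[c("class", "conditions",
                                                "bin_centers", "step")]
    runs <- matrix(NA_real_, n_runs, B)
    for (r in seq_len(n_runs)) {
      pp <- make_pseudopopulation(sub, n_splits = n_splits,
                                  seed = derive_seed(seed, 7L, i, r))
      runs[r, ] <- nb_crossvalidate(pp, preselect_p = preselect_p,
                                    seed = derive_seed(seed, 8L, i, r))$mi
    }
    mi[i, ] <- gaussian_smooth(colMeans(runs), step, smoothing_sd)
  }
  max_mi <- log2(K)
  mi_mean <- colMeans(mi)
  structure(list(mi = mi, mi_mean = mi_mean,
                 mi_sd = apply(mi, 2, sd), bin_centers = centers,
                 K = K, max_mi = max_mi, threshold = max_mi / 3,
                 significance_mask = mi_mean > max_mi / 3,
                 config = list(n_iterations = n_iterations, n_runs = n_runs,
                               smoothing_sd = smoothing_sd,
                               preselect_p = preselect_p)),
            class = "decoding_result")
}

#' Mutual-information time course with number-matched subsampling
#'
#' Each iteration draws `n_subsample` units with replacement and averages
#' `n_runs` full leave-one-split-out cross-validation cycles with fresh
#' splits; the run-averaged MI curve is smoothed with a Gaussian kernel
#' (SD = `smoothing_sd`, truncated at 3 SD). The across-iteration mean and
#' SD are reported, with the significance mask where the mean MI exceeds
#' one third of its theoretical maximum `log2 K`.
#'
#' @param population a `decoding_population`.
#' @param n_subsample units drawn with replacement per iteration (default
#'   65); `NULL` uses all units without resampling.
#' @param n_iterations,n_runs repetition structure (defaults 50 and 10).
#' @param smoothing_sd Gaussian kernel SD in seconds (default 0.04).
#' @param preselect_p feature-preselection threshold (default 0.5; 1 keeps
#'   every unit).
#' @param n_splits splits per run (default: all available trials).
#' @param seed integer seed.
#' @return a `decoding_result`: `mi` (iterations x bins, bits), `mi_mean`,
#'   `mi_sd`, `bin_centers`, `K`, `max_mi`, `threshold`,
#'   `significance_mask`, `config`.
#' @export
decode_timecourse <- function(population, n_subsample = 65L,
                              n_iterations = 50L, n_runs = 10L,
                              smoothing_sd = 0.04, preselect_p = 0.5,
                              n_splits = NULL, seed = 1L) {
  U <- length(population)
  sample_fun <- if (is.null(n_subsample)) {
    function(i) seq_len(U)
  } else {
    function(i) with_seed(derive_seed(seed, 3L, i),
                          sample.int(U, n_subsample, replace = TRUE))
  }
  decode_engine(population, sample_fun, n_iterations, n_runs, smoothing_sd,
                preselect_p, n_splits, seed)
}

#' Per-class decoding with fixed per-area sampling
#'
#' For each cell class, every iteration draws (with replacement) a fixed
#' number of that class's units from each area, pools them into one
#' pseudo-population, and decodes as in [decode_timecourse()].
#'
#' @param population a `decoding_population` (with `area` attribute).
#' @param class per-unit class labels aligned with the population.
#' @param n_per_class_per_area units drawn per area (default 20).
#' @inheritParams decode_timecourse
#' @return named list of `decoding_result`, one per class.
#' @export
classwise_decode <- function(population, class, n_per_class_per_area = 20L,
                             n_iterations = 50L, n_runs = 10L,
                             smoothing_sd = 0.04, preselect_p = 0.5,
                             n_splits = NULL, seed = 1L) {
  area <- attr(population, "area")
  if (is.null(area)) stop("population lacks per-unit areas")
  classes <- sort(unique(class))
  areas <- sort(unique(area))
  out <- lapply(classes, function(cl) {
    for (a in areas) {
      if (!any(class == cl & area == a))
        stop(sprintf("class %s has no units in area %s", cl, a))
    }
    pools <- lapply(areas, function(a) which(class == cl & area == a))
    sample_fun <- function(i) {
      with_seed(derive_seed(seed, 4L, match(cl, classes), i), {
        unlist(lapply(pools, function(p) {
          p[sample.int(length(p), n_per_class_per_area, replace = TRUE)]
        }))
      })
    }
    decode_engine(population, sample_fun, n_iterations, n_runs, smoothing_sd,
                  preselect_p, n_splits, derive_seed(seed, 5L, match(cl, classes)))
  })
  names(out) <- as.character(classes)
  out
}

#' Information-onset latency with number-matched standard error
#'
#' Per iteration, the onset is the first bin whose (smoothed) MI exceeds one
#' third of the theoretical maximum; the mean across iterations is reported
#' with SE = SD(onsets) x `ref_size` / `n_area`, the correction for the
#' subsample size relative to the reference population.
#'
#' @param result a `decoding_result`.
#' @param n_area size of the population the subsamples were drawn from.
#' @param ref_size number-matched subsample size (default 65).
#' @param min_prop minimum fraction of iterations that must cross the
#'   threshold (default 0.5); below it the onset is reported as absent.
#' @return list with `onset_mean`, `onset_se`, `onsets` (per iteration,
#'   `NA` when never crossed), `prop_crossed`, `threshold`.
#' @export
onset_time <- function(result, n_area, ref_size = 65, min_prop = 0.5) {
  thr <- result$threshold
  onsets <- apply(result$mi, 1, function(curve) {
    i <- which(curve > thr)
    if (length(i)) result$bin_centers[i[1]] else NA_real_
  })
  prop <- mean(!is.na(onsets))
  if (prop < min_prop) {
    return(list(onset_mean = NA_real_, onset_se = NA_real_, onsets = onsets,
                prop_crossed = prop, threshold = thr))
  }
  oc <- onsets[!is.na(onsets)]
  list(onset_mean = mean(oc), onset_se = sd(oc) * ref_size / n_area,
       onsets = onsets, prop_crossed = prop, threshold = thr)
}

#' Two-sample z test on two estimates with standard errors
#'
#' @param mean_a,se_a,mean_b,se_b estimates and their SEs.
#' @return list with `z` and the two-tailed normal `p`.
#' @export
z_test_means <- function(mean_a, se_a, mean_b, se_b) {
  z <- (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare two information onsets
#'
#' Two-tailed two-sample z test on the onset means using their
#' subsample-corrected standard errors.
#'
#' @param a,b [onset_time()] results.
#' @return list with `z` and `p`; both `NA` (with a message) when either
#'   onset is absent.
#' @export
compare_onsets <- function(a, b) {
  if (is.na(a$onset_mean) || is.na(b$onset_mean)) {
    message("onset absent in at least one result; comparison undefined")
    return(list(z = NA_real_, p = NA_real_))
  }
  z_test_means(a$onset_mean, a$onset_se, b$onset_mean, b$onset_se)
}

#' Epoch-averaged mutual information per iteration
#'
#' Mean MI inside the window (default 200-700 ms after object presentation)
#' for each iteration, with a number-matched SE for cross-population z
#' comparisons via [z_test_means()].
#'
#' @param result a `decoding_result`.
#' @param window epoch in seconds on the result's time base.
#' @param n_area,ref_size as in [onset_time()]; when `n_area` is `NULL` the
#'   SE is the plain SD across iterations.
#' @return list with `values` (per iteration), `mean`, `se`.
#' @export
epoch_average_mi <- function(result, window = c(0.2, 0.7), n_area = NULL,
                             ref_size = 65) {
  inside <- result$bin_centers >= window[1] - 1e-12 &
    result$bin_centers <= window[2] + 1e-12
  if (!any(inside)) stop("window outside the decoded span")
  vals <- rowMeans(result$mi[, inside, drop = FALSE])
  se <- if (is.null(n_area)) sd(vals) else sd(vals) * ref_size / n_area
  list(values = vals, mean = mean(vals), se = se)
}

#' Maximum theoretical mutual information for K equiprobable conditions
#'
#' `log2 K` bits: 1 for Go/No-Go decoding, 1.585 for three-object decoding;
#' used to normalize MI curves and to set the onset threshold at one third.
#'
#' @param K number of conditions.
#' @return bits.
#' @export
max_theoretical_mi <- function(K) {
  if (K < 1) stop("K must be a positive count")
  log2(K)
}

#' Number-matched subsample size
#'
#' The decoding subsample equals three quarters of the smallest area's unit
#' count, rounded half up (86 units give 65).
#'
#' @param n_by_area unit counts per area.
#' @param fraction fraction of the smallest area (default 3/4).
#' @return integer subsample size.
#' @export
number_matched_size <- function(n_by_area, fraction = 0.75) {
  as.integer(floor(fraction * min(n_by_area) + 0.5))
}
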