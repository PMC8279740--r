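# Cell-class clustering in the (trough-to-peak, repolarization) plane:
# diagonal-covariance Gaussian mixture fitted by EM over many k-means++
# replicates, component number selected by BIC, hard assignment by maximum
# posterior, confusion-matrix separation accuracy, and confidence ellipses.

# log posterior responsibilities for points under a fitted mixture
gmm_posteriors <- function(x, means, variances, weights) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- nrow(means)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lp[, k] <- log(weights[k]) +
      rowSums(vapply(seq_len(ncol(x)), function(j) {
        stats::dnorm(x[, j], means[k, j], sqrt(variances[k, j]), log = TRUE)
      }, numeric(n)))
  }
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Fit a diagonal-covariance Gaussian mixture by multi-replicate EM
#'
#' EM with k-means++ initialization; `n_replicates` runs (default 500), each
#' to convergence or at most `max_iter` iterations (default 100), keeping the
#' replicate with the largest log-likelihood. Component covariances are
#' constrained to be diagonal; variances are floored at `var_floor` and the
#' fit is flagged when the floor binds.
#'
#' @param features n x 2 matrix (trough-to-peak, repolarization; ms).
#' @param K number of components.
#' @param seed integer seed.
#' @param n_replicates,max_iter,tol,var_floor EM control parameters.
#' @return list with `means` (K x 2), `variances` (K x 2, diagonal entries),
#'   `weights`, `loglik`, `posteriors` (n x K), `variance_floored`.
#' @export
fit_gmm <- function(features, K, seed = 1L, n_replicates = 500L,
                    max_iter = 100L, tol = 1e-5, var_floor = 1e-6) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (K > nrow(unique(x)))
    stop("K exceeds the number of distinct feature points")
  fit <- with_seed(seed,
    .gmm_diag_em(x, as.integer(K), as.integer(n_replicates),
                 as.integer(max_iter), tol, var_floor))
  fit$posteriors <- gmm_posteriors(x, fit$means, fit$variances, fit$weights)
  fit$K <- K
  fit
}

#' Select the number of cell classes by BIC
#'
#' Fits mixtures with K = 1..`Kmax` components and keeps the K minimizing
#' BIC = -2 log L + (5K - 1) log n (each diagonal bivariate component has
#' 2 means + 2 variances + 1 weight, with one weight constrained). Ties go to
#' the smallest K. Classes are renumbered by ascending mean trough-to-peak,
#' so class 1 is the narrowest-spiking class.
#'
#' @inheritParams fit_gmm
#' @param Kmax largest component number scanned (default 10).
#' @return a `cell_class_model`: the selected fit plus `bic_by_K`,
#'   `assignments` (hard, max posterior), `posteriors`, `n`.
#' @export
select_K_by_bic <- function(features, Kmax = 10L, seed = 1L,
                            n_replicates = 500L, max_iter = 100L,
                            tol = 1e-5, var_floor = 1e-6) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2) stop("at least 2 feature points required")
  Kcap <- min(Kmax, nrow(unique(x)))
  if (Kcap < Kmax)
    warning(sprintf("only %d distinct points; scanning K = 1..%d", Kcap, Kcap))
  fits <- vector("list", Kcap)
  bic <- rep(NA_real_, Kcap)
  for (K in seq_len(Kcap)) {
    fits[[K]] <- fit_gmm(x, K, seed = derive_seed(seed, K),
                         n_replicates = n_replicates, max_iter = max_iter,
                         tol = tol, var_floor = var_floor)
    bic[K] <- -2 * fits[[K]]$loglik + (5 * K - 1) * log(n)
  }
  Kbest <- which.min(bic)      # which.min takes the first (smallest K) on ties
  fit <- fits[[Kbest]]
  ord <- order(fit$means[, 1])  # class 1 = narrowest trough-to-peak
  fit$means <- fit$means[ord, , drop = FALSE]
  fit$variances <- fit$variances[ord, , drop = FALSE]
  fit$weights <- fit$weights[ord]
  fit$posteriors <- fit$posteriors[, ord, drop = FALSE]
  fit$bic_by_K <- stats::setNames(bic, seq_len(Kcap))
  fit$assignments <- max.col(fit$posteriors, ties.method = "first")
  fit$n <- n
  class(fit) <- "cell_class_model"
  fit
}

#' Separation accuracy of a fitted mixture via simulated draws
#'
#' Draws `n_draws` points from the fitted mixture with known component
#' labels, classifies each by maximum posterior, and reports the
#' row-normalized confusion matrix and the accuracy (mean of the diagonal).
#'
#' @param model a `cell_class_model` or [fit_gmm()] result.
#' @param n_draws number of simulated points (default 10^4).
#' @param seed integer seed.
#' @return list with `confusion` (K x K, rows = true class, rows sum to 1)
#'   and `accuracy`.
#' @export
separation_accuracy <- function(model, n_draws = 10000L, seed = 1L) {
  K <- nrow(model$means)
  if (n_draws < K) stop("`n_draws` must be at least K")
  d <- ncol(model$means)
  sim <- with_seed(seed, {
    comp <- sample.int(K, n_draws, replace = TRUE, prob = model$weights)
    x <- matrix(0, n_draws, d)
    for (j in seq_len(d))
      x[, j] <- rnorm(n_draws, model$means[comp, j],
                      sqrt(model$variances[comp, j]))
    list(comp = comp, x = x)
  })
  post <- gmm_posteriors(sim$x, model$means, model$variances, model$weights)
  pred <- max.col(post, ties.method = "first")
  conf <- table(factor(sim$comp, levels = seq_len(K)),
                factor(pred, levels = seq_len(K)))
  conf <- conf / rowSums(conf)
  list(confusion = unclass(as.matrix(conf)),
       accuracy = mean(diag(as.matrix(conf))))
}

#' Per-class confidence ellipses
#'
#' With diagonal covariances the ellipses are axis-aligned; the semi-axes are
#' the per-dimension SDs scaled to the requested bivariate-normal coverage
#' (the 68% ellipse is the bivariate analog of the standard error).
#'
#' @param model a fitted mixture.
#' @param coverage coverage probability (default 0.68).
#' @param var_floor variance value treated as degenerate.
#' @return data.frame with one row per class: center, semi-axes,
#'   orientation (0: axis-aligned), and a `degenerate` flag.
#' @export
confidence_ellipses <- function(model, coverage = 0.68, var_floor = 1e-6) {
  r <- sqrt(qchisq(coverage, df = 2))
  K <- nrow(model$means)
  data.frame(
    class = seq_len(K),
    center_x = model$means[, 1], center_y = model$means[, 2],
    semiaxis_x = r * sqrt(model$variances[, 1]),
    semiaxis_y = r * sqrt(model$variances[, 2]),
    orientation = 0,
    degenerate = model$variances[, 1] <= var_floor |
      model$variances[, 2] <= var_floor)
}

#' Compare cell-class composition across areas
#'
#' Per-area class counts and proportions; a Pearson chi-square
#' goodness-of-fit test of each area's class distribution against the pooled
#' distribution; and pairwise chi-square homogeneity tests between areas
#' (no continuity correction).
#'
#' @param class per-unit class labels.
#' @param area per-unit area labels.
#' @return list with `counts` (area x class), `proportions`, `vs_pooled`
#'   (per-area chi-square and p), `pairwise` (data.frame of area pairs).
#' @export
compare_class_composition <- function(class, area) {
  keep <- !is.na(class) & !is.na(area)
  tab <- table(area = area[keep], class = class[keep])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("empty areas excluded: ", paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  pooled <- colSums(tab) / sum(tab)
  vs_pooled <- do.call(rbind, lapply(rownames(tab), function(a) {
    o <- tab[a, ]
    e <- sum(o) * pooled
    chi2 <- sum((o - e)^2 / e)
    data.frame(area = a, chi2 = chi2,
               p = pchisq(chi2, df = length(o) - 1, lower.tail = FALSE))
  }))
  areas <- rownames(tab)
  pairs <- if (length(areas) >= 2) t(utils::combn(areas, 2)) else
    matrix(character(0), 0, 2)
  pairwise <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    m <- tab[pairs[i, ], , drop = FALSE]
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    data.frame(area_1 = pairs[i, 1], area_2 = pairs[i, 2],
               chi2 = unname(ct$statistic), p = ct$p.value)
  }))
  list(counts = unclass(as.matrix(tab)),
       proportions = unclass(as.matrix(tab / rowSums(tab))),
       vs_pooled = vs_pooled, pairwise = pairwise)
}
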