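# Shared fixtures and independent oracles, all built in code at test time.

# construct a binned_activity object directly from a rate matrix
fake_binned <- function(rate, bin_centers, bin_width = 0.2, step = 0.02,
                        condition = rep("Go", nrow(rate)),
                        task = rep("EXE", nrow(rate))) {
  structure(list(rate = rate, counts = rate * bin_width,
                 bin_centers = bin_centers, bin_width = bin_width,
                 step = step, alignment = "t_go_signal",
                 trial_id = seq_len(nrow(rate)), task = task,
                 condition = condition,
                 object = rep("ring", nrow(rate))),
            class = "binned_activity")
}

# construct a decoding_population from a rate function
# rate_fun(unit, condition_index, bin_centers) -> expected counts per bin
make_poisson_population <- function(n_units, n_per_cond, conditions,
                                    rate_fun, bin_centers, seed,
                                    area = NULL) {
  set.seed(seed)
  units <- lapply(seq_len(n_units), function(u) {
    lab <- rep(conditions, each = n_per_cond)
    counts <- t(vapply(seq_along(lab), function(i) {
      mu <- rate_fun(u, match(lab[i], conditions), bin_centers)
      rpois(length(bin_centers), mu)
    }, numeric(length(bin_centers))))
    list(counts = counts, label = factor(lab, levels = conditions))
  })
  structure(units, class = "decoding_population",
            bin_centers = bin_centers,
            step = if (length(bin_centers) > 1) diff(bin_centers[1:2]) else 0.02,
            conditions = conditions,
            unit_id = sprintf("u%02d", seq_len(n_units)),
            area = if (is.null(area)) rep("A1", n_units) else area)
}

# brute-force Bayes-rule prediction for Poisson naive Bayes: full posterior
# over classes from exact Poisson likelihoods (independent oracle for the
# log-score implementation)
nb_oracle_predict <- function(lambda, x, log_prior = NULL) {
  K <- ncol(lambda)
  if (is.null(log_prior)) log_prior <- rep(-log(K), K)
  lp <- vapply(seq_len(K), function(k) {
    sum(dpois(x, lambda[, k], log = TRUE)) + log_prior[k]
  }, numeric(1))
  which.max(lp)
}

# direct plug-in mutual information evaluation (independent of the package)
mi_plugin_direct <- function(m) {
  p <- m / sum(m)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      tot <- tot + p[i, j] *
        log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  }
  tot
}

# one simulated unit pushed through the sliding-test classifier: Poisson
# counts at `base` spk/s with `depth` added over `dur_bins` bins from +0.1 s
sim_classified_unit <- function(depth, seed, n_trials = 30, base = 10,
                                dur_bins = 21) {
  set.seed(seed)
  centers <- seq(-0.2, 0.8, by = 0.02)
  lam <- matrix(base, n_trials, length(centers))
  on <- which(centers >= 0.1 & centers < 0.1 + 0.02 * dur_bins)
  lam[, on] <- base + depth
  counts <- matrix(rpois(length(lam), lam * 0.2), n_trials)
  b <- fake_binned(counts / 0.2, centers)
  baseline <- rpois(n_trials, base * 0.5) / 0.5
  classify_response(b, baseline)
}

# minimal decoding_result for onset/epoch arithmetic tests
fake_decoding_result <- function(mi, bin_centers, K = 2) {
  structure(list(mi = mi, mi_mean = colMeans(mi),
                 mi_sd = apply(mi, 2, sd), bin_centers = bin_centers,
                 K = K, max_mi = log2(K), threshold = log2(K) / 3,
                 significance_mask = colMeans(mi) > log2(K) / 3,
                 config = list()),
            class = "decoding_result")
}
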