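# Pseudo-population construction, feature preselection, the Poisson naive
# Bayes classifier against a brute-force Bayes oracle, plug-in mutual
# information, onset estimation and z comparisons.

flat_rate <- function(u, k, centers) rep(5, length(centers))

test_that("splits hold one data point per condition", {
  centers <- seq(-0.2, 0.8, 0.02)[1:11]
  pop <- make_poisson_population(4, 30, c("Go", "NoGo"), flat_rate,
                                 centers, seed = 1)
  pp <- make_pseudopopulation(pop, seed = 2)
  expect_equal(dim(pp$x), c(4, 11, 2, 30))          # 30 splits x 2 = 60 points
  pop3 <- make_poisson_population(4, 10, c("ring", "small", "big"),
                                  flat_rate, centers, seed = 1)
  pp3 <- make_pseudopopulation(pop3, seed = 2)
  expect_equal(dim(pp3$x)[3:4], c(3, 10))           # 10 splits x 3 = 30 points

  expect_identical(make_pseudopopulation(pop, seed = 2)$x, pp$x)
  expect_error(make_pseudopopulation(pop, n_splits = 31, seed = 1),
               "fewer than 31 trials")

  # every data point is one of the unit's own trials
  u1 <- pop[[1]]
  drawn <- pp$x[1, , 1, ]
  go_rows <- u1$counts[u1$label == "Go", , drop = FALSE]
  expect_true(all(apply(drawn, 2, function(v) {
    any(apply(go_rows, 1, function(r) all(r == v)))
  })))
})

test_that("preselection keeps selective units and drops flat ones", {
  set.seed(3)
  x_flat <- matrix(7, 2, 20)                       # identical condition means
  lab <- factor(rep(c("a", "b"), each = 10))
  expect_equal(preselect_features(x_flat, lab), c(1, 1))

  x_sel <- rbind(c(rpois(10, 2), rpois(10, 40)),
                 rpois(20, 5))
  p <- preselect_features(x_sel, lab)
  expect_lt(p[1], 1e-6)
  # threshold 1 keeps everything (identity mask)
  expect_true(all(p < 1))
})

test_that("Poisson NB training floors rates and recovers class means", {
  lab <- factor(c("a", "b"))
  x1 <- cbind(c(3, 0), c(5, 0))                    # one point per class
  m <- train_poisson_nb(x1, lab)
  expect_equal(m$lambda, cbind(a = c(3, 1e-3), b = c(5, 1e-3)))

  set.seed(4)
  lab2 <- factor(rep(c("a", "b"), each = 200))
  x2 <- rbind(c(rpois(200, 4), rpois(200, 9)))
  m2 <- train_poisson_nb(x2, lab2)
  expect_lt(abs(m2$lambda[1, "a"] - 4), 2 * sqrt(4 / 200))
  expect_lt(abs(m2$lambda[1, "b"] - 9), 2 * sqrt(9 / 200))
})

test_that("classification matches the brute-force Bayes oracle everywhere", {
  # all count configurations up to 3 spikes per bin on small instances
  set.seed(5)
  for (rep in 1:5) {
    n_feat <- sample(2:4, 1)                       # units x bins flattened
    K <- sample(2:3, 1)
    lambda <- matrix(runif(n_feat * K, 0.2, 6), n_feat, K)
    model <- list(lambda = lambda, classes = paste0("c", 1:K), floor = 1e-3)
    grid <- as.matrix(expand.grid(rep(list(0:3), n_feat)))
    pred <- classify_poisson_nb(model, t(grid))
    oracle <- apply(grid, 1, function(x) nb_oracle_predict(lambda, x))
    expect_equal(pred, unname(oracle))
  }

  # perfectly separated rates decode perfectly
  centers <- seq(0, 0.2, 0.02)
  pop <- make_poisson_population(3, 10, c("lo", "hi"), function(u, k, ce) {
    rep(c(0, 10)[k], length(ce))
  }, centers, seed = 6)
  pp <- make_pseudopopulation(pop, seed = 1)
  cv <- mirrorpop:::nb_crossvalidate(pp, seed = 1)
  expect_true(all(cv$mi > 0.99))

  # label shuffling drives accuracy to chance
  pop_sh <- lapply(pop, function(u) {
    u$label <- sample(u$label); u
  })
  attributes(pop_sh) <- attributes(pop)
  pp_sh <- make_pseudopopulation(pop_sh, seed = 2)
  cv_sh <- mirrorpop:::nb_crossvalidate(pp_sh, seed = 2)
  acc <- apply(cv_sh$confusion, 1, function(m) sum(diag(m)) / sum(m))
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / (20 * length(centers))) + 0.05)
})

test_that("plug-in MI matches direct evaluation", {
  expect_equal(mi_from_confusion(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(mi_from_confusion(rbind(c(5, 5), c(5, 5))), 0)
  m <- rbind(c(9, 1), c(1, 9))
  expect_equal(mi_from_confusion(m), mi_plugin_direct(m), tolerance = 1e-12)
  expect_equal(mi_from_confusion(m), 1 - (-0.9 * log2(0.9) - 0.1 * log2(0.1)),
               tolerance = 1e-12)
  expect_error(mi_from_confusion(rbind(c(-1, 0), c(0, 1))), "nonnegative")
})

test_that("normalization constants and subsample arithmetic are exact", {
  expect_equal(max_theoretical_mi(2), 1)
  expect_equal(round(max_theoretical_mi(3), 3), 1.585)
  expect_equal(number_matched_size(c(86, 106, 163)), 65L)
})

test_that("onset estimation applies the 1/3 threshold and 65/N correction", {
  centers <- seq(-0.2, 0.8, 0.02)
  # iterations crossing at known bin indices
  idx <- rep(c(19, 21, 23), length.out = 9)
  mi <- t(vapply(idx, function(ci) {
    as.numeric(seq_along(centers) >= ci) * 0.9
  }, numeric(length(centers))))
  res <- fake_decoding_result(mi, centers, K = 2)
  on <- onset_time(res, n_area = 106)
  cross <- centers[idx]
  expect_equal(on$onset_mean, mean(cross))
  expect_equal(on$onset_se, sd(cross) * 65 / 106)

  # curve above threshold from the first bin
  mi_hi <- matrix(0.9, 3, length(centers))
  expect_equal(onset_time(fake_decoding_result(mi_hi, centers), 10)$onset_mean,
               centers[1])
  # never crossed: onset absent
  mi_lo <- matrix(0.05, 3, length(centers))
  expect_true(is.na(onset_time(fake_decoding_result(mi_lo, centers),
                               10)$onset_mean))
})

test_that("onset z comparisons follow the normal formula", {
  a <- list(onset_mean = 0.1, onset_se = 0.05)
  b <- list(onset_mean = 0.3, onset_se = 0.05)
  cmp <- compare_onsets(a, b)
  expect_equal(cmp$z, -2.828427, tolerance = 1e-6)
  expect_equal(cmp$p, 2 * pnorm(-2.828427), tolerance = 1e-6)
  same <- compare_onsets(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_message(cmp_na <- compare_onsets(a, list(onset_mean = NA,
                                                  onset_se = NA)),
                 "undefined")
  expect_true(is.na(cmp_na$z))
})

test_that("epoch-averaged MI matches constant curves and flags bad windows", {
  centers <- seq(0, 1, 0.02)
  mi <- matrix(0.4, 6, length(centers))
  res <- fake_decoding_result(mi, centers)
  ep <- epoch_average_mi(res, c(0.2, 0.7))
  expect_equal(ep$mean, 0.4)
  expect_error(epoch_average_mi(res, c(5, 6)), "outside")
})

test_that("decoded MI rises where the planted condition difference starts", {
  centers <- seq(-0.2, 0.8, 0.02)
  t_star <- 0.3
  pop <- make_poisson_population(14, 16, c("Go", "NoGo"), function(u, k, ce) {
    base <- rep(2, length(ce))
    if (k == 1) base <- base + 4 * (ce >= t_star)
    base
  }, centers, seed = 7)
  dec <- decode_timecourse(pop, n_subsample = 14, n_iterations = 6,
                           n_runs = 3, seed = 8)
  expect_true(any(dec$significance_mask))
  first_sig <- dec$bin_centers[which(dec$significance_mask)[1]]
  expect_lt(abs(first_sig - t_star), 0.06 + 1e-9)

  # shuffled labels: empty significance mask
  pop_sh <- lapply(pop, function(u) {
    u$label <- sample(u$label); u
  })
  attributes(pop_sh) <- attributes(pop)
  dec_sh <- decode_timecourse(pop_sh, n_subsample = 14, n_iterations = 6,
                              n_runs = 3, seed = 9)
  expect_false(any(dec_sh$significance_mask))

  # MI bounded by log2 K up to smoothing spillover
  expect_true(all(dec$mi <= dec$max_mi * 1.01))
  expect_true(all(dec$mi >= 0))
})

test_that("more iterations stabilize the mean MI curve", {
  centers <- seq(0, 0.3, 0.02)
  pop <- make_poisson_population(8, 12, c("Go", "NoGo"), function(u, k, ce) {
    rep(c(3, 5)[k], length(ce))
  }, centers, seed = 10)
  spread <- function(n_it) {
    curves <- vapply(1:6, function(s) {
      mean(decode_timecourse(pop, n_subsample = 8, n_iterations = n_it,
                             n_runs = 1, seed = 100 + 7 * s + n_it)$mi_mean)
    }, numeric(1))
    sd(curves)
  }
  expect_lt(spread(12), spread(2))
})

test_that("classwise decoding samples a fixed number per class and area", {
  centers <- seq(0, 0.3, 0.02)
  area <- rep(c("AIP", "F5", "F6"), each = 6)
  pop <- make_poisson_population(18, 8, c("Go", "NoGo"), function(u, k, ce) {
    rep(c(2, 6)[k], length(ce))
  }, centers, seed = 11, area = area)
  cls <- rep(c(1, 2), 9)
  res <- classwise_decode(pop, cls, n_per_class_per_area = 4,
                          n_iterations = 2, n_runs = 1, seed = 12)
  expect_named(res, c("1", "2"))
  expect_s3_class(res[["1"]], "decoding_result")

  # a class missing from one area errors cleanly, naming both
  cls_bad <- c(rep(1, 6), rep(1, 6), rep(2, 6))  # class 1 absent from F6
  expect_error(classwise_decode(pop, cls_bad, n_per_class_per_area = 2,
                                n_iterations = 1, n_runs = 1),
               "class 1 has no units in area F6")
})
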