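# Internal helpers shared across modules.

# 32-bit helpers on doubles (doubles hold these values exactly)
mul32 <- function(a, b) {
  a_hi <- a %/% 65536
  a_lo <- a %% 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}
# MurmurHash3 finalizer: full avalanche, so nearby keys give unrelated seeds
fmix32 <- function(h) {
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

#' Derive a reproducible sub-seed from a session seed
#'
#' All stochastic operations take an integer seed; per-unit and per-trial
#' streams are split off a single session seed with this hash so that
#' regenerating one unit does not disturb the others. The hash has full
#' avalanche (MurmurHash3 finalizer), which matters: consecutive integers
#' fed to [set.seed()] yield noticeably correlated streams, so sub-seeds
#' must be scrambled, not sequential.
#'
#' @param seed integer session seed.
#' @param ... integer keys (unit index, trial index, replicate ...).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 3323198485
  for (k in keys)
    h <- fmix32(xor32(mul32(h, 2654435761), as.numeric(k) %% 4294967296))
  as.integer(h %% 2147483647)
}

# evaluate `expr` under a given seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# TRUE for positions inside a run of >= min_run consecutive TRUEs
runs_at_least <- function(mask, min_run) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  keep <- r$values & r$lengths >= min_run
  rep(keep, r$lengths)
}

# Gaussian smoothing on a regular grid; kernel truncated at +/- 3 SD and
# renormalized at the edges so a constant input stays constant.
gaussian_smooth <- function(y, step, sd) {
  if (sd <= 0) return(y)
  half <- max(1L, ceiling(3 * sd / step))
  k <- exp(-0.5 * ((-half:half) * step / sd)^2)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(y[lo:hi] * kk) / sum(kk)
  }
  out
}

# center of 200-ms windows advanced by `step`, fully inside [w1, w2]
bin_centers_in <- function(window, bin_width, step) {
  lo <- window[1] + bin_width / 2
  hi <- window[2] - bin_width / 2
  if (hi < lo - 1e-12) stop("window shorter than one bin")
  seq(lo, hi + 1e-12, by = step)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
}
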