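#' First return map of an ISI series
#'
#' The ordered pairs `(ISI_i, ISI_{i+1})`.  Deterministic dynamics show up
#' as structure (curves, clusters) in this map; an uncorrelated series
#' fills a featureless cloud.
#'
#' @param isis an `isi_series` or numeric vector of at least 2 values.
#' @return A `return_map`: list with a two-column `pairs` matrix.
#' @export
first_return_map <- function(isis) {
  x <- as_isi_vector(isis)
  if (length(x) < 2)
    stop("need at least 2 ISIs for a return map", call. = FALSE)
  structure(list(pairs = cbind(isi_i = x[-length(x)], isi_next = x[-1])),
            class = "return_map")
}

#' @export
print.return_map <- function(x, ...) {
  cat(sprintf("First return map: %d pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' Delay embedding
#'
#' Maps a scalar series to points
#' `X_i = (s_i, ..., s_(i+m-1))`, `i = 1 ... N-m+1` (delay fixed at 1).
#'
#' @param series numeric vector of length at least `m`.
#' @param m embedding dimension.
#' @return An `(N-m+1) x m` matrix, one state point per row.
#' @export
delay_embed <- function(series, m) {
  series <- as.numeric(series)
  n <- length(series)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (n < m) stop("series shorter than embedding dimension", call. = FALSE)
  np <- n - m + 1
  out <- matrix(NA_real_, np, m)
  for (j in seq_len(m)) out[, j] <- series[j:(j + np - 1)]
  out
}

#' Normalized prediction error
#'
#' Nearest-neighbor nonlinear prediction: each delay-embedded point
#' `X_i` with a valid `h`-step future is predicted by the average future
#' of its `k = max(1, round(eps * P))` nearest neighbors (Euclidean
#' distance, self excluded, `P` the number of valid base points), and the
#' root-mean-square prediction error is normalized by the RMS error of
#' the baseline predictor, the mean of the whole series:
#' \deqn{NPE = \sqrt{\sum_i (\hat s_i - s_i)^2} / \sqrt{\sum_i (\bar s - s_i)^2}}
#' Values far below 1 indicate short-term determinism; an uncorrelated
#' series gives values near 1.
#'
#' @param series numeric vector (an ISI series, typically).
#' @param m embedding dimension.
#' @param eps neighbor fraction in (0, 1); the number of neighbors is
#'   `max(1, round(eps * P))`.
#' @param h prediction step: the future of `X_i = (s_i ... s_(i+m-1))` is
#'   `s_(i+m-1+h)`.
#' @param theiler temporal exclusion window around each base point
#'   (0 = exclude only the point itself).
#' @return The NPE value (non-negative scalar).
#' @export
npe <- function(series, m = 4, eps = 0.01, h = 1, theiler = 0) {
  series <- as.numeric(series)
  n <- length(series)
  if (eps <= 0 || eps >= 1) stop("'eps' must be in (0, 1)", call. = FALSE)
  if (h < 1) stop("'h' must be >= 1", call. = FALSE)
  if (n < m + h + 10)
    stop("series too short for this embedding and horizon", call. = FALSE)
  if (stats::var(series) == 0)
    stop("series has zero variance", call. = FALSE)
  # valid base points: those with an h-step future inside the series
  p_valid <- n - m + 1 - h
  if (p_valid < 2)
    stop("series too short for this embedding and horizon", call. = FALSE)
  X <- delay_embed(series, m)[seq_len(p_valid), , drop = FALSE]
  fut <- series[(m + h):(m + h + p_valid - 1)]
  k <- max(1L, as.integer(round(eps * p_valid)))
  D <- as.matrix(stats::dist(X))
  pred <- numeric(p_valid)
  for (i in seq_len(p_valid)) {
    d <- D[i, ]
    excl <- abs(seq_len(p_valid) - i) <= theiler
    d[excl] <- Inf
    # ties broken by smaller index (order() is stable)
    nb <- order(d)[seq_len(k)]
    pred[i] <- mean(fut[nb])
  }
  xbar <- mean(series)
  sqrt(sum((pred - fut)^2)) / sqrt(sum((xbar - fut)^2))
}

#' Random-shuffle surrogate
#'
#' A uniformly random permutation of the series (Fisher-Yates under a
#' seeded generator).  The value distribution is preserved exactly; all
#' temporal structure is destroyed.  The caller's RNG state is left
#' untouched.
#'
#' @param series numeric vector of length at least 2.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return The permuted series.
#' @export
surrogate_shuffle <- function(series, seed) {
  series <- as.numeric(series)
  if (length(series) < 2) stop("need at least 2 values", call. = FALSE)
  with_preserved_rng({
    set.seed(seed)
    sample(series)
  })
}

# evaluate expr without disturbing the caller's RNG state
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Surrogate-data determinism test
#'
#' Computes the normalized prediction error for `h = 1 ... h_max` on the
#' original series and on an ensemble of independent random-shuffle
#' surrogates, and summarizes the ensemble by its per-step mean and
#' standard deviation.  A deterministic series shows `npe_original` well
#' below the surrogate band at short horizons; the surrogates themselves
#' sit near 1 at every horizon.
#'
#' @inheritParams npe
#' @param h_max largest prediction step.
#' @param n_surrogates ensemble size.
#' @param seed seed for the surrogate permutations (surrogate `j` uses
#'   `seed + j`).
#' @return An `npe_result`: list with `h_values`, `npe_original`,
#'   `npe_surrogate_mean`, `npe_surrogate_sd`, the per-surrogate matrix
#'   `npe_surrogates` (`n_surrogates` rows) and the `config` used.
#' @export
npe_test <- function(series, m = 4, eps = 0.01, h_max = 10,
                     n_surrogates = 10, seed = 1, theiler = 0) {
  series <- as.numeric(series)
  hs <- seq_len(h_max)
  orig <- vapply(hs, function(h) npe(series, m, eps, h, theiler), 0)
  surr <- matrix(NA_real_, n_surrogates, h_max)
  for (j in seq_len(n_surrogates)) {
    s <- surrogate_shuffle(series, seed + j)
    surr[j, ] <- vapply(hs, function(h) npe(s, m, eps, h, theiler), 0)
  }
  structure(list(h_values = hs, npe_original = orig,
                 npe_surrogate_mean = colMeans(surr),
                 npe_surrogate_sd = apply(surr, 2, stats::sd),
                 npe_surrogates = surr,
                 config = list(m = m, eps = eps, h_max = h_max,
                               n_surrogates = n_surrogates, seed = seed,
                               theiler = theiler)),
            class = "npe_result")
}

#' @export
print.npe_result <- function(x, ...) {
  cat(sprintf("NPE test (m = %d, eps = %g, %d surrogates)\n",
              x$config$m, x$config$eps, x$config$n_surrogates))
  df <- data.frame(h = x$h_values, npe = round(x$npe_original, 4),
                   surr_mean = round(x$npe_surrogate_mean, 4),
                   surr_sd = round(x$npe_surrogate_sd, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
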