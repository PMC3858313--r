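# Independent oracles used by the tests.  These deliberately avoid the
# package's own implementation paths.

# Equilibrium of the HR flow by bisection on the reduced steady-state
# equation: at an equilibrium y = c - d x^2 and z = s (x - x_rest), so
# g(x) = c - d x^2 - a x^3 + b x^2 - s (x - x_rest) + I = 0.
hr_equilibrium_oracle <- function(params, lower = -4, upper = 4,
                                  tol = 1e-12) {
  g <- function(x) params$c - params$d * x^2 - params$a * x^3 +
    params$b * x^2 - params$s * (x - params$x_rest) + params$I
  xs <- seq(lower, upper, length.out = 4001)
  gs <- g(xs)
  i <- which(gs[-1] * gs[-length(gs)] <= 0)[1]
  stopifnot(!is.na(i))
  lo <- xs[i]; hi <- xs[i + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  c(x = x, y = params$c - params$d * x^2,
    z = params$s * (x - params$x_rest))
}

# central-difference Jacobian of hr_derivative
numeric_jacobian <- function(state, params, eps = 1e-6) {
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    up <- state; dn <- state
    up[j] <- up[j] + eps; dn[j] <- dn[j] - eps
    J[, j] <- (hr_derivative(up, params) - hr_derivative(dn, params)) /
      (2 * eps)
  }
  J
}

# naive nearest-neighbor NPE: plain loops, no distance matrix; mirrors
# the definition directly and independently of the package's vectorized
# implementation
naive_npe <- function(series, m, eps, h) {
  n <- length(series)
  p <- n - m + 1 - h
  X <- t(vapply(seq_len(p), function(i) series[i:(i + m - 1)],
                numeric(m)))
  fut <- vapply(seq_len(p), function(i) series[i + m - 1 + h], 0)
  k <- max(1L, as.integer(round(eps * p)))
  pred <- numeric(p)
  for (i in seq_len(p)) {
    d <- rep(Inf, p)
    for (j in seq_len(p)) {
      if (j == i) next
      d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    nb <- integer(0)
    remaining <- seq_len(p)
    for (s in seq_len(k)) {
      best <- remaining[which.min(d[remaining])]
      nb <- c(nb, best)
      remaining <- setdiff(remaining, best)
    }
    pred[i] <- mean(fut[nb])
  }
  sqrt(sum((pred - fut)^2)) / sqrt(sum((mean(series) - fut)^2))
}

# 1-D cluster-counting period oracle: the number of distinct ISI values
# at a relative tolerance (gaps in the sorted values larger than
# tol * mean split clusters)
isi_cluster_count <- function(isis, rel_tol = 0.01) {
  x <- sort(isis)
  1L + sum(diff(x) > rel_tol * mean(x))
}

# exactly k-periodic ISI series from a random base pattern
make_periodic_series <- function(k, reps = 60, seed = 1) {
  set.seed(seed)
  repeat {
    # k strictly increasing, well-separated values: a cycle of k distinct
    # values has fundamental period exactly k
    base <- sort(stats::runif(k, 0.1, 1))
    if (k == 1 || min(diff(base)) > 0.05) break
  }
  rep(base, reps)
}

# cached chaotic ISI series at the reference point (I=2.53, r=0.0245)
chaotic_isis <- local({
  cache <- NULL
  function(n = 500) {
    if (is.null(cache) || length(cache) < n) {
      sim <- simulate_isis(hr_params(I = 2.53, r = 0.0245), n_isis = 1000,
                           t_max = 2e5)
      cache <<- sim$isis$isis
    }
    utils::tail(cache, n)
  }
})

# character labels of a list of regime_label objects
segment_labels_of <- function(labels) vapply(labels, format, "")
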