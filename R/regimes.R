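#' Regime label
#'
#' A classification of a firing pattern: `periodic` (with its period, the
#' number of distinct ISIs per repeating cycle), `chaotic`, `stochastic`,
#' `quiescent`, or `unclassified`.  `evidence` carries the diagnostics the
#' decision was based on (e.g. `lle`, `npe_h1`, `period_tol_used`).
#'
#' @param kind one of `"periodic"`, `"chaotic"`, `"stochastic"`,
#'   `"quiescent"`, `"unclassified"`.
#' @param period integer period, required iff `kind == "periodic"`.
#' @param evidence named list of diagnostic values.
#' @return A `regime_label` object.
#' @export
regime_label <- function(kind, period = NULL, evidence = list()) {
  kind <- match.arg(kind, c("periodic", "chaotic", "stochastic",
                            "quiescent", "unclassified"))
  if (kind == "periodic") {
    if (is.null(period) || period < 1)
      stop("periodic labels need a period >= 1", call. = FALSE)
    period <- as.integer(period)
  } else if (!is.null(period)) {
    stop("only periodic labels carry a period", call. = FALSE)
  }
  structure(list(kind = kind, period = period, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.regime_label <- function(x, ...) {
  if (x$kind == "periodic") sprintf("period-%d", x$period) else x$kind
}

# equality for merging purposes: same kind and, if periodic, same period
same_label <- function(a, b) {
  a$kind == b$kind && identical(a$period, b$period)
}

#' Classification settings
#'
#' Shared configuration for regime classification.
#'
#' @param rel_tol relative ISI tolerance for period detection on noiseless
#'   model output.
#' @param rel_tol_noisy tolerance for jittered or experimental-like series.
#' @param k_max largest period searched.
#' @param lle_threshold Lyapunov exponent (per model-time unit) above which
#'   an aperiodic noiseless point is called chaotic; aperiodic points below
#'   it are left unclassified (guards against long transients).
#' @param n_isis ISIs collected per parameter point.
#' @param tail_n number of trailing ISIs analyzed for periodicity.
#' @param min_len minimum series length for data-driven classification.
#' @param dt,t_transient,transient_spikes,t_max integration settings, as in
#'   [simulate_isis].
#' @param lle_t_transient,lle_t_average Lyapunov settings, as in
#'   [largest_lyapunov].
#' @param npe_m,npe_eps,npe_h_max,npe_surrogates,npe_seed settings of the
#'   nonlinear-prediction determinism test, as in [npe_test].
#' @return A list of class `regime_config`.
#' @export
regime_config <- function(rel_tol = 0.01, rel_tol_noisy = 0.05, k_max = 8,
                          lle_threshold = 0.001, n_isis = 300,
                          tail_n = 200, min_len = 200, dt = 0.01,
                          t_transient = 500, transient_spikes = 50,
                          t_max = 4e4, lle_t_transient = 500,
                          lle_t_average = 5000, npe_m = 4, npe_eps = 0.01,
                          npe_h_max = 10, npe_surrogates = 10,
                          npe_seed = 1) {
  structure(as.list(environment()), class = "regime_config")
}

as_isi_vector <- function(isis) {
  if (inherits(isis, "isi_series")) isis$isis else as.numeric(isis)
}

# Jitter-robust period detector used for noisy/experimental-like series.
# For each candidate k the ISIs fall into k phase classes; the series is
# period-k when every phase is "tight" around its own median:
#   (a) the phase's robust scale (80th percentile of |v - median(v)|,
#       divided by 1.282, the Gaussian q80 factor) is below
#       1.5 * rel_tol * median(v) -- accepts multiplicative Gaussian
#       jitter up to cv = rel_tol with a 1.5x estimation margin; and
#   (b) no value deviates by more than 8 * rel_tol * median(v) -- a
#       Gaussian phase stays under ~3.5 cv, while chaotic or alternating
#       series place occasional far excursions (long or skipped
#       intervals) in the phase, which this cap rejects even when the
#       bulk of the phase is narrow.
# The deterministic max-difference rule of classify_period() cannot play
# this role: with Gaussian jitter its statistic concentrates near
# 4 * cv, so a 5% tolerance would reject 5% jitter outright.
robust_period <- function(x, rel_tol, k_max, tail_n = length(x)) {
  x <- utils::tail(x, tail_n)
  n <- length(x)
  for (k in seq_len(k_max)) {
    ok <- all(vapply(seq_len(k), function(ph) {
      v <- x[seq(ph, n, by = k)]
      m <- stats::median(v)
      dev <- abs(v - m)
      sigma_hat <- stats::quantile(dev, 0.8, names = FALSE) / 1.282
      sigma_hat < 1.5 * rel_tol * m && max(dev) < 8 * rel_tol * m
    }, TRUE))
    if (ok) return(k)
  }
  NA_integer_
}

#' Detect the period of an ISI series
#'
#' The period is the smallest `k <= k_max` such that the series, over its
#' analyzed tail, satisfies `|isi[i+k] - isi[i]| / mean(isis) < rel_tol`
#' for all `i`.  A period-2 series is therefore reported as 2, never 4.
#'
#' @param isis an `isi_series` or numeric vector.
#' @param rel_tol relative tolerance (fraction of the mean ISI).
#' @param k_max largest period tried.
#' @param tail_n number of trailing values analyzed (the series must be at
#'   least `4 * k_max` long).
#' @return The integer period, or `NA_integer_` if no period `<= k_max`
#'   fits (an aperiodic tail).
#' @export
classify_period <- function(isis, rel_tol = 0.01, k_max = 8,
                            tail_n = 200) {
  x <- as_isi_vector(isis)
  if (length(x) < 4 * k_max)
    stop(sprintf("need at least %d ISIs to test periods up to %d",
                 4 * k_max, k_max), call. = FALSE)
  x <- utils::tail(x, tail_n)
  n <- length(x)
  mu <- mean(x)
  for (k in seq_len(k_max)) {
    if (max(abs(x[(k + 1):n] - x[1:(n - k)])) / mu < rel_tol)
      return(k)
  }
  NA_integer_
}

#' Classify a noiseless parameter point
#'
#' Simulates the deterministic model at `params`, discards the transient,
#' and labels the point: `quiescent` if fewer than 2 spikes remain,
#' `periodic(k)` if [classify_period] finds a period, otherwise `chaotic`
#' when the largest Lyapunov exponent exceeds the configured threshold and
#' `unclassified` when it does not.
#'
#' @param params an [hr_params] object with zero noise.
#' @param config a [regime_config].
#' @param initial initial state (useful for continuation along scans).
#' @return A [regime_label] with populated evidence.
#' @export
classify_point <- function(params, config = regime_config(),
                           initial = hr_initial_state()) {
  if (params$noise_intensity > 0)
    stop("classify_point applies to the noiseless model", call. = FALSE)
  sim <- simulate_isis(params, n_isis = config$n_isis, initial = initial,
                       dt = config$dt, t_transient = config$t_transient,
                       transient_spikes = config$transient_spikes,
                       t_max = config$t_max)
  if (!is.na(sim$blowup_time))
    return(regime_label("unclassified",
                        evidence = list(error = "blowup",
                                        blowup_time = sim$blowup_time)))
  if (is.null(sim$isis) || length(sim$isis$isis) < 2)
    return(regime_label("quiescent",
                        evidence = list(n_spikes = length(sim$spike_times))))
  k <- tryCatch(classify_period(sim$isis, rel_tol = config$rel_tol,
                                k_max = config$k_max,
                                tail_n = config$tail_n),
                error = function(e) NA_integer_)
  if (!is.na(k))
    return(regime_label("periodic", period = k,
                        evidence = list(period_tol_used = config$rel_tol)))
  lle <- largest_lyapunov(params, t_transient = config$lle_t_transient,
                          t_average = config$lle_t_average,
                          dt = config$dt, initial = sim$end_state)
  ev <- list(lle = lle, period_tol_used = config$rel_tol)
  if (lle > config$lle_threshold) regime_label("chaotic", evidence = ev)
  else regime_label("unclassified", evidence = ev)
}

#' Classify an ISI series (data only)
#'
#' For records where no Lyapunov exponent is computable (experimental or
#' experimental-like data): the series is `periodic(k)` if a period fits
#' under the noise-tolerant, jitter-robust phase test (the smallest `k`
#' whose phase classes are all tight, measured by the phase median
#' absolute deviation relative to the series median -- tolerant of
#' multiplicative jitter up to about `rel_tol_noisy`); otherwise it is
#' `chaotic` when the
#' normalized prediction error of the original series at one-step
#' prediction falls below the random-shuffle surrogate ensemble's
#' mean minus 3 standard deviations (short-term predictability that
#' shuffling destroys), and `stochastic` when it does not.
#'
#' @param isis an `isi_series` or numeric vector.
#' @param config a [regime_config].
#' @return A [regime_label] with `npe_h1`, `surr_mean_h1`, `surr_sd_h1`
#'   evidence for aperiodic series.
#' @export
classify_series <- function(isis, config = regime_config()) {
  x <- as_isi_vector(isis)
  if (length(x) < config$min_len)
    stop(sprintf("need at least %d ISIs (got %d)", config$min_len,
                 length(x)), call. = FALSE)
  k <- robust_period(x, rel_tol = config$rel_tol_noisy,
                     k_max = config$k_max, tail_n = config$tail_n)
  if (!is.na(k))
    return(regime_label("periodic", period = k,
                        evidence = list(period_tol_used =
                                          config$rel_tol_noisy)))
  res <- npe_test(x, m = config$npe_m, eps = config$npe_eps,
                  h_max = config$npe_h_max,
                  n_surrogates = config$npe_surrogates,
                  seed = config$npe_seed)
  npe1 <- res$npe_original[1]
  cut <- res$npe_surrogate_mean[1] - 3 * res$npe_surrogate_sd[1]
  ev <- list(npe_h1 = npe1, surr_mean_h1 = res$npe_surrogate_mean[1],
             surr_sd_h1 = res$npe_surrogate_sd[1],
             period_tol_used = config$rel_tol_noisy)
  if (npe1 < cut) regime_label("chaotic", evidence = ev)
  else regime_label("stochastic", evidence = ev)
}

#' Regime segment
#'
#' A half-open run `[start_index, end_index)` of ISIs sharing a regime.
#'
#' @param label a [regime_label].
#' @param start_index,end_index ISI indices, `end_index > start_index`.
#' @param start_time,end_time optional record times.
#' @return A `regime_segment` object.
#' @export
regime_segment <- function(label, start_index, end_index,
                           start_time = NA_real_, end_time = NA_real_) {
  if (end_index <= start_index)
    stop("end_index must exceed start_index", call. = FALSE)
  structure(list(label = label, start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 start_time = start_time, end_time = end_time),
            class = "regime_segment")
}

#' @export
print.regime_segment <- function(x, ...) {
  cat(sprintf("[%d, %d) %s\n", x$start_index, x$end_index,
              format(x$label)))
  invisible(x)
}

#' Segment a nonstationary ISI record into regimes
#'
#' Classifies a sliding window (step 1) along the record with the
#' data-driven rules of [classify_series], merges runs of equal labels,
#' drops runs shorter than one window (absorbing them into the preceding
#' segment), and places each boundary at the center of the transition
#' window.  The returned segments are ordered, non-overlapping and cover
#' the whole record.
#'
#' @param isis an `isi_series` (record times, when present as
#'   `origin_times`, are attached to the segments) or numeric vector.
#' @param window window length in ISIs.
#' @param config a [regime_config]; `min_len` is ignored (the window is
#'   the analysis length).
#' @param step window step; 1 gives the finest boundaries, larger values
#'   trade resolution for speed.
#' @return List of [regime_segment]s.
#' @export
segment_scenario <- function(isis, window = 100, config = regime_config(),
                             step = 1) {
  x <- as_isi_vector(isis)
  times <- if (inherits(isis, "isi_series")) isis$origin_times else NULL
  n <- length(x)
  if (n < 2 * window)
    stop("record must be at least two windows long", call. = FALSE)
  starts <- seq(1, n - window + 1, by = step)
  cfg <- config
  cfg$min_len <- window
  cfg$tail_n <- window
  cfg$npe_h_max <- 1  # the chaos/stochastic call only uses h = 1
  labs <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    w <- x[starts[j]:(starts[j] + window - 1)]
    labs[[j]] <- classify_series(w, cfg)
  }
  # run-length encode window labels
  runs <- list()
  run_start <- 1
  for (j in seq_along(labs)) {
    if (j < length(labs) && same_label(labs[[j + 1]], labs[[run_start]]))
      next
    runs[[length(runs) + 1]] <- list(label = labs[[run_start]],
                                     from = run_start, to = j)
    run_start <- j + 1
  }
  # provisional ISI-index segments, each boundary at the center of the
  # transition window
  segs <- lapply(seq_along(runs), function(idx) {
    lo <- if (idx == 1) 1L else
      as.integer(starts[runs[[idx - 1]]$to] + floor(window / 2))
    hi <- if (idx == length(runs)) n + 1L else
      as.integer(starts[runs[[idx]]$to] + floor(window / 2))
    list(label = runs[[idx]]$label, lo = lo, hi = max(hi, lo + 1L))
  })
  # windows straddling a regime change produce spurious short runs (a
  # half-and-half window is aperiodic and often registers as chaotic);
  # such segments are shorter than one window by construction, so drop
  # any sub-window segment, absorbing it into its longer neighbor, and
  # re-merge equal labels, until all segments span at least one window
  repeat {
    if (length(segs) <= 1) break
    len <- vapply(segs, function(s) s$hi - s$lo, 0L)
    short <- which(len < window)
    if (length(short) == 0) break
    i <- short[which.min(len[short])]
    left <- if (i > 1) len[i - 1] else -1L
    right <- if (i < length(segs)) len[i + 1] else -1L
    if (left >= right) {
      segs[[i - 1]]$hi <- segs[[i]]$hi
    } else {
      segs[[i + 1]]$lo <- segs[[i]]$lo
    }
    segs[[i]] <- NULL
    j <- 1
    while (j < length(segs)) {
      if (same_label(segs[[j]]$label, segs[[j + 1]]$label)) {
        segs[[j]]$hi <- segs[[j + 1]]$hi
        segs[[j + 1]] <- NULL
      } else j <- j + 1
    }
  }
  lapply(segs, function(s) {
    st <- if (!is.null(times)) times[s$lo] else NA_real_
    et <- if (!is.null(times)) times[min(s$hi - 1, n)] else NA_real_
    regime_segment(s$label, s$lo, s$hi, st, et)
  })
}

#' Compact label sequence of a segment list
#'
#' @param segments list of [regime_segment]s (or a `bifurcation_scenario`).
#' @return Character vector such as `c("period-1", "chaotic", "period-2")`.
#' @export
segment_labels <- function(segments) {
  if (inherits(segments, "bifurcation_scenario"))
    return(vapply(segments$labels, format, ""))
  vapply(segments, function(s) format(s$label), "")
}
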