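#' Specification of a synthetic experimental-like record
#'
#' Describes how to emulate a pacemaker recording: the model parameters
#' (or a slow drift along a parameter line for "washout" records, where
#' the perfusing solution changes the membrane dynamics gradually),
#' multiplicative ISI jitter standing in for measurement and biological
#' variability, and an optional sampling-rate quantization emulating a
#' digitized acquisition system.
#'
#' @param base_params an [hr_params] object; for washout records this is
#'   overridden point-by-point by the drift line.
#' @param drift_line a [parameter_line] along which `(I, r)` drifts, or
#'   `NULL` for stationary records.
#' @param drift_profile `"exponential"` (approach toward the line's end
#'   with time constant `duration / 3`, mirroring the gradual and
#'   continual effect of a solution change) or `"linear"`.
#' @param duration drift duration in model-time units (required with a
#'   drift line).
#' @param isi_jitter_cv coefficient of variation of multiplicative
#'   Gaussian ISI jitter (must be < 0.2).
#' @param sampling_rate samples per time unit; spike times are quantized
#'   to `1 / sampling_rate` before ISIs are formed (use `1e4` to emulate
#'   a 10 kHz acquisition of a seconds-scale record), or `NULL` for no
#'   quantization.
#' @param seed integer seed; all randomness in the generators derives
#'   from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(base_params, drift_line = NULL,
                           drift_profile = c("exponential", "linear"),
                           duration = NULL, isi_jitter_cv = 0.005,
                           sampling_rate = NULL, seed = 1) {
  drift_profile <- match.arg(drift_profile)
  if (isi_jitter_cv < 0 || isi_jitter_cv >= 0.2)
    stop("isi_jitter_cv must be in [0, 0.2)", call. = FALSE)
  if (!is.null(drift_line)) {
    if (is.null(duration) || duration <= 0)
      stop("a drift line needs a positive duration", call. = FALSE)
    stopifnot(inherits(drift_line, "parameter_line"))
  }
  structure(list(base_params = base_params, drift_line = drift_line,
                 drift_profile = drift_profile, duration = duration,
                 isi_jitter_cv = isi_jitter_cv,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

quantize_times <- function(times, rate) {
  if (is.null(rate)) times else round(times * rate) / rate
}

apply_jitter <- function(isis, cv) {
  if (cv <= 0) return(isis)
  jit <- isis * (1 + cv * stats::rnorm(length(isis)))
  pmax(jit, 0.01 * isis)  # clip positive
}

#' Stationary synthetic ISI record
#'
#' Integrates the noiseless model at `base_params` until `n_isis`
#' post-transient ISIs are collected, optionally quantizes the spike
#' times, multiplies each ISI by `(1 + cv * N(0,1))` (clipped positive),
#' and attaches the noiseless regime label as ground truth.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_spec] without drift line.
#' @param n_isis number of ISIs to generate.
#' @param config a [regime_config] used for the ground-truth label.
#' @return List with `isis` (an `isi_series`) and `truth` (a
#'   [regime_label]).
#' @export
gen_stationary <- function(spec, n_isis = 500, config = regime_config()) {
  if (!is.null(spec$drift_line))
    stop("gen_stationary is for drift-free specs; see gen_washout",
         call. = FALSE)
  params <- spec$base_params
  if (params$noise_intensity > 0)
    stop("stationary records are generated from the noiseless model",
         call. = FALSE)
  cfg <- config
  cfg$n_isis <- max(config$n_isis, n_isis)
  sim <- simulate_isis(params, n_isis = n_isis, dt = config$dt,
                       t_transient = config$t_transient,
                       transient_spikes = config$transient_spikes,
                       t_max = 1e6)
  if (is.null(sim$isis) || length(sim$isis$isis) < n_isis)
    stop("parameters do not sustain firing; cannot generate", call. = FALSE)
  truth <- classify_point(params, cfg)
  spikes <- quantize_times(sim$spike_times, spec$sampling_rate)
  raw <- diff(spikes)
  raw <- utils::tail(raw[raw > 0], n_isis)
  out <- with_preserved_rng({
    set.seed(spec$seed)
    apply_jitter(raw, spec$isi_jitter_cv)
  })
  list(isis = isi_series(out, units = "model_time"), truth = truth)
}

#' Locate a period-adding boundary along a line
#'
#' Bisection on the line fraction for the boundary where the noiseless
#' period label steps from `k` to `k + 1` (period-adding without chaos,
#' as found at low `r` left of the comb-shaped region).
#'
#' @param line a [parameter_line] whose start lies in the period-`k`
#'   regime and whose end lies in period-`k+1`.
#' @param k the period on the start side.
#' @param config a [regime_config].
#' @param tol bisection tolerance on the line fraction.
#' @return List with `fraction`, `I`, `r` of the boundary and the
#'   bracketing labels.
#' @export
find_period_adding_boundary <- function(line, k, config = regime_config(),
                                        tol = 1 / 512) {
  pts <- function(f) list(I = line$start[1] + f * (line$end[1] -
                                                     line$start[1]),
                          r = line$start[2] + f * (line$end[2] -
                                                     line$start[2]))
  lab_at <- function(f) {
    p <- pts(f)
    classify_point(hr_params(I = p$I, r = p$r), config)
  }
  is_k <- function(lab) lab$kind == "periodic" && lab$period == k
  lo <- 0; hi <- 1
  l_lo <- lab_at(lo); l_hi <- lab_at(hi)
  if (!is_k(l_lo))
    stop(sprintf("line start is %s, not period-%d", format(l_lo), k),
         call. = FALSE)
  if (is_k(l_hi))
    stop("line end still has the starting period", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_k(lab_at(mid))) lo <- mid else hi <- mid
  }
  f <- (lo + hi) / 2
  p <- pts(f)
  list(fraction = f, I = p$I, r = p$r, label_low = l_lo,
       label_high = l_hi)
}

#' Noise-induced stochastic alternation at a period-adding boundary
#'
#' Places the model at a period-adding bifurcation point (located by
#' bisection along `boundary_line` when `spec$base_params` carries no
#' noise placement there) and integrates with additive noise.  Near the
#' boundary, noise makes the firing alternate irregularly between the
#' period-`k` and period-`(k+1)` patterns: the ISI values still fall in
#' the two patterns' clusters, but the sequence of cluster visits is
#' random -- stochastic firing, as opposed to chaos.
#'
#' @param spec a [synthetic_spec]; `base_params$noise_intensity` sets the
#'   noise.  Zero noise is the degenerate control (a purely periodic
#'   record); an intensity of about 0.1 on the recovery equation gives a
#'   clear irregular alternation between the adjacent patterns.
#' @param n_isis number of ISIs.
#' @param boundary_line line along which the boundary is located; the
#'   default low-`r` segment crosses the period-3 to period-4 boundary.
#' @param k period on the start side of the boundary.
#' @param config a [regime_config].
#' @return List with `isis`, `truth` (a [regime_label]: `stochastic`, or
#'   `periodic` with a warning when the noise failed to induce
#'   alternation), and `boundary` (from [find_period_adding_boundary]).
#' @export
gen_stochastic_alternation <- function(spec, n_isis = 500,
                                       boundary_line =
                                         parameter_line("P34",
                                                        c(2.50, 0.0055),
                                                        c(2.53, 0.0040)),
                                       k = 3,
                                       config = regime_config()) {
  bd <- find_period_adding_boundary(boundary_line, k, config)
  sigma <- spec$base_params$noise_intensity
  noiseless_control <- sigma == 0
  params <- hr_params(I = bd$I, r = bd$r, noise_intensity = sigma,
                      noise_on = spec$base_params$noise_on)
  sim <- with_preserved_rng({
    set.seed(spec$seed)
    simulate_isis(params, n_isis = n_isis, dt = config$dt,
                  t_transient = config$t_transient,
                  transient_spikes = config$transient_spikes,
                  t_max = 1e6)
  })
  if (is.null(sim$isis) || length(sim$isis$isis) < n_isis)
    stop("boundary parameters do not sustain firing", call. = FALSE)
  x <- sim$isis$isis
  # alternation check: does the sequence of periodic patterns vary?
  kk <- robust_period(x, rel_tol = config$rel_tol_noisy,
                      k_max = config$k_max, tail_n = config$tail_n)
  if (!is.na(kk)) {
    if (!noiseless_control)
      warning("noise too small to induce alternation; record is periodic",
              call. = FALSE)
    truth <- regime_label("periodic", period = kk,
                          evidence = list(noise_intensity = sigma))
  } else {
    truth <- regime_label("stochastic",
                          evidence = list(noise_intensity = sigma,
                                          boundary_I = bd$I,
                                          boundary_r = bd$r))
  }
  list(isis = isi_series(x, units = "model_time"), truth = truth,
       boundary = bd)
}

#' Nonstationary "washout" record with slowly drifting parameters
#'
#' Integrates the model while `(I, r)` moves continuously along
#' `spec$drift_line` under the drift profile over `spec$duration`,
#' emulating the gradual change of membrane dynamics as the extracellular
#' solution is replaced.  The true regime schedule is obtained from a
#' stationary pre-scan of the same line: each scan regime's boundary
#' fraction is mapped through the drift profile to a record time.
#'
#' @param spec a [synthetic_spec] with a drift line.
#' @param config a [regime_config].
#' @param prescan_points resolution of the stationary pre-scan.
#' @return List with `isis` (time-stamped `isi_series`), `truth_segments`
#'   (list of [regime_segment]s with ISI indices and record times) and
#'   `scenario` (the stationary pre-scan scenario).
#' @export
gen_washout <- function(spec, config = regime_config(),
                        prescan_points = 60) {
  line <- spec$drift_line
  if (is.null(line)) stop("spec has no drift line", call. = FALSE)
  zero_length <- all(line$start == line$end)
  profile_code <- if (spec$drift_profile == "linear") 1L else 2L
  drift <- c(profile_code, spec$duration, line$start[1], line$start[2],
             line$end[1], line$end[2])
  params <- hr_params(I = line$start[1], r = line$start[2],
                      noise_intensity =
                        spec$base_params$noise_intensity,
                      noise_on = spec$base_params$noise_on)
  res <- with_preserved_rng({
    set.seed(spec$seed)
    hr_spikes_cpp(pars_vec(params), hr_initial_state(), spec$duration,
                  config$dt, params$noise_intensity,
                  as.integer(params$noise_on == "y"), 0, 1, -1L, drift)
  })
  st <- res$spike_times
  truncated <- !is.na(res$blowup_time)
  keep <- st >= config$t_transient
  st <- st[keep]
  if (length(st) < 2)
    stop("drift record contains too few spikes", call. = FALSE)
  st_q <- quantize_times(st, spec$sampling_rate)
  raw <- diff(st_q)
  ok <- raw > 0
  raw <- raw[ok]
  end_times <- st_q[-1][ok]
  out <- with_preserved_rng({
    set.seed(spec$seed + 1L)
    apply_jitter(raw, spec$isi_jitter_cv)
  })
  isis <- isi_series(out, units = "model_time", origin_times = end_times)
  # truth schedule from a stationary pre-scan of the same line
  if (zero_length) {
    lab <- classify_point(hr_params(I = line$start[1], r = line$start[2]),
                          config)
    truth <- list(regime_segment(lab, 1, length(out) + 1,
                                 end_times[1], end_times[length(end_times)]))
    scen <- NULL
  } else {
    scan <- scan_line(parameter_line(line$name, line$start, line$end,
                                     prescan_points), config)
    scen <- extract_scenario(scan)
    # map run boundaries (line fractions) to record times through the
    # drift profile, then to ISI indices
    frac_to_time <- function(f) {
      if (spec$drift_profile == "linear") f * spec$duration
      else {
        # f = 1 - exp(-3 t / T)  =>  t = -T/3 log(1 - f)
        f <- pmin(f, 1 - 1e-12)
        -spec$duration / 3 * log(1 - f)
      }
    }
    nseg <- length(scen$labels)
    pts <- line_points(parameter_line(line$name, line$start, line$end,
                                      prescan_points))
    truth <- list()
    for (s in seq_len(nseg)) {
      f_lo <- if (s == 1) 0 else
        (pts$fraction[scen$to_index[s - 1]] +
           pts$fraction[scen$from_index[s]]) / 2
      f_hi <- if (s == nseg) 1 else
        (pts$fraction[scen$to_index[s]] +
           pts$fraction[scen$from_index[s + 1]]) / 2
      t_lo <- frac_to_time(f_lo); t_hi <- frac_to_time(f_hi)
      idx <- which(end_times >= t_lo & end_times < t_hi)
      if (length(idx) == 0) next
      truth[[length(truth) + 1]] <-
        regime_segment(scen$labels[[s]], min(idx), max(idx) + 1,
                       end_times[min(idx)], end_times[max(idx)])
    }
  }
  list(isis = isis, truth_segments = truth, scenario = scen,
       truncated = truncated)
}
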