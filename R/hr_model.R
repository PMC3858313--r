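#' Hindmarsh-Rose model parameters
#'
#' Bundles the eight constants of the Hindmarsh-Rose (HR) three-variable
#' neuron model together with the two bifurcation parameters used throughout
#' this package -- the injected current `I` and the slow time-scale constant
#' `r` -- and an additive noise intensity for stochastic simulations.
#' All quantities are dimensionless, as is conventional for the HR model.
#'
#' The deterministic flow is
#' \deqn{dx/dt = y - a x^3 + b x^2 - z + I}
#' \deqn{dy/dt = c - d x^2 - y}
#' \deqn{dz/dt = r (s (x - x_{rest}) - z)}
#' where `x` is the membrane potential, `y` the recovery variable and `z`
#' the slow adaption current.
#'
#' @param I injected current (dimensionless).
#' @param r slow time-scale constant; must be positive.
#' @param a,b,c,d,s,x_rest fixed model constants.  The defaults
#'   (1, 3, 1, 5, 4, -1.6) are the values standardly used for two-parameter
#'   studies of the model in the `(I, r)` plane.
#' @param noise_intensity standard-deviation scale of additive white noise;
#'   0 gives the deterministic model.
#' @param noise_on which equation receives the noise term, `"y"` (default)
#'   or `"x"`.
#' @return An object of class `hr_params`.
#' @examples
#' p <- hr_params(I = 2.53, r = 0.0245)
#' hr_derivative(c(0, 0, 0), p)
#' @export
hr_params <- function(I, r, a = 1, b = 3, c = 1, d = 5, s = 4,
                      x_rest = -1.6, noise_intensity = 0,
                      noise_on = c("y", "x")) {
  noise_on <- match.arg(noise_on)
  vals <- c(I = I, r = r, a = a, b = b, c = c, d = d, s = s,
            x_rest = x_rest, noise_intensity = noise_intensity)
  if (any(!is.finite(vals)))
    stop("all HR parameters must be finite", call. = FALSE)
  if (r <= 0) stop("'r' must be > 0", call. = FALSE)
  if (noise_intensity < 0)
    stop("'noise_intensity' must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, s = s, x_rest = x_rest,
                 r = r, I = I, noise_intensity = noise_intensity,
                 noise_on = noise_on),
            class = "hr_params")
}

#' @export
print.hr_params <- function(x, ...) {
  cat("Hindmarsh-Rose parameters\n")
  cat(sprintf("  I = %g, r = %g\n", x$I, x$r))
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g, s = %g, x_rest = %g\n",
              x$a, x$b, x$c, x$d, x$s, x$x_rest))
  if (x$noise_intensity > 0)
    cat(sprintf("  noise: intensity %g on d%s/dt\n", x$noise_intensity,
                x$noise_on))
  invisible(x)
}

# numeric vector in the layout the compiled core expects
pars_vec <- function(params) {
  c(a = params$a, b = params$b, c = params$c, d = params$d, s = params$s,
    x_rest = params$x_rest, r = params$r, I = params$I)
}

no_drift <- c(0, 0, 0, 0, 0, 0)

as_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 3 || any(!is.finite(state)))
    stop("state must be 3 finite numbers (x, y, z)", call. = FALSE)
  state
}

#' Time derivative of the HR flow
#'
#' @param state numeric vector `(x, y, z)`.
#' @param params an [hr_params] object.
#' @return Named numeric vector `(dx, dy, dz)`.
#' @export
hr_derivative <- function(state, params) {
  st <- as_state(state)
  x <- st[1]; y <- st[2]; z <- st[3]
  c(dx = y - params$a * x^3 + params$b * x^2 - z + params$I,
    dy = params$c - params$d * x^2 - y,
    dz = params$r * (params$s * (x - params$x_rest) - z))
}

#' Analytic Jacobian of the HR flow
#'
#' @inheritParams hr_derivative
#' @return A 3x3 numeric matrix.
#' @export
hr_jacobian <- function(state, params) {
  st <- as_state(state)
  x <- st[1]
  matrix(c(-3 * params$a * x^2 + 2 * params$b * x, 1, -1,
           -2 * params$d * x, -1, 0,
           params$r * params$s, 0, -params$r),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("dx", "dy", "dz"), c("x", "y", "z")))
}

#' Default initial state
#'
#' A state near the resting branch of the model; any transient from it is
#' discarded before analysis, so the precise value is not critical.
#' @return Numeric vector `(x, y, z)`.
#' @export
hr_initial_state <- function() c(-1.6, -11.8, 0)

#' Integrate the HR model
#'
#' Fixed-step integration: classical 4th-order Runge-Kutta when
#' `noise_intensity` is zero, Euler-Maruyama (noise added to the configured
#' equation, scaled by `sqrt(dt)`) otherwise.
#'
#' @param params an [hr_params] object.
#' @param initial initial state `(x, y, z)`.
#' @param t_end end time (model-time units); the trajectory covers
#'   `[0, t_end]`.
#' @param dt integration step.
#' @param seed optional integer seed for the stochastic path; ignored when
#'   `noise_intensity` is zero.
#' @return An `hr_trajectory`: list with `times`, a `states` matrix
#'   (columns `x`, `y`, `z`) and the `params` used.
#' @export
hr_integrate <- function(params, initial = hr_initial_state(), t_end,
                         dt = 0.01, seed = NULL) {
  stopifnot(dt > 0, t_end >= 0)
  initial <- as_state(initial)
  if (params$noise_intensity > 0 && !is.null(seed)) set.seed(seed)
  res <- hr_traj_cpp(pars_vec(params), initial, t_end, dt,
                     params$noise_intensity,
                     as.integer(params$noise_on == "y"), no_drift)
  if (!is.na(res$blowup_time))
    stop(sprintf("integration blew up at t = %g", res$blowup_time),
         call. = FALSE)
  structure(list(times = res$t,
                 states = cbind(x = res$x, y = res$y, z = res$z),
                 params = params, dt = dt),
            class = "hr_trajectory")
}

#' @export
print.hr_trajectory <- function(x, ...) {
  cat(sprintf("HR trajectory: %d samples, t in [%g, %g], dt = %g\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$dt))
  invisible(x)
}

#' Detect spikes in a trajectory
#'
#' Spikes are interior local maxima of the membrane potential `x` at or
#' above `threshold`, at least `min_separation` apart; the peak time is
#' refined by quadratic interpolation through the three samples around each
#' maximum.
#'
#' @param traj an `hr_trajectory` (or a list with `times` and `states`).
#' @param threshold minimum `x` value for a spike peak.  The default 0
#'   separates HR action potentials (which peak well above 0) from
#'   subthreshold oscillations.
#' @param min_separation refractory floor between accepted peaks
#'   (model-time units).
#' @return A `spike_train`: list with `spike_times` and a `units` tag.
#' @export
detect_spikes <- function(traj, threshold = 0, min_separation = 1) {
  if (length(traj$times) == 0) stop("empty trajectory", call. = FALSE)
  st <- detect_spikes_cpp(traj$times, traj$states[, "x"], threshold,
                          min_separation)
  spike_train(st, units = "model_time")
}

#' Construct a spike train
#'
#' @param spike_times strictly increasing spike times.
#' @param units `"model_time"` or `"seconds"`.
#' @return A `spike_train` object.
#' @export
spike_train <- function(spike_times, units = c("model_time", "seconds")) {
  units <- match.arg(units)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(spike_times = spike_times, units = units),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes (%s)\n", length(x$spike_times),
              x$units))
  invisible(x)
}

#' Construct an ISI series
#'
#' @param isis positive interspike intervals, in temporal order.
#' @param units `"model_time"` or `"seconds"`.
#' @param origin_times optional spike time at which each interval ends.
#' @return An `isi_series` object.
#' @export
isi_series <- function(isis, units = c("model_time", "seconds"),
                       origin_times = NULL) {
  units <- match.arg(units)
  isis <- as.numeric(isis)
  if (any(!is.finite(isis)) || any(isis <= 0))
    stop("ISIs must be finite and positive", call. = FALSE)
  if (!is.null(origin_times) && length(origin_times) != length(isis))
    stop("origin_times must match isis in length", call. = FALSE)
  structure(list(isis = isis, units = units, origin_times = origin_times),
            class = "isi_series")
}

#' @export
print.isi_series <- function(x, ...) {
  cat(sprintf("ISI series: %d intervals (%s), mean %.4g\n",
              length(x$isis), x$units, mean(x$isis)))
  invisible(x)
}

#' @export
length.isi_series <- function(x) length(x$isis)

#' Interspike intervals from a spike train
#'
#' The time intervals between successive spike maxima, in order.
#'
#' @param train a `spike_train`.
#' @return An `isi_series`; units are propagated from the train.
#' @export
isis_from_spikes <- function(train) {
  st <- train$spike_times
  if (length(st) < 2)
    stop("need at least 2 spikes to form ISIs", call. = FALSE)
  isi_series(diff(st), units = train$units, origin_times = st[-1])
}

#' Largest Lyapunov exponent of the deterministic HR flow
#'
#' Benettin's method: the state and a unit tangent vector are evolved
#' together (the tangent under the analytic Jacobian), the tangent is
#' renormalized every `renorm_interval`, and the exponent is the mean log
#' stretch factor per unit time after discarding a transient.
#'
#' @param params an [hr_params] object with `noise_intensity = 0`.
#' @param t_transient transient discarded before averaging.
#' @param t_average averaging time; must be at least
#'   `100 * renorm_interval`.
#' @param renorm_interval time between tangent renormalizations.
#' @param dt integration step.
#' @param initial initial state.
#' @param tangent0 initial tangent direction (normalized internally).
#' @return The exponent, per model-time unit.  Negative values indicate
#'   convergence to an equilibrium, values near zero a limit cycle, and
#'   positive values chaos.
#' @export
largest_lyapunov <- function(params, t_transient = 500, t_average = 5000,
                             renorm_interval = 1, dt = 0.01,
                             initial = hr_initial_state(),
                             tangent0 = c(1, 0, 0)) {
  if (params$noise_intensity > 0)
    stop("the Lyapunov exponent is defined for the noiseless model",
         call. = FALSE)
  stopifnot(t_average >= 100 * renorm_interval)
  res <- hr_lle_cpp(pars_vec(params), as_state(initial), dt, t_transient,
                    t_average, renorm_interval, as.numeric(tangent0))
  if (!is.na(res$blowup_time))
    stop(sprintf("integration blew up at t = %g", res$blowup_time),
         call. = FALSE)
  res$lle
}

#' Simulate and reduce to an ISI series
#'
#' Convenience wrapper used by the scanning and generator code: integrates
#' the model, collects spike peak times on the fly, discards a transient
#' (`t_transient` model-time units or the first `transient_spikes` spikes,
#' whichever is longer) and returns the ISI series.
#'
#' @inheritParams hr_integrate
#' @param n_isis number of post-transient ISIs requested.
#' @param t_transient transient time to discard.
#' @param transient_spikes minimum number of initial spikes to discard.
#' @param threshold,min_separation spike-detection settings, as in
#'   [detect_spikes].
#' @param t_max hard cap on simulated time.
#' @return List with `isis` (an `isi_series`, possibly shorter than
#'   requested if `t_max` was hit), `spike_times`, `end_state` and
#'   `n_spikes_total`.
#' @export
simulate_isis <- function(params, n_isis = 300,
                          initial = hr_initial_state(), dt = 0.01,
                          t_transient = 500, transient_spikes = 50,
                          threshold = 0, min_separation = 1,
                          t_max = 1e5, seed = NULL) {
  if (params$noise_intensity > 0 && !is.null(seed)) set.seed(seed)
  max_spk <- n_isis + transient_spikes + 60
  res <- hr_spikes_cpp(pars_vec(params), as_state(initial), t_max, dt,
                       params$noise_intensity,
                       as.integer(params$noise_on == "y"),
                       threshold, min_separation, max_spk, no_drift)
  st <- res$spike_times
  keep <- st >= t_transient
  if (length(st) >= transient_spikes)
    keep <- keep & seq_along(st) > transient_spikes
  st_kept <- st[keep]
  isis <- if (length(st_kept) >= 2) {
    isi_series(utils::tail(diff(st_kept), n_isis),
               units = "model_time",
               origin_times = utils::tail(st_kept[-1], n_isis))
  } else NULL
  list(isis = isis, spike_times = st_kept, end_state = res$end_state,
       n_spikes_total = length(st), blowup_time = res$blowup_time)
}
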