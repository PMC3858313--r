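test_that("the derivative matches hand-evaluated values", {
  p0 <- hr_params(I = 0, r = 0.0245)
  expect_equal(unname(hr_derivative(c(0, 0, 0), p0)),
               c(0, 1, 0.0245 * 4 * 1.6))
  p <- hr_params(I = 2.53, r = 0.0245)
  expect_equal(unname(hr_derivative(c(1, 0, 0), p)),
               c(2 + 2.53, 1 - 5, 0.0245 * (4 * 2.6)))
})

test_that("the derivative vanishes at the bisection equilibrium", {
  for (I in c(0, 1.0, 2.53)) {
    p <- hr_params(I = I, r = 0.0245)
    eq <- hr_equilibrium_oracle(p)
    expect_lt(max(abs(hr_derivative(eq, p))), 1e-10)
  }
})

test_that("the analytic Jacobian agrees with central differences", {
  set.seed(5)
  p <- hr_params(I = 2.53, r = 0.0245)
  for (rep in 1:10) {
    st <- stats::rnorm(3, sd = 2)
    expect_equal(unname(hr_jacobian(st, p)), numeric_jacobian(st, p),
                 tolerance = 1e-5)
    # trace identity
    expect_equal(sum(diag(hr_jacobian(st, p))),
                 -3 * p$a * st[1]^2 + 2 * p$b * st[1] - 1 - p$r)
  }
  expect_equal(unname(hr_jacobian(c(0, 0.3, -2), p)),
               matrix(c(0, 1, -1, 0, -1, 0, 4 * p$r, 0, -p$r), 3,
                      byrow = TRUE))
})

test_that("integration covers [0, t_end] and t_end = 0 is the initial state", {
  p <- hr_params(I = 2.53, r = 0.0245)
  tr <- hr_integrate(p, t_end = 0)
  expect_equal(length(tr$times), 1L)
  expect_equal(unname(tr$states[1, ]), hr_initial_state())
  tr <- hr_integrate(p, t_end = 10, dt = 0.01)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 10)
  expect_equal(unique(round(diff(tr$times), 12)), 0.01)
})

test_that("a stable equilibrium stays put under integration", {
  p <- hr_params(I = 0, r = 0.0245)
  eq <- hr_equilibrium_oracle(p)
  # verify stability via the Jacobian's eigenvalues first
  ev <- eigen(hr_jacobian(eq, p))$values
  expect_true(all(Re(ev) < 0))
  tr <- hr_integrate(p, initial = eq, t_end = 100)
  expect_lt(max(abs(tr$states[, "x"] - eq["x"])), 1e-6)
})

test_that("deterministic integration is reproducible and convergent", {
  p <- hr_params(I = 2.53, r = 0.030)  # periodic point
  a <- hr_integrate(p, t_end = 100, dt = 0.01)
  b <- hr_integrate(p, t_end = 100, dt = 0.01)
  expect_identical(a$states, b$states)
  fine <- hr_integrate(p, t_end = 100, dt = 0.005)
  expect_lt(abs(a$states[nrow(a$states), "x"] -
                  fine$states[nrow(fine$states), "x"]), 1e-6)
})

test_that("the integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- hr_params(I = 2.53, r = 0.030)
  rhs <- function(t, y, parms) list(unname(hr_derivative(y, p)))
  ref <- deSolve::ode(y = c(x = -1.6, y = -11.8, z = 0),
                      times = seq(0, 50, by = 0.01), func = rhs,
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  mine <- hr_integrate(p, t_end = 50, dt = 0.01)
  expect_equal(unname(mine$states[nrow(mine$states), "x"]),
               unname(ref[nrow(ref), "x"]), tolerance = 1e-5)
})

test_that("spike detection finds analytic maxima of a sine wave", {
  t <- seq(0, 50, by = 0.01)
  traj <- list(times = t, states = cbind(x = 2 * sin(t), y = 0, z = 0))
  sp <- detect_spikes(traj, threshold = 0, min_separation = 1)
  expected <- pi / 2 + 2 * pi * (0:7)
  expect_equal(length(sp$spike_times), 8L)
  expect_lt(max(abs(sp$spike_times - expected)), 0.01)
})

test_that("spike detection on flat input finds nothing", {
  traj <- list(times = 0:100, states = cbind(x = rep(1, 101), y = 0, z = 0))
  expect_equal(length(detect_spikes(traj)$spike_times), 0L)
})

test_that("spike count is invariant to halving dt", {
  # horizon short enough that the dt-halving perturbation (~1e-9) cannot
  # be amplified into a different spike count by the chaotic divergence
  p <- hr_params(I = 2.53, r = 0.0245)
  n <- sapply(c(0.01, 0.005), function(dt) {
    sim <- simulate_isis(p, n_isis = 1e6, dt = dt, t_max = 1500,
                         t_transient = 500, transient_spikes = 0)
    length(sim$spike_times)
  })
  expect_gt(n[1], 10)
  expect_equal(n[1], n[2])
})

test_that("chaotic parameters sustain spiking with the reported ISI mix", {
  sim <- simulate_isis(hr_params(I = 2.53, r = 0.0245), n_isis = 300,
                       t_max = 1e5)
  expect_gte(length(sim$spike_times), 100)
  x <- sim$isis$isis
  # middle ISIs, coupled long/short pairs, and occasional much longer ISIs
  expect_gt(max(x), 1.8 * stats::median(x))
  expect_lt(min(x), 0.8 * stats::median(x))
})

test_that("ISIs are successive spike-time differences", {
  tr <- spike_train(c(0, 1, 3, 6))
  expect_equal(isis_from_spikes(tr)$isis, c(1, 2, 3))
  tr2 <- spike_train(sort(stats::runif(17)))
  expect_equal(length(isis_from_spikes(tr2)$isis), 16L)
  expect_error(isis_from_spikes(spike_train(1.5)), "at least 2")
})

test_that("the largest Lyapunov exponent separates the three regimes", {
  expect_gt(largest_lyapunov(hr_params(I = 2.53, r = 0.0245)), 0)
  # surrounding periodic band: limit-cycle exponent ~ 0
  expect_lt(abs(largest_lyapunov(hr_params(I = 2.53, r = 0.018))), 0.002)
  expect_lt(abs(largest_lyapunov(hr_params(I = 2.53, r = 0.030))), 0.002)
  # quiescent convergence to equilibrium: negative exponent
  expect_lt(largest_lyapunov(hr_params(I = 0, r = 0.0245)), 0)
})

test_that("the exponent is robust to renormalization interval and tangent", {
  p <- hr_params(I = 2.53, r = 0.0245)
  base <- largest_lyapunov(p)
  for (ri in c(0.5, 2)) {
    v <- largest_lyapunov(p, renorm_interval = ri)
    expect_lt(abs(v - base) / base, 0.10)
  }
  v <- largest_lyapunov(p, tangent0 = c(0.3, -1, 2))
  expect_lt(abs(v - base) / base, 0.10)
})

test_that("noisy integration is seed-reproducible", {
  p <- hr_params(I = 2.53, r = 0.0245, noise_intensity = 0.05)
  a <- hr_integrate(p, t_end = 50, seed = 42)
  b <- hr_integrate(p, t_end = 50, seed = 42)
  expect_identical(a$states, b$states)
  c2 <- hr_integrate(p, t_end = 50, seed = 43)
  expect_false(identical(a$states, c2$states))
})
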