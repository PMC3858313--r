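test_that("gen_stationary without jitter reproduces the model exactly", {
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.028),
                         isi_jitter_cv = 0, seed = 1)
  rec <- gen_stationary(spec, n_isis = 150)
  expect_equal(length(rec$isis$isis), 150L)
  expect_equal(rec$truth$kind, "periodic")
  expect_equal(rec$truth$period, 1L)
  # period-1: essentially constant ISIs
  expect_lt(diff(range(rec$isis$isis)) / mean(rec$isis$isis), 0.01)
})

test_that("gen_stationary is bit-identical for a fixed seed", {
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.0245), seed = 9)
  a <- gen_stationary(spec, n_isis = 200)
  b <- gen_stationary(spec, n_isis = 200)
  expect_identical(a$isis$isis, b$isis$isis)
  expect_identical(format(a$truth), format(b$truth))
  spec2 <- synthetic_spec(hr_params(I = 2.53, r = 0.0245), seed = 10)
  expect_false(identical(a$isis$isis,
                         gen_stationary(spec2, 200)$isis$isis))
})

test_that("generated chaotic records are recovered by classify_series", {
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.0245),
                         isi_jitter_cv = 0.005, seed = 2)
  rec <- gen_stationary(spec, n_isis = 500)
  expect_equal(rec$truth$kind, "chaotic")
  expect_equal(classify_series(rec$isis)$kind, "chaotic")
})

test_that("jittered periodic records are recovered at the noisy tolerance", {
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.018),
                         isi_jitter_cv = 0.05, seed = 3)
  rec <- gen_stationary(spec, n_isis = 300)
  expect_equal(rec$truth$period, 2L)
  lab <- classify_series(rec$isis,
                         regime_config(rel_tol_noisy = 0.05))
  expect_equal(lab$kind, "periodic")
  expect_equal(lab$period, 2L)
})

test_that("generator truth agrees with classify_point at non-boundary points", {
  pts <- list(c(2.40, 0.030), c(2.53, 0.0245), c(2.60, 0.020),
              c(2.50, 0.007), c(3.00, 0.020), c(2.45, 0.012))
  for (pt in pts) {
    spec <- synthetic_spec(hr_params(I = pt[1], r = pt[2]),
                           isi_jitter_cv = 0, seed = 4)
    rec <- gen_stationary(spec, n_isis = 250)
    direct <- classify_point(hr_params(I = pt[1], r = pt[2]))
    expect_equal(format(rec$truth), format(direct),
                 info = sprintf("I=%g r=%g", pt[1], pt[2]))
  }
})

test_that("quiescent parameters cannot generate a record", {
  spec <- synthetic_spec(hr_params(I = 0, r = 0.02), seed = 1)
  expect_error(gen_stationary(spec, 100), "cannot generate")
})

test_that("sampling-rate quantization moves spike times onto the grid", {
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.028),
                         isi_jitter_cv = 0, sampling_rate = 10,
                         seed = 1)
  rec <- gen_stationary(spec, n_isis = 100)
  expect_true(all(abs(rec$isis$isis * 10 -
                        round(rec$isis$isis * 10)) < 1e-9))
})

test_that("the period-adding boundary is bracketed by bisection", {
  bd <- find_period_adding_boundary(
    parameter_line("P34", c(2.50, 0.0055), c(2.53, 0.0040)), k = 3)
  expect_equal(bd$label_low$period, 3L)
  expect_equal(bd$label_high$period, 4L)
  expect_gt(bd$fraction, 0)
  expect_lt(bd$fraction, 1)
  # labels immediately on either side of the boundary differ
  eps <- 0.05
  f <- function(fr) {
    I <- 2.50 + fr * 0.03
    r <- 0.0055 + fr * (-0.0015)
    classify_point(hr_params(I = I, r = r))$period
  }
  expect_equal(f(max(0, bd$fraction - eps)), 3L)
  expect_equal(f(min(1, bd$fraction + eps)), 4L)
})

test_that("zero noise at the boundary is the degenerate periodic control", {
  spec <- synthetic_spec(hr_params(I = 2.5, r = 0.005,
                                   noise_intensity = 0), seed = 5)
  out <- gen_stochastic_alternation(spec, n_isis = 250)
  expect_equal(out$truth$kind, "periodic")
})

test_that("moderate noise induces bimodal alternation between patterns", {
  spec <- synthetic_spec(hr_params(I = 2.5, r = 0.005,
                                   noise_intensity = 0.1), seed = 7)
  out <- gen_stochastic_alternation(spec, n_isis = 500)
  expect_equal(out$truth$kind, "stochastic")
  x <- out$isis$isis
  # ISIs fall into the short (intra-burst) and long (inter-burst)
  # clusters of both patterns
  longs <- x > mean(range(x))
  expect_gt(mean(longs), 0.1)
  expect_lt(mean(longs), 0.6)
  # both cycle lengths (2 shorts for period-3, 3 shorts for period-4)
  # occur many times: irregular alternation, not a pure pattern
  r <- rle(!longs)
  shorts_per_cycle <- r$lengths[r$values]
  expect_gt(sum(shorts_per_cycle == 2), 10)
  expect_gt(sum(shorts_per_cycle == 3), 10)
})

test_that("a zero-length drift gives a stationary record with one segment", {
  ln <- parameter_line("pt", c(2.53, 0.028), c(2.53, 0.028), 1)
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.028),
                         drift_line = ln, duration = 2e4, seed = 6)
  out <- gen_washout(spec)
  expect_equal(length(out$truth_segments), 1L)
  expect_equal(format(out$truth_segments[[1]]$label), "period-1")
  expect_equal(out$truth_segments[[1]]$start_index, 1L)
})

test_that("washout output is seed-reproducible", {
  ln <- parameter_line("seg", c(2.35, 0.028), c(2.55, 0.026), 2)
  spec <- synthetic_spec(hr_params(I = 2.35, r = 0.028),
                         drift_line = ln, duration = 1e4, seed = 8)
  a <- gen_washout(spec, prescan_points = 5)
  b <- gen_washout(spec, prescan_points = 5)
  expect_identical(a$isis$isis, b$isis$isis)
  expect_equal(length(a$isis$origin_times), length(a$isis$isis))
  expect_true(all(diff(a$isis$origin_times) > 0))
})

test_that("reversing the drift line reverses the regime sequence", {
  fwd <- scan_line(parameter_line("f", c(2.35, 0.028), c(2.98, 0.022),
                                  40))
  rev_ <- scan_line(parameter_line("b", c(2.98, 0.022), c(2.35, 0.028),
                                   40))
  lf <- segment_labels(extract_scenario(fwd))
  lr <- segment_labels(extract_scenario(rev_))
  expect_equal(lf, rev(lr))
})
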