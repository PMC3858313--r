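test_that("classify_period is exact on constructed k-periodic series", {
  for (k in 1:8) {
    x <- make_periodic_series(k, reps = 40, seed = k)
    expect_equal(classify_period(x, k_max = 8), k)
    # invariance to cyclic rotation
    for (shift in c(1, k %/% 2 + 1)) {
      rot <- c(x[-seq_len(shift)], x[seq_len(shift)])
      expect_equal(classify_period(rot, k_max = 8), k)
    }
  }
})

test_that("the smallest period wins and tolerance is honored", {
  expect_equal(classify_period(rep(0.5, 40)), 1L)
  expect_equal(classify_period(rep(c(0.1, 0.3), 30)), 2L)
  # 1% wobble around a constant: period 1 at 5% tolerance, none at 0.1%
  set.seed(2)
  x <- 0.5 * (1 + 0.01 * stats::rnorm(200))
  expect_equal(classify_period(x, rel_tol = 0.05), 1L)
  expect_true(is.na(classify_period(x, rel_tol = 0.001)))
  expect_error(classify_period(rep(0.5, 10), k_max = 8), "at least")
})

test_that("chaotic model ISIs are aperiodic", {
  expect_true(is.na(classify_period(chaotic_isis(300), k_max = 8)))
})

test_that("classify_point labels the reference points of the plane", {
  expect_equal(classify_point(hr_params(I = 2.53, r = 0.0245))$kind,
               "chaotic")
  above <- classify_point(hr_params(I = 2.53, r = 0.0275))
  expect_equal(above$kind, "periodic")
  expect_equal(above$period, 1L)
  expect_equal(classify_point(hr_params(I = 0, r = 0.0245))$kind,
               "quiescent")
})

test_that("periodic labels match the cluster-counting oracle", {
  # points with known distinct regimes along the fixed-I classical scan
  for (r in c(0.030, 0.018, 0.007, 0.0045)) {
    lab <- classify_point(hr_params(I = 2.5, r = r))
    expect_equal(lab$kind, "periodic")
    sim <- simulate_isis(hr_params(I = 2.5, r = r), n_isis = 200,
                         t_max = 4e4)
    expect_equal(lab$period,
                 isi_cluster_count(utils::tail(sim$isis$isis, 150)))
  }
})

test_that("classify_series recovers periodicity under jitter and flags chaos", {
  # jittered period-2 from the generator
  spec <- synthetic_spec(hr_params(I = 2.53, r = 0.018),
                         isi_jitter_cv = 0.05, seed = 3)
  rec <- gen_stationary(spec, n_isis = 300)
  lab <- classify_series(rec$isis)
  expect_equal(lab$kind, "periodic")
  expect_equal(lab$period, 2L)
  # chaotic series is chaotic; its shuffle is stochastic
  x <- chaotic_isis(500)
  expect_equal(classify_series(x)$kind, "chaotic")
  expect_equal(classify_series(surrogate_shuffle(x, 9))$kind,
               "stochastic")
})

test_that("segment_scenario returns one segment for a stationary record", {
  x <- make_periodic_series(1, reps = 400, seed = 1)
  segs <- segment_scenario(x, window = 100, step = 10)
  expect_equal(length(segs), 1L)
  expect_equal(segs[[1]]$label$kind, "periodic")
  expect_equal(segs[[1]]$label$period, 1L)
  expect_equal(segs[[1]]$start_index, 1L)
  expect_equal(segs[[1]]$end_index, length(x) + 1L)
})

test_that("segment_scenario finds the boundary between concatenated regimes", {
  p1 <- gen_stationary(synthetic_spec(hr_params(I = 2.53, r = 0.028),
                                      isi_jitter_cv = 0.005, seed = 4),
                       n_isis = 500)
  p2 <- gen_stationary(synthetic_spec(hr_params(I = 2.53, r = 0.018),
                                      isi_jitter_cv = 0.005, seed = 5),
                       n_isis = 500)
  rec <- c(p1$isis$isis, p2$isis$isis)
  window <- 100
  segs <- segment_scenario(rec, window = window, step = 5)
  expect_equal(length(segs), 2L)
  expect_equal(segment_labels(segs), c("period-1", "period-2"))
  # segments tile the record and the boundary is within one window of 500
  expect_equal(segs[[1]]$start_index, 1L)
  expect_equal(segs[[1]]$end_index, segs[[2]]$start_index)
  expect_equal(segs[[2]]$end_index, length(rec) + 1L)
  expect_lt(abs(segs[[1]]$end_index - 501), window)
})

test_that("segments are contiguous with differing adjacent labels", {
  x <- c(make_periodic_series(1, 150, seed = 6) * 0.4,
         make_periodic_series(3, 60, seed = 7),
         make_periodic_series(2, 100, seed = 8))
  segs <- segment_scenario(x, window = 60, step = 5)
  for (i in seq_along(segs)) {
    if (i > 1) {
      expect_equal(segs[[i]]$start_index, segs[[i - 1]]$end_index)
      expect_false(format(segs[[i]]$label) ==
                     format(segs[[i - 1]]$label))
    }
  }
  expect_equal(segs[[1]]$start_index, 1L)
  expect_equal(segs[[length(segs)]]$end_index, length(x) + 1L)
})

test_that("regime labels validate their invariants", {
  expect_error(regime_label("periodic"), "period")
  expect_error(regime_label("chaotic", period = 2), "periodic")
  expect_equal(format(regime_label("periodic", 3)), "period-3")
  lab <- regime_label("chaotic", evidence = list(lle = 0.005))
  expect_equal(as_json_list(lab)$evidence$lle, 0.005)
})
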