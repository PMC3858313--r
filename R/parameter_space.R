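#' A straight segment in the (I, r) parameter plane
#'
#' Scans along such lines emulate the gradual effect of decreasing
#' extracellular calcium on a pacemaker: the injected current `I`
#' increases while the slow time constant `r` decreases, at a
#' preparation-specific slope.
#'
#' @param name identifier (free-form; presets use `BL1`...`BL4`,
#'   `TL1`...`TL4`, `ML0`, `SL1`).
#' @param start,end `(I, r)` pairs.
#' @param n_points number of scan points (`>= 1`).
#' @return A `parameter_line` object.
#' @seealso [line_preset] for the built-in lines.
#' @export
parameter_line <- function(name, start, end, n_points = 150) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2 || length(end) != 2)
    stop("start and end must be (I, r) pairs", call. = FALSE)
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  if (n_points > 1 && all(start == end))
    stop("start must differ from end unless n_points == 1", call. = FALSE)
  structure(list(name = name, start = start, end = end,
                 n_points = as.integer(n_points)),
            class = "parameter_line")
}

#' @export
print.parameter_line <- function(x, ...) {
  cat(sprintf("%s: (I=%g, r=%g) -> (I=%g, r=%g), %d points\n", x$name,
              x$start[1], x$start[2], x$end[1], x$end[2], x$n_points))
  invisible(x)
}

#' Points along a parameter line
#'
#' @param line a [parameter_line].
#' @return Data frame with columns `index`, `I`, `r`, `fraction`.
#' @export
line_points <- function(line) {
  f <- if (line$n_points == 1) 0 else
    (seq_len(line$n_points) - 1) / (line$n_points - 1)
  data.frame(index = seq_len(line$n_points),
             I = line$start[1] + f * (line$end[1] - line$start[1]),
             r = line$start[2] + f * (line$end[2] - line$start[2]),
             fraction = f)
}

# Built-in line endpoints.  The BL lines all cross the chaotic band that
# separates period-1 from period-2 firing, then diverge: BL1 swings right
# of the comb-shaped region into tonic period-1 spiking; BL2 descends
# through the period-doubling cascade (2-4-chaos-3); BL3 enters the
# period-adding-with-chaos part of the comb; BL4 stays left of the comb
# where period adding proceeds without chaos.  SL1 clips a period-4 tongue
# and returns through period-2 to period-1.  ML0 is the classical scan at
# fixed I = 2.5.  The TL lines are reference scans of the comb region
# itself.  Endpoints are this package's transcription, chosen so each
# scan reproduces its documented regime order; all are overridable via
# parameter_line().
.line_presets <- list(
  BL1 = list(start = c(2.35, 0.028),  end = c(3.61, 0.016)),
  BL2 = list(start = c(2.46, 0.0285), end = c(3.055, 0.012)),
  BL3 = list(start = c(2.48, 0.028),  end = c(3.05, 0.007)),
  BL4 = list(start = c(2.455, 0.0245), end = c(2.52, 0.004)),
  SL1 = list(start = c(2.42, 0.0285), end = c(4.00, 0.004)),
  ML0 = list(start = c(2.50, 0.035),  end = c(2.50, 0.001)),
  TL1 = list(start = c(3.00, 0.026),  end = c(3.12, 0.018)),
  TL2 = list(start = c(2.92, 0.024),  end = c(3.06, 0.013)),
  TL3 = list(start = c(2.76, 0.013),  end = c(2.96, 0.0065)),
  TL4 = list(start = c(2.32, 0.012),  end = c(2.42, 0.003))
)

#' Built-in scan lines
#'
#' @param name one of `BL1`...`BL4`, `TL1`...`TL4`, `ML0`, `SL1`.
#' @param n_points number of scan points.
#' @return A [parameter_line].
#' @export
line_preset <- function(name, n_points = 150) {
  if (!name %in% names(.line_presets))
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(names(.line_presets), collapse = ", ")),
         call. = FALSE)
  p <- .line_presets[[name]]
  parameter_line(name, p$start, p$end, n_points)
}

#' Scan a line in parameter space
#'
#' Integrates the noiseless model at each point along the line in order,
#' discarding a transient and recording the tail ISIs and a regime label.
#' The initial state at each point is the final state of the previous one
#' (continuation), which follows attractors the way a slow experimental
#' parameter drift does; the first point starts from `initial`.  A
#' blow-up at a point is recorded as an unclassified label with an error
#' flag and the scan continues from a fresh initial state.
#'
#' @param line a [parameter_line].
#' @param config a [regime_config].
#' @param initial state for the first point.
#' @param record_isis number of tail ISIs stored per point (for
#'   bifurcation-diagram plotting); labels always use `config$n_isis`.
#' @return A `bifurcation_diagram`: list with `line`, `points` (data
#'   frame), `isi_sets` (list of numeric vectors) and `labels` (list of
#'   [regime_label]s).
#' @export
scan_line <- function(line, config = regime_config(),
                      initial = hr_initial_state(), record_isis = 60) {
  pts <- line_points(line)
  n <- nrow(pts)
  isi_sets <- vector("list", n)
  labels <- vector("list", n)
  st <- as_state(initial)
  for (i in seq_len(n)) {
    params <- hr_params(I = pts$I[i], r = pts$r[i])
    sim <- simulate_isis(params, n_isis = config$n_isis, initial = st,
                         dt = config$dt, t_transient = config$t_transient,
                         transient_spikes = config$transient_spikes,
                         t_max = config$t_max)
    if (!is.na(sim$blowup_time)) {
      labels[[i]] <- regime_label("unclassified",
                                  evidence = list(error = "blowup",
                                                  blowup_time =
                                                    sim$blowup_time))
      isi_sets[[i]] <- numeric(0)
      st <- as_state(initial)
      next
    }
    st <- sim$end_state
    if (is.null(sim$isis) || length(sim$isis$isis) < 2) {
      labels[[i]] <- regime_label("quiescent",
                                  evidence = list(n_spikes =
                                                    length(sim$spike_times)))
      isi_sets[[i]] <- numeric(0)
      next
    }
    isi_sets[[i]] <- utils::tail(sim$isis$isis, record_isis)
    k <- tryCatch(classify_period(sim$isis, rel_tol = config$rel_tol,
                                  k_max = config$k_max,
                                  tail_n = config$tail_n),
                  error = function(e) NA_integer_)
    if (!is.na(k)) {
      labels[[i]] <- regime_label("periodic", period = k,
                                  evidence = list(period_tol_used =
                                                    config$rel_tol))
    } else {
      lle <- largest_lyapunov(params,
                              t_transient = config$lle_t_transient,
                              t_average = config$lle_t_average,
                              dt = config$dt, initial = st)
      ev <- list(lle = lle, period_tol_used = config$rel_tol)
      labels[[i]] <- if (lle > config$lle_threshold)
        regime_label("chaotic", evidence = ev)
      else regime_label("unclassified", evidence = ev)
    }
  }
  structure(list(line = line, points = pts, isi_sets = isi_sets,
                 labels = labels),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram along %s (%d points)\n", x$line$name,
              nrow(x$points)))
  sc <- extract_scenario(x)
  cat("  scenario:", paste(segment_labels(sc), collapse = " -> "), "\n")
  invisible(x)
}

#' Extract the regime scenario from a diagram
#'
#' Run-length encodes the labels along the scan direction, absorbs
#' single-point runs into the longer neighboring run, and reports each
#' transition boundary as the parameter midpoint between the adjacent
#' differing points.
#'
#' @param diagram a `bifurcation_diagram`.
#' @return A `bifurcation_scenario`: list with `labels` (list of
#'   [regime_label]s), `from_index`/`to_index` (inclusive point ranges)
#'   and `boundaries` (data frame of `I`, `r` midpoints between runs).
#' @export
extract_scenario <- function(diagram) {
  labs <- diagram$labels
  n <- length(labs)
  if (n == 0) stop("empty diagram", call. = FALSE)
  runs <- list()
  start <- 1
  for (i in seq_len(n)) {
    if (i < n && same_label(labs[[i + 1]], labs[[start]])) next
    runs[[length(runs) + 1]] <- list(label = labs[[start]], from = start,
                                     to = i)
    start <- i + 1
  }
  # absorb single-point runs into the longer neighbor
  repeat {
    if (length(runs) <= 1) break
    len <- vapply(runs, function(r) r$to - r$from + 1, 0)
    sing <- which(len == 1)
    sing <- sing[vapply(sing, function(i) {
      # only absorb if a neighbor is a genuine (longer) run
      (i > 1 && len[i - 1] > 1) || (i < length(runs) && len[i + 1] > 1)
    }, TRUE)]
    if (length(sing) == 0) break
    i <- sing[1]
    left <- if (i > 1) len[i - 1] else -1
    right <- if (i < length(runs)) len[i + 1] else -1
    if (left >= right) runs[[i - 1]]$to <- runs[[i]]$to
    else runs[[i + 1]]$from <- runs[[i]]$from
    runs[[i]] <- NULL
    # merge newly adjacent equal labels
    j <- 1
    while (j < length(runs)) {
      if (same_label(runs[[j]]$label, runs[[j + 1]]$label)) {
        runs[[j]]$to <- runs[[j + 1]]$to
        runs[[j + 1]] <- NULL
      } else j <- j + 1
    }
  }
  pts <- diagram$points
  nb <- length(runs) - 1
  boundaries <- data.frame(I = numeric(nb), r = numeric(nb))
  if (nb > 0) for (i in seq_len(nb)) {
    a <- runs[[i]]$to; b <- runs[[i + 1]]$from
    boundaries$I[i] <- (pts$I[a] + pts$I[b]) / 2
    boundaries$r[i] <- (pts$r[a] + pts$r[b]) / 2
  }
  structure(list(labels = lapply(runs, `[[`, "label"),
                 from_index = vapply(runs, `[[`, 0, "from"),
                 to_index = vapply(runs, `[[`, 0, "to"),
                 boundaries = boundaries,
                 line = diagram$line),
            class = "bifurcation_scenario")
}

#' @export
print.bifurcation_scenario <- function(x, ...) {
  cat(sprintf("Scenario along %s: %s\n", x$line$name,
              paste(vapply(x$labels, format, ""), collapse = " -> ")))
  invisible(x)
}

#' Configuration of the Lyapunov map
#'
#' @param dt integration step.
#' @param t_transient transient discarded per cell.
#' @param t_average averaging time per cell.
#' @param renorm_interval tangent renormalization interval.
#' @param cold_start_pass also evaluate every cell from the fixed initial
#'   state and keep the larger exponent.  The model is multistable in
#'   parts of the plane (chaotic and periodic attractors coexist); a map
#'   built from a single initial condition per cell understates where a
#'   chaotic attractor exists.  Continuation along increasing `r` plus a
#'   cold pass covers both basins at reasonable cost.
#' @return A list of class `lle_map_config`.
#' @export
lle_map_config <- function(dt = 0.01, t_transient = 500,
                           t_average = 10000, renorm_interval = 1,
                           cold_start_pass = TRUE) {
  structure(as.list(environment()), class = "lle_map_config")
}

#' Largest-Lyapunov-exponent map over a parameter rectangle
#'
#' Evaluates [largest_lyapunov] on an `n_I x n_r` grid.  Within each
#' column of fixed `I` the state is continued from cell to cell along
#' increasing `r`; when `cold_start_pass` is set (the default) every cell
#' is additionally evaluated from the fixed initial state and the larger
#' exponent is kept (see [lle_map_config]).  Deterministic for a fixed
#' configuration.  Cells where the integration blows up are stored as
#' `NA`.
#'
#' @param I_range,r_range rectangle bounds; the defaults cover the
#'   region in which both chaotic regions of the model lie.
#' @param n_I,n_r grid resolution (`>= 2` each).  112 x 70 resolves the
#'   comb structure well; 56 x 35 is sufficient to separate and count
#'   the two chaotic regions.
#' @param config an [lle_map_config].
#' @return An `lle_map`: list with `I_axis`, `r_axis` and an
#'   `n_r x n_I` matrix `values` (rows indexed by `r`).
#' @export
compute_lle_map <- function(I_range = c(2.3, 3.42),
                            r_range = c(0.001, 0.035), n_I = 56,
                            n_r = 35, config = lle_map_config()) {
  stopifnot(n_I >= 2, n_r >= 2)
  I_axis <- seq(I_range[1], I_range[2], length.out = n_I)
  r_axis <- seq(r_range[1], r_range[2], length.out = n_r)
  vals <- matrix(NA_real_, n_r, n_I,
                 dimnames = list(NULL, NULL))
  cell <- function(I, r, st) {
    hr_lle_cpp(c(a = 1, b = 3, c = 1, d = 5, s = 4, x_rest = -1.6,
                 r = r, I = I), st, config$dt, config$t_transient,
               config$t_average, config$renorm_interval, c(1, 0, 0))
  }
  for (i in seq_len(n_I)) {
    st <- hr_initial_state()
    for (j in seq_len(n_r)) {
      res <- cell(I_axis[i], r_axis[j], st)
      if (is.na(res$blowup_time)) {
        vals[j, i] <- res$lle
        st <- res$end_state
      } else st <- hr_initial_state()
    }
    if (config$cold_start_pass) {
      for (j in seq_len(n_r)) {
        res <- cell(I_axis[i], r_axis[j], hr_initial_state())
        if (is.na(res$blowup_time))
          vals[j, i] <- max(vals[j, i], res$lle, na.rm = TRUE)
      }
    }
  }
  structure(list(I_axis = I_axis, r_axis = r_axis, values = vals,
                 config = config),
            class = "lle_map")
}

#' @export
print.lle_map <- function(x, ...) {
  cat(sprintf("LLE map: %d x %d cells, I in [%g, %g], r in [%g, %g]\n",
              length(x$I_axis), length(x$r_axis), min(x$I_axis),
              max(x$I_axis), min(x$r_axis), max(x$r_axis)))
  cat(sprintf("  exponent range: [%.4g, %.4g]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# 4-connected components of a logical matrix, iterative flood fill;
# returns an integer label matrix (0 = background)
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i0, j0), 1, 2)
    lab[i0, j0] <- cur
    while (nrow(stack) > 0) {
      i <- stack[nrow(stack), 1]; j <- stack[nrow(stack), 2]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Label connected chaotic regions of an LLE map
#'
#' Thresholds the map (`value > threshold`), labels 4-connected
#' components, and discards components smaller than `min_cells`.
#' 4-connectivity is deliberately conservative: it keeps distinct
#' chaotic regions separate on coarse grids.
#'
#' @param map an `lle_map`.
#' @param threshold exponent cutoff for "chaotic".
#' @param min_cells smallest component kept.
#' @return A `chaotic_regions` object: `count`, `regions` (list of
#'   two-column cell-index matrices, rows = `r` index, cols = `I`
#'   index), `label_matrix`, plus the `threshold` and `min_cells` used.
#' @export
label_chaotic_regions <- function(map, threshold = 0.002, min_cells = 4) {
  mask <- !is.na(map$values) & map$values > threshold
  lab <- label_components_4(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  regions <- list()
  relabel <- matrix(0L, nrow(lab), ncol(lab))
  for (id in ids) {
    cells <- which(lab == id, arr.ind = TRUE)
    if (nrow(cells) < min_cells) next
    regions[[length(regions) + 1]] <- cells
    relabel[lab == id] <- length(regions)
  }
  structure(list(count = length(regions), regions = regions,
                 label_matrix = relabel, threshold = threshold,
                 min_cells = min_cells, I_axis = map$I_axis,
                 r_axis = map$r_axis),
            class = "chaotic_regions")
}

#' @export
print.chaotic_regions <- function(x, ...) {
  cat(sprintf("%d chaotic region(s) (threshold %g, min %d cells)\n",
              x$count, x$threshold, x$min_cells))
  for (i in seq_len(x$count)) {
    cells <- x$regions[[i]]
    cat(sprintf("  region %d: %d cells, I in [%.3f, %.3f], r in [%.4f, %.4f]\n",
                i, nrow(cells), min(x$I_axis[cells[, 2]]),
                max(x$I_axis[cells[, 2]]), min(x$r_axis[cells[, 1]]),
                max(x$r_axis[cells[, 1]])))
  }
  invisible(x)
}

#' Which region contains the cell nearest a parameter point
#'
#' @param regions a `chaotic_regions` object.
#' @param I,r the parameter point.
#' @return The region index (1-based), or `NA` if the nearest cell is not
#'   chaotic.
#' @export
region_at <- function(regions, I, r) {
  j <- which.min(abs(regions$I_axis - I))
  i <- which.min(abs(regions$r_axis - r))
  lab <- regions$label_matrix[i, j]
  if (lab == 0L) NA_integer_ else lab
}
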