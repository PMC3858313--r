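#' Read an ISI file
#'
#' Plain text, one positive interval per line (or a single-column CSV).
#' Lines starting with `#` are header lines; a `# units: <u>` header sets
#' the units (default seconds, the convention for recorded data).
#'
#' @param path file path.
#' @return An `isi_series`.
#' @export
read_isi_file <- function(path) {
  vals <- read_value_file(path, "ISI")
  if (length(vals$values) == 0)
    stop(sprintf("empty input: %s", path), call. = FALSE)
  bad <- which(vals$values <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive ISI at line %d of %s",
                 vals$lines[bad[1]], path), call. = FALSE)
  isi_series(vals$values, units = vals$units)
}

#' Read a spike-time file
#'
#' Plain text, one spike time per line, strictly increasing.  `#` header
#' lines as in [read_isi_file].
#'
#' @param path file path.
#' @return A `spike_train`.
#' @export
read_spike_file <- function(path) {
  vals <- read_value_file(path, "spike time")
  if (length(vals$values) == 0)
    stop(sprintf("empty input: %s", path), call. = FALSE)
  if (length(vals$values) > 1) {
    d <- diff(vals$values)
    if (any(d <= 0)) {
      at <- which(d <= 0)[1] + 1
      stop(sprintf("spike times must be strictly increasing; violated at line %d of %s",
                   vals$lines[at], path), call. = FALSE)
    }
  }
  spike_train(vals$values, units = vals$units)
}

read_value_file <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  units <- "seconds"
  values <- numeric(0)
  lines <- integer(0)
  for (i in seq_along(raw)) {
    ln <- trimws(raw[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*units:\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) {
        if (!m[2] %in% c("seconds", "model_time"))
          stop(sprintf("unknown units '%s' at line %d of %s", m[2], i,
                       path), call. = FALSE)
        units <- m[2]
      }
      next
    }
    ln <- sub(",$", "", ln)
    v <- suppressWarnings(as.numeric(ln))
    if (is.na(v))
      stop(sprintf("cannot parse %s at line %d of %s: '%s'", what, i,
                   path, raw[i]), call. = FALSE)
    values <- c(values, v)
    lines <- c(lines, i)
  }
  list(values = values, units = units, lines = lines)
}

#' Write an ISI series to a plain-text file
#'
#' One value per line, preceded by `#` header lines carrying the units
#' and any provenance (parameters, seed) supplied.
#'
#' @param isis an `isi_series`.
#' @param path output path.
#' @param provenance named list written as `# name: value` headers.
#' @return `path`, invisibly.
#' @export
write_isi_file <- function(isis, path, provenance = list()) {
  hdr <- c(sprintf("# units: %s", isis$units),
           vapply(names(provenance), function(nm)
             sprintf("# %s: %s", nm, format(provenance[[nm]])), ""))
  writeLines(c(hdr, format(isis$isis, digits = 15, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}

#' Write a spike train to a plain-text file
#'
#' @param train a `spike_train`.
#' @param path output path.
#' @param provenance named list written as `# name: value` headers.
#' @return `path`, invisibly.
#' @export
write_spike_file <- function(train, path, provenance = list()) {
  hdr <- c(sprintf("# units: %s", train$units),
           vapply(names(provenance), function(nm)
             sprintf("# %s: %s", nm, format(provenance[[nm]])), ""))
  writeLines(c(hdr, format(train$spike_times, digits = 15, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Columns `t,x,y,z`.
#'
#' @param traj an `hr_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = traj$times, x = traj$states[, "x"],
                   y = traj$states[, "y"], z = traj$states[, "z"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a bifurcation diagram as long-format CSV
#'
#' Columns `param_index,I,r,isi`, one row per recorded tail ISI.
#'
#' @param diagram a `bifurcation_diagram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  n <- vapply(diagram$isi_sets, length, 0L)
  df <- data.frame(param_index = rep(diagram$points$index, n),
                   I = rep(diagram$points$I, n),
                   r = rep(diagram$points$r, n),
                   isi = unlist(diagram$isi_sets))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an LLE map as CSV
#'
#' A matrix block with the `I` axis as the header row and the `r` axis
#' as the first column.
#'
#' @param map an `lle_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lle_map_csv <- function(map, path) {
  df <- cbind(data.frame(r = map$r_axis),
              as.data.frame(map$values))
  names(df)[-1] <- sprintf("I_%.6g", map$I_axis)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# jsonlite-friendly representations -------------------------------------

#' Convert a package result to a plain list for JSON output
#'
#' @param x a package result object.
#' @param ... unused.
#' @return A list suitable for jsonlite.
#' @export
as_json_list <- function(x, ...) UseMethod("as_json_list")

#' @export
as_json_list.regime_label <- function(x, ...) {
  out <- list(kind = x$kind)
  if (!is.null(x$period)) out$period <- x$period
  if (length(x$evidence) > 0) out$evidence <- x$evidence
  out
}

#' @export
as_json_list.regime_segment <- function(x, ...) {
  list(label = as_json_list(x$label), start_index = x$start_index,
       end_index = x$end_index, start_time = x$start_time,
       end_time = x$end_time)
}

#' @export
as_json_list.bifurcation_scenario <- function(x, ...) {
  list(line = list(name = x$line$name, start = x$line$start,
                   end = x$line$end, n_points = x$line$n_points),
       labels = lapply(x$labels, as_json_list),
       from_index = x$from_index, to_index = x$to_index,
       boundaries = x$boundaries)
}

#' @export
as_json_list.npe_result <- function(x, ...) {
  list(h = x$h_values, npe = x$npe_original,
       surr_mean = x$npe_surrogate_mean, surr_sd = x$npe_surrogate_sd,
       config = x$config)
}

#' @export
as_json_list.chaotic_regions <- function(x, ...) {
  list(count = x$count, threshold = x$threshold, min_cells = x$min_cells,
       regions = lapply(x$regions, function(cells)
         list(n_cells = nrow(cells),
              I_range = range(x$I_axis[cells[, 2]]),
              r_range = range(x$r_axis[cells[, 1]]))))
}

#' Write any package result as JSON
#'
#' @param x an object with an [as_json_list] method.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(as_json_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
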