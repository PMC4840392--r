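#' Simulation grid
#'
#' A uniform sampling grid for the difference-equation simulators. The first
#' sample has index n = 1 and sits at elapsed time 0; consecutive samples are
#' `dt` minutes apart.
#'
#' @param n_steps Number of samples (>= 1).
#' @param dt Sampling interval in minutes (> 0). Default 1, i.e. one
#'   measurement per minute.
#' @return An object of class `sim_grid`.
#' @examples
#' sim_grid(60)
#' @export
sim_grid <- function(n_steps, dt = 1) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || is.na(n_steps) ||
      n_steps < 1 || n_steps != floor(n_steps)) {
    stop("`n_steps` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (minutes)", call. = FALSE)
  }
  structure(list(n_steps = as.integer(n_steps), dt = as.numeric(dt)),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d samples, dt = %g min (%g min total)\n",
              x$n_steps, x$dt, (x$n_steps - 1) * x$dt))
  invisible(x)
}

#' Concentration time series
#'
#' A uniformly sampled trajectory of a molecular species (protein
#' concentration in uM by default), the basic signal type shared by all
#' simulators, estimators and transforms in the package.
#'
#' @param values Numeric vector of samples; all finite. Values must be
#'   nonnegative unless `role` marks the series as a noise/error/control
#'   signal.
#' @param dt Sampling interval in minutes.
#' @param name Species label (e.g. `"y"`).
#' @param units Unit string, default `"uM"`.
#' @param role One of `"concentration"`, `"noise"`, `"error"`, `"control"`,
#'   `"reference"`. Only `"concentration"` enforces nonnegativity.
#' @return A numeric vector of class `conc_ts` with attributes `dt`, `name`,
#'   `units`, `role`.
#' @examples
#' conc_ts(c(10, 9, 8.1), name = "y")
#' @export
conc_ts <- function(values, dt = 1, name = "y", units = "uM",
                    role = c("concentration", "noise", "error", "control",
                             "reference")) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a time series needs at least one sample",
                                call. = FALSE)
  if (any(!is.finite(values))) stop("all samples must be finite",
                                    call. = FALSE)
  if (role == "concentration" && any(values < 0)) {
    stop("concentration samples must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number (minutes)", call. = FALSE)
  }
  structure(values, dt = as.numeric(dt), name = as.character(name),
            units = as.character(units), role = role, class = "conc_ts")
}

#' @export
print.conc_ts <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<conc_ts> %s [%s], %d samples, dt = %g min\n",
              attr(x, "name"), attr(x, "units"), n, attr(x, "dt")))
  shown <- utils::head(as.numeric(x), 8L)
  cat(" ", paste(signif(shown, 6), collapse = ", "),
      if (n > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Sampling interval of a time series
#' @param x A `conc_ts`.
#' @return The sampling interval in minutes.
#' @export
sampling_interval <- function(x) {
  stopifnot(inherits(x, "conc_ts"))
  attr(x, "dt")
}

#' Elapsed-time axis of a time series
#' @param x A `conc_ts`.
#' @return Numeric vector of elapsed minutes; the first sample is at 0.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "conc_ts"))
  (seq_along(x) - 1) * attr(x, "dt")
}

#' @export
as.data.frame.conc_ts <- function(x, ...) {
  df <- data.frame(time_min = time_axis(x), value = as.numeric(x))
  names(df)[2] <- attr(x, "name")
  df
}

#' Constant input series
#'
#' Convenience constructor for a constant trajectory (e.g. a sustained
#' activated transcription factor at 10 uM).
#'
#' @param level Constant level (>= 0).
#' @param grid A [sim_grid()].
#' @param name Species label.
#' @return A `conc_ts`.
#' @export
const_input <- function(level, grid, name = "x") {
  conc_ts(rep(as.numeric(level), grid$n_steps), dt = grid$dt, name = name)
}

#' Step input series
#'
#' Zero before `onset`, `level` from sample `onset` onward.
#'
#' @param level Step height.
#' @param grid A [sim_grid()].
#' @param onset Sample index (1-based) at which the step turns on.
#' @param name Species label.
#' @return A `conc_ts`.
#' @export
step_input <- function(level, grid, onset = 1L, name = "x") {
  v <- numeric(grid$n_steps)
  if (onset <= grid$n_steps) v[onset:grid$n_steps] <- level
  conc_ts(v, dt = grid$dt, name = name)
}

# internal: grid implied by a conc_ts
grid_of <- function(x) sim_grid(length(x), attr(x, "dt"))

# internal: check a series sits on a grid
check_on_grid <- function(x, grid, what = "input series") {
  if (length(x) != grid$n_steps ||
      abs(attr(x, "dt") - grid$dt) > 1e-12 * max(grid$dt, 1)) {
    stop(sprintf("%s does not match the simulation grid (%d samples, dt %g)",
                 what, grid$n_steps, grid$dt), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write time series to CSV
#'
#' One CSV dialect is used throughout: `#`-prefixed metadata lines
#' (`dt_min`, `units`, and optionally `seed`), then a header
#' `time_min,<species1>,...`, then one row per sample. Values are written at
#' full precision so that a write/read round trip is exact.
#'
#' @param series A `conc_ts` or a (possibly named) list of `conc_ts` sharing
#'   one grid.
#' @param path Output file path.
#' @param seed Optional integer recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, seed = NULL) {
  if (inherits(series, "conc_ts")) series <- list(series)
  stopifnot(length(series) >= 1L, all(vapply(series, inherits, TRUE, "conc_ts")))
  g <- grid_of(series[[1]])
  for (s in series) check_on_grid(s, g, attr(s, "name"))
  nms <- vapply(series, function(s) attr(s, "name"), "")
  units <- vapply(series, function(s) attr(s, "units"), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_min: %s", format(g$dt, digits = 17)), con)
  writeLines(sprintf("# units: %s", paste(unique(units), collapse = ",")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines(paste(c("time_min", nms), collapse = ","), con)
  tm <- (seq_len(g$n_steps) - 1) * g$dt
  mat <- cbind(tm, do.call(cbind, lapply(series, as.numeric)))
  lines <- apply(mat, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read time series from CSV
#'
#' Parses the dialect written by [write_timeseries()]: `#` metadata lines, a
#' `time_min,...` header, one row per sample. The time column must be
#' uniform to within a relative tolerance of 1e-9.
#'
#' @param path Input file path.
#' @return A named list of `conc_ts`, with attributes `dt`, `units` and
#'   (if recorded) `seed` on the list.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("malformed time-series CSV: no data rows",
                              call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_min") {
    stop("malformed header: first column must be `time_min`", call. = FALSE)
  }
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(vapply(cells, length, 0L) != length(header))) {
    stop("malformed row: wrong number of columns", call. = FALSE)
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), ncol = length(header), byrow = TRUE))
  if (any(is.na(mat))) stop("non-numeric cell in time-series CSV",
                            call. = FALSE)
  tm <- mat[, 1]
  if (length(tm) >= 2) {
    steps <- diff(tm)
    dt <- steps[1]
    if (dt <= 0 || any(abs(steps - dt) > 1e-9 * max(abs(dt), 1))) {
      stop("non-uniform time column (grid must be uniformly sampled)",
           call. = FALSE)
    }
  } else {
    dt <- if (!is.null(meta$dt_min)) as.numeric(meta$dt_min) else 1
  }
  if (!is.null(meta$dt_min)) dt <- as.numeric(meta$dt_min)
  units <- if (!is.null(meta$units)) strsplit(meta$units, ",")[[1]][1] else "uM"
  out <- list()
  for (j in seq_along(header)[-1]) {
    v <- mat[, j]
    role <- if (any(v < 0)) "noise" else "concentration"
    out[[header[j]]] <- conc_ts(v, dt = dt, name = header[j], units = units,
                                role = role)
  }
  if (!is.null(meta$seed)) attr(out, "seed") <- as.integer(meta$seed)
  attr(out, "dt") <- dt
  attr(out, "units") <- units
  out
}
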