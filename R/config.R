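#' Read and validate a run configuration
#'
#' Run configurations are YAML files with a fixed schema. Top-level keys
#' (all optional unless noted):
#' \describe{
#'   \item{scenario}{Free-text run name (required).}
#'   \item{motif}{`kind` (`two_gene`, `decay`, `autoreg`) plus its
#'     parameters (`p_xy`, `p_y`, `b0`, `y_max`, `kind`/`strength` for
#'     autoregulation), `x_const`, `y1`.}
#'   \item{grid}{`n_steps`, `dt`.}
#'   \item{noise}{`mean`, `sd`, `targets`; requires a top-level `seed`.}
#'   \item{estimation}{`method` (`ls`, `wiener`, `lms`), `M`, `N`, `mu`.}
#'   \item{control}{`p_cx`, `p_x`, `K_P`, `K_I`, `K_D` or `desired_pole`,
#'     `reference` (`level`, `onset`).}
#'   \item{seed}{Integer; mandatory when `noise` is present.}
#'   \item{output}{Output CSV path.}
#' }
#' Unknown keys at any level are rejected with a message naming them, so a
#' typo fails fast before any simulation runs.
#'
#' @param path Path to a YAML config file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list with the schema above.
#' @export
validate_run_config <- function(cfg) {
  allowed_top <- c("scenario", "motif", "grid", "noise", "estimation",
                   "control", "seed", "output")
  allowed_sub <- list(
    motif = c("kind", "p_xy", "p_y", "b0", "y_max", "autoreg_kind",
              "strength", "x_const", "y1"),
    grid = c("n_steps", "dt"),
    noise = c("mean", "sd", "targets"),
    estimation = c("method", "M", "N", "mu"),
    control = c("p_cx", "p_x", "K_P", "K_I", "K_D", "desired_pole",
                "reference"))
  reject_unknown <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  reject_unknown(cfg, allowed_top, "top level")
  if (is.null(cfg$scenario)) stop("config needs a `scenario` name",
                                  call. = FALSE)
  for (sec in names(allowed_sub)) {
    if (!is.null(cfg[[sec]]))
      reject_unknown(cfg[[sec]], allowed_sub[[sec]], sec)
  }
  if (!is.null(cfg$control$reference))
    reject_unknown(cfg$control$reference, c("level", "onset"),
                   "control$reference")
  if (!is.null(cfg$noise) && is.null(cfg$seed))
    stop("a stochastic scenario (noise section) requires a `seed`",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run a simulation scenario from a config
#'
#' Executes the motif described by a [read_run_config()] config, with
#' optional noise, and returns the trajectories plus a flat summary
#' (steady state and response time where defined).
#'
#' @param cfg A `run_config` (or path to one).
#' @return List with `series` (named `conc_ts` list) and `summary` (flat
#'   named list).
#' @export
run_scenario <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  m <- cfg$motif
  if (is.null(m)) stop("config has no `motif` section", call. = FALSE)
  gsec <- cfg$grid
  grid <- sim_grid(if (is.null(gsec$n_steps)) 100L else gsec$n_steps,
                   if (is.null(gsec$dt)) 1 else gsec$dt)
  x_const <- if (is.null(m$x_const)) 10 else m$x_const
  y1 <- if (is.null(m$y1)) 0 else m$y1
  x <- const_input(x_const, grid)
  kind <- if (is.null(m$kind)) "two_gene" else m$kind
  base <- two_gene_params(p_xy = if (is.null(m$p_xy)) 0 else m$p_xy,
                          p_y = m$p_y,
                          b0 = if (is.null(m$b0)) 0 else m$b0,
                          y_max = m$y_max)
  series <- if (!is.null(cfg$noise)) {
    ns <- noise_spec(mean = if (is.null(cfg$noise$mean)) 0 else cfg$noise$mean,
                     sd = if (is.null(cfg$noise$sd)) 1 else cfg$noise$sd,
                     seed = cfg$seed,
                     targets = if (is.null(cfg$noise$targets)) "x"
                               else unlist(cfg$noise$targets))
    simulate_with_noise(motif_model(if (kind == "decay") "decay"
                                    else "two_gene", base),
                        x, ns, grid = grid, y1 = y1)
  } else if (kind == "decay") {
    list(x = x, y = simulate_decay(base$p_y, y1, grid))
  } else if (kind == "autoreg") {
    ap <- autoreg_params(base, kind = m$autoreg_kind, strength = m$strength)
    list(x = x, y = simulate_autoregulation(ap, x, y1 = y1, grid = grid))
  } else {
    list(x = x, y = simulate_two_gene(base, x, y1 = y1, grid = grid))
  }
  summary <- list(scenario = cfg$scenario, kind = kind,
                  final_y = as.numeric(series$y[length(series$y)]))
  if (kind == "two_gene" && base$p_y < 1 &&
      base$p_xy * x_const + base$b0 > 0) {
    summary$steady_state <- steady_state(base, x_const)$value
    summary$response_time_min <-
      response_time(base, x_const, dt = grid$dt)$elapsed_minutes
  }
  list(series = series, summary = summary)
}
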