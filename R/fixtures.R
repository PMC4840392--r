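#' Fixture catalog
#'
#' Named, fully seeded scenario generators covering every standard study
#' condition used by the package's tests and examples: step responses of
#' the two-gene cascade at the reference parameter sets, co-modulation
#' pulse trains, initial-value/disturbance robustness runs, extrinsic and
#' intrinsic noise records, time-varying estimation data, a synthetic
#' p53-like oscillation (five cycles per 30 hours, hourly sampling),
#' a feedback network under a step disturbance, and a PID tracking run.
#' Every fixture is fully determined by `(name, seed)`.
#'
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() {
  c("fig2", "fig3a", "fig3b", "fig3c", "fig4", "fig5", "fig6a", "fig6b",
    "fig6c", "fig7", "fig9", "fig11", "fig12")
}

# internal: build the in-memory fixture (list of conc_ts + params record)
build_fixture <- function(name, seed) {
  g60 <- sim_grid(60)
  two_gene_run <- function(p_xy, p_y) {
    x <- const_input(10, g60)
    y <- simulate_two_gene(two_gene_params(p_xy, p_y), x)
    list(series = list(x = x, y = y),
         params = list(p_xy = p_xy, p_y = p_y, x_const = 10, y1 = 0,
                       n_steps = 60, dt = 1))
  }
  switch(
    name,
    fig2 = two_gene_run(0.2, 0.9),
    fig3a = two_gene_run(0.15, 0.9),
    fig3b = two_gene_run(0.15, 0.4),
    fig3c = two_gene_run(0.9, 0.4),
    fig4 = {
      # co-modulation pulse trains: fast params give short, crisp pulses;
      # slow params give long ones
      g <- sim_grid(240)
      x_fast <- conc_ts(rep(rep(c(10, 0), each = 15), 8), name = "x")
      x_slow <- conc_ts(rep(rep(c(10, 0), each = 30), 4), name = "x")
      y_fast <- simulate_two_gene(two_gene_params(0.9, 0.4), x_fast,
                                  name = "y_fast")
      y_slow <- simulate_two_gene(two_gene_params(0.15, 0.9), x_slow,
                                  name = "y_slow")
      list(series = list(x_fast = x_fast, y_fast = y_fast,
                         x_slow = x_slow, y_slow = y_slow),
           params = list(fast = c(p_xy = 0.9, p_y = 0.4),
                         slow = c(p_xy = 0.15, p_y = 0.9),
                         pulse_high = 10, n_steps = 240, dt = 1))
    },
    fig5 = {
      g <- sim_grid(300)
      x <- const_input(10, g)
      p <- two_gene_params(0.2, 0.9)
      y0 <- simulate_two_gene(p, x, y1 = 0, name = "y_init0")
      y5 <- simulate_two_gene(p, x, y1 = 5, name = "y_init5")
      # additive pulse disturbance on y at n = 150, width 5, size +10
      yd <- as.numeric(simulate_two_gene(p, x))
      for (n in 150:154) yd[n] <- yd[n] + 10
      for (n in 155:300) yd[n] <- p$p_y * yd[n - 1] + p$p_xy * x[n - 1]
      list(series = list(x = x, y_init0 = y0, y_init5 = y5,
                         y_disturbed = conc_ts(yd, name = "y_disturbed")),
           params = list(p_xy = 0.2, p_y = 0.9, x_const = 10,
                         disturbance = list(size = 10, onset = 150,
                                            width = 5),
                         n_steps = 300, dt = 1))
    },
    fig6a = ,
    fig6b = ,
    fig6c = {
      g <- sim_grid(500)
      x <- const_input(10, g)
      model <- motif_model("two_gene", two_gene_params(0.2, 0.9))
      targets <- switch(name, fig6a = character(0), fig6b = "x",
                        fig6c = c("x", "y"))
      sims <- if (length(targets) == 0) {
        y <- simulate_two_gene(model$params, x)
        list(x = x, y = y)
      } else {
        simulate_with_noise(model, x,
                            noise_spec(0, 1, seed = seed, targets = targets))
      }
      list(series = sims,
           params = list(p_xy = 0.2, p_y = 0.9, x_const = 10,
                         noise = list(mean = 0, sd = 1, targets = targets),
                         n_steps = 500, dt = 1))
    },
    fig7 = {
      # time-varying two-gene data for estimator comparison: production
      # gain switches mid-run, plus unit extrinsic noise on x
      g <- sim_grid(1000)
      x_base <- const_input(10, g)
      eps <- with_seed(seed, stats::rnorm(1000, 0, 1))
      xv <- pmax(as.numeric(x_base) + eps, 0)
      p_xy_t <- c(rep(0.2, 500), rep(0.5, 500))
      y <- numeric(1000)
      for (n in 2:1000) y[n] <- max(0.9 * y[n - 1] + p_xy_t[n] * xv[n - 1], 0)
      list(series = list(x = conc_ts(xv, name = "x"),
                         y = conc_ts(y, name = "y")),
           params = list(p_xy = c(0.2, 0.5), switch_at = 501, p_y = 0.9,
                         noise_sd = 1, n_steps = 1000, dt = 1))
    },
    fig9 = {
      # synthetic p53-like oscillation: five cycles per 30 hours, hourly
      # sampling (dt = 60 min), 180 samples; small seeded jitter
      n <- 180
      f_cph <- 5 / 30                      # cycles per hour
      t_hr <- 0:(n - 1)
      jitter <- with_seed(seed, stats::rnorm(n, 0, 0.2))
      v <- pmax(10 + 5 * sin(2 * pi * f_cph * t_hr) + jitter, 0)
      list(series = list(p53 = conc_ts(v, dt = 60, name = "p53")),
           params = list(cycles_per_hour = f_cph, amplitude = 5,
                         baseline = 10, jitter_sd = 0.2, n_steps = n,
                         dt = 60))
    },
    fig11 = {
      g <- sim_grid(400)
      x <- const_input(10, g)
      fp <- feedback_params(p_xc = 0.2, p_cy = 0.5, p_yc = 0.1, p_y = 0.8)
      sim <- simulate_feedback_network(fp, x,
                                       dist = step_disturbance(1, 150))
      list(series = list(x = x, y = sim$y, c = sim$c, e = sim$e),
           params = list(p_xc = 0.2, p_cy = 0.5, p_yc = 0.1, p_y = 0.8,
                         p_c = 0, disturbance = list(magnitude = 1,
                                                     onset = 150),
                         n_steps = 400, dt = 1))
    },
    fig12 = {
      g <- sim_grid(200)
      plant <- plant_params(p_cx = 0.3, p_x = 0.8)
      gains <- tune_pid(plant, 0.5)
      r <- step_input(10, g, onset = 10, name = "r")
      sim <- simulate_pid_control(plant, gains, r)
      list(series = list(r = sim$r, x = sim$x, c = sim$c, e = sim$e),
           params = list(p_cx = 0.3, p_x = 0.8, desired_pole = 0.5,
                         K_P = gains$K_P, K_I = gains$K_I, K_D = 0,
                         reference = list(level = 10, onset = 10),
                         n_steps = 200, dt = 1))
    },
    stop(sprintf("unknown fixture name '%s' (see fixture_names())", name),
         call. = FALSE)
  )
}

#' Generate a named fixture on disk
#'
#' Writes the fixture's trajectories as one CSV (the package dialect, see
#' [write_timeseries()]) plus a JSON manifest recording the scenario name,
#' seed and every parameter, so regeneration from `(name, seed)` is
#' bit-identical.
#'
#' @param name One of [fixture_names()].
#' @param seed Integer seed (used by the stochastic fixtures; recorded for
#'   all).
#' @param dir Output directory (created if needed). Default `tempdir()`.
#' @return Invisibly, a list with `csv`, `manifest` (paths) and `series`
#'   (the in-memory trajectories).
#' @examples
#' fx <- generate_fixture("fig3a", seed = 1)
#' names(fx$series)
#' @export
generate_fixture <- function(name, seed = 1L, dir = tempdir()) {
  if (!name %in% fixture_names())
    stop(sprintf("unknown fixture name '%s' (see fixture_names())", name),
         call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- build_fixture(name, as.integer(seed))
  csv <- file.path(dir, paste0(name, ".csv"))
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  write_timeseries(fx$series, csv, seed = seed)
  jsonlite::write_json(
    list(fixture = name, seed = as.integer(seed), parameters = fx$params),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, manifest = manifest, series = fx$series,
                 params = fx$params))
}
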