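#' Two-gene cascade parameters
#'
#' Parameters of the basic difference-equation motif in which an activated
#' upstream protein x drives production of a downstream protein y:
#' \deqn{y(n) = p_y y(n-1) + p_{xy} x(n-1) + b_0}
#' `p_y` is the retention fraction (the share of y surviving one step of
#' degradation/dilution) and `p_xy` the per-step production gain. A value of
#' `p_y` above 1 would make y grow without input, below 0 would make it
#' negative; both are rejected.
#'
#' @param p_xy Production gain, >= 0.
#' @param p_y Retention fraction in \[0, 1\].
#' @param b0 Basal (input-independent) production, >= 0. Default 0.
#' @param y_max Optional saturation ceiling (> 0): the updated level is
#'   clamped to `min(y, y_max)`, modelling finite ribosome availability.
#' @return An object of class `two_gene_params`.
#' @examples
#' two_gene_params(p_xy = 0.2, p_y = 0.9)
#' @export
two_gene_params <- function(p_xy, p_y, b0 = 0, y_max = NULL) {
  if (!is.numeric(p_y) || length(p_y) != 1L || is.na(p_y) ||
      p_y < 0 || p_y > 1) {
    stop("`p_y` must lie in [0, 1]: values above 1 make y grow unboundedly, ",
         "below 0 make it negative", call. = FALSE)
  }
  if (!is.numeric(p_xy) || length(p_xy) != 1L || !is.finite(p_xy) || p_xy < 0)
    stop("`p_xy` must be a finite nonnegative number", call. = FALSE)
  if (!is.numeric(b0) || length(b0) != 1L || !is.finite(b0) || b0 < 0)
    stop("`b0` must be a finite nonnegative number", call. = FALSE)
  if (!is.null(y_max) && (!is.numeric(y_max) || length(y_max) != 1L ||
                          !is.finite(y_max) || y_max <= 0))
    stop("`y_max`, if set, must be > 0", call. = FALSE)
  structure(list(p_xy = as.numeric(p_xy), p_y = as.numeric(p_y),
                 b0 = as.numeric(b0), y_max = y_max),
            class = "two_gene_params")
}

#' @export
print.two_gene_params <- function(x, ...) {
  cat(sprintf("<two_gene_params> p_xy = %g, p_y = %g, b0 = %g%s\n",
              x$p_xy, x$p_y, x$b0,
              if (is.null(x$y_max)) "" else sprintf(", y_max = %g", x$y_max)))
  invisible(x)
}

#' Autoregulation parameters
#'
#' Positive (PAR) or negative (NAR) autoregulation adds a self-term to the
#' two-gene recursion: `+ par * y(n-1)` for PAR, `- nar * y(n-1)` for NAR.
#' PAR slows the response and raises the steady state; NAR does the
#' opposite.
#'
#' @param base A [two_gene_params()] object.
#' @param kind `"PAR"` or `"NAR"`.
#' @param strength Autoregulation parameter (> 0); its sign is implied by
#'   `kind`.
#' @return An object of class `autoreg_params`.
#' @export
autoreg_params <- function(base, kind = c("PAR", "NAR"), strength) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "two_gene_params"))
  if (!is.numeric(strength) || length(strength) != 1L ||
      !is.finite(strength) || strength <= 0)
    stop("`strength` must be > 0 (use simulate_two_gene for strength 0)",
         call. = FALSE)
  structure(list(base = base, kind = kind, strength = as.numeric(strength)),
            class = "autoreg_params")
}

#' Feedforward-loop parameters
#'
#' Three-species coherent (C1) and incoherent (IC1) type-1 feedforward
#' loops, and a four-species interlocked pair of FFLs. All species follow
#' the same retention + linear production structure as the two-gene motif:
#' \itemize{
#'   \item C1:  `y(n) = p_y y(n-1) + p_xy x(n-1)`;
#'     `z(n) = p_z z(n-1) + p_xz x(n-1) + p_yz y(n-1)` (the indirect branch
#'     through y delays z relative to direct activation).
#'   \item IC1: as C1 but the y branch represses z
#'     (`- p_yz y(n-1)`, clamped at 0), producing a pulse under a sustained
#'     step in x.
#'   \item INTERLOCKED: a second FFL chained onto the first,
#'     `w(n) = p_w w(n-1) + p_yw y(n-1) + p_zw z(n-1)`, giving sequential
#'     (ordered) expression of y, z, w.
#' }
#'
#' @param kind `"C1"`, `"IC1"` or `"INTERLOCKED"`.
#' @param retention Named numeric vector of per-species retention fractions
#'   in \[0,1\]: needs `y`, `z` (and `w` for INTERLOCKED).
#' @param gains Named numeric vector of per-edge production gains >= 0:
#'   needs `p_xy`, `p_xz`, `p_yz` (and `p_yw`, `p_zw` for INTERLOCKED).
#' @param basal Named numeric vector of per-species basal production >= 0;
#'   defaults to 0 for every species.
#' @return An object of class `ffl_params`.
#' @export
ffl_params <- function(kind = c("C1", "IC1", "INTERLOCKED"),
                       retention, gains, basal = NULL) {
  kind <- match.arg(kind)
  species <- if (kind == "INTERLOCKED") c("y", "z", "w") else c("y", "z")
  edges <- if (kind == "INTERLOCKED")
    c("p_xy", "p_xz", "p_yz", "p_yw", "p_zw") else c("p_xy", "p_xz", "p_yz")
  if (!all(species %in% names(retention)))
    stop("`retention` must name: ", paste(species, collapse = ", "),
         call. = FALSE)
  if (!all(edges %in% names(gains)))
    stop("`gains` must name: ", paste(edges, collapse = ", "), call. = FALSE)
  retention <- retention[species]
  gains <- gains[edges]
  if (any(retention < 0 | retention > 1))
    stop("every retention fraction must lie in [0, 1]", call. = FALSE)
  if (any(gains < 0)) stop("every production gain must be >= 0",
                           call. = FALSE)
  if (is.null(basal)) basal <- stats::setNames(numeric(length(species)),
                                               species)
  basal0 <- stats::setNames(numeric(length(species)), species)
  basal0[names(basal)] <- basal
  if (any(basal0 < 0)) stop("basal production must be >= 0", call. = FALSE)
  structure(list(kind = kind, retention = retention, gains = gains,
                 basal = basal0, species = species),
            class = "ffl_params")
}

#' Extrinsic noise specification
#'
#' Gaussian extrinsic noise added per sample to the named species' level
#' after its update and before it feeds downstream equations. The default
#' (mean 0, sd 1) matches the standard global-fluctuation scenario. The
#' realization is fully determined by `seed`.
#'
#' @param mean Noise mean. Default 0.
#' @param sd Noise standard deviation, >= 0. Default 1.
#' @param seed Integer seed; mandatory, so that identical specs reproduce
#'   identical realizations.
#' @param targets Character vector of species names receiving noise
#'   (e.g. `c("x")` or `c("x", "y")`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mean = 0, sd = 1, seed, targets = "x") {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory for a noise specification", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be >= 0", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 seed = as.integer(seed), targets = as.character(targets)),
            class = "noise_spec")
}

#' Motif model container
#'
#' Bundles a motif kind with its parameter object, as accepted by
#' [simulate_with_noise()].
#'
#' @param kind One of `"decay"`, `"two_gene"`, `"autoreg"`, `"ffl"`.
#' @param params The matching parameter object.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(kind = c("two_gene", "decay", "autoreg", "ffl"),
                        params) {
  kind <- match.arg(kind)
  cls <- switch(kind, two_gene = "two_gene_params", decay = "two_gene_params",
                autoreg = "autoreg_params", ffl = "ffl_params")
  if (!inherits(params, cls))
    stop(sprintf("`params` must be a <%s> for kind '%s'", cls, kind),
         call. = FALSE)
  structure(list(kind = kind, params = params), class = "motif_model")
}

# internal: run a seeded computation without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# internal: record clamp events as an attribute
note_clamps <- function(ts, n_clamped) {
  attr(ts, "clamp_events") <- n_clamped
  ts
}

#' Pure degradation/dilution
#'
#' First-order decay of a protein that is no longer produced:
#' `y(n) = p_y * y(n-1)`. A smaller retention `p_y` means faster
#' degradation.
#'
#' @param p_y Retention fraction in \[0, 1\].
#' @param y1 Initial concentration (>= 0) at the first sample.
#' @param grid A [sim_grid()].
#' @return A `conc_ts`; nonincreasing and nonnegative.
#' @examples
#' simulate_decay(0.9, 10, sim_grid(4))  # 10, 9, 8.1, 7.29
#' @export
simulate_decay <- function(p_y, y1, grid) {
  if (!is.numeric(p_y) || length(p_y) != 1L || is.na(p_y) ||
      p_y < 0 || p_y > 1)
    stop("`p_y` must lie in [0, 1]: a value above 1 makes y increase, ",
         "below 0 makes it negative", call. = FALSE)
  if (y1 < 0) stop("`y1` must be >= 0", call. = FALSE)
  y <- numeric(grid$n_steps)
  y[1] <- y1
  if (grid$n_steps > 1) for (n in 2:grid$n_steps) y[n] <- p_y * y[n - 1]
  conc_ts(y, dt = grid$dt, name = "y")
}

#' Simulate the two-gene cascade
#'
#' Iterates `y(n) = p_y y(n-1) + p_xy x(n-1) + b0`, optionally clamped to a
#' saturation ceiling `y_max`, given the upstream trajectory `x`.
#'
#' @param params A [two_gene_params()].
#' @param x Upstream `conc_ts` on the same grid.
#' @param y1 Initial concentration of y (>= 0). Default 0.
#' @param grid Optional [sim_grid()]; defaults to the grid of `x`.
#' @param name Output species label.
#' @return A `conc_ts` for y.
#' @examples
#' g <- sim_grid(60)
#' y <- simulate_two_gene(two_gene_params(0.2, 0.9), const_input(10, g))
#' tail(as.numeric(y), 1)  # approaches 0.2 * 10 / (1 - 0.9) = 20
#' @export
simulate_two_gene <- function(params, x, y1 = 0, grid = NULL, name = "y") {
  stopifnot(inherits(params, "two_gene_params"), inherits(x, "conc_ts"))
  if (is.null(grid)) grid <- grid_of(x)
  check_on_grid(x, grid, "`x`")
  if (y1 < 0) stop("`y1` must be >= 0", call. = FALSE)
  y <- numeric(grid$n_steps)
  y[1] <- y1
  clamped <- 0L
  if (grid$n_steps > 1) {
    for (n in 2:grid$n_steps) {
      v <- params$p_y * y[n - 1] + params$p_xy * x[n - 1] + params$b0
      if (!is.null(params$y_max) && v > params$y_max) {
        v <- params$y_max
        clamped <- clamped + 1L
      }
      if (v < 0) { v <- 0; clamped <- clamped + 1L }
      y[n] <- v
    }
  }
  note_clamps(conc_ts(y, dt = grid$dt, name = name), clamped)
}

#' Simulate an autoregulated gene
#'
#' Adds a self-term to the two-gene recursion:
#' `y(n) = (p_y +/- strength) y(n-1) + p_xy x(n-1) + b0`, `+` for PAR and
#' `-` for NAR. NAR trajectories are clamped at 0 from below; PAR runs whose
#' effective retention exceeds 1 are allowed but guarded against overflow
#' (divergence beyond 1e12 uM raises an unstable-motif error).
#'
#' @param params An [autoreg_params()].
#' @param x Upstream `conc_ts`.
#' @param y1 Initial concentration (>= 0).
#' @param grid Optional [sim_grid()]; defaults to the grid of `x`.
#' @param overflow_guard Divergence threshold in uM. Default 1e12.
#' @return A `conc_ts` for y.
#' @export
simulate_autoregulation <- function(params, x, y1 = 0, grid = NULL,
                                    overflow_guard = 1e12) {
  stopifnot(inherits(params, "autoreg_params"), inherits(x, "conc_ts"))
  if (is.null(grid)) grid <- grid_of(x)
  check_on_grid(x, grid, "`x`")
  if (y1 < 0) stop("`y1` must be >= 0", call. = FALSE)
  b <- params$base
  self_term <- if (params$kind == "PAR") params$strength else -params$strength
  p_eff <- b$p_y + self_term
  y <- numeric(grid$n_steps)
  y[1] <- y1
  clamped <- 0L
  if (grid$n_steps > 1) {
    for (n in 2:grid$n_steps) {
      v <- p_eff * y[n - 1] + b$p_xy * x[n - 1] + b$b0
      if (!is.null(b$y_max) && v > b$y_max) { v <- b$y_max; clamped <- clamped + 1L }
      if (v < 0) { v <- 0; clamped <- clamped + 1L }
      if (v > overflow_guard) {
        stop(sprintf(paste0("unstable motif: PAR trajectory exceeded the ",
                            "overflow guard (%g uM) at sample %d ",
                            "(effective retention %g > 1)"),
                     overflow_guard, n, p_eff), call. = FALSE)
      }
      y[n] <- v
    }
  }
  note_clamps(conc_ts(y, dt = grid$dt, name = "y"), clamped)
}

#' Simulate a feedforward loop
#'
#' Iterates the per-species recursions of a C1, IC1 or interlocked FFL (see
#' [ffl_params()]) driven by the upstream trajectory `x`. All outputs are
#' clamped at 0 from below (relevant for the repressing branch of IC1).
#'
#' @param params An [ffl_params()].
#' @param x Upstream `conc_ts`.
#' @param init Named numeric vector of initial concentrations per species
#'   (>= 0); missing species raise an error. Default: all 0.
#' @param grid Optional [sim_grid()]; defaults to the grid of `x`.
#' @return Named list of `conc_ts`, one per downstream species
#'   (`y`, `z`, and `w` for INTERLOCKED).
#' @export
simulate_ffl <- function(params, x, init = NULL, grid = NULL) {
  stopifnot(inherits(params, "ffl_params"), inherits(x, "conc_ts"))
  if (is.null(grid)) grid <- grid_of(x)
  check_on_grid(x, grid, "`x`")
  sp <- params$species
  if (is.null(init)) init <- stats::setNames(numeric(length(sp)), sp)
  if (!all(sp %in% names(init)))
    stop("missing initial value for species: ",
         paste(setdiff(sp, names(init)), collapse = ", "), call. = FALSE)
  if (any(init[sp] < 0)) stop("initial concentrations must be >= 0",
                              call. = FALSE)
  N <- grid$n_steps
  r <- params$retention
  gn <- params$gains
  b <- params$basal
  yz_sign <- if (params$kind == "IC1") -1 else 1
  Y <- numeric(N); Z <- numeric(N)
  Y[1] <- init[["y"]]; Z[1] <- init[["z"]]
  W <- if ("w" %in% sp) { w <- numeric(N); w[1] <- init[["w"]]; w } else NULL
  clamped <- 0L
  if (N > 1) {
    for (n in 2:N) {
      vy <- r[["y"]] * Y[n - 1] + gn[["p_xy"]] * x[n - 1] + b[["y"]]
      vz <- r[["z"]] * Z[n - 1] + gn[["p_xz"]] * x[n - 1] +
        yz_sign * gn[["p_yz"]] * Y[n - 1] + b[["z"]]
      if (vy < 0) { vy <- 0; clamped <- clamped + 1L }
      if (vz < 0) { vz <- 0; clamped <- clamped + 1L }
      Y[n] <- vy; Z[n] <- vz
      if (!is.null(W)) {
        vw <- r[["w"]] * W[n - 1] + gn[["p_yw"]] * Y[n - 1] +
          gn[["p_zw"]] * Z[n - 1] + b[["w"]]
        if (vw < 0) { vw <- 0; clamped <- clamped + 1L }
        W[n] <- vw
      }
    }
  }
  out <- list(y = conc_ts(Y, dt = grid$dt, name = "y"),
              z = conc_ts(Z, dt = grid$dt, name = "z"))
  if (!is.null(W)) out$w <- conc_ts(W, dt = grid$dt, name = "w")
  attr(out, "clamp_events") <- clamped
  out
}

#' Simulate a motif with extrinsic noise
#'
#' Adds seeded Gaussian extrinsic noise to the targeted species and
#' propagates it through the motif equations, so that noise on an upstream
#' species appears downstream as intrinsic noise. Noise is added to a
#' species' level after its update and before it feeds downstream
#' equations; negative post-noise levels are clamped to 0 (clamp counts are
#' recorded in the `clamp_events` attribute). With the same seed and spec
#' the realization is reproduced exactly.
#'
#' @param model A [motif_model()] (kinds `"two_gene"` and `"decay"`
#'   supported; x is the only upstream species).
#' @param x_base Noise-free upstream `conc_ts`.
#' @param noise A [noise_spec()]; targets drawn from `c("x", "y")`.
#' @param grid Optional [sim_grid()]; defaults to the grid of `x_base`.
#' @param y1 Initial downstream concentration.
#' @return Named list with elements `x` (post-noise upstream) and `y`
#'   (downstream), both `conc_ts`.
#' @export
simulate_with_noise <- function(model, x_base, noise, grid = NULL, y1 = 0) {
  stopifnot(inherits(model, "motif_model"), inherits(x_base, "conc_ts"),
            inherits(noise, "noise_spec"))
  if (!model$kind %in% c("two_gene", "decay"))
    stop("noise injection is implemented for the two-gene and decay motifs",
         call. = FALSE)
  if (is.null(grid)) grid <- grid_of(x_base)
  check_on_grid(x_base, grid, "`x_base`")
  bad <- setdiff(noise$targets, c("x", "y"))
  if (length(bad)) stop("unknown noise targets: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  N <- grid$n_steps
  draws <- with_seed(noise$seed, {
    list(x = stats::rnorm(N, noise$mean, noise$sd),
         y = stats::rnorm(N, noise$mean, noise$sd))
  })
  clamped <- 0L
  xv <- as.numeric(x_base)
  if ("x" %in% noise$targets) {
    xv <- xv + draws$x
    neg <- xv < 0
    clamped <- clamped + sum(neg)
    xv[neg] <- 0
  }
  p <- model$params
  p_xy <- if (model$kind == "decay") 0 else p$p_xy
  y <- numeric(N)
  y[1] <- y1
  add_y <- "y" %in% noise$targets
  if (add_y) {
    v <- y[1] + draws$y[1]
    if (v < 0) { v <- 0; clamped <- clamped + 1L }
    y[1] <- v
  }
  if (N > 1) {
    for (n in 2:N) {
      v <- p$p_y * y[n - 1] + p_xy * xv[n - 1] + p$b0
      if (!is.null(p$y_max) && v > p$y_max) { v <- p$y_max; clamped <- clamped + 1L }
      if (add_y) v <- v + draws$y[n]
      if (v < 0) { v <- 0; clamped <- clamped + 1L }
      y[n] <- v
    }
  }
  out <- list(x = conc_ts(xv, dt = grid$dt, name = "x"),
              y = conc_ts(y, dt = grid$dt, name = "y"))
  attr(out, "clamp_events") <- clamped
  out
}
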