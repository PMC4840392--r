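#' Negative-feedback network parameters
#'
#' A controller gene c senses the input x and the output y and drives y's
#' production, closing a negative feedback loop:
#' \deqn{c(n) = p_c c(n-1) + p_{xc} x(n-1) - p_{yc} y(n-1)}
#' \deqn{y(n) = p_y y(n-1) + p_{cy} c(n-1) + d(n)}
#' The negative sign on the `y(n-1)` term in c's update is the negative
#' feedback (y downregulates c); `d(n)` is an additive disturbance on the
#' output. All gains are nonnegative; `p_c` is the controller gene's own
#' retention (default 0: the controller re-computes the error signal each
#' step).
#'
#' @param p_xc Input-to-controller gain >= 0.
#' @param p_cy Controller-to-output production gain >= 0.
#' @param p_yc Output-to-controller (negative feedback) gain >= 0.
#' @param p_y Output retention in \[0, 1\].
#' @param p_c Controller retention in \[0, 1\]. Default 0.
#' @return An object of class `feedback_params`.
#' @export
feedback_params <- function(p_xc, p_cy, p_yc, p_y, p_c = 0) {
  vals <- c(p_xc = p_xc, p_cy = p_cy, p_yc = p_yc)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("gains `p_xc`, `p_cy`, `p_yc` must be finite and >= 0",
         call. = FALSE)
  for (r in list(p_y = p_y, p_c = p_c)) {
    if (!is.finite(r) || r < 0 || r > 1)
      stop("retentions `p_y`, `p_c` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p_xc = p_xc, p_cy = p_cy, p_yc = p_yc, p_y = p_y,
                 p_c = p_c),
            class = "feedback_params")
}

#' Step disturbance
#'
#' An additive step of size `magnitude` entering the output update from
#' sample `onset` onward.
#'
#' @param magnitude Step size (any sign).
#' @param onset 1-based sample index, >= 1.
#' @return An object of class `step_disturbance`.
#' @export
step_disturbance <- function(magnitude, onset = 1L) {
  if (onset < 1 || onset != floor(onset))
    stop("`onset` must be an integer >= 1", call. = FALSE)
  structure(list(magnitude = as.numeric(magnitude),
                 onset = as.integer(onset)),
            class = "step_disturbance")
}

#' Closed-loop transfer function of the feedback network
#'
#' Eliminating c from the two feedback recursions gives
#' \deqn{H(z) = \frac{p_{cy} p_{xc} z^{-2}}
#'   {(1 - p_y z^{-1})(1 - p_c z^{-1}) + p_{cy} p_{yc} z^{-2}},}
#' whose denominator roots are the two closed-loop poles.
#'
#' @param params A [feedback_params()].
#' @return A [transfer_function()] from X(z) to Y(z).
#' @export
feedback_closed_loop_tf <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  den <- c(1, -(params$p_y + params$p_c),
           params$p_y * params$p_c + params$p_cy * params$p_yc)
  transfer_function(num = c(0, 0, params$p_cy * params$p_xc), den = den)
}

#' Simulate the negative-feedback network
#'
#' Iterates the coupled controller/output recursions (see
#' [feedback_params()]) under an input trajectory and an optional step
#' disturbance on the output. Output concentrations are clamped at 0 from
#' below (clamp counts recorded in the `clamp_events` attribute); the
#' controller signal c is a gene product too and is clamped likewise.
#' Closed-loop divergence (|y| beyond `guard`) raises an instability error
#' reporting the pole magnitudes.
#'
#' @param params A [feedback_params()].
#' @param x Input `conc_ts`.
#' @param dist Optional [step_disturbance()].
#' @param y1,c1 Initial output / controller concentrations. Default 0.
#' @param grid Optional [sim_grid()]; defaults to the grid of `x`.
#' @param guard Divergence guard. Default 1e12.
#' @param clamp Clamp y and c at 0 from below. Default TRUE; set FALSE for
#'   linear analysis (e.g. validating the final-value theorem).
#' @return Named list of `conc_ts`: `y` (output), `c` (controller), and
#'   `e` (the error signal `p_xc x(n) - p_yc y(n)`).
#' @export
simulate_feedback_network <- function(params, x, dist = NULL, y1 = 0,
                                      c1 = 0, grid = NULL, guard = 1e12,
                                      clamp = TRUE) {
  stopifnot(inherits(params, "feedback_params"), inherits(x, "conc_ts"))
  if (!is.null(dist)) stopifnot(inherits(dist, "step_disturbance"))
  if (is.null(grid)) grid <- grid_of(x)
  check_on_grid(x, grid, "`x`")
  N <- grid$n_steps
  y <- numeric(N); cc <- numeric(N)
  y[1] <- y1; cc[1] <- c1
  clamped <- 0L
  d_at <- function(n) {
    if (is.null(dist) || n < dist$onset) 0 else dist$magnitude
  }
  if (N > 1) {
    for (n in 2:N) {
      vy <- params$p_y * y[n - 1] + params$p_cy * cc[n - 1] + d_at(n)
      vc <- params$p_c * cc[n - 1] + params$p_xc * x[n - 1] -
        params$p_yc * y[n - 1]
      if (clamp) {
        if (vy < 0) { vy <- 0; clamped <- clamped + 1L }
        if (vc < 0) { vc <- 0; clamped <- clamped + 1L }
      }
      if (abs(vy) > guard) {
        pm <- Mod(tf_poles(feedback_closed_loop_tf(params))$poles)
        stop(sprintf("unstable closed loop: |y| exceeded %g at sample %d (pole magnitudes %s)",
                     guard, n, paste(signif(pm, 4), collapse = ", ")),
             call. = FALSE)
      }
      y[n] <- vy; cc[n] <- vc
    }
  }
  e <- params$p_xc * as.numeric(x) - params$p_yc * y
  out <- list(y = conc_ts(y, dt = grid$dt, name = "y",
                          role = if (clamp) "concentration" else "error"),
              c = conc_ts(cc, dt = grid$dt, name = "c", role = "control"),
              e = conc_ts(e, dt = grid$dt, name = "e", role = "error"))
  attr(out, "clamp_events") <- clamped
  out
}

#' Steady-state error under a step disturbance (final value theorem)
#'
#' For a stable loop the final value theorem applied to the
#' disturbance-to-error transfer of the feedback network with a step
#' disturbance of size `dist_magnitude` gives the closed form
#' \deqn{e_D(\infty) = \frac{-p_{yc}\, d_0\, (1 - p_c)}
#'   {(1 - p_y)(1 - p_c) + p_{cy} p_{yc}}.}
#' Its magnitude shrinks when the production gain `p_cy` is increased or
#' the output retention `p_y` is decreased: production and degradation
#' rates shape the network's robustness to disturbances.
#'
#' @param params A [feedback_params()]; all closed-loop poles must be
#'   strictly inside the unit circle.
#' @param dist_magnitude Step size d0.
#' @return Scalar steady-state error contribution of the disturbance.
#' @export
steady_state_error <- function(params, dist_magnitude) {
  stopifnot(inherits(params, "feedback_params"))
  ps <- tf_poles(feedback_closed_loop_tf(params))
  if (!is_stable(ps))
    stop(sprintf("final value theorem inapplicable: closed loop is not stable (pole magnitudes %s)",
                 paste(signif(Mod(ps$poles), 4), collapse = ", ")),
         call. = FALSE)
  -params$p_yc * dist_magnitude * (1 - params$p_c) /
    ((1 - params$p_y) * (1 - params$p_c) + params$p_cy * params$p_yc)
}

#' Poles of a transfer function
#'
#' Roots of the denominator polynomial in z (after clearing the z^-1
#' powers). A discrete-time system is stable when every pole lies strictly
#' inside the unit circle; a unit-magnitude pole is marginal (it neither
#' decays nor grows).
#'
#' @param H A [transfer_function()].
#' @return An object of class `pole_set`: `poles` (complex),
#'   `magnitudes`, `classification` (`"stable"`, `"marginal"`,
#'   `"unstable"`).
#' @export
tf_poles <- function(H) {
  stopifnot(inherits(H, "transfer_function"))
  den <- H$den
  if (length(den) < 2)
    stop("denominator degree must be >= 1 to have poles", call. = FALSE)
  # H in z^-1 with den d0 + d1 z^-1 + ... + dk z^-k  <=>  z-polynomial
  # d0 z^k + ... + dk; polyroot wants ascending coefficients.
  poles <- polyroot(rev(den))
  mags <- Mod(poles)
  tol <- 1e-9
  cls <- if (any(mags > 1 + tol)) "unstable"
  else if (any(abs(mags - 1) <= tol)) "marginal"
  else "stable"
  structure(list(poles = poles, magnitudes = mags, classification = cls),
            class = "pole_set")
}

#' @export
print.pole_set <- function(x, ...) {
  cat(sprintf("<pole_set> %s; |poles| = %s\n", x$classification,
              paste(signif(x$magnitudes, 4), collapse = ", ")))
  invisible(x)
}

#' Is a pole set (or transfer function) stable?
#'
#' Strict stability: every pole magnitude < 1. Marginal pole sets (a
#' magnitude within 1e-9 of 1) return FALSE but are flagged in the
#' `pole_set` classification.
#'
#' @param x A `pole_set` or `transfer_function`.
#' @return Logical.
#' @export
is_stable <- function(x) {
  if (inherits(x, "transfer_function")) x <- tf_poles(x)
  stopifnot(inherits(x, "pole_set"))
  x$classification == "stable"
}

#' State-space form of the feedback network
#'
#' Writes the coupled recursions as `s(n) = A s(n-1) + B u(n-1)` with state
#' `s = (y, c)^T` and input `u = x`:
#' \deqn{A = \begin{pmatrix} p_y & p_{cy} \\ -p_{yc} & p_c \end{pmatrix},
#'   \quad B = \begin{pmatrix} 0 \\ p_{xc} \end{pmatrix}.}
#' The eigenvalues of A equal the poles of the closed-loop transfer
#' function; the system is stable when every eigenvalue magnitude is below
#' one.
#'
#' @param params A [feedback_params()].
#' @return An object of class `state_space_model`: `A`, `B`,
#'   `state_names`, `eigenvalues`.
#' @export
to_state_space <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  A <- matrix(c(params$p_y, params$p_cy,
                -params$p_yc, params$p_c),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("y", "c"), c("y", "c")))
  B <- matrix(c(0, params$p_xc), nrow = 2,
              dimnames = list(c("y", "c"), "x"))
  structure(list(A = A, B = B, state_names = c("y", "c"),
                 eigenvalues = eigen(A, only.values = TRUE)$values),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat("<state_space_model> state (y, c)\nA =\n")
  print(x$A)
  cat(sprintf("eigenvalue magnitudes: %s\n",
              paste(signif(Mod(x$eigenvalues), 4), collapse = ", ")))
  invisible(x)
}

#' PID controller gains
#'
#' @param K_P,K_I,K_D Nonnegative proportional / integral / derivative
#'   gains; at least one must be positive for active control.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(K_P = 0, K_I = 0, K_D = 0) {
  g <- c(K_P = K_P, K_I = K_I, K_D = K_D)
  if (any(!is.finite(g)) || any(g < 0))
    stop("PID gains must be finite and >= 0", call. = FALSE)
  structure(as.list(g), class = "pid_gains")
}

#' Light-driven plant parameters
#'
#' First-order model of an optogenetically actuated protein: measured
#' fluorescence `x(n) = p_x x(n-1) + p_cx c(n-1)` where `c` is the applied
#' light intensity.
#'
#' @param p_cx Light-to-protein gain >= 0.
#' @param p_x Protein retention in \[0, 1\].
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(p_cx, p_x) {
  if (!is.finite(p_cx) || p_cx < 0) stop("`p_cx` must be >= 0",
                                         call. = FALSE)
  if (!is.finite(p_x) || p_x < 0 || p_x > 1)
    stop("`p_x` must lie in [0, 1]", call. = FALSE)
  structure(list(p_cx = p_cx, p_x = p_x), class = "plant_params")
}

#' Closed-loop transfer function of the PID loop
#'
#' Reference-to-output transfer of the PID-controlled first-order plant,
#' used to inspect closed-loop poles. The characteristic polynomial (in
#' z^-1) is
#' `(1 - z^-1)(1 - p_x z^-1) + p_cx z^-1 [K_P (1 - z^-1) + K_I +
#'  K_D (1 - z^-1)^2]`.
#'
#' @param plant A [plant_params()].
#' @param gains A [pid_gains()].
#' @return A [transfer_function()].
#' @export
pid_closed_loop_tf <- function(plant, gains) {
  stopifnot(inherits(plant, "plant_params"), inherits(gains, "pid_gains"))
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
        out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  padd <- function(a, b) {
    n <- max(length(a), length(b))
    c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  }
  dif <- c(1, -1)                     # (1 - z^-1)
  if (gains$K_I > 0) {
    # controller K_P + K_D (1 - z^-1) + K_I / (1 - z^-1) over (1 - z^-1)
    ctrl_num <- padd(padd(gains$K_P * dif, gains$K_I),
                     gains$K_D * conv(dif, dif))
    ctrl_den <- dif
  } else {
    ctrl_num <- padd(gains$K_P, gains$K_D * dif)
    ctrl_den <- 1
  }
  num <- conv(c(0, plant$p_cx), ctrl_num)    # p_cx z^-1 * controller
  den <- padd(conv(c(1, -plant$p_x), ctrl_den), num)
  transfer_function(num = num, den = den)
}

#' Simulate the in-silico PID control loop
#'
#' Closes the loop around the light-driven plant: at each step the
#' measured level is compared with the reference,
#' `e(n) = r(n) - x(n)`, and the light intensity is computed by a
#' positional discrete PID law with rectangular-sum integral and
#' backward-difference derivative,
#' \deqn{c(n) = K_P e(n) + K_I \sum_{k \le n} e(k) + K_D (e(n) - e(n-1)).}
#' The plant then responds as `x(n) = p_x x(n-1) + p_cx c(n-1)`. Light
#' intensity cannot be negative, so c is clamped at 0; while the clamp is
#' active the integral term is frozen (anti-windup), and clamp events are
#' counted in the `clamp_events` attribute. Optional Gaussian measurement
#' noise is added to the fluorescence reading used by the controller.
#'
#' @param plant A [plant_params()].
#' @param gains A [pid_gains()].
#' @param r Reference `conc_ts` (role `"reference"` or concentration).
#' @param noise Optional [noise_spec()] (targets `"x"`) for measurement
#'   noise.
#' @param x1 Initial plant level. Default 0.
#' @param grid Optional [sim_grid()]; defaults to the grid of `r`.
#' @param guard Divergence guard on |x|. Default 1e12.
#' @return Named list of `conc_ts`: `x` (plant output), `c` (light), `e`
#'   (tracking error), `r` (reference echo).
#' @export
simulate_pid_control <- function(plant, gains, r, noise = NULL, x1 = 0,
                                 grid = NULL, guard = 1e12) {
  stopifnot(inherits(plant, "plant_params"), inherits(gains, "pid_gains"),
            inherits(r, "conc_ts"))
  if (is.null(grid)) grid <- grid_of(r)
  check_on_grid(r, grid, "`r`")
  N <- grid$n_steps
  meas_noise <- if (is.null(noise)) numeric(N) else {
    stopifnot(inherits(noise, "noise_spec"))
    with_seed(noise$seed, stats::rnorm(N, noise$mean, noise$sd))
  }
  x <- numeric(N); cc <- numeric(N); e <- numeric(N)
  x[1] <- x1
  integ <- 0
  e_prev <- 0
  clamped <- 0L
  for (n in seq_len(N)) {
    if (n > 1) {
      x[n] <- plant$p_x * x[n - 1] + plant$p_cx * cc[n - 1]
      if (abs(x[n]) > guard)
        stop(sprintf("closed-loop divergence at sample %d with gains K_P=%g, K_I=%g, K_D=%g",
                     n, gains$K_P, gains$K_I, gains$K_D), call. = FALSE)
    }
    x_meas <- x[n] + meas_noise[n]
    e[n] <- r[n] - x_meas
    integ_try <- integ + e[n]
    c_raw <- gains$K_P * e[n] + gains$K_I * integ_try +
      gains$K_D * (e[n] - e_prev)
    if (c_raw < 0) {
      cc[n] <- 0
      clamped <- clamped + 1L
      # anti-windup: do not accumulate the integral while clamped
    } else {
      cc[n] <- c_raw
      integ <- integ_try
    }
    e_prev <- e[n]
  }
  out <- list(x = conc_ts(pmax(x, 0), dt = grid$dt, name = "x"),
              c = conc_ts(cc, dt = grid$dt, name = "c", role = "control"),
              e = conc_ts(e, dt = grid$dt, name = "e", role = "error"),
              r = conc_ts(as.numeric(r), dt = grid$dt, name = "r",
                          role = "reference"))
  attr(out, "clamp_events") <- clamped
  out
}

#' Online plant identification by LMS
#'
#' Runs the LMS adaptive filter on a (light, fluorescence) record with one
#' input lag and one output lag, so the tracked weights are per-step
#' estimates of the plant parameters: `(p_cx_hat(n), p_x_hat(n))`.
#'
#' @param c_series Applied light `conc_ts`/numeric.
#' @param x_series Measured fluorescence `conc_ts`/numeric, same length.
#' @param mu LMS step size. Default 1e-3.
#' @param w0 Initial weights. Default c(0, 0).
#' @return An `lms_fit` whose weight columns are named `p_cx_hat`,
#'   `p_x_hat`.
#' @export
identify_plant_online <- function(c_series, x_series, mu = 1e-3,
                                  w0 = c(0, 0)) {
  fit <- fit_lms(c_series, x_series, lag_structure(1, 1), mu = mu, w0 = w0)
  colnames(fit$weights) <- c("p_cx_hat", "p_x_hat")
  names(fit$final_weights) <- c("p_cx_hat", "p_x_hat")
  fit
}

#' PI tuning by pole placement
#'
#' For the first-order plant the PI-controlled loop (K_D = 0) has the
#' characteristic polynomial
#' `z^2 + (p_cx (K_P + K_I) - 1 - p_x) z + (p_x - p_cx K_P)`. Placing the
#' poles at `{q, q^2}` (the requested dominant pole and a faster secondary
#' pole) gives
#' \deqn{K_P = (p_x - q^3)/p_{cx}, \qquad K_I = (1-q)(1-q^2)/p_{cx}.}
#' The integral gain is always positive, so a tuned loop tracks step
#' references with zero steady-state error.
#'
#' @param plant_est A [plant_params()] (e.g. from online identification);
#'   `p_cx` must be positive (control authority).
#' @param desired_pole Dominant closed-loop pole q in (0, 1).
#' @return A [pid_gains()] with `K_D = 0`; the achieved closed-loop pole
#'   set is attached as attribute `poles`.
#' @export
tune_pid <- function(plant_est, desired_pole) {
  stopifnot(inherits(plant_est, "plant_params"))
  if (plant_est$p_cx <= 0)
    stop("infeasible: `p_cx` = 0 gives no control authority", call. = FALSE)
  if (!is.finite(desired_pole) || desired_pole <= 0 || desired_pole >= 1)
    stop("`desired_pole` must lie in (0, 1)", call. = FALSE)
  q <- desired_pole
  K_P <- (plant_est$p_x - q^3) / plant_est$p_cx
  K_I <- (1 - q) * (1 - q^2) / plant_est$p_cx
  if (K_P < 0)
    stop(sprintf("infeasible placement: required K_P = %g < 0 for desired pole %g",
                 K_P, q), call. = FALSE)
  g <- pid_gains(K_P = K_P, K_I = K_I, K_D = 0)
  ps <- tf_poles(pid_closed_loop_tf(plant_est, g))
  if (!is_stable(ps))
    stop("pole placement produced an unstable loop (should not happen for q in (0,1))",
         call. = FALSE)
  attr(g, "poles") <- ps
  g
}
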