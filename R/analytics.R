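#' Steady-state level of the two-gene cascade
#'
#' Under a constant input x, the recursion
#' `y(n) = p_y y(n-1) + p_xy x(n-1) + b0` converges (for `p_y < 1`) to
#' \deqn{y_\infty = \frac{p_{xy}\,\bar x + b_0}{1 - p_y},}
#' independently of the initial value. The closed form is returned together
#' with a convergence check obtained by iterating the recursion until the
#' relative one-step change drops below `tolerance`.
#'
#' @param params A [two_gene_params()] (any `y_max` is ignored here; the
#'   closed form describes the unsaturated recursion).
#' @param x_const Constant input concentration (uM).
#' @param tolerance Relative one-step change declaring convergence.
#'   Default 1e-9.
#' @param max_steps Iteration cap. Default 1e6.
#' @return An object of class `steady_state_result` with fields `value`
#'   (closed form), `sim_value`, `converged`, `n_at_convergence`,
#'   `tolerance`.
#' @examples
#' steady_state(two_gene_params(0.15, 0.9), 10)$value  # 15
#' @export
steady_state <- function(params, x_const, tolerance = 1e-9,
                         max_steps = 1e6) {
  stopifnot(inherits(params, "two_gene_params"))
  if (params$p_y > 1) stop("`p_y` > 1: no steady state (diverging)",
                           call. = FALSE)
  forcing <- params$p_xy * x_const + params$b0
  if (params$p_y == 1) {
    if (forcing != 0)
      stop("no steady state: p_y = 1 with nonzero forcing grows linearly",
           call. = FALSE)
    value <- 0
  } else {
    value <- forcing / (1 - params$p_y)
  }
  y_prev <- 0
  converged <- FALSE
  n_at <- NA_integer_
  n <- 1L
  while (n < max_steps) {
    n <- n + 1L
    y <- params$p_y * y_prev + forcing
    if (abs(y - y_prev) / max(abs(y), .Machine$double.eps) < tolerance) {
      converged <- TRUE
      n_at <- n
      y_prev <- y
      break
    }
    y_prev <- y
  }
  structure(list(value = value, sim_value = y_prev, converged = converged,
                 n_at_convergence = n_at, tolerance = tolerance),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state> %.6g uM (simulated %.6g, %s at n = %s)\n",
              x$value, x$sim_value,
              if (x$converged) "converged" else "not converged",
              x$n_at_convergence))
  invisible(x)
}

# internal: discrete response-time step count with a tiny boundary slack so
# that exact-threshold parameter choices (p_y = exp(-1/k)) land on k
response_steps <- function(p_y, slack = 1e-12) {
  if (p_y <= 0) return(1L)
  thr <- exp(-1)  # remaining fraction 1/e <=> level at 1 - 1/e of steady state
  k <- 1L
  frac <- p_y
  while (frac > thr + slack) {
    k <- k + 1L
    frac <- frac * p_y
  }
  k
}

#' Response time of the two-gene cascade
#'
#' The response time is the time for y, started at 0 under a constant
#' input, to first reach 1 - 1/e (about 63.2%) of its steady-state level.
#' With sampling interval `dt` the trajectory is
#' `y(n) = y_inf (1 - p_y^(n-1))`, so the reported value is `dt * k` with k
#' the smallest integer such that `1 - p_y^k >= 1 - 1/e`. The continuous
#' time constant `-1/ln(p_y)` (in steps) is reported alongside for
#' reference. The response time depends only on `p_y`, not on `p_xy`.
#'
#' @param params A [two_gene_params()] with `p_y < 1`.
#' @param x_const Constant input concentration; only used to check that the
#'   steady state is positive (a zero steady state has no response time).
#' @param dt Sampling interval in minutes. Default 1.
#' @return An object of class `response_time_result` with fields
#'   `elapsed_minutes`, `steps`, `threshold_fraction` (= 1 - 1/e exactly)
#'   and `continuous_tau` (steps).
#' @examples
#' response_time(two_gene_params(0.15, 0.9), 10)$elapsed_minutes  # 10
#' response_time(two_gene_params(0.15, 0.4), 10)$elapsed_minutes  # 2
#' @export
response_time <- function(params, x_const, dt = 1) {
  stopifnot(inherits(params, "two_gene_params"))
  if (params$p_y >= 1) stop("`p_y` must be < 1 for a finite response time",
                            call. = FALSE)
  ss <- params$p_xy * x_const + params$b0
  if (ss <= 0)
    stop("undefined response time: steady state is zero", call. = FALSE)
  k <- response_steps(params$p_y)
  tau_cont <- if (params$p_y > 0) -1 / log(params$p_y) else 0
  structure(list(elapsed_minutes = dt * k, steps = k,
                 threshold_fraction = 1 - exp(-1),
                 continuous_tau = tau_cont),
            class = "response_time_result")
}

#' @export
print.response_time_result <- function(x, ...) {
  cat(sprintf(
    "<response_time> %g min (%d steps to 63.2%%; continuous tau %.3g steps)\n",
    x$elapsed_minutes, x$steps, x$continuous_tau))
  invisible(x)
}

#' Co-modulation design: hit a target steady state at a target response time
#'
#' Production affects only the steady-state level while degradation sets
#' the response time, so the two can be co-modulated independently: pick
#' the retention from the response-time target, then the production gain
#' from the steady-state target. Among the retentions whose discrete
#' response time equals `target_rt` the largest (slowest compliant
#' degradation) is returned: `p_y = exp(-dt / target_rt)`, and
#' `p_xy = target_ss * (1 - p_y) / x_const`.
#'
#' @param target_ss Target steady-state level (> 0), uM.
#' @param target_rt Target response time in minutes (a multiple of `dt`,
#'   >= `dt`).
#' @param x_const Constant input concentration (> 0).
#' @param dt Sampling interval in minutes. Default 1.
#' @return A [two_gene_params()] that round-trips through [steady_state()]
#'   and [response_time()].
#' @examples
#' design_comodulation(15, 2, 10)
#' @export
design_comodulation <- function(target_ss, target_rt, x_const, dt = 1) {
  if (!is.numeric(target_ss) || target_ss <= 0)
    stop("infeasible target: `target_ss` must be > 0", call. = FALSE)
  if (!is.numeric(x_const) || x_const <= 0)
    stop("infeasible target: `x_const` must be > 0", call. = FALSE)
  k <- target_rt / dt
  if (target_rt < dt || abs(k - round(k)) > 1e-9)
    stop("infeasible target: `target_rt` must be a multiple of `dt`, >= `dt`",
         call. = FALSE)
  k <- round(k)
  p_y <- if (k == 1) 0 else exp(-1 / k)
  # guard the floating-point boundary: insist the discrete response time hits k
  while (response_steps(p_y) > k) p_y <- p_y * (1 - 1e-12)
  p_xy <- target_ss * (1 - p_y) / x_const
  if (p_xy < 0 || p_y < 0 || p_y >= 1)
    stop("infeasible target: no (p_xy, p_y) in range achieves it",
         call. = FALSE)
  two_gene_params(p_xy = p_xy, p_y = p_y)
}

#' Matrix form of the two-gene recursion
#'
#' The recursion can be written as one linear system `A y = f`: `A` is
#' lower bidiagonal with unit diagonal and `-p_y` on the subdiagonal, and
#' the forcing vector `f` carries the initial condition in its first entry
#' and `p_xy x(n-1) + b0` below. Solving the system reproduces the
#' iterative simulation exactly. Given A and x we can recover y by linear
#' solve, and the representation makes the linear-algebraic structure of
#' the motif explicit.
#'
#' @param params A [two_gene_params()] (saturation is not representable
#'   linearly and must be unset).
#' @param x Upstream `conc_ts`.
#' @param y1 Initial concentration.
#' @return An object of class `linear_system_form` with fields
#'   `system_matrix` (n x n), `forcing_vector` (length n).
#' @export
build_linear_system <- function(params, x, y1 = 0) {
  stopifnot(inherits(params, "two_gene_params"), inherits(x, "conc_ts"))
  if (!is.null(params$y_max))
    stop("the saturated recursion is nonlinear; unset `y_max`", call. = FALSE)
  n <- length(x)
  A <- diag(1, n)
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- -params$p_y
  f <- c(y1, if (n > 1) params$p_xy * as.numeric(x)[1:(n - 1)] + params$b0)
  structure(list(system_matrix = A, forcing_vector = f,
                 dt = attr(x, "dt")),
            class = "linear_system_form")
}

#' Solve a linear-system form for the trajectory
#'
#' Forward-substitutes the lower-triangular system from
#' [build_linear_system()]; the result equals the iterative simulation to
#' machine precision.
#'
#' @param ls A `linear_system_form`.
#' @return A `conc_ts` for y.
#' @export
solve_linear_system <- function(ls) {
  stopifnot(inherits(ls, "linear_system_form"))
  y <- forwardsolve(ls$system_matrix, ls$forcing_vector)
  conc_ts(pmax(y, 0), dt = ls$dt, name = "y")
}
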