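#' ARX lag structure
#'
#' The general linear prediction model for the downstream protein uses `M`
#' past input samples and `N` past output samples:
#' \deqn{y(n) = a_1 x(n-1) + \dots + a_M x(n-M) +
#'       b_1 y(n-1) + \dots + b_N y(n-N).}
#' The two-gene motif is the special case M = N = 1 with `a_1 = p_xy`,
#' `b_1 = p_y`.
#'
#' @param M Number of past input terms (>= 0).
#' @param N_lags Number of past output terms (>= 0); `M + N_lags >= 1`.
#' @return An object of class `lag_structure`.
#' @export
lag_structure <- function(M, N_lags) {
  if (M < 0 || N_lags < 0 || M + N_lags < 1 ||
      M != floor(M) || N_lags != floor(N_lags))
    stop("`M` and `N_lags` must be nonnegative integers with M + N_lags >= 1",
         call. = FALSE)
  structure(list(M = as.integer(M), N_lags = as.integer(N_lags)),
            class = "lag_structure")
}

# internal: weight names in the canonical order (inputs first, then outputs)
weight_names <- function(lag) {
  c(if (lag$M > 0) paste0("a", seq_len(lag$M)),
    if (lag$N_lags > 0) paste0("b", seq_len(lag$N_lags)))
}

#' Assemble the ARX regression problem
#'
#' Builds one data vector d(n) = (x(n-1)...x(n-M), y(n-1)...y(n-N))^T per
#' valid time index n, stacked as rows, together with the matching targets
#' y(n). Valid indices start at `max(M, N_lags) + 1`.
#'
#' @param x Input `conc_ts` (or numeric vector).
#' @param y Output `conc_ts` (or numeric vector) of the same length.
#' @param lag A [lag_structure()].
#' @return List with `rows` (matrix, one data vector per row, columns named
#'   a1..aM, b1..bN), `targets` (y(n)), and `n_index` (the time indices).
#' @export
build_regression <- function(x, y, lag) {
  stopifnot(inherits(lag, "lag_structure"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  L <- length(y)
  start <- max(lag$M, lag$N_lags) + 1L
  if (L < start + 0L || L - start + 1L < 1L)
    stop(sprintf("series too short for lag structure (need > %d samples)",
                 start - 1L), call. = FALSE)
  idx <- start:L
  cols <- list()
  for (m in seq_len(lag$M)) cols[[length(cols) + 1L]] <- x[idx - m]
  for (k in seq_len(lag$N_lags)) cols[[length(cols) + 1L]] <- y[idx - k]
  rows <- do.call(cbind, cols)
  colnames(rows) <- weight_names(lag)
  list(rows = rows, targets = y[idx], n_index = idx)
}

# internal: minimum-norm least-squares via SVD with eps-scaled rank cutoff
minnorm_solve <- function(A, b, warn_context) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < ncol(A)) {
    warning(sprintf("%s: rank-deficient system (rank %d of %d); returning the minimum-norm solution",
                    warn_context, r, ncol(A)), call. = FALSE)
  }
  if (r == 0) return(numeric(ncol(A)))
  w <- sv$v[, seq_len(r), drop = FALSE] %*%
    (crossprod(sv$u[, seq_len(r), drop = FALSE], b) / sv$d[seq_len(r)])
  drop(w)
}

#' Least-squares ARX fit
#'
#' Finds the weight vector w minimizing the summed squared one-step
#' prediction error `sum((y(n) - w^T d(n))^2)` over the assembled rows.
#' Solved by singular value decomposition; a rank-deficient design (e.g.
#' constant input with converged constant output) falls back to the
#' minimum-norm solution with a warning.
#'
#' @param rows Design matrix from [build_regression()] (or the list it
#'   returns, from which `rows`/`targets` are taken).
#' @param targets Target vector y(n); ignored if `rows` is the list.
#' @return Named numeric weight vector (class `weight_vector`), inputs
#'   first then outputs.
#' @examples
#' g <- sim_grid(100)
#' x <- const_input(10, g)
#' y <- simulate_two_gene(two_gene_params(0.2, 0.9), x)
#' reg <- build_regression(x, y, lag_structure(1, 1))
#' fit_least_squares(reg)  # recovers (0.2, 0.9)
#' @export
fit_least_squares <- function(rows, targets = NULL) {
  if (is.list(rows) && !is.null(rows$rows)) {
    targets <- rows$targets
    rows <- rows$rows
  }
  stopifnot(is.matrix(rows), length(targets) == nrow(rows))
  if (nrow(rows) < ncol(rows))
    stop("need at least as many rows as weights", call. = FALSE)
  w <- minnorm_solve(rows, targets, "least squares")
  structure(stats::setNames(w, colnames(rows)), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Wiener-filter ARX fit
#'
#' Solves the normal equations `R w = p` where the correlation matrix
#' `R = E[d d^T]` and cross-correlation vector `p = E[d y]` are estimated
#' by sample averages over a single realization (the ergodic estimate; true
#' expectations would require an ensemble of repeated experiments). On
#' identical sample windows this coincides with the least-squares solution.
#'
#' @param x Input `conc_ts`/numeric.
#' @param y Output `conc_ts`/numeric.
#' @param lag A [lag_structure()].
#' @return Named `weight_vector`; the estimated `R` and `p` are attached as
#'   attributes `R` and `p_vec`. A singular `R` falls back to the
#'   minimum-norm pseudo-solution with a warning.
#' @export
fit_wiener <- function(x, y, lag) {
  reg <- build_regression(x, y, lag)
  n <- nrow(reg$rows)
  R <- crossprod(reg$rows) / n
  p_vec <- drop(crossprod(reg$rows, reg$targets)) / n
  w <- tryCatch(drop(solve(R, p_vec)), error = function(e) {
    minnorm_solve(R, p_vec, "Wiener filter (singular correlation matrix)")
  })
  out <- structure(stats::setNames(w, colnames(reg$rows)),
                   class = "weight_vector")
  attr(out, "R") <- R
  attr(out, "p_vec") <- p_vec
  out
}

#' LMS adaptive ARX fit
#'
#' The least-mean-squares filter updates the weights by stochastic gradient
#' descent on the instantaneous squared error: at each valid n,
#' \deqn{\hat y(n) = w(n)^T d(n), \quad e(n) = y(n) - \hat y(n), \quad
#'       w(n+1) = w(n) + \mu\, e(n)\, d(n).}
#' Unlike the least-squares and Wiener fits the weights are time-varying,
#' so the filter can track parameter drift; the error is large at first and
#' shrinks as the filter adapts.
#'
#' @param x Input `conc_ts`/numeric.
#' @param y Output `conc_ts`/numeric.
#' @param lag A [lag_structure()].
#' @param mu Step size (> 0). Default 1e-3.
#' @param w0 Initial weights (default all zero).
#' @param guard Divergence guard on `max(abs(w))`. Default 1e8.
#' @return An object of class `lms_fit`: `weights` (matrix, one row per
#'   step; row i is w at the i-th valid index, before its update),
#'   `final_weights` (`weight_vector` after the last update), `predictions`
#'   and `errors` (aligned with `n_index`), `mu`.
#' @export
fit_lms <- function(x, y, lag, mu = 1e-3, w0 = NULL, guard = 1e8) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("`mu` must be a single nonnegative number", call. = FALSE)
  reg <- build_regression(x, y, lag)
  k <- ncol(reg$rows)
  if (is.null(w0)) w0 <- numeric(k)
  if (length(w0) != k) stop("`w0` length must match the lag structure",
                            call. = FALSE)
  n_steps <- nrow(reg$rows)
  W <- matrix(NA_real_, n_steps, k, dimnames = list(NULL, colnames(reg$rows)))
  yhat <- numeric(n_steps)
  err <- numeric(n_steps)
  w <- as.numeric(w0)
  for (i in seq_len(n_steps)) {
    d <- reg$rows[i, ]
    W[i, ] <- w
    yhat[i] <- sum(w * d)
    err[i] <- reg$targets[i] - yhat[i]
    w <- w + mu * err[i] * d
    if (max(abs(w)) > guard)
      stop(sprintf("LMS diverged (|w| > %g) at step %d: step size mu = %g is unstable for these data",
                   guard, i, mu), call. = FALSE)
  }
  structure(list(weights = W,
                 final_weights = structure(
                   stats::setNames(w, colnames(reg$rows)),
                   class = "weight_vector"),
                 predictions = yhat, errors = err,
                 n_index = reg$n_index, mu = mu),
            class = "lms_fit")
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf("<lms_fit> %d steps, mu = %g\n", nrow(x$weights), x$mu))
  cat("final weights:\n")
  print(stats::setNames(as.numeric(x$final_weights), names(x$final_weights)))
  invisible(x)
}

#' One-step ARX prediction
#'
#' Applies a fixed weight vector to the data vectors of a series pair:
#' `yhat(n) = w^T d(n)`, `e(n) = y(n) - yhat(n)`.
#'
#' @param w A `weight_vector` (or plain numeric) matching `lag`.
#' @param x Input series.
#' @param y Output series.
#' @param lag A [lag_structure()].
#' @return List with `predicted`, `error` (numeric, aligned with
#'   `n_index`), and `n_index`.
#' @export
predict_arx <- function(w, x, y, lag) {
  reg <- build_regression(x, y, lag)
  if (length(w) != ncol(reg$rows))
    stop("weight length does not match the lag structure", call. = FALSE)
  yhat <- drop(reg$rows %*% as.numeric(w))
  list(predicted = yhat, error = reg$targets - yhat, n_index = reg$n_index)
}
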