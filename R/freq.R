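#' Rational transfer function in z^-1
#'
#' Represents `H(z) = (num[1] + num[2] z^-1 + ...) /
#' (den[1] + den[2] z^-1 + ...)` with the leading denominator coefficient
#' normalized to 1.
#'
#' @param num Numerator coefficients of increasing powers of z^-1.
#' @param den Denominator coefficients, `den[1]` nonzero (normalized to 1).
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(num, den) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (!length(den) || den[1] == 0)
    stop("the leading denominator coefficient must be nonzero", call. = FALSE)
  if (any(!is.finite(num)) || any(!is.finite(den)))
    stop("coefficients must be finite", call. = FALSE)
  if (den[1] != 1) {
    num <- num / den[1]
    den <- den / den[1]
  }
  structure(list(num = num, den = den), class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  fmt <- function(co) paste(
    sprintf("%+g z^-%d", co, seq_along(co) - 1L), collapse = " ")
  cat("<transfer_function>\n  H(z) = [", fmt(x$num), "] / [", fmt(x$den),
      "]\n", sep = "")
  invisible(x)
}

#' Transfer function of the two-gene cascade
#'
#' The z-transform of `y(n) = p_y y(n-1) + p_xy x(n-1)` gives
#' \deqn{H(z) = \frac{p_{xy} z^{-1}}{1 - p_y z^{-1}},}
#' a first-order IIR low-pass filter with a single pole at `p_y`. Its DC
#' gain `H(1) = p_xy / (1 - p_y)` equals the steady-state gain of the
#' motif, and for `p_y` in (0,1) the magnitude response decreases
#' monotonically with frequency: the cascade passes slow input variation
#' and attenuates fast (noise-like) variation.
#'
#' @param params A [two_gene_params()] with `p_y < 1`.
#' @return A [transfer_function()].
#' @examples
#' dc_gain(transfer_from_two_gene(two_gene_params(0.2, 0.9)))  # 2
#' @export
transfer_from_two_gene <- function(params) {
  stopifnot(inherits(params, "two_gene_params"))
  if (params$p_y >= 1) stop("`p_y` must be < 1 for a stable filter",
                            call. = FALSE)
  transfer_function(num = c(0, params$p_xy), den = c(1, -params$p_y))
}

# internal: evaluate a polynomial in z^-1 at points z on the unit circle
polyval_zinv <- function(co, z) {
  acc <- rep(0 + 0i, length(z))
  zi <- 1 / z
  pow <- rep(1 + 0i, length(z))
  for (c_k in co) {
    acc <- acc + c_k * pow
    pow <- pow * zi
  }
  acc
}

#' Evaluate a transfer function at given z
#' @param H A `transfer_function`.
#' @param z Complex points (e.g. `exp(1i * omega)`).
#' @return Complex values H(z).
#' @export
eval_tf <- function(H, z) {
  stopifnot(inherits(H, "transfer_function"))
  polyval_zinv(H$num, z) / polyval_zinv(H$den, z)
}

#' DC gain of a transfer function
#' @param H A `transfer_function`.
#' @return `H(1)` as a real number.
#' @export
dc_gain <- function(H) Re(eval_tf(H, 1 + 0i))

#' Frequency (Bode) response
#'
#' Evaluates `H(e^{j omega})` on a uniform grid of angular frequencies over
#' \[0, pi\] radians per sample and reports magnitude (dB) and phase.
#'
#' @param H A `transfer_function`.
#' @param n_points Grid size. Default 512.
#' @return An object of class `freq_response`: `omega`, `magnitude`,
#'   `magnitude_db`, `phase_rad`.
#' @export
freq_response <- function(H, n_points = 512) {
  stopifnot(inherits(H, "transfer_function"), n_points >= 2)
  omega <- seq(0, pi, length.out = n_points)
  z <- exp(1i * omega)
  den_val <- polyval_zinv(H$den, z)
  bad <- which(Mod(den_val) < 1e-12)
  if (length(bad))
    stop(sprintf("unit-circle pole: denominator vanishes at omega = %.6g rad/sample",
                 omega[bad[1]]), call. = FALSE)
  val <- polyval_zinv(H$num, z) / den_val
  structure(list(omega = omega, magnitude = Mod(val),
                 magnitude_db = 20 * log10(Mod(val)),
                 phase_rad = Arg(val)),
            class = "freq_response")
}

#' @export
print.freq_response <- function(x, ...) {
  cat(sprintf("<freq_response> %d points over [0, pi]; |H(0)| = %.4g, |H(pi)| = %.4g\n",
              length(x$omega), x$magnitude[1],
              x$magnitude[length(x$magnitude)]))
  invisible(x)
}

#' White-noise gain of the two-gene cascade
#'
#' The long-run ratio of output to input noise standard deviation for white
#' noise driving the first-order filter:
#' `sqrt(p_xy^2 / (1 - p_y^2))`. Below 1 whenever the cascade attenuates
#' upstream fluctuations (the usual regime), which is why downstream
#' intrinsic noise is smaller than the extrinsic noise that caused it.
#'
#' @param params A [two_gene_params()] with `p_y < 1`.
#' @return Scalar noise gain.
#' @export
noise_gain <- function(params) {
  stopifnot(inherits(params, "two_gene_params"))
  if (params$p_y >= 1) stop("`p_y` must be < 1", call. = FALSE)
  sqrt(params$p_xy^2 / (1 - params$p_y^2))
}

#' Discrete Fourier transform of a time series
#'
#' Computes `X(omega(m)) = sum_{n=0}^{N-1} x(n) exp(-j omega(m) n)` at the
#' analysis frequencies `omega(m) = 2 pi m / N`, m = 0..N-1 (radians per
#' sampling interval). For real input the magnitude spectrum is mirrored:
#' `|X(omega(m))| = |X(omega(N-m))|`, so only the first half carries
#' independent information.
#'
#' @param x A `conc_ts` or numeric vector.
#' @param dt Sampling interval in minutes (taken from `x` when it is a
#'   `conc_ts`).
#' @return An object of class `dft_result`: `m`, `omega_m` (rad/sample),
#'   `X` (complex), `magnitude`, `cycles_per_min` (= m / (N dt)), `dt`,
#'   `n`.
#' @examples
#' d <- dft(conc_ts(c(2, 0, 4, 7), dt = 1, name = "x"))
#' d$magnitude  # 13, sqrt(53), 1, sqrt(53)
#' @export
dft <- function(x, dt = NULL) {
  if (inherits(x, "conc_ts")) {
    if (is.null(dt)) dt <- attr(x, "dt")
    x <- as.numeric(x)
  }
  if (is.null(dt)) dt <- 1
  if (!length(x)) stop("empty series", call. = FALSE)
  N <- length(x)
  X <- stats::fft(x)
  m <- 0:(N - 1)
  structure(list(m = m, omega_m = 2 * pi * m / N, X = X,
                 magnitude = Mod(X),
                 cycles_per_min = m / (N * dt), dt = dt, n = N),
            class = "dft_result")
}

#' @export
print.dft_result <- function(x, ...) {
  cat(sprintf("<dft_result> N = %d, dt = %g min\n", x$n, x$dt))
  invisible(x)
}

#' Dominant oscillation frequency
#'
#' Returns the frequency (cycles per minute) of the largest-magnitude DFT
#' bin over the non-mirrored half of the spectrum, m = 1..floor(N/2) (the
#' DC bin is excluded by default and the mirror half is disregarded). Ties
#' break toward the lower frequency.
#'
#' @param res A [dft()] result with `N >= 2`.
#' @param exclude_dc Exclude the m = 0 bin. Default TRUE.
#' @return Scalar frequency in cycles per minute, with attributes `m`
#'   (the winning bin) and `cycles_per_hour`.
#' @export
dominant_frequency <- function(res, exclude_dc = TRUE) {
  stopifnot(inherits(res, "dft_result"))
  if (res$n < 2) stop("need at least 2 samples", call. = FALSE)
  lo <- if (exclude_dc) 1L else 0L
  hi <- res$n %/% 2L
  cand <- which(res$m >= lo & res$m <= hi)
  mags <- res$magnitude[cand]
  if (all(mags <= 0))
    stop("undefined peak: spectrum is identically zero over the search band",
         call. = FALSE)
  # ties (to within rounding) break toward the lower frequency
  top <- max(mags)
  best <- cand[which(mags >= top * (1 - 1e-9))[1]]
  out <- res$cycles_per_min[best]
  attr(out, "m") <- res$m[best]
  attr(out, "cycles_per_hour") <- out * 60
  out
}
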