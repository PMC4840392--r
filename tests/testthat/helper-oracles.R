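# Independent oracles and shared fixture builders for the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(N^2) direct-summation DFT, independent of stats::fft
dft_direct <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(m) {
    sum(x * exp(-1i * 2 * pi * m * (0:(N - 1)) / N))
  }, complex(1))
}

# polynomial roots via companion-matrix eigenvalues (oracle for tf_poles);
# coefficients of z^k .. z^0 (descending)
roots_companion <- function(coefs) {
  coefs <- coefs / coefs[1]
  k <- length(coefs) - 1L
  if (k == 0) return(complex(0))
  C <- matrix(0, k, k)
  if (k > 1) C[cbind(2:k, 1:(k - 1))] <- 1
  C[1, ] <- -coefs[-1]
  eigen(C, only.values = TRUE)$values
}

# two-gene record with a mid-run production-gain switch and noisy input
make_switching_record <- function(n = 4000, p_xy1 = 0.2, p_xy2 = 0.5,
                                  p_y = 0.9, seed = 42) {
  set.seed(seed)
  xv <- pmax(10 + rnorm(n), 0)
  p_xy_t <- c(rep(p_xy1, n %/% 2), rep(p_xy2, n - n %/% 2))
  y <- numeric(n)
  for (k in 2:n) y[k] <- p_y * y[k - 1] + p_xy_t[k] * xv[k - 1]
  list(x = conc_ts(xv, name = "x"), y = conc_ts(y, name = "y"),
       switch_at = n %/% 2 + 1L)
}

expect_tsequal <- function(a, b, tol = 1e-12) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
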