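test_that("pure decay follows the hand-iterated sequences", {
  expect_equal(as.numeric(simulate_decay(0.9, 10, sim_grid(4))),
               c(10, 9, 8.1, 7.29))
  expect_equal(as.numeric(simulate_decay(0.1, 10, sim_grid(3))),
               c(10, 1, 0.1))
  expect_equal(as.numeric(simulate_decay(1, 10, sim_grid(5))), rep(10, 5))
  y <- simulate_decay(0.73, 8, sim_grid(50))
  expect_true(all(diff(as.numeric(y)) <= 0))
  expect_true(all(as.numeric(y) >= 0))
  expect_error(simulate_decay(1.1, 10, sim_grid(3)), "\\[0, 1\\]")
  expect_error(simulate_decay(-0.1, 10, sim_grid(3)), "\\[0, 1\\]")
})

test_that("two-gene cascade reproduces the hand iteration and its limit", {
  g <- sim_grid(200)
  x <- const_input(10, g)
  y <- simulate_two_gene(two_gene_params(0.2, 0.9), x)
  expect_equal(as.numeric(y)[2:4], c(2.0, 3.8, 5.42))
  expect_equal(as.numeric(y)[200], 20, tolerance = 1e-6)
  # production terms vanish -> identical to pure decay
  y0 <- simulate_two_gene(two_gene_params(0, 0.9), x, y1 = 10)
  expect_tsequal(y0, simulate_decay(0.9, 10, g))
  expect_error(simulate_two_gene(two_gene_params(0.2, 0.9),
                                 const_input(10, sim_grid(10)), grid = g),
               "grid")
  expect_error(simulate_two_gene(two_gene_params(0.2, 0.9), x, y1 = -1),
               "y1")
})

test_that("basal production and saturation act as specified", {
  g <- sim_grid(300)
  x <- const_input(10, g)
  yb <- simulate_two_gene(two_gene_params(0.2, 0.9, b0 = 0.5), x)
  expect_equal(as.numeric(yb)[300], (0.2 * 10 + 0.5) / 0.1, tolerance = 1e-6)
  ys <- simulate_two_gene(two_gene_params(0.2, 0.9, y_max = 12), x)
  expect_true(max(as.numeric(ys)) <= 12)
  expect_equal(as.numeric(ys)[300], 12)
  expect_gt(attr(ys, "clamp_events"), 0)
})

test_that("two-gene response is linear and superposable when unclamped", {
  g <- sim_grid(80)
  p <- two_gene_params(0.3, 0.8)
  set.seed(11)
  x1 <- conc_ts(runif(80, 0, 10))
  x2 <- conc_ts(runif(80, 0, 10))
  y1 <- as.numeric(simulate_two_gene(p, x1))
  y2 <- as.numeric(simulate_two_gene(p, x2))
  y_scaled <- as.numeric(simulate_two_gene(p, conc_ts(3 * as.numeric(x1))))
  y_sum <- as.numeric(simulate_two_gene(p, conc_ts(as.numeric(x1) +
                                                     as.numeric(x2))))
  expect_equal(y_scaled, 3 * y1, tolerance = 1e-12)
  expect_equal(y_sum, y1 + y2, tolerance = 1e-12)
})

test_that("steady state is independent of the initial value and recovers from a pulse", {
  g <- sim_grid(500)
  x <- const_input(10, g)
  p <- two_gene_params(0.2, 0.9)
  ya <- simulate_two_gene(p, x, y1 = 0)
  yb <- simulate_two_gene(p, x, y1 = 5)
  expect_lt(abs(ya[500] - yb[500]), 1e-6)
  # additive pulse on y: trajectory returns to the pre-disturbance level
  yd <- as.numeric(ya)
  yd[250] <- yd[250] + 10
  for (n in 251:500) yd[n] <- p$p_y * yd[n - 1] + p$p_xy * x[n - 1]
  expect_lt(abs(yd[500] - ya[500]), 1e-4)
})

test_that("PAR raises and NAR lowers steady state and response time", {
  g <- sim_grid(400)
  x <- const_input(10, g)
  base <- two_gene_params(0.2, 0.9)
  y0 <- as.numeric(simulate_two_gene(base, x))
  y_par <- as.numeric(simulate_autoregulation(
    autoreg_params(base, "PAR", 0.05), x))
  y_nar <- as.numeric(simulate_autoregulation(
    autoreg_params(base, "NAR", 0.2), x))
  half_time <- function(y) which(y >= 0.632 * y[length(y)])[1]
  expect_gt(y_par[400], y0[400])
  expect_lt(y_nar[400], y0[400])
  expect_gt(half_time(y_par), half_time(y0))
  expect_lt(half_time(y_nar), half_time(y0))
})

test_that("unstable PAR trips the overflow guard with a clear diagnostic", {
  g <- sim_grid(2000)
  x <- const_input(10, g)
  expect_error(
    simulate_autoregulation(
      autoreg_params(two_gene_params(0.2, 0.9), "PAR", 0.2), x),
    "unstable motif")
})

test_that("FFL variants show delay, pulse and sequential expression", {
  g <- sim_grid(200)
  x <- step_input(10, g)
  half_time <- function(y) which(y >= 0.5 * y[length(y)])[1]

  c1 <- simulate_ffl(
    ffl_params("C1", retention = c(y = 0.9, z = 0.9),
               gains = c(p_xy = 0.2, p_xz = 0.1, p_yz = 0.1)), x)
  z_direct <- simulate_two_gene(two_gene_params(0.1, 0.9), x, name = "z")
  expect_gt(half_time(as.numeric(c1$z)), half_time(as.numeric(z_direct)))

  ic1 <- simulate_ffl(
    ffl_params("IC1", retention = c(y = 0.9, z = 0.8),
               gains = c(p_xy = 0.2, p_xz = 0.5, p_yz = 0.15)), x)
  z <- as.numeric(ic1$z)
  expect_lt(which.max(z), length(z))       # peak strictly before the end
  expect_gt(max(z), z[length(z)])          # pulse exceeds the final level
  expect_true(all(z >= 0))

  il <- simulate_ffl(
    ffl_params("INTERLOCKED",
               retention = c(y = 0.9, z = 0.9, w = 0.9),
               gains = c(p_xy = 0.2, p_xz = 0.05, p_yz = 0.1,
                         p_yw = 0.02, p_zw = 0.1)), x)
  times <- c(half_time(as.numeric(il$y)), half_time(as.numeric(il$z)),
             half_time(as.numeric(il$w)))
  expect_true(all(diff(times) > 0))

  zero <- simulate_ffl(
    ffl_params("C1", retention = c(y = 0.9, z = 0.9),
               gains = c(p_xy = 0, p_xz = 0, p_yz = 0)), x)
  expect_true(all(as.numeric(zero$y) == 0) && all(as.numeric(zero$z) == 0))
  expect_error(
    simulate_ffl(ffl_params("C1", retention = c(y = 0.9, z = 0.9),
                            gains = c(p_xy = 0.2, p_xz = 0.1, p_yz = 0.1)),
                 x, init = c(y = 0)),
    "missing initial value")
})

test_that("seeded noise is reproducible and vanishes at sd = 0", {
  g <- sim_grid(300)
  x <- const_input(10, g)
  model <- motif_model("two_gene", two_gene_params(0.2, 0.9))
  a <- simulate_with_noise(model, x, noise_spec(0, 1, seed = 5,
                                                targets = c("x", "y")))
  b <- simulate_with_noise(model, x, noise_spec(0, 1, seed = 5,
                                                targets = c("x", "y")))
  expect_identical(as.numeric(a$x), as.numeric(b$x))
  expect_identical(as.numeric(a$y), as.numeric(b$y))
  quiet <- simulate_with_noise(model, x, noise_spec(0, 0, seed = 5,
                                                    targets = "x"))
  expect_tsequal(quiet$y, simulate_two_gene(model$params, x))
  # noise drawing must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_with_noise(model, x,
                                              noise_spec(0, 1, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("downstream fluctuations are attenuated relative to upstream noise", {
  g <- sim_grid(10000)
  x <- const_input(10, g)
  p <- two_gene_params(0.2, 0.9)
  sim <- simulate_with_noise(motif_model("two_gene", p), x,
                             noise_spec(0, 1, seed = 21, targets = "x"))
  y_clean <- as.numeric(simulate_two_gene(p, x))
  dev <- as.numeric(sim$y) - y_clean
  burn <- 200
  expect_lt(sd(dev[-(1:burn)]), 1)  # filter gain ~0.46 < 1
})
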