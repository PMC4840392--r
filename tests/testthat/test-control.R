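fp_default <- function() feedback_params(p_xc = 0.2, p_cy = 0.5,
                                          p_yc = 0.1, p_y = 0.8)

test_that("feedback simulation reduces to open loop when the loop is severed", {
  g <- sim_grid(300)
  x <- const_input(10, g)
  open <- feedback_params(p_xc = 0.2, p_cy = 0.5, p_yc = 0, p_y = 0.8)
  sim <- simulate_feedback_network(open, x)
  # with p_yc = 0, c settles to p_xc * x and y to a two-gene response on c
  expect_equal(as.numeric(sim$c)[300], 0.2 * 10, tolerance = 1e-9)
  expect_equal(as.numeric(sim$y)[300], 0.5 * 2 / (1 - 0.8),
               tolerance = 1e-6)
  zero <- simulate_feedback_network(fp_default(),
                                    const_input(0, g))
  expect_true(all(as.numeric(zero$y) == 0) && all(as.numeric(zero$c) == 0))
})

test_that("negative feedback shrinks the steady-state offset left by a disturbance", {
  g <- sim_grid(2000)
  x <- const_input(10, g)
  d <- step_disturbance(1, 1000)
  with_fb <- fp_default()
  # matched DC behavior without feedback: same undisturbed steady state
  y_fb0 <- as.numeric(simulate_feedback_network(with_fb, x)$y)[2000]
  no_fb <- feedback_params(p_xc = 0.2, p_cy = 0.5, p_yc = 0, p_y = 0.8)
  scale <- y_fb0 / as.numeric(simulate_feedback_network(no_fb, x)$y)[2000]
  no_fb_matched <- feedback_params(p_xc = 0.2 * scale, p_cy = 0.5,
                                   p_yc = 0, p_y = 0.8)
  off_fb <- as.numeric(simulate_feedback_network(with_fb, x, d)$y)[2000] -
    y_fb0
  off_open <- as.numeric(
    simulate_feedback_network(no_fb_matched, x, d)$y)[2000] -
    as.numeric(simulate_feedback_network(no_fb_matched, x)$y)[2000]
  expect_lt(abs(off_fb), abs(off_open))
})

test_that("the final-value steady-state error matches long simulations", {
  g <- sim_grid(3000)
  x <- const_input(10, g)
  d0 <- 1.5
  set.seed(23)
  n_ok <- 0
  while (n_ok < 12) {
    fp <- feedback_params(p_xc = runif(1, 0.05, 0.5),
                          p_cy = runif(1, 0.1, 0.8),
                          p_yc = runif(1, 0.02, 0.3),
                          p_y = runif(1, 0.2, 0.95),
                          p_c = runif(1, 0, 0.5))
    if (!is_stable(feedback_closed_loop_tf(fp))) next
    n_ok <- n_ok + 1
    pred <- steady_state_error(fp, d0)
    base <- simulate_feedback_network(fp, x, clamp = FALSE)
    dist <- simulate_feedback_network(fp, x, step_disturbance(d0, 1500),
                                      clamp = FALSE)
    sim_err <- as.numeric(dist$e)[3000] - as.numeric(base$e)[3000]
    expect_lt(abs(pred - sim_err), 1e-6)
  }
  expect_equal(steady_state_error(fp_default(), 0), 0)
})

test_that("disturbance error shrinks with more production and less retention", {
  base <- fp_default()
  e0 <- abs(steady_state_error(base, 1))
  doubled <- feedback_params(0.2, 1.0, 0.1, 0.8)
  expect_lt(abs(steady_state_error(doubled, 1)), e0)
  lower_py <- feedback_params(0.2, 0.5, 0.1, 0.5)
  expect_lt(abs(steady_state_error(lower_py, 1)), e0)
  # monotone over sweeps
  errs_cy <- vapply(seq(0.2, 1.4, by = 0.2), function(p_cy)
    abs(steady_state_error(feedback_params(0.2, p_cy, 0.1, 0.8), 1)), 0)
  expect_true(all(diff(errs_cy) < 0))
  errs_py <- vapply(seq(0.1, 0.9, by = 0.1), function(p_y)
    abs(steady_state_error(feedback_params(0.2, 0.5, 0.1, p_y), 1)), 0)
  expect_true(all(diff(errs_py) > 0))
  unstable <- feedback_params(0.2, 3, 3, 0.99)
  expect_error(steady_state_error(unstable, 1), "inapplicable")
})

test_that("poles match constructed factorizations and an eigenvalue oracle", {
  H1 <- transfer_from_two_gene(two_gene_params(0.2, 0.9))
  expect_equal(tf_poles(H1)$poles, 0.9 + 0i, tolerance = 1e-12)
  # (1 - 0.5 z^-1)^2 -> double pole at 0.5
  H2 <- transfer_function(1, c(1, -1, 0.25))
  expect_equal(sort(Mod(tf_poles(H2)$poles)), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_true(is_stable(H2))
  set.seed(14)
  for (i in 1:20) {
    den <- c(1, runif(2, -1.5, 1.5))
    got <- tf_poles(transfer_function(1, den))$poles
    oracle <- roots_companion(den)
    expect_equal(sort(Re(got)), sort(Re(oracle)), tolerance = 1e-9)
    expect_equal(sort(Mod(got)), sort(Mod(oracle)), tolerance = 1e-9)
  }
  expect_error(tf_poles(transfer_function(1, 1)), "degree")
})

test_that("state-space eigenvalues equal the closed-loop poles", {
  # decoupled: A is triangular, eigenvalues are the retentions
  dec <- to_state_space(feedback_params(0.3, 0, 0, 0.7, p_c = 0.4))
  expect_equal(sort(Re(dec$eigenvalues)), c(0.4, 0.7))
  # degenerate identity dynamics: marginal eigenvalues at 1
  ident <- to_state_space(feedback_params(0, 0, 0, 1, p_c = 1))
  expect_equal(Mod(ident$eigenvalues), c(1, 1))
  expect_equal(tf_poles(feedback_closed_loop_tf(
    feedback_params(0, 0, 0, 1, p_c = 1)))$classification, "marginal")
  set.seed(15)
  for (i in 1:20) {
    fp <- feedback_params(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 0.5),
                          runif(1, 0, 1), p_c = runif(1, 0, 1))
    ev <- to_state_space(fp)$eigenvalues
    ps <- tf_poles(feedback_closed_loop_tf(fp))$poles
    expect_equal(sort(Mod(ev)), sort(Mod(ps)), tolerance = 1e-9)
    expect_equal(sort(Re(ev)), sort(Re(ps)), tolerance = 1e-9)
  }
})

test_that("pole stability predicts empirical boundedness", {
  g <- sim_grid(2000)
  x <- const_input(1, g)
  set.seed(16)
  checked <- 0
  while (checked < 100) {
    fp <- feedback_params(runif(1, 0, 1), runif(1, 0, 2), runif(1, 0, 2),
                          runif(1, 0, 1), p_c = runif(1, 0, 1))
    ps <- tf_poles(feedback_closed_loop_tf(fp))
    if (ps$classification == "marginal" ||
        abs(max(ps$magnitudes) - 1) < 0.02) next  # skip near-marginal cases
    checked <- checked + 1
    sim <- tryCatch(
      simulate_feedback_network(fp, x, clamp = FALSE, guard = 1e9),
      error = function(e) "diverged")
    bounded <- !identical(sim, "diverged") &&
      max(abs(as.numeric(sim$y))) < 1e6
    expect_identical(bounded, is_stable(ps))
  }
})

test_that("PID control tracks a step with integral action and offsets without", {
  plant <- plant_params(0.3, 0.8)
  g <- sim_grid(600)
  r <- step_input(10, g, onset = 2)
  gains <- tune_pid(plant, 0.5)
  sim <- simulate_pid_control(plant, gains, r)
  tail_err <- abs(as.numeric(sim$e)[541:600])
  expect_lt(max(tail_err), 1e-3 * 10)
  # proportional-only control leaves the closed-form bias
  p_only <- pid_gains(K_P = 1)
  simp <- simulate_pid_control(plant, p_only, r)
  offset_expected <- 10 / (1 + 1 * 0.3 / (1 - 0.8))
  expect_equal(as.numeric(simp$e)[600], offset_expected, tolerance = 1e-6)
  # no control: the plant just decays from its initial level
  passive <- simulate_pid_control(plant, pid_gains(), r, x1 = 5)
  expect_tsequal(passive$x, simulate_decay(0.8, 5, g))
  # an overdriven proportional loop is flagged unstable by its poles and
  # never settles in simulation (the light clamp keeps it oscillating)
  hot <- pid_gains(K_P = 50)
  expect_false(is_stable(pid_closed_loop_tf(plant, hot)))
  sim_hot <- simulate_pid_control(plant, hot, r)
  expect_gt(max(abs(as.numeric(sim_hot$e)[541:600])), 1)
})

test_that("online identification recovers and tracks the plant parameters", {
  plant <- plant_params(0.3, 0.8)
  g <- sim_grid(3000)
  # persistently exciting light input
  set.seed(19)
  cv <- pmax(5 + 2 * sin(2 * pi * (0:2999) / 40) + rnorm(3000, 0, 0.5), 0)
  x <- numeric(3000)
  for (n in 2:3000) x[n] <- 0.8 * x[n - 1] + 0.3 * cv[n - 1]
  fit <- identify_plant_online(cv, x, mu = 5e-3)
  expect_equal(colnames(fit$weights), c("p_cx_hat", "p_x_hat"))
  expect_lt(max(abs(as.numeric(fit$final_weights) - c(0.3, 0.8))), 1e-2)
  # frozen at w0 when mu = 0
  frz <- identify_plant_online(cv, x, mu = 0, w0 = c(0.5, 0.5))
  expect_true(all(frz$weights == 0.5))
  # retention switch mid-run: estimate tracks within 5e-2 within 500 samples
  p_x_t <- c(rep(0.8, 1500), rep(0.6, 1500))
  x2 <- numeric(3000)
  for (n in 2:3000) x2[n] <- p_x_t[n] * x2[n - 1] + 0.3 * cv[n - 1]
  fit2 <- identify_plant_online(cv, x2, mu = 2e-3)
  at <- which(fit2$n_index == 2001)
  expect_lt(abs(fit2$weights[at, "p_x_hat"] - 0.6), 5e-2)
})

test_that("PI pole placement hits the requested dominant pole", {
  plant <- plant_params(0.3, 0.8)
  gains <- tune_pid(plant, 0.5)
  ps <- tf_poles(pid_closed_loop_tf(plant, gains))
  expect_lt(abs(max(Mod(ps$poles)) - 0.5), 1e-6)
  expect_identical(gains$K_D, 0)
  expect_gt(gains$K_I, 0)
  expect_error(tune_pid(plant_params(0, 0.8), 0.5), "no control authority")
  expect_error(tune_pid(plant, 1.2), "desired_pole")
  # the tuned loop settles within the horizon implied by the placed pole
  g <- sim_grid(80)
  sim <- simulate_pid_control(plant, gains, step_input(10, g, onset = 2))
  # |e| decays ~ 0.5^n: 1% of the step well before n = 80
  expect_lt(abs(as.numeric(sim$e)[80]), 0.01 * 10)
})
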