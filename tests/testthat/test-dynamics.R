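test_that("sigmoid has midpoint symmetry, saturation and the closed form", {
  expect_equal(sigmoid(0.5, beta = 10, theta = 0.5), 0.5)
  expect_equal(sigmoid(0.5, beta = 123, theta = 0.5), 0.5)
  expect_equal(sigmoid(1e6, 10, 0.5), 1)
  expect_equal(sigmoid(-1e6, 10, 0.5), 0)
  # closed-form value at z = 0, beta = 10, theta = 0.5
  expect_equal(sigmoid(0, 10, 0.5), 1 / (1 + exp(5)), tolerance = 1e-12)
  # strictly increasing
  z <- seq(-2, 2, length.out = 101)
  expect_true(all(diff(sigmoid(z, 10, 0.5)) > 0))
})

test_that("regulation field scales the interaction sum and adds the input", {
  J <- matrix(0L, 4, 4)
  net <- grn(J)
  p <- grn_dynamics()
  expect_equal(regulation_field(net, rep(0.5, 4), p, 0), rep(0, 4))
  z <- regulation_field(net, rep(0.5, 4), p, 1)
  expect_equal(z, c(1, 0, 0, 0))

  J[3, 2] <- -1L  # regulation from gene 2 to gene 3
  net <- grn(J)
  x <- c(0, 0.8, 0, 0)
  expect_equal(regulation_field(net, x, p, 0)[3], -0.8 / 2)  # sqrt(4) = 2
  p2 <- grn_dynamics(scaling_mode = "inverse-sqrt-indegree")
  expect_equal(regulation_field(net, x, p2, 0)[3], -0.8)  # indegree 1
  expect_error(regulation_field(net, 1:3, p, 0), "length")
})

test_that("derivative vanishes exactly at the fixed-point condition", {
  net <- test_net(5, 0.5)
  p <- grn_dynamics()
  # on a network with no interactions the field does not depend on x, so
  # the fixed-point condition x = sigmoid(z) + delta can be written down
  empty <- grn(matrix(0L, 5, 5))
  x_star <- rep(sigmoid(0, p$beta, p$theta) + p$delta, 5)
  expect_equal(grn_derivative(empty, x_star, p, 0), rep(0, 5),
               tolerance = 1e-14)
  # boundedness forcing: any state above 1 + delta has negative derivative
  hi <- rep(1 + p$delta, 5)
  expect_true(all(grn_derivative(net, hi, p, 1) <= 1e-12))
})

test_that("trajectories stay in bounds, start at x0 and are deterministic", {
  set.seed(5)
  p <- fast_dynamics()
  for (k in 1:5) {
    net <- random_grn(8, runif(1, 0.2, 0.6))
    x0 <- runif(8)
    tr <- integrate_grn(net, p, I = 1, x0 = x0, duration = 30)
    expect_equal(unname(tr$states[1, ]), x0)
    expect_true(all(tr$states >= -1e-12))
    expect_true(all(tr$states <= 1 + p$delta + 1e-12))
  }
  net <- test_net(6)
  a <- integrate_grn(net, p, 1, rep(0, 6), 20)
  b <- integrate_grn(net, p, 1, rep(0, 6), 20)
  expect_identical(a$states, b$states)
})

test_that("relaxation finds the analytic fixed point of the empty network", {
  p <- grn_dynamics()
  net <- grn(matrix(0L, 4, 4))
  ss <- relax_to_steady_state(net, p, I = 0)
  expect_true(ss$converged)
  expect_false(ss$oscillatory)
  x_star <- sigmoid(0, p$beta, p$theta) + p$delta
  # derivative tolerance 1e-8 puts the state within ~1e-8 of the root
  expect_lt(max(abs(ss$state - x_star)), 1e-7)
  # derivative at the returned state obeys the tolerance
  expect_lt(max(abs(grn_derivative(net, ss$state, p, 0))), p$ss_tol)
  # starting at the steady state, relaxation is immediate
  ss2 <- relax_to_steady_state(net, p, 0, x0 = ss$state)
  expect_equal(ss2$relaxation_time, 0)
})

test_that("steady states agree across step sizes", {
  net <- iffl_fixture("upward")
  for (dt in c(0.01, 0.005)) {
    p <- grn_dynamics(beta = 40, dt = dt)
    ss <- relax_to_steady_state(net, p, I = 1)
    if (dt == 0.01) ref <- ss$state
    expect_true(ss$converged)
    expect_equal(ss$state, ref, tolerance = 10 * p$ss_tol)
  }
})

test_that("integration matches an independent stiff-solver oracle", {
  net <- iffl_fixture("upward")
  p <- grn_dynamics(beta = 40)
  base <- relax_to_steady_state(net, p, I = 0)
  tr <- integrate_grn(net, p, I = 1, x0 = base$state, duration = 20,
                      record_every = 100L)
  ode_rhs <- function(t, x, parms)
    list(grn_derivative(net, x, p, I = 1))
  ref <- deSolve::ode(y = base$state, times = tr$times, func = ode_rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(tr$states), unname(ref[, -1]), tolerance = 1e-6)
})

test_that("step response reproduces trivial protocols", {
  net <- iffl_fixture("upward")
  p <- fast_dynamics(beta = 40)
  # no perturbation: I0 = I1 leaves the system at baseline
  sr <- step_response(net, p, grn_schedule(I0 = 0, I1 = 0))
  dev <- sweep(sr$trajectory$states, 2, sr$baseline$state)
  expect_lt(max(abs(dev)), 1e-6)
  # canonical step: input trace monotone increasing, target pulses
  sr <- step_response(net, p, grn_schedule())
  input_trace <- sr$trajectory$states[, net$input]
  expect_true(all(diff(input_trace) >= -1e-12))
  target_dev <- sr$trajectory$states[, net$target] -
    sr$baseline$state[net$target]
  expect_gt(max(target_dev), 0.02)                  # transient pulse
  expect_lt(tail(target_dev, 1), 0.5 * max(target_dev))  # returns toward base
})

test_that("a driven negative-feedback ring is flagged oscillatory", {
  # repressilator-style ring 1 -> 2 -> 3 -| 1 under sustained drive; with
  # in-degree scaling each single edge transmits its full signal and the
  # delayed negative feedback sustains a limit cycle
  J <- matrix(0L, 4, 4)
  J[2, 1] <- 1L; J[3, 2] <- 1L; J[1, 3] <- -1L
  net <- grn(J)
  p <- grn_dynamics(beta = 40, t_max = 400,
                    scaling_mode = "inverse-sqrt-indegree")
  ss <- relax_to_steady_state(net, p, I = 1)
  expect_false(ss$converged)
  expect_true(ss$oscillatory)
  expect_true(all(ss$state >= 0 & ss$state <= 1 + p$delta))
})

test_that("trajectory files round-trip through the TSV format", {
  net <- test_net(4, 0.5)
  tr <- integrate_grn(net, fast_dynamics(), 1, rep(0, 4), 5,
                      record_every = 10L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times, tolerance = 1e-8)
  expect_equal(back$states, tr$states, tolerance = 1e-8)
})
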