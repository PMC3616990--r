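#' Dynamics parameters for sigmoidal expression kinetics
#'
#' Parameters of the expression model
#' \deqn{dx_i/dt = \sigma(\beta (z_i - \theta)) - x_i + \delta,}
#' where \eqn{z_i} is the scaled regulatory field of gene *i* (see
#' [regulation_field()]), \eqn{\sigma} is the logistic function,
#' \eqn{\beta} the gain (a Hill-coefficient analogue), \eqn{\theta} the
#' expression threshold, and \eqn{\delta} a small basal (leak) expression.
#' Expression levels live in `[0, 1 + delta]`; time is measured in units of
#' the protein degradation time (the decay term has unit rate).
#'
#' @param beta sigmoid gain (> 0). Larger values sharpen the on/off switch.
#' @param theta expression threshold in (0, 1).
#' @param delta basal leak expression, `0 <= delta < theta`.
#' @param scaling_mode normalizer of the interaction sum: `"inverse-sqrt-N"`
#'   divides by `sqrt(n_genes)`, `"inverse-sqrt-indegree"` by
#'   `sqrt(max(1, in-degree))`, keeping the field comparable to `theta`
#'   regardless of network size.
#' @param dt fixed integration step (4th-order Runge-Kutta).
#' @param t_max cap on relaxation time per phase.
#' @param ss_tol steady-state tolerance on `max |dx/dt|`.
#' @param avg_window duration over which the final state is time-averaged
#'   when the dynamics do not converge to a fixed point.
#' @param osc_tol tolerance for declaring a non-converged run oscillatory
#'   (agreement of two successive `avg_window` means).
#' @return an object of class `grn_dynamics`.
#' @export
grn_dynamics <- function(beta = 10, theta = 0.5, delta = 0.001,
                         scaling_mode = c("inverse-sqrt-N",
                                          "inverse-sqrt-indegree"),
                         dt = 0.01, t_max = 1000, ss_tol = 1e-8,
                         avg_window = 100, osc_tol = 0.01) {
  scaling_mode <- match.arg(scaling_mode)
  stopifnot(beta > 0, theta > 0, theta < 1, delta >= 0, delta < theta,
            dt > 0, t_max > 0, ss_tol > 0, avg_window > 0,
            avg_window < t_max, osc_tol > 0)
  structure(list(beta = beta, theta = theta, delta = delta,
                 scaling_mode = scaling_mode, dt = dt, t_max = t_max,
                 ss_tol = ss_tol, avg_window = avg_window,
                 osc_tol = osc_tol),
            class = "grn_dynamics")
}

#' @export
print.grn_dynamics <- function(x, ...) {
  cat(sprintf(
    "Expression dynamics: beta = %g, theta = %g, delta = %g (%s scaling)\n",
    x$beta, x$theta, x$delta, x$scaling_mode))
  cat(sprintf("  RK4 dt = %g, t_max = %g, ss_tol = %g, avg_window = %g\n",
              x$dt, x$t_max, x$ss_tol, x$avg_window))
  invisible(x)
}

#' Step-input signal schedule
#'
#' The external signal applied to the input gene: level `I0` while the
#' system relaxes to its pre-stimulus steady state, switching to `I1` at
#' time 0. The canonical protocol is a step from no signal (`I0 = 0`) to a
#' saturating signal (`I1 = 1`).
#'
#' @param I0 pre-switch signal level (>= 0).
#' @param I1 post-switch signal level.
#' @export
grn_schedule <- function(I0 = 0, I1 = 1) {
  stopifnot(I0 >= 0)
  structure(list(I0 = I0, I1 = I1), class = "grn_schedule")
}

# per-gene interaction-sum normalizer s_i
scale_vector <- function(net, params) {
  if (params$scaling_mode == "inverse-sqrt-N") {
    rep(sqrt(net$n_genes), net$n_genes)
  } else {
    indeg <- rowSums(net$J != 0L)
    sqrt(pmax(1, indeg))
  }
}

scaled_J <- function(net, params) net$J / scale_vector(net, params)

#' Sigmoidal expression response
#'
#' `sigmoid(z) = 1 / (1 + exp(-beta * (z - theta)))`, the probability-like
#' expression output for a regulatory field `z`. Approaches a step function
#' with threshold `theta` as `beta` grows; the exponent is saturated so the
#' evaluation never overflows.
#'
#' @param z regulatory field (vectorized).
#' @param beta gain (> 0).
#' @param theta threshold.
#' @export
sigmoid <- function(z, beta, theta) {
  a <- pmin(700, pmax(-700, -beta * (z - theta)))
  1 / (1 + exp(a))
}

#' Regulatory field acting on each gene
#'
#' `z[i] = sum_j J[i, j] x[j] / s_i + I * [i == input]`, where `s_i` is the
#' normalizer selected by `params$scaling_mode`.
#'
#' @param net a `grn`.
#' @param x expression vector of length `n_genes`.
#' @param params a [grn_dynamics()] object.
#' @param I current external signal level.
#' @export
regulation_field <- function(net, x, params, I) {
  if (length(x) != net$n_genes)
    stop("state vector has length ", length(x), ", expected ", net$n_genes)
  z <- as.vector(net$J %*% x) / scale_vector(net, params)
  z[net$input] <- z[net$input] + I
  z
}

#' Time derivative of the expression state
#'
#' @inheritParams regulation_field
#' @return `dx/dt`, a numeric vector.
#' @export
grn_derivative <- function(net, x, params, I) {
  z <- regulation_field(net, x, params, I)
  sigmoid(z, params$beta, params$theta) - x + params$delta
}

new_trajectory <- function(times, states) {
  colnames(states) <- paste0("x", seq_len(ncol(states)))
  structure(list(times = times, states = states), class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("Expression trajectory: %d genes, %d time points, t in [%g, %g]\n",
              ncol(x$states), length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
plot.grn_trajectory <- function(x, ..., highlight = NULL) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "expression", ...)
  if (!is.null(highlight))
    graphics::lines(x$times, x$states[, highlight], lwd = 3)
  invisible(x)
}

#' Integrate the expression dynamics at constant signal
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration of the
#' expression ODE for `duration` time units under signal level `I`.
#'
#' @inheritParams regulation_field
#' @param x0 initial expression vector, components in `[0, 1 + delta]`.
#' @param duration integration time (> 0).
#' @param record_every store every k-th step (the initial state is always
#'   stored).
#' @return a `grn_trajectory` with `times` and a time-by-gene `states`
#'   matrix.
#' @export
integrate_grn <- function(net, params, I, x0, duration, record_every = 1L) {
  stopifnot(inherits(net, "grn"), inherits(params, "grn_dynamics"),
            duration > 0, length(x0) == net$n_genes)
  if (any(x0 < 0) || any(x0 > 1 + params$delta))
    stop("x0 components must lie in [0, 1 + delta]")
  n_steps <- ceiling(duration / params$dt)
  st <- cpp_integrate(scaled_J(net, params), x0, net$input - 1L, I,
                      params$beta, params$theta, params$delta, params$dt,
                      n_steps, as.integer(record_every))
  times <- seq(0, by = params$dt * record_every, length.out = nrow(st))
  new_trajectory(times, st)
}

#' Relax to the steady state under a constant signal
#'
#' Integrates until `max |dx/dt| <= ss_tol` or `t_max` is reached. If the
#' trajectory does not converge but its two trailing `avg_window` means
#' agree to `osc_tol`, the run is flagged oscillatory and the window
#' average is returned as the representative state.
#'
#' @inheritParams integrate_grn
#' @return a `grn_steady` object with fields `state`, `converged`,
#'   `oscillatory` and `relaxation_time`.
#' @export
relax_to_steady_state <- function(net, params, I,
                                  x0 = rep(0, net$n_genes)) {
  stopifnot(inherits(net, "grn"), inherits(params, "grn_dynamics"),
            length(x0) == net$n_genes)
  r <- cpp_relax(scaled_J(net, params), x0, net$input - 1L, I, params$beta,
                 params$theta, params$delta, params$dt, params$t_max,
                 params$ss_tol, params$avg_window, params$osc_tol)
  r$state <- as.vector(r$state)
  class(r) <- "grn_steady"
  r
}

#' @export
print.grn_steady <- function(x, ...) {
  cat(sprintf("Steady state (%s%s) after t = %g\n",
              if (x$converged) "converged" else "not converged",
              if (x$oscillatory) ", oscillatory" else "",
              x$relaxation_time))
  print(signif(x$state, 6))
  invisible(x)
}

#' Step-input response protocol
#'
#' The canonical protocol behind every fitness evaluation: all genes start
#' at the off state (or fully on, with `initial_state = "on"`), relax under
#' `I0` to the pre-stimulus baseline, then the signal switches to `I1` at
#' time 0 and the post-switch trajectory is recorded until the new steady
#' state (or `t_max`).
#'
#' @inheritParams integrate_grn
#' @param schedule a [grn_schedule()].
#' @param initial_state `"off"` (all genes at 0, the canonical and hardest
#'   initial condition) or `"on"` (all genes at 1).
#' @return a list of class `grn_step_response` with components `baseline`
#'   (a `grn_steady`) and `trajectory` (the post-switch `grn_trajectory`).
#' @export
step_response <- function(net, params = grn_dynamics(),
                          schedule = grn_schedule(),
                          initial_state = c("off", "on"),
                          record_every = 1L) {
  initial_state <- match.arg(initial_state)
  x0 <- rep(if (initial_state == "on") 1 else 0, net$n_genes)
  baseline <- relax_to_steady_state(net, params, schedule$I0, x0)
  # find the post-switch horizon first (cheap, no recording), then record;
  # a full avg_window of settled dynamics is appended so that steady-state
  # deviations can be read off the stored trajectory
  post <- cpp_relax(scaled_J(net, params), baseline$state, net$input - 1L,
                    schedule$I1, params$beta, params$theta, params$delta,
                    params$dt, params$t_max, params$ss_tol,
                    params$avg_window, params$osc_tol)
  horizon <- if (post$converged)
    post$relaxation_time + params$avg_window else params$t_max
  traj <- integrate_grn(net, params, schedule$I1, baseline$state, horizon,
                        record_every)
  structure(list(baseline = baseline, trajectory = traj,
                 schedule = schedule),
            class = "grn_step_response")
}

#' @export
print.grn_step_response <- function(x, ...) {
  cat(sprintf("Step response (I %g -> %g)\n", x$schedule$I0, x$schedule$I1))
  cat("  baseline: "); print(x$baseline)
  cat("  post-switch: "); print(x$trajectory)
  invisible(x)
}

#' @export
plot.grn_step_response <- function(x, ...) {
  plot(x$trajectory, ...)
  graphics::abline(h = x$baseline$state, col = "grey80", lty = 3)
  invisible(x)
}

#' Read / write a trajectory TSV
#'
#' First column `time`, then `x1..xN`, 9 significant digits.
#'
#' @param traj a `grn_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = signif(traj$times, 9),
                   signif(traj$states, 9))
  names(df) <- c("time", colnames(traj$states))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  new_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]))
}
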