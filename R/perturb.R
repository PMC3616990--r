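#' Fitness under single-edge deletion
#'
#' For every nonzero interaction entry, the edge is removed, the fitness is
#' recomputed under the step-input protocol, and the edge restored; the
#' report gives the mean over all removals. Cooperative networks, in which
#' every gene's adaptation leans on the others, lose more fitness per
#' removed edge than few-gene motif solutions. The input network is never
#' modified.
#'
#' @inheritParams step_response
#' @return an object of class `grn_perturbation` with `original_fitness`,
#'   `mean_fitness_edge_deletion`, `n_edges_removed`, a per-edge
#'   data.frame, and a `zero_edges` flag.
#' @export
edge_deletion_fitness <- function(net, params = grn_dynamics(),
                                  schedule = grn_schedule()) {
  stopifnot(inherits(net, "grn"))
  orig <- network_fitness(net, params, schedule)
  nz <- which(net$J != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    return(structure(list(original_fitness = orig,
                          mean_fitness_edge_deletion = orig,
                          n_edges_removed = 0L, per_edge = NULL,
                          zero_edges = TRUE),
                     class = "grn_perturbation"))
  }
  muts <- vector("list", nrow(nz))
  for (k in seq_len(nrow(nz))) {
    J <- net$J
    J[nz[k, 1], nz[k, 2]] <- 0L
    muts[[k]] <- grn(J, net$input, net$target)
  }
  ev <- evaluate_population(muts, params, schedule)
  per_edge <- data.frame(source = nz[, 2], target = nz[, 1],
                         sign = net$J[nz], fitness = ev$fitness)
  structure(list(original_fitness = orig,
                 mean_fitness_edge_deletion = mean(ev$fitness),
                 n_edges_removed = nrow(nz), per_edge = per_edge,
                 zero_edges = FALSE),
            class = "grn_perturbation")
}

#' @export
print.grn_perturbation <- function(x, ...) {
  cat(sprintf("Single-edge deletion: %d edges\n", x$n_edges_removed))
  cat(sprintf("  original fitness:          %.4f\n", x$original_fitness))
  cat(sprintf("  mean fitness after removal: %.4f\n",
              x$mean_fitness_edge_deletion))
  invisible(x)
}

#' Stochastic expression trajectory (Langevin dynamics)
#'
#' Euler-Maruyama integration of the expression ODE with additive Gaussian
#' white noise of amplitude `sigma` per gene (`sigma * sqrt(dt)` times a
#' standard normal per step); states are clipped to `[0, 1 + delta]` after
#' every step. With `sigma = 0` this is plain deterministic Euler at the
#' same step size. Noise draws consume R's RNG.
#'
#' @inheritParams integrate_grn
#' @param sigma noise amplitude (>= 0).
#' @export
noisy_trajectory <- function(net, params, I, x0, sigma, duration,
                             record_every = 1L) {
  stopifnot(inherits(net, "grn"), sigma >= 0, duration > 0,
            length(x0) == net$n_genes)
  n_steps <- ceiling(duration / params$dt)
  st <- cpp_noisy_integrate(scaled_J(net, params), x0, net$input - 1L, I,
                            params$beta, params$theta, params$delta,
                            params$dt, n_steps, sigma,
                            as.integer(record_every))
  times <- seq(0, by = params$dt * record_every, length.out = nrow(st))
  new_trajectory(times, st)
}

#' Fitness under expression noise
#'
#' Runs the step-input protocol with Langevin dynamics `n_reps` times and
#' returns the mean target adaptiveness and its standard error. Both the
#' pre- and post-switch phases are integrated with noise for fixed
#' durations; the baseline and the final level are time averages over the
#' trailing window of each phase.
#'
#' @inheritParams step_response
#' @param sigma noise amplitude.
#' @param n_reps number of stochastic replicates.
#' @param t_pre,t_post durations of the two phases (time units).
#' @return list with `mean`, `se`, `sigma`, `n_reps`, and the per-replicate
#'   `values` (fitness) and `abar` values.
#' @export
noisy_fitness <- function(net, params = grn_dynamics(),
                          schedule = grn_schedule(), sigma = 0.05,
                          n_reps = 10, t_pre = 100, t_post = 200,
                          initial_state = c("off", "on")) {
  stopifnot(n_reps >= 1, sigma >= 0)
  initial_state <- match.arg(initial_state)
  vals <- matrix(NA_real_, n_reps, 2)
  for (r in seq_len(n_reps))
    vals[r, ] <- noisy_eval(net, params, schedule, sigma, t_pre, t_post,
                            initial_state)
  list(mean = mean(vals[, 1]),
       se = if (n_reps > 1) stats::sd(vals[, 1]) / sqrt(n_reps) else 0,
       mean_abar = mean(vals[, 2]),
       sigma = sigma, n_reps = n_reps,
       values = vals[, 1], abar = vals[, 2])
}

#' Parameter sweeps over evolutionary or dynamical conditions
#'
#' Re-runs [evolve()] across a grid of one parameter and records the final
#' best network's fitness and average adaptiveness per replicate:
#' \describe{
#'   \item{`network_size`}{grid of gene counts `N`.}
#'   \item{`mutation_rate`}{grid of per-entry mutation rates `mu`.}
#'   \item{`noise_level`}{grid of expression-noise amplitudes `sigma`
#'     applied during evolution; the recorded fitness and adaptiveness are
#'     re-measured without noise.}
#'   \item{`gain`}{grid of sigmoid gains `beta`.}
#'   \item{`input_level`}{re-evaluates already-evolved `networks` across an
#'     `(I0, I1)` grid without re-evolving; `grid` is a data.frame or
#'     2-column matrix of `(I0, I1)` pairs.}
#' }
#' Each (grid value, replicate) cell runs with its own recorded seed, so
#' any cell can be recomputed independently.
#'
#' @param kind one of `"network_size"`, `"mutation_rate"`, `"noise_level"`,
#'   `"gain"`, `"input_level"`.
#' @param grid numeric vector of parameter values (or `(I0, I1)` pairs for
#'   `input_level`).
#' @param replicates evolution replicates per grid value.
#' @param n_genes network size for kinds that do not sweep it.
#' @param config an [evolution_config()].
#' @param params a [grn_dynamics()].
#' @param schedule a [grn_schedule()].
#' @param seed base seed; cell seeds are derived deterministically.
#' @param networks list of `grn` objects (for `input_level` only).
#' @return an object of class `grn_sweep`: data.frame with one row per
#'   (value, replicate): `kind`, `value`, `replicate`, `seed`, `fitness`,
#'   `abar`.
#' @export
parameter_sweep <- function(kind = c("network_size", "mutation_rate",
                                     "noise_level", "gain", "input_level"),
                            grid, replicates = 1, n_genes = 20,
                            config = evolution_config(),
                            params = grn_dynamics(),
                            schedule = grn_schedule(), seed = 1,
                            networks = NULL) {
  kind <- match.arg(kind)
  stopifnot(replicates >= 1)
  if (kind == "input_level") {
    if (is.null(networks))
      stop("input_level sweeps evaluate already-evolved networks; ",
           "supply `networks`")
    grid <- as.matrix(grid)
    stopifnot(ncol(grid) == 2)
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      sch <- grn_schedule(I0 = grid[g, 1], I1 = grid[g, 2])
      for (k in seq_along(networks)) {
        resp <- grn_response(networks[[k]], params, sch)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, value = paste0(grid[g, 1], "->", grid[g, 2]),
          I0 = grid[g, 1], I1 = grid[g, 2], replicate = k, seed = NA_integer_,
          fitness = resp$fitness, abar = resp$avg_adaptiveness)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("grn_sweep", "data.frame")
    return(out)
  }
  stopifnot(length(grid) >= 1)
  rows <- list()
  for (g in seq_along(grid)) {
    for (r in seq_len(replicates)) {
      cell_seed <- (seed + 7919L * (g - 1L) + 104729L * (r - 1L)) %% .Machine$integer.max
      val <- grid[g]
      cfg <- config; prm <- params; ng <- n_genes; sg <- 0
      if (kind == "network_size") ng <- as.integer(val)
      if (kind == "mutation_rate")
        cfg <- utils::modifyList(config, list(mu = val))
      if (kind == "gain") prm$beta <- val
      if (kind == "noise_level") sg <- val
      run <- evolve(ng, structure(cfg, class = "evolution_config"), prm,
                    schedule, seed = cell_seed, sigma = sg,
                    record_networks = "none")
      best <- run$final_best
      # report noise-free performance of the evolved network
      resp <- grn_response(best, prm, schedule)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, value = val, replicate = r, seed = cell_seed,
        fitness = resp$fitness, abar = resp$avg_adaptiveness)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grn_sweep", "data.frame")
  out
}

#' @export
print.grn_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): %d cells\n", x$kind[1], nrow(x)))
  agg <- stats::aggregate(cbind(fitness, abar) ~ value, data = x, FUN = median)
  print(agg, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.grn_sweep <- function(x, ...) {
  v <- if (is.numeric(x$value)) x$value else seq_along(unique(x$value))
  graphics::plot(v, x$fitness, col = "steelblue", pch = 8, log = "",
                 xlab = x$kind[1], ylab = "fitness / Abar",
                 ylim = c(0, 1.05), ...)
  graphics::points(v, x$abar, col = "firebrick", pch = 3)
  graphics::legend("topright", bty = "n", pch = c(8, 3),
                   col = c("steelblue", "firebrick"),
                   legend = c("fitness", "average adaptiveness"))
  invisible(x)
}
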