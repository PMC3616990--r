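#' Genetic-algorithm configuration
#'
#' The selection scheme: each generation, `M` networks are evaluated, the
#' `Ms` fittest are kept, and each survivor produces `M/Ms` mutants that
#' constitute the next generation (the survivors themselves are not copied
#' forward, so there is no elitism). Mutation flips each mutable matrix
#' entry with probability `mu` to one of the other two ternary values.
#' With `selection_noise > 0`, each survivor slot is instead filled by a
#' uniformly random non-survivor with that probability, modelling noisy
#' selection.
#'
#' @param M population size.
#' @param Ms number of survivors per generation; must divide `M`.
#' @param mu per-entry mutation probability per generation.
#' @param n_generations number of generations to run.
#' @param selection_noise probability in `[0, 1)` that a survivor slot is
#'   filled by a random non-survivor.
#' @param init_density nonzero probability for entries of the initial
#'   random population.
#' @export
evolution_config <- function(M = 100, Ms = 10, mu = 0.003,
                             n_generations = 1000, selection_noise = 0,
                             init_density = 0.3) {
  stopifnot(Ms >= 1, Ms <= M, M %% Ms == 0, mu >= 0, mu <= 1,
            n_generations >= 1, selection_noise >= 0, selection_noise < 1,
            init_density >= 0, init_density <= 1)
  structure(list(M = M, Ms = Ms, mu = mu, n_generations = n_generations,
                 selection_noise = selection_noise,
                 init_density = init_density),
            class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf(
    "GA config: M = %d, Ms = %d, mu = %g, %d generations%s, init density %g\n",
    x$M, x$Ms, x$mu, x$n_generations,
    if (x$selection_noise > 0)
      sprintf(", selection noise %g", x$selection_noise) else "",
    x$init_density))
  invisible(x)
}

#' Select surviving parents by fitness
#'
#' With no selection noise, returns the indices of the `Ms` largest fitness
#' values, ties broken in favour of the lower index. With selection noise
#' `p`, each survivor slot is independently replaced with probability `p`
#' by a uniform random index not already selected.
#'
#' @param fitness numeric vector of population fitnesses.
#' @param Ms number of survivors.
#' @param selection_noise per-slot replacement probability.
#' @return integer vector of `Ms` distinct indices.
#' @export
select_parents <- function(fitness, Ms, selection_noise = 0) {
  stopifnot(Ms <= length(fitness))
  surv <- order(fitness, decreasing = TRUE)[seq_len(Ms)]
  if (selection_noise > 0) {
    for (k in seq_len(Ms)) {
      if (stats::runif(1) < selection_noise) {
        pool <- setdiff(seq_along(fitness), surv)
        if (length(pool)) surv[k] <- pool[sample.int(length(pool), 1)]
      }
    }
  }
  surv
}

#' Produce the next generation from the selected parents
#'
#' Each parent yields exactly `M / length(parents)` mutants via
#' [mutate_grn()]; the parents themselves are not carried over unmutated.
#'
#' @param parents list of `grn` objects.
#' @param M population size; must be a multiple of `length(parents)`.
#' @param mu per-entry mutation probability.
#' @return list of `M` networks.
#' @export
next_generation <- function(parents, M, mu) {
  stopifnot(M %% length(parents) == 0)
  per <- M %/% length(parents)
  out <- vector("list", M)
  k <- 0L
  for (p in parents)
    for (i in seq_len(per)) {
      k <- k + 1L
      out[[k]] <- mutate_grn(p, mu)
    }
  out
}

# evaluate a list of networks, memoising deterministic evaluations by the
# matrix contents (mutants frequently coincide with their parent when mu is
# small, and survivors recur across generations)
evaluate_population <- function(nets, params, schedule, cache = NULL,
                                sigma = 0, noise_t_pre = 100,
                                noise_t_post = 200, initial_state = "off") {
  M <- length(nets)
  fitness <- numeric(M); abar <- numeric(M)
  if (sigma > 0) {
    # stochastic evaluations cannot be cached
    for (m in seq_len(M)) {
      v <- noisy_eval(nets[[m]], params, schedule, sigma,
                      noise_t_pre, noise_t_post, initial_state)
      fitness[m] <- v[1]; abar[m] <- v[2]
    }
    return(list(fitness = fitness, abar = abar))
  }
  keys <- vapply(nets, function(nt) rawToChar(as.raw(nt$J + 49L)), "")
  todo <- logical(M)
  for (m in seq_len(M)) {
    hit <- if (is.null(cache)) NULL else cache[[keys[m]]]
    if (is.null(hit)) todo[m] <- TRUE
    else { fitness[m] <- hit[1]; abar[m] <- hit[2] }
  }
  if (any(todo)) {
    im <- which(todo)
    res <- cpp_evaluate_population(
      lapply(nets[im], `[[`, "J"),
      nets[[1]]$input - 1L, nets[[1]]$target - 1L,
      schedule$I0, schedule$I1, params$beta, params$theta, params$delta,
      params$dt, params$t_max, params$ss_tol, params$avg_window,
      params$osc_tol, params$scaling_mode == "inverse-sqrt-indegree",
      initial_state == "on")
    fitness[im] <- res$fitness; abar[im] <- res$abar
    if (!is.null(cache))
      for (k in seq_along(im))
        cache[[keys[im[k]]]] <- c(res$fitness[k], res$abar[k])
  }
  list(fitness = fitness, abar = abar)
}

noisy_eval <- function(net, params, schedule, sigma, t_pre, t_post,
                       initial_state) {
  x0 <- rep(if (initial_state == "on") 1 else 0, net$n_genes)
  w <- min(params$avg_window, t_pre / 2, t_post / 2)
  r <- cpp_noisy_response(scaled_J(net, params), x0, net$input - 1L,
                          schedule$I0, schedule$I1, params$beta,
                          params$theta, params$delta, params$dt,
                          t_pre, t_post, w, sigma)
  f <- as.vector(r$dmax) - as.vector(r$dstat)
  c(f[net$target],
    average_adaptiveness(f, net$input, net$target))
}

#' Evolve regulatory networks for a single-target adaptive response
#'
#' The central fitting routine. A population of random ternary networks is
#' evolved by truncation selection on the target gene's adaptiveness
#' (response peak minus steady-state shift under the step-input protocol).
#' Selection for the adaptation of this one gene is the only pressure;
#' cooperative adaptation of the remaining genes, when the network is large
#' enough, emerges on its own and is tracked via the average adaptiveness.
#'
#' All randomness (initial population, mutation, selection noise,
#' expression noise) consumes R's RNG in a fixed order, so a given `seed`
#' reproduces the run bit for bit.
#'
#' @param n_genes number of genes per network.
#' @param config an [evolution_config()].
#' @param params a [grn_dynamics()].
#' @param schedule a [grn_schedule()].
#' @param seed integer RNG seed, or `NULL` to continue the current stream.
#' @param sigma expression-noise amplitude during fitness evaluation
#'   (0 = deterministic dynamics; > 0 evolves under a Langevin equation).
#' @param record_networks `"best"` stores the fittest network of every
#'   generation, `"none"` only the final best.
#' @param initial_state initial expression state for the protocol, see
#'   [step_response()].
#' @param verbose print per-generation progress.
#' @return an object of class `grn_evolution` with `history` (data.frame of
#'   per-generation summaries), `fitness` and `abar` (generation-by-member
#'   matrices), `best_networks`, `final_best` (a `grn`), the config echo
#'   and the seed.
#' @examples
#' \donttest{
#' run <- evolve(8, evolution_config(M = 20, Ms = 4, n_generations = 20),
#'               seed = 1)
#' summary(run)
#' }
#' @export
evolve <- function(n_genes, config = evolution_config(),
                   params = grn_dynamics(), schedule = grn_schedule(),
                   seed = NULL, sigma = 0,
                   record_networks = c("best", "none"),
                   initial_state = c("off", "on"), verbose = FALSE) {
  stopifnot(inherits(config, "evolution_config"),
            inherits(params, "grn_dynamics"))
  record_networks <- match.arg(record_networks)
  initial_state <- match.arg(initial_state)
  if (!is.null(seed)) set.seed(seed)
  M <- config$M; Ms <- config$Ms; G <- config$n_generations
  pop <- replicate(M, random_grn(n_genes, config$init_density),
                   simplify = FALSE)
  cache <- new.env(parent = emptyenv())
  fit_mat <- matrix(NA_real_, G, M)
  abar_mat <- matrix(NA_real_, G, M)
  best_nets <- if (record_networks == "best") vector("list", G) else NULL
  hist <- data.frame(generation = seq_len(G), best_fitness = NA_real_,
                     best_abar = NA_real_, mean_fitness = NA_real_,
                     mean_abar = NA_real_)
  final_best <- NULL
  for (g in seq_len(G)) {
    ev <- evaluate_population(pop, params, schedule, cache, sigma = sigma,
                              initial_state = initial_state)
    fit_mat[g, ] <- ev$fitness
    abar_mat[g, ] <- ev$abar
    top <- which.max(ev$fitness)
    hist$best_fitness[g] <- ev$fitness[top]
    hist$best_abar[g] <- ev$abar[top]
    hist$mean_fitness[g] <- mean(ev$fitness)
    hist$mean_abar[g] <- mean(ev$abar)
    if (!is.null(best_nets)) best_nets[[g]] <- pop[[top]]
    final_best <- pop[[top]]
    if (verbose)
      message(sprintf("generation %d: best fitness %.4f, best Abar %.4f",
                      g, ev$fitness[top], ev$abar[top]))
    if (g < G) {
      surv <- select_parents(ev$fitness, Ms, config$selection_noise)
      pop <- next_generation(pop[surv], M, config$mu)
    }
  }
  structure(list(history = hist, fitness = fit_mat, abar = abar_mat,
                 best_networks = best_nets, final_best = final_best,
                 n_genes = n_genes, config = config, params = params,
                 schedule = schedule, seed = seed, sigma = sigma,
                 initial_state = initial_state),
            class = "grn_evolution")
}

#' @export
print.grn_evolution <- function(x, ...) {
  G <- nrow(x$history)
  cat(sprintf("Evolved %d networks of %d genes for %d generations\n",
              x$config$M, x$n_genes, G))
  cat(sprintf("  final best fitness:       %.4f\n", x$history$best_fitness[G]))
  cat(sprintf("  final best adaptiveness:  %.4f\n", x$history$best_abar[G]))
  invisible(x)
}

#' @export
summary.grn_evolution <- function(object, ...) {
  print(object)
  G <- nrow(object$history)
  picks <- unique(pmax(1, round(c(1, G / 4, G / 2, 3 * G / 4, G))))
  cat("\nTrajectory of the generation best:\n")
  print(object$history[picks, ], row.names = FALSE, digits = 4)
  cat("\nFinal best network:\n")
  print(object$final_best)
  invisible(object)
}

#' @export
plot.grn_evolution <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best_fitness, type = "l", log = "x",
                 ylim = c(0, 1.05), xlab = "generation",
                 ylab = "fitness / average adaptiveness", col = "steelblue",
                 ...)
  graphics::lines(h$generation, h$best_abar, col = "firebrick")
  graphics::lines(h$generation, h$mean_fitness, col = "steelblue", lty = 3)
  graphics::lines(h$generation, h$mean_abar, col = "firebrick", lty = 3)
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 3, 3),
                   col = c("steelblue", "firebrick", "steelblue", "firebrick"),
                   legend = c("best fitness", "best Abar", "mean fitness",
                              "mean Abar"))
  invisible(x)
}

#' @export
coef.grn_evolution <- function(object, ...) object$final_best$J

#' Best network of an evolution run
#'
#' @param run a `grn_evolution` object.
#' @param generation generation to take the best network from (default:
#'   last). Requires `record_networks = "best"` for generations before the
#'   last.
#' @export
best_network <- function(run, generation = NULL) {
  stopifnot(inherits(run, "grn_evolution"))
  if (is.null(generation)) return(run$final_best)
  if (is.null(run$best_networks))
    stop("per-generation networks were not recorded")
  run$best_networks[[generation]]
}

#' Write an evolution run record as JSON lines
#'
#' One JSON object per generation (index, best/mean fitness and average
#' adaptiveness, optionally the full population arrays down-sampled by
#' `stride`), preceded by a config echo object. The final best network is
#' written alongside in the network TSV format.
#'
#' @param run a `grn_evolution`.
#' @param path output `.jsonl` path.
#' @param stride keep every `stride`-th generation's full population
#'   arrays (0 = summaries only).
#' @export
write_run_record <- function(run, path, stride = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  echo <- list(record = "config", n_genes = run$n_genes,
               config = unclass(run$config),
               params = unclass(run$params),
               schedule = unclass(run$schedule),
               sigma = run$sigma, seed = run$seed)
  writeLines(jsonlite::toJSON(echo, auto_unbox = TRUE, digits = NA), con)
  for (g in seq_len(nrow(run$history))) {
    rec <- as.list(run$history[g, ])
    if (stride > 0 && g %% stride == 0) {
      rec$fitness_values <- run$fitness[g, ]
      rec$adaptiveness_values <- run$abar[g, ]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  write_grn(run$final_best, paste0(sub("\\.jsonl?$", "", path),
                                   "_best_network.tsv"))
  invisible(path)
}
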