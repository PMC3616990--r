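#' Per-gene adaptive-response metrics
#'
#' For each gene the post-switch trajectory is reduced to three numbers:
#' `delta_max`, the maximum absolute deviation from baseline; `delta_stat`,
#' the absolute deviation of the time-averaged final state (mean over the
#' trailing `avg_window`) from baseline; and the adaptiveness
#' `f = delta_max - delta_stat`. A perfectly adapting gene has a large
#' transient (`delta_max`) but returns exactly to baseline
#' (`delta_stat = 0`); a monotone response has `delta_max = delta_stat`
#' and hence `f = 0`.
#'
#' @param baseline pre-switch steady-state expression vector.
#' @param traj a `grn_trajectory` covering at least `avg_window` of settled
#'   dynamics at its end.
#' @param avg_window duration of the final time average.
#' @return a data.frame with one row per gene: `gene`, `delta_max`,
#'   `delta_stat`, `f`, `direction` (`"upward"`/`"downward"`, from the sign
#'   of the deviation at the time of maximum), and `partial_ratio`
#'   (`delta_stat/delta_max`, 0 for perfect adaptation, `NA` with no
#'   response).
#' @export
gene_response_metrics <- function(baseline, traj, avg_window) {
  stopifnot(inherits(traj, "grn_trajectory"),
            length(baseline) == ncol(traj$states))
  times <- traj$times
  span <- times[length(times)] - times[1]
  if (span < avg_window)
    stop("trajectory spans ", span, " time units, shorter than avg_window = ",
         avg_window)
  dev <- sweep(traj$states, 2, baseline)
  adev <- abs(dev)
  at_max <- apply(adev, 2, which.max)
  delta_max <- adev[cbind(at_max, seq_along(baseline))]
  in_win <- times >= times[length(times)] - avg_window
  delta_stat <- abs(colMeans(traj$states[in_win, , drop = FALSE]) - baseline)
  f <- delta_max - delta_stat
  dirsign <- dev[cbind(at_max, seq_along(baseline))]
  data.frame(
    gene = seq_along(baseline),
    delta_max = delta_max,
    delta_stat = delta_stat,
    f = f,
    direction = ifelse(dirsign >= 0, "upward", "downward"),
    partial_ratio = ifelse(delta_max > 0, delta_stat / delta_max, NA_real_))
}

#' Classify a gene's response
#'
#' `none` if the gene barely responds (`delta_max < eps_resp`); otherwise
#' `adaptive` if the adaptiveness `f` reaches `eps_adapt`, else
#' `monotonic`. The thresholds are reported alongside any classification.
#'
#' @param delta_max maximum absolute deviation (vectorized).
#' @param f adaptiveness (vectorized).
#' @param eps_resp response threshold in (0, 1).
#' @param eps_adapt adaptiveness threshold in (0, 1).
#' @return character vector in `{"none", "monotonic", "adaptive"}`.
#' @export
classify_response <- function(delta_max, f, eps_resp = 0.1,
                              eps_adapt = 0.05) {
  stopifnot(eps_resp > 0, eps_resp < 1, eps_adapt > 0, eps_adapt < 1)
  ifelse(delta_max < eps_resp, "none",
         ifelse(f >= eps_adapt, "adaptive", "monotonic"))
}

#' Average adaptiveness over non-terminal genes
#'
#' The arithmetic mean of per-gene adaptiveness `f` over all genes except
#' the input and the target. The input gene is excluded because it always
#' responds monotonically to the signal; the target because selection
#' forces its adaptation. A value near 1 marks a cooperative adaptive
#' response in which essentially every gene adapts.
#'
#' @param f numeric vector of per-gene adaptiveness.
#' @param input,target indices excluded from the mean.
#' @export
average_adaptiveness <- function(f, input, target) {
  mean(f[-c(input, target)])
}

#' Target-activating and target-inhibiting groups
#'
#' Gene `j` is `activating` if it has a `+1` edge directly into the target,
#' `inhibiting` for `-1`, and `neutral` with no direct edge. The input and
#' target genes are labeled by their roles. In evolved cooperative
#' networks the non-terminal genes split almost completely into the
#' activating and inhibiting groups.
#'
#' @param net a `grn`.
#' @return character vector of length `n_genes`.
#' @export
assign_target_groups <- function(net) {
  sgn <- net$J[net$target, ]
  grp <- ifelse(sgn > 0, "activating", ifelse(sgn < 0, "inhibiting",
                                              "neutral"))
  grp[net$input] <- "input"
  grp[net$target] <- "target"
  grp
}

#' Fitness of a network under the step-input protocol
#'
#' Runs the canonical step response and returns the adaptiveness
#' `f = delta_max - delta_stat` of the target gene, the quantity the
#' genetic algorithm selects on. Bounded by `1 + delta`.
#'
#' @inheritParams step_response
#' @export
network_fitness <- function(net, params = grn_dynamics(),
                            schedule = grn_schedule(),
                            initial_state = c("off", "on")) {
  grn_response(net, params, schedule, initial_state = initial_state)$fitness
}

#' Full adaptive-response summary of a network
#'
#' Runs the step-input protocol (without storing the trajectory) and
#' returns per-gene response metrics, the target fitness, the average
#' adaptiveness over non-terminal genes, response classes and target
#' groups.
#'
#' @inheritParams step_response
#' @param eps_resp,eps_adapt classification thresholds, see
#'   [classify_response()].
#' @return an object of class `grn_response`: a list with `per_gene` (a
#'   data.frame), `fitness`, `avg_adaptiveness`, `baseline`,
#'   `base_converged`, `post_converged`, `post_oscillatory` and the
#'   thresholds used.
#' @export
grn_response <- function(net, params = grn_dynamics(),
                         schedule = grn_schedule(),
                         eps_resp = 0.1, eps_adapt = 0.05,
                         initial_state = c("off", "on")) {
  stopifnot(inherits(net, "grn"), inherits(params, "grn_dynamics"))
  initial_state <- match.arg(initial_state)
  x0 <- rep(if (initial_state == "on") 1 else 0, net$n_genes)
  r <- cpp_response(scaled_J(net, params), x0, net$input - 1L,
                    schedule$I0, schedule$I1, params$beta, params$theta,
                    params$delta, params$dt, params$t_max, params$ss_tol,
                    params$avg_window, params$osc_tol)
  dmax <- as.vector(r$dmax); dstat <- as.vector(r$dstat)
  f <- dmax - dstat
  per_gene <- data.frame(
    gene = seq_len(net$n_genes),
    group = assign_target_groups(net),
    delta_max = dmax, delta_stat = dstat, f = f,
    direction = ifelse(as.vector(r$direction) >= 0, "upward", "downward"),
    class = classify_response(dmax, f, eps_resp, eps_adapt),
    partial_ratio = ifelse(dmax > 0, dstat / dmax, NA_real_))
  structure(list(
    per_gene = per_gene,
    fitness = f[net$target],
    avg_adaptiveness = average_adaptiveness(f, net$input, net$target),
    baseline = as.vector(r$baseline),
    base_converged = r$base_converged,
    post_converged = r$post_converged,
    post_oscillatory = r$post_oscillatory,
    eps_resp = eps_resp, eps_adapt = eps_adapt,
    schedule = schedule),
    class = "grn_response")
}

#' @export
print.grn_response <- function(x, ...) {
  cat(sprintf("Adaptive response summary (I %g -> %g)\n",
              x$schedule$I0, x$schedule$I1))
  cat(sprintf("  target fitness:       %.4f\n", x$fitness))
  cat(sprintf("  average adaptiveness: %.4f\n", x$avg_adaptiveness))
  tab <- table(factor(x$per_gene$class,
                      levels = c("adaptive", "monotonic", "none")))
  cat("  response classes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  if (!x$base_converged)
    cat("  WARNING: pre-stimulus baseline did not converge\n")
  if (x$post_oscillatory)
    cat("  note: post-switch dynamics oscillatory; final state time-averaged\n")
  invisible(x)
}

#' @export
summary.grn_response <- function(object, ...) {
  print(object)
  cat("\nPer-gene metrics:\n")
  print(object$per_gene, digits = 4, row.names = FALSE)
  invisible(object)
}

#' Write a response report (TSV + JSON summary)
#'
#' One TSV row per gene (index, group, delta_max, delta_stat, f, direction,
#' class, partial_ratio) and a JSON sidecar with the fitness, average
#' adaptiveness, class counts and classification thresholds.
#'
#' @param resp a `grn_response`.
#' @param path output TSV path; the JSON summary is written next to it with
#'   extension `.json`.
#' @export
write_response_report <- function(resp, path) {
  utils::write.table(resp$per_gene, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- table(resp$per_gene$class)
  js <- list(fitness = resp$fitness,
             avg_adaptiveness = resp$avg_adaptiveness,
             class_counts = as.list(tab),
             eps_resp = resp$eps_resp, eps_adapt = resp$eps_adapt,
             base_converged = resp$base_converged,
             post_oscillatory = resp$post_oscillatory)
  jsonlite::write_json(js, paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
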