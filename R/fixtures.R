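#' Three-gene incoherent feed-forward loop fixtures
#'
#' Reference networks for the two minimal adaptive sign patterns on
#' (input, middle, target): `"upward"` has input->middle `+`,
#' middle->target `-`, input->target `+` (the receiver pulses up, then the
#' delayed inhibition pulls it back); `"downward"` has input->middle `+`,
#' middle->target `+`, input->target `-` (direct inhibition, delayed
#' activation). No other edges.
#'
#' @param variant `"upward"` or `"downward"`.
#' @return a 3-gene `grn` (input gene 1, target gene 3).
#' @export
iffl_fixture <- function(variant = c("upward", "downward")) {
  variant <- match.arg(variant)
  J <- matrix(0L, 3, 3)
  J[2, 1] <- 1L  # input -> middle
  if (variant == "upward") {
    J[3, 2] <- -1L; J[3, 1] <- 1L
  } else {
    J[3, 2] <- 1L; J[3, 1] <- -1L
  }
  grn(J, input = 1L, target = 3L)
}

#' Two-group cooperative network construction
#'
#' Builds the idealized structure evolved cooperative networks converge
#' to: a target-activating group and a target-inhibiting group in which
#' genes within a group activate each other, genes across groups inhibit
#' each other, the activating group feeds the target with `+1` and the
#' inhibiting group with `-1`, and the input excites the activating group.
#'
#' @param n_act,n_inh group sizes (>= 1).
#' @param density probability of keeping each inter-gene group edge (1 =
#'   dense construction, deterministic; < 1 sparsifies using R's RNG).
#' @return a `grn` of `n_act + n_inh + 2` genes (input first, target
#'   last).
#' @export
two_group_network <- function(n_act, n_inh, density = 1) {
  stopifnot(n_act >= 1, n_inh >= 1, density > 0, density <= 1)
  n <- n_act + n_inh + 2L
  act <- seq(2L, 1L + n_act)
  inh <- seq(2L + n_act, 1L + n_act + n_inh)
  J <- matrix(0L, n, n)
  for (i in act) for (j in act) if (i != j) J[i, j] <- 1L
  for (i in inh) for (j in inh) if (i != j) J[i, j] <- 1L
  for (i in act) for (j in inh) { J[i, j] <- -1L; J[j, i] <- -1L }
  J[act, 1L] <- 1L              # input excites the activating group
  J[n, act] <- 1L               # activating group -> target
  J[n, inh] <- -1L              # inhibiting group -| target
  if (density < 1) {
    amon <- c(act, inh)
    for (i in amon) for (j in amon)
      if (i != j && J[i, j] != 0L && stats::runif(1) > density)
        J[i, j] <- 0L
  }
  grn(J, input = 1L, target = n)
}

#' Exhaustively enumerate small networks
#'
#' Yields every admissible ternary interaction matrix for `n_genes` genes
#' exactly once, in lexicographic order of the mutable entries counted in
#' base 3 (`0, +1, -1` for digit values 0, 1, 2), starting from the zero
#' matrix. The target's outgoing column is fixed at zero; self-loops are
#' excluded by default, giving `3^(n^2 - n - (n-1))` networks (81 for
#' `n = 3`).
#'
#' @param n_genes network size (kept small; see `max_networks`).
#' @param self_loops include diagonal entries in the enumeration universe.
#' @param max_networks guard against unintentionally huge enumerations.
#' @return a list of `grn` objects with attributes `n_mutable` and
#'   `universe_size`.
#' @export
enumerate_networks <- function(n_genes, self_loops = FALSE,
                               max_networks = 200000) {
  net0 <- grn(matrix(0L, n_genes, n_genes))
  idx <- mutable_entries(net0, self_loops = self_loops)
  count <- 3^length(idx)
  if (count > max_networks)
    stop("enumeration universe has ", count, " networks, above the guard of ",
         max_networks)
  digit_to_sign <- c(0L, 1L, -1L)
  out <- vector("list", count)
  for (k in seq_len(count)) {
    code <- k - 1L
    J <- matrix(0L, n_genes, n_genes)
    for (d in seq_along(idx)) {
      J[idx[d]] <- digit_to_sign[code %% 3L + 1L]
      code <- code %/% 3L
    }
    out[[k]] <- grn(J, net0$input, net0$target)
  }
  attr(out, "n_mutable") <- length(idx)
  attr(out, "universe_size") <- count
  out
}

#' Exhaustive fitness search over small networks
#'
#' Evaluates every enumerated network under the step-input protocol and
#' returns fitness and average adaptiveness per network, the basis for
#' identifying the highest-fitness small topologies and their motif
#' content.
#'
#' @inheritParams enumerate_networks
#' @param params a [grn_dynamics()]; high gain (large `beta`) sharpens the
#'   distinction between adapting and non-adapting topologies.
#' @param schedule a [grn_schedule()].
#' @return data.frame with `index`, `fitness`, `abar`; the enumerated
#'   networks are attached as attribute `networks`.
#' @export
exhaustive_search <- function(n_genes, params = grn_dynamics(beta = 40),
                              schedule = grn_schedule(),
                              self_loops = FALSE, max_networks = 200000) {
  nets <- enumerate_networks(n_genes, self_loops, max_networks)
  ev <- evaluate_population(nets, params, schedule)
  out <- data.frame(index = seq_along(nets), fitness = ev$fitness,
                    abar = ev$abar)
  attr(out, "networks") <- nets
  out
}
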