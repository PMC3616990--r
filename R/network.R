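#' Ternary signed gene regulatory network
#'
#' Constructs a regulatory network of `n_genes` genes from a ternary signed
#' interaction matrix. Entry `J[i, j]` encodes regulation FROM gene `j` TO
#' gene `i`: `+1` excitatory, `-1` inhibitory, `0` absent. One gene receives
#' the external signal (the input gene) and one gene defines fitness (the
#' target gene). Outgoing regulation from the target is prohibited, so the
#' target's adaptive response cannot feed back into the rest of the network.
#'
#' Genes are indexed 1..n. By convention the input gene is gene 1 and the
#' target gene is gene n; both are configurable.
#'
#' @param J integer matrix with entries in `{-1, 0, 1}`.
#' @param input index of the gene receiving the external signal.
#' @param target index of the gene whose response defines fitness.
#' @return an object of class `grn`.
#' @examples
#' net <- iffl_fixture("upward")
#' print(net)
#' @export
grn <- function(J, input = 1L, target = nrow(J)) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square")
  n <- nrow(J)
  if (n < 3L) stop("a regulatory network needs at least 3 genes")
  if (!all(J %in% c(-1L, 0L, 1L)))
    stop("all interaction entries must be -1, 0 or +1")
  input <- as.integer(input); target <- as.integer(target)
  if (input < 1L || input > n || target < 1L || target > n)
    stop("input/target index out of range")
  if (input == target) stop("input and target genes must differ")
  if (any(J[, target] != 0L))
    stop("no outgoing regulation from the target gene is allowed ",
         "(column ", target, " of J must be zero)")
  storage.mode(J) <- "integer"
  dimnames(J) <- NULL
  structure(list(n_genes = n, J = J, input = input, target = target),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  ne <- sum(x$J != 0L)
  cat(sprintf("Gene regulatory network: %d genes, %d signed edges\n",
              x$n_genes, ne))
  cat(sprintf("  input gene: %d, target gene: %d\n", x$input, x$target))
  cat(sprintf("  edge density over mutable entries: %.3f\n",
              ne / length(mutable_entries(x))))
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  grp <- assign_target_groups(object)
  cat(sprintf("Network of %d genes (input %d, target %d)\n",
              object$n_genes, object$input, object$target))
  cat(sprintf("  excitatory edges: %d, inhibitory edges: %d\n",
              sum(object$J == 1L), sum(object$J == -1L)))
  cat("  target groups: ",
      paste(sprintf("%s=%d", names(table(grp)), table(grp)), collapse = ", "),
      "\n", sep = "")
  invisible(object)
}

# linear indices of matrix entries the mutation operator may touch:
# everything except the target's outgoing column (and optionally the
# diagonal, for the exhaustive enumeration universe)
mutable_entries <- function(net, self_loops = TRUE) {
  n <- net$n_genes
  idx <- matrix(seq_len(n * n), n, n)
  keep <- col(idx) != net$target
  if (!self_loops) keep <- keep & (row(idx) != col(idx))
  idx[keep]
}

#' Random regulatory network
#'
#' Each mutable entry (all entries outside the target's outgoing column) is
#' nonzero with probability `init_density`, with sign +1 or -1 equiprobably.
#' Draws consume R's RNG; use [set.seed()] for reproducibility.
#'
#' @param n_genes number of genes (>= 3).
#' @param init_density probability that a mutable entry is nonzero.
#' @inheritParams grn
#' @return a `grn` object.
#' @export
random_grn <- function(n_genes, init_density = 0.3, input = 1L,
                       target = n_genes) {
  stopifnot(init_density >= 0, init_density <= 1)
  J <- matrix(0L, n_genes, n_genes)
  net <- grn(J, input, target)
  idx <- mutable_entries(net)
  on <- idx[stats::runif(length(idx)) < init_density]
  J[on] <- ifelse(stats::runif(length(on)) < 0.5, -1L, 1L)
  grn(J, input, target)
}

#' Mutate a network's interaction matrix
#'
#' Each mutable entry is independently selected with probability `mu`; a
#' selected entry is replaced by one of the other two values of
#' `{-1, 0, +1}`, equiprobably. The target's outgoing column is never
#' touched and the original network is unmodified.
#'
#' @param net a `grn` object.
#' @param mu per-entry mutation probability.
#' @return a new `grn` object.
#' @export
mutate_grn <- function(net, mu) {
  stopifnot(inherits(net, "grn"), mu >= 0, mu <= 1)
  J <- net$J
  idx <- mutable_entries(net)
  hit <- idx[stats::runif(length(idx)) < mu]
  if (length(hit)) {
    old <- J[hit]
    # the two alternatives to v in {-1,0,1} are the other residues mod 3
    shift <- ifelse(stats::runif(length(hit)) < 0.5, 1L, 2L)
    J[hit] <- ((old + 1L + shift) %% 3L) - 1L
  }
  grn(J, net$input, net$target)
}

#' Read / write a network edge-list file
#'
#' The plain-text format is a TSV with a header block of `#key<TAB>value`
#' lines (`n_genes`, `input`, `target`; all gene indices 1-based) followed
#' by a `source<TAB>target<TAB>sign` column header and one row per edge,
#' with `sign` in `{-1, +1}`. The writer emits rows sorted by (source,
#' target); the reader rejects malformed rows with their line number.
#'
#' @param path file path.
#' @return `read_grn` returns a `grn`; `write_grn` returns `path` invisibly.
#' @export
read_grn <- function(path) {
  lines <- readLines(path)
  meta <- list()
  body_at <- 0L
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    } else {
      body_at <- k
      break
    }
  }
  need <- c("n_genes", "input", "target")
  if (!all(need %in% names(meta)))
    stop("missing header line(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  n <- as.integer(meta$n_genes)
  input <- as.integer(meta$input)
  target <- as.integer(meta$target)
  J <- matrix(0L, n, n)
  if (body_at > 0L) {
    body <- lines[body_at:length(lines)]
    offs <- body_at
    if (length(body) && grepl("^source\t", body[1])) {
      body <- body[-1]; offs <- offs + 1L
    }
    for (k in seq_along(body)) {
      if (!nzchar(body[k])) next
      fld <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
      lineno <- offs + k - 1L
      if (length(fld) != 3)
        stop("line ", lineno, ": expected 3 tab-separated fields")
      src <- suppressWarnings(as.integer(fld[1]))
      dst <- suppressWarnings(as.integer(fld[2]))
      sgn <- suppressWarnings(as.integer(fld[3]))
      if (is.na(src) || is.na(dst) || src < 1 || src > n || dst < 1 || dst > n)
        stop("line ", lineno, ": edge index out of range 1..", n)
      if (is.na(sgn) || !(sgn %in% c(-1L, 1L)))
        stop("line ", lineno, ": sign must be -1 or +1, got '", fld[3], "'")
      J[dst, src] <- sgn
    }
  }
  if (any(J[, target] != 0L))
    stop("file declares an edge out of the target gene ", target,
         "; outgoing regulation from the target is prohibited")
  grn(J, input, target)
}

#' @rdname read_grn
#' @param net a `grn` object.
#' @export
write_grn <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  nz <- which(net$J != 0L, arr.ind = TRUE)
  rows <- data.frame(source = nz[, 2], target = nz[, 1],
                     sign = net$J[nz])
  rows <- rows[order(rows$source, rows$target), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n_genes\t%d", net$n_genes),
               sprintf("#input\t%d", net$input),
               sprintf("#target\t%d", net$target),
               "source\ttarget\tsign"), con)
  if (nrow(rows))
    writeLines(sprintf("%d\t%d\t%d", rows$source, rows$target, rows$sign),
               con)
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' Edges carry a `sign` attribute in `{-1, +1}`; vertices carry a `role`
#' attribute (`input`, `target` or `internal`).
#'
#' @param net a `grn` object.
#' @return an [igraph::graph] object.
#' @export
grn_igraph <- function(net) {
  nz <- which(net$J != 0L, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = net$n_genes, directed = TRUE)
  role <- rep("internal", net$n_genes)
  role[net$input] <- "input"; role[net$target] <- "target"
  g <- igraph::set_vertex_attr(g, "role", value = role)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(net$n_genes)))
  if (nrow(nz)) {
    g <- igraph::add_edges(g, rbind(nz[, 2], nz[, 1]))
    g <- igraph::set_edge_attr(g, "sign", value = net$J[nz])
  }
  g
}

#' Export a network as GraphML
#'
#' @inheritParams grn_igraph
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(grn_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @export
plot.grn <- function(x, ...) {
  g <- grn_igraph(x)
  cols <- ifelse(igraph::E(g)$sign > 0, "firebrick", "steelblue")
  vcol <- c(input = "grey70", target = "black", internal = "white")
  igraph::plot.igraph(
    g, edge.color = cols,
    vertex.color = vcol[igraph::V(g)$role],
    vertex.label.color = ifelse(igraph::V(g)$role == "target",
                                "white", "black"), ...)
  invisible(x)
}
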