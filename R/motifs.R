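#' Feed-forward-loop sign patterns on (input, middle, target)
#'
#' A middle gene `m` forms a feed-forward loop (FFL) when the three edges
#' input->m, m->target and input->target all exist; the pattern is the sign
#' triple `(s_im, s_mt, s_it)`, giving 8 possible patterns. An FFL is
#' *incoherent* when the two-step path carries the opposite net sign to the
#' direct edge; incoherent FFLs can produce pulse-like (adaptive)
#' responses.
#'
#' @param net a `grn`.
#' @return an object of class `motif_census`: a data.frame with one row
#'   per sign pattern (`s_im`, `s_mt`, `s_it`, `pattern`, `count`,
#'   `fraction`, `incoherent`, `minimal_adaptive`), with attributes
#'   `total` (number of FFLs found) and `zero_total` flag. Fractions are
#'   normalized by the total FFL count and are `NA` when no FFL exists.
#' @export
ffl_census <- function(net) {
  stopifnot(inherits(net, "grn"))
  pat <- expand.grid(s_it = c(-1L, 1L), s_mt = c(-1L, 1L),
                     s_im = c(-1L, 1L))[, c("s_im", "s_mt", "s_it")]
  key <- function(a, b, c) paste(a, b, c)
  counts <- stats::setNames(integer(8), key(pat$s_im, pat$s_mt, pat$s_it))
  J <- net$J; inp <- net$input; tgt <- net$target
  s_it <- J[tgt, inp]
  if (s_it != 0L) {
    for (m in seq_len(net$n_genes)) {
      if (m == inp || m == tgt) next
      s_im <- J[m, inp]; s_mt <- J[tgt, m]
      if (s_im != 0L && s_mt != 0L) {
        k <- key(s_im, s_mt, s_it)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  total <- sum(counts)
  out <- data.frame(
    s_im = pat$s_im, s_mt = pat$s_mt, s_it = pat$s_it,
    pattern = paste0(ifelse(pat$s_im > 0, "+", "-"),
                     ifelse(pat$s_mt > 0, "+", "-"),
                     ifelse(pat$s_it > 0, "+", "-")),
    count = as.integer(counts),
    fraction = if (total > 0) counts / total else rep(NA_real_, 8),
    incoherent = (pat$s_im * pat$s_mt) != pat$s_it,
    minimal_adaptive = is_minimal_adaptive_ffl(pat$s_im, pat$s_mt, pat$s_it))
  structure(out, class = c("motif_census", "data.frame"),
            total = total, zero_total = total == 0, census = "ffl")
}

#' Minimal adaptive FFL patterns
#'
#' The two incoherent FFL sign patterns that can generate an adaptive
#' pulse when all genes start from the off state: `(+, -, +)` (direct
#' activation, delayed inhibition; upward-adaptive receiver) and
#' `(+, +, -)` (direct inhibition, delayed activation; downward-adaptive
#' receiver, which requires the receiver to sit above its floor at
#' baseline). Vectorized over the three sign arguments.
#'
#' @param s_im,s_mt,s_it edge signs in `{-1, +1}` (input->middle,
#'   middle->target, input->target).
#' @export
is_minimal_adaptive_ffl <- function(s_im, s_mt, s_it) {
  (s_im == 1L & s_mt == -1L & s_it == 1L) |
    (s_im == 1L & s_mt == 1L & s_it == -1L)
}

#' @export
print.motif_census <- function(x, ...) {
  kind <- attr(x, "census")
  cat(sprintf("%s census: %d motifs\n",
              if (identical(kind, "ffl")) "FFL sign-pattern" else
                "Signed triad", attr(x, "total")))
  if (attr(x, "zero_total")) cat("  (no motifs found; fractions undefined)\n")
  print.data.frame(utils::head(x[order(-x$count), , drop = FALSE], 12),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

# canonical form of a 3x3 ternary adjacency: the lexicographically smallest
# row-major string over the 6 node permutations, self-loops zeroed
triad_canonical <- function(A) {
  diag(A) <- 0L
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  best <- NULL
  for (p in perms) {
    s <- paste(c("-", "0", "+")[A[p, p] + 2L], collapse = "")
    if (is.null(best) || s < best) best <- s
  }
  best
}

#' Census of all signed three-gene motifs
#'
#' Enumerates every unordered gene triple, canonicalizes the induced signed
#' subgraph (self-loops excluded) under node permutation, and counts
#' occurrences per isomorphism class. Class labels are the canonical
#' 3x3 adjacency itself, written column-major with characters `-`, `0`, `+`
#' (entry (i,j) = regulation from j to i). Classes are annotated with
#' structural reads: whether the triad contains a feed-forward loop, a
#' negative feedback loop (3-cycle with negative sign product), a mutually
#' activating pair or a mutually inhibiting pair -- the motif families that
#' distinguish cooperative from few-gene adaptive networks.
#'
#' @param net a `grn` with at least 3 genes.
#' @return a `motif_census` data.frame (`class`, `count`, `fraction`,
#'   `ffl`, `negative_feedback`, `mutual_activation`,
#'   `mutual_inhibition`), counts summing to `choose(n, 3)`.
#' @export
triad_census <- function(net) {
  stopifnot(inherits(net, "grn"), net$n_genes >= 3)
  n <- net$n_genes
  counts <- new.env(parent = emptyenv())
  trips <- utils::combn(n, 3)
  for (k in seq_len(ncol(trips))) {
    tri <- trips[, k]
    cls <- triad_canonical(net$J[tri, tri, drop = FALSE])
    counts[[cls]] <- (if (is.null(counts[[cls]])) 0L else counts[[cls]]) + 1L
  }
  classes <- sort(ls(counts))
  cnt <- vapply(classes, function(k) counts[[k]], 0L)
  total <- sum(cnt)
  ann <- t(vapply(classes, triad_class_traits, logical(4)))
  out <- data.frame(class = classes, count = as.integer(cnt),
                    fraction = cnt / total,
                    ffl = ann[, 1], negative_feedback = ann[, 2],
                    mutual_activation = ann[, 3],
                    mutual_inhibition = ann[, 4],
                    row.names = NULL)
  structure(out, class = c("motif_census", "data.frame"),
            total = total, zero_total = total == 0, census = "triad")
}

# structural annotations of a canonical triad class string
triad_class_traits <- function(cls) {
  v <- match(strsplit(cls, "")[[1]], c("-", "0", "+")) - 2L
  A <- matrix(v, 3, 3)
  has_ffl <- FALSE
  for (p in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                 c(3, 2, 1))) {
    B <- A[p, p]  # roles: 1 = source, 2 = middle, 3 = sink
    if (B[2, 1] != 0 && B[3, 2] != 0 && B[3, 1] != 0) has_ffl <- TRUE
  }
  cyc1 <- A[2, 1] != 0 && A[3, 2] != 0 && A[1, 3] != 0
  cyc2 <- A[1, 2] != 0 && A[2, 3] != 0 && A[3, 1] != 0
  nfb <- (cyc1 && A[2, 1] * A[3, 2] * A[1, 3] < 0) ||
    (cyc2 && A[1, 2] * A[2, 3] * A[3, 1] < 0)
  mut_act <- any(A * t(A) == 1 & A == 1)
  mut_inh <- any(A * t(A) == 1 & A == -1)
  c(has_ffl, nfb, mut_act, mut_inh)
}

#' Random-network motif baseline
#'
#' Samples networks whose mutable entries are i.i.d. over `{-1, 0, +1}`
#' with the given frequencies (target column zeroed), averages their
#' censuses, and -- for FFL patterns -- also returns the closed-form
#' expected pattern fractions under independence: each edge's conditional
#' sign is `+` with probability `p(+)/(p(+)+p(-))`, so pattern
#' `(a, b, c)` has expected share `q(a) q(b) q(c)`.
#'
#' @param n_genes network size.
#' @param sign_freq numeric length-3 vector of frequencies for
#'   `(-1, 0, +1)`, summing to 1.
#' @param n_samples number of sampled networks.
#' @param census `"ffl"` or `"triad"`.
#' @param input,target role indices.
#' @return a data.frame of mean fractions with Monte-Carlo standard
#'   errors; for `census = "ffl"` an extra column `expected` holds the
#'   analytic fractions.
#' @export
random_motif_baseline <- function(n_genes, sign_freq = c(0.15, 0.7, 0.15),
                                  n_samples = 200,
                                  census = c("ffl", "triad"),
                                  input = 1L, target = n_genes) {
  census <- match.arg(census)
  stopifnot(length(sign_freq) == 3, abs(sum(sign_freq) - 1) < 1e-9,
            all(sign_freq >= 0), n_samples >= 1)
  draw <- function() {
    J <- matrix(0L, n_genes, n_genes)
    net0 <- grn(J, input, target)
    idx <- mutable_entries(net0)
    J[idx] <- sample(c(-1L, 0L, 1L), length(idx), replace = TRUE,
                     prob = sign_freq)
    grn(J, input, target)
  }
  rows <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    cen <- if (census == "ffl") ffl_census(draw()) else triad_census(draw())
    if (attr(cen, "total") > 0)
      rows[[s]] <- stats::setNames(
        cen$count / attr(cen, "total"),
        if (census == "ffl") cen$pattern else cen$class)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no motifs found in any sampled network")
  keys <- sort(unique(unlist(lapply(rows, names))))
  fr <- matrix(0, length(rows), length(keys),
               dimnames = list(NULL, keys))
  for (s in seq_along(rows)) fr[s, names(rows[[s]])] <- rows[[s]]
  m <- colMeans(fr)
  se <- apply(fr, 2, stats::sd) / sqrt(nrow(fr))
  out <- data.frame(key = keys, mean_fraction = as.numeric(m),
                    se = as.numeric(se), row.names = NULL)
  if (census == "ffl") {
    q <- sign_freq[c(1, 3)] / sum(sign_freq[c(1, 3)])  # P(sign | edge)
    qs <- function(s) ifelse(s > 0, q[2], q[1])
    pat <- ffl_census(grn(matrix(0L, 3, 3)))  # pattern table scaffold
    expected <- qs(pat$s_im) * qs(pat$s_mt) * qs(pat$s_it)
    out$expected <- expected[match(out$key, pat$pattern)]
  }
  out[order(-out$mean_fraction), ]
}

#' Interaction fractions within and between target groups
#'
#' Counts every nonzero directed edge among non-terminal genes that belong
#' to the activating or inhibiting group (see [assign_target_groups()])
#' into six bins: excitatory/inhibitory within the activating group,
#' within the inhibiting group, and between the groups (both directions
#' pooled). In cooperative networks, within-group edges are predominantly
#' excitatory and cross-group edges predominantly inhibitory. Edges
#' touching neutral genes are excluded from the fractions and reported
#' separately.
#'
#' @param net a `grn`.
#' @return a list of class `group_fractions`: data.frame `fractions`
#'   (`pair`, `sign`, `count`, `fraction`), `n_edges` counted,
#'   `n_neutral_edges` excluded, and a `zero_total` flag.
#' @export
group_interaction_fractions <- function(net) {
  grp <- assign_target_groups(net)
  nz <- which(net$J != 0L, arr.ind = TRUE)
  bins <- expand.grid(pair = c("act-act", "inh-inh", "act-inh"),
                      sign = c("excitatory", "inhibitory"),
                      stringsAsFactors = FALSE)
  bins$count <- 0L
  n_neutral <- 0L
  for (k in seq_len(nrow(nz))) {
    to <- nz[k, 1]; from <- nz[k, 2]
    gf <- grp[from]; gt <- grp[to]
    if (gf %in% c("input", "target") || gt %in% c("input", "target")) next
    if (gf == "neutral" || gt == "neutral") { n_neutral <- n_neutral + 1L; next }
    pair <- if (gf == "activating" && gt == "activating") "act-act"
    else if (gf == "inhibiting" && gt == "inhibiting") "inh-inh"
    else "act-inh"
    sgn <- if (net$J[to, from] > 0) "excitatory" else "inhibitory"
    i <- which(bins$pair == pair & bins$sign == sgn)
    bins$count[i] <- bins$count[i] + 1L
  }
  total <- sum(bins$count)
  bins$fraction <- if (total > 0) bins$count / total else NA_real_
  structure(list(fractions = bins, n_edges = total,
                 n_neutral_edges = n_neutral, zero_total = total == 0),
            class = "group_fractions")
}

#' @export
print.group_fractions <- function(x, ...) {
  cat(sprintf(
    "Group interaction fractions over %d edges (%d neutral-touching excluded)\n",
    x$n_edges, x$n_neutral_edges))
  if (x$zero_total) cat("  (no edges among grouped genes)\n")
  print(x$fractions, row.names = FALSE, digits = 4)
  invisible(x)
}
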