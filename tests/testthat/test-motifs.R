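test_that("the upward fixture is a single (+,-,+) feed-forward loop", {
  cen <- ffl_census(iffl_fixture("upward"))
  expect_equal(attr(cen, "total"), 1)
  hit <- cen[cen$count > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pattern, "+-+")
  expect_equal(hit$fraction, 1)
  expect_true(hit$minimal_adaptive)
  expect_true(hit$incoherent)

  empty <- grn(matrix(0L, 4, 4))
  cen0 <- ffl_census(empty)
  expect_equal(attr(cen0, "total"), 0)
  expect_true(attr(cen0, "zero_total"))
  expect_true(all(is.na(cen0$fraction)))
})

test_that("exactly the two reachable incoherent patterns are minimal adaptive", {
  expect_true(is_minimal_adaptive_ffl(1, -1, 1))
  expect_true(is_minimal_adaptive_ffl(1, 1, -1))
  expect_false(is_minimal_adaptive_ffl(1, 1, 1))    # coherent
  expect_false(is_minimal_adaptive_ffl(-1, -1, 1))  # middle never activates
  expect_false(is_minimal_adaptive_ffl(-1, 1, 1))
  # 2 of the 8 patterns qualify, both incoherent
  pats <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  ok <- is_minimal_adaptive_ffl(pats$a, pats$b, pats$c)
  expect_equal(sum(ok), 2)
  expect_true(all((pats$a * pats$b != pats$c)[ok]))
})

test_that("triad canonicalization is idempotent and permutation-invariant", {
  set.seed(41)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (k in 1:50) {
    A <- matrix(sample(c(-1L, 0L, 1L), 9, replace = TRUE), 3, 3)
    diag(A) <- 0L
    cls <- coopadapt:::triad_canonical(A)
    # idempotent: canonical of the canonical matrix is itself
    v <- match(strsplit(cls, "")[[1]], c("-", "0", "+")) - 2L
    expect_equal(coopadapt:::triad_canonical(matrix(v, 3, 3)),
                 cls)
    # identical for every node relabeling
    for (p in perms)
      expect_equal(coopadapt:::triad_canonical(A[p, p]), cls)
    # oracle: the explicit minimum over all 6 permutations
    strs <- vapply(perms, function(p)
      paste(c("-", "0", "+")[A[p, p] + 2L], collapse = ""), "")
    expect_equal(cls, min(strs))
  }
})

test_that("triad census partitions all triples and is relabel-invariant", {
  set.seed(19)
  net <- random_grn(9, 0.35)
  cen <- triad_census(net)
  expect_equal(sum(cen$count), choose(9, 3))
  expect_equal(sum(cen$fraction), 1)

  # relabel the non-terminal genes: class counts must not change
  perm <- c(1, sample(2:8), 9)
  J2 <- net$J[perm, perm]
  cen2 <- triad_census(grn(J2, input = 1, target = 9))
  expect_equal(cen[order(cen$class), c("class", "count")],
               cen2[order(cen2$class), c("class", "count")],
               ignore_attr = TRUE)
})

test_that("triad classes are annotated with their structural motifs", {
  # a pure negative feedback 3-cycle among genes 1..3 (target 4 isolated)
  J <- matrix(0L, 4, 4)
  J[2, 1] <- 1L; J[3, 2] <- 1L; J[1, 3] <- -1L
  cen <- triad_census(grn(J))
  nfb_row <- cen[cen$negative_feedback, ]
  expect_equal(sum(nfb_row$count), 1)
  expect_false(any(cen$ffl & cen$count > 0 & cen$negative_feedback))

  # mutual activation / inhibition pairs
  J <- matrix(0L, 4, 4)
  J[2, 1] <- 1L; J[1, 2] <- 1L; J[3, 2] <- -1L; J[2, 3] <- -1L
  cen <- triad_census(grn(J))
  expect_true(any(cen$mutual_activation & cen$count > 0))
  expect_true(any(cen$mutual_inhibition & cen$count > 0))
})

test_that("sampled FFL baseline matches the closed-form independence law", {
  set.seed(77)
  bl <- random_motif_baseline(8, sign_freq = c(0.2, 0.5, 0.3),
                              n_samples = 150, census = "ffl")
  # every pattern's sampled mean within 4 sigma of the analytic value
  expect_true(all(abs(bl$mean_fraction - bl$expected) <=
                    4 * pmax(bl$se, 1e-3)))
  # closed form itself: q(+) = 0.6, q(-) = 0.4
  pp <- bl$expected[bl$key == "+++"]
  expect_equal(pp, 0.6^3, tolerance = 1e-12)
  mm <- bl$expected[bl$key == "---"]
  expect_equal(mm, 0.4^3, tolerance = 1e-12)
})

test_that("baseline sampling error shrinks with the sample count", {
  set.seed(88)
  bl1 <- random_motif_baseline(6, n_samples = 50, census = "ffl")
  bl2 <- random_motif_baseline(6, n_samples = 200, census = "ffl")
  # standard errors roughly halve when quadrupling the samples
  m1 <- mean(bl1$se); m2 <- mean(bl2$se)
  expect_lt(m2, m1 * 0.75)
})

test_that("group interaction fractions count the six bins correctly", {
  net <- two_group_network(3, 2)
  gf <- group_interaction_fractions(net)
  fr <- gf$fractions
  # by construction: within-group edges all +, cross-group all -
  expect_equal(fr$count[fr$pair == "act-act" & fr$sign == "inhibitory"], 0L)
  expect_equal(fr$count[fr$pair == "inh-inh" & fr$sign == "inhibitory"], 0L)
  expect_equal(fr$count[fr$pair == "act-inh" & fr$sign == "excitatory"], 0L)
  expect_equal(fr$count[fr$pair == "act-act" & fr$sign == "excitatory"],
               3L * 2L)
  expect_equal(fr$count[fr$pair == "inh-inh" & fr$sign == "excitatory"],
               2L * 1L)
  expect_equal(fr$count[fr$pair == "act-inh" & fr$sign == "inhibitory"],
               2L * 3L * 2L)
  expect_equal(sum(fr$fraction), 1)

  # a hand-built two-activator network with a single + edge between them
  J <- matrix(0L, 4, 4)
  J[4, 2] <- 1L; J[4, 3] <- 1L; J[3, 2] <- 1L
  gf2 <- group_interaction_fractions(grn(J))
  expect_equal(gf2$n_edges, 1L)
  expect_equal(gf2$fractions$fraction[
    gf2$fractions$pair == "act-act" &
      gf2$fractions$sign == "excitatory"], 1)

  # no edges among grouped genes -> flagged
  J <- matrix(0L, 4, 4)
  J[4, 2] <- 1L
  expect_true(group_interaction_fractions(grn(J))$zero_total)
})
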