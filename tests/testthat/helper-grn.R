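# shared fixtures and fast parameter sets for the test suite

# dynamics settings used when the test checks structure rather than
# high-precision values: coarser step and a short relaxation cap
fast_dynamics <- function(...) {
  grn_dynamics(dt = 0.05, t_max = 200, ...)
}

# small random network with reproducible contents
test_net <- function(n = 6, density = 0.4, seed = 42) {
  set.seed(seed)
  random_grn(n, density)
}

# build a grn_trajectory directly from a states matrix (for metric tests
# that need hand-constructed traces)
toy_trajectory <- function(states, dt = 1) {
  states <- as.matrix(states)
  structure(list(times = seq(0, by = dt, length.out = nrow(states)),
                 states = `colnames<-`(states,
                                       paste0("x", seq_len(ncol(states))))),
            class = "grn_trajectory")
}

expect_valid_grn <- function(net) {
  expect_s3_class(net, "grn")
  expect_true(all(net$J %in% c(-1L, 0L, 1L)))
  expect_true(all(net$J[, net$target] == 0L))
}
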