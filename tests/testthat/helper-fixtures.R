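# Small connectomes built in code for the structural-operator tests.

# 3-node toy with known weights; region 1 is the stroke target.
toy_conn3 <- function() {
  w <- matrix(0, 3, 3)
  w[2, 1] <- 4; w[1, 2] <- 1; w[3, 2] <- 2; w[2, 3] <- 0.5
  connectome(w, labels = c("rM1", "A", "B"), stroke_region = 1L)
}

# 4-node toy where exactly one node (2) has links to the stroke region (1);
# node 2 also connects to nodes 3 and 4.
toy_conn4_single_donor <- function() {
  w <- matrix(0, 4, 4)
  w[2, 1] <- 3          # stroke -> node 2
  w[1, 2] <- 2          # node 2 -> stroke
  w[3, 2] <- 1; w[2, 3] <- 0.5
  w[4, 2] <- 2; w[2, 4] <- 1.5
  w[4, 3] <- 0.25       # a link not involving the donor
  connectome(w, labels = c("rM1", "D", "A", "B"), stroke_region = 1L)
}

# complete graph with uniform weights (no self-loops)
complete_conn <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  connectome(w, stroke_region = 1L)
}

# small fast adex setup for contract tests
small_arch <- function(seed = 1L) {
  network_architecture(N_exc = 80L, N_inh = 20L, p_connect = 0.05,
                       seed = seed)
}
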