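# Programmatic fixtures shared across test files.

# random binary kernel
rand_kernel <- function(N, T, p = 0.5) {
  binary_kernel(matrix(rbinom(N * T, 1L, p), N, T))
}

# random causal (strictly "past-coupling") kinetic matrix
rand_causal_B <- function(T, scale = 0.3) {
  B <- matrix(rnorm(T * T, sd = scale), T, T)
  B[upper.tri(B, diag = TRUE)] <- 0
  B
}

# random action parameters on a small lattice
rand_params <- function(N, T, lam = 1, representation = "binary",
                        with_input = TRUE) {
  action_params(A = matrix(rnorm(N * N, sd = 0.4), N, N),
                B = rand_causal_B(T),
                I = if (with_input) matrix(rnorm(N * T, sd = 0.3), N, T),
                lam = lam, representation = representation, N = N, T = T)
}

# independent triple-loop evaluation of the action (oracle; no linear
# algebra shared with the implementation)
brute_force_action <- function(X, A, B, I) {
  N <- nrow(X); T <- ncol(X)
  tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) for (a in seq_len(T))
    tot <- tot + A[i, j] * X[i, a] * X[j, a]
  for (a in seq_len(T)) for (b in seq_len(T)) for (i in seq_len(N))
    tot <- tot + B[a, b] * X[i, a] * X[i, b]
  for (i in seq_len(N)) for (a in seq_len(T))
    tot <- tot - I[i, a] * X[i, a]
  tot
}

# brute-force partition function by explicit state loop (oracle)
brute_force_log_partition <- function(p) {
  L <- p$N * p$T
  lv <- if (p$representation == "binary") c(0, 1) else c(-1, 1)
  acts <- numeric(2^L)
  for (s in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(L)]
    X <- matrix(lv[bits + 1L], p$N, p$T)
    acts[s + 1L] <- brute_force_action(X, p$A, p$B, p$I)
  }
  m <- max(-p$lam * acts)
  m + log(sum(exp(-p$lam * acts - m)))
}
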