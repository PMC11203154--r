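test_that("action_value matches trivial cases and the loop oracle", {
  k1 <- binary_kernel(matrix(1, 1, 1))
  p0 <- action_params(lam = 1, N = 1, T = 1)
  expect_equal(action_value(k1, p0), 0)
  pa <- action_params(A = matrix(0.7, 1, 1), N = 1, T = 1)
  expect_equal(action_value(k1, pa), 0.7)
  set.seed(60)
  for (r in 1:30) {
    rep <- sample(c("binary", "spin"), 1)
    p <- rand_params(2, 2, representation = rep)
    k <- rand_kernel(2, 2)
    X <- if (rep == "binary") phi_matrix(k) else sigma_matrix(k)
    expect_equal(action_value(k, p),
                 brute_force_action(X, p$A, p$B, p$I), tolerance = 1e-12)
  }
  expect_error(action_value(rand_kernel(3, 2), rand_params(2, 2)),
               "dimension mismatch")
})

test_that("binary and spin parameterisations agree up to the constant", {
  set.seed(61)
  for (r in 1:30) {
    p <- rand_params(3, 4)
    sp <- spin_parameters(p)
    k <- rand_kernel(3, 4)
    expect_equal(action_value(k, p),
                 action_value(k, sp$params) + sp$constant,
                 tolerance = 1e-10)
  }
})

test_that("non-causal kinetic matrices are rejected", {
  B <- matrix(0, 3, 3); B[1, 2] <- 1
  expect_error(action_params(B = B, N = 2, T = 3), "causal")
  Bd <- matrix(0, 3, 3); Bd[2, 2] <- 1
  expect_error(action_params(B = Bd, N = 2, T = 3), "causal")
})

test_that("lagrangian split has the stated potential/kinetic structure", {
  set.seed(62)
  k <- to_spin(rand_kernel(4, 5))
  pB0 <- action_params(A = matrix(rnorm(16), 4, 4), lam = 1,
                       representation = "spin", N = 4, T = 5)
  for (a in 1:5) expect_equal(lagrangian_split(k, pB0, a)$kinetic, 0)
  # nearest-step kinetic coupling: K(alpha) = B0 * N * q_{alpha, alpha-1}
  B0 <- 0.8
  B <- matrix(0, 5, 5)
  B[cbind(2:5, 1:4)] <- -B0
  p <- action_params(B = B, lam = 1, representation = "spin", N = 4, T = 5)
  sig <- sigma_matrix(k)
  for (a in 2:5) {
    q <- mean(sig[, a] * sig[, a - 1])
    expect_equal(lagrangian_split(k, p, a)$kinetic, B0 * 4 * q)
  }
  expect_equal(lagrangian_split(k, p, 1)$kinetic, 0)
})

test_that("summed Lagrangian reproduces the action on random instances", {
  set.seed(63)
  for (r in 1:50) {
    N <- sample(2:4, 1); T <- sample(2:5, 1)
    p <- rand_params(N, T, representation = "spin")
    k <- rand_kernel(N, T)
    expect_equal(action_from_lagrangian(k, p), action_value(k, p),
                 tolerance = 1e-10)
  }
})

test_that("pulse kernel satisfies the overlap identity", {
  const <- magnetization_kernel(matrix(1, 3, 4))
  expect_true(all(pulse_kernel(const) == 0))
  flip <- magnetization_kernel(cbind(rep(1, 3), rep(-1, 3)))
  expect_equal(unclass(pulse_kernel(flip))[, 2], rep(-2L, 3))
  # worked example: slices (+,-,-) -> (+,+,-)
  sig <- cbind(c(1, -1, -1), c(1, 1, -1))
  k <- magnetization_kernel(sig)
  d <- pulse_kernel(k)
  expect_equal(sum(d[, 2]^2), 4)
  q <- mean(sig[, 1] * sig[, 2])
  expect_equal(2 * 3 * (1 - q), 4)
  expect_error(pulse_kernel(magnetization_kernel(matrix(1, 2, 1))),
               "two time bins")
  set.seed(64)
  for (r in 1:30) {
    k <- to_spin(rand_kernel(5, 6))
    sig <- sigma_matrix(k)
    d <- pulse_kernel(k)
    for (a in 2:6) {
      q <- mean(sig[, a] * sig[, a - 1])
      expect_equal(sum(d[, a]^2), 2 * 5 * (1 - q))
    }
  }
})

test_that("nearest-step and pulse Lagrangians differ by a constant", {
  set.seed(65)
  B0 <- 0.6; N <- 4; T <- 6
  B <- matrix(0, T, T)
  B[cbind(2:T, 1:(T - 1))] <- -B0
  p <- action_params(B = B, lam = 1, representation = "spin", N = N, T = T)
  diffs <- c()
  for (r in 1:10) {
    k <- to_spin(rand_kernel(N, T))
    d <- pulse_kernel(k)
    for (a in 2:T) {
      L_overlap <- lagrangian_split(k, p, a)$lagrangian
      L_pulse <- -lagrangian_split(k, p, a)$potential -
        0.5 * B0 * sum(d[, a]^2)
      diffs <- c(diffs, L_overlap - L_pulse)
    }
  }
  expect_equal(diffs, rep(B0 * N, length(diffs)))
})

test_that("partition function: uniform, two-state and replica cases", {
  # zero action on N*T = 4 sites: G = 2^4
  p0 <- action_params(lam = 1, N = 2, T = 2)
  expect_equal(partition_function(p0)$log_partition, log(16))
  # single spin in a field h: G = 2 cosh(lam h)
  h <- 0.9; lam <- 1.3
  p1 <- action_params(I = matrix(h, 1, 1), lam = lam,
                      representation = "spin", N = 1, T = 1)
  expect_equal(partition_function(p1)$log_partition, log(2 * cosh(lam * h)))
  # replica factorisation G(A, 0) = Z(A)^T at N = 2, T = 3
  set.seed(66)
  A <- matrix(rnorm(4, sd = 0.5), 2, 2)
  pT <- action_params(A = A, lam = 0.8, representation = "spin",
                      N = 2, T = 3)
  p1rep <- action_params(A = A, lam = 0.8, representation = "spin",
                         N = 2, T = 1)
  expect_equal(partition_function(pT)$log_partition,
               3 * partition_function(p1rep)$log_partition,
               tolerance = 1e-10)
  expect_error(partition_function(rand_params(5, 5)), "cap")
})

test_that("enumeration agrees with the state-loop oracle", {
  set.seed(67)
  for (rep in c("binary", "spin")) {
    p <- rand_params(2, 2, lam = 0.9, representation = rep)
    expect_equal(partition_function(p)$log_partition,
                 brute_force_log_partition(p), tolerance = 1e-10)
  }
})

test_that("mcmc partition estimate matches enumeration within error", {
  set.seed(68)
  p <- rand_params(2, 3, lam = 0.8, representation = "spin")
  exact <- partition_function(p)$log_partition
  est <- partition_function(p, mode = "mcmc", seed = 7, sweeps = 1500L)
  expect_lt(abs(est$log_partition - exact), max(4 * est$mc_stderr, 0.05))
})

test_that("gibbs averages: uniform limit, tanh closed form, mcmc oracle", {
  # near-zero lambda: uniform measure, <sigma> ~ 0
  set.seed(69)
  p_small <- action_params(A = matrix(rnorm(4), 2, 2), lam = 1e-9,
                           representation = "spin", N = 2, T = 2)
  expect_equal(gibbs_average(function(X) X[1, 1], p_small)$value, 0,
               tolerance = 1e-6)
  # single spin: <sigma> = tanh(lam h)
  h <- 0.7; lam <- 1.1
  p1 <- action_params(I = matrix(h, 1, 1), lam = lam,
                      representation = "spin", N = 1, T = 1)
  expect_equal(gibbs_average(function(X) X[1, 1], p1)$value,
               tanh(lam * h), tolerance = 1e-12)
  # enumeration vs a long mcmc run on random instances
  for (r in 1:3) {
    p <- rand_params(2, 3, lam = 0.6, representation = "spin")
    obs <- function(X) X[1, 1] * X[2, 3]
    exact <- gibbs_average(obs, p)$value
    est <- gibbs_average(obs, p, mode = "mcmc", seed = 100 + r,
                         n_samples = 4000L, thin = 2L)
    expect_lt(abs(est$value - exact), max(3 * est$stderr, 0.05))
  }
})

test_that("input partition function and the rho-average identity", {
  expect_equal(input_partition(matrix(0, 2, 3)), log(64))
  expect_equal(input_partition(matrix(1, 1, 1), lam = 1),
               log(2 * cosh(1)))
  # G(A, B, I) = R(I) * <exp(-lam * A(M | A, B))>_rho by enumeration
  set.seed(70)
  p <- rand_params(2, 2, lam = 0.7, representation = "spin")
  p_noI <- action_params(A = p$A, B = p$B, lam = p$lam,
                         representation = "spin", N = 2, T = 2)
  S <- spikelft:::enumerate_states(4, c(-1, 1))
  rho_w <- exp(p$lam * as.vector(S %*% as.vector(p$I)))
  rho_w <- rho_w / sum(rho_w)
  inner <- sum(rho_w * exp(-p$lam * spikelft:::state_actions(S, p_noI)))
  lhs <- partition_function(p)$log_partition
  expect_equal(lhs, input_partition(p$I, p$lam) + log(inner),
               tolerance = 1e-10)
})

test_that("max-entropy limit: B = 0, T = 1 is the Ising Hamiltonian", {
  set.seed(71)
  for (r in 1:20) {
    N <- 4
    A <- matrix(rnorm(N * N), N, N)
    h <- rnorm(N)
    p <- action_params(A = A, I = matrix(h, N, 1), lam = 1, N = N, T = 1)
    sp <- spin_parameters(p)
    sig <- matrix(sample(c(-1, 1), N, replace = TRUE), N, 1)
    k <- magnetization_kernel(sig)
    ising <- sum(outer(sig[, 1], sig[, 1]) * A / 4) -
      sum(sp$params$I[, 1] * sig[, 1])
    expect_equal(action_value(k, sp$params), ising, tolerance = 1e-12)
  }
})

test_that("Gibbs bound holds for random product measures", {
  set.seed(72)
  p <- rand_params(2, 3, lam = 0.9, representation = "spin")
  psi <- partition_function(p)$free_action
  for (r in 1:100) {
    zeta <- runif(6, 0.02, 0.98)
    expect_gte(free_action_functional(p, zeta) - psi, -1e-10)
  }
  # equality at the Gibbs measure of a product model (pure input)
  I <- matrix(rnorm(6, sd = 0.5), 2, 3)
  pp <- action_params(I = I, lam = 1.2, representation = "spin",
                      N = 2, T = 3)
  probs_gibbs <- as.vector(1 / (1 + exp(-2 * pp$lam * I)))
  expect_equal(free_action_functional(pp, probs_gibbs),
               partition_function(pp)$free_action, tolerance = 1e-10)
})

test_that("ground state search finds the enumerated minimum", {
  set.seed(73)
  p <- rand_params(2, 3, lam = 2, representation = "spin")
  gs <- ground_state(p)
  expect_true(gs$exact)
  S <- spikelft:::enumerate_states(6, c(-1, 1))
  expect_equal(gs$action, min(spikelft:::state_actions(S, p)))
  # annealing fallback reaches the same minimum on this small instance
  gs2 <- ground_state(p, cap = 2L, seed = 5, lambda_max = 30)
  expect_false(gs2$exact)
  expect_lt(gs2$action - gs$action, 1e-8)
})
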