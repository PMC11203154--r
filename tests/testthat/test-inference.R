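# exact spin moments of a model P(s) ~ exp(sum_{l<l'} J s s' + sum h s),
# by enumeration (oracle, independent of the sampling machinery)
exact_spin_moments <- function(J, h) {
  L <- length(h)
  S <- spikelft:::enumerate_states(L, c(-1, 1))
  logw <- 0.5 * rowSums((S %*% J) * S) + as.vector(S %*% h)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  m <- as.vector(crossprod(S, w))
  C2 <- crossprod(S, S * w) - tcrossprod(m)
  list(m = m, C = (C2 + t(C2)) / 2, probs = w, states = S)
}

as_gc <- function(mom, n = 1e6) {
  structure(list(values = mom$C, means = mom$m, n_samples = n,
                 N = length(mom$m), T = 1L),
            class = "grand_covariance")
}

test_that("Callen inversion and its error bar", {
  sol <- callen_invert(rep(0, 4), 100)
  expect_equal(sol$fields, rep(0, 4))
  expect_equal(sol$field_stderr, rep(0.1, 4))
  expect_equal(callen_invert(tanh(1), 50)$fields, 1)
  expect_error(callen_invert(c(0.2, 1), 10), "infinite field")
})

test_that("Callen error bars match repeated-simulation spread", {
  set.seed(80)
  lamI <- 0.4
  n <- 500
  p_plus <- (1 + tanh(lamI)) / 2
  hats <- replicate(200, atanh(2 * mean(runif(n) < p_plus) - 1))
  predicted <- cosh(lamI) / sqrt(n)
  expect_lt(abs(sd(hats) / predicted - 1), 0.2)
})

test_that("naive mean field inverts the covariance", {
  gc_id <- structure(list(values = diag(3), means = rep(0, 3),
                          n_samples = 100, N = 3, T = 1),
                     class = "grand_covariance")
  expect_equal(invert_naive_mf(gc_id)$couplings, matrix(0, 3, 3))
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  gc <- structure(list(values = C, means = c(0, 0), n_samples = 100,
                       N = 2, T = 1), class = "grand_covariance")
  expect_equal(invert_naive_mf(gc)$couplings[1, 2], 2 / 3)
})

test_that("TAP reduces to naive mean field at zero magnetisation", {
  set.seed(81)
  mom <- exact_spin_moments(matrix(0.2, 4, 4) - diag(0.2, 4), rep(0, 4))
  gc <- as_gc(mom)
  expect_equal(max(abs(gc$means)), 0, tolerance = 1e-12)
  expect_equal(invert_tap(gc)$couplings, invert_naive_mf(gc)$couplings,
               tolerance = 1e-12)
  # identity covariance with nonzero means gives zero couplings
  gc_id <- structure(list(values = diag(3), means = c(0.2, -0.1, 0.3),
                          n_samples = 100, N = 3, T = 1),
                     class = "grand_covariance")
  expect_equal(invert_tap(gc_id)$couplings, matrix(0, 3, 3))
})

test_that("independent-pair inversion: closed forms and 2-spin exactness", {
  gc0 <- structure(list(values = diag(2), means = c(0, 0), n_samples = 10,
                        N = 2, T = 1), class = "grand_covariance")
  expect_equal(invert_independent_pair(gc0)$couplings[1, 2], 0)
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  gc <- structure(list(values = C, means = c(0, 0), n_samples = 10,
                       N = 2, T = 1), class = "grand_covariance")
  expect_equal(invert_independent_pair(gc)$couplings[1, 2], atanh(0.5))
  set.seed(82)
  for (r in 1:20) {
    J12 <- rnorm(1, sd = 0.5)
    J <- matrix(c(0, J12, J12, 0), 2, 2)
    h <- rnorm(2, sd = 0.3)
    mom <- exact_spin_moments(J, h)
    sol <- invert_independent_pair(as_gc(mom))
    expect_equal(sol$couplings[1, 2], J12, tolerance = 1e-10)
  }
})

test_that("Sessak-Monasson: 2-spin reduction, zero limit, beats IP", {
  C <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  gc <- structure(list(values = C, means = c(0, 0), n_samples = 10,
                       N = 2, T = 1), class = "grand_covariance")
  expect_equal(invert_sessak_monasson(gc)$couplings[1, 2],
               invert_independent_pair(gc)$couplings[1, 2],
               tolerance = 1e-12)
  Ctiny <- matrix(c(1, 1e-9, 1e-9, 1), 2, 2)
  gct <- structure(list(values = Ctiny, means = c(0, 0), n_samples = 10,
                        N = 2, T = 1), class = "grand_covariance")
  expect_lt(abs(invert_sessak_monasson(gct)$couplings[1, 2]), 1e-8)
  # sparse weak couplings on 10 sites, exact moments: SM rmse <= IP rmse
  set.seed(83)
  L <- 10
  J <- matrix(0, L, L)
  pairs <- which(upper.tri(J))
  on <- sample(pairs, 8)
  J[on] <- rnorm(8, sd = 0.15)
  J <- J + t(J)
  mom <- exact_spin_moments(J, rnorm(L, sd = 0.1))
  gc <- as_gc(mom)
  off <- upper.tri(J)
  rmse <- function(sol) sqrt(mean((sol$couplings[off] - J[off])^2))
  expect_lte(rmse(invert_sessak_monasson(gc)),
             rmse(invert_independent_pair(gc)))
})

test_that("all inverters vanish on factorised covariances", {
  mom <- exact_spin_moments(matrix(0, 5, 5), c(0.3, -0.2, 0, 0.5, -0.4))
  gc <- as_gc(mom)
  for (method in c("nmf", "tap", "ip", "sm")) {
    sol <- invert_couplings(gc, method)
    expect_lt(max(abs(sol$couplings)), 1e-10)
  }
})

test_that("TAP is accurate for weak couplings with exact moments", {
  set.seed(84)
  L <- 6
  J <- matrix(rnorm(L * L, sd = 0.1 / sqrt(L)), L, L)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  mom <- exact_spin_moments(J, rnorm(L, sd = 0.1))
  sol <- invert_tap(as_gc(mom))
  off <- upper.tri(J)
  expect_lt(sqrt(mean((sol$couplings[off] - J[off])^2)) /
              sqrt(mean(J[off]^2)), 0.1)
})

test_that("couplings are recovered from Gibbs-sampled rasters", {
  # known spin model, couplings of scale 0.3/sqrt(N); exact-probability
  # sampling by enumeration, then Sessak-Monasson reconstruction
  set.seed(85)
  N <- 10
  J <- matrix(rnorm(N * N, sd = 0.3 / sqrt(N)), N, N)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  mom <- exact_spin_moments(J, rep(0, N))
  idx <- sample.int(nrow(mom$states), 1e5, replace = TRUE,
                    prob = mom$probs)
  gc <- grand_covariance(mom$states[idx, , drop = FALSE], N = N, T = 1L)
  sol <- invert_sessak_monasson(gc)
  off <- upper.tri(J)
  expect_gte(cor(sol$couplings[off], J[off]), 0.9)
})

test_that("grand covariance has the spin diagonal and symmetry", {
  set.seed(86)
  samples <- lapply(1:200, function(r) to_spin(rand_kernel(3, 4, 0.4)))
  gc <- grand_covariance(samples)
  expect_equal(gc$values, t(gc$values))
  expect_equal(diag(gc$values), 1 - gc$means^2, tolerance = 1e-12)
  expect_equal(gc$N, 3)
  expect_equal(gc$T, 4)
})

test_that("non-relativistic reduction matches the ensemble covariances", {
  set.seed(87)
  N <- 3; T <- 4
  for (r in 1:20) {
    trials <- lapply(1:15, function(s) rand_kernel(N, T, runif(1, .2, .8)))
    gc <- grand_covariance(trials)
    red <- reduce_nonrelativistic(gc)
    eh <- ensemble_hypermatrix(trial_ensemble(trials))
    expect_equal(red$space_cov, eh$covariances$delta_C, tolerance = 1e-12)
    expect_equal(red$time_cov, eh$covariances$delta_Q, tolerance = 1e-12)
  }
  expect_equal(reduce_nonrelativistic(grand_covariance(
    lapply(1:5, function(s) rand_kernel(N, T))))$parameter_count,
    N * T * (N + T))
})

test_that("reduction of a product measure is near-diagonal", {
  set.seed(88)
  trials <- lapply(1:4000, function(s) rand_kernel(4, 3, 0.5))
  red <- reduce_nonrelativistic(grand_covariance(trials))
  offd <- red$space_cov[upper.tri(red$space_cov)]
  expect_lt(max(abs(offd)), 4 / sqrt(4000 * 3))
})
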