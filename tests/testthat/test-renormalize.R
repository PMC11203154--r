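test_that("bin renormalization is the any-spike indicator per block", {
  phi <- matrix(0, 4, 6)
  phi[1, 2] <- 1           # one spike in the (1,1) block
  k <- binary_kernel(phi, tau_ms = 1)
  bp <- block_partition(2, 2, 3, 2)
  coarse <- bin_renormalize(k, bp)
  expect_equal(coarse$values[1, 1], 1L)
  expect_equal(sum(coarse$values), 1L)
  expect_equal(coarse$tau_ms, 2)
  # identity when blocks are 1 x 1
  bp1 <- block_partition(4, 1, 6, 1)
  expect_identical(bin_renormalize(k, bp1)$values, k$values)
})

test_that("bin renormalization never creates or inflates activity", {
  set.seed(90)
  for (r in 1:30) {
    k <- rand_kernel(6, 8, runif(1, 0.05, 0.6))
    bp <- block_partition(3, 2, 2, 4)
    coarse <- bin_renormalize(k, bp)
    expect_lte(sum(coarse$values), sum(k$values))
    # a coarse 1 implies at least one fine spike in the block
    for (i1 in 1:3) for (a1 in 1:2) {
      blk <- k$values[(i1 - 1) * 2 + 1:2, (a1 - 1) * 4 + 1:4]
      expect_equal(coarse$values[i1, a1], as.integer(any(blk == 1)))
    }
  }
})

test_that("shape policies truncate or pad as requested", {
  k <- rand_kernel(5, 7)
  bp <- block_partition(2, 2, 3, 2)
  expect_error(bin_renormalize(k, bp), "policy")
  expect_warning(ct <- bin_renormalize(k, bp, policy = "truncate"),
                 "truncating")
  expect_equal(dim(ct$values), c(2L, 3L))
  k2 <- rand_kernel(3, 5)
  expect_warning(cp <- bin_renormalize(k2, bp, policy = "pad"),
                 "padding")
  expect_equal(dim(cp$values), c(2L, 3L))
})

test_that("decimation keeps the representative site", {
  const <- binary_kernel(matrix(1, 4, 4))
  bp <- block_partition(2, 2, 2, 2)
  expect_true(all(decimate(const, bp)$values == 1L))
  # checkerboard: representatives are the odd (1-based) sites
  cb <- binary_kernel(outer(1:4, 1:4, function(i, a) (i + a) %% 2))
  dec <- decimate(cb, bp)
  expect_equal(dec$values, matrix(0L, 2, 2))   # (odd+odd) %% 2 = 0
  dec2 <- decimate(cb, bp, offset_space = 2L)
  expect_equal(dec2$values, matrix(1L, 2, 2))
  expect_error(decimate(cb, bp, offset_space = 3L), "outside")
})

test_that("decimation composes with composed block sizes", {
  set.seed(91)
  k <- rand_kernel(8, 8, 0.4)
  once <- decimate(decimate(k, block_partition(4, 2, 4, 2)),
                   block_partition(2, 2, 2, 2))
  composed <- decimate(k, block_partition(2, 4, 2, 4))
  expect_identical(once$values, composed$values)
})

test_that("electrode lattice and Utah-96 geometry", {
  u <- utah96_lattice()
  expect_equal(u$n_sites, 96L)
  expect_equal(sum(u$mask), 96L)
  expect_false(u$mask[1, 1] || u$mask[1, 10] || u$mask[10, 1] ||
                 u$mask[10, 10])
  full <- electrode_lattice(c(2, 3), pitch_um = 100)
  expect_equal(full$n_sites, 6L)
  # row-major order
  expect_equal(full$sites$row, c(1, 1, 1, 2, 2, 2))
  expect_equal(full$sites$col, c(1, 2, 3, 1, 2, 3))
})

test_that("electrode kernel ORs neurons within a listening volume", {
  lat <- electrode_lattice(c(1, 2), pitch_um = 100)
  # one neuron per site: output equals input
  k <- rand_kernel(2, 5)
  pos <- cbind(c(0, 100), c(0, 0))
  ek <- electrode_kernel(k, pos, lat)
  expect_equal(unname(ek$values), unname(k$values))
  # two neurons in one cell: site active if either fires
  k2 <- binary_kernel(rbind(c(1, 0, 0), c(0, 1, 0)))
  ek2 <- electrode_kernel(k2, cbind(c(0, 10), c(0, 0)), lat)
  expect_equal(unname(ek2$values), rbind(c(1L, 1L, 0L), c(0L, 0L, 0L)))
  # outside neurons: error by default, droppable
  k3 <- binary_kernel(matrix(1, 1, 3))
  expect_error(electrode_kernel(k3, cbind(500, 500), lat), "outside")
  ek3 <- electrode_kernel(k3, cbind(500, 500), lat, outside = "drop")
  expect_equal(sum(ek3$values), 0L)
})

test_that("electrode kernel commutes with time binning", {
  set.seed(92)
  lat <- electrode_lattice(c(2, 2), pitch_um = 100)
  k <- rand_kernel(8, 12, 0.3)
  assign <- rep(1:4, each = 2)
  bp_fine <- block_partition(8, 1, 4, 3)
  bp_coarse <- block_partition(4, 1, 4, 3)
  a <- bin_renormalize(electrode_kernel(k, assign, lat), bp_coarse)
  b <- electrode_kernel(bin_renormalize(k, bp_fine), assign, lat)
  expect_equal(unname(a$values), unname(b$values))
})

test_that("effective couplings reduce to the originals for 1x1 blocks", {
  set.seed(93)
  p <- rand_params(2, 2, with_input = FALSE)
  bp <- block_partition(2, 1, 2, 1)
  ec <- effective_couplings(p, bp, enumerate = TRUE)
  expect_equal(ec$a_hat, p$A, tolerance = 1e-12)
  expect_equal(ec$b_hat, p$B, tolerance = 1e-12)
  # with 1x1 blocks each coarse configuration has a single preimage and a
  # vanishing perturbation
  expect_lt(max(abs(ec$delta_action)), 1e-10)
})

test_that("uniform-coupling block sums add the intra-block couplings", {
  a0 <- 0.25
  p <- action_params(A = matrix(a0, 4, 4), lam = 1, N = 4, T = 2)
  bp <- block_partition(2, 2, 2, 1)
  full <- binary_kernel(matrix(1, 4, 2))
  ec <- effective_couplings(p, bp, samples = list(full))
  s <- spikelft:::block_action_sums(matrix(1, 4, 2), p, bp)
  # every block sum is a0 * N2^2 * T2 on the fully active kernel
  expect_true(all(abs(s$A_arr - a0 * 4) < 1e-12))
  expect_equal(ec$a_hat, matrix(a0 * 4, 2, 2))
})

test_that("renormalized partition identity is exact under enumeration", {
  set.seed(94)
  for (r in 1:5) {
    p <- rand_params(2, 2, lam = 0.8, with_input = FALSE)
    bp <- block_partition(1, 2, 1, 2)
    ec <- effective_couplings(p, bp, enumerate = TRUE)
    logG <- partition_function(p)$log_partition
    keys <- names(ec$delta_action)
    terms <- vapply(keys, function(key) {
      coarse <- matrix(as.integer(strsplit(key, "")[[1]]), bp$N1, bp$T1)
      act <- sum(ec$a_hat * tcrossprod(coarse)) +
        sum(ec$b_hat * crossprod(coarse))
      -p$lam * (act + ec$delta_action[[key]])
    }, numeric(1))
    m <- max(terms)
    expect_equal(m + log(sum(exp(terms - m))), logG, tolerance = 1e-10)
  }
})

test_that("binned structured rasters keep their time correlations better than i.i.d.", {
  # qualitative renormalization stability: correlation between fine and
  # upsampled coarse joint-spike patterns, structured vs i.i.d. raster
  set.seed(95)
  T <- 200; N <- 30
  burst <- matrix(0L, N, T)
  centers <- seq(10, T - 10, by = 20)
  for (cc in centers) {
    act <- sample(N, 12)
    burst[act, cc + (-3:3)] <-
      (matrix(runif(12 * 7), 12, 7) < 0.6) * 1L
  }
  k_str <- binary_kernel(burst)
  k_iid <- rand_kernel(N, T, mean(burst))
  upsample <- function(m, f) m[rep(seq_len(nrow(m)), each = f),
                               rep(seq_len(ncol(m)), each = f)]
  score <- function(k) {
    bp <- block_partition(N, 1, T / 10, 10)
    fine <- correlation_set(k)$q_star
    coarse <- correlation_set(bin_renormalize(k, bp))$q_star
    cor(as.vector(fine), as.vector(upsample(coarse, 10)))
  }
  expect_gt(score(k_str), score(k_iid))
})
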