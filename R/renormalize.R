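# ---------------------------------------------------------------------------
# Kernel coarse-graining: block partitions, bin renormalization (any-spike
# indicator per block), decimation (representative site per block), the
# electrode kernel for planar multielectrode arrays, and effective-coupling
# bookkeeping for the renormalized action.
# ---------------------------------------------------------------------------

#' Block partition of a kernel
#'
#' Splits the N neurons into `n_blocks_space` contiguous blocks of
#' `block_size_space` and the T bins into `n_blocks_time` blocks of
#' `block_size_time` (N = N1 * N2, T = T1 * T2).
#'
#' @param n_blocks_space,block_size_space space factorisation (N1, N2).
#' @param n_blocks_time,block_size_time time factorisation (T1, T2).
#' @return an object of class `block_partition`.
#' @export
block_partition <- function(n_blocks_space, block_size_space,
                            n_blocks_time, block_size_time) {
  v <- c(n_blocks_space, block_size_space, n_blocks_time, block_size_time)
  if (any(v < 1) || any(v != as.integer(v)))
    stop("block counts and sizes must be positive integers")
  structure(list(N1 = as.integer(n_blocks_space),
                 N2 = as.integer(block_size_space),
                 T1 = as.integer(n_blocks_time),
                 T2 = as.integer(block_size_time)),
            class = "block_partition")
}

# Check/trim a kernel matrix against a partition; returns the (possibly
# truncated or padded) phi matrix.
conform_blocks <- function(phi, bp, policy = c("strict", "truncate", "pad")) {
  policy <- match.arg(policy)
  needN <- bp$N1 * bp$N2
  needT <- bp$T1 * bp$T2
  if (nrow(phi) == needN && ncol(phi) == needT) return(phi)
  if (policy == "strict")
    stop(sprintf(
      "kernel is %d x %d but partition requires %d x %d (set policy)",
      nrow(phi), ncol(phi), needN, needT))
  if (policy == "truncate") {
    if (nrow(phi) < needN || ncol(phi) < needT)
      stop("kernel too small to truncate to the partition")
    warning(sprintf("truncating kernel from %d x %d to %d x %d",
                    nrow(phi), ncol(phi), needN, needT))
    return(phi[seq_len(needN), seq_len(needT), drop = FALSE])
  }
  if (nrow(phi) > needN || ncol(phi) > needT)
    stop("kernel too large to pad to the partition")
  out <- matrix(0L, needN, needT)
  out[seq_len(nrow(phi)), seq_len(ncol(phi))] <- phi
  warning(sprintf("zero-padding kernel from %d x %d to %d x %d",
                  nrow(phi), ncol(phi), needN, needT))
  out
}

#' Bin renormalization of a kernel
#'
#' Coarse-grains the kernel over the blocks of `bp` with the any-spike
#' indicator: the coarse cell is 1 iff its N2 x T2 block contains at least
#' one spike. The clock time is rescaled by the time block size. This never
#' creates activity where a block had none.
#'
#' @param k a binary kernel.
#' @param bp a [block_partition()].
#' @param policy what to do when the shape does not factor: `"strict"`
#'   (error), `"truncate"` trailing rows/bins, or `"pad"` with zeros.
#' @return the coarse [binary_kernel()] (N1 x T1).
#' @export
bin_renormalize <- function(k, bp, policy = "strict") {
  phi <- conform_blocks(phi_matrix(k), bp, policy)
  gN <- rep(seq_len(bp$N1), each = bp$N2)
  gT <- rep(seq_len(bp$T1), each = bp$T2)
  counts <- t(rowsum(t(rowsum(phi, gN)), gT))
  dimnames(counts) <- NULL
  binary_kernel((counts > 0) * 1L, tau_ms = k$tau_ms * bp$T2,
                t0_bin = k$t0_bin %/% bp$T2)
}

#' Renormalization by decimation
#'
#' Keeps one representative site per block (Kadanoff decimation): the coarse
#' cell equals the fine kernel at the block's representative position
#' (`offset` within each block, default the first site).
#'
#' @inheritParams bin_renormalize
#' @param offset_space,offset_time 1-based representative position inside
#'   each block.
#' @return the coarse [binary_kernel()] (N1 x T1).
#' @export
decimate <- function(k, bp, policy = "strict", offset_space = 1L,
                     offset_time = 1L) {
  if (offset_space < 1L || offset_space > bp$N2)
    stop("offset_space outside the spatial block")
  if (offset_time < 1L || offset_time > bp$T2)
    stop("offset_time outside the temporal block")
  phi <- conform_blocks(phi_matrix(k), bp, policy)
  rows <- (seq_len(bp$N1) - 1L) * bp$N2 + offset_space
  cols <- (seq_len(bp$T1) - 1L) * bp$T2 + offset_time
  binary_kernel(phi[rows, cols, drop = FALSE],
                tau_ms = k$tau_ms * bp$T2, t0_bin = k$t0_bin %/% bp$T2)
}

# ---------------------------------------------------------------------------
# Electrode lattice and electrode kernel
# ---------------------------------------------------------------------------

#' Planar electrode lattice
#'
#' A rectangular grid of recording sites with a boolean mask of active
#' sites. Site centres sit at `(col - 1) * pitch, (row - 1) * pitch` and the
#' listening radius bounds the neuron-to-site assignment.
#'
#' @param grid_shape integer (rows, cols).
#' @param mask logical rows x cols matrix of recording sites (default all
#'   TRUE).
#' @param pitch_um centre-to-centre electrode spacing in micrometres.
#' @param listening_radius_um assignment radius (default half the pitch).
#' @return an object of class `electrode_lattice` with row-major `sites`
#'   (data.frame of row, col, x, y) for the masked sites.
#' @export
electrode_lattice <- function(grid_shape, mask = NULL, pitch_um = 400,
                              listening_radius_um = pitch_um / 2) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask)) mask <- matrix(TRUE, grid_shape[1L], grid_shape[2L])
  if (!all(dim(mask) == grid_shape)) stop("mask shape must match grid_shape")
  rc <- which(t(mask), arr.ind = TRUE)      # row-major order over sites
  sites <- data.frame(row = rc[, 2L], col = rc[, 1L])
  sites$x <- (sites$col - 1) * pitch_um
  sites$y <- (sites$row - 1) * pitch_um
  structure(list(grid_shape = grid_shape, mask = mask, pitch_um = pitch_um,
                 listening_radius_um = listening_radius_um, sites = sites,
                 n_sites = nrow(sites)),
            class = "electrode_lattice")
}

#' @export
print.electrode_lattice <- function(x, ...) {
  cat(sprintf(
    "electrode lattice %d x %d, pitch %g um: %d recording sites\n",
    x$grid_shape[1L], x$grid_shape[2L], x$pitch_um, x$n_sites))
  invisible(x)
}

#' The Utah-96 lattice
#'
#' 10 x 10 grid with the four corner sites silent, leaving 96 recording
#' channels; 0.4 mm pitch.
#'
#' @inheritParams electrode_lattice
#' @return an [electrode_lattice()] with 96 sites.
#' @export
utah96_lattice <- function(pitch_um = 400,
                           listening_radius_um = pitch_um / 2) {
  mask <- matrix(TRUE, 10L, 10L)
  mask[cbind(c(1L, 1L, 10L, 10L), c(1L, 10L, 1L, 10L))] <- FALSE
  electrode_lattice(c(10L, 10L), mask, pitch_um, listening_radius_um)
}

#' Assign neurons to lattice sites
#'
#' Each neuron is assigned to the nearest active site centre within the
#' listening radius, or to none.
#'
#' @param neuron_positions N x 2 matrix of (x, y) positions in micrometres.
#' @param lattice an [electrode_lattice()].
#' @return integer vector of site indices (row-major over active sites),
#'   NA for unassigned neurons.
#' @export
assign_neurons <- function(neuron_positions, lattice) {
  pos <- as.matrix(neuron_positions)
  if (ncol(pos) != 2L) stop("neuron_positions must be N x 2")
  sx <- lattice$sites$x
  sy <- lattice$sites$y
  vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (sx - pos[i, 1L])^2 + (sy - pos[i, 2L])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= lattice$listening_radius_um) j else NA_integer_
  }, integer(1L))
}

#' Electrode (decimated) kernel of a raster
#'
#' Builds the per-site on/off kernel: a site is active in bin alpha iff any
#' neuron assigned to its listening volume fires in that bin. Output rows
#' follow the lattice's row-major site order.
#'
#' @param raster a binary kernel of the underlying neurons.
#' @param neuron_positions N x 2 positions (micrometres), or an integer
#'   vector of precomputed site assignments (NA = outside).
#' @param lattice an [electrode_lattice()].
#' @param outside `"error"` to fail on unassigned neurons, `"drop"` to
#'   silently ignore them.
#' @return a [binary_kernel()] with one row per recording site.
#' @export
electrode_kernel <- function(raster, neuron_positions, lattice,
                             outside = c("error", "drop")) {
  outside <- match.arg(outside)
  phi <- phi_matrix(raster)
  assign <- if (is.matrix(neuron_positions) ||
                is.data.frame(neuron_positions))
    assign_neurons(neuron_positions, lattice) else
      as.integer(neuron_positions)
  if (length(assign) != nrow(phi))
    stop("one position/assignment per raster row required")
  if (anyNA(assign) && outside == "error")
    stop(sum(is.na(assign)),
         " neuron(s) fall outside every listening volume")
  keep <- !is.na(assign)
  out <- matrix(0L, lattice$n_sites, ncol(phi))
  if (any(keep)) {
    agg <- rowsum(phi[keep, , drop = FALSE], assign[keep])
    out[as.integer(rownames(agg)), ] <- (agg > 0) * 1L
  }
  binary_kernel(out, tau_ms = raster$tau_ms, t0_bin = raster$t0_bin,
                neuron_labels = sprintf("site_r%dc%d", lattice$sites$row,
                                        lattice$sites$col))
}

# ---------------------------------------------------------------------------
# Effective couplings of the renormalized action
# ---------------------------------------------------------------------------

# Per-configuration block sums of the action terms over a partition:
# A_arr[i1, j1, a1] = sum over the block of A_ij * phi_ia * phi_ja,
# B_arr[i1, a1, b1] = sum over the block of B_ab * phi_ia * phi_ib,
# coarse = any-spike indicator kernel.
block_action_sums <- function(phi, p, bp) {
  gN <- rep(seq_len(bp$N1), each = bp$N2)
  gT <- rep(seq_len(bp$T1), each = bp$T2)
  A_arr <- array(0, c(bp$N1, bp$N1, bp$T1))
  for (a1 in seq_len(bp$T1)) {
    cols <- which(gT == a1)
    P <- tcrossprod(phi[, cols, drop = FALSE])
    M <- p$A * P
    A_arr[, , a1] <- t(rowsum(t(rowsum(M, gN)), gN))
  }
  B_arr <- array(0, c(bp$N1, bp$T1, bp$T1))
  for (i1 in seq_len(bp$N1)) {
    rows <- which(gN == i1)
    G <- crossprod(phi[rows, , drop = FALSE])
    M <- p$B * G
    B_arr[i1, , ] <- t(rowsum(t(rowsum(M, gT)), gT))
  }
  counts <- t(rowsum(t(rowsum(phi, gN)), gT))
  list(A_arr = A_arr, B_arr = B_arr, coarse = (counts > 0) * 1L)
}

coarse_key <- function(coarse) paste(as.vector(coarse), collapse = "")

#' Effective couplings of the bin-renormalized action
#'
#' For each supplied (or enumerated) fine configuration, computes the
#' per-block coupling sums entering the renormalized action, splits them
#' into a stationary part (the renormalized matrices `a_hat`, `b_hat`) and
#' per-configuration fluctuations, and, in enumeration mode, the exact
#' log-sum perturbation of the coarse action. The stationary part is the
#' mean of the block sums over the cells where the coarse product is 1 (the
#' entries that actually enter the action), which makes `a_hat = A` and
#' `b_hat = B` exact for 1 x 1 blocks.
#'
#' In enumeration mode the renormalized theory is exact:
#' `G(A, B) = sum over coarse kernels of
#'  exp(-lam * action(coarse | a_hat, b_hat) - lam * delta_action(coarse))`.
#'
#' @param p binary-representation [action_params()].
#' @param bp a [block_partition()] factorising (N, T).
#' @param samples optional list of binary kernels (or 0/1 matrices) from
#'   which the stationary couplings are estimated.
#' @param enumerate if TRUE (requires N * T <= cap), enumerate all fine
#'   kernels: stationary couplings use all configurations and the exact
#'   per-coarse-configuration perturbation `delta_action` is returned.
#' @param cap enumeration cap on N * T.
#' @return an object of class `effective_couplings` with `a_hat` (N1 x N1),
#'   `b_hat` (T1 x T1), `fluctuations` (per configuration: arrays `dA`,
#'   `dB`, the coarse kernel), and in enumeration mode `delta_action`
#'   (named by coarse-configuration key).
#' @export
effective_couplings <- function(p, bp, samples = NULL, enumerate = FALSE,
                                cap = 20L) {
  if (p$representation != "binary")
    stop("effective couplings are defined for the binary representation")
  if (bp$N1 * bp$N2 != p$N || bp$T1 * bp$T2 != p$T)
    stop("partition does not factorise the parameter dimensions")
  if (enumerate) {
    L <- p$N * p$T
    if (L > cap) stop("enumeration cap exceeded: N*T = ", L, " > ", cap)
    S <- enumerate_states(L, c(0, 1))
    configs <- lapply(seq_len(nrow(S)), function(r) matrix(S[r, ], p$N, p$T))
  } else {
    if (is.null(samples) || length(samples) == 0L)
      stop("supply samples or set enumerate = TRUE")
    configs <- lapply(samples, function(k)
      if (inherits(k, "spike_kernel")) phi_matrix(k) else as.matrix(k))
  }
  sums <- lapply(configs, block_action_sums, p = p, bp = bp)

  # stationary parts: conditional means over cells with coarse product 1
  accA <- matrix(0, bp$N1, bp$N1); cntA <- matrix(0, bp$N1, bp$N1)
  accB <- matrix(0, bp$T1, bp$T1); cntB <- matrix(0, bp$T1, bp$T1)
  allA <- matrix(0, bp$N1, bp$N1); allB <- matrix(0, bp$T1, bp$T1)
  nA <- 0
  for (s in sums) {
    ck <- s$coarse
    for (a1 in seq_len(bp$T1)) {
      w <- tcrossprod(ck[, a1])
      accA <- accA + s$A_arr[, , a1] * w
      cntA <- cntA + w
      allA <- allA + s$A_arr[, , a1]
    }
    for (i1 in seq_len(bp$N1)) {
      w <- tcrossprod(ck[i1, ])
      accB <- accB + s$B_arr[i1, , ] * w
      cntB <- cntB + w
      allB <- allB + s$B_arr[i1, , ]
    }
    nA <- nA + 1
  }
  a_hat <- ifelse(cntA > 0, accA / pmax(cntA, 1),
                  allA / (nA * bp$T1))
  b_hat <- ifelse(cntB > 0, accB / pmax(cntB, 1),
                  allB / (nA * bp$N1))

  fluct <- lapply(sums, function(s) {
    dA <- s$A_arr - array(a_hat, dim(s$A_arr))
    dB <- s$B_arr
    for (i1 in seq_len(bp$N1)) dB[i1, , ] <- dB[i1, , ] - b_hat
    list(dA = dA, dB = dB, coarse = s$coarse)
  })

  out <- list(a_hat = a_hat, b_hat = b_hat, fluctuations = fluct,
              partition = bp)
  if (enumerate) {
    # Gamma(fine, coarse) = sum dA * coarse outer products + dB likewise;
    # delta_action(coarse) = -log sum exp(-lam Gamma) / lam over the fibre
    gamma_vals <- vapply(fluct, function(fl) {
      g <- 0
      for (a1 in seq_len(bp$T1))
        g <- g + sum(fl$dA[, , a1] * tcrossprod(fl$coarse[, a1]))
      for (i1 in seq_len(bp$N1))
        g <- g + sum(fl$dB[i1, , ] * tcrossprod(fl$coarse[i1, ]))
      g
    }, numeric(1L))
    keys <- vapply(fluct, function(fl) coarse_key(fl$coarse), character(1L))
    delta <- tapply(gamma_vals, keys, function(g)
      -log_sum_exp(-p$lam * g) / p$lam)
    out$delta_action <- delta
  }
  structure(out, class = "effective_couplings")
}

#' @export
print.effective_couplings <- function(x, ...) {
  cat(sprintf(
    "effective couplings: %d x %d spatial blocks, %d x %d temporal blocks (%d configs)\n",
    x$partition$N1, x$partition$N2, x$partition$T1, x$partition$T2,
    length(x$fluctuations)))
  invisible(x)
}
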