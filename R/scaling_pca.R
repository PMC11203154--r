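# ---------------------------------------------------------------------------
# Coupling-distribution scaling with population size, and the PCA action.
#
# Pairwise couplings are modelled as a stationary plus a fluctuating
# Gaussian term carried by a binary axonal adjacency matrix Lambda, both
# divided by the mean connectivity g(Lambda). With g = N^alpha the entry
# standard deviation scales as N^(-alpha): alpha = 1 is the
# Sherrington-Kirkpatrick-style normalisation, alpha = 1/2 the sub-linear
# regime reported for retinal couplings.
# ---------------------------------------------------------------------------

#' Connectivity model for coupling generation
#'
#' @param N number of neurons (>= 2).
#' @param alpha connectivity exponent: mean connectivity g = N^alpha.
#' @param axon_matrix optional symmetric binary Lambda (zero diagonal);
#'   default fully connected. When supplied, `g` is computed from it as
#'   `sum(Lambda) / N` unless `use_exponent` is TRUE.
#' @param J0_scale standard deviation of the stationary Gaussian J0.
#' @param use_exponent force `g = N^alpha` even with an explicit Lambda.
#' @param stationary_per_pair resample the stationary J0 per pair instead of
#'   once per matrix (the stationary reading keeps one draw per matrix).
#' @return an object of class `connectivity_model`.
#' @export
connectivity_model <- function(N, alpha = 0.5, axon_matrix = NULL,
                               J0_scale = 1, use_exponent = is.null(axon_matrix),
                               stationary_per_pair = FALSE) {
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2")
  use_exponent <- use_exponent   # force before axon_matrix is defaulted
  if (is.null(axon_matrix)) {
    axon_matrix <- matrix(1L, N, N)
    diag(axon_matrix) <- 0L
  }
  axon_matrix <- as.matrix(axon_matrix)
  if (!all(dim(axon_matrix) == N)) stop("axon matrix must be N x N")
  if (!all(axon_matrix %in% c(0L, 1L))) stop("axon matrix must be binary")
  if (any(axon_matrix != t(axon_matrix))) stop("axon matrix must be symmetric")
  if (any(diag(axon_matrix) != 0)) stop("axon matrix must have zero diagonal")
  g <- if (use_exponent) N^alpha else sum(axon_matrix) / N
  if (g == 0) stop("empty connectivity: g(Lambda) = 0")
  structure(list(N = N, alpha = alpha, axon_matrix = axon_matrix, g = g,
                 J0_scale = J0_scale,
                 stationary_per_pair = stationary_per_pair),
            class = "connectivity_model")
}

#' Generate a coupling matrix from a connectivity model
#'
#' Draws `A_ij = (J0 + J_ij) * Lambda_ij / g` with J0 (stationary) and J_ij
#' (fluctuating, symmetric) standard Gaussians, so the entry standard
#' deviation on the connected support is `1/g = N^(-alpha)` in the exponent
#' regime.
#'
#' @param model a [connectivity_model()].
#' @param seed integer seed (mandatory).
#' @return symmetric N x N coupling matrix with zero diagonal.
#' @export
generate_couplings <- function(model, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  N <- model$N
  J0 <- if (model$stationary_per_pair) {
    m <- matrix(rnorm(N * N, sd = model$J0_scale), N, N)
    (m + t(m)) / sqrt(2)
  } else rnorm(1L, sd = model$J0_scale)
  Jf <- matrix(rnorm(N * N), N, N)
  Jf <- (Jf + t(Jf)) / sqrt(2)
  A <- (J0 + Jf) * model$axon_matrix / model$g
  diag(A) <- 0
  A
}

#' Fit the coupling-variance scaling exponent
#'
#' Given coupling samples at several population sizes, fits the entry
#' distribution at each N (Gaussian maximum likelihood and raw first two
#' moments) and regresses log standard deviation on log N: the scaling
#' exponent estimate is minus the slope. Gaussianity is summarised by the
#' excess kurtosis per N.
#'
#' @param coupling_samples named list: names are the N values, elements are
#'   numeric vectors of coupling entries pooled at that N.
#' @return an object of class `scaling_fit` with `exponent_hat`, `stderr`,
#'   per-N `table` (sd_ml, sd_moment, excess_kurtosis) and the `fit` lm.
#' @export
scaling_fit <- function(coupling_samples) {
  if (length(coupling_samples) < 3L)
    stop("need at least 3 distinct N values")
  Ns <- as.numeric(names(coupling_samples))
  if (anyNA(Ns)) stop("list names must be the N values")
  tab <- do.call(rbind, lapply(seq_along(Ns), function(j) {
    v <- coupling_samples[[j]]
    if (sd(v) == 0) stop("degenerate (constant) samples at N = ", Ns[j])
    n <- length(v)
    sd_ml <- sqrt(mean((v - mean(v))^2))   # Gaussian ML
    z <- (v - mean(v)) / sd_ml
    data.frame(N = Ns[j], sd_ml = sd_ml, sd_moment = sd(v),
               excess_kurtosis = mean(z^4) - 3)
  }))
  fit <- lm(log(sd_ml) ~ log(N), data = tab)
  fit_mom <- lm(log(sd_moment) ~ log(N), data = tab)
  s <- summary(fit)$coefficients
  structure(list(exponent_hat = -unname(coef(fit)[2L]),
                 stderr = unname(s["log(N)", "Std. Error"]),
                 exponent_hat_moment = -unname(coef(fit_mom)[2L]),
                 table = tab, fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "scaling fit over %d sizes: alpha_hat = %.4f +/- %.4f (moments: %.4f)\n",
    nrow(x$table), x$exponent_hat, x$stderr, x$exponent_hat_moment))
  invisible(x)
}

#' Simulate and fit coupling scaling in one call
#'
#' Generates `reps` coupling matrices at each size with the stated exponent
#' and refits it; used by the acceptance checks.
#'
#' @param sizes vector of N values (>= 3 of them).
#' @param alpha true exponent used for generation.
#' @param reps replicate matrices per size.
#' @param seed base seed; replicate r at size j uses `seed + 1000*j + r`.
#' @return a [scaling_fit()].
#' @export
scaling_recovery <- function(sizes, alpha = 0.5, reps = 50L, seed = 1L) {
  samples <- lapply(seq_along(sizes), function(j) {
    model <- connectivity_model(sizes[j], alpha = alpha)
    unlist(lapply(seq_len(reps), function(r) {
      A <- generate_couplings(model, seed = seed + 1000L * j + r)
      A[upper.tri(A)]
    }))
  })
  names(samples) <- sizes
  scaling_fit(samples)
}

# ---------------------------------------------------------------------------
# PCA as a purely potential lattice action
# ---------------------------------------------------------------------------

#' PCA of a kernel as a lattice action
#'
#' The rank-n PCA of the kernel minimises the Frobenius discrepancy between
#' the kernel and its projection onto an n-dimensional subspace; the
#' minimiser Y collects the top-n eigenvectors of Omega Omega', the
#' associated action value is `-Tr(Y' Omega Omega' Y)` (minus the top-n
#' eigenvalue sum) and the induced pairwise potential is `A = -Y Y'`
#' (symmetric, rank <= n, trace -n). The Frobenius objective differs from
#' the action by the constant `Tr(Omega' Omega)`.
#'
#' Time-domain PCA (the purely kinetic dual) is obtained by transposing the
#' kernel with `domain = "time"`.
#'
#' @param k a binary kernel.
#' @param n_components number of components, 1 <= n <= N (or T in the time
#'   domain).
#' @param domain `"space"` (default) or `"time"`.
#' @return list with `basis` (columns = eigenvectors), `eigenvalues` (all),
#'   `action_value`, `objective` (Frobenius discrepancy) and
#'   `induced_couplings`.
#' @export
pca_action <- function(k, n_components, domain = c("space", "time")) {
  domain <- match.arg(domain)
  X <- phi_matrix(k)
  if (domain == "time") X <- t(X)
  n_max <- nrow(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > n_max)
    stop("n_components must lie in 1..", n_max)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  # deterministic sign: first nonzero component of each eigenvector positive
  Y <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(Y))) {
    nz <- which(abs(Y[, j]) > 1e-12)[1L]
    if (!is.na(nz) && Y[nz, j] < 0) Y[, j] <- -Y[, j]
  }
  action <- -sum(eg$values[seq_len(n_components)])
  list(basis = Y, eigenvalues = eg$values, action_value = action,
       objective = sum(diag(crossprod(X))) + action,
       induced_couplings = -tcrossprod(Y))
}
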