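# ---------------------------------------------------------------------------
# The lattice action
#
# A(X | A, B, I) = sum_ij A_ij sum_a X_ia X_ja      (potential, equal time)
#                + sum_ab B_ab sum_i X_ia X_ib      (kinetic, cross time)
#                - sum_ia I_ia X_ia                 (external input)
#
# The input enters with a minus sign so that a positive input favours
# activity under the Gibbs weight exp(-lambda * A): this is the convention
# under which the input partition function factorises into 2cosh(lam*I)
# terms and the Callen inversion reads lam*I = atanh(m).
#
# with X the kernel matrix in the representation declared by the parameters
# (binary phi in {0,1} or spin sigma in {-1,+1}). Causality requires the
# kinetic matrix B to couple each time alpha only to strictly earlier bins
# beta < alpha; B is stored full T x T and validated to have nonzeros only
# at [alpha, beta] with beta < alpha.  The Gibbs weight is exp(-lambda * A)
# with lambda the inverse Planck constant.
# ---------------------------------------------------------------------------

#' Parameters of the lattice action
#'
#' Bundles the potential matrix A (N x N), the kinetic matrix B (T x T,
#' causal: nonzero only where the column/time index is strictly smaller than
#' the row index), the input kernel I (N x T), the inverse Planck constant
#' `lam` and the representation the action is evaluated in.
#'
#' @param A potential matrix (N x N), or NULL for zero.
#' @param B kinetic matrix (T x T), or NULL for zero.
#' @param I input kernel (N x T), or NULL for zero.
#' @param lam positive inverse Planck constant (temperature-like).
#' @param representation `"binary"` or `"spin"`.
#' @param N,T dimensions; required only when the corresponding matrices are
#'   NULL and cannot be inferred.
#' @return an object of class `action_parameters`.
#' @export
action_params <- function(A = NULL, B = NULL, I = NULL, lam = 1,
                          representation = c("binary", "spin"),
                          N = NULL, T = NULL) {
  representation <- match.arg(representation)
  if (is.null(N)) N <- if (!is.null(A)) nrow(A) else if (!is.null(I)) nrow(I)
    else stop("cannot infer N: supply A, I or N")
  if (is.null(T)) T <- if (!is.null(B)) nrow(B) else if (!is.null(I)) ncol(I)
    else stop("cannot infer T: supply B, I or T")
  if (is.null(A)) A <- matrix(0, N, N)
  if (is.null(B)) B <- matrix(0, T, T)
  if (is.null(I)) I <- matrix(0, N, T)
  A <- as.matrix(A); B <- as.matrix(B); I <- as.matrix(I)
  if (!all(dim(A) == c(N, N))) stop("A must be N x N")
  if (!all(dim(B) == c(T, T))) stop("B must be T x T")
  if (!all(dim(I) == c(N, T))) stop("I must be N x T")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("lam must be a positive finite scalar")
  if (any(B[upper.tri(B, diag = TRUE)] != 0))
    stop("non-causal B: entries allowed only for time pairs beta < alpha")
  structure(list(A = A, B = B, I = I, lam = lam,
                 representation = representation, N = N, T = T),
            class = "action_parameters")
}

#' @export
print.action_parameters <- function(x, ...) {
  cat(sprintf(
    "action parameters (%s): N = %d, T = %d, lambda = %g | nonzero A %d, B %d, I %d\n",
    x$representation, x$N, x$T, x$lam,
    sum(x$A != 0), sum(x$B != 0), sum(x$I != 0)))
  invisible(x)
}

kernel_state_matrix <- function(k, p) {
  X <- if (p$representation == "binary") phi_matrix(k) else sigma_matrix(k)
  if (nrow(X) != p$N || ncol(X) != p$T)
    stop("dimension mismatch between kernel and action parameters")
  X
}

#' Evaluate the lattice action on a kernel
#'
#' @param k a kernel (converted to the representation of `p`).
#' @param p [action_params()].
#' @return scalar action value.
#' @examples
#' p <- action_params(A = matrix(1, 1, 1), lam = 1, T = 1,
#'                    representation = "binary")
#' action_value(binary_kernel(matrix(1, 1, 1)), p)  # = 1
#' @export
action_value <- function(k, p) {
  X <- kernel_state_matrix(k, p)
  sum(p$A * tcrossprod(X)) + sum(p$B * crossprod(X)) - sum(p$I * X)
}

#' Transform binary action parameters to the spin representation
#'
#' Substituting phi = (sigma + 1)/2 into the binary action gives a spin
#' action with rescaled couplings A/4 and B/4, an adjusted input, and an
#' additive constant:
#' `action_value(k, p_binary) = action_value(k, spin$params) + spin$constant`
#' for every kernel `k`.
#'
#' @param p binary-representation [action_params()].
#' @return list with `params` (spin representation) and `constant`.
#' @export
spin_parameters <- function(p) {
  if (p$representation != "binary")
    stop("spin_parameters expects binary-representation parameters")
  A_t <- p$A / 4
  B_t <- p$B / 4
  rowA <- rowSums(p$A + t(p$A)) / 4         # length N
  colB <- rowSums(p$B + t(p$B)) / 4         # length T
  I_t <- p$I / 2 - matrix(rowA, p$N, p$T) -
    matrix(colB, p$N, p$T, byrow = TRUE)
  const <- p$T * sum(p$A) / 4 + p$N * sum(p$B) / 4 - sum(p$I) / 2
  list(params = action_params(A_t, B_t, I_t, p$lam, "spin"),
       constant = const)
}

#' Offset-induced currents of the centred-field formulation
#'
#' When the action is written for the centred field psi = phi - offset, any
#' asymmetry of A and B generates effective one-body currents proportional
#' to the offset.
#'
#' @param p [action_params()].
#' @param offset global kernel offset (grand mean of the binary kernel).
#' @return list with `I_space` (length N) and `I_time` (length T).
#' @export
derived_currents <- function(p, offset) {
  list(I_space = offset * rowSums(p$A - t(p$A)),
       I_time = offset * rowSums(p$B - t(p$B)))
}

# ---------------------------------------------------------------------------
# Lagrangian split and the pulse kernel
# ---------------------------------------------------------------------------

#' Potential/kinetic Lagrangian split at one time bin
#'
#' At time alpha the potential term is H(alpha) = sum_ij A_ij s_ia s_ja and
#' the kinetic term K(alpha) = -N sum_{beta < alpha} B_ab q_ab with q the
#' overlap between time slices; the Lagrangian is L(alpha) = -H + K.  The
#' action (with zero input) is recovered as minus the summed Lagrangian,
#' `action_value = sum_alpha (H - K)`; see [action_from_lagrangian()].  For
#' the nearest-step kinetic matrix `B[alpha, alpha-1] = -B0` the kinetic term
#' is `K(alpha) = B0 * N * q_{alpha, alpha-1}`.
#'
#' @param k a kernel (used in spin form).
#' @param p spin-representation [action_params()]; B must be causal.
#' @param alpha time index in 1..T.
#' @return list with `potential` (H), `kinetic` (K) and `lagrangian` (-H + K).
#' @export
lagrangian_split <- function(k, p, alpha) {
  sig <- sigma_matrix(k)
  if (nrow(sig) != p$N || ncol(sig) != p$T)
    stop("dimension mismatch between kernel and action parameters")
  alpha <- as.integer(alpha)
  if (alpha < 1L || alpha > p$T) stop("alpha out of range")
  s_a <- sig[, alpha]
  H <- drop(crossprod(s_a, p$A %*% s_a))
  K <- 0
  if (alpha > 1L) {
    beta <- seq_len(alpha - 1L)
    overlaps <- as.vector(crossprod(sig[, beta, drop = FALSE], s_a)) # N*q
    K <- -sum(p$B[alpha, beta] * overlaps)
  }
  list(potential = H, kinetic = K, lagrangian = -H + K)
}

#' Rebuild the action from the Lagrangian
#'
#' Sums `potential - kinetic` over all time bins (equal to minus the summed
#' Lagrangian) and adds the input term; equals [action_value()] in the spin
#' representation.
#'
#' @inheritParams lagrangian_split
#' @return scalar action value.
#' @export
action_from_lagrangian <- function(k, p) {
  tot <- 0
  for (alpha in seq_len(p$T)) {
    ls <- lagrangian_split(k, p, alpha)
    tot <- tot + ls$potential - ls$kinetic
  }
  tot - sum(p$I * sigma_matrix(k))
}

#' Pulse (momentum) kernel
#'
#' Time difference of the spin kernel along each row:
#' `dsigma[i, alpha] = sigma[i, alpha] - sigma[i, alpha - 1]`, with the first
#' column zero by convention. Entries lie in {-2, 0, 2}, and the squared
#' norm of column alpha satisfies
#' `||dsigma_alpha||^2 = 2 * N * (1 - q_{alpha, alpha-1})`.
#'
#' @param k a kernel with at least two time bins.
#' @return an N x T integer matrix of class `pulse_kernel`.
#' @export
pulse_kernel <- function(k) {
  sig <- sigma_matrix(k)
  if (ncol(sig) < 2L) stop("pulse kernel requires at least two time bins")
  d <- cbind(0L, sig[, -1L, drop = FALSE] - sig[, -ncol(sig), drop = FALSE])
  structure(d, class = c("pulse_kernel", class(d)))
}

# ---------------------------------------------------------------------------
# Grand (mixed-space) coupling form of the action
# ---------------------------------------------------------------------------

#' Mixed-space quadratic form of the action
#'
#' Flattens the action into the grand index l = (alpha - 1) * N + i:
#' `A(X) = 0.5 * s' W s + c' s` with `W = kron(diag(T), A + A') +
#' kron(B + B', diag(N))` and `c = -vec(I)`. Used by the enumeration and
#' Metropolis backends and by the inference tests (the true mixed-space
#' couplings of a model are `-lam * W` off-diagonal under the inverse-Ising
#' sign convention).
#'
#' @param p [action_params()].
#' @return list with symmetric `W` (L x L), field `c` (length L) and `L`.
#' @export
grand_coupling <- function(p) {
  W <- kronecker(diag(p$T), p$A + t(p$A)) +
    kronecker(p$B + t(p$B), diag(p$N))
  list(W = W, c = -as.vector(p$I), L = p$N * p$T)
}

# All states of L binary sites as a (2^L x L) matrix with entries in
# `levels` (c(0,1) or c(-1,1)).
enumerate_states <- function(L, levels = c(0, 1)) {
  n <- 2^L
  if (n > 2^21) stop("enumeration of ", L, " sites is too large")
  idx <- 0:(n - 1)
  bits <- vapply(seq_len(L), function(j) idx %/% 2^(j - 1) %% 2,
                 numeric(n))
  matrix(levels[bits + 1], nrow = n, ncol = L)
}

# action values for all rows of a state matrix S (states in the
# representation of p, grand order)
state_actions <- function(S, p) {
  gc <- grand_coupling(p)
  0.5 * rowSums((S %*% gc$W) * S) + as.vector(S %*% gc$c)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# ---------------------------------------------------------------------------
# Partition function, Gibbs averages, sampling
# ---------------------------------------------------------------------------

#' Partition function and free action
#'
#' Computes `log G = log sum_X exp(-lam * A(X))` over all kernels in the
#' declared representation, either by exact enumeration (requires
#' `N * T <= cap`) or by thermodynamic integration over lambda with
#' Metropolis estimates of the mean action (`mode = "mcmc"`). The free
#' action is `Psi = -log(G) / lam`.
#'
#' @param p [action_params()].
#' @param mode `"enumeration"` or `"mcmc"`.
#' @param cap enumeration cap on N * T (default 20).
#' @param seed integer seed, mandatory for `"mcmc"`.
#' @param n_grid lambda-grid size for thermodynamic integration.
#' @param sweeps Metropolis sweeps per grid point used for the mean-action
#'   estimate (after `burnin` sweeps).
#' @param burnin burn-in sweeps per grid point.
#' @return an object of class `gibbs_state` with `log_partition`,
#'   `free_action`, `mode` and (mcmc) `mc_stderr`.
#' @export
partition_function <- function(p, mode = c("enumeration", "mcmc"),
                               cap = 20L, seed = NULL, n_grid = 21L,
                               sweeps = 500L, burnin = 1000L) {
  mode <- match.arg(mode)
  L <- p$N * p$T
  if (mode == "enumeration") {
    if (L > cap)
      stop("enumeration cap exceeded: N*T = ", L, " > ", cap)
    levels <- if (p$representation == "binary") c(0, 1) else c(-1, 1)
    S <- enumerate_states(L, levels)
    acts <- state_actions(S, p)
    logG <- log_sum_exp(-p$lam * acts)
    return(structure(list(log_partition = logG,
                          free_action = -logG / p$lam,
                          mode = mode, mc_stderr = 0),
                     class = "gibbs_state"))
  }
  if (is.null(seed)) stop("seed is mandatory for mcmc mode")
  # spin-representation thermodynamic integration:
  # log G(lam) = L log 2 - integral_0^lam <A>_u du
  sp <- if (p$representation == "binary") spin_parameters(p) else
    list(params = p, constant = 0)
  gc <- grand_coupling(sp$params)
  lam_grid <- seq(0, p$lam, length.out = n_grid)
  mean_a <- se_a <- numeric(n_grid)
  init <- sample_init_state(L, seed)
  for (g in seq_along(lam_grid)) {
    samp <- metropolis_sample_cpp(gc$W, gc$c, lam_grid[g], sweeps, burnin,
                                  1L, seed + g, init)
    acts <- 0.5 * rowSums((samp %*% gc$W) * samp) + as.vector(samp %*% gc$c)
    mean_a[g] <- mean(acts)
    se_a[g] <- sd(acts) / sqrt(effective_sample_size(acts))
    init <- samp[nrow(samp), ]
  }
  h <- diff(lam_grid)
  integral <- sum(h * (head(mean_a, -1) + tail(mean_a, -1)) / 2)
  int_se <- sqrt(sum((h * (head(se_a, -1) + tail(se_a, -1)) / 2)^2))
  logG_spin <- L * log(2) - integral
  logG <- logG_spin - p$lam * sp$constant
  structure(list(log_partition = logG, free_action = -logG / p$lam,
                 mode = mode, mc_stderr = int_se),
            class = "gibbs_state")
}

#' @export
print.gibbs_state <- function(x, ...) {
  cat(sprintf("Gibbs state (%s): log G = %.6f, free action Psi = %.6f",
              x$mode, x$log_partition, x$free_action))
  if (x$mode == "mcmc") cat(sprintf(" (mc stderr %.2g)", x$mc_stderr))
  cat("\n")
  invisible(x)
}

sample_init_state <- function(L, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample(c(-1L, 1L), L, replace = TRUE)
}

# crude autocorrelation-based effective sample size
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  acf_vals <- stats::acf(x, lag.max = min(100L, n - 1L),
                         plot = FALSE)$acf[-1L]
  pos <- acf_vals[acf_vals > 0.05]
  max(1, n / (1 + 2 * sum(pos)))
}

#' Gibbs (WGL) average of an observable
#'
#' Computes the expectation of `observable(X)` under the Gibbs measure
#' `exp(-lam * A(X)) / G`, with `X` the N x T kernel matrix in the
#' representation of `p`. Enumeration mode is exact; mcmc mode uses
#' single-site Metropolis with random scan and reports a standard error
#' based on the effective sample size.
#'
#' @param observable function taking an N x T matrix and returning a scalar.
#' @param p [action_params()].
#' @param mode `"enumeration"` or `"mcmc"`.
#' @param cap enumeration cap on N * T.
#' @param seed mandatory for mcmc.
#' @param n_samples,burnin,thin Metropolis controls (sweeps).
#' @return list with `value`, `stderr` (0 for enumeration) and `ess`.
#' @export
gibbs_average <- function(observable, p, mode = c("enumeration", "mcmc"),
                          cap = 20L, seed = NULL, n_samples = 2000L,
                          burnin = 1000L, thin = 1L) {
  mode <- match.arg(mode)
  L <- p$N * p$T
  if (mode == "enumeration") {
    if (L > cap) stop("enumeration cap exceeded: N*T = ", L, " > ", cap)
    levels <- if (p$representation == "binary") c(0, 1) else c(-1, 1)
    S <- enumerate_states(L, levels)
    acts <- state_actions(S, p)
    w <- exp(-p$lam * (acts - min(acts)))
    w <- w / sum(w)
    vals <- apply(S, 1L, function(s) {
      v <- observable(matrix(s, p$N, p$T))
      if (!is.finite(v)) stop("non-finite observable value")
      v
    })
    return(list(value = sum(w * vals), stderr = 0, ess = Inf))
  }
  if (is.null(seed)) stop("seed is mandatory for mcmc mode")
  samp <- sample_gibbs_states(p, n_samples, seed, burnin = burnin,
                              thin = thin)
  vals <- apply(samp, 1L, function(s) observable(matrix(s, p$N, p$T)))
  if (any(!is.finite(vals))) stop("non-finite observable value")
  ess <- effective_sample_size(vals)
  list(value = mean(vals), stderr = sd(vals) / sqrt(ess), ess = ess)
}

# Draw Metropolis samples of kernel states (rows = states in grand order,
# in the representation of p).
sample_gibbs_states <- function(p, n_samples, seed, burnin = 1000L,
                                thin = 1L) {
  sp <- if (p$representation == "binary") spin_parameters(p) else
    list(params = p, constant = 0)
  gc <- grand_coupling(sp$params)
  init <- sample_init_state(gc$L, seed)
  samp <- metropolis_sample_cpp(gc$W, gc$c, p$lam, n_samples, burnin,
                                thin, seed + 1L, init)
  if (p$representation == "binary") (samp + 1L) %/% 2L else samp
}

#' Input partition function
#'
#' For the pure input action `-sum I_ia s_ia` on spins the partition
#' function factorises: `log R(I) = sum_ia log(2 * cosh(lam * I_ia))`.
#'
#' @param I input kernel (N x T matrix).
#' @param lam inverse Planck constant.
#' @return `log R(I)`.
#' @export
input_partition <- function(I, lam = 1) {
  if (!all(is.finite(I))) stop("input kernel must be finite")
  # log(2 cosh(x)) computed stably for large |x|
  x <- abs(lam * I)
  sum(x + log1p(exp(-2 * x)))
}

# ---------------------------------------------------------------------------
# Gibbs variational bound and ground states
# ---------------------------------------------------------------------------

#' Free-action functional of a product test measure
#'
#' For a product measure zeta over spins with P(s_l = +1) = probs[l], the
#' functional `F(zeta) = <A>_zeta + <log zeta>_zeta / lam` upper-bounds the
#' free action Psi for every zeta, with equality at the Gibbs measure
#' (Gibbs variational principle).
#'
#' @param p spin-representation [action_params()] (binary parameters are
#'   transformed internally and the constant added).
#' @param probs per-site probabilities of +1, length N * T, in (0, 1)
#'   (entries of exactly 0/1 are handled by their zero-entropy limit).
#' @return scalar `F(zeta)`.
#' @export
free_action_functional <- function(p, probs) {
  sp <- if (p$representation == "binary") spin_parameters(p) else
    list(params = p, constant = 0)
  gc <- grand_coupling(sp$params)
  if (length(probs) != gc$L) stop("probs must have length N * T")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  m <- 2 * probs - 1
  dW <- diag(gc$W)
  mean_action <- 0.5 * (drop(crossprod(m, gc$W %*% m)) - sum(dW * m^2) +
                          sum(dW)) + sum(gc$c * m)
  ent_terms <- ifelse(probs %in% c(0, 1), 0,
                      probs * log(probs) + (1 - probs) * log(1 - probs))
  mean_action + sp$constant + sum(ent_terms) / p$lam
}

#' Ground-state search (classical limit)
#'
#' The lambda -> infinity limit selects minimisers of the action. Under the
#' enumeration cap the exact minimum is found by exhaustive search;
#' otherwise simulated annealing (Metropolis with an increasing lambda
#' ladder) returns the best state visited.
#'
#' @param p [action_params()].
#' @param cap enumeration cap on N * T.
#' @param seed seed for the annealing fallback.
#' @param lambda_max,n_ladder,sweeps annealing controls.
#' @return list with `state` (N x T matrix in the representation of `p`),
#'   `action`, and `exact` (TRUE if found by enumeration).
#' @export
ground_state <- function(p, cap = 20L, seed = 1L, lambda_max = 50,
                         n_ladder = 25L, sweeps = 200L) {
  L <- p$N * p$T
  if (L <= cap) {
    levels <- if (p$representation == "binary") c(0, 1) else c(-1, 1)
    S <- enumerate_states(L, levels)
    acts <- state_actions(S, p)
    best <- which.min(acts)
    return(list(state = matrix(S[best, ], p$N, p$T), action = acts[best],
                exact = TRUE))
  }
  sp <- if (p$representation == "binary") spin_parameters(p) else
    list(params = p, constant = 0)
  gc <- grand_coupling(sp$params)
  init <- sample_init_state(L, seed)
  best_s <- init
  best_a <- Inf
  lams <- seq(0.1, lambda_max, length.out = n_ladder)
  for (g in seq_along(lams)) {
    samp <- metropolis_sample_cpp(gc$W, gc$c, lams[g], sweeps, 0L, 1L,
                                  seed + g, init)
    acts <- 0.5 * rowSums((samp %*% gc$W) * samp) +
      as.vector(samp %*% gc$c)
    i <- which.min(acts)
    if (acts[i] < best_a) {
      best_a <- acts[i]
      best_s <- samp[i, ]
    }
    init <- samp[nrow(samp), ]
  }
  state <- if (p$representation == "binary") (best_s + 1L) %/% 2L else best_s
  list(state = matrix(state, p$N, p$T),
       action = best_a + sp$constant, exact = FALSE)
}
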