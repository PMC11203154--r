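# ---------------------------------------------------------------------------
# Inverse-Ising reconstruction of fields and couplings from measured means
# and covariances over the mixed (neuron, time) index.
#
# Sign convention: the reconstructed couplings F are those of the standard
# inverse-Ising literature, i.e. a Gibbs weight exp(sum_{l<l'} F_ll' s_l s_l'
# + sum_l h_l s_l). Under the package's action convention exp(-lam * A) with
# A = 0.5 s'Ws + c's, the true mixed-space couplings are F = -lam * W
# (off-diagonal) and h = -lam * c. All reconstructed coupling matrices are
# symmetric with zero diagonal; self-interaction is absorbed into fields.
# ---------------------------------------------------------------------------

#' Grand covariance over the mixed space
#'
#' Estimates means and the L x L covariance `C_ll' = <s_l s_l'> - <s_l><s_l'>`
#' from spin samples. Samples can be a list of kernels (or matrices) or a
#' matrix with one flattened state per row (grand order, column-major over
#' the N x T kernel).
#'
#' @param samples list of kernels/matrices, or an n x L matrix of spin states.
#' @param N,T kernel dimensions (required when `samples` is a flat matrix
#'   whose shape cannot be inferred; otherwise taken from the first kernel).
#' @param symmetrize average the empirical covariance with its transpose
#'   (exactly symmetric estimators are unaffected).
#' @return an object of class `grand_covariance` with `values` (L x L),
#'   `means` (length L), `n_samples`, `N`, `T`.
#' @export
grand_covariance <- function(samples, N = NULL, T = NULL,
                             symmetrize = TRUE) {
  if (is.list(samples)) {
    first <- samples[[1L]]
    mat <- if (inherits(first, "spike_kernel")) sigma_matrix(first) else
      as.matrix(first)
    N <- nrow(mat); T <- ncol(mat)
    flat <- t(vapply(samples, function(k) {
      m <- if (inherits(k, "spike_kernel")) sigma_matrix(k) else as.matrix(k)
      as.vector(2 * (m == 1) - 1)   # tolerate 0/1 input
    }, numeric(N * T)))
  } else {
    flat <- as.matrix(samples)
    flat <- 2 * (flat == 1) - 1
    if (is.null(N) || is.null(T)) {
      N <- ncol(flat); T <- 1L
    }
  }
  if (ncol(flat) != N * T) stop("sample length must equal N * T")
  n <- nrow(flat)
  m <- colMeans(flat)
  C <- crossprod(flat) / n - tcrossprod(m)
  if (symmetrize) C <- (C + t(C)) / 2
  structure(list(values = C, means = m, n_samples = n, N = N, T = T),
            class = "grand_covariance")
}

#' @export
print.grand_covariance <- function(x, ...) {
  cat(sprintf("grand covariance: L = %d (N = %d, T = %d), n = %d samples\n",
              length(x$means), x$N, x$T, x$n_samples))
  invisible(x)
}

new_inverse_solution <- function(couplings, fields, method,
                                 field_stderr = NULL, flags = NULL) {
  diag(couplings) <- 0
  structure(list(couplings = couplings, fields = fields, method = method,
                 field_stderr = field_stderr, flags = flags),
            class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat(sprintf("inverse solution (%s): %d sites", x$method,
              length(x$fields)))
  if (!is.null(x$flags) && any(x$flags))
    cat(sprintf(", %d flagged entries", sum(x$flags)))
  cat("\n")
  invisible(x)
}

#' Field reconstruction by Callen inversion
#'
#' For a free (non-interacting) theory the fields follow from the means:
#' `lam * I_l = atanh(m_l)`, with sampling error
#' `delta(lam * I_l) = cosh(lam * I_l) / sqrt(n_samples)`.
#'
#' @param m vector of mean magnetisations, all strictly inside (-1, 1).
#' @param n_samples number of samples behind the estimate (for error bars).
#' @return an [new_inverse_solution] object with zero couplings, `fields`
#'   (the lam-scaled inputs) and `field_stderr`.
#' @export
callen_invert <- function(m, n_samples) {
  if (any(abs(m) >= 1))
    stop("infinite field: |m| = 1 cannot be inverted (saturated site)")
  lamI <- atanh(m)
  err <- cosh(lamI) / sqrt(n_samples)
  new_inverse_solution(matrix(0, length(m), length(m)), lamI, "callen",
                       field_stderr = err)
}

regularized_inverse <- function(C, ridge = NULL) {
  L <- nrow(C)
  if (is.null(ridge)) ridge <- 1e-8 * sum(diag(C)) / L
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  applied <- FALSE
  if (is.null(Ci) || !all(is.finite(Ci))) {
    Ci <- solve(C + diag(ridge, L))
    applied <- TRUE
  }
  list(inv = Ci, ridge_applied = applied)
}

#' Naive mean-field coupling inversion
#'
#' `F = -(C^-1)` off the diagonal, diagonal zeroed. A small ridge is added
#' automatically if the covariance is numerically singular.
#'
#' @param gc a [grand_covariance()].
#' @param ridge optional ridge added to the diagonal on singularity
#'   (default `1e-8 * trace / L`).
#' @return an inverse solution with `fields` from the mean-field
#'   self-consistency `h_l = atanh(m_l) - sum_l' F_ll' m_l'`.
#' @export
invert_naive_mf <- function(gc, ridge = NULL) {
  ri <- regularized_inverse(gc$values, ridge)
  if (any(!is.finite(ri$inv))) {
    kap <- tryCatch(kappa(gc$values), error = function(e) Inf)
    stop("singular covariance (condition number ~ ", format(kap), ")")
  }
  F_mat <- -ri$inv
  diag(F_mat) <- 0
  h <- atanh(pmin(pmax(gc$means, -1 + 1e-12), 1 - 1e-12)) -
    as.vector(F_mat %*% gc$means)
  new_inverse_solution(F_mat, h, "nmf",
                       flags = matrix(ri$ridge_applied, 1, 1))
}

#' TAP coupling inversion
#'
#' Thouless-Anderson-Palmer correction of naive mean field:
#' `F_ll' = -2 K_ll' / (1 + sqrt(1 - 8 m_l m_l' K_ll'))` with
#' `K = C^-1`. At m = 0 this reduces exactly to the naive mean-field
#' solution. Pairs with negative discriminant are flagged and fall back to
#' the naive mean-field value.
#'
#' @inheritParams invert_naive_mf
#' @return an inverse solution; `flags` marks discriminant failures.
#' @export
invert_tap <- function(gc, ridge = NULL) {
  ri <- regularized_inverse(gc$values, ridge)
  K <- ri$inv
  m <- gc$means
  disc <- 1 - 8 * outer(m, m) * K
  bad <- disc < 0
  disc[bad] <- 1        # placeholder; flagged entries get the nMF value
  F_mat <- -2 * K / (1 + sqrt(disc))
  F_mat[bad] <- -K[bad]
  diag(F_mat) <- 0
  h <- atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)) -
    as.vector(F_mat %*% m)
  new_inverse_solution(F_mat, h, "tap", flags = bad)
}

#' Independent-pair coupling inversion
#'
#' Treats every pair of sites as an isolated two-spin system and inverts its
#' joint distribution in closed form:
#' `F_ll' = (1/4) * log [ ((1+m)(1+m') + C)((1-m)(1-m') + C) /
#'                        ((1+m)(1-m') - C)((1-m)(1+m') - C) ]`.
#' At m = 0 this is `atanh(C_ll')`; on a true two-spin system it is exact.
#'
#' @inheritParams invert_naive_mf
#' @return an inverse solution; `flags` marks pairs whose log arguments were
#'   not positive (entries set to NA).
#' @export
invert_independent_pair <- function(gc) {
  m <- gc$means
  C <- gc$values
  p1 <- outer(1 + m, 1 + m) + C
  p2 <- outer(1 - m, 1 - m) + C
  p3 <- outer(1 + m, 1 - m) - C
  p4 <- outer(1 - m, 1 + m) - C
  bad <- p1 <= 0 | p2 <= 0 | p3 <= 0 | p4 <= 0
  diag(bad) <- FALSE
  F_mat <- 0.25 * (log(abs(p1)) + log(abs(p2)) - log(abs(p3)) -
                     log(abs(p4)))
  F_mat[bad] <- NA_real_
  diag(F_mat) <- 0
  h <- atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12))
  new_inverse_solution(F_mat, h, "ip", flags = bad)
}

#' Sessak-Monasson coupling inversion
#'
#' Small-correlation expansion combining the independent-pair closed form
#' with the inverse-covariance term:
#' `F^SM = F^IP - (C^-1)_ll' - C_ll' / ((1 - m^2)(1 - m'^2) - C_ll'^2)`.
#' The subtraction removes the double-counted two-spin contribution, so at
#' L = 2 the formula reduces to the independent-pair solution exactly.
#'
#' @inheritParams invert_naive_mf
#' @return an inverse solution; `flags` inherited from the independent-pair
#'   part plus degenerate denominators.
#' @export
invert_sessak_monasson <- function(gc, ridge = NULL) {
  ip <- invert_independent_pair(gc)
  ri <- regularized_inverse(gc$values, ridge)
  m <- gc$means
  C <- gc$values
  den <- outer(1 - m^2, 1 - m^2) - C^2
  bad <- ip$flags | den == 0
  diag(bad) <- FALSE
  F_mat <- ip$couplings - ri$inv - C / den
  F_mat[bad] <- NA_real_
  diag(F_mat) <- 0
  h <- atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)) -
    as.vector(ifelse(is.na(F_mat), 0, F_mat) %*% m)
  new_inverse_solution(F_mat, h, "sm", flags = bad)
}

#' Dispatch on an inversion method name
#'
#' @param gc a [grand_covariance()].
#' @param method one of `"callen"`, `"nmf"`, `"tap"`, `"ip"`, `"sm"`.
#' @param n_samples used by `"callen"` error bars (defaults to the
#'   covariance's sample count).
#' @return an inverse solution.
#' @export
invert_couplings <- function(gc, method = c("sm", "nmf", "tap", "ip",
                                            "callen"),
                             n_samples = gc$n_samples) {
  method <- match.arg(method)
  switch(method,
         callen = callen_invert(gc$means, n_samples),
         nmf = invert_naive_mf(gc),
         tap = invert_tap(gc),
         ip = invert_independent_pair(gc),
         sm = invert_sessak_monasson(gc))
}

#' Non-relativistic reduction of the grand covariance
#'
#' The simplified action correlates only equal-time neuron pairs and
#' equal-neuron time pairs, so of the (NT)^2 grand-covariance entries only
#' the N x N equal-time block average and the T x T equal-neuron block
#' average carry parameters:
#' `space_cov[i, j] = mean_alpha C[(i,alpha),(j,alpha)]` and
#' `time_cov[alpha, beta] = mean_i C[(i,alpha),(i,beta)]`,
#' reducing the parameter count from (NT)^2 to NT(N+T).
#'
#' @param gc a [grand_covariance()] with N and T set.
#' @return list with `space_cov` (N x N), `time_cov` (T x T) and
#'   `parameter_count`.
#' @export
reduce_nonrelativistic <- function(gc) {
  N <- gc$N; T <- gc$T
  C <- gc$values
  space_cov <- matrix(0, N, N)
  for (a in seq_len(T)) {
    idx <- (a - 1L) * N + seq_len(N)
    space_cov <- space_cov + C[idx, idx]
  }
  space_cov <- space_cov / T
  time_cov <- matrix(0, T, T)
  for (i in seq_len(N)) {
    idx <- (seq_len(T) - 1L) * N + i
    time_cov <- time_cov + C[idx, idx]
  }
  time_cov <- time_cov / N
  list(space_cov = space_cov, time_cov = time_cov,
       parameter_count = N * T * (N + T))
}
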