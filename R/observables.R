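# ---------------------------------------------------------------------------
# Second-order observables: correlation matrices, autocorrelation profiles,
# ergodicity diagnostics and Wasserstein distances between mean-spectra.
# ---------------------------------------------------------------------------

#' Second-order correlation matrices of a kernel
#'
#' For the binary kernel Omega the space-correlation matrix is
#' Phi = Omega Omega' / T (N x N) and the joint-spike (time) matrix is
#' Pi = Omega' Omega / N (T x T).  The spin versions C = M M' / T and
#' Q = M' M / N follow from the spin kernel M.  Free-field (rank-one)
#' references are the outer products of the first-order averages, and the
#' connected matrices subtract them:
#' C* = Phi - f f', Q* = Pi - omega omega' (binary) and
#' C_conn = C - m m', Q_conn = Q - mu mu' (spin).  The spin-connected
#' matrices equal exactly 4 times the binary-connected ones.
#'
#' @param k a kernel in either representation.
#' @param representation which hypermatrix to return: `"binary"` gives
#'   Phi/Pi plus connected variants, `"spin"` gives C/Q plus connected
#'   variants, `"both"` (default) gives everything.
#' @return an object of class `correlation_set`; diagonals satisfy
#'   `diag(phi) = f`, `diag(pi) = omega`, `diag(C) = diag(Q) = 1`.
#' @export
correlation_set <- function(k, representation = c("both", "binary", "spin")) {
  representation <- match.arg(representation)
  phi <- phi_matrix(k)
  N <- nrow(phi); T <- ncol(phi)
  fo <- first_order(k)
  out <- list(first_order = fo, representation = representation)
  if (representation != "spin") {
    Phi <- tcrossprod(phi) / T
    Pi  <- crossprod(phi) / N
    out$phi <- Phi
    out$pi <- Pi
    out$phi0 <- tcrossprod(fo$row_rates)
    out$pi0 <- tcrossprod(fo$col_activity)
    out$c_star <- Phi - out$phi0
    out$q_star <- Pi - out$pi0
  }
  if (representation != "binary") {
    sig <- 2 * phi - 1
    C <- tcrossprod(sig) / T
    Q <- crossprod(sig) / N
    out$spin_c <- C
    out$spin_q <- Q
    out$spin_c0 <- tcrossprod(fo$m)
    out$spin_q0 <- tcrossprod(fo$mu)
    out$spin_c_star <- C - out$spin_c0
    out$spin_q_star <- Q - out$spin_q0
  }
  structure(out, class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("correlation set (%s): ", x$representation))
  have <- intersect(c("phi", "pi", "spin_c", "spin_q"), names(x))
  cat(paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Histogram of connected-correlation values
#'
#' Off-diagonal value distribution of a connected correlation matrix, with
#' Freedman-Diaconis bin widths by default.
#'
#' @param mat a square matrix (e.g. `c_star` from [correlation_set()]).
#' @param breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]-free binning; either `"FD"` or a number of bins.
#' @return a list with `mids`, `counts`, `density`, `breaks`.
#' @export
correlation_histogram <- function(mat, breaks = "FD") {
  v <- mat[row(mat) != col(mat)]
  if (identical(breaks, "FD")) {
    iqr <- stats::IQR(v)
    h <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else diff(range(v)) / 30
    nb <- if (h > 0) max(1L, ceiling(diff(range(v)) / h)) else 1L
  } else nb <- as.integer(breaks)
  edges <- seq(min(v), max(v), length.out = nb + 1L)
  if (nb == 1L || diff(range(v)) == 0) {
    return(list(mids = mean(v), counts = length(v), density = 1,
                breaks = range(v)))
  }
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nb)
  counts <- tabulate(idx, nb)
  w <- diff(edges)
  list(mids = (edges[-1L] + edges[-(nb + 1L)]) / 2, counts = counts,
       density = counts / (sum(counts) * w), breaks = edges)
}

#' Check the spin/binary connected-correlation scaling
#'
#' The connected correlations computed from spins equal 4 times those
#' computed from binary activities, exactly. This verifies the identity
#' entrywise and reports the largest absolute deviation.
#'
#' @param k a kernel.
#' @return a list with `ok` (deviation below `tol`), `max_abs_deviation`,
#'   and `tol`.
#' @param tol numeric tolerance (default 1e-12).
#' @export
connected_scaling_check <- function(k, tol = 1e-12) {
  cs <- correlation_set(k, "both")
  dev <- max(abs(cs$spin_c_star - 4 * cs$c_star),
             abs(cs$spin_q_star - 4 * cs$q_star))
  list(ok = dev < tol, max_abs_deviation = dev, tol = tol)
}

# ---------------------------------------------------------------------------
# Autocorrelation profiles and ergodicity
# ---------------------------------------------------------------------------

#' Lagged autocorrelation and overlap profile
#'
#' For each lag k = 1..max_lag computes, in the spin representation,
#' \itemize{
#'   \item `per_neuron` chi[i, k]: the lag-k autocorrelation of neuron i,
#'     averaged over the T - k valid bin pairs;
#'   \item `per_time_overlap` q[alpha, k]: the overlap between the population
#'     states at alpha and alpha - k (rows alpha <= k are NA);
#'   \item `delta[k]`: the lag-averaged overlap (equals the neuron-averaged
#'     chi exactly, by exchanging the order of summation);
#'   \item `delta0[k]`: the free-field part from the column means mu;
#'   \item `delta_star[k] = delta[k] - delta0[k]`: the connected profile,
#'     identical in both representations up to the factor 4.
#' }
#' Sums over alpha are truncated to alpha > k and normalised by the count
#' T - k, so each lag is an unbiased per-pair average; the per-lag `counts`
#' and `stderr` expose the loss of precision as k approaches T.
#'
#' @param k a kernel (converted to spins internally).
#' @param max_lag maximum lag, must be < T.
#' @return an object of class `autocorrelation_profile`.
#' @export
autocorrelation_profile <- function(k, max_lag) {
  sig <- sigma_matrix(k)
  N <- nrow(sig); T <- ncol(sig)
  max_lag <- as.integer(max_lag)
  if (max_lag >= T) stop("max_lag must be smaller than the number of bins")
  if (max_lag < 1L) stop("max_lag must be >= 1")
  mu <- colMeans(sig)
  chi <- matrix(NA_real_, N, max_lag)
  qmat <- matrix(NA_real_, T, max_lag)
  delta <- delta0 <- delta_star <- se <- numeric(max_lag)
  counts <- integer(max_lag)
  for (kk in seq_len(max_lag)) {
    a <- (kk + 1L):T
    prod_mat <- sig[, a, drop = FALSE] * sig[, a - kk, drop = FALSE]
    chi[, kk] <- rowMeans(prod_mat)
    qv <- colMeans(prod_mat)            # overlap q_{alpha, alpha-k}
    qmat[a, kk] <- qv
    counts[kk] <- length(a)
    delta[kk] <- mean(qv)
    delta0[kk] <- mean(mu[a] * mu[a - kk])
    dsv <- qv - mu[a] * mu[a - kk]
    delta_star[kk] <- mean(dsv)
    se[kk] <- if (length(dsv) > 1L) sd(dsv) / sqrt(length(dsv)) else NA_real_
  }
  structure(
    list(per_neuron = chi, per_time_overlap = qmat, delta = delta,
         delta0 = delta0, delta_star = delta_star, counts = counts,
         stderr = se, max_lag = max_lag),
    class = "autocorrelation_profile"
  )
}

#' @export
print.autocorrelation_profile <- function(x, ...) {
  cat(sprintf("autocorrelation profile, lags 1..%d\n", x$max_lag))
  print(round(rbind(delta = x$delta, delta_star = x$delta_star,
                    stderr = x$stderr), 4))
  invisible(x)
}

#' Ergodicity and stationarity diagnostics
#'
#' A kernel is "ergodic in mean" when per-neuron time averages m_i and
#' per-bin space averages mu_alpha all coincide, and "ergodic in
#' correlation" when per-neuron lagged autocorrelations coincide with the
#' time overlaps at the same lag. Weak stationarity requires mu_alpha
#' constant and the overlap to depend only on the lag. All diagnostics are
#' reported in spin units.
#'
#' @param k a kernel.
#' @param max_lag lags for the correlation diagnostics
#'   (default `min(10, T - 1)`).
#' @return a list with `mean_discrepancy` (max over pairs |m_i - mu_alpha|),
#'   `corr_discrepancy` (max over i, alpha, k of |chi_ik - q_{alpha,alpha-k}|),
#'   `mu_variance` (weak-stationarity: variance of mu), and
#'   `overlap_alpha_sd` (per-lag sd of the overlap across alpha).
#' @export
ergodicity_report <- function(k, max_lag = NULL) {
  fo <- first_order(k)
  T <- n_bins(k)
  if (is.null(max_lag)) max_lag <- min(10L, T - 1L)
  mean_disc <- max(abs(outer(fo$m, fo$mu, "-")))
  corr_disc <- NA_real_
  overlap_sd <- NULL
  if (max_lag >= 1L) {
    prof <- autocorrelation_profile(k, max_lag)
    dev <- 0
    for (kk in seq_len(max_lag)) {
      qv <- prof$per_time_overlap[, kk]
      qv <- qv[!is.na(qv)]
      dev <- max(dev, max(abs(outer(prof$per_neuron[, kk], qv, "-"))))
    }
    corr_disc <- dev
    overlap_sd <- apply(prof$per_time_overlap, 2,
                        function(x) sd(x[!is.na(x)]))
  }
  list(mean_discrepancy = mean_disc, corr_discrepancy = corr_disc,
       mu_variance = if (length(fo$mu) > 1L) var(fo$mu) else 0,
       overlap_alpha_sd = overlap_sd)
}

# ---------------------------------------------------------------------------
# Wasserstein distance between empirical distributions
# ---------------------------------------------------------------------------

#' Wasserstein distance of order k between two samples
#'
#' Computes W_k between the empirical distributions of `a` and `b` from the
#' quantile representation: W_k^k is the mean k-th power of the difference
#' between the two quantile functions. With equal sample sizes this pairs the
#' sorted values directly; with unequal sizes both quantile functions are
#' evaluated (right-continuous inverse CDF) on a common grid of
#' `max(length(a), length(b))` midpoints.
#'
#' The order-1 case is the earth-mover distance; order-k convergence is weak
#' convergence plus convergence of the first k moments.
#'
#' @param a,b non-empty numeric vectors.
#' @param order k >= 1.
#' @return non-negative scalar W_k.
#' @export
wasserstein <- function(a, b, order = 1) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input")
  if (order < 1) stop("order must be >= 1")
  if (length(a) == length(b)) {
    qa <- sort(a); qb <- sort(b)
  } else {
    G <- max(length(a), length(b))
    s <- (seq_len(G) - 0.5) / G
    qa <- quantile_spectrum_eval(quantile_spectrum(a), s)
    qb <- quantile_spectrum_eval(quantile_spectrum(b), s)
  }
  mean(abs(qa - qb)^order)^(1 / order)
}
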