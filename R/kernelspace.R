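#' @useDynLib spikelft, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom sd var cor coef lm quantile setNames
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Core kernel types
#
# A spike raster is stored as an N x T matrix: rows are neurons (space V),
# columns are clock-time bins (time S).  The binary representation uses
# entries in {0,1} ("activity kernel"); the spin representation uses {-1,+1}
# ("magnetization kernel"), related entrywise by sigma = 2*phi - 1.
# Metadata (clock time tau in ms, the bin index of the alignment event, and
# neuron labels) travels with the matrix and is never inferred from it.
# ---------------------------------------------------------------------------

new_kernel <- function(values, tau_ms, neuron_labels, t0_bin, class) {
  structure(
    list(values = values, tau_ms = tau_ms,
         neuron_labels = neuron_labels, t0_bin = t0_bin),
    class = c(class, "spike_kernel")
  )
}

#' Construct a binary activity kernel
#'
#' The activity kernel is the N x T matrix of 0/1 spike indicators: rows are
#' neurons, columns are clock-time bins of duration `tau_ms`. It is the basic
#' container of the package; all observables, actions and coarse-grainings
#' operate on it (or on its spin counterpart, see [to_spin()]).
#'
#' @param values numeric or integer matrix with entries exactly 0 or 1.
#' @param tau_ms positive clock time per bin, in milliseconds.
#' @param neuron_labels optional character vector of row identifiers.
#' @param t0_bin integer bin index of the alignment event (0 = window start).
#' @return an object of class `binary_kernel`.
#' @examples
#' k <- binary_kernel(matrix(c(1, 1, 0, 1), 2, 2))
#' first_order(k)$offset_binary
#' @export
binary_kernel <- function(values, tau_ms = 1, neuron_labels = NULL,
                          t0_bin = 0L) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("kernel must have at least one neuron and one time bin")
  if (anyNA(values) || !all(values == 0L | values == 1L))
    stop("invalid kernel: every entry must be exactly 0 or 1")
  if (!is.numeric(tau_ms) || length(tau_ms) != 1L || tau_ms <= 0)
    stop("tau_ms must be a positive scalar")
  storage.mode(values) <- "integer"
  if (!is.null(neuron_labels)) {
    if (length(neuron_labels) != nrow(values))
      stop("neuron_labels length must equal the number of rows")
    rownames(values) <- neuron_labels
  }
  new_kernel(values, tau_ms, neuron_labels, as.integer(t0_bin),
             "binary_kernel")
}

#' Construct a spin (magnetization) kernel
#'
#' Same layout as [binary_kernel()] but with entries in {-1, +1}.
#'
#' @inheritParams binary_kernel
#' @return an object of class `magnetization_kernel`.
#' @export
magnetization_kernel <- function(values, tau_ms = 1, neuron_labels = NULL,
                                 t0_bin = 0L) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("kernel must have at least one neuron and one time bin")
  if (anyNA(values) || !all(values == -1L | values == 1L))
    stop("invalid kernel: every entry must be exactly -1 or +1")
  storage.mode(values) <- "integer"
  if (!is.null(neuron_labels)) {
    if (length(neuron_labels) != nrow(values))
      stop("neuron_labels length must equal the number of rows")
    rownames(values) <- neuron_labels
  }
  new_kernel(values, tau_ms, neuron_labels, as.integer(t0_bin),
             "magnetization_kernel")
}

#' @export
print.spike_kernel <- function(x, ...) {
  rep <- if (inherits(x, "binary_kernel")) "binary {0,1}" else "spin {-1,+1}"
  cat(sprintf("<%s> %d neurons x %d bins, tau = %g ms, t0 bin = %d\n",
              rep, nrow(x$values), ncol(x$values), x$tau_ms, x$t0_bin))
  invisible(x)
}

#' Number of neurons / time bins of a kernel
#' @param k a kernel.
#' @return integer count.
#' @export
n_neurons <- function(k) nrow(k$values)

#' @rdname n_neurons
#' @export
n_bins <- function(k) ncol(k$values)

#' Spin/binary duality maps
#'
#' `to_spin()` applies sigma = 2*phi - 1 entrywise, `to_binary()` inverts it
#' with phi = (sigma + 1)/2. Metadata is preserved and
#' `to_binary(to_spin(k))` is the identity.
#'
#' @param k a [binary_kernel()] (for `to_spin`) or [magnetization_kernel()]
#'   (for `to_binary`). Passing a kernel already in the target representation
#'   returns it unchanged.
#' @return the kernel in the other representation.
#' @export
to_spin <- function(k) {
  if (inherits(k, "magnetization_kernel")) return(k)
  if (!inherits(k, "binary_kernel")) stop("not a binary kernel")
  new_kernel(2L * k$values - 1L, k$tau_ms, k$neuron_labels, k$t0_bin,
             "magnetization_kernel")
}

#' @rdname to_spin
#' @export
to_binary <- function(k) {
  if (inherits(k, "binary_kernel")) return(k)
  if (!inherits(k, "magnetization_kernel")) stop("not a magnetization kernel")
  new_kernel((k$values + 1L) %/% 2L, k$tau_ms, k$neuron_labels, k$t0_bin,
             "binary_kernel")
}

# return the {0,1} matrix of any kernel
phi_matrix <- function(k) {
  if (inherits(k, "binary_kernel")) k$values else (k$values + 1L) %/% 2L
}

# return the {-1,1} matrix of any kernel
sigma_matrix <- function(k) {
  if (inherits(k, "magnetization_kernel")) k$values else 2L * k$values - 1L
}

# ---------------------------------------------------------------------------
# Index maps
# ---------------------------------------------------------------------------

#' Index maps between neuron/time and the mixed ("grand") space
#'
#' The mixed space collapses the pair (i, alpha) into a single index
#' l = (alpha - 1) * N + i, of size L = N * T (column-major over the kernel
#' matrix, so `as.vector(k$values)` is already in grand order).  `theta` is an
#' optional relabelling permutation of the neurons; it defaults to the
#' identity.
#'
#' @param N,T kernel dimensions.
#' @param theta optional permutation of `1:N`.
#' @return a list with `theta`, `theta_inv`, `L`, and the two maps
#'   `to_grand(i, alpha)` and `from_grand(l)` (the latter returns a
#'   two-column matrix of (i, alpha) pairs).
#' @export
index_maps <- function(N, T, theta = NULL) {
  if (is.null(theta)) theta <- seq_len(N)
  if (!identical(sort(theta), seq_len(N) * 1L) &&
      !identical(sort(theta), as.numeric(seq_len(N))))
    stop("theta must be a permutation of 1:N")
  theta <- as.integer(theta)
  theta_inv <- order(theta)
  list(
    theta = theta, theta_inv = theta_inv, N = N, T = T, L = N * T,
    to_grand = function(i, alpha) (alpha - 1L) * N + i,
    from_grand = function(l) {
      cbind(i = (l - 1L) %% N + 1L, alpha = (l - 1L) %/% N + 1L)
    }
  )
}

#' Permute kernel rows by a neuron relabelling
#'
#' @param k a kernel.
#' @param theta permutation of `1:N`; row `r` of the result is row `theta[r]`
#'   of the input.
#' @return kernel with permuted rows.
#' @export
apply_theta <- function(k, theta) {
  v <- k$values[theta, , drop = FALSE]
  lab <- if (!is.null(k$neuron_labels)) k$neuron_labels[theta] else NULL
  new_kernel(v, k$tau_ms, lab, k$t0_bin, class(k)[1L])
}

#' Sort neurons by activity in a baseline window
#'
#' Returns the permutation that orders neurons by decreasing spike count in
#' the first `baseline_bins` bins, ties broken by original index. This mirrors
#' the common display convention of sorting rasters by activity during the
#' pre-stimulus baseline.
#'
#' @param k a binary kernel.
#' @param baseline_bins number of initial bins of the baseline (default 250).
#' @param decreasing sort direction.
#' @return an integer permutation usable with [apply_theta()].
#' @export
baseline_activity_order <- function(k, baseline_bins = 250L,
                                    decreasing = TRUE) {
  baseline_bins <- min(baseline_bins, n_bins(k))
  counts <- rowSums(phi_matrix(k)[, seq_len(baseline_bins), drop = FALSE])
  order(counts, seq_len(n_neurons(k)), decreasing = c(decreasing, FALSE),
        method = "radix")
}

# ---------------------------------------------------------------------------
# First-order observables
# ---------------------------------------------------------------------------

#' First-order observables of a kernel
#'
#' Computes the offsets (grand means) and the row/column averages in both
#' representations:
#' \itemize{
#'   \item `offset_binary` / `offset_spin`: the grand mean of the binary and
#'     spin kernels, linked by `offset_spin = 2 * offset_binary - 1`;
#'   \item `row_rates` (`f`): per-neuron firing rate per bin (length N);
#'   \item `col_activity` (`omega`): per-bin population activity (length T);
#'   \item `m`, `mu`: the spin counterparts of `f` and `omega`.
#' }
#' The mean of `f` and the mean of `omega` both equal the binary offset
#' (and likewise for `m`, `mu` and the spin offset).
#'
#' @param k a kernel in either representation.
#' @return an object of class `first_order_summary`.
#' @export
first_order <- function(k) {
  phi <- phi_matrix(k)
  f <- rowMeans(phi)
  omega <- colMeans(phi)
  off <- mean(f)
  structure(
    list(offset_binary = off, offset_spin = 2 * off - 1,
         row_rates = f, col_activity = omega,
         m = 2 * f - 1, mu = 2 * omega - 1),
    class = "first_order_summary"
  )
}

#' @export
print.first_order_summary <- function(x, ...) {
  cat(sprintf(
    "first-order summary: offset (binary) %.4f, offset (spin) %+.4f\n",
    x$offset_binary, x$offset_spin))
  cat(sprintf("  f: N = %d, mean %.4f | omega: T = %d, mean %.4f\n",
              length(x$row_rates), mean(x$row_rates),
              length(x$col_activity), mean(x$col_activity)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Quantile spectra (order statistics of the first-order vectors)
# ---------------------------------------------------------------------------

#' Empirical quantile spectrum of a vector
#'
#' The "spectrum" of a first-order vector is its order statistics viewed as a
#' right-continuous step function on (0, 1]: the empirical quantile function.
#' For a vector of length n the support is quantised in steps of 1/n.
#'
#' @param v finite numeric vector (e.g. `f` or `omega` from [first_order()]).
#' @return an object of class `quantile_spectrum` with fields
#'   `sorted_values`, `support_step` and `n`.
#' @export
quantile_spectrum <- function(v) {
  if (length(v) == 0L) stop("empty vector has no quantile spectrum")
  if (!all(is.finite(v))) stop("vector must be finite")
  structure(
    list(sorted_values = sort(v), support_step = 1 / length(v),
         n = length(v)),
    class = "quantile_spectrum"
  )
}

#' Evaluate a quantile spectrum at probabilities s
#'
#' Right-continuous inverse CDF: the value at `s` in ((j-1)/n, j/n] is the
#' j-th order statistic.
#'
#' @param spec a [quantile_spectrum()].
#' @param s probabilities in (0, 1].
#' @return numeric vector of quantiles.
#' @export
quantile_spectrum_eval <- function(spec, s) {
  if (any(s <= 0 | s > 1)) stop("s must lie in (0, 1]")
  spec$sorted_values[pmin(ceiling(s * spec$n), spec$n)]
}

#' @export
print.quantile_spectrum <- function(x, ...) {
  cat(sprintf("quantile spectrum on %d levels (step %.4g): min %.4g max %.4g\n",
              x$n, x$support_step, x$sorted_values[1L],
              x$sorted_values[x$n]))
  invisible(x)
}
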