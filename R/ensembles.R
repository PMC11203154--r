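# ---------------------------------------------------------------------------
# Trial ensembles: repeated experimental trials share the neuron set and a
# common analysis window; integer time shifts re-cut each trial's window to
# align the replicas before ensemble averages are taken.
# ---------------------------------------------------------------------------

#' Build a trial ensemble
#'
#' Each trial is a binary kernel over the same N neurons; the analysis
#' window of common length T is cut from each recording starting at
#' `window_start[k]` (1-based). A time shift nu shifts the window start, so
#' positive shifts move spikes to earlier window coordinates.
#'
#' @param trials list of [binary_kernel()]s (or 0/1 matrices) with equal row
#'   counts.
#' @param window_start integer vector (recycled) of window start bins.
#' @param window_length common window length T; defaults to the largest
#'   length that fits every trial at its start bin.
#' @param events optional data.frame with per-trial event bins (e.g.
#'   `go_bin`, `movement_bin`) used for event alignment and shift bounds.
#' @param alignment_event label of the event the windows are aligned to.
#' @return an object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(trials, window_start = 1L, window_length = NULL,
                           events = NULL, alignment_event = NULL) {
  if (length(trials) == 0L) stop("empty ensemble")
  trials <- lapply(trials, function(k)
    if (inherits(k, "spike_kernel")) to_binary(k) else binary_kernel(k))
  N <- n_neurons(trials[[1L]])
  if (!all(vapply(trials, n_neurons, integer(1L)) == N))
    stop("all trials must share the same number of neurons")
  n <- length(trials)
  window_start <- rep_len(as.integer(window_start), n)
  lens <- vapply(trials, n_bins, integer(1L))
  if (is.null(window_length))
    window_length <- min(lens - window_start + 1L)
  window_length <- as.integer(window_length)
  if (any(window_start < 1L) ||
      any(window_start + window_length - 1L > lens))
    stop("analysis window falls outside a recorded trial")
  structure(list(trials = trials, window_start = window_start,
                 T = window_length, N = N, n = n,
                 shifts = integer(n), events = events,
                 alignment_event = alignment_event),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("trial ensemble: %d trials, %d neurons, window T = %d\n",
              x$n, x$N, x$T))
  if (any(x$shifts != 0))
    cat("  shifts:", paste(x$shifts, collapse = " "), "\n")
  invisible(x)
}

# window of trial k as a 0/1 matrix (N x T)
trial_window <- function(e, k) {
  s <- e$window_start[k]
  phi_matrix(e$trials[[k]])[, s:(s + e$T - 1L), drop = FALSE]
}

#' Apply integer time shifts to an ensemble
#'
#' Re-cuts every trial's window at `start + nu[k]`; errors if a shifted
#' window leaves the recorded range.
#'
#' @param e a [trial_ensemble()].
#' @param nu integer shift vector (length n or scalar).
#' @return the shifted ensemble (shifts are accumulated in `$shifts`).
#' @export
apply_timeshifts <- function(e, nu) {
  nu <- rep_len(as.integer(nu), e$n)
  ns <- e$window_start + nu
  lens <- vapply(e$trials, n_bins, integer(1L))
  if (any(ns < 1L) || any(ns + e$T - 1L > lens))
    stop("shift pushes an analysis window out of the recorded range")
  e$window_start <- ns
  e$shifts <- e$shifts + nu
  e
}

#' Feasible shift range of each trial
#'
#' @param e a [trial_ensemble()].
#' @return n x 2 matrix of (lo, hi) shifts keeping every window in range.
#' @export
shift_bounds <- function(e) {
  lens <- vapply(e$trials, n_bins, integer(1L))
  cbind(lo = 1L - e$window_start,
        hi = lens - e$T - e$window_start + 1L)
}

#' Trial-overlap matrix
#'
#' Entry (k, k') is the mean over neurons and window bins of the product of
#' the two trials' binary windows; the diagonal is each trial's activity
#' density.
#'
#' @param e a [trial_ensemble()].
#' @return an object of class `trial_overlap` with `values` (n x n) and
#'   `norm` (squared Frobenius norm).
#' @export
trial_overlap_matrix <- function(e) {
  flat <- vapply(seq_len(e$n), function(k) as.vector(trial_window(e, k)),
                 numeric(e$N * e$T))
  Q <- crossprod(flat) / (e$N * e$T)
  structure(list(values = Q, norm = sum(Q^2)), class = "trial_overlap")
}

#' @export
print.trial_overlap <- function(x, ...) {
  cat(sprintf("trial overlap matrix %d x %d, ||Q||^2 = %.6f\n",
              nrow(x$values), nrow(x$values), x$norm))
  invisible(x)
}

overlap_norm_at <- function(e, nu) {
  trial_overlap_matrix(apply_timeshifts(e, nu))$norm
}

#' Align trials by overlap-norm maximisation
#'
#' Finds the integer shift vector (within per-trial bounds) maximising the
#' squared Frobenius norm of the trial-overlap matrix. Exhaustive search is
#' used when the product of range sizes does not exceed
#' `exhaustive_limit`; otherwise coordinate ascent from `n_restarts` random
#' starting points (plus the zero shift) is used, so the returned norm is
#' never below the zero-shift norm.
#'
#' @param e a [trial_ensemble()].
#' @param bounds n x 2 integer matrix of per-trial (lo, hi) shift bounds;
#'   defaults to the recording-feasible range intersected with
#'   `max_abs_shift`.
#' @param max_abs_shift cap on |shift| for the default bounds.
#' @param exhaustive_limit search-space size below which enumeration is used.
#' @param n_restarts random restarts for coordinate ascent.
#' @param seed RNG seed for the restarts.
#' @return list with `shifts`, `norm`, `norm_zero` and `method`.
#' @export
align_trials <- function(e, bounds = NULL, max_abs_shift = 5L,
                         exhaustive_limit = 1e4, n_restarts = 10L,
                         seed = 1L) {
  fb <- shift_bounds(e)
  if (is.null(bounds)) {
    bounds <- cbind(pmax(fb[, 1L], -max_abs_shift),
                    pmin(fb[, 2L], max_abs_shift))
  } else {
    bounds <- cbind(pmax(bounds[, 1L], fb[, 1L]),
                    pmin(bounds[, 2L], fb[, 2L]))
  }
  if (any(bounds[, 1L] > bounds[, 2L]))
    stop("empty feasible shift set for some trial")
  ranges <- lapply(seq_len(e$n), function(k) bounds[k, 1L]:bounds[k, 2L])
  sizes <- vapply(ranges, length, integer(1L))
  norm_zero <- overlap_norm_at(e, integer(e$n))
  if (prod(sizes) <= exhaustive_limit) {
    grid <- as.matrix(expand.grid(ranges))
    norms <- apply(grid, 1L, function(nu) overlap_norm_at(e, nu))
    best <- which.max(norms)
    return(list(shifts = as.integer(grid[best, ]), norm = norms[best],
                norm_zero = norm_zero, method = "exhaustive"))
  }
  set.seed(seed)
  best_nu <- integer(e$n)
  best_norm <- norm_zero
  starts <- c(list(integer(e$n)),
              lapply(seq_len(n_restarts), function(r)
                vapply(ranges, function(rg) sample(rg, 1L), integer(1L))))
  for (nu in starts) {
    repeat {
      improved <- FALSE
      for (k in sample(e$n)) {
        cand <- nu
        vals <- vapply(ranges[[k]], function(v) {
          cand[k] <- v
          overlap_norm_at(e, cand)
        }, numeric(1L))
        v_best <- ranges[[k]][which.max(vals)]
        if (v_best != nu[k] && max(vals) > overlap_norm_at(e, nu)) {
          nu[k] <- v_best
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    cur <- overlap_norm_at(e, nu)
    if (cur > best_norm) {
      best_norm <- cur
      best_nu <- nu
    }
  }
  list(shifts = best_nu, norm = best_norm, norm_zero = norm_zero,
       method = "coordinate_ascent")
}

#' Align trials on a recorded event
#'
#' Shifts each window so that the given event bin lands at the same window
#' coordinate in every trial (that of the first trial).
#'
#' @param e a [trial_ensemble()] with an `events` data.frame.
#' @param event column name in `e$events` (e.g. `"movement_bin"`).
#' @return the aligned ensemble.
#' @export
align_on_event <- function(e, event) {
  if (is.null(e$events) || !event %in% names(e$events))
    stop("ensemble has no recorded event column '", event, "'")
  bins <- e$events[[event]]
  nu <- as.integer(bins - bins[1L] - (e$window_start - e$window_start[1L]))
  apply_timeshifts(e, nu)
}

#' Ensemble-averaged hypermatrix
#'
#' Averages the spin kernels and spin correlation matrices over trials and
#' forms the ensemble covariance corrections
#' `delta_C = <C> - <M><M>'/T` and `delta_Q = <Q> - <M>'<M>/N`, which vanish
#' exactly when all trials are identical (in particular for n = 1).
#'
#' @param e an aligned [trial_ensemble()].
#' @return an object of class `ensemble_hypermatrix` with `mean_kernel`
#'   (N x T, spin scale), `mean_corr` (`C`, `Q`), and `covariances`
#'   (`delta_C`, `delta_Q`).
#' @export
ensemble_hypermatrix <- function(e) {
  Msum <- matrix(0, e$N, e$T)
  Csum <- matrix(0, e$N, e$N)
  Qsum <- matrix(0, e$T, e$T)
  for (k in seq_len(e$n)) {
    sig <- 2 * trial_window(e, k) - 1
    Msum <- Msum + sig
    Csum <- Csum + tcrossprod(sig) / e$T
    Qsum <- Qsum + crossprod(sig) / e$N
  }
  Mbar <- Msum / e$n
  Cbar <- Csum / e$n
  Qbar <- Qsum / e$n
  structure(
    list(mean_kernel = Mbar,
         mean_corr = list(C = Cbar, Q = Qbar),
         covariances = list(delta_C = Cbar - tcrossprod(Mbar) / e$T,
                            delta_Q = Qbar - crossprod(Mbar) / e$N),
         n = e$n),
    class = "ensemble_hypermatrix"
  )
}

#' @export
print.ensemble_hypermatrix <- function(x, ...) {
  cat(sprintf(
    "ensemble hypermatrix over %d trials: ||delta_C|| = %.4g, ||delta_Q|| = %.4g\n",
    x$n, sqrt(sum(x$covariances$delta_C^2)),
    sqrt(sum(x$covariances$delta_Q^2))))
  invisible(x)
}

#' Cut a window from a kernel
#'
#' @param k a kernel.
#' @param start 1-based first bin.
#' @param length window length.
#' @return the windowed kernel (same representation).
#' @export
cut_window <- function(k, start, length) {
  if (start < 1L || start + length - 1L > n_bins(k))
    stop("window outside the recorded range")
  v <- k$values[, start:(start + length - 1L), drop = FALSE]
  new_kernel(v, k$tau_ms, k$neuron_labels,
             k$t0_bin - (start - 1L), class(k)[1L])
}
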