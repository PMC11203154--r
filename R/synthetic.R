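# ---------------------------------------------------------------------------
# Synthetic raster generators: everything the toolkit consumes can be
# produced here with a mandatory seed (bit-reproducible streams).
# ---------------------------------------------------------------------------

#' Bernoulli raster with an absolute refractory period
#'
#' Each neuron fires independently per bin with probability `rate_per_bin`,
#' but is silenced for `refractory_bins` bins after every spike, so every
#' inter-spike interval exceeds the refractory period. The resulting
#' empirical rate is biased down to approximately
#' `rate / (1 + rate * refractory_bins)` (renewal process), and the time
#' covariance acquires a suppressed band within `refractory_bins` of the
#' diagonal — the discrete analogue of the refractory "dark band" seen in
#' cortical recordings.
#'
#' @param n_neurons,n_bins raster dimensions.
#' @param rate_per_bin firing probability per clock bin, in (0, 1).
#' @param refractory_bins non-negative integer r (< n_bins).
#' @param seed integer seed (mandatory).
#' @param tau_ms clock time of the generated raster.
#' @return a [binary_kernel()].
#' @export
generate_refractory_raster <- function(n_neurons, n_bins, rate_per_bin,
                                       refractory_bins = 0L, seed,
                                       tau_ms = 1) {
  if (missing(seed)) stop("seed is mandatory")
  if (rate_per_bin <= 0 || rate_per_bin >= 1)
    stop("rate_per_bin must lie in (0, 1)")
  r <- as.integer(refractory_bins)
  if (r < 0L || r >= n_bins) stop("refractory_bins must lie in [0, n_bins)")
  set.seed(seed)
  draws <- matrix(runif(n_neurons * n_bins) < rate_per_bin, n_neurons,
                  n_bins)
  if (r == 0L) return(binary_kernel(draws * 1L, tau_ms = tau_ms))
  phi <- matrix(0L, n_neurons, n_bins)
  last <- rep(-Inf, n_neurons)
  for (a in seq_len(n_bins)) {
    can <- (a - last) > r
    fire <- can & draws[, a]
    phi[fire, a] <- 1L
    last[fire] <- a
  }
  binary_kernel(phi, tau_ms = tau_ms)
}

#' Gibbs-sampled rasters from a lattice action
#'
#' Draws `n_trials` kernels from the Gibbs measure `exp(-lam * A)/G` of the
#' given action. Three samplers are available: exact enumeration (inverse
#' CDF over all states, requires N * T within the cap), Metropolis MCMC,
#' and a causal chain that samples each time slice from its conditional
#' Gibbs step given the past (via the Lagrangian); the causal chain
#' coincides with the global measure only for nearest-step kinetic
#' couplings with configuration-independent normalisation.
#'
#' @param p [action_params()].
#' @param n_trials number of kernels to draw.
#' @param seed integer seed (mandatory).
#' @param mode `"enumeration"`, `"mcmc"` or `"causal"`.
#' @param cap enumeration cap on N * T (`"causal"` enumerates 2^N states
#'   per slice and caps N instead).
#' @param burnin,thin Metropolis controls (sweeps).
#' @return a [trial_ensemble()] of binary kernels.
#' @export
generate_gibbs_raster <- function(p, n_trials, seed,
                                  mode = c("enumeration", "mcmc", "causal"),
                                  cap = 20L, burnin = 1000L, thin = 2L) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  L <- p$N * p$T
  to_kernel <- function(s) {
    m <- matrix(s, p$N, p$T)
    if (p$representation == "spin") m <- (m + 1L) %/% 2L
    binary_kernel(m)
  }
  if (mode == "enumeration") {
    if (L > cap) stop("enumeration cap exceeded: N*T = ", L, " > ", cap)
    levels <- if (p$representation == "binary") c(0, 1) else c(-1, 1)
    S <- enumerate_states(L, levels)
    acts <- state_actions(S, p)
    w <- exp(-p$lam * (acts - min(acts)))
    set.seed(seed)
    idx <- sample.int(nrow(S), n_trials, replace = TRUE, prob = w)
    trials <- lapply(idx, function(r) to_kernel(S[r, ]))
  } else if (mode == "mcmc") {
    samp <- sample_gibbs_states(p, n_trials, seed, burnin = burnin,
                                thin = thin)
    trials <- lapply(seq_len(nrow(samp)), function(r) to_kernel(samp[r, ]))
  } else {
    if (p$N > cap) stop("causal mode enumerates 2^N slice states; N > ", cap)
    trials <- lapply(seq_len(n_trials), function(tr) {
      causal_gibbs_kernel(p, seed + tr - 1L)
    })
  }
  trial_ensemble(trials)
}

# Sequential conditional-Gibbs sampler over time slices: at each alpha the
# slice sigma_Valpha is drawn from exp(-lam * [H(alpha) - K(alpha) + input])
# normalised over the 2^N slice states, conditioning on the realized past.
causal_gibbs_kernel <- function(p, seed) {
  sp <- if (p$representation == "binary") spin_parameters(p) else
    list(params = p, constant = 0)
  ps <- sp$params
  set.seed(seed)
  slice_states <- enumerate_states(p$N, c(-1, 1))
  # per-state potential + input pieces reused across alpha
  pot <- 0.5 * rowSums((slice_states %*% (ps$A + t(ps$A))) * slice_states)
  sig <- matrix(0L, p$N, p$T)
  for (a in seq_len(p$T)) {
    e <- pot - as.vector(slice_states %*% ps$I[, a])
    if (a > 1L) {
      past <- sig[, seq_len(a - 1L), drop = FALSE]
      # kinetic contribution: sum_{b<a} B[a,b] * (s_a . s_b)
      kin_field <- past %*% ps$B[a, seq_len(a - 1L)]
      e <- e + as.vector(slice_states %*% kin_field)
    }
    w <- exp(-ps$lam * (e - min(e)))
    sig[, a] <- slice_states[sample.int(length(w), 1L, prob = w), ]
  }
  binary_kernel((sig + 1L) %/% 2L)
}

#' Columnar-lattice raster with per-site neuron groups
#'
#' Emulates a planar layer of cortical minitubes sampled by a
#' multielectrode array: each active lattice site hosts
#' `neurons_per_cell` neurons whose firing co-activates within the cell.
#' Each bin, a cell fires with `cell_rate`; given a cell event, each member
#' neuron joins with probability `co_activation` (1 = the whole cell fires
#' together; members also fire alone at `baseline_rate`).
#'
#' @param lattice an [electrode_lattice()].
#' @param n_bins number of clock bins.
#' @param neurons_per_cell neurons in each site's listening volume.
#' @param cell_rate per-bin probability of a cell event.
#' @param co_activation probability a member fires given its cell event.
#' @param baseline_rate independent per-neuron floor rate.
#' @param seed integer seed (mandatory).
#' @return list with `raster` (fine [binary_kernel()]), `positions`
#'   (N x 2, at the site centres) and `assignments` (site index per neuron).
#' @export
generate_columnar_kernel <- function(lattice, n_bins, neurons_per_cell = 3L,
                                     cell_rate = 0.05, co_activation = 0.8,
                                     baseline_rate = 0.005, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ns <- lattice$n_sites
  N <- ns * neurons_per_cell
  phi <- matrix(0L, N, n_bins)
  assignments <- rep(seq_len(ns), each = neurons_per_cell)
  for (s in seq_len(ns)) {
    rows <- which(assignments == s)
    events <- runif(n_bins) < cell_rate
    joins <- matrix(runif(length(rows) * n_bins) < co_activation,
                    length(rows), n_bins)
    solo <- matrix(runif(length(rows) * n_bins) < baseline_rate,
                   length(rows), n_bins)
    phi[rows, ] <- ((joins & matrix(events, length(rows), n_bins,
                                    byrow = TRUE)) | solo) * 1L
  }
  positions <- cbind(x = lattice$sites$x[assignments],
                     y = lattice$sites$y[assignments])
  list(raster = binary_kernel(phi), positions = positions,
       assignments = assignments)
}

#' Jittered trial ensemble from a base raster
#'
#' Replicates a base kernel `n` times, shifts each copy by a uniform random
#' integer jitter, and flips each cell independently with probability
#' `noise_flip_prob`. The true jitters are recorded so alignment can be
#' scored against them: recovering shift `-jitter[k]` (relative to trial 1)
#' realigns the ensemble.
#'
#' @param base a binary kernel; the analysis window is its central part,
#'   leaving `max(abs(jitter_range))` bins of slack on both sides.
#' @param n number of trials.
#' @param jitter_range integer vector (e.g. `-3:3`) the jitters are drawn
#'   from.
#' @param noise_flip_prob per-cell flip probability.
#' @param seed integer seed (mandatory).
#' @return a [trial_ensemble()] with attribute `true_jitter`.
#' @export
generate_trial_ensemble <- function(base, n, jitter_range = -3:3,
                                    noise_flip_prob = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  slack <- max(abs(jitter_range))
  Tfull <- n_bins(base)
  if (Tfull <= 2L * slack) stop("jitter exceeds the window slack")
  phi <- phi_matrix(base)
  jit <- sample(jitter_range, n, replace = TRUE)
  trials <- lapply(seq_len(n), function(k) {
    m <- phi
    if (jit[k] != 0L) {
      m <- matrix(0L, nrow(phi), Tfull)
      src <- seq_len(Tfull) - jit[k]
      ok <- src >= 1L & src <= Tfull
      m[, which(ok)] <- phi[, src[ok]]
    }
    if (noise_flip_prob > 0) {
      flips <- matrix(runif(length(m)) < noise_flip_prob, nrow(m))
      m <- (m + flips) %% 2L
    }
    binary_kernel(m, tau_ms = base$tau_ms)
  })
  e <- trial_ensemble(trials, window_start = slack + 1L,
                      window_length = Tfull - 2L * slack)
  attr(e, "true_jitter") <- jit
  e
}
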