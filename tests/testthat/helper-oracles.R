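# Shared oracles and fixture builders, independent of the code paths they
# check.

# Brute-force forward likelihood of a 2-state Gaussian HMM: sum over all
# 2^T state paths.
enumerate_loglik <- function(x, mu, sd, A, pi0) {
  T <- length(x)
  total <- 0
  for (code in 0:(2^T - 1)) {
    path <- as.integer(intToBits(code))[1:T] + 1L
    p <- pi0[path[1]] * stats::dnorm(x[1], mu[path[1]], sd[path[1]])
    if (T > 1) {
      for (t in 2:T) {
        p <- p * A[path[t - 1], path[t]] *
          stats::dnorm(x[t], mu[path[t]], sd[path[t]])
      }
    }
    total <- total + p
  }
  log(total)
}

# Brute-force most-likely path by enumeration (returns state indices).
enumerate_viterbi <- function(x, mu, sd, A, pi0) {
  T <- length(x)
  best <- NULL
  best_lp <- -Inf
  for (code in 0:(2^T - 1)) {
    path <- as.integer(intToBits(code))[1:T] + 1L
    lp <- log(pi0[path[1]]) +
      stats::dnorm(x[1], mu[path[1]], sd[path[1]], log = TRUE)
    if (T > 1) {
      for (t in 2:T) {
        lp <- lp + log(A[path[t - 1], path[t]]) +
          stats::dnorm(x[t], mu[path[t]], sd[path[t]], log = TRUE)
      }
    }
    if (lp > best_lp) {
      best_lp <- lp
      best <- path
    }
  }
  list(path = best, logp = best_lp)
}

# Build a two_state_hmm object directly (bypassing fitting).
make_hmm <- function(level_open, level_closed, sd, p_stay = c(0.95, 0.95),
                     initial = c(0.5, 0.5)) {
  structure(list(level_open = level_open, level_closed = level_closed,
                 sd = rep(sd, length.out = 2),
                 transition = rbind(c(p_stay[1], 1 - p_stay[1]),
                                    c(1 - p_stay[2], p_stay[2])),
                 initial = initial, loglik = NA_real_, n_iter = 0L,
                 converged = TRUE),
            class = "two_state_hmm")
}

# Minimal valid trace metadata.
base_meta <- function(...) {
  utils::modifyList(
    list(ligand = "AP5A", concentration = 1, conc_unit = "uM",
         trap_k1_pN_per_nm = 0.3, trap_k2_pN_per_nm = 0.3,
         trap_separation_nm = 420, sampling_rate_hz = 30000),
    list(...))
}

# Trace from a plain signal vector.
make_trace <- function(signal, fs = 30000, force = NULL, ...) {
  lid_trace(time_s = (seq_along(signal) - 0.5) / fs, signal_nm = signal,
            force_pN = force, meta = base_meta(sampling_rate_hz = fs, ...))
}

# Scalar bisection oracle for the tether force balance.
bisect_tether <- function(D, x_prot, model, tol = 1e-10) {
  bal <- function(f) {
    model$k_eff * (D - x_prot -
                     wlc_extension(f, model$dna, model$constants)) - f
  }
  lo <- 0; hi <- model$k_eff * (D - x_prot)
  if (bal(lo) <= 0) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (bal(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
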