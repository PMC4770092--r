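#' Fit a two-state Gaussian hidden Markov model to a trace
#'
#' Baum-Welch maximum-likelihood fit of a two-state HMM with Gaussian
#' emissions, run on the stored (unfiltered) signal. Initialization splits
#' the signal at its 2-means partition; iteration stops when the
#' log-likelihood gain falls below `tol` per sample or after `max_iter`
#' iterations. The log-likelihood is non-decreasing across iterations.
#'
#' State 1 is the level with the larger signal: under the construct-
#' extension convention the open (extended) conformation.
#'
#' @param trace A [lid_trace()] with at least 1000 samples (shorter traces
#'   are accepted only with `allow_short = TRUE`, used by small exactness
#'   tests). Traces whose history records display filtering are rejected:
#'   detection runs on unfiltered data only.
#' @param init Optional list with `level_open`, `level_closed`, `sd`
#'   (scalar or length 2), `p_stay` (scalar or length 2).
#' @param tol Convergence threshold on delta log-likelihood per sample.
#' @param max_iter Maximum Baum-Welch iterations.
#' @param allow_short Skip the minimum-length check.
#' @return An object of class `two_state_hmm`: `level_open`,
#'   `level_closed`, `sd` (length 2: open, closed), `transition` (2x2,
#'   rows open/closed), `initial`, `loglik`, `n_iter`, `converged`.
#' @export
fit_hmm <- function(trace, init = NULL, tol = 1e-8, max_iter = 500,
                    allow_short = FALSE) {
  stopifnot(inherits(trace, "lid_trace"))
  if (any(grepl("^lowpass", trace$meta$history))) {
    stop("trace history records display filtering; fit the HMM on the ",
         "unfiltered stored data")
  }
  x <- trace$signal_nm
  n <- length(x)
  if (n < 1000 && !allow_short) {
    stop("trace too short for HMM fitting (", n, " samples < 1000)")
  }
  if (is.null(init)) {
    km <- stats::kmeans(x, centers = matrix(stats::quantile(
      x, c(0.25, 0.75), names = FALSE), ncol = 1))
    mu <- sort(km$centers[, 1], decreasing = TRUE)  # open = upper level
    sd0 <- max(stats::sd(x - mu[km$cluster][
      order(km$centers[, 1], decreasing = TRUE)[km$cluster]]),
      1e-6 * max(abs(mu)))
    # simpler robust residual sd
    sd0 <- max(sqrt(min(km$withinss / km$size)), 1e-9)
    if (abs(mu[1] - mu[2]) < 0.1 * sd0) {
      stop("signal looks unimodal (2-means levels collapse within ",
           "0.1 sd); two-state fit not meaningful")
    }
    init <- list(level_open = mu[1], level_closed = mu[2],
                 sd = c(sd0, sd0), p_stay = c(0.99, 0.99))
  }
  mu <- c(init$level_open, init$level_closed)
  sd2 <- rep(init$sd, length.out = 2)
  p_stay <- rep(init$p_stay %||% 0.99, length.out = 2)
  A <- rbind(c(p_stay[1], 1 - p_stay[1]),
             c(1 - p_stay[2], p_stay[2]))
  pi0 <- c(0.5, 0.5)
  ll_old <- -Inf
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    B <- cbind(stats::dnorm(x, mu[1], sd2[1]),
               stats::dnorm(x, mu[2], sd2[2]))
    B[B < 1e-300] <- 1e-300
    es <- .hmm_estep(B, A, pi0)
    ll <- es$loglik
    g <- es$gamma
    xi <- es$xi_sum
    # M-step
    pi0 <- g[1, ] / sum(g[1, ])
    A <- xi / rowSums(xi)
    w <- colSums(g)
    mu <- colSums(g * x) / w
    sd2 <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / w)
    sd2 <- pmax(sd2, 1e-9)
    if (is.finite(ll_old) && (ll - ll_old) < tol * n) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) break
    ll_old <- ll
  }
  # keep state 1 = open (upper level)
  if (mu[1] < mu[2]) {
    mu <- rev(mu); sd2 <- rev(sd2); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
  }
  if (abs(mu[1] - mu[2]) < 0.1 * mean(sd2)) {
    stop("degenerate HMM fit: levels collapsed within 0.1 sd; ",
         "data may be single-state")
  }
  # a resolvable two-state signal separates its levels by at least half a
  # noise SD and is kinetically persistent; fits on unimodal data land
  # well below both
  if (abs(mu[1] - mu[2]) < 0.5 * mean(sd2) ||
      A[1, 1] + A[2, 2] < 1.2) {
    stop("no two-component structure detected (levels ",
         sprintf("%.3g", abs(mu[1] - mu[2])), " nm apart vs noise sd ",
         sprintf("%.3g", mean(sd2)),
         "); data look unimodal/single-state")
  }
  structure(list(level_open = mu[1], level_closed = mu[2], sd = sd2,
                 transition = A, initial = pi0, loglik = ll,
                 n_iter = n_iter, converged = converged),
            class = "two_state_hmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.two_state_hmm <- function(x, ...) {
  cat(sprintf(
    "Two-state HMM: open %.3f nm (sd %.3f), closed %.3f nm (sd %.3f)\n",
    x$level_open, x$sd[1], x$level_closed, x$sd[2]))
  cat(sprintf("  P(stay open) = %.6f, P(stay closed) = %.6f\n",
              x$transition[1, 1], x$transition[2, 2]))
  cat(sprintf("  loglik = %.2f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

.hmm_emissions <- function(hmm, x) {
  cbind(stats::dnorm(x, hmm$level_open, hmm$sd[1]),
        stats::dnorm(x, hmm$level_closed, hmm$sd[2]))
}

#' Forward log-likelihood of a trace under a fitted HMM
#'
#' @param hmm A `two_state_hmm`.
#' @param trace A [lid_trace()].
#' @return The exact forward log-likelihood.
#' @export
hmm_loglik <- function(hmm, trace) {
  B <- .hmm_emissions(hmm, trace$signal_nm)
  .hmm_loglik(B, hmm$transition, hmm$initial)
}

#' Posterior state probabilities per sample
#'
#' @param hmm A `two_state_hmm`.
#' @param trace A [lid_trace()].
#' @return T x 2 matrix of posteriors (columns open, closed); rows sum
#'   to 1.
#' @export
hmm_posterior <- function(hmm, trace) {
  B <- .hmm_emissions(hmm, trace$signal_nm)
  B[B < 1e-300] <- 1e-300
  es <- .hmm_estep(B, hmm$transition, hmm$initial)
  colnames(es$gamma) <- c("open", "closed")
  es$gamma
}

#' Most probable state path (Viterbi decoding)
#'
#' Deterministic; ties are broken toward remaining in the previous state.
#'
#' @param hmm A `two_state_hmm`.
#' @param trace A [lid_trace()].
#' @return Character vector of `"open"`/`"closed"` per sample.
#' @export
viterbi_path <- function(hmm, trace) {
  B <- .hmm_emissions(hmm, trace$signal_nm)
  B[B < 1e-300] <- 1e-300
  path <- .hmm_viterbi(log(B), log(hmm$transition), log(hmm$initial))
  c("open", "closed")[path + 1L]
}

#' Extract a censoring-aware dwell set from a decoded path
#'
#' Run-length encodes the state path; per-dwell mean force comes from the
#' trace's force channel. The first and last dwells are truncated by the
#' observation window and flagged censored. A diagnostic attribute
#' `min_reliable_dwell_s` (two sample periods) marks the detector
#' dead time below which dwells are unreliable; no missed-event
#' correction is applied.
#'
#' @param path Character vector from [viterbi_path()] (or ground truth).
#' @param trace The aligned [lid_trace()].
#' @return A `dwell_set`; if the path has two or fewer dwells every dwell
#'   is censored and a warning is raised.
#' @export
extract_dwells <- function(path, trace) {
  stopifnot(length(path) == length(trace$signal_nm))
  dt <- stats::median(diff(trace$time_s))
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  t0 <- trace$time_s[1] - dt / 2
  force <- rep(NA_real_, length(r$lengths))
  if (!is.null(trace$force_pN)) {
    force <- vapply(seq_along(starts), function(i) {
      mean(trace$force_pN[starts[i]:ends[i]])
    }, numeric(1))
  }
  censored <- logical(length(r$lengths))
  censored[1] <- TRUE
  censored[length(censored)] <- TRUE
  ds <- dwell_set(state = r$values,
                  t_start_s = t0 + (starts - 1L) * dt,
                  duration_s = r$lengths * dt,
                  mean_force_pN = force,
                  censored = censored,
                  meta = trace$meta[c("ligand", "concentration",
                                      "conc_unit", "trap_separation_nm")])
  attr(ds, "min_reliable_dwell_s") <- 2 * dt
  if (nrow(ds) <= 2) {
    warning("path has <= 2 dwells: all censored, no usable dwells")
  }
  ds
}

#' Low-pass filter a trace for display
#'
#' Zero-phase Butterworth smoothing (order 2, applied forward and
#' backward) at the display cutoff, 37.5 Hz by convention. Display only:
#' detection must run on the unfiltered data, and [fit_hmm()] rejects
#' filtered traces. The DC level is preserved.
#'
#' @param trace A [lid_trace()].
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @return The filtered trace with the filter recorded in the processing
#'   history.
#' @export
lowpass_display <- function(trace, cutoff_hz = 37.5) {
  stopifnot(inherits(trace, "lid_trace"))
  fs <- trace$meta$sampling_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop("cutoff ", cutoff_hz, " Hz at or above Nyquist (", fs / 2, " Hz)")
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  x <- trace$signal_nm
  n <- length(x)
  # odd-reflection padding so start-up transients decay inside the pad
  npad <- min(n - 1, ceiling(3 * fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(npad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - npad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  trace$signal_nm <- yp[(npad + 1):(npad + n)]
  trace_append_history(trace, sprintf("lowpass_%gHz", cutoff_hz))
}
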