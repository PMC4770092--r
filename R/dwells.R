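#' Censoring-aware dwell set
#'
#' The list of (state, duration, mean force) intervals extracted from a
#' trace or produced by the generator. The first and last dwells of a
#' trace are truncated by the observation window and must be flagged
#' censored; censored dwells are excluded from rate estimates.
#'
#' @param state Character vector, `"open"` or `"closed"`, alternating.
#' @param t_start_s Dwell start times, seconds.
#' @param duration_s Dwell durations, seconds (> 0).
#' @param mean_force_pN Mean tether force during the dwell.
#' @param censored Logical flags.
#' @param meta Named list of source metadata (ligand, concentration, ...).
#' @return A `dwell_set`: a data frame with a `meta` attribute.
#' @export
dwell_set <- function(state, t_start_s, duration_s, mean_force_pN,
                      censored, meta = list()) {
  n <- length(state)
  stopifnot(length(t_start_s) == n, length(duration_s) == n,
            length(mean_force_pN) == n, length(censored) == n)
  if (!all(state %in% c("open", "closed"))) {
    stop("states must be 'open' or 'closed'")
  }
  if (any(duration_s <= 0)) stop("dwell durations must be positive")
  if (n > 1 && any(state[-1] == state[-n])) {
    stop("dwell states must alternate")
  }
  structure(data.frame(state = state, t_start_s = t_start_s,
                       duration_s = duration_s,
                       mean_force_pN = mean_force_pN,
                       censored = as.logical(censored),
                       stringsAsFactors = FALSE),
            class = c("dwell_set", "data.frame"),
            meta = meta)
}

#' @export
print.dwell_set <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Dwell set: %d dwells (%d usable)", nrow(x),
              sum(!x$censored)))
  if (!is.null(m$ligand)) {
    cat(sprintf(", %s %g %s", m$ligand, m$concentration, m$conc_unit))
  }
  cat("\n")
  for (s in c("open", "closed")) {
    sel <- x$state == s & !x$censored
    if (any(sel)) {
      cat(sprintf("  %s: n = %d, mean dwell = %.4g s, mean force = %.3g pN\n",
                  s, sum(sel), mean(x$duration_s[sel]),
                  mean(x$mean_force_pN[sel])))
    }
  }
  invisible(x)
}

#' Usable (uncensored) dwells of one state
#'
#' @param dwells A `dwell_set`.
#' @param state `"open"` or `"closed"`.
#' @return The subset data frame of uncensored dwells in that state.
#' @export
usable_dwells <- function(dwells, state) {
  stopifnot(inherits(dwells, "dwell_set"), state %in% c("open", "closed"))
  dwells[dwells$state == state & !dwells$censored, , drop = FALSE]
}
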