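#' Construct a passive-mode trace
#'
#' A trace is the raw observable of a fixed-trap-separation experiment: a
#' time series of the construct extension signal (nm), optionally with a
#' per-sample force channel (pN), plus the metadata needed to interpret it
#' (ligand identity and concentration, trap stiffnesses and separation,
#' sampling rate, generator seed) and an append-only processing history.
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param signal_nm Signal in nm (construct extension convention).
#' @param force_pN Optional per-sample force in pN.
#' @param meta Named list of metadata. Mandatory keys:
#'   `ligand`, `concentration`, `conc_unit`, `trap_k1_pN_per_nm`,
#'   `trap_k2_pN_per_nm`, `trap_separation_nm`, `sampling_rate_hz`.
#'   Optional: `seed`, `history` (character vector, append-only).
#' @return An object of class `lid_trace`.
#' @export
lid_trace <- function(time_s, signal_nm, force_pN = NULL, meta = list()) {
  if (length(time_s) != length(signal_nm)) {
    stop("time and signal lengths differ")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1
    stop("time not strictly increasing at sample ", bad)
  }
  if (!is.null(force_pN) && length(force_pN) != length(time_s)) {
    stop("force channel length differs from time")
  }
  missing_keys <- setdiff(trace_required_meta(), names(meta))
  if (length(missing_keys) > 0) {
    stop("missing mandatory trace metadata: ",
         paste(missing_keys, collapse = ", "))
  }
  if (is.null(meta$history)) meta$history <- character(0)
  structure(list(time_s = as.numeric(time_s),
                 signal_nm = as.numeric(signal_nm),
                 force_pN = if (is.null(force_pN)) NULL
                            else as.numeric(force_pN),
                 meta = meta),
            class = "lid_trace")
}

trace_required_meta <- function() {
  c("ligand", "concentration", "conc_unit", "trap_k1_pN_per_nm",
    "trap_k2_pN_per_nm", "trap_separation_nm", "sampling_rate_hz")
}

#' @export
print.lid_trace <- function(x, ...) {
  n <- length(x$time_s)
  dur <- if (n > 1) x$time_s[n] - x$time_s[1] else 0
  cat(sprintf("Trace: %d samples, %.3f s, %s %g %s, fs = %g Hz\n",
              n, dur, x$meta$ligand, x$meta$concentration,
              x$meta$conc_unit, x$meta$sampling_rate_hz))
  if (length(x$meta$history) > 0) {
    cat("  history:", paste(x$meta$history, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.lid_trace <- function(x, ...) {
  d <- data.frame(time_s = x$time_s, signal_nm = x$signal_nm)
  if (!is.null(x$force_pN)) d$force_pN <- x$force_pN
  d
}

trace_append_history <- function(trace, step) {
  trace$meta$history <- c(trace$meta$history, step)
  trace
}
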