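#' Tether model: traps in series with DNA handles and protein
#'
#' The dumbbell geometry: two optical traps of stiffness `k1`, `k2`
#' (effective series stiffness `k_eff = (1/k1 + 1/k2)^-1`) connected
#' through dsDNA handles and the protein. The polypeptide parameters are
#' used for unfolded protein segments in force-distance analysis.
#'
#' @param dna [wlc_params()] for the dsDNA handles.
#' @param polypeptide Optional [wlc_params()] for unfolded polypeptide.
#' @param k1_pN_per_nm,k2_pN_per_nm Trap stiffnesses in pN/nm (> 0).
#' @param constants A [lid_constants()] object.
#' @return An object of class `tether_model`.
#' @export
tether_model <- function(dna = dna_wlc_params(),
                         polypeptide = polypeptide_wlc_params(n_residues = 30),
                         k1_pN_per_nm = 0.3, k2_pN_per_nm = 0.3,
                         constants = lid_constants()) {
  stopifnot(inherits(dna, "wlc_params"),
            k1_pN_per_nm > 0, k2_pN_per_nm > 0)
  structure(list(dna = dna, polypeptide = polypeptide,
                 k1 = k1_pN_per_nm, k2 = k2_pN_per_nm,
                 k_eff = 1 / (1 / k1_pN_per_nm + 1 / k2_pN_per_nm),
                 constants = constants),
            class = "tether_model")
}

#' Force balance of the trap-DNA-protein series system
#'
#' At fixed trap separation `D` and protein extension `x_p`, solves the
#' unique tension satisfying
#' \deqn{F = k_{eff}\,(D - x_p - x_{DNA}(F))}
#' where `x_DNA(F)` is the WLC extension of the handles. A slack geometry
#' (no positive-tension solution) returns zero force with `slack = TRUE`.
#'
#' @param trap_separation_nm Trap-centre separation in nm.
#' @param protein_extension_nm Protein contribution to the extension in nm.
#' @param model A [tether_model()].
#' @param slack_tol_pN Tension below which the geometry is reported slack
#'   (the inextensible WLC keeps an arbitrarily small entropic tension at
#'   any extension, so "no tension" is a threshold, not an exact zero).
#' @return List with `force_pN`, `bead_deflection_sum_nm` (= F/k_eff) and
#'   logical `slack`.
#' @export
solve_tether_equilibrium <- function(trap_separation_nm,
                                     protein_extension_nm, model,
                                     slack_tol_pN = 0.05) {
  stopifnot(inherits(model, "tether_model"))
  gap <- trap_separation_nm - protein_extension_nm
  if (gap <= 0) {
    stop("trap separation must exceed protein extension")
  }
  bal <- function(f) {
    model$k_eff * (gap - wlc_extension(f, model$dna, model$constants)) - f
  }
  if (bal(0) <= 0) {
    return(list(force_pN = 0, bead_deflection_sum_nm = 0, slack = TRUE))
  }
  hi <- model$k_eff * gap  # force if DNA had zero extension
  f <- stats::uniroot(bal, c(0, hi), tol = 1e-10)$root
  if (f < slack_tol_pN) {
    return(list(force_pN = 0, bead_deflection_sum_nm = 0, slack = TRUE))
  }
  list(force_pN = f, bead_deflection_sum_nm = f / model$k_eff,
       slack = FALSE)
}

#' Constant-force linker correction of a trace
#'
#' Removes the non-Hookean compliance of the dsDNA handles: for each data
#' point the handle extension at the instantaneous force is computed from
#' the fitted WLC parameters and subtracted from the signal, so the
#' remaining signal is the protein extension and level separations are
#' comparable across force biases. The transform is recorded in the
#' processing history and refuses to run twice unless `force = TRUE`.
#'
#' @param trace A [lid_trace()]. Must carry a force channel, or enough
#'   metadata (`trap_k1/k2`, `trap_separation_nm`) to compute one from the
#'   signal.
#' @param params [wlc_params()] of the DNA handles.
#' @param model Optional [tether_model()]; defaults to one built from the
#'   trace metadata and `params`.
#' @param force Logical; re-apply even if the history already records the
#'   transform.
#' @return The corrected `lid_trace` (signal in nm of protein extension).
#' @export
constant_force_transform <- function(trace, params, model = NULL,
                                     force = FALSE) {
  stopifnot(inherits(trace, "lid_trace"), inherits(params, "wlc_params"))
  if ("constant_force_transform" %in% trace$meta$history && !force) {
    stop("trace already carries a constant_force_transform in its ",
         "processing history; pass force = TRUE to re-apply")
  }
  if (is.null(model)) {
    m <- trace$meta
    if (is.null(m$trap_k1_pN_per_nm) || is.null(m$trap_k2_pN_per_nm)) {
      stop("trap stiffness metadata missing; cannot build tether model")
    }
    model <- tether_model(dna = params,
                          k1_pN_per_nm = m$trap_k1_pN_per_nm,
                          k2_pN_per_nm = m$trap_k2_pN_per_nm)
  }
  f <- trace$force_pN
  if (is.null(f)) {
    D <- trace$meta$trap_separation_nm
    if (is.null(D)) stop("no force channel and no trap separation metadata")
    # signal is construct extension: deflection sum = D - signal
    f <- model$k_eff * (D - trace$signal_nm)
    f[f < 0] <- 0
  }
  # interpolate the handle extension on a force grid (cheap and accurate)
  fr <- range(f)
  grid <- seq(fr[1], fr[2], length.out = 512)
  if (fr[1] == fr[2]) grid <- fr[1]
  xg <- wlc_extension(grid, params, model$constants)
  x_dna <- if (length(grid) == 1) rep(xg, length(f)) else {
    stats::approx(grid, xg, xout = f)$y
  }
  trace$signal_nm <- trace$signal_nm - x_dna
  trace$force_pN <- f
  trace_append_history(trace, "constant_force_transform")
}
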