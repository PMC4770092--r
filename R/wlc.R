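#' Worm-like chain parameters
#'
#' Parameter container for the Marko-Siggia interpolation formula, with an
#' optional enthalpic stretch modulus for extensible chains. Defaults are
#' not supplied here: dsDNA handles and unfolded polypeptide use different
#' values (see [dna_wlc_params()] and [polypeptide_wlc_params()]).
#'
#' @param persistence_nm Persistence length in nm (> 0).
#' @param contour_nm Contour length in nm (> 0).
#' @param stretch_pN Optional stretch modulus in pN (> 0); `NULL` means
#'   inextensible.
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(persistence_nm, contour_nm, stretch_pN = NULL) {
  stopifnot(is.numeric(persistence_nm), length(persistence_nm) == 1,
            persistence_nm > 0,
            is.numeric(contour_nm), length(contour_nm) == 1, contour_nm > 0)
  if (!is.null(stretch_pN)) {
    stopifnot(is.numeric(stretch_pN), length(stretch_pN) == 1,
              stretch_pN > 0)
  }
  structure(list(persistence_nm = persistence_nm,
                 contour_nm = contour_nm,
                 stretch_pN = stretch_pN),
            class = "wlc_params")
}

#' Field-standard WLC defaults for dsDNA handles and unfolded polypeptide
#'
#' dsDNA: persistence length 50 nm, contour 360 nm (the handle length used
#' in the experiments). Polypeptide: persistence length 0.7 nm, contour
#' 0.365 nm per residue.
#'
#' @param contour_nm Contour length in nm.
#' @param persistence_nm Persistence length in nm.
#' @param stretch_pN Optional stretch modulus in pN.
#' @return A [wlc_params()] object.
#' @export
dna_wlc_params <- function(contour_nm = 360, persistence_nm = 50,
                           stretch_pN = NULL) {
  wlc_params(persistence_nm, contour_nm, stretch_pN)
}

#' @rdname dna_wlc_params
#' @param n_residues Number of residues (contour = 0.365 nm/residue).
#' @export
polypeptide_wlc_params <- function(n_residues = NULL, contour_nm = NULL,
                                   persistence_nm = 0.7) {
  if (is.null(contour_nm)) {
    if (is.null(n_residues)) stop("give n_residues or contour_nm")
    contour_nm <- 0.365 * n_residues
  }
  wlc_params(persistence_nm, contour_nm)
}

# Marko-Siggia interpolation at relative extension l = x/L (inextensible).
.ms_force <- function(l, persistence_nm, kBT) {
  (kBT / persistence_nm) * (1 / (4 * (1 - l)^2) - 0.25 + l)
}

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation formula
#' \deqn{F(x) = \frac{k_BT}{P}\left[\frac{1}{4(1-x/L)^2} - \frac14 +
#'   \frac{x}{L}\right]}
#' For an extensible chain (finite stretch modulus `S`), `x/L` is replaced
#' by `x/L - F/S` and the implicit equation is solved numerically.
#'
#' @param extension_nm Extension(s) in nm. Inextensible chains require
#'   `0 <= extension < contour`.
#' @param params A [wlc_params()] object.
#' @param constants A [lid_constants()] object.
#' @return Force(s) in pN; strictly increasing and continuous in extension.
#' @export
wlc_force <- function(extension_nm, params, constants = lid_constants()) {
  stopifnot(inherits(params, "wlc_params"))
  L <- params$contour_nm
  P <- params$persistence_nm
  kBT <- constants$kBT
  if (any(extension_nm < 0)) {
    stop("negative extension: ", min(extension_nm), " nm")
  }
  if (is.null(params$stretch_pN)) {
    if (any(extension_nm >= L)) {
      stop("extension ", max(extension_nm),
           " nm reaches or exceeds contour length ", L,
           " nm (inextensible chain)")
    }
    return(.ms_force(extension_nm / L, P, kBT))
  }
  S <- params$stretch_pN
  # Implicit: F = ms(x/L - F/S). Monotone in F, solve per point.
  vapply(extension_nm, function(x) {
    g <- function(f) .ms_force(pmin(x / L - f / S, 1 - 1e-12), P, kBT) - f
    if (x == 0) return(0)
    upper <- max(10, 2 * S * (x / L))
    while (g(upper) > 0) upper <- upper * 2
    stats::uniroot(g, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
}

#' Worm-like chain extension at a given force (numerical inverse)
#'
#' Inverts [wlc_force()] by bracketed bisection to a relative tolerance of
#' 1e-9, so that `wlc_force(wlc_extension(F)) == F` to that accuracy.
#'
#' @param force_pN Force(s) in pN, must be >= 0.
#' @param params A [wlc_params()] object.
#' @param constants A [lid_constants()] object.
#' @return Extension(s) in nm; monotone in force.
#' @export
wlc_extension <- function(force_pN, params, constants = lid_constants()) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force_pN < 0)) {
    stop("negative force: ", min(force_pN), " pN")
  }
  L <- params$contour_nm
  vapply(force_pN, function(f) {
    if (f == 0) return(0)
    if (is.null(params$stretch_pN)) {
      g <- function(x) wlc_force(x, params, constants) - f
      lo <- 0
      hi <- L * (1 - 1e-14)
      # bisection to near machine precision: the force diverges at the
      # contour length, so the extension interval must shrink far below
      # the requested relative force accuracy of 1e-9
      while ((hi - lo) > 2e-13 * L) {
        mid <- (lo + hi) / 2
        if (g(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    } else {
      # extensible: x = L*(l_ms(F) + F/S) with l_ms the inextensible inverse
      inext <- wlc_params(params$persistence_nm, params$contour_nm)
      x_in <- wlc_extension(f, inext, constants)
      x_in + L * f / params$stretch_pN
    }
  }, numeric(1))
}
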