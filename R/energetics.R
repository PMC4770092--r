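#' Equilibrium free energy of closing from rate constants
#'
#' \deqn{\Delta G(\mathrm{open}\to\mathrm{closed}) = -k_BT\,
#'   \ln(k_{close}/k_{open})}
#' Negative when closing is favoured. Evaluated at whatever force the
#' rates refer to; with zero-force extrapolated rates it gives the
#' zero-force equilibrium free energy.
#'
#' @param k_close,k_open Rate constants in 1/s (> 0).
#' @param constants A [lid_constants()] object.
#' @return Free energy in kBT.
#' @export
dG_from_rates <- function(k_close, k_open, constants = lid_constants()) {
  if (any(k_close <= 0) || any(k_open <= 0)) {
    stop("rates must be positive")
  }
  -log(k_close / k_open)
}

#' Binding free-energy change in the competition assay
#'
#' Signed difference of the apparent inhibitor binding free energy with
#' and without nucleotide, at matched inhibitor concentration and force
#' treatment. Positive values mean the nucleotide destabilizes apparent
#' inhibitor binding (it blocks inhibitor rebinding during open dwells).
#'
#' @param dG_ref Free energy (kBT) at reference (inhibitor-only)
#'   conditions.
#' @param dG_with_ligand Free energy (kBT) with nucleotide added.
#' @param conditions_ref,conditions_ligand Optional named lists of
#'   condition metadata; if both given, entries shared by name must match.
#' @return The difference `dG_with_ligand - dG_ref` in kBT.
#' @export
ddG_competition <- function(dG_ref, dG_with_ligand,
                            conditions_ref = NULL,
                            conditions_ligand = NULL) {
  if (!is.null(conditions_ref) && !is.null(conditions_ligand)) {
    shared <- intersect(names(conditions_ref), names(conditions_ligand))
    for (k in shared) {
      if (!identical(conditions_ref[[k]], conditions_ligand[[k]])) {
        stop("mismatched condition '", k, "' between reference and ",
             "ligand measurements")
      }
    }
  }
  dG_with_ligand - dG_ref
}

#' Fit a dissociation constant to concentration-dependent ddG data
#'
#' Least-squares fit of the single-site competition model
#' \deqn{\Delta\Delta G([L]) = k_BT \ln(1 + [L]/K_D)}
#' by Levenberg-Marquardt on \eqn{\log K_D}. Needs at least 3
#' concentrations spanning at least one decade. If every concentration
#' lies well below the fitted \eqn{K_D} the constant is unidentifiable
#' and only a lower bound is reported, with a warning.
#'
#' @param points Data frame with columns `conc` (one common unit) and
#'   `ddG_kBT`; optional `se` column used as weights.
#' @param conc_unit Unit label carried through to the result.
#' @return An object of class `kd_fit` with `KD`, `KD_se`, `conc_unit`,
#'   `lower_bound_only`, `fit` (the `nls` object), `points`.
#' @export
fit_kd_from_ddG <- function(points, conc_unit = "uM") {
  stopifnot(all(c("conc", "ddG_kBT") %in% names(points)))
  d <- as.data.frame(points)
  d <- d[d$conc > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 nonzero concentrations")
  if (max(d$conc) / min(d$conc) < 10) {
    stop("concentrations must span at least one decade")
  }
  w <- if (!is.null(d$se) && all(d$se > 0)) 1 / d$se^2 else NULL
  # start: concentration at which ddG = ln 2
  start_kd <- stats::approx(d$ddG_kBT, d$conc, xout = log(2),
                            rule = 2, ties = mean)$y
  fm <- .nlsLM(ddG_kBT ~ log(1 + conc / exp(logKD)),
                          data = d, weights = w,
                          start = list(logKD = log(max(start_kd,
                                                       min(d$conc)))))
  logKD <- stats::coef(fm)[["logKD"]]
  KD <- exp(logKD)
  KD_se <- KD * summary(fm)$coefficients["logKD", "Std. Error"]
  lower_only <- all(d$conc < KD / 5)
  if (lower_only) {
    warning("all concentrations lie well below the fitted KD; ",
            "treat KD as a lower bound only")
  }
  structure(list(KD = KD, KD_se = KD_se, conc_unit = conc_unit,
                 lower_bound_only = lower_only, fit = fm, points = d),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Single-site binding fit: KD = %.4g +/- %.2g %s%s\n",
              x$KD, x$KD_se, x$conc_unit,
              if (x$lower_bound_only) " (lower bound only)" else ""))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(KD = object$KD)

#' @export
predict.kd_fit <- function(object, conc, ...) {
  log(1 + conc / object$KD)
}

#' Fraction of the open dwell during which substrate blocks rebinding
#'
#' From the lengthening of mean open dwells when substrate is added to the
#' competition assay: if the inhibitor can only rebind while the enzyme is
#' substrate-free, the blocked fraction is
#' \deqn{1 - \tau_{open,ref}/\tau_{open,ligand}.}
#'
#' @param tau_open_ref Mean open dwell without substrate, seconds.
#' @param tau_open_ligand Mean open dwell with substrate, seconds (must be
#'   >= `tau_open_ref`: substrate cannot shorten the reference dwell in
#'   this model).
#' @return Dimensionless fraction in [0, 1).
#' @examples
#' blocked_fraction(5e-3, 0.5)  # 0.99
#' @export
blocked_fraction <- function(tau_open_ref, tau_open_ligand) {
  if (any(tau_open_ref <= 0) || any(tau_open_ligand <= 0)) {
    stop("dwell lifetimes must be positive")
  }
  if (any(tau_open_ligand < tau_open_ref)) {
    stop("tau_open_ligand < tau_open_ref: ligand cannot shorten the ",
         "reference open dwell in this model")
  }
  1 - tau_open_ref / tau_open_ligand
}
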