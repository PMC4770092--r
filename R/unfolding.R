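# ATP-lid equilibrium unfolding: branch fits to force-distance curves and
# the composite-area free energy of the folding/unfolding transition.

# model trap distance at force F for a set of serial elements
.branch_distance <- function(force_pN, elements, k_eff, constants) {
  x <- force_pN / k_eff
  for (el in elements) {
    if (is.numeric(el)) {
      x <- x + el             # rigid offset (folded protein)
    } else {
      x <- x + vapply(force_pN, wlc_extension, numeric(1),
                      params = el, constants = constants)
    }
  }
  x
}

# invert a branch: force at trap distance D
.branch_force <- function(D, elements, k_eff, constants, f_max = 80) {
  vapply(D, function(d) {
    g <- function(f) .branch_distance(f, elements, k_eff, constants) - d
    if (g(1e-6) > 0) return(0)
    stats::uniroot(g, c(1e-6, f_max), tol = 1e-8)$root
  }, numeric(1))
}

#' Fit folded and unfolded elasticity branches of a force-distance curve
#'
#' The folded branch (below the transition window) is the DNA handles in
#' series with the traps and the folded protein; the unfolded branch
#' (above the window) adds the released polypeptide as a second WLC in
#' series with extra contour length. Both fits run in distance space
#' (model trap distance at the measured force), exclude the transition
#' window (default 13-20 pN, where the fast equilibrium transition
#' lives), and share the DNA parameters: persistence length and contour
#' length are fitted on the folded branch, then held fixed while the
#' polypeptide contour gain is fitted on the unfolded branch.
#'
#' @param fec A `lid_fec` force-distance curve.
#' @param tether A [tether_model()] providing trap stiffness, starting DNA
#'   parameters and the polypeptide persistence length.
#' @param transition_window_pN Force window excluded from both fits.
#' @param folded_extension_nm Extension of the folded protein (fixed).
#' @param min_force_pN Lower force cut for the folded fit (noise floor).
#' @return An object of class `fec_branches`: `dna` (fitted
#'   [wlc_params()]), `contour_gain_nm` (+ se), `folded_extension_nm`,
#'   `k_eff`, fit objects and the excluded window.
#' @export
fit_branches <- function(fec, tether = tether_model(),
                         transition_window_pN = c(13, 20),
                         folded_extension_nm = 2,
                         min_force_pN = 1) {
  stopifnot(inherits(fec, "lid_fec"))
  F <- fec$force_pN
  D <- fec$trap_distance_nm
  lo <- F >= min_force_pN & F < transition_window_pN[1]
  hi <- F > transition_window_pN[2]
  if (sum(lo) < 10) {
    stop("curve does not span the folded branch below ",
         transition_window_pN[1], " pN")
  }
  if (sum(hi) < 10) {
    stop("curve does not span the unfolded branch above ",
         transition_window_pN[2],
         " pN; cannot fit the unfolded state (folded-only data?)")
  }
  cst <- tether$constants
  keff <- tether$k_eff
  df_lo <- data.frame(D = D[lo], F = F[lo])
  model_folded <- function(F, P, L) {
    F / keff + folded_extension_nm +
      vapply(F, wlc_extension, numeric(1), params = wlc_params(P, L),
             constants = cst)
  }
  fm_fold <- .nlsLM(
    D ~ model_folded(F, P, L),
    data = df_lo,
    start = list(P = tether$dna$persistence_nm,
                 L = tether$dna$contour_nm),
    control = minpack.lm::nls.lm.control(maxiter = 100))
  cf <- stats::coef(fm_fold)
  dna_fit <- wlc_params(cf[["P"]], cf[["L"]])
  df_hi <- data.frame(D = D[hi], F = F[hi])
  pp_P <- tether$polypeptide$persistence_nm
  model_unfolded <- function(F, Lg) {
    F / keff +
      vapply(F, wlc_extension, numeric(1), params = dna_fit,
             constants = cst) +
      vapply(F, wlc_extension, numeric(1),
             params = wlc_params(pp_P, Lg), constants = cst)
  }
  fm_unf <- .nlsLM(
    D ~ model_unfolded(F, Lg),
    data = df_hi,
    start = list(Lg = max(diff(range(D[hi])), 5)),
    control = minpack.lm::nls.lm.control(maxiter = 100))
  sm_f <- summary(fm_fold)$coefficients
  sm_u <- summary(fm_unf)$coefficients
  structure(list(dna = dna_fit,
                 dna_se = c(P = sm_f["P", "Std. Error"],
                            L = sm_f["L", "Std. Error"]),
                 contour_gain_nm = stats::coef(fm_unf)[["Lg"]],
                 contour_gain_se_nm = sm_u["Lg", "Std. Error"],
                 polypeptide_persistence_nm = pp_P,
                 folded_extension_nm = folded_extension_nm,
                 k_eff = keff, constants = cst,
                 transition_window_pN = transition_window_pN,
                 fit_folded = fm_fold, fit_unfolded = fm_unf),
            class = "fec_branches")
}

#' @export
print.fec_branches <- function(x, ...) {
  cat(sprintf(
    "Branch fits: DNA P = %.3g nm, L = %.4g nm; contour gain = %.4g +/- %.2g nm\n",
    x$dna$persistence_nm, x$dna$contour_nm, x$contour_gain_nm,
    x$contour_gain_se_nm))
  invisible(x)
}

#' Free energy of the equilibrium folding/unfolding transition
#'
#' Integrates the force-distance curve over trap distance. The energy of
#' the whole system is the area under the folded-branch fit up to the
#' crossover force (default 10 pN, reducing the influence of noise at low
#' forces) plus the area under the measured curve above it; subtracting
#' the area under the unfolded-branch fit over the same distance range
#' leaves the free energy of the folding/unfolding transition. Trap and
#' linker work cancel in the subtraction.
#'
#' @param fec A `lid_fec`.
#' @param branches A `fec_branches` from [fit_branches()].
#' @param crossover_pN Force below which the folded fit replaces the
#'   measured curve (default 10).
#' @return An object of class `unfolding_energy`: `dG_kBT`, `se_kBT`
#'   (from the measured-curve noise), `bounds_nm`, `crossover_nm` and the
#'   branch force curves on the data grid.
#' @export
transition_free_energy <- function(fec, branches, crossover_pN = 10) {
  stopifnot(inherits(fec, "lid_fec"), inherits(branches, "fec_branches"))
  D <- fec$trap_distance_nm
  Fm <- fec$force_pN
  ord <- order(D)
  D <- D[ord]; Fm <- Fm[ord]
  cst <- branches$constants
  fold_el <- list(branches$dna, branches$folded_extension_nm)
  unf_el <- list(branches$dna,
                 wlc_params(branches$polypeptide_persistence_nm,
                            branches$contour_gain_nm))
  f_fold <- .branch_force(D, fold_el, branches$k_eff, cst)
  f_unf <- .branch_force(D, unf_el, branches$k_eff, cst)
  if (max(f_fold) < crossover_pN) {
    stop("crossover force ", crossover_pN,
         " pN outside the folded-fit range of the data")
  }
  i_x <- which(f_fold >= crossover_pN)[1]
  total <- c(f_fold[seq_len(i_x - 1)], Fm[i_x:length(D)])
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  area_total <- trapz(D, total)
  area_unf <- trapz(D, f_unf)
  kBT <- cst$kBT
  # noise contribution: distance of the measured curve to the nearer branch
  res_sd <- stats::sd(pmin(abs(Fm - f_fold), abs(Fm - f_unf)))
  n_meas <- length(D) - i_x + 1
  dD <- stats::median(diff(D))
  se <- res_sd * dD * sqrt(n_meas) / kBT
  structure(list(dG_kBT = (area_total - area_unf) / kBT,
                 se_kBT = se,
                 bounds_nm = range(D),
                 crossover_nm = D[i_x],
                 crossover_pN = crossover_pN,
                 branch_forces = data.frame(trap_distance_nm = D,
                                            folded_pN = f_fold,
                                            unfolded_pN = f_unf)),
            class = "unfolding_energy")
}

#' @export
print.unfolding_energy <- function(x, ...) {
  cat(sprintf(
    "Equilibrium unfolding free energy: %.3g +/- %.2g kBT (crossover %.3g pN)\n",
    x$dG_kBT, x$se_kBT, x$crossover_pN))
  invisible(x)
}

#' Dissociation constant from nucleotide-stabilized unfolding energies
#'
#' Ligand binding stabilizes the folded lid, raising the unfolding free
#' energy with concentration as
#' \deqn{\Delta G([L]) = \Delta G^0 + k_BT \ln(1 + [L]/K_D)}
#' Both the apo free energy and \eqn{K_D} are fitted (Levenberg-
#' Marquardt) unless `dG0_kBT` is supplied, in which case the apo value is
#' held fixed. This is the cross-check route to the same \eqn{K_D} as the
#' competition-assay fit.
#'
#' @param points Data frame with columns `conc` (one common unit; the apo
#'   point `conc = 0` may be included) and `dG_kBT`; optional `se`.
#' @param dG0_kBT Optional fixed apo free energy; mandatory if no apo
#'   point is present.
#' @param conc_unit Unit label for reporting.
#' @return An object of class `stabilization_fit` (also `kd_fit`):
#'   `KD`, `KD_se`, `dG0_kBT` (+ se when fitted), `fit`, `points`.
#' @export
fit_nucleotide_stabilization <- function(points, dG0_kBT = NULL,
                                         conc_unit = "uM") {
  stopifnot(all(c("conc", "dG_kBT") %in% names(points)))
  d <- as.data.frame(points)
  has_apo <- any(d$conc == 0)
  if (!has_apo && is.null(dG0_kBT)) {
    stop("supply dG0_kBT or include an apo (conc = 0) point")
  }
  nz <- d[d$conc > 0, , drop = FALSE]
  if (nrow(nz) < 3) stop("need >= 3 nonzero concentrations")
  if (max(nz$conc) / min(nz$conc) < 10) {
    stop("concentrations must span at least one decade")
  }
  w <- if (!is.null(d$se) && all(d$se > 0)) 1 / d$se^2 else NULL
  g0_start <- if (!is.null(dG0_kBT)) dG0_kBT else
    mean(d$dG_kBT[d$conc == 0])
  half <- stats::approx(nz$dG_kBT - g0_start, nz$conc, xout = log(2),
                        rule = 2, ties = mean)$y
  if (is.null(dG0_kBT)) {
    fm <- .nlsLM(dG_kBT ~ g0 + log(1 + conc / exp(logKD)),
                            data = d, weights = w,
                            start = list(g0 = g0_start,
                                         logKD = log(half)))
    sm <- summary(fm)$coefficients
    g0 <- stats::coef(fm)[["g0"]]
    g0_se <- sm["g0", "Std. Error"]
  } else {
    g0 <- dG0_kBT; g0_se <- NA_real_
    fm <- .nlsLM(dG_kBT ~ g0 + log(1 + conc / exp(logKD)),
                            data = d, weights = w,
                            start = list(logKD = log(half)))
    sm <- summary(fm)$coefficients
  }
  KD <- exp(stats::coef(fm)[["logKD"]])
  KD_se <- KD * sm["logKD", "Std. Error"]
  structure(list(KD = KD, KD_se = KD_se, dG0_kBT = g0,
                 dG0_se_kBT = g0_se, conc_unit = conc_unit,
                 lower_bound_only = all(nz$conc < KD / 5),
                 fit = fm, points = d),
            class = c("stabilization_fit", "kd_fit"))
}

#' @export
print.stabilization_fit <- function(x, ...) {
  cat(sprintf(
    "Nucleotide stabilization fit: dG0 = %.3g kBT, KD = %.4g +/- %.2g %s\n",
    x$dG0_kBT, x$KD, x$KD_se, x$conc_unit))
  invisible(x)
}
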