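#' Two-dimensional lid-opening free-energy grid
#'
#' A rectangular grid of free energies (kBT) over the AMP-lid and ATP-lid
#' opening coordinates (Angstrom: centre-of-mass distances between lid and
#' core residue groups). Masked (NA) cells mark omitted umbrella windows.
#'
#' @param d_AMP_A Strictly increasing AMP-lid axis, Angstrom.
#' @param d_ATP_A Strictly increasing ATP-lid axis, Angstrom.
#' @param free_energy_kBT Matrix `length(d_AMP_A) x length(d_ATP_A)` in
#'   kBT; NA cells allowed, at least one finite cell required.
#' @return An object of class `pmf_grid`.
#' @export
pmf_grid <- function(d_AMP_A, d_ATP_A, free_energy_kBT) {
  stopifnot(is.matrix(free_energy_kBT),
            nrow(free_energy_kBT) == length(d_AMP_A),
            ncol(free_energy_kBT) == length(d_ATP_A))
  if (length(d_AMP_A) > 1 && any(diff(d_AMP_A) <= 0) ||
      length(d_ATP_A) > 1 && any(diff(d_ATP_A) <= 0)) {
    stop("grid axes must be strictly increasing")
  }
  if (!any(is.finite(free_energy_kBT))) {
    stop("grid has no finite cells")
  }
  structure(list(d_AMP_A = d_AMP_A, d_ATP_A = d_ATP_A,
                 free_energy_kBT = free_energy_kBT),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf(
    "PMF grid: %d x %d cells (%d masked), AMP-lid %.4g-%.4g A, ATP-lid %.4g-%.4g A\n",
    length(x$d_AMP_A), length(x$d_ATP_A),
    sum(!is.finite(x$free_energy_kBT)),
    min(x$d_AMP_A), max(x$d_AMP_A), min(x$d_ATP_A), max(x$d_ATP_A)))
  invisible(x)
}

#' Location of the global free-energy minimum
#'
#' Deterministic: ties are broken toward the smallest coordinates
#' (AMP-lid axis first); a tie is flagged in the result.
#'
#' @param grid A [pmf_grid()].
#' @return List with `d0_AMP_A`, `d0_ATP_A`, `G_min_kBT`, `tie`.
#' @export
find_global_minimum <- function(grid) {
  stopifnot(inherits(grid, "pmf_grid"))
  g <- grid$free_energy_kBT
  gmin <- min(g, na.rm = TRUE)
  hits <- which(g == gmin, arr.ind = TRUE)
  # order by AMP index then ATP index: smallest coordinates first
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(d0_AMP_A = grid$d_AMP_A[hits[1, 1]],
       d0_ATP_A = grid$d_ATP_A[hits[1, 2]],
       G_min_kBT = gmin,
       tie = nrow(hits) > 1)
}

#' Project a 2D lid-opening landscape onto a 1D lid-to-lid coordinate
#'
#' The projection coordinate combines the displacements of both lid
#' coordinates from the location of the global minimum; with the default
#' `combine = "sum"` (lid motions assumed mainly orthogonal)
#' \deqn{d = (d_{AMP} - d_{0,AMP}) + (d_{ATP} - d_{0,ATP}).}
#' Cells are binned on this coordinate (default bin width: the largest
#' axis spacing) and reduced within each bin either by Boltzmann
#' marginalization, \eqn{-k_BT\ln\sum e^{-G/k_BT}} (default), or by the
#' bin minimum. The Boltzmann profile is shifted so its minimum is zero;
#' it never exceeds the min-reduction profile.
#'
#' @param grid A [pmf_grid()].
#' @param method Within-bin reduction: `"boltzmann"` or `"min"`.
#' @param bin_width_A Bin width on the projected coordinate.
#' @param combine How the two displacements form the coordinate:
#'   `"sum"` (default) or a function `(dAMP, dATP) -> d`.
#' @return An object of class `pmf_profile`: data frame columns `d_A`,
#'   `G_kBT`, plus attribute `provenance` recording minimum location,
#'   method, and any force applied.
#' @export
project_to_1d <- function(grid, method = c("boltzmann", "min"),
                          bin_width_A = NULL, combine = "sum") {
  stopifnot(inherits(grid, "pmf_grid"))
  method <- match.arg(method)
  m0 <- find_global_minimum(grid)
  if (is.character(combine)) {
    if (combine != "sum") stop("unknown combine rule: ", combine)
    cfun <- function(a, b) a + b
  } else {
    cfun <- combine
  }
  dA <- outer(grid$d_AMP_A - m0$d0_AMP_A,
              rep(1, length(grid$d_ATP_A)))
  dB <- outer(rep(1, length(grid$d_AMP_A)),
              grid$d_ATP_A - m0$d0_ATP_A)
  d <- cfun(dA, dB)
  g <- grid$free_energy_kBT
  keep <- is.finite(g)
  d <- d[keep]; g <- g[keep]
  if (is.null(bin_width_A)) {
    sp <- c(diff(grid$d_AMP_A), diff(grid$d_ATP_A))
    bin_width_A <- if (length(sp) > 0) max(sp) else 1
  }
  bin <- round(d / bin_width_A)
  centers <- sort(unique(bin)) * bin_width_A
  G <- vapply(sort(unique(bin)), function(b) {
    gs <- g[bin == b]
    if (method == "min") min(gs) else -log(sum(exp(-gs)))
  }, numeric(1))
  if (method == "boltzmann") G <- G - min(G)
  structure(data.frame(d_A = centers, G_kBT = G),
            class = c("pmf_profile", "data.frame"),
            provenance = list(d0_AMP_A = m0$d0_AMP_A,
                              d0_ATP_A = m0$d0_ATP_A,
                              minimum_tie = m0$tie,
                              method = method,
                              bin_width_A = bin_width_A,
                              force_pN = 0))
}

#' Tilt a 1D free-energy profile by an external force
#'
#' \deqn{G'(d) = G(d) - F\,d} with the pN.Angstrom work converted to kBT
#' through the configured constants; the biased profile is shifted so its
#' new minimum is zero, matching how profiles under load are reported.
#'
#' @param profile A `pmf_profile`.
#' @param force_pN External force in pN (15 pN is the load representative
#'   of the experiments).
#' @param constants A [lid_constants()] object.
#' @return The biased, min-shifted `pmf_profile`; provenance records the
#'   accumulated force.
#' @export
apply_external_force <- function(profile, force_pN,
                                 constants = lid_constants()) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (!all(is.finite(profile$G_kBT))) stop("profile must be finite")
  # 1 pN * 1 A = 0.1 pN nm
  work_kBT <- force_pN * 0.1 * profile$d_A / constants$kBT
  profile$G_kBT <- profile$G_kBT - work_kBT
  profile$G_kBT <- profile$G_kBT - min(profile$G_kBT)
  prov <- attr(profile, "provenance")
  prov$force_pN <- prov$force_pN + force_pN
  attr(profile, "provenance") <- prov
  profile
}

#' @export
print.pmf_profile <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf(
    "PMF profile: %d bins over %.4g-%.4g A (%s reduction, %g pN bias)\n",
    nrow(x), min(x$d_A), max(x$d_A), prov$method, prov$force_pN))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$d_A, x$G_kBT, type = "l",
       xlab = "lid-to-lid coordinate (A)",
       ylab = "free energy (kBT)", ...)
  invisible(x)
}
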