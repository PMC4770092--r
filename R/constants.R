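#' Physical constants at a fixed temperature
#'
#' Bundles the absolute temperature with the thermal energy `kBT` used
#' throughout: Bell-model exponents, Boltzmann occupancies, free-energy
#' conversions. The Boltzmann constant is 0.0138065 pN nm / K, so the
#' default 298 K gives kBT = 4.114 pN nm.
#'
#' @param temperature_K Absolute temperature in kelvin (default 298).
#' @return An object of class `lid_constants` with fields `temperature_K`
#'   and `kBT` (pN nm).
#' @examples
#' lid_constants()$kBT  # 4.114 pN nm
#' @export
lid_constants <- function(temperature_K = 298) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("temperature_K must be a single positive number, got: ",
         temperature_K)
  }
  structure(
    list(temperature_K = temperature_K,
         kBT = 0.0138065 * temperature_K),
    class = "lid_constants"
  )
}

#' @export
print.lid_constants <- function(x, ...) {
  cat(sprintf("Constants: T = %g K, kBT = %.4f pN nm\n",
              x$temperature_K, x$kBT))
  invisible(x)
}

#' Convert kcal/mol to kBT units
#'
#' Uses the gas constant R = 0.0019872 kcal/(mol K): 1 kcal/mol equals
#' 1/(0.0019872 * T) kBT at temperature T.
#'
#' @param x Energies in kcal/mol.
#' @param constants A [lid_constants()] object.
#' @return Energies in kBT.
#' @export
kcal_per_mol_to_kBT <- function(x, constants = lid_constants()) {
  x / (0.0019872 * constants$temperature_K)
}

#' @rdname kcal_per_mol_to_kBT
#' @export
kBT_to_kcal_per_mol <- function(x, constants = lid_constants()) {
  x * (0.0019872 * constants$temperature_K)
}

# nlsLM evaluates an explicit weights = NULL to numeric(0); drop the
# argument instead.
.nlsLM <- function(formula, data, start, weights = NULL, ...) {
  args <- list(formula = formula, data = data, start = start, ...)
  if (!is.null(weights)) args$weights <- weights
  do.call(minpack.lm::nlsLM, args)
}

# Concentration bookkeeping: values carry a unit tag; everything internal
# works in micromolar.
.conc_factors_uM <- c(nM = 1e-3, uM = 1, mM = 1e3, M = 1e6)

#' Convert a tagged concentration to micromolar
#'
#' @param value Numeric concentration value(s).
#' @param unit One of `"nM"`, `"uM"`, `"mM"`, `"M"`.
#' @return Concentration in micromolar.
#' @export
conc_to_uM <- function(value, unit) {
  unit <- as.character(unit)
  bad <- !unit %in% names(.conc_factors_uM)
  if (any(bad)) {
    stop("unknown concentration unit(s): ",
         paste(unique(unit[bad]), collapse = ", "))
  }
  value * unname(.conc_factors_uM[unit])
}
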