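#' Closing and opening rate estimates from a dwell set
#'
#' Exponential maximum likelihood: the closing rate is the reciprocal mean
#' of the uncensored open dwells (the open state ends by closing), the
#' opening rate the reciprocal mean of the uncensored closed dwells. The
#' force of a rate point is the mean dwell force of the originating state.
#' Standard errors come from a seeded nonparametric bootstrap.
#'
#' @param dwells A `dwell_set`.
#' @param min_dwells Minimum uncensored dwells per state (default 5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return A `rate_points` data frame with one row per direction:
#'   `direction` (closing/opening), `force_pN`, `rate_s`, `se_s`,
#'   `concentration`, `conc_unit`, `n_dwells`.
#' @export
rates_from_dwells <- function(dwells, min_dwells = 5, n_boot = 1000,
                              seed = 1) {
  stopifnot(inherits(dwells, "dwell_set"))
  meta <- attr(dwells, "meta")
  one <- function(state, direction) {
    d <- usable_dwells(dwells, state)
    if (nrow(d) < min_dwells) {
      stop("insufficient uncensored ", state, " dwells (", nrow(d),
           " < ", min_dwells, ") for the ", direction, " rate")
    }
    rate <- 1 / mean(d$duration_s)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      1 / mean(sample(d$duration_s, replace = TRUE))
    }, numeric(1))
    data.frame(direction = direction,
               force_pN = mean(d$mean_force_pN),
               rate_s = rate,
               se_s = stats::sd(boot),
               concentration = meta$concentration %||% NA_real_,
               conc_unit = meta$conc_unit %||% NA_character_,
               n_dwells = nrow(d))
  }
  out <- rbind(one("open", "closing"), one("closed", "opening"))
  class(out) <- c("rate_points", "data.frame")
  out
}

#' Global Bell-model fit of force-dependent rates
#'
#' Fits the Bell rate law \eqn{k(F) = k_0 \exp(F \Delta x / k_BT)} to rate
#' points measured at several forces, as a weighted least-squares fit on
#' log rates (variance-stabilizing; weights \eqn{(k/\sigma_k)^2}). One
#' transition-state distance \eqn{\Delta x} is shared across all
#' concentrations. In `mode = "closing"` each concentration gets its own
#' zero-force rate \eqn{k_{0,close}} (closing is bimolecular); in
#' `mode = "opening"` a single shared \eqn{k_{0,open}} is fitted
#' (opening is concentration independent). On log scale the model is
#' linear in its parameters, so the weighted least-squares solution is the
#' exact optimum; quoted errors are 1 s.d. statistical errors.
#'
#' The sign convention is that \eqn{\Delta x > 0} accelerates the rate
#' with force; closing rates typically carry a small negative
#' \eqn{\Delta x}.
#'
#' @param points Data frame with columns `force_pN`, `rate_s`, optional
#'   `se_s`, `concentration` (numeric, one common unit), optional
#'   `conc_unit`.
#' @param mode `"closing"` or `"opening"`.
#' @param weighted Use `se_s` weights when available (default TRUE).
#' @param constants A [lid_constants()] object.
#' @return An object of class `bell_fit`: `mode`, `delta_x_nm` (+ se),
#'   `k0` (named vector per concentration for closing, length 1 for
#'   opening) with `k0_se`, `cov` (covariance of (log k0 ..., delta_x)),
#'   `points`, `fit` (the underlying `lm`).
#' @export
fit_bell <- function(points, mode = c("closing", "opening"),
                     weighted = TRUE, constants = lid_constants()) {
  mode <- match.arg(mode)
  stopifnot(all(c("force_pN", "rate_s") %in% names(points)))
  if (any(points$rate_s <= 0)) stop("rates must be positive")
  if (length(unique(points$force_pN)) < 2) {
    stop("need rate points at >= 2 forces: delta_x is unidentifiable ",
         "from a single force")
  }
  kBT <- constants$kBT
  d <- as.data.frame(points)
  if (is.null(d$concentration)) d$concentration <- NA_real_
  d$conc_f <- factor(d$concentration)
  y <- log(d$rate_s)
  w <- NULL
  if (weighted && !is.null(d$se_s) && all(is.finite(d$se_s)) &&
      all(d$se_s > 0)) {
    w <- (d$rate_s / d$se_s)^2
  }
  if (mode == "closing") {
    if (nlevels(d$conc_f) > 1) {
      fm <- stats::lm(y ~ 0 + conc_f + force_pN, data = d, weights = w)
      cf <- stats::coef(fm)
      k0 <- exp(cf[grep("^conc_f", names(cf))])
    } else {
      fm <- stats::lm(y ~ force_pN, data = d, weights = w)
      cf <- stats::coef(fm)
      k0 <- exp(cf[["(Intercept)"]])
    }
    names(k0) <- levels(d$conc_f)
  } else {
    fm <- stats::lm(y ~ force_pN, data = d, weights = w)
    cf <- stats::coef(fm)
    k0 <- exp(cf[["(Intercept)"]])
    names(k0) <- "all"
  }
  V <- suppressWarnings(stats::vcov(fm))  # silent on interpolating fits
  se <- sqrt(diag(V))
  slope_i <- which(names(cf) == "force_pN")
  delta_x <- cf[[slope_i]] * kBT
  delta_x_se <- se[[slope_i]] * kBT
  k0_se <- k0 * se[-slope_i]   # delta method on log scale
  structure(list(mode = mode, delta_x_nm = delta_x,
                 delta_x_se_nm = delta_x_se,
                 k0 = k0, k0_se = k0_se, cov = V, kBT = kBT,
                 points = d[setdiff(names(d), "conc_f")], fit = fm),
            class = "bell_fit")
}

#' @rdname fit_bell
#' @export
fit_bell_global_closing <- function(points, weighted = TRUE,
                                    constants = lid_constants()) {
  fit_bell(points, "closing", weighted, constants)
}

#' @rdname fit_bell
#' @export
fit_bell_global_opening <- function(points, weighted = TRUE,
                                    constants = lid_constants()) {
  fit_bell(points, "opening", weighted, constants)
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("Global Bell fit (%s): delta_x = %.4g +/- %.2g nm\n",
              x$mode, x$delta_x_nm, x$delta_x_se_nm))
  for (i in seq_along(x$k0)) {
    cat(sprintf("  k0[%s] = %.4g +/- %.2g 1/s\n", names(x$k0)[i],
                x$k0[i], x$k0_se[i]))
  }
  invisible(x)
}

#' @export
summary.bell_fit <- function(object, ...) {
  cat(sprintf("Global Bell fit, %s direction, %d points, %d forces\n",
              object$mode, nrow(object$points),
              length(unique(object$points$force_pN))))
  print(object)
  cat("Residual summary (log rate):\n")
  print(summary(stats::residuals(object$fit)))
  invisible(object)
}

#' @export
coef.bell_fit <- function(object, ...) {
  c(object$k0, delta_x_nm = object$delta_x_nm)
}

#' @export
predict.bell_fit <- function(object, force_pN,
                             concentration = names(object$k0)[1], ...) {
  k0 <- object$k0[as.character(concentration)]
  if (anyNA(k0)) stop("unknown concentration: ", concentration)
  unname(k0) * exp(force_pN * object$delta_x_nm / object$kBT)
}

#' @export
residuals.bell_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Zero-force rates from a Bell fit
#'
#' The zero-force rate is the fitted intercept \eqn{k_0}; its standard
#' error is propagated from the covariance matrix by the delta method.
#' With `per_concentration = TRUE` (closing fits) the bimolecular rate
#' constant `k0 / concentration` is also reported, which collapses all
#' concentrations onto one value when closing is diffusion-limited
#' binding.
#'
#' @param fit A `bell_fit`.
#' @param per_concentration Report `k0 / concentration` as well.
#' @return Data frame with `concentration`, `k0_s`, `se_s` and optionally
#'   `k0_per_conc`.
#' @export
extrapolate_zero_force <- function(fit, per_concentration = FALSE) {
  stopifnot(inherits(fit, "bell_fit"))
  out <- data.frame(concentration = names(fit$k0),
                    k0_s = unname(fit$k0), se_s = unname(fit$k0_se))
  if (per_concentration) {
    conc <- suppressWarnings(as.numeric(out$concentration))
    out$k0_per_conc <- out$k0_s / conc
    out$k0_per_conc_se <- out$se_s / conc
  }
  out
}
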