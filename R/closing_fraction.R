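# Substrate-induced partial closing: the fraction-of-full-closing
# observable, its force-dependent two-state occupancy model (global fit),
# and the concentration-dependent binding/closing model.

#' Fraction of full closing from level separations
#'
#' The substrate-induced shift of the open level in the competition assay,
#' normalized by the full (inhibitor-only) closing distance at the same
#' force:
#' \deqn{f = (L_{full} - L_{comp})/L_{full}}
#' where `L_full` is the open/closed level separation with inhibitor only
#' and `L_comp` the separation in the nucleotide competition experiment.
#'
#' @param L_full_nm Full conformational change, inhibitor-only (nm, > 0).
#' @param L_comp_nm Conformational change in the competition experiment
#'   (nm, between 0 and `L_full_nm`).
#' @return Dimensionless fraction in [0, 1].
#' @examples
#' fraction_of_full_closing(1.6, 1.28)  # 0.2
#' @export
fraction_of_full_closing <- function(L_full_nm, L_comp_nm) {
  if (any(L_full_nm <= 0)) stop("L_full must be positive")
  if (any(L_comp_nm < 0) || any(L_comp_nm > L_full_nm)) {
    stop("L_comp must lie between 0 and L_full")
  }
  (L_full_nm - L_comp_nm) / L_full_nm
}

#' Force-dependent closed-state occupancy (two-state Bell model)
#'
#' \deqn{p_{closed}(F) = \frac{k_{close}(F)}{k_{close}(F)+k_{open}(F)}
#'   = \frac{1}{1 + (k_{0,open}/k_{0,close}) e^{F\Delta x/k_BT}}}
#' where \eqn{\Delta x} is the total size of the conformational change
#' (closing and opening transition-state distances combined). Decreasing
#' in force for \eqn{\Delta x > 0}.
#'
#' @param force_pN Force(s) in pN.
#' @param k0_close,k0_open Zero-force rates (1/s, > 0).
#' @param delta_x_nm Size of the conformational change, nm.
#' @param constants A [lid_constants()] object.
#' @return Probability of the closed state.
#' @export
p_closed <- function(force_pN, k0_close, k0_open, delta_x_nm,
                     constants = lid_constants()) {
  if (any(k0_close <= 0) || any(k0_open <= 0)) {
    stop("rates must be positive")
  }
  1 / (1 + (k0_open / k0_close) *
         exp(force_pN * delta_x_nm / constants$kBT))
}

# L_full(F): accept a scalar, a (force, L) table interpolated linearly,
# or a function.
.L_full_fun <- function(L_full) {
  if (is.function(L_full)) return(L_full)
  if (is.data.frame(L_full)) {
    stopifnot(all(c("force_pN", "L_nm") %in% names(L_full)))
    return(function(f) stats::approx(L_full$force_pN, L_full$L_nm,
                                     xout = f, rule = 2)$y)
  }
  if (is.numeric(L_full) && length(L_full) == 1) {
    return(function(f) rep(L_full, length(f)))
  }
  stop("L_full must be a scalar, a (force_pN, L_nm) data frame, ",
       "or a function")
}

#' Model curve: fraction of full closing versus force
#'
#' The occupancy model scaled to the observable: a substrate-induced
#' conformational change of size \eqn{\Delta x} shifts the open level by
#' \eqn{\Delta x\, p_{closed}(F)}, so the fraction of full closing is
#' \deqn{f(F) = \frac{\Delta x}{L_{full}(F)}\,
#'   \frac{1}{1 + r\, e^{F\Delta x/k_BT}}}
#' with \eqn{r = k_{0,open}/k_{0,close}} the zero-force rate ratio.
#'
#' @param force_pN Force(s) in pN.
#' @param delta_x_nm Substrate-induced conformational change, nm.
#' @param rate_ratio Zero-force opening/closing rate ratio.
#' @param L_full Full closing distance: scalar nm, `(force_pN, L_nm)`
#'   data frame (interpolated linearly), or function of force.
#' @param constants A [lid_constants()] object.
#' @return Fraction(s) of full closing.
#' @export
closing_fraction_curve <- function(force_pN, delta_x_nm, rate_ratio,
                                   L_full = 1.6,
                                   constants = lid_constants()) {
  Lf <- .L_full_fun(L_full)(force_pN)
  (delta_x_nm / Lf) /
    (1 + rate_ratio * exp(force_pN * delta_x_nm / constants$kBT))
}

#' Global fit of the force-dependent fraction of full closing
#'
#' Levenberg-Marquardt fit of [closing_fraction_curve()] to fraction
#' points at several forces and substrate concentrations: one shared
#' \eqn{\Delta x} and one zero-force rate ratio
#' \eqn{r_c = k_{0,open}/k_{0,close}} per concentration. The fixed
#' alternative in which substrate fully closes one of the two lids
#' (\eqn{\Delta x = L_{full}(F)/2}, ratio per concentration still free) is
#' fitted alongside for model comparison; the residual sums of squares of
#' both models are reported.
#'
#' @param points Data frame with columns `force_pN`, `fraction`,
#'   `conc` (numeric, common unit), optional `se`.
#' @param L_full Full closing distance specification (see
#'   [closing_fraction_curve()]); default 1.6 nm.
#' @param start Optional list with `delta_x_nm` and `rate_ratio` starting
#'   values.
#' @param constants A [lid_constants()] object.
#' @return An object of class `fraction_force_fit`: `delta_x_nm` (+ se),
#'   `rate_ratio` (named per concentration, + se), `cov`, `rss_free`,
#'   `rss_one_lid`, `preferred` (`"partial"` or `"one_lid"`), `L_full`,
#'   `fit`, `fit_one_lid`, `points`.
#' @export
fit_fraction_force <- function(points, L_full = 1.6, start = NULL,
                               constants = lid_constants()) {
  stopifnot(all(c("force_pN", "fraction", "conc") %in% names(points)))
  d <- as.data.frame(points)
  if (length(unique(d$conc)) < 1 || length(unique(d$force_pN)) < 2) {
    stop("need fraction points at >= 2 forces: delta_x is ",
         "unidentifiable from a single force")
  }
  kBT <- constants$kBT
  Lfun <- .L_full_fun(L_full)
  d$Lf <- Lfun(d$force_pN)
  d$ci <- as.integer(factor(d$conc))
  m <- length(unique(d$ci))
  w <- if (!is.null(d$se) && all(d$se > 0)) 1 / d$se^2 else NULL
  if (is.null(start)) {
    f0 <- max(d$fraction)
    start <- list(delta_x_nm = max(f0, 0.05) * mean(d$Lf),
                  rate_ratio = max(1 / max(f0, 0.05) - 1, 0.1))
  }
  # one named log-ratio parameter per concentration (nlsLM does not
  # accept vector-valued parameters)
  lr_names <- paste0("lr", seq_len(m))
  lr_vec <- paste0("c(", paste(lr_names, collapse = ", "), ")[ci]")
  env <- list2env(list(kBT = kBT), parent = environment())
  form <- stats::as.formula(
    paste0("fraction ~ (dx / Lf) / (1 + exp(", lr_vec,
           " + force_pN * dx / kBT))"), env = env)
  st <- c(list(dx = start$delta_x_nm),
          stats::setNames(as.list(rep(log(start$rate_ratio), m)),
                          lr_names))
  fm <- .nlsLM(form, data = d, weights = w, start = st,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fm)
  V <- stats::vcov(fm)
  sm <- summary(fm)$coefficients
  dx <- cf[["dx"]]
  lr <- cf[lr_names]
  conc_levels <- levels(factor(d$conc))
  ratio <- exp(lr)
  names(ratio) <- conc_levels
  ratio_se <- ratio * sm[lr_names, "Std. Error"]
  # fixed alternative: full closing of exactly one lid, dx = L_full(F)/2
  form_fc <- stats::as.formula(
    paste0("fraction ~ 0.5 / (1 + exp(", lr_vec,
           " + force_pN * (Lf / 2) / kBT))"), env = env)
  fm_fc <- .nlsLM(form_fc, data = d, weights = w, start = st[lr_names],
                  control = minpack.lm::nls.lm.control(maxiter = 200))
  rss <- function(f) sum(stats::residuals(f)^2)
  rss_free <- rss(fm); rss_fc <- rss(fm_fc)
  structure(list(delta_x_nm = dx,
                 delta_x_se_nm = sm["dx", "Std. Error"],
                 rate_ratio = ratio, rate_ratio_se = ratio_se,
                 cov = V, kBT = kBT, constants = constants,
                 L_full = L_full,
                 rss_free = rss_free, rss_one_lid = rss_fc,
                 preferred = if (rss_free < rss_fc) "partial"
                             else "one_lid",
                 fit = fm, fit_one_lid = fm_fc, points = d),
            class = "fraction_force_fit")
}

#' @export
print.fraction_force_fit <- function(x, ...) {
  cat(sprintf(
    "Fraction-of-closing global fit: delta_x = %.3g +/- %.2g nm\n",
    x$delta_x_nm, x$delta_x_se_nm))
  for (i in seq_along(x$rate_ratio)) {
    cat(sprintf("  k0_open/k0_close [%s] = %.4g +/- %.2g\n",
                names(x$rate_ratio)[i], x$rate_ratio[i],
                x$rate_ratio_se[i]))
  }
  cat(sprintf(
    "  RSS partial-closing %.4g vs one-lid-full-closure %.4g -> %s\n",
    x$rss_free, x$rss_one_lid,
    if (x$preferred == "partial") "partial closing preferred"
    else "one-lid closure preferred"))
  invisible(x)
}

#' @export
coef.fraction_force_fit <- function(object, ...) {
  c(delta_x_nm = object$delta_x_nm, object$rate_ratio)
}

#' @export
predict.fraction_force_fit <- function(object, force_pN,
                                       concentration =
                                         names(object$rate_ratio)[1],
                                       ...) {
  r <- object$rate_ratio[as.character(concentration)]
  if (anyNA(r)) stop("unknown concentration: ", concentration)
  closing_fraction_curve(force_pN, object$delta_x_nm, unname(r),
                         object$L_full, object$constants)
}

#' Fraction of full closing extrapolated to zero force
#'
#' Evaluates the fitted model at F = 0 for one concentration, with a
#' delta-method standard error from the fit covariance.
#'
#' @param fit A `fraction_force_fit`.
#' @param concentration One of the fitted concentrations.
#' @return List with `fraction` and `se`.
#' @export
zero_force_fraction <- function(fit, concentration) {
  stopifnot(inherits(fit, "fraction_force_fit"))
  key <- as.character(concentration)
  idx <- match(key, names(fit$rate_ratio))
  if (is.na(idx)) stop("unknown concentration: ", key)
  L0 <- .L_full_fun(fit$L_full)(0)
  r <- unname(fit$rate_ratio[idx])
  dx <- fit$delta_x_nm
  f <- (dx / L0) / (1 + r)
  # gradient wrt (dx, lr_idx); other lr's don't enter at this conc
  par_names <- rownames(fit$cov)
  g <- numeric(length(par_names))
  names(g) <- par_names
  g["dx"] <- (1 / L0) / (1 + r)
  lr_name <- if (length(fit$rate_ratio) == 1) "lr" else
    paste0("lr", idx)
  if (!lr_name %in% par_names) {
    lr_name <- grep("^lr", par_names, value = TRUE)[idx]
  }
  g[lr_name] <- -(dx / L0) * r / (1 + r)^2
  se <- sqrt(drop(t(g) %*% fit$cov %*% g))
  list(fraction = f, se = se)
}

#' Concentration-dependent closing model (binding to open and closed
#' states)
#'
#' Describes the zero-force fraction of full closing versus substrate
#' concentration through a four-state scheme (unbound/bound x
#' open/closed). With dissociation constants
#' \eqn{K_{open} = [UO][L]/[BO]} and \eqn{K_{close} = [UC][L]/[BC]}, and
#' the unbound conformational equilibrium
#' \eqn{K_{conf} = [UC]/[UO] = k_{close,unbound}/k_{open,unbound}} fixed
#' from the published unbound rates (closing 2000 1/s, opening 6500 1/s),
#' the unbound-closed concentration is negligible at measurement forces
#' and the closed-state probability reduces to
#' \deqn{P_{closed}([L]) = \frac{K_{conf}[L]/K_{close}}
#'   {1 + [L]/K_{open} + K_{conf}[L]/K_{close}}}
#' The observable is `f_max * P_closed([L])` with
#' `f_max = delta_x / L_full(0)` known from the force-dependence fit.
#'
#' @param conc_uM Concentration(s).
#' @param K_open_uM,K_close_uM Dissociation constants for the open and
#'   closed conformations.
#' @param f_max Saturating-occupancy fraction of full closing.
#' @param unbound_rates Named vector `c(opening = ..., closing = ...)` in
#'   1/s; default `c(opening = 6500, closing = 2000)`.
#' @return Fraction(s) of full closing at zero force.
#' @export
concentration_closing_curve <- function(conc_uM, K_open_uM, K_close_uM,
                                        f_max = 1,
                                        unbound_rates = c(opening = 6500,
                                                          closing = 2000)) {
  K_conf <- unbound_rates[["closing"]] / unbound_rates[["opening"]]
  bc <- K_conf * conc_uM / K_close_uM
  f_max * bc / (1 + conc_uM / K_open_uM + bc)
}

#' Fit the concentration-dependent closing model
#'
#' Levenberg-Marquardt fit of [concentration_closing_curve()] to
#' zero-force fraction points, estimating `K_open` and `K_close` on log
#' scale. Needs at least 4 concentrations spanning at least 2 decades.
#' If the data do not approach the fitted saturation plateau, `K_close`
#' is only bounded and a warning is raised.
#'
#' @param points Data frame with columns `conc_uM`, `fraction`, optional
#'   `se`.
#' @param f_max Saturating-occupancy amplitude (fixed input, from the
#'   force-dependence fit).
#' @param unbound_rates As in [concentration_closing_curve()].
#' @return An object of class `conc_closing_fit`: `K_open_uM`,
#'   `K_close_uM` (+ se), `f_max`, `unbound_rates`, `plateau`,
#'   `saturating`, `fit`, `points`.
#' @export
fit_concentration_model <- function(points, f_max = 1,
                                    unbound_rates = c(opening = 6500,
                                                      closing = 2000)) {
  stopifnot(all(c("conc_uM", "fraction") %in% names(points)))
  d <- as.data.frame(points)
  d <- d[d$conc_uM > 0, , drop = FALSE]
  if (nrow(d) < 4) stop("need >= 4 nonzero concentrations")
  if (max(d$conc_uM) / min(d$conc_uM) < 100) {
    stop("concentrations must span at least two decades")
  }
  K_conf <- unbound_rates[["closing"]] / unbound_rates[["opening"]]
  w <- if (!is.null(d$se) && all(d$se > 0)) 1 / d$se^2 else NULL
  half <- stats::approx(d$fraction, d$conc_uM,
                        xout = max(d$fraction) / 2, rule = 2,
                        ties = mean)$y
  fm <- .nlsLM(
    fraction ~ f_max * (K_conf * conc_uM / exp(lKc)) /
      (1 + conc_uM / exp(lKo) + K_conf * conc_uM / exp(lKc)),
    data = d, weights = w,
    start = list(lKo = log(half), lKc = log(half * K_conf)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fm)
  sm <- summary(fm)$coefficients
  K_open <- exp(cf[["lKo"]]); K_close <- exp(cf[["lKc"]])
  plateau <- f_max * K_conf * K_open / (K_conf * K_open + K_close)
  pred_max <- concentration_closing_curve(max(d$conc_uM), K_open,
                                          K_close, f_max, unbound_rates)
  saturating <- pred_max >= 0.9 * plateau
  if (!saturating) {
    warning("data do not approach the fitted saturation plateau; ",
            "K_close is only bounded by these data")
  }
  structure(list(K_open_uM = K_open,
                 K_open_se_uM = K_open * sm["lKo", "Std. Error"],
                 K_close_uM = K_close,
                 K_close_se_uM = K_close * sm["lKc", "Std. Error"],
                 f_max = f_max, unbound_rates = unbound_rates,
                 plateau = plateau, saturating = saturating,
                 cov = stats::vcov(fm), fit = fm, points = d),
            class = "conc_closing_fit")
}

#' @export
print.conc_closing_fit <- function(x, ...) {
  cat(sprintf(
    "Concentration-closing fit: K_open = %.4g +/- %.2g uM, K_close = %.4g +/- %.2g uM\n",
    x$K_open_uM, x$K_open_se_uM, x$K_close_uM, x$K_close_se_uM))
  cat(sprintf("  saturation plateau = %.3g (f_max = %.3g)%s\n",
              x$plateau, x$f_max,
              if (x$saturating) "" else " [not reached by data]"))
  invisible(x)
}

#' @export
coef.conc_closing_fit <- function(object, ...) {
  c(K_open_uM = object$K_open_uM, K_close_uM = object$K_close_uM)
}

#' @export
predict.conc_closing_fit <- function(object, conc_uM, ...) {
  concentration_closing_curve(conc_uM, object$K_open_uM,
                              object$K_close_uM, object$f_max,
                              object$unbound_rates)
}
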