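#' Configuration for simulating a passive-mode two-state trace
#'
#' Defines the generative model the analysis assumes: a two-state
#' (open/closed) continuous-time Markov telegraph with Bell-model
#' force-dependent rates, forces computed self-consistently from the trap
#' and WLC tether mechanics, additive Ornstein-Uhlenbeck bead/tether noise,
#' high-rate sampling followed by block averaging to the stored rate.
#'
#' The closing propensity is bimolecular: `k_close(F) = k_close0 * [L] *
#' exp(F * dx_close / kBT)` with `k_close0` in 1/(uM s) and the
#' concentration converted to uM. Opening is unimolecular. The sign
#' convention is that a positive `delta_x` accelerates the rate with force.
#'
#' @param k_close0 Zero-force closing rate constant, 1/(uM s) (bimolecular).
#' @param delta_x_close_nm Transition-state distance of closing, nm (may be
#'   negative; closing is typically slowed by force).
#' @param k_open0 Zero-force opening rate, 1/s.
#' @param delta_x_open_nm Transition-state distance of opening, nm.
#' @param concentration,conc_unit Ligand concentration with unit tag.
#' @param ligand Ligand name (metadata).
#' @param protein_contraction_nm Open-to-closed length change along the
#'   pulling axis (default 1.6 nm, the full two-lid closing distance).
#' @param protein_extension_open_nm Protein extension in the open state.
#' @param trap_separation_nm Trap-centre separation.
#' @param tether A [tether_model()].
#' @param sampling_rate_hz Acquisition rate (default 150000).
#' @param average_to_hz Stored rate after block averaging (default 30000);
#'   must divide `sampling_rate_hz`.
#' @param noise_sd_nm Stationary standard deviation of the OU noise.
#' @param noise_corner_hz OU corner frequency (default 5000); must be below
#'   the acquisition Nyquist frequency.
#' @param duration_s Trace duration in seconds.
#' @param seed Mandatory integer seed.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(k_close0 = 0.18e3,
                             delta_x_close_nm = -0.1,
                             k_open0 = 1,
                             delta_x_open_nm = 1.5,
                             concentration = 1, conc_unit = "uM",
                             ligand = "AP5A",
                             protein_contraction_nm = 1.6,
                             protein_extension_open_nm = 10,
                             trap_separation_nm = 420,
                             tether = tether_model(),
                             sampling_rate_hz = 150000,
                             average_to_hz = 30000,
                             noise_sd_nm = 0.35,
                             noise_corner_hz = 5000,
                             duration_s = 10,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory: no silent nondeterminism")
  }
  stopifnot(k_close0 >= 0, k_open0 > 0, concentration >= 0,
            protein_contraction_nm > 0, protein_extension_open_nm > 0,
            trap_separation_nm > 0, sampling_rate_hz > 0,
            average_to_hz > 0, average_to_hz <= sampling_rate_hz,
            noise_sd_nm >= 0, noise_corner_hz > 0, duration_s > 0)
  if (sampling_rate_hz %% average_to_hz != 0) {
    stop("average_to_hz must divide sampling_rate_hz")
  }
  if (noise_corner_hz >= sampling_rate_hz / 2) {
    stop("noise corner frequency at or above Nyquist")
  }
  structure(as.list(environment()), class = "trace_sim_config")
}

# per-state tether equilibria (open/closed forces and extensions)
.state_mechanics <- function(config) {
  x_open <- config$protein_extension_open_nm
  x_closed <- x_open - config$protein_contraction_nm
  eq_o <- solve_tether_equilibrium(config$trap_separation_nm, x_open,
                                   config$tether)
  eq_c <- solve_tether_equilibrium(config$trap_separation_nm, x_closed,
                                   config$tether)
  kBT <- config$tether$constants$kBT
  list(force_open = eq_o$force_pN, force_closed = eq_c$force_pN,
       # signal = construct extension = D - deflection sum
       level_open = config$trap_separation_nm - eq_o$bead_deflection_sum_nm,
       level_closed = config$trap_separation_nm -
         eq_c$bead_deflection_sum_nm,
       kBT = kBT)
}

#' Simulate the exact open/closed state path of a trace
#'
#' Gillespie simulation of the two-state telegraph. Rates are evaluated at
#' each state's self-consistent tether force and held constant within a
#' dwell. The closing propensity is proportional to ligand concentration;
#' zero concentration yields a single open dwell.
#'
#' @param config A [trace_sim_config()].
#' @return A `dwell_set` (see [dwell_set()]) covering `duration_s`, with
#'   the first and last dwells flagged censored, plus attributes
#'   `mechanics` (state forces/levels) and `config`.
#' @export
simulate_state_path <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  mech <- .state_mechanics(config)
  kBT <- mech$kBT
  conc_uM <- conc_to_uM(config$concentration, config$conc_unit)
  k_close <- config$k_close0 * conc_uM *
    exp(mech$force_open * config$delta_x_close_nm / kBT)
  k_open <- config$k_open0 *
    exp(mech$force_closed * config$delta_x_open_nm / kBT)
  set.seed(config$seed)
  t <- 0
  state <- "open"  # start in the open state
  states <- character(0); starts <- numeric(0); durs <- numeric(0)
  repeat {
    rate <- if (state == "open") k_close else k_open
    dwell <- if (rate > 0) stats::rexp(1, rate) else Inf
    end <- min(t + dwell, config$duration_s)
    states <- c(states, state); starts <- c(starts, t)
    durs <- c(durs, end - t)
    t <- end
    if (t >= config$duration_s) break
    state <- if (state == "open") "closed" else "open"
  }
  censored <- logical(length(durs))
  censored[1] <- TRUE
  censored[length(durs)] <- TRUE
  force <- ifelse(states == "open", mech$force_open, mech$force_closed)
  ds <- dwell_set(state = states, t_start_s = starts, duration_s = durs,
                  mean_force_pN = force, censored = censored,
                  meta = list(ligand = config$ligand,
                              concentration = config$concentration,
                              conc_unit = config$conc_unit,
                              trap_separation_nm =
                                config$trap_separation_nm,
                              seed = config$seed))
  attr(ds, "mechanics") <- mech
  attr(ds, "config") <- config
  ds
}

#' Render a dwell path into a sampled, noisy trace
#'
#' Assigns each state its deflection level from the tether force balance,
#' adds discrete Ornstein-Uhlenbeck noise (AR(1) with the configured
#' stationary SD and corner frequency) at the acquisition rate, then block
#' averages to the storage rate, mirroring 150 kHz acquisition averaged to
#' 30 kHz. The ground-truth state path is resampled to the output grid
#' (majority state within each block).
#'
#' @param dwells A `dwell_set` from [simulate_state_path()].
#' @param config The same [trace_sim_config()] (defaults to the one stored
#'   on the dwell set).
#' @return A [lid_trace()] with per-sample true force channel and an extra
#'   element `true_state` (character vector per output sample). The true
#'   state levels are stored in the metadata.
#' @export
render_trace <- function(dwells, config = attr(dwells, "config")) {
  stopifnot(inherits(dwells, "dwell_set"),
            inherits(config, "trace_sim_config"))
  mech <- attr(dwells, "mechanics")
  if (is.null(mech)) mech <- .state_mechanics(config)
  fs <- config$sampling_rate_hz
  n_hi <- round(config$duration_s * fs)
  t_hi <- (seq_len(n_hi) - 0.5) / fs
  idx <- findInterval(t_hi, dwells$t_start_s)
  open_hi <- dwells$state[idx] == "open"
  level <- ifelse(open_hi, mech$level_open, mech$level_closed)
  sig <- level
  if (config$noise_sd_nm > 0) {
    set.seed(config$seed + 1L)
    a <- exp(-2 * pi * config$noise_corner_hz / fs)
    innov_sd <- config$noise_sd_nm * sqrt(1 - a^2)
    eps <- stats::rnorm(n_hi, sd = innov_sd)
    eps[1] <- stats::rnorm(1, sd = config$noise_sd_nm)  # stationary start
    ou <- as.numeric(stats::filter(eps, a, method = "recursive"))
    sig <- sig + ou
  }
  fac <- fs %/% config$average_to_hz
  n_lo <- n_hi %/% fac
  sig <- colMeans(matrix(sig[seq_len(n_lo * fac)], nrow = fac))
  open_frac <- colMeans(matrix(as.numeric(open_hi[seq_len(n_lo * fac)]),
                               nrow = fac))
  true_state <- ifelse(open_frac >= 0.5, "open", "closed")
  force <- ifelse(true_state == "open", mech$force_open,
                  mech$force_closed)
  time_lo <- (seq_len(n_lo) - 0.5) * (fac / fs)
  tr <- lid_trace(time_lo, sig, force_pN = force,
                  meta = list(ligand = config$ligand,
                              concentration = config$concentration,
                              conc_unit = config$conc_unit,
                              trap_k1_pN_per_nm = config$tether$k1,
                              trap_k2_pN_per_nm = config$tether$k2,
                              trap_separation_nm =
                                config$trap_separation_nm,
                              sampling_rate_hz = config$average_to_hz,
                              seed = config$seed,
                              level_open_nm = mech$level_open,
                              level_closed_nm = mech$level_closed,
                              force_open_pN = mech$force_open,
                              force_closed_pN = mech$force_closed))
  tr$true_state <- true_state
  tr
}

#' Simulate a full synthetic trace (state path + rendering)
#'
#' @param config A [trace_sim_config()].
#' @return A [lid_trace()] as from [render_trace()], with the exact dwell
#'   set attached as attribute `dwells`.
#' @export
simulate_trace <- function(config) {
  dw <- simulate_state_path(config)
  tr <- render_trace(dw, config)
  attr(tr, "dwells") <- dw
  tr
}

#' Simulate exponential dwell sets on a force-concentration grid
#'
#' Direct sampler for rate-estimation and Bell-fit tests: for each
#' (force, concentration) condition draws `n_dwells` open and closed dwell
#' durations from the Bell-model exponential distributions, bypassing trace
#' rendering and detection.
#'
#' @param forces_pN Vector of forces.
#' @param concentrations_uM Vector of ligand concentrations in uM.
#' @param k_close0 Bimolecular zero-force closing rate constant, 1/(uM s).
#' @param delta_x_close_nm,delta_x_open_nm Transition-state distances, nm.
#' @param k_open0 Zero-force opening rate, 1/s.
#' @param n_dwells Dwells per state per condition.
#' @param seed Integer seed.
#' @param constants A [lid_constants()] object.
#' @return A list of `dwell_set` objects, one per condition, named
#'   `"F<force>_c<conc>"`.
#' @export
simulate_dwell_grid <- function(forces_pN, concentrations_uM,
                                k_close0 = 0.18e3,
                                delta_x_close_nm = -0.1,
                                k_open0 = 1, delta_x_open_nm = 1.5,
                                n_dwells = 500, seed,
                                constants = lid_constants()) {
  if (missing(seed)) stop("seed is mandatory")
  kBT <- constants$kBT
  out <- list()
  i <- 0L
  for (conc in concentrations_uM) {
    for (f in forces_pN) {
      i <- i + 1L
      set.seed(seed + i)
      kc <- k_close0 * conc * exp(f * delta_x_close_nm / kBT)
      ko <- k_open0 * exp(f * delta_x_open_nm / kBT)
      dur_open <- stats::rexp(n_dwells, kc)
      dur_closed <- stats::rexp(n_dwells, ko)
      n <- 2L * n_dwells
      st <- rep(c("open", "closed"), n_dwells)
      dur <- as.vector(rbind(dur_open, dur_closed))
      ds <- dwell_set(state = st,
                      t_start_s = cumsum(c(0, dur[-n])),
                      duration_s = dur,
                      mean_force_pN = rep(f, n),
                      censored = rep(FALSE, n),
                      meta = list(ligand = "sim",
                                  concentration = conc,
                                  conc_unit = "uM",
                                  force_pN = f, seed = seed + i))
      out[[sprintf("F%g_c%g", f, conc)]] <- ds
    }
  }
  out
}

#' Configuration for simulating a force-distance curve
#'
#' The constant-velocity stretch of the tethered protein in the
#' fast-exchange (equilibrium) limit: at each trap distance the measured
#' force is the Boltzmann-weighted mixture of the folded branch (DNA
#' handles only) and the unfolded branch (DNA in series with the released
#' polypeptide), producing a hump-like equilibrium transition between the
#' branches. A stochastic hopping mode is available for detector stress
#' tests.
#'
#' @param folding_free_energy_kBT Free energy of folding at zero load (kBT).
#' @param unfolded_contour_gain_nm Polypeptide contour released on
#'   unfolding, nm.
#' @param folded_extension_nm Extension of the folded protein along the
#'   pulling axis, nm.
#' @param pulling_velocity_nm_s Trap velocity (sets point spacing together
#'   with `sample_rate_hz`).
#' @param sample_rate_hz Output point rate.
#' @param distance_range_nm Trap-separation range `c(min, max)`.
#' @param tether A [tether_model()] (its polypeptide persistence length is
#'   used for the unfolded branch).
#' @param force_noise_pN Additive Gaussian force noise SD.
#' @param exchange_rate_hz Relaxation rate for the hopping mode.
#' @param mode `"equilibrium"` (default) or `"hopping"`.
#' @param seed Mandatory integer seed.
#' @return An object of class `fec_sim_config`.
#' @export
fec_sim_config <- function(folding_free_energy_kBT = 11.7,
                           unfolded_contour_gain_nm = 10,
                           folded_extension_nm = 2,
                           pulling_velocity_nm_s = 150,
                           sample_rate_hz = 200,
                           distance_range_nm = c(330, 510),
                           tether = tether_model(),
                           force_noise_pN = 0.05,
                           exchange_rate_hz = 1000,
                           mode = c("equilibrium", "hopping"),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  stopifnot(folding_free_energy_kBT >= 0, unfolded_contour_gain_nm > 0,
            pulling_velocity_nm_s > 0, sample_rate_hz > 0,
            length(distance_range_nm) == 2,
            diff(distance_range_nm) > 0)
  structure(as.list(environment()), class = "fec_sim_config")
}

#' Simulate a constant-velocity force-distance curve
#'
#' @param config A [fec_sim_config()].
#' @return A `lid_fec` object: data frame with `trap_distance_nm` and
#'   `force_pN`, attributes `velocity_nm_s`, `direction`, `config`.
#' @export
simulate_fec <- function(config) {
  stopifnot(inherits(config, "fec_sim_config"))
  th <- config$tether
  kBT <- th$constants$kBT
  dD <- config$pulling_velocity_nm_s / config$sample_rate_hz
  D <- seq(config$distance_range_nm[1], config$distance_range_nm[2],
           by = dD)
  pep <- wlc_params(th$polypeptide$persistence_nm,
                    config$unfolded_contour_gain_nm)
  f_fold <- vapply(D, function(d) {
    solve_tether_equilibrium(d, config$folded_extension_nm, th)$force_pN
  }, numeric(1))
  # unfolded branch: DNA + polypeptide in series, folded extension released
  f_unf <- vapply(D, function(d) {
    bal <- function(f) {
      th$k_eff * (d - wlc_extension(f, th$dna, th$constants) -
                    wlc_extension(f, pep, th$constants)) - f
    }
    if (bal(0) <= 0) return(0)
    stats::uniroot(bal, c(0, th$k_eff * d), tol = 1e-10)$root
  }, numeric(1))
  # elastic energies (pN nm) by cumulative trapezoid over trap distance
  cumtrapz <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dD))
  V_f <- cumtrapz(f_fold)
  V_u <- cumtrapz(f_unf)
  dE <- (config$folding_free_energy_kBT * kBT + V_u - V_f) / kBT
  p_fold <- 1 / (1 + exp(-dE))
  set.seed(config$seed)
  if (config$mode == "equilibrium") {
    force <- p_fold * f_fold + (1 - p_fold) * f_unf
  } else {
    folded <- TRUE
    force <- numeric(length(D))
    dt <- 1 / config$sample_rate_hz
    for (i in seq_along(D)) {
      k_u <- config$exchange_rate_hz * (1 - p_fold[i])
      k_f <- config$exchange_rate_hz * p_fold[i]
      rate <- if (folded) k_u else k_f
      if (stats::runif(1) < 1 - exp(-rate * dt)) folded <- !folded
      force[i] <- if (folded) f_fold[i] else f_unf[i]
    }
  }
  if (config$force_noise_pN > 0) {
    force <- force + stats::rnorm(length(D), sd = config$force_noise_pN)
  }
  structure(data.frame(trap_distance_nm = D, force_pN = force),
            class = c("lid_fec", "data.frame"),
            velocity_nm_s = config$pulling_velocity_nm_s,
            direction = "stretch",
            branches_true = data.frame(trap_distance_nm = D,
                                       folded_pN = f_fold,
                                       unfolded_pN = f_unf,
                                       p_fold = p_fold),
            config = config)
}
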