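test_that("fraction of full closing is the normalized level shift", {
  expect_equal(fraction_of_full_closing(1.6, 1.6), 0)
  expect_equal(fraction_of_full_closing(1.6, 0), 1)
  expect_equal(fraction_of_full_closing(1.6, 1.28), 0.2)
  expect_error(fraction_of_full_closing(1.6, 1.7), "between")
  expect_error(fraction_of_full_closing(0, 0), "positive")
})

test_that("closed-state occupancy has the Boltzmann two-state form", {
  expect_equal(p_closed(0, 10, 10, 0.5), 0.5)
  expect_equal(p_closed(1e4, 10, 10, 0.5), 0, tolerance = 1e-12)
  expect_error(p_closed(8, -1, 1, 0.5), "positive")
  # decreasing in force for positive delta_x
  p <- p_closed(seq(0, 20, by = 1), 100, 10, 1.2)
  expect_true(all(diff(p) < 0))
  # matches a Gillespie closed-state occupancy at ~8 pN
  tc <- trace_sim_config(k_close0 = 150, delta_x_close_nm = -0.2,
                         k_open0 = 40, delta_x_open_nm = 1.0,
                         concentration = 1, duration_s = 25, seed = 19,
                         protein_contraction_nm = 0.05,
                         trap_separation_nm = 406)
  dw <- simulate_state_path(tc)
  occ <- sum(dw$duration_s[dw$state == "closed"]) / sum(dw$duration_s)
  F <- mean(dw$mean_force_pN)
  p_model <- p_closed(F, 150, 40, 1.2)
  n <- sum(dw$state == "closed")
  expect_lt(abs(occ - p_model),
            3 * sqrt(p_model * (1 - p_model) / n) * 2)
})

test_that("noise-free occupancy-model curves are recovered exactly", {
  cst <- lid_constants()
  forces <- c(4, 7, 10, 13)
  pts <- do.call(rbind, lapply(c(2, 0.5), function(r) {
    data.frame(force_pN = forces,
               fraction = closing_fraction_curve(forces, 0.45, r, 1.6,
                                                 cst),
               conc = if (r == 2) 100 else 1000)
  }))
  fit <- fit_fraction_force(pts, L_full = 1.6, constants = cst)
  expect_equal(fit$delta_x_nm, 0.45, tolerance = 1e-6)
  expect_equal(unname(fit$rate_ratio), c(2, 0.5), tolerance = 1e-5)
  expect_lt(fit$rss_free, 1e-12)
})

test_that("ATP-like and ADP-like conformational changes are recovered within 2 sd", {
  cst <- lid_constants()
  forces <- c(6, 8, 10, 12, 14)
  concs <- c(100, 300, 1000)
  for (cfg in list(list(dx = 0.5, ratios = c(4, 2, 1), seed = 20),
                   list(dx = 0.7, ratios = c(3, 1.5, 0.8), seed = 21))) {
    set.seed(cfg$seed)
    pts <- do.call(rbind, lapply(seq_along(concs), function(i) {
      f <- closing_fraction_curve(forces, cfg$dx, cfg$ratios[i], 1.6,
                                  cst)
      data.frame(force_pN = forces,
                 fraction = f * (1 + stats::rnorm(5, sd = 0.05)),
                 conc = concs[i], se = pmax(f * 0.05, 1e-4))
    }))
    fit <- fit_fraction_force(pts, L_full = 1.6, constants = cst)
    expect_lt(abs(fit$delta_x_nm - cfg$dx), 2 * fit$delta_x_se_nm)
    expect_equal(fit$preferred, "partial")
  }
})

test_that("model discrimination works in both directions", {
  cst <- lid_constants()
  forces <- c(6, 8, 10, 12, 14)
  concs <- c(100, 1000)
  gen <- function(dx, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(concs), function(i) {
      r <- c(3, 1)[i]
      f <- closing_fraction_curve(forces, dx, r, 1.6, cst)
      data.frame(force_pN = forces,
                 fraction = f * (1 + stats::rnorm(5, sd = 0.05)),
                 conc = concs[i], se = pmax(f * 0.05, 1e-4))
    }))
  }
  # partially-closing truth (dx = 0.5): one-lid closure rejected
  fit_pc <- fit_fraction_force(gen(0.5, 31), L_full = 1.6,
                               constants = cst)
  expect_equal(fit_pc$preferred, "partial")
  expect_gt(fit_pc$rss_one_lid / fit_pc$rss_free, 5)
  # full one-lid closure truth (dx = 0.8 = L/2): the free fit should find
  # dx ~ L/2, and the fixed model should fit comparably well
  fit_fc <- fit_fraction_force(gen(0.8, 32), L_full = 1.6,
                               constants = cst)
  expect_lt(abs(fit_fc$delta_x_nm - 0.8), 2.5 * fit_fc$delta_x_se_nm)
  expect_lt(fit_fc$rss_one_lid / fit_fc$rss_free, 3)
})

test_that("zero-force fraction evaluation and its limits", {
  cst <- lid_constants()
  forces <- c(6, 10, 14)
  set.seed(33)
  pts <- data.frame(force_pN = forces,
                    fraction = closing_fraction_curve(forces, 0.5, 2,
                                                      1.6, cst),
                    conc = 100)
  fit <- fit_fraction_force(pts, L_full = 1.6, constants = cst)
  z <- zero_force_fraction(fit, 100)
  expect_equal(z$fraction, (0.5 / 1.6) / 3, tolerance = 1e-4)
  expect_error(zero_force_fraction(fit, 999), "unknown")
  # limits of the model curve itself
  expect_equal(closing_fraction_curve(0, 0.5, 1e12, 1.6), 0,
               tolerance = 1e-10)
  expect_equal(closing_fraction_curve(0, 0.5, 0, 1.6), 0.5 / 1.6)
})

test_that("zero-force fraction matches Monte-Carlo zero-force occupancy", {
  cst <- lid_constants()
  # at F = 0 the occupancy is 1/(1+r); simulate a telegraph at zero force
  r <- 1.5
  k_close <- 100; k_open <- k_close * r
  set.seed(34)
  n <- 4000
  open_d <- stats::rexp(n, k_close)
  closed_d <- stats::rexp(n, k_open)
  occ_mc <- sum(closed_d) / (sum(open_d) + sum(closed_d))
  frac_mc <- 0.5 / 1.6 * occ_mc
  forces <- c(6, 10, 14)
  pts <- data.frame(force_pN = forces,
                    fraction = closing_fraction_curve(forces, 0.5, r,
                                                      1.6, cst),
                    conc = 1)
  fit <- fit_fraction_force(pts, L_full = 1.6, constants = cst)
  z <- zero_force_fraction(fit, 1)
  se_mc <- frac_mc / sqrt(n)
  expect_lt(abs(z$fraction - frac_mc), 3 * se_mc)
})

test_that("the concentration-dependent closing model has the documented algebra", {
  # [L] = 0 anchors at zero
  expect_equal(concentration_closing_curve(0, 100, 50, f_max = 0.3), 0)
  # symmetric case: K_open = K_close, saturation plateau from manual
  # evaluation of the simplified expression:
  # plateau = f_max * K_conf/(K_conf + 1) with K_conf = 2000/6500
  K_conf <- 2000 / 6500
  got <- concentration_closing_curve(1e12, 100, 100, f_max = 1)
  expect_equal(got, K_conf / (K_conf + 1), tolerance = 1e-8)
  # monotone increasing in concentration
  v <- concentration_closing_curve(10^seq(0, 5, by = 0.5), 300, 100,
                                   f_max = 0.3)
  expect_true(all(diff(v) > 0))
})

test_that("K_open and K_close are recovered from noisy zero-force fractions", {
  set.seed(35)
  conc <- c(10, 30, 100, 300, 1000, 3000, 10000)
  truth <- concentration_closing_curve(conc, 300, 120, f_max = 0.3125)
  pts <- data.frame(conc_uM = conc,
                    fraction = truth * (1 + stats::rnorm(7, sd = 0.05)),
                    se = pmax(truth * 0.05, 1e-4))
  fit <- fit_concentration_model(pts, f_max = 0.3125)
  expect_lt(abs(fit$K_open_uM - 300), 2 * fit$K_open_se_uM)
  expect_lt(abs(fit$K_close_uM - 120), 2.5 * fit$K_close_se_uM)
  expect_true(fit$saturating)
  expect_error(fit_concentration_model(pts[1:3, ], f_max = 0.3),
               ">= 4")
  expect_error(
    fit_concentration_model(data.frame(conc_uM = c(10, 20, 40, 80),
                                       fraction = c(1, 2, 3, 4) / 10),
                            f_max = 0.3), "decades")
})

test_that("competition traces run end to end to the generator delta_x", {
  # headline parameter-recovery: simulate competition traces where fast
  # nucleotide exchange shifts the open level by dx * p_closed(F), detect
  # states, form the fraction observable, fit the occupancy model
  cst <- lid_constants()
  dx_true <- 0.5
  ratios <- c(3, 1)        # per concentration (ATP 300 and 1000 uM)
  concs <- c(300, 1000)
  seps <- c(400, 420, 440) # ~ 7.4, 10, 12.7 pN
  th <- tether_model()
  pts <- NULL
  seed <- 500
  for (ci in seq_along(concs)) {
    for (D in seps) {
      seed <- seed + 1
      # open level shifts toward closed by dx * p_closed at this force
      F_open <- solve_tether_equilibrium(D, 10, th)$force_pN
      p <- p_closed(F_open, 1 / ratios[ci], 1, dx_true, cst)
      tc <- trace_sim_config(duration_s = 2, seed = seed,
                             trap_separation_nm = D,
                             protein_extension_open_nm = 10 - dx_true * p,
                             protein_contraction_nm = 1.6 - dx_true * p,
                             noise_sd_nm = 0.3)
      tr <- simulate_trace(tc)
      corr <- constant_force_transform(tr, th$dna)
      hmm <- fit_hmm(corr)
      L_comp <- hmm$level_open - hmm$level_closed
      frac <- fraction_of_full_closing(1.6, min(L_comp, 1.6))
      pts <- rbind(pts, data.frame(force_pN = F_open, fraction = frac,
                                   conc = concs[ci]))
    }
  }
  fit <- fit_fraction_force(pts, L_full = 1.6, constants = cst)
  expect_lt(abs(fit$delta_x_nm - dx_true),
            max(2 * fit$delta_x_se_nm, 0.1))
  expect_equal(fit$preferred, "partial")
})
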