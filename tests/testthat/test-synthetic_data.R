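test_that("zero ligand concentration gives a single open dwell", {
  tc <- trace_sim_config(concentration = 0, duration_s = 1, seed = 1)
  dw <- simulate_state_path(tc)
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$state, "open")
  expect_true(all(dw$censored))
})

test_that("force-independent telegraph dwells follow exponential theory", {
  # delta_x = 0 both ways: open dwell mean must equal 1/(k_close0 * [L])
  tc <- trace_sim_config(k_close0 = 100, delta_x_close_nm = 0,
                         k_open0 = 80, delta_x_open_nm = 0,
                         concentration = 2, conc_unit = "uM",
                         duration_s = 18, seed = 31)
  dw <- simulate_state_path(tc)
  open_d <- usable_dwells(dw, "open")$duration_s
  expect_gt(length(open_d), 900)
  k_true <- 100 * 2
  se <- (1 / k_true) / sqrt(length(open_d))
  expect_lt(abs(mean(open_d) - 1 / k_true), 3 * se)
  closed_d <- usable_dwells(dw, "closed")$duration_s
  se_c <- (1 / 80) / sqrt(length(closed_d))
  expect_lt(abs(mean(closed_d) - 1 / 80), 3 * se_c)
})

test_that("doubling concentration halves open dwells and leaves closed dwells unchanged", {
  mk <- function(conc, seed) {
    tc <- trace_sim_config(k_close0 = 100, delta_x_close_nm = 0,
                           k_open0 = 60, delta_x_open_nm = 0,
                           concentration = conc, duration_s = 12,
                           seed = seed)
    simulate_state_path(tc)
  }
  d1 <- mk(1, 41); d2 <- mk(2, 42)
  o1 <- usable_dwells(d1, "open")$duration_s
  o2 <- usable_dwells(d2, "open")$duration_s
  c1 <- usable_dwells(d1, "closed")$duration_s
  c2 <- usable_dwells(d2, "closed")$duration_s
  se_ratio <- mean(o2) * sqrt(1 / length(o1) + 1 / length(o2))
  expect_lt(abs(mean(o1) / 2 - mean(o2)), 3 * se_ratio)
  se_c <- mean(c1) * sqrt(1 / length(c1) + 1 / length(c2))
  expect_lt(abs(mean(c1) - mean(c2)), 3 * se_c)
})

test_that("noiseless rendering has exactly two signal values", {
  tc <- trace_sim_config(duration_s = 0.5, seed = 5, noise_sd_nm = 0)
  tr <- simulate_trace(tc)
  # block averaging can mix levels at transitions; interior samples of
  # each dwell take exactly the two state levels
  vals <- unique(round(tr$signal_nm, 9))
  expect_lte(length(setdiff(vals, round(c(tr$meta$level_open_nm,
                                          tr$meta$level_closed_nm), 9))),
             sum(tr$true_state[-1] != tr$true_state[-length(tr$true_state)]))
  expect_true(all(abs(tr$signal_nm - tr$meta$level_open_nm) < 1.7 ))
})

test_that("rendered noise matches the configured stationary SD", {
  tc <- trace_sim_config(concentration = 0, duration_s = 10, seed = 8,
                         noise_sd_nm = 0.5, noise_corner_hz = 5000)
  tr <- simulate_trace(tc)
  # stationary SD at the acquisition rate, reduced by block averaging of
  # correlated AR(1) samples: oracle from the OU autocovariance
  a <- exp(-2 * pi * 5000 / 150000)
  m <- 5
  var_block <- (0.5^2 / m^2) *
    (m + 2 * sum((m - 1:(m - 1)) * a^(1:(m - 1))))
  expect_equal(stats::sd(tr$signal_nm), sqrt(var_block), tolerance = 0.05)
})

test_that("level separation after linker correction equals the contraction", {
  tc <- trace_sim_config(duration_s = 2, seed = 13, noise_sd_nm = 0.3)
  tr <- simulate_trace(tc)
  corr <- constant_force_transform(tr, tc$tether$dna)
  sep <- mean(corr$signal_nm[tr$true_state == "open"]) -
    mean(corr$signal_nm[tr$true_state == "closed"])
  expect_equal(sep, 1.6, tolerance = 0.02)
})

test_that("the generator is seed-deterministic and seeds are independent", {
  tc <- trace_sim_config(duration_s = 1, seed = 99)
  t1 <- simulate_trace(tc)
  t2 <- simulate_trace(tc)
  expect_identical(t1$signal_nm, t2$signal_nm)
  expect_identical(attr(t1, "dwells")$duration_s,
                   attr(t2, "dwells")$duration_s)
  # different seeds: same dwell distribution (KS)
  mk <- function(seed) {
    tc <- trace_sim_config(k_close0 = 100, delta_x_close_nm = 0,
                           k_open0 = 80, delta_x_open_nm = 0,
                           concentration = 1, duration_s = 10,
                           seed = seed)
    usable_dwells(simulate_state_path(tc), "open")$duration_s
  }
  ks <- suppressWarnings(stats::ks.test(mk(1), mk(2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("dwell survival is exponential for force-independent configs", {
  tc <- trace_sim_config(k_close0 = 100, delta_x_close_nm = 0,
                         k_open0 = 80, delta_x_open_nm = 0,
                         concentration = 1, duration_s = 15, seed = 55)
  d <- usable_dwells(simulate_state_path(tc), "open")$duration_s
  ks <- suppressWarnings(
    stats::ks.test(d, "pexp", rate = 1 / mean(d)))
  expect_gt(ks$p.value, 0.01)
})

test_that("open-state occupancy follows the closed-form occupancy model", {
  # cross-module check: Gillespie occupancy vs p_closed at ~equal state
  # forces (tiny contraction keeps both states at the same force)
  tc <- trace_sim_config(k_close0 = 150, delta_x_close_nm = -0.2,
                         k_open0 = 40, delta_x_open_nm = 1.0,
                         concentration = 1, duration_s = 30, seed = 66,
                         protein_contraction_nm = 0.05)
  dw <- simulate_state_path(tc)
  occ <- sum(dw$duration_s[dw$state == "closed"]) / sum(dw$duration_s)
  F <- mean(dw$mean_force_pN)
  p <- p_closed(F, 150 * 1, 40, delta_x_nm = 1.0 - (-0.2))
  n_cyc <- sum(dw$state == "closed")
  se <- sqrt(p * (1 - p) / n_cyc) * 2  # conservative
  expect_lt(abs(occ - p), 3 * se)
})

test_that("simulated force-distance curves behave across the free-energy range", {
  # enormous folding free energy: curve identical to the folded branch
  fc <- fec_sim_config(folding_free_energy_kBT = 500, seed = 2,
                       force_noise_pN = 0)
  fec <- simulate_fec(fc)
  bt <- attr(fec, "branches_true")
  expect_equal(fec$force_pN, bt$folded_pN, tolerance = 1e-9)
  # zero free energy: occupancies equal where both branches accessible,
  # measured force midway between the branches
  fc0 <- fec_sim_config(folding_free_energy_kBT = 0, seed = 2,
                        force_noise_pN = 0,
                        distance_range_nm = c(430, 470))
  f0 <- simulate_fec(fc0)
  b0 <- attr(f0, "branches_true")
  mid_dev <- f0$force_pN - (b0$folded_pN + b0$unfolded_pN) / 2
  expect_lt(max(abs(mid_dev[b0$p_fold > 0.45 & b0$p_fold < 0.55])), 0.2)
})

test_that("curve integration recovers the generator folding free energy", {
  fec <- simulate_fec(fec_sim_config(seed = 17))
  br <- fit_branches(fec)
  en <- transition_free_energy(fec, br)
  expect_equal(en$dG_kBT, 11.7, tolerance = 0.5 / 11.7)
})

test_that("config validation rejects impossible settings", {
  expect_error(trace_sim_config(duration_s = 1), "seed")
  expect_error(trace_sim_config(seed = 1, noise_corner_hz = 8e4),
               "Nyquist")
  expect_error(trace_sim_config(seed = 1, sampling_rate_hz = 150000,
                                average_to_hz = 40000), "divide")
  expect_error(fec_sim_config(), "seed")
})

test_that("hopping mode produces two-branch switching around the hump", {
  fc <- fec_sim_config(seed = 12, mode = "hopping", force_noise_pN = 0)
  fec <- simulate_fec(fc)
  bt <- attr(fec, "branches_true")
  mix <- bt$p_fold > 0.2 & bt$p_fold < 0.8
  on_fold <- abs(fec$force_pN - bt$folded_pN) < 1e-9
  on_unf <- abs(fec$force_pN - bt$unfolded_pN) < 1e-9
  expect_true(all(on_fold | on_unf))
  expect_gt(sum(on_fold[mix]), 0)
  expect_gt(sum(on_unf[mix]), 0)
})
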