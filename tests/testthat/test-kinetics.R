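make_dwells <- function(open_d, closed_d, force = 8, conc = 1,
                        censor_extra = FALSE) {
  n <- length(open_d) + length(closed_d)
  st <- rep(c("open", "closed"), length.out = n)
  dur <- as.vector(rbind(open_d, closed_d))[1:n]
  cens <- rep(FALSE, n)
  if (censor_extra) cens[c(1, n)] <- TRUE
  dwell_set(state = st, t_start_s = cumsum(c(0, dur[-n])),
            duration_s = dur, mean_force_pN = rep(force, n),
            censored = cens,
            meta = list(ligand = "AP5A", concentration = conc,
                        conc_unit = "uM"))
}

test_that("constant dwells give the reciprocal rate with zero bootstrap error", {
  dw <- make_dwells(rep(0.1, 20), rep(0.1, 20))
  rp <- rates_from_dwells(dw, n_boot = 100, seed = 1)
  expect_equal(rp$rate_s, c(10, 10))
  expect_equal(rp$se_s, c(0, 0))
  expect_equal(rp$force_pN, c(8, 8))
})

test_that("exponential dwell samples are estimated within 3 standard errors", {
  set.seed(91)
  open_d <- stats::rexp(1000, 50)
  closed_d <- stats::rexp(1000, 5)
  rp <- rates_from_dwells(make_dwells(open_d, closed_d), seed = 2)
  # exponential MLE: se(k_hat) ~ k/sqrt(n)
  expect_lt(abs(rp$rate_s[rp$direction == "closing"] - 50),
            3 * 50 / sqrt(1000))
  expect_lt(abs(rp$rate_s[rp$direction == "opening"] - 5),
            3 * 5 / sqrt(1000))
  # bootstrap se close to the theoretical MLE se
  expect_equal(rp$se_s[1], 50 / sqrt(1000), tolerance = 0.2)
})

test_that("censored dwells are excluded from rate estimates", {
  set.seed(92)
  open_d <- stats::rexp(200, 20)
  closed_d <- stats::rexp(200, 10)
  base <- make_dwells(open_d, closed_d)
  r1 <- rates_from_dwells(base, seed = 3)
  # prepend/append huge censored dwells: estimates unchanged
  padded <- make_dwells(c(99, open_d, 99), c(99, closed_d, 99))
  padded$censored[c(1, 2, nrow(padded) - 1, nrow(padded))] <- TRUE
  r2 <- rates_from_dwells(padded, seed = 3)
  expect_equal(r1$rate_s, r2$rate_s)
  expect_error(rates_from_dwells(make_dwells(stats::rexp(3, 1),
                                             stats::rexp(3, 1))),
               "insufficient")
})

test_that("noise-free Bell points are recovered exactly", {
  cst <- lid_constants()
  f <- c(5, 8, 11, 14)
  for (dx in c(-0.1, 0.6)) {
    k <- 3 * exp(f * dx / cst$kBT)
    fit <- fit_bell(data.frame(force_pN = f, rate_s = k,
                               concentration = 1), "opening")
    expect_lt(max(abs(stats::residuals(fit))), 1e-10)
    expect_equal(fit$delta_x_nm, dx, tolerance = 1e-9)
    expect_equal(unname(fit$k0), 3, tolerance = 1e-9)
  }
})

test_that("global closing fit recovers generator truth within 2 sd", {
  grid <- simulate_dwell_grid(forces_pN = c(6, 8.5, 11, 14),
                              concentrations_uM = c(0.25, 1, 4),
                              k_close0 = 180, delta_x_close_nm = -0.1,
                              k_open0 = 1, delta_x_open_nm = 1.5,
                              n_dwells = 500, seed = 12)
  pts <- do.call(rbind, lapply(grid, rates_from_dwells, n_boot = 200,
                               seed = 5))
  fc <- fit_bell(pts[pts$direction == "closing", ], "closing")
  fo <- fit_bell(pts[pts$direction == "opening", ], "opening")
  expect_lt(abs(fc$delta_x_nm - (-0.1)), 2 * fc$delta_x_se_nm)
  expect_lt(abs(fo$delta_x_nm - 1.5), 2 * fo$delta_x_se_nm)
  truth_k0 <- 180 * c(0.25, 1, 4)
  for (i in 1:3) {
    expect_lt(abs(fc$k0[i] - truth_k0[i]), 2 * fc$k0_se[i])
  }
  expect_lt(abs(fo$k0 - 1), 2 * fo$k0_se)
  # zero-force extrapolation is the fitted intercept, and bimolecular
  # normalization collapses concentrations onto one rate constant
  z <- extrapolate_zero_force(fc, per_concentration = TRUE)
  expect_identical(z$k0_s, unname(fc$k0))
  for (i in 1:3) {
    expect_lt(abs(z$k0_per_conc[i] - 180), 2 * z$k0_per_conc_se[i])
  }
})

test_that("opening fit shares one k0 and ignores concentration labels", {
  cst <- lid_constants()
  f <- rep(c(6, 9, 12), 2)
  set.seed(93)
  k <- 1.2 * exp(f * 1.4 / cst$kBT) * (1 + stats::rnorm(6, sd = 0.03))
  pts <- data.frame(force_pN = f, rate_s = k,
                    concentration = rep(c(1, 10), each = 3))
  f1 <- fit_bell(pts, "opening")
  pts2 <- pts
  pts2$concentration <- rep(c(10, 1), each = 3)  # permuted labels
  f2 <- fit_bell(pts2, "opening")
  expect_equal(f1$delta_x_nm, f2$delta_x_nm)
  expect_equal(unname(f1$k0), unname(f2$k0))
  expect_length(f1$k0, 1)
})

test_that("a single force makes delta_x unidentifiable", {
  pts <- data.frame(force_pN = c(8, 8, 8), rate_s = c(1, 2, 3),
                    concentration = c(1, 2, 3))
  expect_error(fit_bell(pts, "closing"), "unidentifiable|2 forces")
})

test_that("delta-method k0 errors agree with a bootstrap over points", {
  cst <- lid_constants()
  f <- c(6, 8, 10, 12, 14)
  set.seed(94)
  mk <- function() {
    k <- 2 * exp(f * 1.2 / cst$kBT) * exp(stats::rnorm(5, sd = 0.05))
    data.frame(force_pN = f, rate_s = k, se_s = 0.05 * k,
               concentration = 1)
  }
  fit <- fit_bell(mk(), "opening")
  boot_k0 <- replicate(300, fit_bell(mk(), "opening")$k0)
  expect_equal(unname(fit$k0_se), stats::sd(boot_k0), tolerance = 0.35)
})

test_that("fitted rates satisfy two-state thermodynamic consistency", {
  # kBT ln(k_open(F)/k_close(F)) from the fits matches the generator free
  # energy at force F, and the transition-state distances add up to the
  # total conformational change
  cst <- lid_constants()
  dx_c <- -0.12; dx_o <- 1.45; k0c <- 150; k0o <- 0.8
  grid <- simulate_dwell_grid(forces_pN = c(6, 9, 12, 15),
                              concentrations_uM = 1,
                              k_close0 = k0c, delta_x_close_nm = dx_c,
                              k_open0 = k0o, delta_x_open_nm = dx_o,
                              n_dwells = 800, seed = 44)
  pts <- do.call(rbind, lapply(grid, rates_from_dwells, n_boot = 200,
                               seed = 6))
  fc <- fit_bell(pts[pts$direction == "closing", ], "closing")
  fo <- fit_bell(pts[pts$direction == "opening", ], "opening")
  dx_tot <- fo$delta_x_nm - fc$delta_x_nm
  se_tot <- sqrt(fo$delta_x_se_nm^2 + fc$delta_x_se_nm^2)
  expect_lt(abs(dx_tot - (dx_o - dx_c)), 2 * se_tot)
  F <- 10
  dG_fit <- log(predict(fo, F) / predict(fc, F, concentration = "1"))
  dG_true <- log((k0o * exp(F * dx_o / cst$kBT)) /
                   (k0c * exp(F * dx_c / cst$kBT)))
  # generous 2-sd band from the fit errors
  se_dG <- sqrt((fo$k0_se / fo$k0)^2 + (fc$k0_se / fc$k0)^2 +
                  (F * se_tot / cst$kBT)^2)
  expect_lt(abs(dG_fit - dG_true), 2 * se_dG)
})

test_that("force dependence of closing discriminates binding mechanisms", {
  # induced fit: closing nearly force independent (small delta_x);
  # conformational selection: closing carries the full conformational
  # change and is strongly force dependent
  mk <- function(dx_close, seed) {
    grid <- simulate_dwell_grid(forces_pN = c(6, 9, 12, 15),
                                concentrations_uM = 1, k_close0 = 150,
                                delta_x_close_nm = dx_close,
                                k_open0 = 1,
                                delta_x_open_nm = 1.6 + dx_close,
                                n_dwells = 500, seed = seed)
    pts <- do.call(rbind, lapply(grid, rates_from_dwells, n_boot = 100,
                                 seed = 7))
    fit_bell(pts[pts$direction == "closing", ], "closing")
  }
  induced <- mk(-0.1, 45)
  select <- mk(-1.6, 46)
  expect_lt(abs(induced$delta_x_nm), 0.3)
  expect_lt(select$delta_x_nm, -1.0)
  expect_gt(abs(select$delta_x_nm), 3 * select$delta_x_se_nm)
})
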