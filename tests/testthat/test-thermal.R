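# Oracles for the bilinear estimator are the analytic intersection of the
# generating lines; the hyperbolic estimator is checked against its own
# closed form (extremum of the model's second derivative at T0).

two_line_curve <- function(Tg, a1 = 1.40, m1 = -2e-4, a2 = 1.60, m2 = -6e-4,
                           T_grid = seq(150, 550, by = 25)) {
  rho <- pmin(a1 + m1 * T_grid, a2 + m2 * T_grid)
  dilatometry_curve(T_grid, rho)
}

test_that("bilinear estimator equals the analytic line intersection on noise-free data", {
  # lines 1.40 - 2e-4 T and 1.60 - 6e-4 T cross at T = 0.20 / 4e-4 = 500 K
  cv <- two_line_curve(Tg = 500)
  est <- suppressWarnings(bilinear_tg(cv))
  expect_equal(est$Tg, line_intersection_T(1.40, -2e-4, 1.60, -6e-4),
               tolerance = 1e-9)
  expect_equal(est$Tg, 500, tolerance = 1e-9)
  expect_gte(est$uncertainty, 0)
  # identical slopes: no crossover
  flat <- dilatometry_curve(seq(150, 550, 25), 1.4 - 2e-4 * seq(150, 550, 25))
  expect_error(bilinear_tg(flat), "parallel")
  # window outside the data span
  expect_error(bilinear_tg(cv, low_range = c(100, 140)), "span")
})

test_that("bilinear recovery on seeded synthetic curves stays within half the transition breadth (median)", {
  errs <- vapply(1:100, function(s) {
    cv <- gen_dilatometry(Tg_true = 420, breadth = 40, noise_sd = 0.002,
                          n_replicas = 5, seed = 2000 + s)
    suppressWarnings(bilinear_tg(cv))$Tg - 420
  }, numeric(1))
  expect_lte(median(abs(errs)), 20)
})

test_that("hyperbolic fit recovers generating parameters to 1e-3 relative", {
  T_grid <- seq(150, 550, by = 10)
  truth <- list(rho0 = 1.30, a = 3e-4, b = -2e-4, T0 = 430, c = 4)
  rho <- ligninpress:::hyperbolic_density(T_grid, truth$rho0, truth$a,
                                          truth$b, truth$T0, truth$c)
  fit <- fit_hyperbolic(dilatometry_curve(T_grid, rho))
  for (p in names(truth))
    expect_lt(abs(fit[[p]] - truth[[p]]) / abs(truth[[p]]), 1e-3)
  # evaluation identity at T = T0: rho = rho0 + b * exp(c/2)
  expect_equal(predict_hyperbolic(fit, fit$T0),
               fit$rho0 + fit$b * exp(fit$c / 2), tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("pure-line data yields a degenerate hyperbolic fit with undefined Tg", {
  T_grid <- seq(150, 550, by = 10)
  cv <- dilatometry_curve(T_grid, 1.4 - 3e-4 * T_grid)
  fit <- fit_hyperbolic(cv)
  expect_true(fit$degenerate)
  expect_error(hyperbolic_tg(fit), "degenerate")
})

test_that("hyperbolic Tg equals the fitted T0 and translates with the data", {
  cv <- gen_dilatometry(Tg_true = 430, noise_sd = 0, seed = 1)
  fit <- fit_hyperbolic(cv)
  est <- hyperbolic_tg(fit)
  expect_equal(est$Tg, fit$T0, tolerance = 0.1)
  # translation equivariance: recenter by +50 K
  shifted <- dilatometry_curve(cv$T_K + 50, cv$rho_gcm3)
  est2 <- hyperbolic_tg(fit_hyperbolic(shifted))
  expect_equal(est2$Tg, est$Tg + 50, tolerance = 0.2)
})

test_that("hyperbolic recovery over 100 seeded curves stays within breadth/2 (median)", {
  errs <- vapply(1:100, function(s) {
    cv <- gen_dilatometry(Tg_true = 420, breadth = 40, noise_sd = 0.002,
                          n_replicas = 5, seed = 2000 + s)
    hyperbolic_tg(fit_hyperbolic(cv))$Tg - 420
  }, numeric(1))
  expect_lte(median(abs(errs)), 20)
})

test_that("onset scan matches a brute-force grid oracle and is monotone in threshold", {
  cv <- gen_dilatometry(Tg_true = 420, breadth = 40, noise_sd = 0.001, seed = 3)
  bl <- suppressWarnings(bilinear_tg(cv))
  fit <- fit_hyperbolic(cv)
  est <- onset_tg(fit, bl$diagnostics$low_line, threshold_pct = 2)
  oracle <- onset_grid_oracle(fit, bl$diagnostics$low_line$coef, 2, fit$T_span)
  expect_equal(est$Tg, oracle, tolerance = 0.1001)
  # monotone non-decreasing in threshold
  tgs <- vapply(c(0.5, 1, 2, 3), function(th)
    onset_tg(fit, bl$diagnostics$low_line, th)$Tg, numeric(1))
  expect_true(all(diff(tgs) >= 0))
  # a fit identical to the line never exceeds the threshold
  line_fit <- fit
  line_fit$b <- 0
  line_fit$rho0 <- bl$diagnostics$low_line$coef[1] +
    bl$diagnostics$low_line$coef[2] * line_fit$T0
  line_fit$a <- -bl$diagnostics$low_line$coef[2]
  expect_error(onset_tg(line_fit, bl$diagnostics$low_line), "no-onset")
})

test_that("onset sits below the bilinear estimate for a broad transition", {
  broad <- gen_dilatometry(slope_glass = -1e-4, slope_melt = -2e-3,
                           breadth = 80, Tg_true = 450, noise_sd = 0.001,
                           seed = 11)
  e <- suppressWarnings(estimate_tg(broad))
  expect_lt(e$onset$Tg, e$bilinear$Tg)
  # and above it for a narrow one
  narrow <- gen_dilatometry(slope_glass = -1e-4, slope_melt = -2e-3,
                            breadth = 10, Tg_true = 450, noise_sd = 0.001,
                            seed = 11)
  en <- suppressWarnings(estimate_tg(narrow))
  expect_gt(en$onset$Tg, en$bilinear$Tg)
})

test_that("all three estimators are equivariant under temperature translation and density scaling", {
  cv <- gen_dilatometry(Tg_true = 420, breadth = 40, noise_sd = 0.001, seed = 5)
  base <- suppressWarnings(estimate_tg(cv))
  moved <- dilatometry_curve(cv$T_K + 30, cv$rho_gcm3 * 2,
                             rho_sd = cv$rho_sd * 2)
  shifted <- suppressWarnings(estimate_tg(
    moved, low_range = c(180, 255), high_range = c(530, 580)))
  for (m in c("bilinear", "hyperbolic", "onset"))
    expect_equal(shifted[[m]]$Tg, base[[m]]$Tg + 30, tolerance = 0.5)
})

test_that("WLF shift and its inverse are consistent", {
  expect_equal(wlf_log_shift(T = 420, Tg = 420, C1 = 10, C2 = 50), 0)
  expect_equal(wlf_log_shift(T = 470, Tg = 420, C1 = 10, C2 = 50), 5.0)
  expect_equal(invert_wlf(0, C1 = 10, C2 = 50), 0)
  expect_equal(invert_wlf(5, C1 = 10, C2 = 50), 50)
  # round trip to 1e-9
  for (L in c(-3, -0.5, 0.7, 4)) {
    dT <- invert_wlf(L, C1 = 10, C2 = 50)
    expect_equal(wlf_log_shift(420 + dT, 420, 10, 50), L, tolerance = 1e-9)
  }
  # shifting to a slower rate gives a negative temperature offset
  L_slow <- log10((10 / 60) / (2.5e9))  # 10 K/min vs 2.5 K/ns, both in K/s
  expect_lt(invert_wlf(L_slow, C1 = 15, C2 = 80), 0)
  # pole handling
  expect_error(wlf_log_shift(370, 420, 10, 50), "pole")
  expect_error(invert_wlf(10, 10, 50), "C1")
})
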