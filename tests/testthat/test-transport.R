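test_that("MSD is exact for stationary and ballistic motion and rejects wrapped input", {
  n <- 51
  still <- manual_traj(list(matrix(1.5, n, 3), matrix(-2, n, 3)), dt = 0.1)
  m <- compute_msd(still, origin_stride = 1)
  expect_true(all(m$msd_nm2 == 0))
  expect_identical(m$msd_nm2[1], 0)

  # deterministic linear motion at speed v: msd(tau) = (v tau)^2
  v <- 0.05  # nm/ns, slow enough that no step exceeds box/2
  t <- seq(0, 5, by = 0.1)
  ballistic <- manual_traj(list(cbind(v * t, 0 * t, 0 * t)), dt = 0.1)
  mb <- compute_msd(ballistic, max_lag = 2.5, origin_stride = 1)
  expect_equal(mb$msd_nm2, (v * mb$lag_ns)^2, tolerance = 1e-12)

  # n_pairs never increases with lag
  expect_true(all(diff(mb$n_pairs) <= 0))

  # a single-step jump over half the box is flagged as wrapped data
  jump <- matrix(0, 11, 3)
  jump[6, 1] <- 15  # box/2 = 10.5
  expect_error(compute_msd(manual_traj(list(jump), dt = 0.1)), "wrapped")
})

test_that("Einstein estimator inverts an exact MSD line and flags negative slopes", {
  # msd = 6 * (1e-12 m^2/s in nm^2/ns) * tau  ->  D = 1e-12 m^2/s
  lag <- seq(0, 10, by = 0.1)
  m <- manual_msd(lag, 6 * 1e-3 * lag)
  est <- einstein_diffusivity(m)
  expect_equal(est$D, 1e-12, tolerance = 1e-12)
  expect_false(est$clamped)

  # averaging replicas then fitting equals fitting then averaging (linearity)
  m1 <- manual_msd(lag, 6e-3 * lag)
  m2 <- manual_msd(lag, 12e-3 * lag)
  avg <- manual_msd(lag, (m1$msd_nm2 + m2$msd_nm2) / 2)
  expect_equal(einstein_diffusivity(avg)$D,
               (einstein_diffusivity(m1)$D + einstein_diffusivity(m2)$D) / 2,
               tolerance = 1e-12)

  # decreasing msd beyond noise: clamped at zero with a warning
  down <- manual_msd(lag, 1 - 0.05 * lag)
  expect_warning(est0 <- einstein_diffusivity(down), "clamping")
  expect_identical(est0$D, 0)
  expect_true(est0$clamped)
})

test_that("Einstein estimator recovers the generator diffusivity on seeded walkers", {
  D <- 2e-13
  w <- gen_random_walks(D_true = D, n_walkers = 300, dt = 0.01, n_steps = 2000,
                        seed = 21)
  est <- einstein_diffusivity(compute_msd(w))
  expect_lt(abs(est$D - D) / D, 0.05)
})

test_that("Arrhenius fits reproduce closed forms and split into branches", {
  # two-point closed form: ~68.9 kJ/mol
  s <- data.frame(T_K = c(300, 600), D_m2s = c(1e-12, 1e-6))
  f <- arrhenius_fit(s)
  expect_equal(f$Ed, two_point_Ed(300, 1e-12, 600, 1e-6), tolerance = 1e-9)
  expect_equal(f$Ed, 68.9, tolerance = 0.05)

  # exact round trip on noise-free input
  clean <- gen_arrhenius_series(D0 = 3e-9, Ed_true = 37.5, lognoise_sd = 0)
  fc <- arrhenius_fit(clean)
  expect_equal(fc$Ed, 37.5, tolerance = 1e-9)
  expect_equal(fc$D0, 3e-9, tolerance = 1e-6)

  # Ed = 0 synthetic: fitted Ed zero within stderr
  flat <- gen_arrhenius_series(Ed_true = 0, lognoise_sd = 0.05, seed = 2)
  ff <- arrhenius_fit(flat)
  expect_lt(abs(ff$Ed), 2 * ff$stderr_Ed + 1e-9)

  # branch split: independent fits below/above with distinct slopes
  lowT <- gen_arrhenius_series(D0 = 1e-10, Ed_true = 20,
                               T_list = c(250, 275, 300, 325), lognoise_sd = 0)
  highT <- gen_arrhenius_series(D0 = 1e-6, Ed_true = 60,
                                T_list = c(400, 450, 500, 550), lognoise_sd = 0)
  both <- rbind(lowT, highT)
  split <- arrhenius_fit(both, branch_split = 360)
  expect_equal(split$below_Tg$Ed, 20, tolerance = 1e-6)
  expect_equal(split$above_Tg$Ed, 60, tolerance = 1e-6)

  # non-positive points are excluded with a warning
  dirty <- data.frame(T_K = c(300, 400, 500), D_m2s = c(0, 1e-12, 1e-10))
  expect_warning(fd <- arrhenius_fit(dirty), "excluded")
  expect_equal(fd$n, 2L)
})

test_that("per-molecule diffusivities are consistent with the Einstein estimate and resolve mixtures", {
  w <- gen_random_walks(D_true = 5e-12, n_walkers = 150, dt = 0.01,
                        n_steps = 1000, seed = 31)
  span <- max(w$times)
  pm <- per_molecule_diffusivity(w, sampling_times = c(0.5, span / 2))
  longest <- pm$per_molecule[pm$per_molecule$tau_ns == max(pm$per_molecule$tau_ns), ]
  ens_mean <- mean(longest$D_eff_m2s)
  est <- einstein_diffusivity(compute_msd(w))
  expect_lt(abs(ens_mean - est$D) / est$D, 0.10)

  # identically distributed walkers: D_eff concentrates around the common D
  meds <- tapply(pm$per_molecule$D_eff_m2s, pm$per_molecule$tau_ns, median)
  expect_true(all(abs(meds - 5e-12) / 5e-12 < 0.25))

  # 50/50 mixture at short tau: components separated by the generator labels
  mix <- gen_random_walks(D_true = c(5e-12, 5e-14), fractions = c(0.5, 0.5),
                          n_walkers = 100, dt = 0.01, n_steps = 500, seed = 33)
  comp <- attr(mix, "ground_truth")$component
  pmix <- per_molecule_diffusivity(mix, sampling_times = 0.1)
  d <- pmix$per_molecule$D_eff_m2s
  med1 <- median(d[comp == 1]); med2 <- median(d[comp == 2])
  valley <- sum(d > med2 * 3 & d < med1 / 3)  # few molecules between modes
  expect_gt(med1 / med2, 20)
  expect_lt(valley / length(d), 0.2)
  # the bimodality coefficient exceeds the uniform benchmark 5/9
  expect_gt(pmix$summary$bimodality_coef[1], 5 / 9)

  expect_error(per_molecule_diffusivity(w, sampling_times = 0), "> 0")
})

test_that("density maps conserve mass and localize mass where molecules are", {
  # uniform points: cells uniform within 3 sigma Poisson bands
  set.seed(4)
  n_mol <- 400
  pts <- lapply(seq_len(n_mol), function(i)
    matrix(runif(3 * 5, 0, 21), ncol = 3))
  traj <- manual_traj(pts, dt = 0.1)
  map <- water_density_map(traj, grid_n = 4)
  expect_equal(sum(map$density) * map$cell_volume_cm3, map$total_mass_g,
               tolerance = 1e-9)
  expected_per_cell <- n_mol / 16
  counts <- map$density * map$cell_volume_cm3 /
    (18.015 / 6.02214076e23)
  expect_true(all(abs(counts - expected_per_cell) <
                    3 * sqrt(expected_per_cell / 5)))

  # all molecules in one octant: >= 99% of mass in that quadrant
  corner <- lapply(1:50, function(i) matrix(runif(3 * 5, 0, 5), ncol = 3))
  cmap <- water_density_map(manual_traj(corner, dt = 0.1), grid_n = 4)
  quad_mass <- sum(cmap$density[1:1, 1:1]) * cmap$cell_volume_cm3
  expect_gte(quad_mass / cmap$total_mass_g, 0.99)

  # single cell equals the bulk species density
  one <- water_density_map(traj, grid_n = 1)
  bulk <- one$total_mass_g / (21^3 * 1e-21)
  expect_equal(one$density[1, 1], bulk, tolerance = 1e-9)

  # empty selection: zero map with flag
  none <- traj; none$positions <- list()
  emap <- water_density_map(none, grid_n = 2)
  expect_true(emap$empty)
  expect_true(all(emap$density == 0))
})
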