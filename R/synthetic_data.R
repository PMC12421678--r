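# Seeded synthetic generators for every observable the analysis stages
# consume: dilatometry curves, Brownian walkers, elastic deformation records,
# and Arrhenius diffusivity series. Each generator stores its ground truth in
# the `ground_truth` attribute of the returned object.

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  force(seed)  # must evaluate before the caller's RNG state is snapshotted
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# hyperbolic two-slope density model; shared by the generator and the
# thermal fitting routines. s = T - T0.
hyperbolic_density <- function(T, rho0, a, b, T0, c) {
  s <- T - T0
  H0 <- s / 2 - sqrt(s^2 / 4 + exp(c))
  rho0 - a * s - b * H0
}

#' Generate a synthetic dilatometry (density vs temperature) curve
#'
#' Emulates stepwise-cooling output: a glassy low-temperature branch with
#' slope `slope_glass` and a rubbery/melt branch with steeper slope
#' `slope_melt`, blended smoothly around the true glass transition
#' `Tg_true` over a half-width `breadth`, plus i.i.d. Gaussian density noise
#' per replica. Replicas are averaged as in production analysis.
#'
#' Two blend models are available. The default `"hyperbolic"` model is
#' `rho(T) = rho0 - a (T - T0) - b H0(T, T0, c)` with
#' `H0 = (T - T0)/2 - sqrt((T - T0)^2/4 + exp(c))`, parameterised by
#' `a = -slope_melt`, `b = slope_melt - slope_glass`, `T0 = Tg_true` and
#' `c = 2 log(breadth)`; its asymptote slopes are exactly `slope_glass`
#' (low T) and `slope_melt` (high T). The `"tanh"` alternative blends the two
#' straight lines through (`Tg_true`, `rho_ref`) with a tanh switch of width
#' `breadth`, and is deliberately mis-specified relative to the hyperbolic
#' fitting model.
#'
#' @param rho_ref g/cm^3; density of the high-temperature asymptote
#'   extrapolated to `Tg_true` (the `rho0` of the hyperbolic model).
#' @param slope_glass dρ/dT on the glassy branch, g/cm^3 per K (e.g. -2e-4).
#' @param slope_melt dρ/dT on the melt branch; must be steeper
#'   (|slope_melt| > |slope_glass|).
#' @param Tg_true K, true transition temperature.
#' @param breadth K, transition half-width (> 0).
#' @param noise_sd g/cm^3, per-point Gaussian noise per replica (>= 0).
#' @param T_grid K, temperatures sampled (default 150-550 K in 25 K steps,
#'   the stepwise-cooling grid).
#' @param n_replicas parallel replicas averaged into the curve (default 5).
#' @param seed integer RNG seed; replica r uses stream `seed + r - 1`.
#' @param model `"hyperbolic"` (default) or `"tanh"`.
#' @param moisture_wt_pct metadata carried on the curve.
#' @return A [dilatometry_curve()] with ground truth in
#'   `attr(, "ground_truth")` and per-replica draws in `attr(, "replicas")`.
#' @export
gen_dilatometry <- function(rho_ref = 1.30, slope_glass = -2e-4,
                            slope_melt = -6e-4, Tg_true = 420, breadth = 40,
                            noise_sd = 0.002, T_grid = seq(150, 550, by = 25),
                            n_replicas = 5, seed = 1,
                            model = c("hyperbolic", "tanh"),
                            moisture_wt_pct = NA_real_) {
  model <- match.arg(model)
  if (length(T_grid) == 0) stop("empty temperature grid")
  if (breadth <= 0) stop("breadth must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(slope_melt) <= abs(slope_glass))
    stop("|slope_melt| must exceed |slope_glass| (expansivity grows above Tg)")
  T_grid <- sort(T_grid)

  mean_rho <- switch(model,
    hyperbolic = hyperbolic_density(
      T_grid, rho0 = rho_ref, a = -slope_melt,
      b = slope_melt - slope_glass, T0 = Tg_true, c = 2 * log(breadth)),
    tanh = {
      w <- (1 + tanh((T_grid - Tg_true) / breadth)) / 2
      lg <- rho_ref + slope_glass * (T_grid - Tg_true)
      lm_ <- rho_ref + slope_melt * (T_grid - Tg_true)
      lg * (1 - w) + lm_ * w
    })

  reps <- vapply(seq_len(n_replicas), function(r) {
    .with_seed(seed + r - 1L, mean_rho + stats::rnorm(length(T_grid), 0, noise_sd))
  }, numeric(length(T_grid)))
  reps <- matrix(reps, nrow = length(T_grid))

  curve <- dilatometry_curve(
    T = T_grid,
    rho = rowMeans(reps),
    rho_sd = if (n_replicas > 1) apply(reps, 1, stats::sd) else rep(0, length(T_grid)),
    n_replicas = n_replicas,
    moisture_wt_pct = moisture_wt_pct
  )
  attr(curve, "replicas") <- reps
  attr(curve, "ground_truth") <- list(
    model = model, rho_ref = rho_ref, slope_glass = slope_glass,
    slope_melt = slope_melt, Tg_true = Tg_true, breadth = breadth,
    noise_sd = noise_sd, seed = seed
  )
  curve
}

#' Generate unwrapped 3-D Brownian walkers with known diffusivity
#'
#' Each walker takes Gaussian increments with per-axis variance
#' `2 D dt` (D converted from m^2/s to nm^2/ns via 1 m^2/s = 1e9 nm^2/ns),
#' giving an ensemble mean-square displacement `6 D t`. Mixtures are
#' supported: `D_true` may be a vector with matching `fractions`, and each
#' walker's component is recorded in the ground truth.
#'
#' @param D_true m^2/s; scalar or vector of mixture component diffusivities.
#' @param fractions mixture weights summing to 1 (default single component).
#' @param n_walkers number of molecules.
#' @param dt ns, time step.
#' @param n_steps steps per walker (trajectory has `n_steps + 1` frames).
#' @param box nm, cubic box edge (metadata; walkers are unwrapped).
#' @param species `"water"` or `"lignin_unit"` metadata.
#' @param temperature,moisture_wt_pct metadata carried on the set.
#' @param seed integer RNG seed.
#' @return A `trajectory_set`: list with `times` (ns), `positions` (list of
#'   (n_steps+1) x 3 matrices, nm), `species`, `box`, `temperature`,
#'   `moisture_wt_pct`; ground truth (component of each walker, D values) in
#'   `attr(, "ground_truth")`.
#' @export
gen_random_walks <- function(D_true = 5e-12, fractions = NULL, n_walkers = 100,
                             dt = 0.01, n_steps = 1000, box = 21,
                             species = "water", temperature = NA_real_,
                             moisture_wt_pct = NA_real_, seed = 1) {
  if (is.null(fractions)) fractions <- rep(1 / length(D_true), length(D_true))
  if (length(fractions) != length(D_true)) stop("fractions must match D_true")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(D_true < 0)) stop("D_true must be >= 0")

  D_nm2_ns <- D_true * 1e9          # 1 m^2/s = 1e9 nm^2/ns
  sd_step <- sqrt(2 * D_nm2_ns * dt)

  .with_seed(seed, {
    comp <- sample.int(length(D_true), n_walkers, replace = TRUE, prob = fractions)
    positions <- lapply(seq_len(n_walkers), function(i) {
      inc <- matrix(stats::rnorm(n_steps * 3L, 0, sd_step[comp[i]]),
                    ncol = 3L)
      rbind(c(0, 0, 0), apply(inc, 2, cumsum))
    })
    out <- list(
      times = seq(0, n_steps) * dt,
      positions = positions,
      species = species,
      box = rep(box, 3L),
      temperature = temperature,
      moisture_wt_pct = moisture_wt_pct
    )
    class(out) <- "trajectory_set"
    attr(out, "ground_truth") <- list(
      D_true = D_true, fractions = fractions, component = comp,
      dt = dt, seed = seed
    )
    out
  })
}

#' Generate a linear-elastic uniaxial deformation record
#'
#' Stress follows Hooke's law `sigma = E_true * strain` with additive
#' Gaussian fluctuation noise emulating pressure-tensor jitter; the two
#' transverse box edges contract as `box_edge * (1 - nu_true * strain)` with
#' small additive length noise. Strain is sampled uniformly from 0 to
#' `max_strain` (>= 0.20 so the standard fitting interval is covered).
#'
#' @param E_true GPa, Young's modulus.
#' @param nu_true Poisson's ratio, in `[0, 0.5)`.
#' @param rate m/s, deformation rate metadata (default 0.1).
#' @param box_edge nm, undeformed cubic box edge.
#' @param max_strain maximum engineering strain (default 0.25).
#' @param strain_step strain increment between samples.
#' @param stress_noise_sd GPa, stress noise (default 0.05).
#' @param box_noise_sd nm, transverse-edge noise (default 0.02).
#' @param axis,temperature,moisture_wt_pct metadata.
#' @param seed integer RNG seed.
#' @return A [deformation_record()] with ground truth attached.
#' @export
gen_deformation <- function(E_true = 2.2, nu_true = 0.35, rate = 0.1,
                            box_edge = 21, max_strain = 0.25,
                            strain_step = 1e-4, stress_noise_sd = 0.05,
                            box_noise_sd = 0.02, axis = "x",
                            temperature = NA_real_, moisture_wt_pct = NA_real_,
                            seed = 1) {
  if (nu_true < 0 || nu_true >= 0.5) stop("nu_true must be in [0, 0.5)")
  if (max_strain < 0.20) stop("max_strain must be >= 0.20")
  strain <- seq(0, max_strain, by = strain_step)
  .with_seed(seed, {
    stress <- E_true * strain + stats::rnorm(length(strain), 0, stress_noise_sd)
    trans1 <- box_edge * (1 - nu_true * strain) +
      stats::rnorm(length(strain), 0, box_noise_sd)
    trans2 <- box_edge * (1 - nu_true * strain) +
      stats::rnorm(length(strain), 0, box_noise_sd)
    rec <- deformation_record(
      axis = axis, strain = strain, stress = stress,
      box_axial = box_edge * (1 + strain),
      box_transverse = cbind(trans1, trans2),
      box_edge0 = box_edge, rate = rate,
      temperature = temperature, moisture_wt_pct = moisture_wt_pct
    )
    attr(rec, "ground_truth") <- list(
      E_true = E_true, nu_true = nu_true, stress_noise_sd = stress_noise_sd,
      box_noise_sd = box_noise_sd, seed = seed
    )
    rec
  })
}

#' Generate an Arrhenius diffusivity-versus-temperature series
#'
#' `D(T) = D0 * exp(-Ed_true / (R T))` with multiplicative log-normal noise
#' (`lognoise_sd` on the natural-log scale).
#'
#' @param D0 m^2/s, pre-exponential factor (> 0).
#' @param Ed_true kJ/mol, activation energy.
#' @param T_list K, temperatures (strictly positive); default the isothermal
#'   production set 300-550 K.
#' @param lognoise_sd log-scale noise sd (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns `T_K` and `D_m2s`; ground truth attached.
#' @export
gen_arrhenius_series <- function(D0 = 1e-8, Ed_true = 50,
                                 T_list = c(300, 400, 450, 475, 500, 525, 550),
                                 lognoise_sd = 0, seed = 1) {
  if (D0 <= 0) stop("D0 must be > 0")
  if (any(T_list <= 0)) stop("temperatures must be positive")
  R <- 8.314462618e-3  # kJ/(mol K)
  D <- D0 * exp(-Ed_true / (R * T_list))
  if (lognoise_sd > 0)
    D <- .with_seed(seed, D * exp(stats::rnorm(length(T_list), 0, lognoise_sd)))
  out <- data.frame(T_K = T_list, D_m2s = D)
  attr(out, "ground_truth") <- list(D0 = D0, Ed_true = Ed_true,
                                    lognoise_sd = lognoise_sd, seed = seed)
  out
}
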