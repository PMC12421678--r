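# Diffusivity analysis: mean-square displacement, Einstein-relation
# diffusivity, Arrhenius activation energies, per-molecule diffusivity
# distributions, and through-thickness mass density maps.

.R_kJ <- 8.314462618e-3  # gas constant, kJ/(mol K)

# frame x molecule coordinate matrices (one per axis); lag arithmetic then
# vectorises across all molecules at once
.coord_matrices <- function(traj) {
  lapply(1:3, function(ax)
    vapply(traj$positions, function(P) P[, ax],
           numeric(length(traj$times))))
}
.NM2_NS_TO_M2_S <- 1e-9  # 1 nm^2/ns = 1e-9 m^2/s
.WATER_MOLAR_MASS <- 18.015
.AVOGADRO <- 6.02214076e23

#' Mean-square displacement of a trajectory set
#'
#' Averages squared displacements over all molecules and over sliding time
#' origins taken every `origin_stride` frames. Lags are evaluated at every
#' frame spacing up to `max_lag`. `msd(0) = 0` exactly. A single-step jump
#' larger than half the box on any axis triggers an unwrapped-coordinate
#' error (wrapped input is rejected, not silently analysed).
#'
#' @param traj a `trajectory_set` (see [gen_random_walks()] for the layout).
#' @param max_lag ns; defaults to half the trajectory span.
#' @param origin_stride frames between sliding origins (default 10).
#' @param n_lags maximum number of distinct lags evaluated (evenly spaced in
#'   lag steps, default 200); the diffusive slope needs far fewer points
#'   than there are frames.
#' @return data.frame of class `msd_series` with `lag_ns`, `msd_nm2`,
#'   `n_pairs` (molecule-origin pairs averaged per lag).
#' @export
compute_msd <- function(traj, max_lag = NULL, origin_stride = 10L,
                        n_lags = 200L) {
  times <- traj$times
  n <- length(times)
  if (n < 2) stop("need at least 2 time points")
  dt <- times[2] - times[1]
  span <- times[n] - times[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag > span) stop("max_lag exceeds the trajectory span")

  co <- .coord_matrices(traj)
  halfbox <- traj$box / 2
  for (ax in 1:3)
    if (max(abs(diff(co[[ax]]))) > halfbox[ax])
      stop("single-step jump exceeds box/2: coordinates look wrapped")

  n_mol <- length(traj$positions)
  max_step <- floor(max_lag / dt)
  lag_steps <- if (max_step <= n_lags) seq_len(max_step) else
    unique(round(seq(1, max_step, length.out = n_lags)))
  msd <- numeric(length(lag_steps) + 1L)
  npairs <- integer(length(lag_steps) + 1L)
  npairs[1] <- n_mol * n
  for (k in seq_along(lag_steps)) {
    L <- lag_steps[k]
    origins <- seq(1L, n - L, by = origin_stride)
    acc <- 0
    for (ax in 1:3) {
      d <- co[[ax]][origins + L, , drop = FALSE] -
        co[[ax]][origins, , drop = FALSE]
      acc <- acc + sum(d * d)
    }
    msd[k + 1L] <- acc / (length(origins) * n_mol)
    npairs[k + 1L] <- length(origins) * n_mol
  }
  out <- data.frame(lag_ns = c(0, lag_steps * dt), msd_nm2 = msd,
                    n_pairs = npairs)
  class(out) <- c("msd_series", "data.frame")
  attr(out, "species") <- traj$species
  attr(out, "temperature") <- traj$temperature
  attr(out, "moisture_wt_pct") <- traj$moisture_wt_pct
  out
}

#' Einstein-relation diffusivity from an MSD series
#'
#' Least-squares slope of MSD versus lag over a fit window, divided by 6
#' (three dimensions), with units converted from nm^2/ns to m^2/s
#' (1 nm^2/ns = 1e-9 m^2/s). The default window spans 10-50% of the
#' available lag range, excluding short-lag ballistic/caging behaviour and
#' the noisy long-lag tail. A fitted slope more than 2 standard errors below
#' zero is clamped to `D = 0` with `clamped = TRUE`.
#'
#' @param msd an `msd_series` from [compute_msd()].
#' @param fit_window ns, `c(min, max)` lag window (default 10-50% of span).
#' @return list of class `diffusivity_estimate`: `D` (m^2/s), `stderr`,
#'   `fit_window`, `clamped`, plus species/temperature/moisture metadata.
#' @export
einstein_diffusivity <- function(msd, fit_window = NULL) {
  span <- max(msd$lag_ns)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * span
  sel <- msd$lag_ns >= fit_window[1] & msd$lag_ns <= fit_window[2]
  if (sum(sel) < 3) stop("fit window contains fewer than 3 lags")
  fit <- stats::lm(msd_nm2 ~ lag_ns, data = msd[sel, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(.lm_vcov(fit)[2, 2])
  clamped <- FALSE
  if (slope < -2 * se) {
    warning("fitted MSD slope significantly negative; clamping D at 0")
    slope <- 0
    clamped <- TRUE
  }
  out <- list(
    D = max(slope, 0) / 6 * .NM2_NS_TO_M2_S,
    stderr = se / 6 * .NM2_NS_TO_M2_S,
    fit_window = fit_window,
    clamped = clamped,
    species = attr(msd, "species"),
    temperature = attr(msd, "temperature"),
    moisture_wt_pct = attr(msd, "moisture_wt_pct")
  )
  class(out) <- "diffusivity_estimate"
  out
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("D = %.3g +/- %.2g m^2/s (window %.2f-%.2f ns)%s\n",
              x$D, x$stderr, x$fit_window[1], x$fit_window[2],
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Arrhenius fit of diffusivity versus temperature
#'
#' Ordinary least squares of `ln D` against `1/T`; the activation energy is
#' `Ed = -R * slope` (R = 8.314 J/(mol K)), reported in kJ/mol. When
#' `branch_split` is given, independent fits are returned below and above
#' the split temperature — the standard treatment when the Arrhenius plot is
#' strongly curved around the glass transition. Non-positive diffusivities
#' are excluded with a warning.
#'
#' @param series data.frame with columns `T_K` and `D_m2s`.
#' @param branch_split K, optional split temperature (e.g. a Tg estimate).
#' @return For a single branch, a list of class `arrhenius_fit` with `D0`
#'   (m^2/s), `Ed` (kJ/mol), `stderr_Ed`, `T_range`, `branch`, `n`. With a
#'   split, a list with elements `below_Tg` and `above_Tg`.
#' @export
arrhenius_fit <- function(series, branch_split = NULL) {
  usable <- is.finite(series$D_m2s) & series$D_m2s > 0
  if (any(!usable))
    warning(sum(!usable), " non-positive diffusivity point(s) excluded")
  series <- series[usable, , drop = FALSE]

  fit_branch <- function(s, branch) {
    if (nrow(s) < 2) stop("fewer than 2 usable points for branch ", branch)
    fit <- stats::lm(log(D_m2s) ~ I(1 / T_K), data = s)
    slope <- unname(stats::coef(fit)[2])
    se <- if (nrow(s) > 2) sqrt(.lm_vcov(fit)[2, 2]) else NA_real_
    out <- list(
      D0 = exp(unname(stats::coef(fit)[1])),
      Ed = -.R_kJ * slope,
      stderr_Ed = .R_kJ * se,
      T_range = range(s$T_K),
      branch = branch,
      n = nrow(s),
      fit = fit
    )
    class(out) <- "arrhenius_fit"
    out
  }

  if (is.null(branch_split)) return(fit_branch(series, "single"))
  list(
    below_Tg = fit_branch(series[series$T_K < branch_split, , drop = FALSE],
                          "below_Tg"),
    above_Tg = fit_branch(series[series$T_K >= branch_split, , drop = FALSE],
                          "above_Tg")
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s): Ed = %.2f kJ/mol (SE %.2f), D0 = %.3g m^2/s, %d temperatures\n",
              x$branch, x$Ed, x$stderr_Ed, x$D0, x$n))
  invisible(x)
}

#' 95% confidence interval for a fitted activation energy
#' @param fit an `arrhenius_fit`.
#' @return kJ/mol, `c(lower, upper)` using the t distribution of the slope.
#' @export
arrhenius_ci <- function(fit) {
  tc <- stats::qt(0.975, df = fit$n - 2)
  fit$Ed + c(-1, 1) * tc * fit$stderr_Ed
}

#' Per-molecule effective diffusivity distribution
#'
#' For each molecule and sampling time `tau`, the effective diffusivity is
#' `D_eff = <|r(t0 + tau) - r(t0)|^2>_origins / (6 tau)` with origins taken
#' every `origin_stride` frames. As `tau` grows the ensemble mean tends to
#' the Einstein estimate; at short `tau` a mixture of mobilities shows up as
#' a multimodal distribution. Per-`tau` summaries include Sarle's
#' bimodality coefficient `(skew^2 + 1) / kurtosis` (values above ~0.555,
#' the uniform-distribution benchmark, suggest bimodality); this is a
#' descriptive indicator, not a test.
#'
#' @param traj a `trajectory_set`.
#' @param sampling_times ns, strictly positive, each within the span.
#' @param origin_stride frames between origins (default 10).
#' @return list with `per_molecule` (data.frame `mol_id`, `tau_ns`,
#'   `D_eff_m2s`) and `summary` (per-`tau` mean, median, sd, quartiles,
#'   bimodality coefficient).
#' @export
per_molecule_diffusivity <- function(traj, sampling_times,
                                     origin_stride = 10L) {
  if (any(sampling_times <= 0)) stop("sampling times must be > 0")
  times <- traj$times
  n <- length(times)
  dt <- times[2] - times[1]
  span <- times[n] - times[1]
  if (any(sampling_times > span)) stop("sampling time exceeds trajectory span")

  co <- .coord_matrices(traj)
  rows <- list()
  for (tau in sampling_times) {
    L <- max(1L, round(tau / dt))
    tau_eff <- L * dt
    origins <- seq(1L, n - L, by = origin_stride)
    sq <- 0
    for (ax in 1:3) {
      d <- co[[ax]][origins + L, , drop = FALSE] -
        co[[ax]][origins, , drop = FALSE]
      sq <- sq + d * d
    }
    D_eff <- colMeans(sq) / (6 * tau_eff) * .NM2_NS_TO_M2_S
    rows[[length(rows) + 1L]] <- data.frame(
      mol_id = seq_along(traj$positions), tau_ns = tau_eff, D_eff_m2s = D_eff)
  }
  per_mol <- do.call(rbind, rows)

  summarise_tau <- function(x) {
    m3 <- mean((x - mean(x))^3); m4 <- mean((x - mean(x))^4)
    s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
    skew <- m3 / s^3; kurt <- m4 / s^4
    c(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75)),
      bimodality_coef = (skew^2 + 1) / kurt)
  }
  sm <- do.call(rbind, lapply(split(per_mol$D_eff_m2s, per_mol$tau_ns),
                              summarise_tau))
  summary_df <- data.frame(tau_ns = as.numeric(rownames(sm)), sm,
                           row.names = NULL)
  list(per_molecule = per_mol, summary = summary_df)
}

#' Through-thickness water mass density map
#'
#' Wraps positions into the periodic box, projects out `axis`, and bins the
#' remaining two in-plane coordinates on a `grid_n` x `grid_n` grid,
#' mass-weighting each molecule and averaging over all frames in
#' `time_window`. Cell densities are in g/cm^3 and satisfy
#' `sum(density * cell_volume) = total species mass` to machine precision.
#'
#' @param traj a `trajectory_set`.
#' @param axis `"x"`, `"y"` or `"z"`: the through-thickness axis averaged out.
#' @param grid_n cells per in-plane axis (>= 1).
#' @param time_window ns, `c(min, max)` frames to average (default all).
#' @param molar_mass g/mol per molecule (default 18.015, water).
#' @return list of class `density_map`: `density` (g/cm^3 matrix), `axis`,
#'   `cell_volume_cm3`, `total_mass_g`, `n_frames`, `empty` flag.
#' @export
water_density_map <- function(traj, axis = "z", grid_n = 10L,
                              time_window = NULL,
                              molar_mass = .WATER_MOLAR_MASS) {
  axis_i <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (grid_n < 1) stop("grid_n must be >= 1")
  times <- traj$times
  if (is.null(time_window)) time_window <- range(times)
  frames <- which(times >= time_window[1] & times <= time_window[2])
  inplane <- setdiff(1:3, axis_i)
  Lx <- traj$box[inplane[1]]; Ly <- traj$box[inplane[2]]
  Lz <- traj$box[axis_i]

  counts <- matrix(0, grid_n, grid_n)
  empty <- length(traj$positions) == 0 || length(frames) == 0
  if (!empty) {
    for (P in traj$positions) {
      u <- P[frames, inplane[1]] %% Lx
      v <- P[frames, inplane[2]] %% Ly
      iu <- pmin(floor(u / Lx * grid_n) + 1L, grid_n)
      iv <- pmin(floor(v / Ly * grid_n) + 1L, grid_n)
      for (k in seq_along(iu)) counts[iu[k], iv[k]] <- counts[iu[k], iv[k]] + 1
    }
    counts <- counts / length(frames)  # average molecules per cell per frame
  }
  mol_mass_g <- molar_mass / .AVOGADRO
  cell_vol_cm3 <- (Lx / grid_n) * (Ly / grid_n) * Lz * 1e-21  # nm^3 -> cm^3
  out <- list(
    density = counts * mol_mass_g / cell_vol_cm3,
    axis = c("x", "y", "z")[axis_i],
    grid_n = grid_n,
    cell_volume_cm3 = cell_vol_cm3,
    total_mass_g = length(traj$positions) * mol_mass_g,
    n_frames = length(frames),
    empty = empty
  )
  class(out) <- "density_map"
  out
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map: %dx%d cells (axis %s averaged), mean %.3g g/cm^3 over %d frames%s\n",
    x$grid_n, x$grid_n, x$axis, mean(x$density), x$n_frames,
    if (x$empty) " [empty selection]" else ""))
  invisible(x)
}
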