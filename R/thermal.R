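# Glass-transition estimation from dilatometry curves (bilinear, hyperbolic,
# onset methods) and Williams-Landel-Ferry rate shifting.

#' Bilinear glass-transition estimate
#'
#' Fits least-squares lines to the low- and high-temperature linear regions
#' of a dilatometry curve and takes the glass transition as their crossover
#' temperature. Defaults use the 150-225 K glassy window and the 500-550 K
#' melt window. A warning is raised when the estimate falls within 100 K of
#' the inner edge of either fitting window, since the crossover is then
#' poorly separated from the fitted region.
#'
#' @param curve a [dilatometry_curve()].
#' @param low_range K, `c(min, max)` of the glassy fitting window.
#' @param high_range K, `c(min, max)` of the melt fitting window.
#' @param uncertainty `"delta"` (first-order propagation through the
#'   intersection formula from the two lines' coefficient covariances) or
#'   `"bootstrap"` (resampling points within each window, 200 resamples).
#' @param n_boot bootstrap resamples when `uncertainty = "bootstrap"`.
#' @param slope_tol minimum slope difference (g/cm^3/K) below which the lines
#'   are declared parallel (no-crossover error).
#' @return A [tg_estimate()] with `diagnostics$low_line`/`$high_line`
#'   (intercept, slope, covariance) and the windows used.
#' @export
bilinear_tg <- function(curve, low_range = c(150, 225),
                        high_range = c(500, 550),
                        uncertainty = c("delta", "bootstrap"), n_boot = 200,
                        slope_tol = 1e-12) {
  uncertainty <- match.arg(uncertainty)
  if (max(low_range) >= min(high_range)) stop("fitting windows must be disjoint")
  span <- range(curve$T_K)
  for (rg in list(low_range, high_range))
    if (rg[1] < span[1] - 1e-9 || rg[2] > span[2] + 1e-9)
      stop("fitting window outside the data span")

  fit_line <- function(rg) {
    sel <- curve$T_K >= rg[1] & curve$T_K <= rg[2]
    if (sum(sel) < 2) stop("fitting window contains fewer than 2 points")
    stats::lm(rho_gcm3 ~ T_K, data = curve[sel, , drop = FALSE])
  }
  f1 <- fit_line(low_range)
  f2 <- fit_line(high_range)
  c1 <- stats::coef(f1); c2 <- stats::coef(f2)
  dm <- c1[2] - c2[2]
  if (abs(dm) < slope_tol)
    stop("no-crossover: fitted lines are parallel within tolerance")
  Tg <- unname((c2[1] - c1[1]) / dm)

  unc <- if (uncertainty == "delta") {
    # gradient of Tg = (a2 - a1)/(m1 - m2) w.r.t. (a, m) of each line
    g1 <- c(-1 / dm, -Tg / dm)
    g2 <- c(1 / dm, Tg / dm)
    v <- as.numeric(t(g1) %*% .lm_vcov(f1) %*% g1 +
                    t(g2) %*% .lm_vcov(f2) %*% g2)
    sqrt(max(v, 0))
  } else {
    boot_one <- function(fit, rg) {
      sel <- which(curve$T_K >= rg[1] & curve$T_K <= rg[2])
      idx <- sample(sel, length(sel), replace = TRUE)
      stats::coef(stats::lm(rho_gcm3 ~ T_K, data = curve[idx, , drop = FALSE]))
    }
    draws <- replicate(n_boot, {
      b1 <- boot_one(f1, low_range); b2 <- boot_one(f2, high_range)
      if (abs(b1[2] - b2[2]) < slope_tol) NA_real_
      else (b2[1] - b1[1]) / (b1[2] - b2[2])
    })
    stats::sd(draws, na.rm = TRUE)
  }

  if (is.finite(Tg) &&
      (Tg < low_range[2] + 100 || Tg > high_range[1] - 100))
    warning("bilinear Tg falls within 100 K of a fitting-window edge")

  tg_estimate("bilinear", Tg, unc, diagnostics = list(
    low_line = list(coef = unname(c1), vcov = .lm_vcov(f1), range = low_range),
    high_line = list(coef = unname(c2), vcov = .lm_vcov(f2), range = high_range),
    uncertainty_method = uncertainty
  ))
}

#' Fit the hyperbolic density model to a dilatometry curve
#'
#' Nonlinear least squares of
#' `rho(T) = rho0 - a (T - T0) - b H0(T, T0, c)` with
#' `H0 = (T - T0)/2 - sqrt((T - T0)^2/4 + exp(c))`. The model interpolates
#' between a melt branch of slope `-a` (high T) and a glassy branch of slope
#' `-(a + b)` (low T) with a crossover of scale `exp(c/2)` K centred at `T0`.
#' Fitting is multi-start over a `T0` grid (and a small `c` grid) with
#' Levenberg-Marquardt refinement; the converged start with the smallest
#' residual norm wins.
#'
#' @param curve a [dilatometry_curve()] with at least 6 points.
#' @param weight_scheme `"uniform"` (default) or `"lowT_taper"`:
#'   inverse-variance weights (from `rho_sd`) multiplied by a linear taper
#'   from 2 at the coldest point to 1 at the hottest, assigning greater
#'   statistical weight to the glassy end.
#' @param T0_grid K, starting values for `T0` (default: 5 quantiles of the
#'   interior span).
#' @param c_grid starting values for `c` (default: widths of 10/30/60 K).
#' @param b_tol |b| below which the fit is flagged degenerate (pure line, no
#'   resolvable transition).
#' @return list of class `hyperbolic_fit` with `rho0`, `a`, `b`, `T0`, `c`,
#'   `residual_norm`, `degenerate`, `T_span`, and the `nls` object in `$fit`.
#' @export
fit_hyperbolic <- function(curve, weight_scheme = c("uniform", "lowT_taper"),
                           T0_grid = NULL, c_grid = NULL, b_tol = 1e-7) {
  weight_scheme <- match.arg(weight_scheme)
  if (nrow(curve) < 6) stop("need at least 6 points spanning both regimes")
  d <- data.frame(T = curve$T_K, rho = curve$rho_gcm3)
  d <- d[order(d$T), ]
  span <- range(d$T)

  if (is.null(T0_grid))
    T0_grid <- stats::quantile(d$T, c(0.25, 0.4, 0.5, 0.6, 0.75), names = FALSE)
  if (is.null(c_grid)) c_grid <- 2 * log(c(10, 30, 60))

  w <- rep(1, nrow(d))
  if (weight_scheme == "lowT_taper") {
    iv <- if (all(is.finite(curve$rho_sd)) && all(curve$rho_sd > 0))
      1 / curve$rho_sd[order(curve$T_K)]^2 else rep(1, nrow(d))
    taper <- seq(2, 1, length.out = nrow(d))  # coldest -> hottest
    w <- iv * taper
  }

  # crude slope estimates from the end thirds for starting values
  n3 <- max(2L, floor(nrow(d) / 3))
  lo <- stats::coef(stats::lm(rho ~ T, data = d[seq_len(n3), ]))
  hi <- stats::coef(stats::lm(rho ~ T, data = d[seq(nrow(d) - n3 + 1, nrow(d)), ]))
  a0 <- -unname(hi[2])
  b0 <- unname(hi[2] - lo[2])
  if (abs(b0) < 1e-12) b0 <- -1e-6

  best <- NULL
  for (T00 in T0_grid) for (c0 in c_grid) {
    start <- list(rho0 = unname(hi[1] + hi[2] * T00), a = a0, b = b0,
                  T0 = T00, c = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rho ~ hyperbolic_density(T, rho0, a, b, T0, c),
        data = d, start = start, weights = w,
        lower = c(rho0 = 0, a = -Inf, b = -Inf, T0 = span[1], c = -Inf),
        upper = c(rho0 = Inf, a = Inf, b = Inf, T0 = span[2], c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  # pure-line data leaves (b, c) unidentifiable and every nonlinear start can
  # fail; fall back to the straight-line limit and flag the fit degenerate
  line <- stats::lm(rho ~ T, data = d, weights = w)
  line_rn <- sqrt(sum(stats::resid(line)^2))
  if (is.null(best) || line_rn <= best$rn) {
    if (is.null(best) && line_rn > 1e-3 * stats::sd(d$rho) * sqrt(nrow(d)))
      stop("hyperbolic fit failed to converge from any start (",
           length(T0_grid) * length(c_grid), " starts tried)")
    T0_mid <- mean(span)
    cl <- stats::coef(line)
    out <- list(rho0 = unname(cl[1] + cl[2] * T0_mid), a = -unname(cl[2]),
                b = 0, T0 = T0_mid, c = 0, residual_norm = line_rn,
                degenerate = TRUE, T_span = span, fit = line,
                weight_scheme = weight_scheme)
    class(out) <- "hyperbolic_fit"
    return(out)
  }

  p <- as.list(stats::coef(best$fit))
  out <- list(rho0 = p$rho0, a = p$a, b = p$b, T0 = p$T0, c = p$c,
              residual_norm = best$rn, degenerate = abs(p$b) < b_tol,
              T_span = span, fit = best$fit,
              weight_scheme = weight_scheme)
  class(out) <- "hyperbolic_fit"
  out
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf(
    "hyperbolic_fit: rho0 = %.4f, a = %.3g, b = %.3g, T0 = %.1f K, c = %.2f (width %.1f K), |resid| = %.2g%s\n",
    x$rho0, x$a, x$b, x$T0, x$c, exp(x$c / 2), x$residual_norm,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Evaluate a fitted hyperbolic density model
#' @param fit a `hyperbolic_fit`.
#' @param T K, temperatures.
#' @return g/cm^3.
#' @export
predict_hyperbolic <- function(fit, T) {
  hyperbolic_density(T, fit$rho0, fit$a, fit$b, fit$T0, fit$c)
}

#' Hyperbolic-method glass-transition estimate
#'
#' Scans the second derivative of the fitted density model over the data span
#' and returns the temperature at the extremum of largest magnitude. For the
#' hyperbolic model family the second derivative is
#' `rho'' = -b exp(c) / (4 ((T-T0)^2/4 + exp(c))^{3/2})`, which is extremal
#' exactly at `T = T0`; the numeric scan is the contract and the closed form
#' is carried in the diagnostics.
#'
#' @param fit a non-degenerate `hyperbolic_fit`.
#' @param T_span K, `c(min, max)` scan range (default the fitted data span).
#' @param resolution K, scan grid step (default 0.01).
#' @return A [tg_estimate()] with method `"hyperbolic"`.
#' @export
hyperbolic_tg <- function(fit, T_span = fit$T_span, resolution = 0.01) {
  if (fit$degenerate)
    stop("undefined Tg: hyperbolic fit is degenerate (|b| below tolerance)")
  Tg_scan <- seq(T_span[1], T_span[2], by = resolution)
  rho <- predict_hyperbolic(fit, Tg_scan)
  d2 <- diff(diff(rho)) / resolution^2
  Tmid <- Tg_scan[-c(1, length(Tg_scan))]
  Tg <- Tmid[which.max(abs(d2))]
  tg_estimate("hyperbolic", Tg, diagnostics = list(
    T0_closed_form = fit$T0, resolution = resolution,
    d2_extremum = d2[which.max(abs(d2))]
  ))
}

#' Onset-method glass-transition estimate
#'
#' Scans upward from the low-temperature end of the span and returns the
#' first temperature at which the relative deviation between the hyperbolic
#' model and the glassy (low-temperature) line of the bilinear fit exceeds
#' `threshold_pct` percent. The scan runs on an interpolated model curve at
#' 0.1 K resolution, not on the raw data points. Marks where the change in
#' thermal expansivity is initiated rather than completed, so for broad
#' transitions it sits well below the bilinear estimate.
#'
#' @param fit a `hyperbolic_fit`.
#' @param lower_line list with `coef = c(intercept, slope)`, normally
#'   `diagnostics$low_line` of a [bilinear_tg()] estimate.
#' @param threshold_pct percent deviation defining the onset (default 2).
#' @param T_span K, scan range (default the fitted data span).
#' @param resolution K, scan step (default 0.1).
#' @return A [tg_estimate()] with method `"onset"`.
#' @export
onset_tg <- function(fit, lower_line, threshold_pct = 2,
                     T_span = fit$T_span, resolution = 0.1) {
  if (threshold_pct <= 0) stop("threshold_pct must be > 0")
  cf <- lower_line$coef
  Tg_scan <- seq(T_span[1], T_span[2], by = resolution)
  rho_hyp <- predict_hyperbolic(fit, Tg_scan)
  rho_line <- cf[1] + cf[2] * Tg_scan
  dev <- abs(rho_hyp - rho_line) / rho_line
  hit <- which(dev > threshold_pct / 100)
  if (!length(hit))
    stop("no-onset: deviation never exceeds ", threshold_pct,
         "% within the scanned span")
  tg_estimate("onset", Tg_scan[hit[1]], diagnostics = list(
    threshold_pct = threshold_pct, resolution = resolution,
    lower_line = cf
  ))
}

#' Estimate Tg by all three methods
#'
#' Convenience wrapper running [bilinear_tg()], [fit_hyperbolic()] +
#' [hyperbolic_tg()], and [onset_tg()] on one curve.
#'
#' @param curve a [dilatometry_curve()].
#' @param methods subset of `c("bilinear", "hyperbolic", "onset")`.
#' @param low_range,high_range bilinear fitting windows.
#' @param threshold_pct onset threshold.
#' @param weight_scheme passed to [fit_hyperbolic()].
#' @return Named list of [tg_estimate()] objects.
#' @export
estimate_tg <- function(curve, methods = c("bilinear", "hyperbolic", "onset"),
                        low_range = c(150, 225), high_range = c(500, 550),
                        threshold_pct = 2,
                        weight_scheme = "uniform") {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  bl <- NULL
  if (any(c("bilinear", "onset") %in% methods))
    bl <- bilinear_tg(curve, low_range, high_range)
  if ("bilinear" %in% methods) out$bilinear <- bl
  if (any(c("hyperbolic", "onset") %in% methods)) {
    hf <- fit_hyperbolic(curve, weight_scheme = weight_scheme)
    if ("hyperbolic" %in% methods) out$hyperbolic <- hyperbolic_tg(hf)
    if ("onset" %in% methods)
      out$onset <- onset_tg(hf, bl$diagnostics$low_line, threshold_pct)
  }
  out
}

#' Williams-Landel-Ferry log shift factor
#'
#' `log10(a_T) = C1 (T - Tg) / (C2 + (T - Tg))`, the empirical
#' time-temperature superposition relation linking rate scaling to the
#' temperature offset from the glass transition.
#'
#' @param T K, temperature.
#' @param Tg K, reference glass-transition temperature.
#' @param C1 dimensionless WLF constant.
#' @param C2 K, WLF constant (> 0).
#' @return log10 shift factor.
#' @export
wlf_log_shift <- function(T, Tg, C1, C2) {
  if (C2 <= 0) stop("C2 must be > 0")
  dT <- T - Tg
  if (any(abs(C2 + dT) < 1e-12)) stop("WLF pole: T - Tg = -C2")
  C1 * dT / (C2 + dT)
}

#' Invert the WLF relation for a temperature offset
#'
#' Closed-form inverse: given a target log10 shift `L` (for rate shifting,
#' `L = log10(rate_target / rate_reference)`), returns
#' `dT = C2 L / (C1 - L)`, the temperature offset `T - Tg` producing that
#' shift. Shifting to a slower rate (`L < 0` with `C1 > 0`) yields a negative
#' offset, i.e. a lower apparent transition temperature.
#'
#' @param log_shift target log10 shift factor; must differ from `C1`.
#' @param C1,C2 WLF constants (`C2 > 0` K). These are system-specific and
#'   must be supplied by the user (e.g. calibrated from constant-rate
#'   cooling series).
#' @return K, temperature offset `T - Tg`.
#' @export
invert_wlf <- function(log_shift, C1, C2) {
  if (C2 <= 0) stop("C2 must be > 0")
  if (abs(log_shift - C1) < 1e-12) stop("log_shift equals C1: no finite offset")
  C2 * log_shift / (C1 - log_shift)
}

#' Effective cooling rate of a stepwise protocol
#'
#' @param dT_step K removed per step (default 25).
#' @param dt_step ns held per step (default 10).
#' @return K/ns.
#' @export
effective_cooling_rate <- function(dT_step = 25, dt_step = 10) {
  if (dt_step <= 0) stop("dt_step must be > 0")
  dT_step / dt_step
}
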