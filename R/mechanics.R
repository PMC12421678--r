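# Elastic constants from uniaxial deformation records: stress smoothing,
# Young's modulus over the standard strain interval, Poisson's ratio from
# transverse box contraction, bulk modulus, and triplicate aggregation.

#' Smooth the stress series of a deformation record
#'
#' Centered moving average over a window of given strain width; pressure
#' tensors fluctuate strongly and are smoothed before any modulus fit.
#' Endpoints use shrinking (partial) windows, so the operation is identity
#' on constant series and preserves series length.
#'
#' @param record a [deformation_record()].
#' @param window strain width of the smoothing window (default 0.01, i.e.
#'   1% strain).
#' @return The record with smoothed `stress`.
#' @export
smooth_stress <- function(record, window = 0.01) {
  if (window <= 0) stop("window must be > 0")
  span <- max(record$strain) - min(record$strain)
  if (window > span) stop("smoothing window wider than the strain span")
  step <- stats::median(diff(record$strain))
  k <- max(1L, round(window / step))
  if (k %% 2 == 0) k <- k + 1L  # centered window needs odd width
  record$stress <- as.numeric(
    zoo::rollapply(zoo::zoo(record$stress), width = k, FUN = mean,
                   align = "center", partial = TRUE))
  record
}

#' Young's modulus from a deformation record
#'
#' Hooke's law `E = sigma / epsilon`, evaluated by default as the
#' least-squares slope of stress versus strain restricted to the
#' 0.3-9.9% strain interval (regression is robust to pressure-tensor
#' fluctuations; a two-point secant over the same interval is available as
#' `mode = "secant"`).
#'
#' @param record a [deformation_record()].
#' @param interval strain fractions `c(min, max)` (default `c(0.003, 0.099)`).
#' @param mode `"regression"` (default) or `"secant"`.
#' @return list with `E` (GPa), `stderr` (GPa; NA for secant), `interval`,
#'   `mode`, `n`.
#' @export
youngs_modulus <- function(record, interval = c(0.003, 0.099),
                           mode = c("regression", "secant")) {
  mode <- match.arg(mode)
  if (interval[1] < min(record$strain) - 1e-12 ||
      interval[2] > max(record$strain) + 1e-12)
    stop("interval outside the recorded strain range")
  sel <- record$strain >= interval[1] & record$strain <= interval[2]
  if (sum(sel) < 3) stop("fewer than 3 samples in the strain interval")
  eps <- record$strain[sel]; sig <- record$stress[sel]
  if (mode == "regression") {
    fit <- stats::lm(sig ~ eps)
    list(E = unname(stats::coef(fit)[2]),
         stderr = sqrt(.lm_vcov(fit)[2, 2]),
         interval = interval, mode = mode, n = sum(sel))
  } else {
    i1 <- which.min(eps); i2 <- which.max(eps)
    list(E = (sig[i2] - sig[i1]) / (eps[i2] - eps[i1]),
         stderr = NA_real_, interval = interval, mode = mode, n = 2L)
  }
}

#' Poisson's ratio from transverse box contraction
#'
#' `nu = (transverse contraction) / (axial elongation)`, evaluated pointwise
#' as `((L0 - L_t(eps)) / L0) / eps` over the strain interval, averaged over
#' the interval points and over both transverse axes. Strains below 2% are
#' excluded by default because the ratio fluctuates strongly there.
#'
#' @param record a [deformation_record()].
#' @param interval strain fractions `c(min, max)` (default `c(0.02, 0.10)`).
#' @return list with `nu`, `stderr` (standard error of the pointwise mean),
#'   `interval`, `n`.
#' @export
poisson_ratio <- function(record, interval = c(0.02, 0.10)) {
  if (is.null(record$box_transverse)) stop("transverse series absent")
  sel <- record$strain >= interval[1] & record$strain <= interval[2] &
    record$strain > 0
  if (!sum(sel)) stop("no samples with nonzero axial elongation in interval")
  eps <- record$strain[sel]
  L0 <- record$box_edge0
  ratios <- sapply(seq_len(ncol(record$box_transverse)), function(j) {
    contraction <- (L0 - record$box_transverse[sel, j]) / L0
    contraction / eps
  })
  vals <- as.numeric(ratios)
  list(nu = mean(vals),
       stderr = stats::sd(vals) / sqrt(length(vals)),
       interval = interval, n = length(vals))
}

#' Bulk modulus from E and nu (Lame relation)
#'
#' `K = -E / (6 (nu - 1/2))`, algebraically `E / (3 (1 - 2 nu))`.
#'
#' @param E GPa, Young's modulus.
#' @param nu Poisson's ratio; must be below `0.5 - 1e-6` (the
#'   incompressible limit).
#' @return GPa.
#' @export
bulk_modulus <- function(E, nu) {
  if (nu >= 0.5 - 1e-6)
    stop("incompressible limit: nu too close to 0.5")
  -E / (6 * (nu - 0.5))
}

#' Aggregate elastic constants over orthogonal pulling directions
#'
#' Deformation runs are performed along x, y and z; per-quantity mean and
#' sample standard deviation are taken across these triplicates. Each axis
#' result is a list with elements `E` and `nu` (e.g. assembled from
#' [youngs_modulus()] and [poisson_ratio()]); the per-axis bulk modulus is
#' recomputed via [bulk_modulus()] before aggregation.
#'
#' @param axis_results list of 1-3 per-axis lists with `E` (GPa) and `nu`.
#' @param rate m/s metadata.
#' @return list of class `elastic_constants`: `E`, `E_sd`, `nu`, `nu_sd`,
#'   `K`, `K_sd` (GPa), `n_directions`, `rate`, `nu_flagged` (TRUE when the
#'   mean nu falls outside [0, 0.5)).
#' @export
aggregate_triplicate <- function(axis_results, rate = NA_real_) {
  n <- length(axis_results)
  if (n < 1) stop("no axis results supplied")
  E <- vapply(axis_results, function(r) r$E, numeric(1))
  nu <- vapply(axis_results, function(r) r$nu, numeric(1))
  K_axis <- mapply(bulk_modulus, E, nu)
  sdev <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  # reported K is recomputed from the aggregated E and nu so the Lame
  # identity K * 3 * (1 - 2 nu) = E holds exactly for the reported triple;
  # the spread comes from the per-axis K values
  out <- list(
    E = mean(E), E_sd = sdev(E),
    nu = mean(nu), nu_sd = sdev(nu),
    K = bulk_modulus(mean(E), mean(nu)), K_sd = sdev(K_axis),
    n_directions = n, rate = rate,
    nu_flagged = mean(nu) < 0 || mean(nu) >= 0.5
  )
  class(out) <- "elastic_constants"
  out
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf(
    "elastic_constants (n = %d directions): E = %.2f +/- %.2f GPa, nu = %.3f +/- %.3f, K = %.2f +/- %.2f GPa\n",
    x$n_directions, x$E, x$E_sd, x$nu, x$nu_sd, x$K, x$K_sd))
  invisible(x)
}

#' Engineering strain rate of a constant-velocity deformation
#'
#' A pulling rate expressed in nm/ns applied to a box of edge `box_nm`
#' corresponds to a strain rate `rate / box` per ns, i.e.
#' `rate / box * 1e9` per second.
#'
#' @param rate_nm_per_ns deformation rate in nm/ns (1 m/s = 1 nm/ns).
#' @param box_nm nm, undeformed box edge.
#' @return 1/s.
#' @export
strain_rate_per_s <- function(rate_nm_per_ns, box_nm) {
  if (box_nm <= 0) stop("box edge must be > 0")
  rate_nm_per_ns / box_nm * 1e9
}
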