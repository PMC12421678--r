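# Constructors for the tabular containers shared across modules.

#' Dilatometry curve container
#'
#' Replica-averaged density versus temperature samples from a stepwise
#' cooling run.
#'
#' @param T K, strictly monotone temperature grid.
#' @param rho g/cm^3, replica-averaged densities (> 0).
#' @param rho_sd per-point spread across replicas (optional).
#' @param n_replicas number of replicas averaged.
#' @param moisture_wt_pct moisture content metadata.
#' @return data.frame of class `dilatometry_curve` with columns `T_K`,
#'   `rho_gcm3`, `rho_sd`; `n_replicas` and `moisture_wt_pct` as attributes.
#' @export
dilatometry_curve <- function(T, rho, rho_sd = rep(NA_real_, length(T)),
                              n_replicas = 1L, moisture_wt_pct = NA_real_) {
  if (length(T) != length(rho)) stop("T and rho lengths differ")
  d <- diff(T)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("T must be strictly monotone")
  if (any(rho <= 0)) stop("densities must be positive")
  out <- data.frame(T_K = T, rho_gcm3 = rho, rho_sd = rho_sd)
  attr(out, "n_replicas") <- n_replicas
  attr(out, "moisture_wt_pct") <- moisture_wt_pct
  class(out) <- c("dilatometry_curve", "data.frame")
  out
}

#' Uniaxial deformation record container
#'
#' Strain, stress and box-dimension series for one pulling direction.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param strain engineering strain series starting at 0, reaching >= 0.20.
#' @param stress GPa series (tensile positive).
#' @param box_axial nm series of the pulled edge.
#' @param box_transverse two-column nm matrix of the transverse edges.
#' @param box_edge0 nm, undeformed edge length.
#' @param rate m/s deformation rate.
#' @param temperature,moisture_wt_pct metadata.
#' @return list of class `deformation_record`.
#' @export
deformation_record <- function(axis, strain, stress, box_axial,
                               box_transverse, box_edge0, rate = NA_real_,
                               temperature = NA_real_,
                               moisture_wt_pct = NA_real_) {
  axis <- match.arg(axis, c("x", "y", "z"))
  n <- length(strain)
  if (length(stress) != n || length(box_axial) != n ||
      nrow(box_transverse) != n)
    stop("series lengths differ")
  if (abs(strain[1]) > 1e-12) stop("strain must start at 0")
  if (max(strain) < 0.20) stop("strain must reach at least 0.20")
  out <- list(axis = axis, strain = strain, stress = stress,
              box_axial = box_axial, box_transverse = box_transverse,
              box_edge0 = box_edge0, rate = rate, temperature = temperature,
              moisture_wt_pct = moisture_wt_pct)
  class(out) <- "deformation_record"
  out
}

#' @export
print.deformation_record <- function(x, ...) {
  cat(sprintf(
    "deformation_record: axis %s, %d samples, strain 0-%.1f%%, rate %s m/s\n",
    x$axis, length(x$strain), 100 * max(x$strain), format(x$rate)))
  invisible(x)
}

#' Glass-transition estimate container
#'
#' @param method `"bilinear"`, `"hyperbolic"` or `"onset"`.
#' @param Tg K.
#' @param uncertainty K, half-width (>= 0).
#' @param diagnostics list of fit metadata (line coefficients, threshold, ...).
#' @return list of class `tg_estimate`.
#' @export
tg_estimate <- function(method, Tg, uncertainty = NA_real_,
                        diagnostics = list()) {
  method <- match.arg(method, c("bilinear", "hyperbolic", "onset"))
  if (!is.na(uncertainty) && uncertainty < 0) stop("uncertainty must be >= 0")
  out <- list(method = method, Tg = Tg, uncertainty = uncertainty,
              diagnostics = diagnostics)
  class(out) <- "tg_estimate"
  out
}

#' @export
print.tg_estimate <- function(x, ...) {
  cat(sprintf("Tg (%s method): %.1f K", x$method, x$Tg))
  if (!is.na(x$uncertainty)) cat(sprintf(" +/- %.1f K", x$uncertainty))
  cat("\n")
  invisible(x)
}
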