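# Experimental paper-sheet computations: tensile index, percentage strength
# changes, and the Arrhenius-style activation energy of wet tensile index
# versus pressing temperature.

#' Tensile index of a paper sheet
#'
#' Tensile strength per unit grammage: `index (N m/g) =
#' strength (N/m) / grammage (g/m^2)` — the specific-strength measure used
#' for sheets.
#'
#' @param strength N/m, tensile strength (>= 0).
#' @param grammage g/m^2, areal mass density (> 0).
#' @return N m/g.
#' @export
tensile_index <- function(strength, grammage) {
  if (any(grammage <= 0)) stop("grammage must be > 0")
  if (any(strength < 0)) stop("strength must be >= 0")
  strength / grammage
}

#' Percentage change relative to a reference value
#'
#' `100 (value - reference) / reference`. The reference must be positive —
#' e.g. an unmeasurable (zero) wet reference admits no percentage change.
#'
#' @param reference reference value (> 0).
#' @param value new value.
#' @return percent change (positive for an increase).
#' @export
percent_increase <- function(reference, value) {
  if (any(reference <= 0)) stop("reference must be > 0")
  100 * (value - reference) / reference
}

#' Activation energy from wet tensile index versus pressing temperature
#'
#' Least-squares fit of `ln(index)` against `1/T` (T in kelvin,
#' `T_K = T_C + 273.15`); the apparent activation energy is
#' `Ea = -R * slope` in kJ/mol. Records with non-positive index are below
#' the measurable threshold and are excluded with a warning rather than
#' treated as censored values.
#'
#' @param records data.frame with columns `T_C` (pressing temperature,
#'   Celsius) and `index` (wet tensile index, N m/g).
#' @param condition `"dry_pressed"` or `"moist_pressed"` metadata.
#' @return list of class `strength_arrhenius_fit`: `Ea` (kJ/mol), `stderr`,
#'   `T_range_C`, `condition`, `n`.
#' @export
strength_activation_energy <- function(records,
                                       condition = c("dry_pressed",
                                                     "moist_pressed")) {
  condition <- match.arg(condition)
  usable <- is.finite(records$index) & records$index > 0
  if (any(!usable))
    warning(sum(!usable),
            " record(s) with non-positive index excluded (unmeasurable)")
  records <- records[usable, , drop = FALSE]
  if (nrow(records) < 2) stop("fewer than 2 usable records")
  T_K <- records$T_C + 273.15
  fit <- stats::lm(log(records$index) ~ I(1 / T_K))
  slope <- unname(stats::coef(fit)[2])
  out <- list(
    Ea = -8.314462618e-3 * slope,
    stderr = if (nrow(records) > 2)
      8.314462618e-3 * sqrt(.lm_vcov(fit)[2, 2]) else NA_real_,
    T_range_C = range(records$T_C),
    condition = condition,
    n = nrow(records)
  )
  class(out) <- "strength_arrhenius_fit"
  out
}

#' @export
print.strength_arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "strength activation energy (%s): Ea = %.1f kJ/mol (SE %.2g), %d temperatures (%g-%g C)\n",
    x$condition, x$Ea, x$stderr, x$n, x$T_range_C[1], x$T_range_C[2]))
  invisible(x)
}

#' Read a sheet tensile record table
#'
#' Reads the sheet CSV layout (`T_C, mc_pct, time_s, pressure_MPa, state,
#' strength_Npm, grammage_gm2`), skipping `#` comment lines, and derives
#' the `tensile_index` column.
#'
#' @param path CSV file; the package ships a reference fixture at
#'   `system.file("extdata", "sheet_tensile_reference.csv",
#'   package = "ligninpress")`.
#' @return data.frame with the input columns plus `tensile_index` (N m/g).
#' @export
read_sheet_records <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("T_C", "state", "strength_Npm", "grammage_gm2")
  if (!all(needed %in% names(d)))
    stop("missing columns: ", paste(setdiff(needed, names(d)), collapse = ", "))
  d$tensile_index <- d$strength_Npm / d$grammage_gm2
  d
}

#' Juxtapose experimental and simulated activation energies
#'
#' Side-by-side report of a sheet-strength activation energy and a diffusion
#' activation energy; no statistical comparison is performed, the two fits
#' are simply tabulated on the common kJ/mol scale.
#'
#' @param strength_fit a `strength_arrhenius_fit`.
#' @param diffusion_fit an `arrhenius_fit` (see [arrhenius_fit()]).
#' @return data.frame with one row per fit: `source`, `Ea_kJmol`, `stderr`,
#'   `n`.
#' @export
compare_activation_energies <- function(strength_fit, diffusion_fit) {
  data.frame(
    source = c(paste0("sheet_", strength_fit$condition),
               paste0("diffusion_", diffusion_fit$branch)),
    Ea_kJmol = c(strength_fit$Ea, diffusion_fit$Ed),
    stderr = c(strength_fit$stderr, diffusion_fit$stderr_Ed),
    n = c(strength_fit$n, diffusion_fit$n)
  )
}
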