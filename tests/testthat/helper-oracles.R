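# Independent oracles used by the unit tests. These deliberately avoid the
# implementation paths they check.

# analytic intersection of two lines rho = a + m * T
line_intersection_T <- function(a1, m1, a2, m2) (a2 - a1) / (m1 - m2)

# brute-force atom tally over a chain's unit formulas (element-by-element)
atom_tally_mass <- function(chain) {
  masses <- c(C = 12.011, H = 1.008, O = 15.999)
  tot <- c(C = 0, H = 0, O = 0)
  for (i in seq_len(nrow(chain$units))) {
    f <- monomer_formula(chain$units$lignol_class[i],
                         chain$units$terminal_mods[[i]])
    tot <- tot + f
  }
  sum(tot * masses) - nrow(chain$linkages) * chain$condensation_loss
}

# direct evaluation of the two asymptotic lines of the dilatometry model
two_line_density <- function(T, rho_ref, slope_glass, slope_melt, Tg) {
  ifelse(T < Tg,
         rho_ref + slope_glass * (T - Tg),
         rho_ref + slope_melt * (T - Tg))
}

# loop-based onset scan at fixed resolution (independent of onset_tg's
# vectorised scan)
onset_grid_oracle <- function(fit, line_coef, threshold_pct, T_span,
                              resolution = 0.1) {
  T <- T_span[1]
  while (T <= T_span[2]) {
    rho_h <- predict_hyperbolic(fit, T)
    rho_l <- line_coef[1] + line_coef[2] * T
    if (abs(rho_h - rho_l) / rho_l > threshold_pct / 100) return(T)
    T <- T + resolution
  }
  NA_real_
}

# closed-form two-point activation energy, kJ/mol
two_point_Ed <- function(T1, D1, T2, D2) {
  8.314462618e-3 * log(D2 / D1) / (1 / T1 - 1 / T2)
}

# build a trajectory_set by hand from a list of position matrices
manual_traj <- function(positions, dt = 0.1, box = c(21, 21, 21),
                        species = "water") {
  out <- list(times = seq(0, nrow(positions[[1]]) - 1) * dt,
              positions = positions, species = species, box = box,
              temperature = NA_real_, moisture_wt_pct = NA_real_)
  class(out) <- "trajectory_set"
  out
}

# manually assembled msd_series
manual_msd <- function(lag, msd) {
  out <- data.frame(lag_ns = lag, msd_nm2 = msd,
                    n_pairs = rep(1L, length(lag)))
  class(out) <- c("msd_series", "data.frame")
  out
}

# exact linear-elastic record with no noise
exact_record <- function(E = 2.2, nu = 0.35, box = 21, max_strain = 0.25,
                         step = 1e-3, axis = "x") {
  strain <- seq(0, max_strain, by = step)
  deformation_record(
    axis = axis, strain = strain, stress = E * strain,
    box_axial = box * (1 + strain),
    box_transverse = cbind(box * (1 - nu * strain), box * (1 - nu * strain)),
    box_edge0 = box
  )
}
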