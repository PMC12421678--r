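# Topology of the 26-unit softwood (spruce milled-wood) lignin chain and
# moisture-dependent system compositions.

# IUPAC 2021 standard atomic weights, g/mol
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999)

#' Nominal elemental formulas for in-chain monolignol residues
#'
#' The base residue is a guaiacyl (coniferyl-derived) C9 phenylpropanoid unit
#' taken with formula C10H12O3 (the C9 skeleton plus the aryl methoxyl carbon),
#' treated as an in-chain residue mass: interunit condensation losses are
#' accounted for separately (default zero, see [chain_molar_mass()]).
#' Terminal-group modifications are expressed as elemental deltas relative to
#' the base residue:
#' \describe{
#'   \item{gamma-carboxyl}{gamma CH2OH to COOH: +1 O, -2 H}
#'   \item{gamma-aldehyde}{gamma CH2OH to CHO: -2 H}
#'   \item{alpha-ketone}{alpha CHOH to C=O: -2 H}
#'   \item{beta-ketone}{carbonyl at the beta carbon: +1 O, -2 H}
#'   \item{alpha-aldehyde-trunc}{side chain truncated to an alpha aldehyde
#'     (beta and gamma carbons removed): -2 C, -4 H}
#' }
#' These are nominal bookkeeping formulas chosen once for mass accounting;
#' they are configurable through the `monomer_mass_table` field of a chain.
#'
#' @param lignol_class character, currently `"guaiacyl"`.
#' @param terminal_mods character vector of modification labels (possibly empty).
#' @return Named integer vector with elements `C`, `H`, `O`.
#' @export
monomer_formula <- function(lignol_class = "guaiacyl", terminal_mods = character()) {
  if (!identical(lignol_class, "guaiacyl"))
    stop("unknown lignol class: ", lignol_class)
  f <- c(C = 10L, H = 12L, O = 3L)
  deltas <- list(
    "gamma-carboxyl"       = c(C = 0L, H = -2L, O = 1L),
    "gamma-aldehyde"       = c(C = 0L, H = -2L, O = 0L),
    "alpha-ketone"         = c(C = 0L, H = -2L, O = 0L),
    "beta-ketone"          = c(C = 0L, H = -2L, O = 1L),
    "alpha-aldehyde-trunc" = c(C = -2L, H = -4L, O = 0L)
  )
  for (m in terminal_mods) {
    if (!m %in% names(deltas)) stop("unknown terminal modification: ", m)
    f <- f + deltas[[m]]
  }
  f
}

#' Molar mass of a residue formula
#' @param formula named vector of atom counts (`C`, `H`, `O`).
#' @return g/mol.
#' @export
formula_mass <- function(formula) {
  sum(.atomic_mass[names(formula)] * formula)
}

#' Build the reference 26-unit softwood lignin chain
#'
#' Constructs the branched 26-repeat-unit guaiacyl chain used as the uniform
#' molecular-weight representation of spruce milled-wood lignin. Units are
#' joined by a beta-O-4 backbone (units i to i+1); two aliphatic alpha-O-gamma
#' ether linkages implicated in branching connect the annotated repeat units.
#' Terminal-group modifications sit on fixed units: gamma-carboxyl on unit 1,
#' gamma-aldehyde on unit 7, a truncated alpha-aldehyde on unit 11,
#' alpha-ketones on units 21 and 26, and a beta-ketone on unit 22.
#'
#' @param ambiguous_range integer pair giving the second alpha-O-gamma
#'   linkage; the structural model's range annotation is ambiguous and is
#'   read as `c(12, 13)` by default.
#' @param condensation_loss g/mol lost per interunit linkage (default 0:
#'   monomer masses are treated as in-chain residue masses).
#' @return A `lignin_chain` object: list with `units` (data.frame of
#'   `index`, `lignol_class`, `terminal_mods`), `linkages` (data.frame of
#'   `kind`, `from_unit`, `to_unit`), `monomer_mass_table`, and
#'   `condensation_loss`.
#' @export
build_reference_chain <- function(ambiguous_range = c(12L, 13L),
                                  condensation_loss = 0) {
  stopifnot(length(ambiguous_range) == 2L, all(ambiguous_range %in% 1:26))
  mods <- list(
    `1`  = "gamma-carboxyl",
    `7`  = "gamma-aldehyde",
    `11` = "alpha-aldehyde-trunc",
    `21` = "alpha-ketone",
    `22` = "beta-ketone",
    `26` = "alpha-ketone"
  )
  units <- data.frame(
    index = 1:26,
    lignol_class = "guaiacyl",
    stringsAsFactors = FALSE
  )
  units$terminal_mods <- lapply(as.character(1:26), function(i) {
    if (i %in% names(mods)) mods[[i]] else character()
  })

  backbone <- data.frame(
    kind = "beta-O-4",
    from_unit = 1:25,
    to_unit = 2:26,
    stringsAsFactors = FALSE
  )
  # the branch-point ether linkages from the modification table
  aog <- data.frame(
    kind = "alpha-O-gamma",
    from_unit = c(2L, as.integer(ambiguous_range[1])),
    to_unit = c(9L, as.integer(ambiguous_range[2])),
    stringsAsFactors = FALSE
  )
  # an alpha-O-gamma between backbone neighbours replaces the backbone bond
  dup <- paste(backbone$from_unit, backbone$to_unit) %in%
    paste(aog$from_unit, aog$to_unit)
  linkages <- rbind(backbone[!dup, ], aog)
  rownames(linkages) <- NULL

  mass_tab <- vapply(seq_len(nrow(units)), function(i) {
    formula_mass(monomer_formula(units$lignol_class[i], units$terminal_mods[[i]]))
  }, numeric(1))

  chain <- list(
    units = units,
    linkages = linkages,
    monomer_mass_table = mass_tab,
    condensation_loss = condensation_loss
  )
  class(chain) <- "lignin_chain"
  validate_chain(chain)
  chain
}

#' @export
print.lignin_chain <- function(x, ...) {
  cat(sprintf("lignin_chain: %d units, %d linkages, M = %.1f g/mol\n",
              nrow(x$units), nrow(x$linkages), chain_molar_mass(x)))
  cat("linkage kinds:",
      paste(sprintf("%s (%d)", names(table(x$linkages$kind)),
                    table(x$linkages$kind)), collapse = ", "), "\n")
  invisible(x)
}

.chain_graph <- function(chain) {
  igraph::graph_from_data_frame(
    chain$linkages[, c("from_unit", "to_unit")],
    directed = FALSE,
    vertices = data.frame(name = chain$units$index)
  )
}

#' Validate structural integrity of a lignin chain
#'
#' Checks unit-index uniqueness, linkage endpoints, absence of self-loops and
#' graph connectivity (a single macromolecule).
#'
#' @param chain a `lignin_chain`.
#' @return The chain, invisibly; errors on violation.
#' @export
validate_chain <- function(chain) {
  u <- chain$units$index
  if (anyDuplicated(u)) stop("duplicate unit indices")
  lk <- chain$linkages
  if (any(lk$from_unit == lk$to_unit)) stop("self-loop linkage")
  if (!all(c(lk$from_unit, lk$to_unit) %in% u))
    stop("linkage endpoint not among units")
  if (nrow(lk) < nrow(chain$units) - 1L) stop("too few linkages to connect chain")
  g <- .chain_graph(chain)
  if (!igraph::is_connected(g))
    stop("chain graph is disconnected: structural-integrity error")
  invisible(chain)
}

#' Count linkages by kind
#'
#' @param chain a `lignin_chain`; must be connected.
#' @return Named integer vector of counts per linkage kind; counts sum to the
#'   total number of linkages.
#' @export
linkage_census <- function(chain) {
  validate_chain(chain)
  tab <- table(chain$linkages$kind)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Molar mass of a lignin chain
#'
#' Sums the per-unit residue masses from the chain's mass table and subtracts
#' the configured condensation loss once per linkage (default loss 0).
#'
#' @param chain a `lignin_chain`.
#' @return g/mol (strictly positive).
#' @export
chain_molar_mass <- function(chain) {
  if (length(chain$monomer_mass_table) != nrow(chain$units))
    stop("monomer mass table does not cover all units: configuration error")
  m <- sum(chain$monomer_mass_table) -
    nrow(chain$linkages) * chain$condensation_loss
  if (!is.finite(m) || m <= 0) stop("non-positive chain mass")
  m
}

#' Assemble a condensed-phase system composition at a target moisture content
#'
#' Computes the number of water molecules needed so that water makes up
#' `moisture_wt_pct` of the total system mass:
#' `n_water = round((mc/(100-mc)) * n_chains * M / M_water)` with
#' `M = chain_molar_mass(chain)` and `M_water = 18.015` g/mol.
#'
#' @param n_chains number of lignin chains (>= 1); the reference condensed
#'   systems use 128.
#' @param moisture_wt_pct target moisture content in weight percent, in
#'   `[0, 100)`.
#' @param chain `lignin_chain` defining the chain molar mass
#'   (default [build_reference_chain()]).
#' @return A `system_composition` list: `n_chains`, `chain_molar_mass`,
#'   `moisture_wt_pct` (requested), `n_water`, `water_molar_mass`,
#'   `achieved_wt_pct`.
#' @export
assemble_system_spec <- function(n_chains, moisture_wt_pct,
                                 chain = build_reference_chain()) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (moisture_wt_pct < 0 || moisture_wt_pct >= 100)
    stop("moisture_wt_pct must be in [0, 100)")
  m_w <- 18.015
  M <- chain_molar_mass(chain)
  n_water <- as.integer(round(
    moisture_wt_pct / (100 - moisture_wt_pct) * n_chains * M / m_w))
  achieved <- 100 * n_water * m_w / (n_water * m_w + n_chains * M)
  out <- list(
    n_chains = as.integer(n_chains),
    chain_molar_mass = M,
    moisture_wt_pct = moisture_wt_pct,
    n_water = n_water,
    water_molar_mass = m_w,
    achieved_wt_pct = achieved
  )
  class(out) <- "system_composition"
  out
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf(
    "system_composition: %d chains (M = %.1f g/mol), %d waters -> %.2f wt %% (target %.1f)\n",
    x$n_chains, x$chain_molar_mass, x$n_water, x$achieved_wt_pct,
    x$moisture_wt_pct))
  invisible(x)
}

#' Export a chain to a structured JSON document
#'
#' Units with modifications and the linkage list are written as JSON so a
#' chain can be rebuilt elsewhere; see [read_chain_json()].
#'
#' @param chain a `lignin_chain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_json <- function(chain, path) {
  doc <- list(
    units = data.frame(
      index = chain$units$index,
      lignol_class = chain$units$lignol_class,
      terminal_mods = vapply(chain$units$terminal_mods, paste,
                             character(1), collapse = ";")
    ),
    linkages = chain$linkages,
    condensation_loss = chain$condensation_loss
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a chain from its JSON export
#' @param path file written by [write_chain_json()].
#' @return A `lignin_chain`.
#' @export
read_chain_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- data.frame(
    index = as.integer(doc$units$index),
    lignol_class = doc$units$lignol_class,
    stringsAsFactors = FALSE
  )
  units$terminal_mods <- lapply(strsplit(doc$units$terminal_mods, ";", fixed = TRUE),
                                function(x) x[nzchar(x)])
  chain <- list(
    units = units,
    linkages = data.frame(
      kind = doc$linkages$kind,
      from_unit = as.integer(doc$linkages$from_unit),
      to_unit = as.integer(doc$linkages$to_unit),
      stringsAsFactors = FALSE
    ),
    monomer_mass_table = vapply(seq_len(nrow(units)), function(i) {
      formula_mass(monomer_formula(units$lignol_class[i], units$terminal_mods[[i]]))
    }, numeric(1)),
    condensation_loss = doc$condensation_loss
  )
  class(chain) <- "lignin_chain"
  validate_chain(chain)
  chain
}

#' Edge-list view of a chain
#' @param chain a `lignin_chain`.
#' @return data.frame with `from_unit`, `to_unit`, `kind`.
#' @export
chain_edge_list <- function(chain) {
  chain$linkages[, c("from_unit", "to_unit", "kind")]
}
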