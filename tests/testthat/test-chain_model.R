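test_that("reference chain has 26 connected units with the tabulated modifications", {
  ch <- build_reference_chain()
  expect_s3_class(ch, "lignin_chain")
  expect_equal(nrow(ch$units), 26L)
  # terminal modifications sit on their stated repeat units
  mod_of <- function(i) ch$units$terminal_mods[[i]]
  expect_identical(mod_of(1), "gamma-carboxyl")
  expect_identical(mod_of(7), "gamma-aldehyde")
  expect_identical(mod_of(11), "alpha-aldehyde-trunc")
  expect_identical(mod_of(21), "alpha-ketone")
  expect_identical(mod_of(22), "beta-ketone")
  expect_identical(mod_of(26), "alpha-ketone")
  expect_length(unlist(ch$units$terminal_mods), 6L)
  # single macromolecule: every unit reachable from unit 1
  g <- igraph::graph_from_data_frame(
    ch$linkages[, c("from_unit", "to_unit")], directed = FALSE,
    vertices = data.frame(name = 1:26))
  expect_true(igraph::is_connected(g))
  # deterministic across calls
  expect_identical(build_reference_chain(), ch)
})

test_that("linkage census conserves edge count and places the ether branch linkages", {
  ch <- build_reference_chain()
  cen <- linkage_census(ch)
  expect_equal(sum(cen), nrow(ch$linkages))
  expect_gte(cen[["alpha-O-gamma"]], 1L)
  aog <- ch$linkages[ch$linkages$kind == "alpha-O-gamma", ]
  expect_true(all(c(aog$from_unit, aog$to_unit) %in% c(2:9, 12, 13)))
  # the ambiguous-range reading is configurable
  ch2 <- build_reference_chain(ambiguous_range = c(12L, 3L))
  aog2 <- ch2$linkages[ch2$linkages$kind == "alpha-O-gamma", ]
  expect_true(any(aog2$from_unit == 12 & aog2$to_unit == 3))
  # two-unit chain: census total 1
  tiny <- ch
  tiny$units <- tiny$units[1:2, ]
  tiny$linkages <- data.frame(kind = "beta-O-4", from_unit = 1L, to_unit = 2L)
  tiny$monomer_mass_table <- tiny$monomer_mass_table[1:2]
  expect_equal(sum(linkage_census(tiny)), 1L)
  # disconnected chain errors
  broken <- ch
  broken$linkages <- broken$linkages[-1, ]
  expect_error(linkage_census(broken), "disconnected")
})

test_that("chain molar mass matches a brute-force per-atom tally", {
  ch <- build_reference_chain()
  expect_equal(chain_molar_mass(ch), atom_tally_mass(ch), tolerance = 1e-12)
  # a single unmodified guaiacyl residue is its table mass exactly
  one <- list(
    units = data.frame(index = 1L, lignol_class = "guaiacyl"),
    linkages = data.frame(kind = character(), from_unit = integer(),
                          to_unit = integer()),
    monomer_mass_table = formula_mass(monomer_formula("guaiacyl")),
    condensation_loss = 0
  )
  one$units$terminal_mods <- list(character())
  class(one) <- "lignin_chain"
  expect_equal(chain_molar_mass(one), formula_mass(monomer_formula("guaiacyl")))
  # two identical units, one linkage, nonzero condensation loss
  two <- build_reference_chain(condensation_loss = 18.015)
  expect_equal(chain_molar_mass(two),
               atom_tally_mass(build_reference_chain()) -
                 nrow(two$linkages) * 18.015)
})

test_that("system composition hits the requested moisture content", {
  # no water at 0 wt %
  expect_equal(assemble_system_spec(128, 0)$n_water, 0L)
  # closed-form oracle at 20 wt %
  ch <- build_reference_chain()
  M <- chain_molar_mass(ch)
  sp <- assemble_system_spec(128, 20, ch)
  expect_equal(sp$n_water, as.integer(round(0.25 * 128 * M / 18.015)))
  # 50 wt %: water mass equals lignin mass within one molecule's rounding
  sp50 <- assemble_system_spec(1, 50, ch)
  expect_lt(abs(sp50$n_water * 18.015 - M), 18.015)
  # round trip within 0.5 points for systems of >= 10 chains
  for (mc in c(5, 10, 15, 20, 25)) {
    sp <- assemble_system_spec(10, mc, ch)
    expect_lt(abs(sp$achieved_wt_pct - mc), 0.5)
  }
  expect_error(assemble_system_spec(128, 100), "moisture")
  expect_error(assemble_system_spec(0, 10), "n_chains")
})

test_that("chain JSON export round-trips", {
  ch <- build_reference_chain()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_chain_json(ch, path)
  back <- read_chain_json(path)
  expect_equal(back$units$index, ch$units$index)
  expect_equal(back$units$terminal_mods, ch$units$terminal_mods)
  expect_equal(back$linkages, ch$linkages)
  expect_equal(chain_molar_mass(back), chain_molar_mass(ch))
  el <- chain_edge_list(ch)
  expect_equal(nrow(el), nrow(ch$linkages))
})
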