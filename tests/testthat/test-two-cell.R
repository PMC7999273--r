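# Two-cell construction and the diazotrophic constraint set.

test_that("heterocyst O2 bound is culture uptake scaled by frequency", {
  expect_equal(heterocyst_o2_bound(0.7, 0.09), 0.063)
  expect_equal(heterocyst_o2_bound(5.3, 0), 0)
  expect_equal(heterocyst_o2_bound(1, 1), 1)
  expect_error(heterocyst_o2_bound(-1, 0.1), ">= 0")
  expect_error(heterocyst_o2_bound(1, 1.2), "<= 1")
})

test_that("growth rate is ln(2) over the doubling time", {
  expect_equal(round(growth_rate_from_doubling_time(3.8), 4), 0.1824)
  expect_equal(growth_rate_from_doubling_time(1), log(2))
  # doubling td halves the rate, for any td
  for (td in c(0.5, 2, 7.3, 24)) {
    expect_equal(growth_rate_from_doubling_time(2 * td),
                 growth_rate_from_doubling_time(td) / 2)
  }
  expect_error(growth_rate_from_doubling_time(0), "> 0")
})

test_that("biomass reaction coefficients are rescaled fraction over molar mass", {
  # single pseudo-precursor: fraction 1, molar mass 0.1 g/mmol -> 10 mmol
  r <- build_biomass_reaction(
    data.frame(precursor = "p", mass_fraction = 1, molar_mass = 0.1),
    gam = 0)
  expect_equal(unname(r$stoichiometry[["p"]]), -10)
  # fractions 0.6/0.6 rescale to 0.5/0.5
  r2 <- build_biomass_reaction(
    data.frame(precursor = c("p1", "p2"), mass_fraction = c(0.6, 0.6),
               molar_mass = c(0.25, 0.5)), gam = 0)
  expect_equal(unname(r2$stoichiometry[["p1"]]), -0.5 / 0.25)
  expect_equal(unname(r2$stoichiometry[["p2"]]), -0.5 / 0.5)
  # spreadsheet-style hand computation: fractions 0.5/0.3/0.2 over
  # masses 0.162/0.110/0.089 g/mmol, 30 mmol GAM
  comp <- data.frame(precursor = c("prot", "carb", "lip"),
                     mass_fraction = c(0.5, 0.3, 0.2),
                     molar_mass = c(0.162, 0.110, 0.089))
  r3 <- build_biomass_reaction(comp, gam = 30)
  expect_equal(unname(r3$stoichiometry[c("prot", "carb", "lip")]),
               -c(0.5 / 0.162, 0.3 / 0.110, 0.2 / 0.089))
  expect_equal(unname(r3$stoichiometry[["atp"]]), -30)
  expect_equal(unname(r3$stoichiometry[["biomass"]]), 1)
  expect_equal(r3$row$kind, "biomass")
  expect_error(build_biomass_reaction(
    data.frame(precursor = "p", mass_fraction = 0, molar_mass = 1)),
    "sum to zero")
})

test_that("two-cell construction arithmetic matches the deletion sets", {
  tpl <- make_mini_template()
  n <- nrow(tpl$reactions)
  cfg <- two_cell_config(
    heterocyst_deletions = c("psii", "rubisco", "gogat"),
    vegetative_deletions = "nitrogenase")
  m <- build_two_cell(tpl, cfg)
  ids <- m$reactions$id
  expect_equal(sum(grepl("__hc$", ids)), n - 3)
  expect_equal(sum(grepl("__vc$", ids)), n - 1)
  expect_equal(sum(m$reactions$kind == "intercell-exchange"), 4)
  expect_equal(nrow(m$reactions), (n - 3) + (n - 1) + 4)
  expect_equal(sum(m$reactions$kind == "biomass"), 2)
  expect_equal(m$objective$reaction, "biomass__vc")
  # inter-cell exchange direction: sucrose flows vc -> hc
  expect_equal(m$stoichiometry$suc_vc_hc_exch,
               c(suc__vc = -1, suc__hc = 1))
  expect_error(build_two_cell(tpl, two_cell_config(
    heterocyst_deletions = "no_such_rxn")), "not in template")
})

test_that("config round-trips through the flat key-value file", {
  cfg <- two_cell_config(heterocyst_deletions = c("a", "b"),
                         vegetative_deletions = "c",
                         co2_uptake_ub = 4.2, heterocyst_fraction = 0.08,
                         couple_glu_gln = FALSE)
  f <- tempfile()
  write_two_cell_config(cfg, f)
  cfg2 <- read_two_cell_config(f)
  expect_equal(cfg2$co2_uptake_ub, 4.2)
  expect_equal(cfg2$heterocyst_fraction, 0.08)
  expect_equal(cfg2$heterocyst_deletions, c("a", "b"))
  expect_false(cfg2$couple_glu_gln)
  expect_equal(cfg2$intercell_exchanges, cfg$intercell_exchanges)
})

test_that("config validation enforces the stated domains", {
  expect_error(two_cell_config(co2_uptake_ub = -1), ">= 0")
  expect_error(two_cell_config(heterocyst_fraction = 0), "\\(0, 1\\)")
  expect_error(two_cell_config(heterocyst_fraction = 1), "\\(0, 1\\)")
})

test_that("constraint set pins the documented bounds on the toy model", {
  toy <- get_toy()
  rx <- toy$model$reactions
  bnd <- function(id) rx[rx$id == id, c("lower_bound", "upper_bound")]
  expect_equal(bnd("ex_co2_in")$upper_bound, 8.5)
  expect_equal(bnd("photon_psii_uptake__vc")$upper_bound, 100)
  expect_equal(bnd("n2_uptake__hc")$upper_bound, 10)
  expect_equal(bnd("o2_uptake__hc")$upper_bound, 0.063)
  expect_equal(bnd("biomass__hc")$lower_bound, 0.1 * 0.1824)
  expect_equal(bnd("suc_vc_hc_exch")$upper_bound, Inf)
})

test_that("glutamate and glutamine inter-cell fluxes are coupled exactly", {
  toy <- get_toy()
  sol <- fba(toy$model)
  expect_equal(sol$fluxes[["glu_vc_hc_exch"]],
               sol$fluxes[["gln_hc_vc_exch"]], tolerance = 1e-8)
  # and in a second, differently-shaped optimum (pFBA)
  sol2 <- pfba(toy$model)
  expect_equal(sol2$fluxes[["glu_vc_hc_exch"]],
               sol2$fluxes[["gln_hc_vc_exch"]], tolerance = 1e-8)
})

test_that("without inter-cell exchange, fixed nitrogen cannot reach biomass", {
  toy <- get_toy()
  exch <- toy$model$reactions$id[
    toy$model$reactions$kind == "intercell-exchange"]
  closed <- set_bounds(toy$model, exch, lb = 0, ub = 0)
  closed <- set_bounds(closed, "biomass__hc", lb = 0)
  sol <- fba(closed)
  expect_equal(sol$objective_value, 0, tolerance = 1e-7)
})

test_that("closing the sucrose shuttle starves the heterocyst and stops growth", {
  toy <- get_toy()
  m <- set_bounds(toy$model, "suc_vc_hc_exch", lb = 0, ub = 0)
  m <- set_bounds(m, "biomass__hc", lb = 0)
  sol <- fba(m)
  expect_equal(sol$objective_value, 0, tolerance = 1e-7)
  # nitrogenase is forced silent in the whole feasible space
  rng <- fva(m, targets = "nitrogenase__hc")
  expect_equal(rng$ranges$min, 0, tolerance = 1e-7)
  expect_equal(rng$ranges$max, 0, tolerance = 1e-7)
})

test_that("the heterocyst never evolves oxygen (no PSII)", {
  toy <- get_toy()
  # no O2-producing reaction exists in the heterocyst compartment
  o2_producers <- Filter(function(rid) {
    st <- toy$model$stoichiometry[[rid]]
    any(names(st) == "o2__hc" & st > 0)
  }, toy$model$reactions$id)
  expect_equal(o2_producers, "o2_uptake__hc")
})
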