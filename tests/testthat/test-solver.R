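# FBA, pFBA, FVA and derived queries.

test_that("toy FBA growth equals the manifest optimum", {
  toy <- get_toy()
  sol <- fba(toy$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, toy$manifest$mu_default,
               tolerance = 1e-8)
  # steady state: S v = 0 within 1e-6
  S <- stoichiometric_matrix(toy$model)
  expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
  # bounds respected
  expect_true(all(sol$fluxes >= toy$model$reactions$lower_bound - 1e-6))
  expect_true(all(sol$fluxes <= toy$model$reactions$upper_bound + 1e-6))
})

test_that("FBA on small networks agrees with the vertex-enumeration oracle", {
  toy <- get_toy()
  # reduced LP: the mini template's flux space
  tpl <- make_mini_template()
  lp <- diazoflux:::lp_from_model(tpl)
  c_obj <- as.numeric(tpl$reactions$id == "biomass")
  res <- diazoflux:::lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub)
  orc <- oracle_lp(c_obj, lp$A, lp$rhs, lp$lb, lp$ub)
  expect_equal(res$objective, orc$objective, tolerance = 1e-9)
})

test_that("all-closed exchanges force a zero objective", {
  toy <- get_toy()
  ex <- toy$model$reactions$id[toy$model$reactions$kind == "exchange"]
  m <- set_bounds(toy$model, ex, lb = 0, ub = 0)
  m <- set_bounds(m, "biomass__hc", lb = 0)
  expect_equal(fba(m)$objective_value, 0, tolerance = 1e-8)
})

test_that("pFBA preserves the optimum and silences futile cycles", {
  toy <- get_toy()
  base <- fba(toy$model)
  par <- pfba(toy$model)
  expect_equal(par$objective_value, base$objective_value,
               tolerance = 1e-6)
  expect_lte(attr(par, "total_flux"),
             sum(abs(base$fluxes)) + 1e-6)
  # a 2-reaction futile cycle parallel to a single path carries no flux
  mets <- rbind(metabolite("a"), metabolite("b"))
  m <- metabolic_model(mets, list(
    reaction("in_a", c(a = 1), 0, 5, kind = "exchange"),
    reaction("path", c(a = -1, b = 1), 0, 10),
    reaction("cyc_fwd", c(a = -1, b = 1), 0, 10),
    reaction("cyc_rev", c(b = -1, a = 1), 0, 10),
    reaction("out_b", c(b = -1), 0, 5, kind = "exchange")),
    objective = "out_b")
  sol <- pfba(m)
  expect_equal(sol$objective_value, 5, tolerance = 1e-8)
  expect_equal(sol$fluxes[["cyc_fwd"]] + sol$fluxes[["cyc_rev"]], 0,
               tolerance = 1e-8)
})

test_that("FVA brackets the FBA flux and matches manifest minima", {
  toy <- get_toy()
  sol <- fba(toy$model)
  targets <- c("suc_vc_hc_exch", "nitrogenase__hc", "glu_vc_hc_exch",
               "calvin__vc", "oppp__hc", "psi_cyclic__hc")
  rng <- fva(toy$model, targets = targets, fix_objective = TRUE)
  for (i in seq_along(targets)) {
    expect_gte(sol$fluxes[[targets[i]]], rng$ranges$min[i] - 1e-6)
    expect_lte(sol$fluxes[[targets[i]]], rng$ranges$max[i] + 1e-6)
  }
  man <- toy$manifest
  expect_equal(rng$ranges$min[1], man$sucrose_min_default,
               tolerance = 1e-6)
  expect_equal(rng$ranges$min[2], man$nitrogenase_min, tolerance = 1e-6)
  expect_equal(rng$ranges$min[3], man$glu_gln_exchange, tolerance = 1e-6)
  # nitrogenase is fully determined at the optimum: N demand / 2
  expect_equal(rng$ranges$max[2], man$nitrogenase_min, tolerance = 1e-6)
})

test_that("a disconnected reaction has flux range (0, 0)", {
  toy <- get_toy()
  m <- toy$model
  m$metabolites <- rbind(m$metabolites, metabolite("orphan_met"))
  m <- add_reaction(m, reaction("orphan", c(orphan_met = 1),
                                -1000, 1000))
  rng <- fva(m, targets = "orphan")
  expect_equal(rng$ranges$min, 0, tolerance = 1e-9)
  expect_equal(rng$ranges$max, 0, tolerance = 1e-9)
})

test_that("objective is invariant to reaction order and reversible splits", {
  toy <- get_toy()
  base <- fba(toy$model)$objective_value
  # reorder
  set.seed(42)
  perm <- sample(nrow(toy$model$reactions))
  m2 <- toy$model
  m2$reactions <- m2$reactions[perm, ]
  rownames(m2$reactions) <- NULL
  m2$stoichiometry <- m2$stoichiometry[m2$reactions$id]
  expect_equal(fba(m2)$objective_value, base, tolerance = 1e-9)
  # split the reversible FNR into forward + reverse halves
  m3 <- toy$model
  st <- m3$stoichiometry$fnr__hc
  m3 <- set_bounds(m3, "fnr__hc", lb = 0)
  m3 <- add_reaction(m3, reaction("fnr_rev__hc", -st, 0, 1000))
  expect_equal(fba(m3)$objective_value, base, tolerance = 1e-9)
})

test_that("relaxing an upper bound never decreases the optimum", {
  toy <- get_toy()
  base <- fba(toy$model)$objective_value
  for (rid in c("ex_co2_in", "photon_psii_uptake__vc", "o2_uptake__hc",
                "suc_vc_hc_exch", "glycolysis__hc")) {
    j <- match(rid, toy$model$reactions$id)
    m <- set_bounds(toy$model, rid,
                    ub = toy$model$reactions$upper_bound[j] * 2 + 10)
    expect_gte(fba(m)$objective_value, base - 1e-9)
  }
})

test_that("minimum inorganic-carbon uptake for target growth is the carbon bound", {
  toy <- get_toy()
  # at the default optimum the CO2 bound is tight, so the minimum uptake
  # needed to reach that growth equals the bound itself
  v <- min_uptake_for_growth(toy$model, "ex_co2_in",
                             toy$manifest$mu_default)
  expect_equal(v, 8.5, tolerance = 1e-6)
  # a maintenance-free target of zero growth needs no carbon
  m0 <- set_bounds(toy$model, "biomass__hc", lb = 0)
  expect_equal(min_uptake_for_growth(m0, "ex_co2_in", 0), 0,
               tolerance = 1e-8)
  # half the growth needs exactly half the carbon plus the turnover share
  mu_half <- toy$manifest$mu_default / 2
  v2 <- min_uptake_for_growth(toy$model, "ex_co2_in", mu_half)
  expect_equal(v2, 15 * (mu_half + 0.01824), tolerance = 1e-6)
})

test_that("metabolite turnover equals production and consumption at steady state", {
  toy <- get_toy()
  sol <- pfba(toy$model)
  # hand case: one producer at flux 2
  mets <- rbind(metabolite("a"), metabolite("b"))
  mm <- metabolic_model(mets, list(
    reaction("src", c(a = 1), 0, 2, kind = "exchange"),
    reaction("conv", c(a = -1, b = 1), 0, 10),
    reaction("snk", c(b = -1), 0, 10, kind = "exchange")),
    objective = "snk")
  s2 <- fba(mm)
  expect_equal(metabolite_turnover(mm, s2, "a"), 2)
  # production == consumption for every toy metabolite
  S <- stoichiometric_matrix(toy$model)
  v <- sol$fluxes[colnames(S)]
  for (met in sample(rownames(S), 12)) {
    contrib <- S[met, ] * v
    expect_equal(sum(contrib[contrib > 0]), -sum(contrib[contrib < 0]),
                 tolerance = 1e-6, info = met)
  }
  expect_error(metabolite_turnover(toy$model, sol, "no_such"), "unknown")
})
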