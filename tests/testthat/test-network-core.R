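# Model containers, consistency checks and the three I/O dialects.

test_that("model validation rejects malformed input", {
  mets <- rbind(metabolite("a"), metabolite("b"))
  expect_error(
    metabolic_model(mets, list(reaction("r1", c(a = -1, z = 1)))),
    "unknown metabolite")
  expect_error(
    metabolic_model(mets, list(reaction("ex", c(a = -1, b = 1),
                                        kind = "exchange"))),
    "exactly one metabolite")
  expect_error(reaction("r", c(a = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound")
  expect_error(
    metabolic_model(rbind(mets, metabolite("a")),
                    list(reaction("r1", c(a = -1, b = 1)))),
    "duplicate metabolite")
})

test_that("formula parsing handles counts, multi-letter tokens and R-groups", {
  expect_equal(parse_formula("C6H12O6P"),
               c(C = 6L, H = 12L, O = 6L, P = 1L))
  expect_equal(parse_formula("NadpH2"), c(H = 2L, Nadp = 1L))
  expect_equal(parse_formula(""), integer(0))          # massless species
  expect_null(parse_formula("C10H16R"))                # R-group exempt
  expect_null(parse_formula("(C5H8O2)n"))              # polymer exempt
  expect_null(parse_formula(NA_character_))
  expect_error(parse_formula("C6#H12"), "unparseable")
})

test_that("mass/charge balance check flags exactly the imbalanced reactions", {
  mets <- rbind(metabolite("h2o", formula = "H2O"),
                metabolite("h2", formula = "H2"),
                metabolite("o2", formula = "O2"),
                metabolite("x", formula = NA_character_))
  m <- metabolic_model(mets, list(
    reaction("split", c(h2o = -2, h2 = 2, o2 = 1)),
    reaction("broken", c(h2o = -1, h2 = 1)),
    reaction("dubious", c(x = -1, h2 = 1)),
    reaction("ex_h2", c(h2 = -1), kind = "exchange")))
  rep <- check_mass_charge_balance(m)
  expect_false("split" %in% rep$reaction)        # 2 H2O -> 2 H2 + O2 ok
  bro <- rep[rep$reaction == "broken", ]
  expect_equal(bro$element, "O")
  expect_equal(bro$imbalance, -1)
  expect_true("unknown" %in% rep[rep$reaction == "dubious", "element"])
  expect_false("ex_h2" %in% rep$reaction)        # exchanges exempt
  # independent of reaction order, and idempotent
  m2 <- m; m2$reactions <- m$reactions[rev(seq_len(4)), ]
  m2$stoichiometry <- m$stoichiometry[m2$reactions$id]
  rep2 <- check_mass_charge_balance(m2)
  expect_setequal(paste(rep$reaction, rep$element),
                  paste(rep2$reaction, rep2$element))
})

test_that("charge imbalance is reported separately", {
  mets <- rbind(metabolite("na", formula = "Na", charge = 1L),
                metabolite("cl", formula = "Cl", charge = -1L))
  m <- metabolic_model(mets, list(reaction("bad", c(na = -1, cl = 1))))
  rep <- check_mass_charge_balance(m)
  expect_true("charge" %in% rep$element)
})

test_that("count_unique collapses cell suffixes and finds the shared core", {
  mets <- rbind(metabolite("m__vc", super_compartment = "vegetative"),
                metabolite("m__hc", super_compartment = "heterocyst"))
  m <- metabolic_model(mets, list(
    reaction("r1__vc", c(m__vc = 1), kind = "demand"),
    reaction("r1__hc", c(m__hc = 1), kind = "demand"),
    reaction("only__vc", c(m__vc = -1), kind = "demand"),
    reaction("plain", c(m__vc = -1), kind = "demand")))
  s <- count_unique(m)
  expect_equal(unname(s$per_cell["vegetative"]), 2)
  expect_equal(unname(s$per_cell["heterocyst"]), 1)
  expect_equal(s$n_shared, 1)
  expect_equal(s$n_unique_reactions, 3)          # r1, only, plain
  expect_equal(s$unsuffixed, "plain")
})

test_that("toy model counts equal the generator's manifest", {
  toy <- get_toy()
  s <- count_unique(toy$model)
  expect_equal(unname(s$per_cell["vegetative"]),
               toy$manifest$counts$vegetative_templates)
  expect_equal(unname(s$per_cell["heterocyst"]),
               toy$manifest$counts$heterocyst_templates)
  expect_equal(s$n_shared, toy$manifest$counts$shared_templates)
  expect_equal(nrow(toy$model$reactions), toy$manifest$counts$reactions)
})

test_that("tabular equation strings parse coefficients and reversibility", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation",
               "r1\tA__vc -> B__vc",
               "r2\t2 A__vc + 0.5 C__vc <=> B__vc"), f)
  m <- load_model(f, "tabular")
  expect_equal(nrow(m$reactions), 2)
  expect_equal(nrow(m$metabolites), 3)
  expect_equal(m$stoichiometry$r2[["A__vc"]], -2)
  expect_equal(m$stoichiometry$r2[["C__vc"]], -0.5)
  expect_equal(m$reactions$lower_bound, c(0, -1000))
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
})

test_that("unreadable or duplicate-id inputs raise parse errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation", "r1\tA -> B", "r1\tA -> C"), f)
  expect_error(load_model(f, "tabular"), "duplicate reaction id")
  f2 <- tempfile(fileext = ".json")
  writeLines("{not json", f2)
  expect_error(load_model(f2, "json"), "parse error")
  expect_error(load_model("/nonexistent/file.tsv"), "does not exist")
})

test_that("write/load round-trips the toy model in all three dialects", {
  toy <- get_toy()
  m <- toy$model
  for (fmt in c("tabular", "json", "sbml")) {
    path <- tempfile(fileext = switch(fmt, tabular = ".tsv",
                                      json = ".json", sbml = ".sbml"))
    write_model(m, path, fmt)
    m2 <- load_model(path, fmt)
    expect_setequal(m2$reactions$id, m$reactions$id)
    expect_setequal(m2$metabolites$id, m$metabolites$id)
    ord <- match(m$reactions$id, m2$reactions$id)
    expect_equal(m2$reactions$lower_bound[ord], m$reactions$lower_bound,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(m2$reactions$upper_bound[ord], m$reactions$upper_bound,
                 tolerance = 1e-9, ignore_attr = TRUE)
    for (rid in m$reactions$id) {
      st1 <- m$stoichiometry[[rid]][order(names(m$stoichiometry[[rid]]))]
      st2 <- m2$stoichiometry[[rid]][order(names(m2$stoichiometry[[rid]]))]
      expect_equal(st2, st1, tolerance = 1e-9, info = paste(fmt, rid))
    }
    expect_equal(m2$objective$reaction, m$objective$reaction)
    # the round-tripped model solves to the same optimum
    expect_equal(fba(m2)$objective_value, fba(m)$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("a freshly loaded model admits the zero flux vector", {
  toy <- get_toy()
  S <- stoichiometric_matrix(toy$model)
  v0 <- numeric(ncol(S))
  expect_true(all(abs(S %*% v0) == 0))
  expect_true(all(toy$model$reactions$lower_bound <= 0 |
                  toy$model$reactions$id == "biomass__hc"))
})
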