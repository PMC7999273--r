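# Strain design: flux spaces, MUST sets, filtering, and the FORCE MILP.

test_that("production pathways conserve backbone carbon and nitrogen", {
  toy <- get_toy()
  paths <- make_pathway_fixtures()
  for (pn in names(paths)) {
    mp <- add_production_pathway(toy$model, paths[[pn]])
    expect_equal(nrow(check_mass_charge_balance(mp)), 0, info = pn)
  }
  # lysine (C6, 2 N) -> valerolactam (C5, 1 N) + CO2, N returned as NH3
  five <- paths$five_aminovalerate
  net <- numeric(0)
  for (r in five$reactions[1:3]) {
    for (mm in names(r$stoichiometry)) {
      net[mm] <- (if (is.na(net[mm])) 0 else net[mm]) + r$stoichiometry[[mm]]
    }
  }
  expect_equal(unname(net["lys__vc"]), -1)
  expect_equal(unname(net["vlac__vc"]), 1)
  expect_equal(unname(net["co2__vc"]), 1)
  expect_equal(unname(net["nh3__vc"]), 1)
  # caprolactam keeps the C6 backbone of succinate + acetyl
  adip <- paths$adipyl_coa
  net <- numeric(0)
  for (r in adip$reactions[1:7]) {
    for (mm in names(r$stoichiometry)) {
      net[mm] <- (if (is.na(net[mm])) 0 else net[mm]) + r$stoichiometry[[mm]]
    }
  }
  expect_equal(unname(net["succ__vc"]), -1)
  expect_equal(unname(net["ac__vc"]), -1)
  expect_equal(unname(net["clac__vc"]), 1)
})

test_that("a pathway without its precursor is rejected", {
  toy <- get_toy()
  spec <- make_pathway_fixtures()$five_aminovalerate
  crippled <- remove_reactions(toy$model, "lys_syn__vc")
  crippled$metabolites <-
    crippled$metabolites[crippled$metabolites$id != "lys__vc", ]
  expect_error(add_production_pathway(crippled, spec), "precursor")
})

test_that("wild-type space honours measured ranges and propagates them", {
  toy <- get_toy()
  # empty MFA table: plain FVA
  wt0 <- wild_type_flux_space(toy$model, NULL,
                              targets = c("calvin__vc", "oppp__hc"))
  plain <- fva(toy$model, targets = c("calvin__vc", "oppp__hc"))
  expect_equal(wt0$ranges$min, plain$ranges$min, tolerance = 1e-8)
  expect_equal(wt0$ranges$max, plain$ranges$max, tolerance = 1e-8)
  # a pinned (a, a) range comes back as (a, a)
  pin <- data.frame(reaction = "glycolysis__vc", min = 0.55, max = 0.55)
  wt1 <- wild_type_flux_space(toy$model, pin, targets = "glycolysis__vc")
  expect_equal(wt1$ranges$min, 0.55, tolerance = 1e-8)
  expect_equal(wt1$ranges$max, 0.55, tolerance = 1e-8)
  # contradictory ranges are rejected, naming the culprit: forcing this
  # much N2 fixation implies more growth than the carbon bound allows
  bad <- data.frame(reaction = "nitrogenase__hc", min = 5, max = 6)
  expect_error(wild_type_flux_space(toy$model, bad), "infeasible")
})

test_that("overproduction space enforces the yield and biomass floors", {
  of <- get_optforce_setup("five_aminovalerate")
  y <- of$over$context$theoretical_yield
  expect_equal(y, 1.5625, tolerance = 1e-6)   # photon-capped: 25/16
  prod_rng <- of$over$ranges[of$over$ranges$reaction == "ex_vlac", ]
  expect_gte(prod_rng$min, 0.9 * y - 1e-6)
  # degenerate fractions reduce to the unconstrained space
  m <- of$model
  free <- overproduction_flux_space(m, "ex_vlac", yield_frac = 0,
                                    biomass_frac = 0,
                                    targets = "glycolysis__vc")
  relaxed <- set_bounds(m, c("biomass__vc", "biomass__hc"), lb = 0)
  plain <- fva(relaxed, targets = "glycolysis__vc")
  expect_equal(free$ranges$min, plain$ranges$min, tolerance = 1e-6)
  expect_equal(free$ranges$max, plain$ranges$max, tolerance = 1e-6)
})

test_that("theoretical caprolactam yield is carbon-capped", {
  of <- get_optforce_setup("adipyl_coa")
  expect_equal(of$over$context$theoretical_yield, 8.5 / 6,
               tolerance = 1e-6)
})

test_that("single-reaction MUST classification follows strict separation", {
  mkr <- function(ids, mins, maxs) {
    structure(list(ranges = data.frame(reaction = ids, min = mins,
                                       max = maxs),
                   context = list()), class = "flux_ranges")
  }
  wt <- mkr(c("a", "b", "c", "d"), c(0, 0, 1, -2), c(1, 1, 2, -1))
  ov <- mkr(c("a", "b", "c", "d"), c(2, 0.5, 0, 0), c(3, 0.8, 0, 0))
  must <- identify_must_single(wt, ov)
  expect_equal(must$must_u, "a")        # (2,3) above (0,1)
  expect_equal(must$must_x, c("c", "d"))  # pinned to zero, wt excludes 0
  expect_length(must$must_l, 0)         # b overlaps
  expect_error(identify_must_single(wt, mkr("z", 0, 1)), "different")
})

test_that("pairwise MUST sets catch couplings single ranges miss", {
  # two parallel routes a->b: individually either can be off, but the
  # overproduction space doubles the total; the sum is forced up while
  # each individual range still overlaps
  mets <- rbind(metabolite("a"), metabolite("b"))
  mk <- function(in_ub, out_lb) {
    m <- metabolic_model(mets, list(
      reaction("src", c(a = 1), 0, in_ub, kind = "exchange"),
      reaction("p1", c(a = -1, b = 1), 0, 2),
      reaction("p2", c(a = -1, b = 1), 0, 2),
      reaction("snk", c(b = -1), out_lb, 4, kind = "exchange")),
      objective = "snk")
    m
  }
  wt_m <- mk(1.5, 0); ov_m <- mk(4, 3)
  wt <- fva(wt_m); wt$context$model <- wt_m
  ov <- fva(ov_m); ov$context$model <- ov_m
  pairs <- rbind(c("p1", "p2"))
  must <- identify_must_pairs(wt_m, wt, ov, pairs = pairs)
  expect_length(must$must_uu, 1)
  expect_equal(sort(must$must_uu[[1]]), c("p1", "p2"))
  expect_length(must$must_ll, 0)
  # neither route is individually separated
  single <- identify_must_single(wt, ov)
  expect_false("p1" %in% single$must_u)
  # oracle check on the sum range
  lp <- diazoflux:::lp_from_model(wt_m)
  j1 <- match("p1", lp$rxn_ids); j2 <- match("p2", lp$rxn_ids)
  verts <- diazoflux:::lp_enumerate_vertices(lp$A, lp$rhs, lp$lb, lp$ub)
  sums <- vapply(verts, function(v) v[j1] + v[j2], numeric(1))
  expect_equal(unname(diazoflux:::combo_range(
    wt_m, c(p1 = 1, p2 = 1))["max"]), max(sums), tolerance = 1e-6)
  # the sum range of (i, i) is twice the single range
  r2 <- diazoflux:::combo_range(wt_m, c(p1 = 2))
  r1 <- fva(wt_m, targets = "p1")$ranges
  expect_equal(unname(r2["min"]), 2 * r1$min, tolerance = 1e-8)
  expect_equal(unname(r2["max"]), 2 * r1$max, tolerance = 1e-8)
  # identical blocked reactions join no set
  blocked_wt <- mk(0, 0); blocked_ov <- mk(0, 0)
  bw <- fva(blocked_wt); bw$context$model <- blocked_wt
  bo <- fva(blocked_ov); bo$context$model <- blocked_ov
  m2 <- identify_must_pairs(blocked_wt, bw, bo, pairs = pairs)
  expect_length(m2$must_uu, 0)
  expect_length(m2$must_ul, 0)
})

test_that("MUST filtering applies the four rules in order", {
  of <- get_optforce_setup("five_aminovalerate")
  raw <- identify_must_single(of$wt, of$over)
  filt <- of$must
  kinds <- setNames(of$model$reactions$kind, of$model$reactions$id)
  # transport/exchange/intercell members are gone
  expect_true(any(kinds[raw$must_u] != "enzymatic"))
  expect_true(all(kinds[filt$must_u] == "enzymatic"))
  # the lysine-to-lactam linear chain collapsed to its first reaction
  expect_true("lys_syn__vc" %in% filt$must_u)
  expect_false(any(c("davB__vc", "davA__vc", "ls_v__vc") %in%
                   filt$must_u))
  # growth-coupled exclusion shrinks MUST_L on demand
  raw2 <- raw
  raw2$must_l <- c(raw2$must_l, "calvin__vc")
  f2 <- filter_must_sets(raw2, of$model, growth_coupled = "calvin__vc")
  expect_false("calvin__vc" %in% f2$must_l)
  # essential / low-flux pruning empties MUST_X here
  expect_length(filt$must_x, 0)
})

test_that("FORCE MILP equals brute-force enumeration across budgets", {
  for (pn in c("five_aminovalerate", "adipyl_coa")) {
    of <- get_optforce_setup(pn)
    prod <- of$spec$product_exchange
    prev <- -Inf
    for (k in 0:3) {
      en <- enumerate_force_sets(of$must, prod, k)
      st <- solve_force_set(of$model, of$must, prod, k)
      milp_g <- if (length(st) > 0) st[[1]]$guaranteed_product_flux else 0
      expect_equal(milp_g, en$guaranteed_flux, tolerance = 1e-5,
                   info = paste(pn, "k =", k))
      # guaranteed flux is non-decreasing in the budget
      expect_gte(en$guaranteed_flux, prev - 1e-9)
      prev <- en$guaranteed_flux
      # members come from the filtered MUST sets
      if (length(st) > 0 && nrow(st[[1]]$members) > 0) {
        expect_true(all(st[[1]]$members$reaction %in%
                        c(of$must$must_u, of$must$must_l,
                          of$must$must_x)))
      }
    }
  }
})

test_that("toy FORCE sets match the manifest reference", {
  toy <- get_toy()
  of <- get_optforce_setup("five_aminovalerate")
  en2 <- enumerate_force_sets(of$must, "ex_vlac", 2)
  expect_equal(en2$guaranteed_flux,
               toy$manifest$optforce$valerolactam$k2, tolerance = 1e-6)
  expect_setequal(en2$members$reaction,
                  toy$manifest$optforce$valerolactam$k2_members)
  of2 <- get_optforce_setup("adipyl_coa")
  en3 <- enumerate_force_sets(of2$must, "ex_clac", 3)
  expect_equal(en3$guaranteed_flux,
               toy$manifest$optforce$caprolactam$k3, tolerance = 1e-6)
  expect_setequal(en3$members$reaction,
                  toy$manifest$optforce$caprolactam$k3_members)
})

test_that("integer cuts enumerate distinct, non-improving alternatives", {
  of <- get_optforce_setup("five_aminovalerate")
  st <- solve_force_set(of$model, of$must, "ex_vlac", k = 2,
                        n_strategies = 4)
  expect_gte(length(st), 2)
  sets <- lapply(st, function(s) sort(s$members$reaction))
  expect_equal(anyDuplicated(sets), 0)
  g <- vapply(st, `[[`, numeric(1), "guaranteed_product_flux")
  expect_true(all(diff(g) <= 1e-9))
})

test_that("k = 0 returns the wild-type guaranteed product flux", {
  of <- get_optforce_setup("five_aminovalerate")
  st <- solve_force_set(of$model, of$must, "ex_vlac", k = 0)
  expect_length(st, 1)
  expect_equal(nrow(st[[1]]$members), 0)
  wtm <- of$wt$context$model
  expect_equal(st[[1]]$guaranteed_product_flux,
               diazoflux:::min_product_flux(wtm, "ex_vlac"),
               tolerance = 1e-9)
})

test_that("manually added knockout candidates enter the search", {
  of <- get_optforce_setup("adipyl_coa")
  st <- solve_force_set(of$model, of$must, "ex_clac", k = 3,
                        extra_knockouts = "sdh__vc", n_strategies = 2)
  cand <- diazoflux:::force_candidates(of$must, "sdh__vc")
  expect_true("sdh__vc" %in% cand$reaction)
  expect_equal(cand$kind[cand$reaction == "sdh__vc"], "knockout")
  en <- enumerate_force_sets(of$must, "ex_clac", 3,
                             extra_knockouts = "sdh__vc")
  g <- if (length(st) > 0) st[[1]]$guaranteed_product_flux else 0
  expect_equal(g, en$guaranteed_flux, tolerance = 1e-5)
})

test_that("fold changes follow the bound-ratio convention", {
  wt <- structure(list(ranges = data.frame(
    reaction = c("r_up", "r_dn", "r_ko", "r_zero"),
    min = c(0.5, 1.0, 0.2, 0), max = c(2.0, 3.0, 0.4, 0))),
    class = "flux_ranges")
  strat <- structure(list(
    k = 3, members = data.frame(
      reaction = c("r_up", "r_dn", "r_ko", "r_zero"),
      kind = c("up", "down", "knockout", "up"),
      level = c(2.4, 0.1, 0, 1.0))), class = "intervention_strategy")
  fc <- fold_changes(strat, wt)
  expect_equal(fc$fold_change[fc$reaction == "r_up"], 1.2)     # 2.4 / 2.0
  expect_equal(fc$fold_change[fc$reaction == "r_dn"], 10)      # 1.0 / 0.1
  expect_true(is.na(fc$fold_change[fc$reaction == "r_ko"]))
  expect_equal(fc$fold_change[fc$reaction == "r_zero"], Inf)   # /0
})

test_that("the cycle reporter flags loops without touching results", {
  toy <- get_toy()
  # add an explicit 2-cycle and find it with everything external closed
  m <- toy$model
  m <- add_reaction(m, reaction("loop_rev", c(ac__vc = -1, co2__vc = -1,
                                              nadph__vc = -1, pyr__vc = 1,
                                              nadp__vc = 1, h2o__vc = 1),
                                0, 1000))
  cyc <- report_cycles(m, candidates = c("loop_rev", "pdh__vc",
                                         "calvin__vc"))
  expect_true(all(c("loop_rev", "pdh__vc") %in% cyc))
  expect_false("calvin__vc" %in% cyc)
})
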