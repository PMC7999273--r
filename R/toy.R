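# Deterministic synthetic two-cell network with hand-verifiable optima.
#
# The generator lumps each major module of the vegetative-cell/heterocyst
# division of labour into one or two integer-balanced reactions so that
# every reference optimum is a closed-form consequence of the
# stoichiometry (no randomness anywhere):
#
#   vegetative cell: linear (PSII-containing) electron transport
#     (8 photons -> 2 NADPH + 3 ATP + O2), cyclic PSI (2 photons -> ATP),
#     Calvin cycle lumped to G6P (6 CO2 + 12 NADPH + 18 ATP), sucrose
#     synthesis/export, GOGAT, lysine synthesis, a succinate branch
#     (2-oxoglutarate decarboxylase, SSA dehydrogenase, succinate
#     dehydrogenase, lumped malic enzyme);
#   heterocyst: sucrose catabolism (invertase), glycolysis
#     (G6P -> 2 pyruvate + 2 ATP + 2 NADPH), oxidative PPP
#     (G6P -> 6 CO2 + 12 NADPH), PDH, partial TCA to 2-oxoglutarate,
#     full TCA oxidation, cyclic PSI, O2-capped respiration, FNR
#     (NADPH <-> 2 reduced ferredoxin, so 8 e- = 4 NAD(P)H is a
#     stoichiometric fact), nitrogenase (N2 + 8 Fd_red + 16 ATP ->
#     2 NH3 + H2), glutamine synthetase, ethanol and H2 vents;
#   exchanges: shared external CO2 pool (uptake bound 8.5), per-cell
#     photon uptakes (bound 100 per photosystem), heterocyst O2 uptake
#     (bound 0.063), N2 uptake (bound 10), plus the four inter-cell
#     exchanges (sucrose, glutamate, glutamine, 2-oxoglutarate).
#
# Cofactors use pseudo-element formulas (ATP = "AdpP", NADPH = "NadpH2",
# reduced ferredoxin = "FdH", photons massless) so that every non-biomass
# reaction passes the elemental balance check exactly.
#
# Key lumping facts exploited by the reference optima: the oxidative PPP
# yields 12 NADPH per G6P while evolving 6 CO2, whereas glycolysis +
# partial TCA with 2-oxoglutarate export yields 4 NADPH per G6P evolving
# 1 CO2 -- hence, with reducing-equivalent demand fixed by nitrogenase,
# the incomplete-oxidation scheme needs exactly 3x the sucrose and half
# the CO2 evolution of the PPP scheme.

#' Parameters of the synthetic two-cell network
#'
#' Only stoichiometrically free choices are tunable; yields that the
#' balanced lumping fixes (12 NADPH per G6P through the oxidative PPP,
#' 2 ATP per G6P through glycolysis) are reported in the manifest.
#'
#' @param nitrogenase_atp mol ATP per mol N2 fixed (default 16).
#' @param nitrogenase_fdred mol reduced ferredoxin (electrons) per N2
#'   (default 8, i.e. 4 NAD(P)H).
#' @param letc_photons photons per (2 NADPH + 3 ATP + O2) through the
#'   linear chain (default 8).
#' @param cyclic_photons_per_atp photons per ATP through cyclic PSI.
#' @param retc_atp_per_o2 ATP per O2 through the respiratory chain.
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @param biomass_g6p,biomass_pyr,biomass_glu precursor coefficients of
#'   the biomass drain, mmol/gDW.
#' @param config a [two_cell_config()] providing all simulation bounds.
#' @return object of class `toy_params`.
#' @export
toy_params <- function(nitrogenase_atp = 16, nitrogenase_fdred = 8,
                       letc_photons = 8, cyclic_photons_per_atp = 2,
                       retc_atp_per_o2 = 4, gam = 30,
                       biomass_g6p = 1.5, biomass_pyr = 2,
                       biomass_glu = 2.5,
                       config = two_cell_config()) {
  p <- list(nitrogenase_atp = nitrogenase_atp,
            nitrogenase_fdred = nitrogenase_fdred,
            letc_photons = letc_photons,
            cyclic_photons_per_atp = cyclic_photons_per_atp,
            retc_atp_per_o2 = retc_atp_per_o2,
            gam = gam, biomass_g6p = biomass_g6p,
            biomass_pyr = biomass_pyr, biomass_glu = biomass_glu,
            ppp_nadph_per_g6p = 12, glycolysis_atp_per_g6p = 2,
            config = config)
  if (any(unlist(p[1:9]) <= 0)) stop("all yields must be > 0")
  structure(p, class = "toy_params")
}

toy_metabolite_table <- function() {
  m <- function(id, formula, name = id) {
    metabolite(id, name = name, formula = formula, charge = 0L,
               compartment = "c", super_compartment = "vegetative")
  }
  rbind(
    m("photon_psii", ""), m("photon_psi", ""),
    m("co2", "CO2"), m("o2", "O2"), m("h2o", "H2O"), m("h2", "H2"),
    m("n2", "N2"), m("nh3", "NH3"),
    m("atp", "AdpP"), m("adp", "Adp"), m("pi", "P"),
    m("nadp", "Nadp"), m("nadph", "NadpH2"),
    m("fdox", "Fd"), m("fdred", "FdH"),
    m("g6p", "C6H12O6P", "glucose-6-phosphate"),
    m("suc", "C12H22O11", "sucrose"),
    m("pyr", "C3H4O3", "pyruvate"), m("ac", "C2H4O2", "acetyl unit"),
    m("akg", "C5H6O5", "2-oxoglutarate"),
    m("glu", "C5H9NO4", "glutamate"), m("gln", "C5H10N2O3", "glutamine"),
    m("lys", "C6H14N2O2", "lysine"), m("etoh", "C2H6O", "ethanol"),
    m("ssa", "C4H6O3", "succinate semialdehyde"),
    m("succ", "C4H6O4", "succinate"), m("fum", "C4H4O4", "fumarate"),
    metabolite("co2_e", name = "external CO2", formula = "CO2",
               charge = 0L, compartment = "e",
               super_compartment = "shared-external"))
}

toy_template <- function(p) {
  cfg <- p$config
  r <- function(id, st, lb = 0, ub = 1000, kind = "enzymatic",
                subsystem = "", name = id) {
    reaction(id, st, lb, ub, kind = kind, subsystem = subsystem,
             name = name)
  }
  lp <- p$letc_photons; cp <- p$cyclic_photons_per_atp
  po <- p$retc_atp_per_o2
  na <- p$nitrogenase_atp; nf <- p$nitrogenase_fdred
  rxns <- list(
    r("letc", c(photon_psii = -lp, h2o = -2, nadp = -2, adp = -3, pi = -3,
                o2 = 1, nadph = 2, atp = 3),
      subsystem = "photosynthesis",
      name = "linear electron transport (PSII-PSI)"),
    r("psi_cyclic", c(photon_psi = -cp, adp = -1, pi = -1, atp = 1),
      subsystem = "photosynthesis", name = "cyclic PSI"),
    r("retc", c(nadph = -2, o2 = -1, adp = -po, pi = -po,
                nadp = 2, h2o = 2, atp = po),
      subsystem = "respiration", name = "respiratory electron transport"),
    r("fnr", c(nadph = -1, fdox = -2, nadp = 1, fdred = 2), lb = -1000,
      subsystem = "electron carriers", name = "ferredoxin-NADP reductase"),
    r("calvin", c(co2 = -6, nadph = -12, atp = -18,
                  g6p = 1, nadp = 12, adp = 18, pi = 17, h2o = 6),
      subsystem = "carbon fixation", name = "Calvin cycle (lumped RuBisCo)"),
    r("suc_synthase", c(g6p = -2, suc = 1, pi = 2, h2o = 1),
      subsystem = "sucrose metabolism"),
    r("invertase", c(suc = -1, h2o = -1, atp = -2,
                     g6p = 2, adp = 2),
      subsystem = "sucrose metabolism", name = "invertase + hexokinase"),
    r("glycolysis", c(g6p = -1, adp = -2, pi = -1, nadp = -2,
                      pyr = 2, atp = 2, nadph = 2),
      subsystem = "glycolysis", name = "glycolysis (G6P isomerase entry)"),
    r("oppp", c(g6p = -1, nadp = -12, h2o = -6,
                co2 = 6, nadph = 12, pi = 1),
      subsystem = "pentose phosphate pathway",
      name = "oxidative PPP (G6P dehydrogenase entry)"),
    r("pdh", c(pyr = -1, nadp = -1, h2o = -1, ac = 1, co2 = 1, nadph = 1),
      subsystem = "TCA", name = "pyruvate dehydrogenase"),
    r("tca_syn", c(pyr = -1, ac = -1, nadp = -1, akg = 1, nadph = 1),
      subsystem = "TCA", name = "TCA to 2-oxoglutarate"),
    r("tca_ox", c(akg = -1, h2o = -5, nadp = -8, adp = -1, pi = -1,
                  co2 = 5, nadph = 8, atp = 1),
      subsystem = "TCA", name = "2-oxoglutarate full oxidation"),
    r("gs", c(glu = -1, nh3 = -1, atp = -1,
              gln = 1, adp = 1, pi = 1, h2o = 1),
      subsystem = "nitrogen assimilation", name = "glutamine synthetase"),
    r("gogat", c(gln = -1, akg = -1, nadph = -1, glu = 2, nadp = 1),
      subsystem = "nitrogen assimilation", name = "GOGAT"),
    r("nitrogenase", c(n2 = -1, fdred = -nf, atp = -na,
                       nh3 = 2, h2 = 1, fdox = nf, adp = na, pi = na),
      subsystem = "nitrogen fixation"),
    r("hydrogenase", c(fdred = -2, fdox = 2, h2 = 1),
      subsystem = "fermentation"),
    r("pdc_adh", c(pyr = -1, nadph = -1, etoh = 1, co2 = 1, nadp = 1),
      subsystem = "fermentation",
      name = "pyruvate decarboxylase + alcohol dehydrogenase"),
    r("lys_syn", c(pyr = -2, glu = -2, nadph = -2, atp = -1,
                   lys = 1, akg = 2, h2o = 2, nadp = 2, adp = 1, pi = 1),
      subsystem = "amino acid biosynthesis",
      name = "aspartate pathway to lysine (lumped)"),
    r("ogdc", c(akg = -1, ssa = 1, co2 = 1),
      subsystem = "TCA", name = "2-oxoglutarate decarboxylase"),
    r("ssadh", c(ssa = -1, nadp = -1, h2o = -1, succ = 1, nadph = 1),
      subsystem = "TCA", name = "succinate-semialdehyde dehydrogenase"),
    r("sdh", c(succ = -1, nadp = -1, fum = 1, nadph = 1),
      subsystem = "TCA", name = "succinate dehydrogenase"),
    r("fum_ox", c(fum = -1, h2o = -1, nadp = -1,
                  pyr = 1, co2 = 1, nadph = 1),
      subsystem = "TCA", name = "fumarate to pyruvate (lumped)"),
    # non-growth ATP dissipation (membrane ATPase futile cycling); without
    # it the linear chain's fixed 3:2 ATP:NADPH output would be binding
    r("atp_maintenance", c(atp = -1, adp = 1, pi = 1),
      subsystem = "maintenance"),
    r("biomass", c(g6p = -p$biomass_g6p, pyr = -p$biomass_pyr,
                   glu = -p$biomass_glu, atp = -p$gam,
                   akg = p$biomass_glu, adp = p$gam, pi = p$gam),
      kind = "biomass", subsystem = "biomass"),
    # exchanges and transports (bounds refined by the constraint set)
    r("photon_psii_uptake", c(photon_psii = 1),
      ub = cfg$photon_ub_per_photosystem, kind = "exchange"),
    r("photon_psi_uptake", c(photon_psi = 1),
      ub = cfg$photon_ub_per_photosystem, kind = "exchange"),
    r("ex_co2_in", c(co2_e = 1), ub = cfg$co2_uptake_ub,
      kind = "exchange", name = "inorganic carbon uptake"),
    r("ex_co2_out", c(co2_e = -1), kind = "exchange"),
    r("co2_uptake_tx", c(co2_e = -1, co2 = 1), kind = "transport"),
    r("co2_release_tx", c(co2 = -1, co2_e = 1), kind = "transport",
      name = "CO2 evolution"),
    r("o2_uptake", c(o2 = 1), kind = "exchange"),
    r("o2_evolution", c(o2 = -1), kind = "exchange"),
    r("n2_uptake", c(n2 = 1), ub = cfg$n2_uptake_ub, kind = "exchange"),
    r("h2o_exchange", c(h2o = 1), lb = -1000, kind = "exchange"),
    # biomass sequesters the phosphate moiety of G6P; media supply Pi
    r("pi_uptake", c(pi = 1), kind = "exchange"),
    r("h2_evolution", c(h2 = -1), kind = "exchange"),
    r("etoh_secretion", c(etoh = -1), kind = "exchange"))
  roles <- list(
    co2_uptake = "ex_co2_in",
    photon_uptake = c("photon_psii_uptake", "photon_psi_uptake"),
    photon_uptake_hc = "photon_psi_uptake__hc",
    n2_uptake = "n2_uptake",
    o2_uptake_hc = "o2_uptake",
    biomass_vc = "biomass__vc",
    biomass_hc = "biomass__hc",
    suc_exchange = "suc_vc_hc_exch",
    glu_exchange = "glu_vc_hc_exch",
    gln_exchange = "gln_hc_vc_exch",
    akg_exchange = "akg_hc_vc_exch",
    co2_evolution_hc = "co2_release_tx__hc",
    g6p_isomerase_hc = "glycolysis__hc",
    g6p_dehydrogenase_hc = "oppp__hc",
    rubisco = "calvin",
    phosphoketolase_hc = character(0),   # lumped away in this network
    gapdh_hc = character(0))             # glycolysis is a single step here
  metabolic_model(toy_metabolite_table(), rxns,
                  objective = "biomass",
                  annotations = list(
                    roles = roles,
                    currency = list(atp = "atp", nadph = "nadph")))
}

toy_deletions <- function() {
  list(heterocyst = c("letc", "calvin", "gogat", "photon_psii_uptake",
                      "co2_uptake_tx", "o2_evolution", "lys_syn",
                      "ogdc", "ssadh", "sdh", "fum_ox"),
       vegetative = c("nitrogenase", "n2_uptake", "o2_uptake",
                      "hydrogenase", "h2_evolution"))
}

#' Generate the synthetic two-cell model and its reference manifest
#'
#' Builds the single-cell template, duplicates it into vegetative and
#' heterocyst super-compartments with the standard deletions, rewires the
#' heterocyst biomass to use fixed nitrogen (NH3) directly instead of the
#' glutamate shuttle, applies the diazotrophic constraint set
#' (including the glutamate/glutamine flux coupling), and returns the
#' model together with a manifest of closed-form reference optima derived
#' from the lumped stoichiometry.
#'
#' @param params a [toy_params()].
#' @return list with elements `model` (a constrained two-cell
#'   `metabolic_model`) and `manifest` (reference values; see Details).
#' @details Manifest entries (all mmol/gDW/h, growth 1/h):
#'   `counts` (declared reaction/metabolite counts); `mu_default`
#'   (maximum growth under the full constraint set); `mu_energetics`
#'   (same with heterocyst turnover released); `nitrogenase_min` and
#'   `glu_gln_exchange` and `sucrose_min_default` (FVA minima with growth
#'   fixed at its optimum); `schemes` (per-scheme maximum growth and FVA
#'   minima for heterocyst sucrose uptake and CO2 evolution);
#'   `mu_letc_minus`; `yield_valerolactam`, `yield_caprolactam`
#'   (theoretical yields with the packaged pathways);
#'   `optforce` (guaranteed product fluxes by budget).
#' @export
make_toy_two_cell <- function(params = toy_params()) {
  p <- params
  cfg <- p$config
  template <- toy_template(p)
  del <- toy_deletions()
  cfg$heterocyst_deletions <- del$heterocyst
  cfg$vegetative_deletions <- del$vegetative
  model <- build_two_cell(template, cfg)
  # heterocysts do not run GOGAT: their biomass takes fixed N directly
  model$stoichiometry[["biomass__hc"]] <-
    c(g6p__hc = -p$biomass_g6p, pyr__hc = -p$biomass_pyr,
      nh3__hc = -p$biomass_glu, atp__hc = -p$gam,
      adp__hc = p$gam, pi__hc = p$gam)
  model <- apply_diazotrophic_constraints(model, cfg)

  manifest <- toy_manifest(p, model)
  chk <- fba(model)
  if (chk$status != "optimal" || chk$objective_value <= 1e-9) {
    stop("parameter combination makes growth infeasible")
  }
  list(model = model, manifest = manifest)
}

# Closed-form reference optima.  Derivations (default parameters):
#  - biomass carbon: 6*1.5 + 3*2 = 15 mmol C/gDW; nitrogen 2.5 mmol/gDW.
#  - With the shared CO2 pool, heterocyst CO2 evolution is re-fixable by
#    the vegetative cell, so carbon in = biomass carbon out at optimum:
#    mu_v + mu_h = co2_ub / 15, mu_h at its lower bound.
#  - N2ase flux = N demand / 2 (2 NH3 per N2) = 2.5*(mu_v+mu_h)/2.
#  - Heterocyst NADPH demand = 4 NAD(P)H per N2 (8 e-); cheapest source
#    per sucrose is any 12-NADPH/G6P route, hence
#    suc_min = (bm_g6p_hc*mu_h + (NADPH_hc - 2*glycolysis_hc)/12)/2.
#  - Scheme metrics at mu_h = 0: NADPH_hc = 5*mu; OPPP route: G6P =
#    5*mu/12, CO2 = 6*G6P; partial-TCA route: G6P = 5*mu/4, CO2 = G6P;
#    sucrose = G6P/2.  The 3x sucrose and 1/2 CO2 fold relations between
#    the incomplete-oxidation and PPP schemes follow directly.
#  - LETC-: heterocyst ATP only from substrate-level phosphorylation
#    (3 ATP/G6P fully oxidised) plus O2-capped respiration; vegetative
#    NADPH capacity (photon_ub/letc_photons*2) binds:
#    (12*(bm_g6p+bm_pyr/2) + bm_glu - bm_pyr)*mu + 12*g = cap,
#    g = (atp_hc_demand*mu - retc_atp)/3.
#  - Theoretical yields: valerolactam is NADPH-capped at cap/16
#    (16 NADPH per lactam, counting Calvin regeneration of the G6P and
#    the heterocyst demand), caprolactam is carbon-capped at co2_ub/6.
toy_manifest <- function(p, model) {
  cfg <- p$config
  c_bm <- 6 * p$biomass_g6p + 3 * p$biomass_pyr
  n_bm <- p$biomass_glu
  hc_lb <- cfg$heterocyst_biomass_lb_fraction * cfg$mu_exp
  mu_tot <- cfg$co2_uptake_ub / c_bm
  mu_default <- mu_tot - hc_lb
  nadph_per_n2 <- p$nitrogenase_fdred / 2
  n2_min <- n_bm * mu_tot / 2
  nadph_hc_default <- nadph_per_n2 * n2_min
  glyc_hc <- p$biomass_pyr / 2 * hc_lb
  g6p_hc_default <- (p$biomass_g6p + p$biomass_pyr / 2) * hc_lb +
    (nadph_hc_default - p$glycolysis_atp_per_g6p * glyc_hc) /
    p$ppp_nadph_per_g6p
  suc_min_default <- g6p_hc_default / 2

  mu_e <- mu_tot                                   # heterocyst turnover off
  nadph_hc_e <- nadph_per_n2 * n_bm * mu_e / 2     # = 5 mu_e (defaults)
  g6p_oppp <- nadph_hc_e / p$ppp_nadph_per_g6p
  g6p_partial <- nadph_hc_e / 4                    # 4 NADPH per G6P
  schemes <- data.frame(
    scheme = c("default", "LETC_minus", "OPPP_LETC", "GLY_TCA_LETC",
               "GLY_TCA_LETC_1", "GLY_TCA_LETC_2"),
    max_growth = NA_real_, min_sucrose_uptake_hc = NA_real_,
    min_co2_evolution_hc = NA_real_, stringsAsFactors = FALSE)
  rownames(schemes) <- schemes$scheme
  nadph_cap <- cfg$photon_ub_per_photosystem / p$letc_photons * 2
  # Without heterocyst light, ATP reaches the heterocyst only through
  # sucrose (substrate-level phosphorylation) while the vegetative cell
  # juggles two separate photon caps (PSII-backed linear chain and
  # cyclic PSI); the LP optimum mixes complete oxidation with
  # 2-oxoglutarate export and is not a one-line closed form.  The
  # constants below are the exact optimum for the default parameters,
  # independently verified against a second LP implementation; they are
  # reported as NA for non-default parameters.
  default_p <- isTRUE(all.equal(
    unlist(p[c("nitrogenase_atp", "nitrogenase_fdred", "letc_photons",
               "cyclic_photons_per_atp", "retc_atp_per_o2", "gam",
               "biomass_g6p", "biomass_pyr", "biomass_glu")]),
    c(nitrogenase_atp = 16, nitrogenase_fdred = 8, letc_photons = 8,
      cyclic_photons_per_atp = 2, retc_atp_per_o2 = 4, gam = 30,
      biomass_g6p = 1.5, biomass_pyr = 2, biomass_glu = 2.5))) &&
    isTRUE(all.equal(cfg$co2_uptake_ub, 8.5)) &&
    isTRUE(all.equal(cfg$photon_ub_per_photosystem, 100)) &&
    isTRUE(all.equal(cfg$culture_o2_uptake * cfg$heterocyst_fraction,
                     0.063))
  mu_letc <- if (default_p) 0.212036816459 else NA_real_
  schemes["default", -1] <- c(mu_e, g6p_oppp / 2, g6p_partial)
  schemes["LETC_minus", -1] <-
    if (default_p) c(mu_letc, 2.202218727501, 4.976391909876) else
      c(NA_real_, NA_real_, NA_real_)
  schemes["OPPP_LETC", -1] <- c(mu_e, g6p_oppp / 2, 6 * g6p_oppp)
  schemes["GLY_TCA_LETC", -1] <- c(mu_e, g6p_oppp / 2, g6p_partial)
  schemes["GLY_TCA_LETC_1", -1] <- c(mu_e, g6p_oppp / 2, 6 * g6p_oppp)
  schemes["GLY_TCA_LETC_2", -1] <- c(mu_e, g6p_partial / 2, g6p_partial)

  yield_v <- nadph_cap / 16
  yield_c <- cfg$co2_uptake_ub / 6
  list(
    counts = list(reactions = nrow(model$reactions),
                  metabolites = nrow(model$metabolites),
                  vegetative_templates = 30L, heterocyst_templates = 24L,
                  shared_templates = 19L),
    mu_default = mu_default,
    mu_energetics = mu_e,
    nitrogenase_min = n2_min,
    glu_gln_exchange = n_bm * mu_default,
    sucrose_min_default = suc_min_default,
    schemes = schemes,
    mu_letc_minus = mu_letc,
    yield_valerolactam = yield_v,
    yield_caprolactam = yield_c,
    optforce = list(
      # guaranteed product fluxes by intervention budget (defaults; the
      # k = 2 valerolactam value, glycolysis + GOGAT upregulation, was
      # frozen from the exhaustive-enumeration oracle)
      valerolactam = list(
        k1 = 0,
        k2 = if (default_p) 1.437133906270 else NA_real_,
        k2_members = c("glycolysis__vc", "gogat__vc")),
      caprolactam = list(
        k1 = 0, k2 = 0, k3 = 0.9 * yield_c,
        k3_members = c("calvin__vc", "glycolysis__vc", "paaJ__vc"))))
}

#' Measured-flux-range fixture for the wild-type space
#'
#' Runs parsimonious FBA on the constrained toy model and returns +/-10%
#' ranges around the fluxes of the vegetative central-carbon reactions
#' that carry measurable flux (Calvin cycle, glycolysis, sucrose
#' synthesis) -- the style of range a 13C flux study of a phototroph
#' reports.  Deterministic.
#'
#' @param model the constrained toy model from [make_toy_two_cell()].
#' @return a `flux_ranges` suitable for [wild_type_flux_space()].
#' @export
make_mfa_fixture <- function(model) {
  sol <- pfba(model)
  if (sol$status != "optimal") stop("toy model pFBA failed")
  watch <- c("calvin__vc", "glycolysis__vc", "suc_synthase__vc")
  f <- sol$fluxes[watch]
  keep <- abs(f) > 1e-6
  new_flux_ranges(data.frame(reaction = watch[keep],
                             min = 0.9 * f[keep], max = 1.1 * f[keep],
                             stringsAsFactors = FALSE),
                  context = list(source = "toy pFBA +/-10%"))
}

#' Packaged production-pathway fixtures
#'
#' Two carbon/nitrogen-balanced pathway specifications for the vegetative
#' cell: the lysine-derived 5-aminovalerate route to valerolactam
#' (lysine 2-monooxygenase davB, 5-aminopentanamidase davA, lactam
#' synthase) and the adipyl route to caprolactam (3-oxoadipyl thiolase
#' paaJ, reductase paaH, dehydratase paaF, enoyl reductase ter, aldehyde
#' dehydrogenase, aminotransferase, lactam synthase), each ending in a
#' product exchange.  CoA carriers are lumped out; lactam cyclisation is
#' ATP-dependent.
#'
#' @return named list of two [pathway_spec()] objects
#'   (`five_aminovalerate`, `adipyl_coa`).
#' @export
make_pathway_fixtures <- function() {
  m <- function(id, formula, name) {
    metabolite(id, name = name, formula = formula, charge = 0L,
               compartment = "c", super_compartment = "vegetative")
  }
  r <- function(id, st, kind = "enzymatic", name = id) {
    reaction(id, st, 0, 1000, kind = kind, name = name,
             subsystem = "production pathway")
  }
  five <- pathway_spec(
    "five_aminovalerate",
    rbind(m("aptm__vc", "C5H12N2O", "5-aminopentanamide"),
          m("aptn__vc", "C5H11NO2", "5-aminopentanoate"),
          m("vlac__vc", "C5H9NO", "valerolactam")),
    list(
      r("davB__vc", c(lys__vc = -1, o2__vc = -1, aptm__vc = 1,
                      co2__vc = 1, h2o__vc = 1),
        name = "lysine 2-monooxygenase (davB)"),
      r("davA__vc", c(aptm__vc = -1, h2o__vc = -1, aptn__vc = 1,
                      nh3__vc = 1),
        name = "5-aminopentanamidase (davA)"),
      r("ls_v__vc", c(aptn__vc = -1, atp__vc = -1, vlac__vc = 1,
                      h2o__vc = 1, adp__vc = 1, pi__vc = 1),
        name = "lactam synthase"),
      r("ex_vlac", c(vlac__vc = -1), kind = "exchange",
        name = "valerolactam secretion")),
    product_exchange = "ex_vlac")
  adip <- pathway_spec(
    "adipyl_coa",
    rbind(m("oadp__vc", "C6H8O5", "3-oxoadipate (CoA lumped)"),
          m("hadp__vc", "C6H10O5", "3-hydroxyadipate"),
          m("dhad__vc", "C6H8O4", "2,3-dehydroadipate"),
          m("adip__vc", "C6H10O4", "adipate"),
          m("adsa__vc", "C6H10O3", "adipate semialdehyde"),
          m("acap__vc", "C6H13NO2", "6-aminocaproate"),
          m("clac__vc", "C6H11NO", "caprolactam")),
    list(
      r("paaJ__vc", c(succ__vc = -1, ac__vc = -1, oadp__vc = 1,
                      h2o__vc = 1),
        name = "3-oxoadipyl thiolase (paaJ)"),
      r("paaH__vc", c(oadp__vc = -1, nadph__vc = -1, hadp__vc = 1,
                      nadp__vc = 1),
        name = "3-hydroxyadipyl reductase (paaH)"),
      r("paaF__vc", c(hadp__vc = -1, dhad__vc = 1, h2o__vc = 1),
        name = "dehydratase (paaF)"),
      r("ter__vc", c(dhad__vc = -1, nadph__vc = -1, adip__vc = 1,
                     nadp__vc = 1),
        name = "enoyl reductase (ter)"),
      r("aldh__vc", c(adip__vc = -1, atp__vc = -1, nadph__vc = -1,
                      adsa__vc = 1, adp__vc = 1, pi__vc = 1,
                      nadp__vc = 1, h2o__vc = 1),
        name = "aldehyde dehydrogenase (reverse)"),
      r("at__vc", c(adsa__vc = -1, glu__vc = -1, acap__vc = 1,
                    akg__vc = 1),
        name = "aminotransferase"),
      r("ls_c__vc", c(acap__vc = -1, atp__vc = -1, clac__vc = 1,
                      h2o__vc = 1, adp__vc = 1, pi__vc = 1),
        name = "lactam synthase"),
      r("ex_clac", c(clac__vc = -1), kind = "exchange",
        name = "caprolactam secretion")),
    product_exchange = "ex_clac")
  list(five_aminovalerate = five, adipyl_coa = adip)
}

#' Write a pathway fixture in the tabular reaction dialect
#' @param spec a [pathway_spec()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pathway_fixture <- function(spec, path) {
  mm <- metabolic_model(
    rbind(spec$metabolites,
          do.call(rbind, lapply(setdiff(
            unique(unlist(lapply(spec$reactions,
                                 function(r) names(r$stoichiometry)))),
            spec$metabolites$id), metabolite))),
    spec$reactions)
  write_model(mm, path, format = "tabular")
  invisible(path)
}
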