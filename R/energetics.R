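# Heterocyst ATP/NAD(P)H source analysis.
#
# Nitrogen fixation demands ATP and reducing equivalents in a 4:1 ratio
# (16 ATP and 4 NAD(P)H, i.e. 8 electrons, per N2).  The scenarios below
# force the heterocyst to meet that demand through specific routes by
# blocking alternatives:
#
#   default       unmodified network
#   LETC_minus    heterocyst photon uptake = 0 (no light-driven electron
#                 transport; cyclic PSI dies with it)
#   OPPP_LETC     G6P and pentose-phosphate intermediates barred from
#                 glycolysis (G6P isomerase, phosphoketolases, GAP
#                 dehydrogenase blocked in the heterocyst): NADPH must
#                 come from the oxidative PPP, ATP from PSI
#   GLY_TCA_LETC  oxidative-PPP entry (G6P dehydrogenase) and
#                 phosphoketolases blocked: reducing power from
#                 glycolysis + TCA
#   GLY_TCA_LETC_1  as GLY_TCA_LETC, plus the 2-oxoglutarate export to
#                 the vegetative cell capped at the GLY_TCA_LETC FVA
#                 minimum (complete oxidation)
#   GLY_TCA_LETC_2  as GLY_TCA_LETC, plus heterocyst CO2 evolution capped
#                 at the GLY_TCA_LETC FVA minimum (incomplete oxidation,
#                 2-oxoglutarate exported)
#
# For this analysis the heterocyst is assumed to have no macromolecular
# turnover: its biomass lower bound is released to 0
# (zero_heterocyst_turnover = TRUE).  Scenario edits address reactions
# through the model's role aliases, so the same code drives any model
# whose roles are mapped.

SCENARIO_NAMES <- c("default", "LETC_minus", "OPPP_LETC", "GLY_TCA_LETC",
                    "GLY_TCA_LETC_1", "GLY_TCA_LETC_2")

#' Define an energy-scheme scenario
#'
#' @param name one of `"default"`, `"LETC_minus"`, `"OPPP_LETC"`,
#'   `"GLY_TCA_LETC"`, `"GLY_TCA_LETC_1"`, `"GLY_TCA_LETC_2"`.
#' @param bound_edits optional data.frame (`reaction`, `lb`, `ub`) of
#'   extra edits applied after the scheme's own.
#' @param zero_heterocyst_turnover release the heterocyst biomass lower
#'   bound to 0 (default `TRUE` for this analysis).
#' @return object of class `scenario`.
#' @export
scenario <- function(name, bound_edits = NULL,
                     zero_heterocyst_turnover = TRUE) {
  name <- match.arg(name, SCENARIO_NAMES)
  structure(list(name = name, bound_edits = bound_edits,
                 zero_heterocyst_turnover = zero_heterocyst_turnover),
            class = "scenario")
}

# roles blocked (ub = lb = 0) by each scheme; `allow_missing` roles are
# declared-absent-tolerant because reduced networks may lump them away.
scenario_blocked_roles <- function(name) {
  switch(name,
    default = character(0),
    LETC_minus = "photon_uptake_hc",
    OPPP_LETC = c("g6p_isomerase_hc", "phosphoketolase_hc", "gapdh_hc"),
    GLY_TCA_LETC = c("g6p_dehydrogenase_hc", "phosphoketolase_hc"),
    GLY_TCA_LETC_1 = c("g6p_dehydrogenase_hc", "phosphoketolase_hc"),
    GLY_TCA_LETC_2 = c("g6p_dehydrogenase_hc", "phosphoketolase_hc"))
}

scenario_base <- function(name) {
  switch(name,
         GLY_TCA_LETC_1 = ,
         GLY_TCA_LETC_2 = "GLY_TCA_LETC",
         NA_character_)
}

#' Apply a scenario's bound edits to a model
#'
#' Blocks the scheme's roles, optionally releases heterocyst biomass, and
#' for the `GLY_TCA_LETC_1`/`_2` variants caps the 2-oxoglutarate export /
#' heterocyst CO2 evolution at the base scheme's FVA minimum, which must
#' be supplied through `base_ranges` (see [evaluate_scheme()], which
#' resolves it automatically).
#'
#' @param model a two-cell `metabolic_model` with role annotations.
#' @param scn a [scenario()].
#' @param base_ranges `flux_ranges` of the base `GLY_TCA_LETC` scheme at
#'   its growth optimum; required by the `_1`/`_2` variants.
#' @return the edited model.
#' @export
apply_scenario <- function(model, scn, base_ranges = NULL) {
  stopifnot(inherits(scn, "scenario"))
  roles_blocked <- scenario_blocked_roles(scn$name)
  tolerant <- c("phosphoketolase_hc", "gapdh_hc")
  for (role in roles_blocked) {
    ids <- resolve_role(model, role, allow_missing = role %in% tolerant)
    if (length(ids) == 0 && !role %in% tolerant) {
      stop("scenario ", scn$name, ": no reaction fulfils role '", role, "'")
    }
    if (length(ids) > 0) model <- set_bounds(model, ids, lb = 0, ub = 0)
  }
  if (scn$name %in% c("GLY_TCA_LETC_1", "GLY_TCA_LETC_2")) {
    if (is.null(base_ranges)) {
      stop("scenario ", scn$name, " needs base_ranges from the ",
           scenario_base(scn$name), " scheme (solve it first)")
    }
    role <- if (scn$name == "GLY_TCA_LETC_1") "akg_exchange" else
      "co2_evolution_hc"
    ids <- resolve_role(model, role)
    cap <- base_ranges$ranges$min[match(ids[1], base_ranges$ranges$reaction)]
    if (is.na(cap)) stop("base_ranges lacks the ", role, " reaction")
    model <- set_bounds(model, ids[1], ub = cap)
  }
  if (isTRUE(scn$zero_heterocyst_turnover)) {
    model <- set_bounds(model, resolve_role(model, "biomass_hc"), lb = 0)
  }
  if (!is.null(scn$bound_edits)) {
    model <- set_bounds(model, scn$bound_edits$reaction,
                        lb = scn$bound_edits$lb, ub = scn$bound_edits$ub)
  }
  model
}

#' Evaluate an ATP/NAD(P)H scheme
#'
#' Applies the scenario, maximises growth, then computes FVA minima for
#' heterocyst sucrose uptake and heterocyst CO2 evolution with growth
#' fixed at its maximum.  For the `GLY_TCA_LETC_1`/`_2` variants the base
#' `GLY_TCA_LETC` scheme is evaluated first to obtain the derived caps.
#'
#' @param model a two-cell `metabolic_model` with role annotations.
#' @param scn a [scenario()] or scenario name.
#' @return a `scheme_metrics` list: `name`, `max_growth`,
#'   `min_sucrose_uptake_hc`, `min_co2_evolution_hc`, `feasible`.
#' @export
evaluate_scheme <- function(model, scn) {
  if (is.character(scn)) scn <- scenario(scn)
  base_ranges <- NULL
  base_name <- scenario_base(scn$name)
  if (!is.na(base_name)) {
    base_model <- apply_scenario(
      model, scenario(base_name,
                      zero_heterocyst_turnover =
                        scn$zero_heterocyst_turnover))
    sol <- fba(base_model)
    if (sol$status != "optimal") {
      stop("base scheme ", base_name, " infeasible")
    }
    base_targets <- c(resolve_role(model, "akg_exchange")[1],
                      resolve_role(model, "co2_evolution_hc")[1])
    base_ranges <- fva(base_model, targets = base_targets,
                       fix_objective = TRUE)
  }
  m <- apply_scenario(model, scn, base_ranges = base_ranges)
  sol <- fba(m)
  if (sol$status != "optimal") {
    return(structure(list(name = scn$name, max_growth = NA_real_,
                          min_sucrose_uptake_hc = NA_real_,
                          min_co2_evolution_hc = NA_real_,
                          feasible = FALSE),
                     class = "scheme_metrics"))
  }
  targets <- c(suc = resolve_role(m, "suc_exchange")[1],
               co2 = resolve_role(m, "co2_evolution_hc")[1])
  rng <- fva(m, targets = unname(targets), fix_objective = TRUE)
  structure(list(name = scn$name,
                 max_growth = sol$objective_value,
                 min_sucrose_uptake_hc =
                   rng$ranges$min[rng$ranges$reaction == targets[["suc"]]],
                 min_co2_evolution_hc =
                   rng$ranges$min[rng$ranges$reaction == targets[["co2"]]],
                 feasible = TRUE),
            class = "scheme_metrics")
}

#' @export
print.scheme_metrics <- function(x, ...) {
  cat(sprintf("scheme %-15s growth %.6g  min suc %.6g  min CO2 %.6g\n",
              x$name, x$max_growth, x$min_sucrose_uptake_hc,
              x$min_co2_evolution_hc))
  invisible(x)
}

#' Evaluate all standard schemes
#'
#' @param model a two-cell `metabolic_model` with role annotations.
#' @param scenarios scenario names to run.
#' @return data.frame, one row per scheme, with the three metrics.
#' @export
evaluate_all_schemes <- function(model, scenarios = SCENARIO_NAMES) {
  rows <- lapply(scenarios, function(nm) {
    m <- evaluate_scheme(model, nm)
    data.frame(scheme = m$name, max_growth = m$max_growth,
               min_sucrose_uptake_hc = m$min_sucrose_uptake_hc,
               min_co2_evolution_hc = m$min_co2_evolution_hc,
               feasible = m$feasible, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ATP to NAD(P)H turnover ratio within a super-compartment
#'
#' Computes the ratio of ATP turnover to combined NADH + NADPH turnover in
#' one cell of a two-cell model, from a (parsimonious) FBA solution, using
#' [metabolite_turnover()].  Which metabolite ids count as ATP/NAD(P)H is
#' read from `model$annotations$currency` (a list with elements `atp`,
#' `nadph`, and optionally `nadh`, holding template metabolite ids).
#'
#' @param model a two-cell `metabolic_model`.
#' @param solution an optimal `flux_solution` (pFBA recommended, so that
#'   futile cycles do not inflate turnover).
#' @param compartment `"vc"` or `"hc"`.
#' @return positive ratio, or `NA` (with a warning) if NAD(P)H turnover
#'   is zero.
#' @export
atp_nadph_ratio <- function(model, solution, compartment = c("hc", "vc")) {
  compartment <- match.arg(compartment)
  cur <- model$annotations$currency
  if (is.null(cur) || is.null(cur$atp) || is.null(cur$nadph)) {
    stop("model does not declare currency metabolites ",
         "(annotations$currency with elements atp, nadph)")
  }
  suffixed <- function(ids) {
    out <- paste0(ids, "__", compartment)
    out[out %in% model$metabolites$id]
  }
  atp_ids <- suffixed(cur$atp)
  nad_ids <- suffixed(c(cur$nadph, cur$nadh))
  atp_t <- sum(vapply(atp_ids, function(m)
    metabolite_turnover(model, solution, m), numeric(1)))
  nad_t <- sum(vapply(nad_ids, function(m)
    metabolite_turnover(model, solution, m), numeric(1)))
  if (nad_t <= 1e-12) {
    warning("NAD(P)H turnover is zero in ", compartment,
            "; ratio undefined")
    return(NA_real_)
  }
  atp_t / nad_t
}
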