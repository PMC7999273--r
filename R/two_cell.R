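# Construction of the two-super-compartment diazotrophic model and the
# standard diazotrophic constraint set.
#
# The physiology encoded here: in a filament growing on N2, ~9% of cells
# differentiate into heterocysts, which lose photosystem II, RuBisCo and
# GOGAT but gain nitrogenase; the vegetative cells fix CO2 and export
# sucrose and glutamate to the heterocyst, which returns glutamine (the
# nitrogen carrier) and 2-oxoglutarate.  Only vegetative cells divide, so
# the vegetative biomass drain is the FBA objective; the heterocyst keeps
# a biomass reaction as a macromolecule-turnover proxy with a lower bound
# of 10% of the experimental growth rate.

#' Configuration of a two-cell diazotrophic model
#'
#' Defaults encode the standard diazotrophic simulation conditions:
#' inorganic-carbon uptake capped at 8.5 mmol/gDW/h (the minimum required
#' for the experimental growth rate), photon uptake capped at
#' 100 mmol/gDW/h per photosystem (restricts futile cycles without
#' limiting biomass yield), N2 uptake at a non-limiting 10 mmol/gDW/h,
#' heterocyst O2 uptake derived from a culture-level uptake of
#' 0.7 mmol/gDW/h and a 9% heterocyst frequency, an experimental growth
#' rate of 0.1824 1/h (3.8 h doubling time), and a heterocyst biomass
#' lower bound of 10% of that rate.
#'
#' @param heterocyst_deletions template reaction ids absent from the
#'   heterocyst (defaults name roles, resolved by the builder: photosystem
#'   II/linear electron transport, RuBisCo, GOGAT).
#' @param vegetative_deletions template reaction ids absent from the
#'   vegetative cell (default: nitrogenase).
#' @param intercell_exchanges data.frame with columns `metabolite`,
#'   `direction` (`"vc_to_hc"` or `"hc_to_vc"`).
#' @param co2_uptake_ub inorganic carbon (CO2/bicarbonate) uptake upper
#'   bound, mmol/gDW/h.
#' @param photon_ub_per_photosystem photon uptake upper bound per
#'   photosystem, mmol/gDW/h.
#' @param n2_uptake_ub N2 uptake upper bound, mmol/gDW/h.
#' @param mu_exp experimental growth rate, 1/h.
#' @param heterocyst_biomass_lb_fraction heterocyst biomass lower bound as
#'   a fraction of `mu_exp`.
#' @param culture_o2_uptake culture-level O2 uptake, mmol/gDW/h.
#' @param heterocyst_fraction fraction of cells that are heterocysts.
#' @param couple_glu_gln enforce equality of the glutamate (vc to hc) and
#'   glutamine (hc to vc) inter-cell fluxes, so glutamate cannot serve as
#'   a heterocyst carbon source.
#' @return object of class `two_cell_config`.
#' @export
two_cell_config <- function(heterocyst_deletions = NULL,
                            vegetative_deletions = NULL,
                            intercell_exchanges = NULL,
                            co2_uptake_ub = 8.5,
                            photon_ub_per_photosystem = 100,
                            n2_uptake_ub = 10,
                            mu_exp = 0.1824,
                            heterocyst_biomass_lb_fraction = 0.1,
                            culture_o2_uptake = 0.7,
                            heterocyst_fraction = 0.09,
                            couple_glu_gln = TRUE) {
  if (is.null(intercell_exchanges)) {
    intercell_exchanges <- data.frame(
      metabolite = c("suc", "glu", "gln", "akg"),
      direction = c("vc_to_hc", "vc_to_hc", "hc_to_vc", "hc_to_vc"),
      stringsAsFactors = FALSE)
  }
  bounds <- c(co2_uptake_ub, photon_ub_per_photosystem, n2_uptake_ub,
              mu_exp, heterocyst_biomass_lb_fraction, culture_o2_uptake)
  if (any(bounds < 0)) stop("all bounds must be >= 0")
  if (heterocyst_fraction <= 0 || heterocyst_fraction >= 1) {
    stop("heterocyst_fraction must lie in (0, 1)")
  }
  structure(list(heterocyst_deletions = heterocyst_deletions,
                 vegetative_deletions = vegetative_deletions,
                 intercell_exchanges = intercell_exchanges,
                 co2_uptake_ub = co2_uptake_ub,
                 photon_ub_per_photosystem = photon_ub_per_photosystem,
                 n2_uptake_ub = n2_uptake_ub,
                 mu_exp = mu_exp,
                 heterocyst_biomass_lb_fraction =
                   heterocyst_biomass_lb_fraction,
                 culture_o2_uptake = culture_o2_uptake,
                 heterocyst_fraction = heterocyst_fraction,
                 couple_glu_gln = couple_glu_gln),
            class = "two_cell_config")
}

#' Write/read a two-cell configuration as a flat key-value file
#' @param config a `two_cell_config`.
#' @param path file path.
#' @return `path` (write) or a `two_cell_config` (read).
#' @export
write_two_cell_config <- function(config, path) {
  scal <- config[!names(config) %in%
                 c("heterocyst_deletions", "vegetative_deletions",
                   "intercell_exchanges")]
  lines <- c(
    vapply(names(scal), function(k) paste0(k, " = ", scal[[k]]),
           character(1)),
    paste0("heterocyst_deletions = ",
           paste(config$heterocyst_deletions, collapse = ",")),
    paste0("vegetative_deletions = ",
           paste(config$vegetative_deletions, collapse = ",")),
    paste0("intercell_exchanges = ",
           paste(config$intercell_exchanges$metabolite,
                 config$intercell_exchanges$direction,
                 sep = ":", collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_two_cell_config
#' @export
read_two_cell_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(trimws(lines))], "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(x) {
    if (length(x) < 2) "" else x[2]
  }), vapply(kv, `[[`, character(1), 1))
  splitc <- function(s) if (!nzchar(s)) NULL else strsplit(s, ",")[[1]]
  ice <- splitc(vals$intercell_exchanges)
  ice_df <- NULL
  if (!is.null(ice)) {
    parts <- strsplit(ice, ":")
    ice_df <- data.frame(metabolite = vapply(parts, `[[`, character(1), 1),
                         direction = vapply(parts, `[[`, character(1), 2),
                         stringsAsFactors = FALSE)
  }
  two_cell_config(
    heterocyst_deletions = splitc(vals$heterocyst_deletions),
    vegetative_deletions = splitc(vals$vegetative_deletions),
    intercell_exchanges = ice_df,
    co2_uptake_ub = as.numeric(vals$co2_uptake_ub),
    photon_ub_per_photosystem = as.numeric(vals$photon_ub_per_photosystem),
    n2_uptake_ub = as.numeric(vals$n2_uptake_ub),
    mu_exp = as.numeric(vals$mu_exp),
    heterocyst_biomass_lb_fraction =
      as.numeric(vals$heterocyst_biomass_lb_fraction),
    culture_o2_uptake = as.numeric(vals$culture_o2_uptake),
    heterocyst_fraction = as.numeric(vals$heterocyst_fraction),
    couple_glu_gln = as.logical(vals$couple_glu_gln))
}

#' Heterocyst oxygen-uptake bound
#'
#' Scales a culture-level O2 uptake rate by the heterocyst frequency to
#' give the per-gDW upper bound on heterocyst O2 uptake: with the default
#' 0.7 mmol/gDW/h culture uptake and 9% heterocysts this is
#' 0.063 mmol/gDW/h.
#'
#' @param culture_uptake culture O2 uptake, mmol/gDW/h.
#' @param heterocyst_fraction fraction of cells that are heterocysts.
#' @return upper bound in mmol/gDW/h.
#' @export
heterocyst_o2_bound <- function(culture_uptake, heterocyst_fraction) {
  if (culture_uptake < 0 || heterocyst_fraction < 0) {
    stop("inputs must be >= 0")
  }
  if (heterocyst_fraction > 1) stop("heterocyst_fraction must be <= 1")
  culture_uptake * heterocyst_fraction
}

#' Growth rate from doubling time
#'
#' `ln(2) / td`; a 3.8 h doubling time gives 0.1824 1/h.
#'
#' @param td doubling time in hours (> 0).
#' @return specific growth rate, 1/h.
#' @export
growth_rate_from_doubling_time <- function(td) {
  if (any(td <= 0)) stop("doubling time must be > 0")
  log(2) / td
}

#' Build a biomass formation reaction from a macromolecular composition
#'
#' Mass fractions are rescaled to sum to 1 g per gDW; each precursor
#' coefficient (mmol/gDW) is its rescaled mass fraction divided by its
#' molar mass (g/mmol).  The reaction consumes the precursors plus
#' growth-associated ATP maintenance and produces 1 g of biomass.
#'
#' @param comp data.frame with columns `precursor` (metabolite id),
#'   `mass_fraction` (g/g, rescaled internally), `molar_mass`
#'   (g/mmol), and optionally `byproduct`/`byproduct_coef` for species
#'   returned per mmol of precursor consumed (e.g. 2-oxoglutarate returned
#'   by amino-acid incorporation).
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @param atp,adp,pi metabolite ids used for the maintenance term.
#' @param biomass_id id of the produced biomass species (coefficient +1,
#'   i.e. 1 g); use `NULL` for a pure drain.
#' @param id reaction id.
#' @return a [reaction()] of kind `"biomass"`.
#' @export
build_biomass_reaction <- function(comp, gam = 30, atp = "atp", adp = "adp",
                                   pi = "pi", biomass_id = "biomass",
                                   id = "biomass_rxn") {
  stopifnot(all(c("precursor", "mass_fraction", "molar_mass") %in%
                names(comp)))
  if (any(comp$mass_fraction < 0) || any(comp$molar_mass <= 0)) {
    stop("mass fractions must be >= 0 and molar masses > 0")
  }
  tot <- sum(comp$mass_fraction)
  if (tot <= 0) stop("mass fractions sum to zero")
  frac <- comp$mass_fraction / tot               # rescale to 1 g total
  stopifnot(abs(sum(frac) - 1) < 1e-9)
  coef <- frac / comp$molar_mass                 # mmol per gDW
  st <- stats::setNames(-coef, comp$precursor)
  if (!is.null(comp$byproduct)) {
    for (i in seq_len(nrow(comp))) {
      bp <- comp$byproduct[i]
      if (!is.na(bp) && nzchar(bp)) {
        cc <- if (is.null(comp$byproduct_coef)) 1 else comp$byproduct_coef[i]
        st[bp] <- (if (is.na(st[bp])) 0 else st[bp]) + cc * coef[i]
      }
    }
  }
  if (gam > 0) {
    st[atp] <- (if (is.na(st[atp])) 0 else st[atp]) - gam
    st[adp] <- (if (is.na(st[adp])) 0 else st[adp]) + gam
    st[pi] <- (if (is.na(st[pi])) 0 else st[pi]) + gam
  }
  if (!is.null(biomass_id)) st[biomass_id] <- 1
  reaction(id, st, lower_bound = 0, upper_bound = 1000, kind = "biomass",
           subsystem = "biomass")
}

# metabolite ids referenced by a set of reactions
mets_used <- function(stoich) unique(unlist(lapply(stoich, names)))

#' Build a two-cell model from a single-cell template
#'
#' Every template reaction is duplicated with `__vc` and `__hc` suffixes
#' (metabolite ids likewise), except reactions touching only
#' shared-external metabolites, which are added once.  Cell-specific
#' deletions are then removed and the configured inter-cell exchange
#' reactions added (`<met>_vc_hc_exch` / `<met>_hc_vc_exch`, irreversible
#' in the stated direction).  The objective becomes the vegetative biomass
#' reaction.  Role aliases recorded in `template$annotations$roles`
#' (template reaction ids) are rewritten to the suffixed ids.
#'
#' @param template a single-cell `metabolic_model`.
#' @param config a [two_cell_config()]; deletion sets must name template
#'   reaction ids.
#' @return a two-cell `metabolic_model`.
#' @export
build_two_cell <- function(template, config = two_cell_config()) {
  rxn_ids <- template$reactions$id
  unknown <- setdiff(c(config$heterocyst_deletions,
                       config$vegetative_deletions), rxn_ids)
  if (length(unknown) > 0) {
    stop("deletion id(s) not in template: ", paste(unknown, collapse = ", "))
  }
  shared_mets <- template$metabolites$id[
    template$metabolites$super_compartment == "shared-external"]
  cellular <- setdiff(template$metabolites$id, shared_mets)

  suffix_st <- function(st, sfx) {
    nm <- names(st)
    nm[nm %in% cellular] <- paste0(nm[nm %in% cellular], sfx)
    stats::setNames(as.numeric(st), nm)
  }
  mets <- list()
  for (cell in c("vc", "hc")) {
    sel <- template$metabolites[template$metabolites$id %in% cellular, ,
                                drop = FALSE]
    sel$id <- paste0(sel$id, "__", cell)
    sel$super_compartment <- if (cell == "vc") "vegetative" else "heterocyst"
    mets[[cell]] <- sel
  }
  mets_shared <- template$metabolites[
    template$metabolites$id %in% shared_mets, , drop = FALSE]
  metabolites <- rbind(mets$vc, mets$hc, mets_shared)

  rxns <- list()
  stoich <- list()
  for (i in seq_len(nrow(template$reactions))) {
    id <- template$reactions$id[i]
    st <- template$stoichiometry[[id]]
    only_shared <- all(names(st) %in% shared_mets)
    cells <- if (only_shared) "shared" else c("vc", "hc")
    for (cell in cells) {
      if (cell == "hc" && id %in% config$heterocyst_deletions) next
      if (cell == "vc" && id %in% config$vegetative_deletions) next
      row <- template$reactions[i, , drop = FALSE]
      if (cell != "shared") {
        row$id <- paste0(id, "__", cell)
        stoich[[row$id]] <- suffix_st(st, paste0("__", cell))
      } else {
        stoich[[row$id]] <- st
      }
      rxns[[length(rxns) + 1L]] <- row
    }
  }
  rxn_df <- do.call(rbind, rxns)
  rownames(rxn_df) <- NULL

  # inter-cell exchanges
  ice <- config$intercell_exchanges
  for (i in seq_len(nrow(ice))) {
    met <- ice$metabolite[i]
    dir <- ice$direction[i]
    from <- if (dir == "vc_to_hc") "vc" else "hc"
    to <- if (dir == "vc_to_hc") "hc" else "vc"
    for (cell in c(from, to)) {
      mid <- paste0(met, "__", cell)
      if (!mid %in% metabolites$id) {
        stop("inter-cell exchange metabolite absent in ", cell, ": ", met)
      }
    }
    rid <- paste0(met, "_", from, "_", to, "_exch")
    st <- stats::setNames(c(-1, 1),
                          paste0(met, "__", c(from, to)))
    rr <- reaction(rid, st, lower_bound = 0, upper_bound = 1000,
                   kind = "intercell-exchange",
                   subsystem = "intercell exchange")
    rxn_df <- rbind(rxn_df, rr$row)
    stoich[[rid]] <- rr$stoichiometry
  }

  # objective: vegetative biomass
  bio <- rxn_df$id[rxn_df$kind == "biomass" & grepl("__vc$", rxn_df$id)]
  if (length(bio) == 0) stop("template has no biomass reaction")
  objective <- list(reaction = bio[1], direction = "max")

  ann <- template$annotations
  if (!is.null(ann$roles)) {
    ann$roles <- lapply(ann$roles, function(ids) {
      out <- unlist(lapply(ids, function(x) {
        hit <- rxn_df$id[rxn_df$id == x | template_id(rxn_df$id) == x]
        if (length(hit) == 0) x else hit
      }))
      unique(out)
    })
  }
  ann$cells <- c("vc", "hc")
  metabolic_model(metabolites,
                  list(reactions = rxn_df, stoichiometry = stoich),
                  objective = objective, annotations = ann)
}

#' Resolve a functional role to reaction ids
#'
#' Looks a role (e.g. `"co2_uptake"`, `"biomass_vc"`) up in
#' `model$annotations$roles`, the alias table that decouples analyses
#' from any one model's id dialect.  A role explicitly mapped to
#' `character(0)` is "declared absent" and resolves to no reactions;
#' an unmapped role is an error unless `allow_missing`.
#'
#' @param model a `metabolic_model`.
#' @param role role name.
#' @param allow_missing return `character(0)` for unmapped roles instead
#'   of erroring.
#' @return character vector of reaction ids (possibly empty).
#' @export
resolve_role <- function(model, role, allow_missing = FALSE) {
  roles <- model$annotations$roles
  if (is.null(roles) || !role %in% names(roles)) {
    if (allow_missing) return(character(0))
    stop("model does not map required role '", role,
         "' (annotations$roles)")
  }
  ids <- roles[[role]]
  ids[ids %in% model$reactions$id]
}

#' Apply the standard diazotrophic constraint set
#'
#' Sets, via the model's role aliases: inorganic-carbon uptake ub;
#' per-photosystem photon uptake ub; N2 uptake ub; heterocyst O2 uptake ub
#' from [heterocyst_o2_bound()]; heterocyst biomass lower bound
#' (`heterocyst_biomass_lb_fraction * mu_exp`); unbounded sucrose and
#' 2-oxoglutarate inter-cell exchanges; and, when `couple_glu_gln`, an
#' equality between the glutamate and glutamine inter-cell fluxes,
#' implemented as a massless pseudo-metabolite balance row (produced by
#' the glutamate exchange, consumed by the glutamine exchange) so the
#' problem remains a pure S v = 0 LP.  The objective is set to the
#' vegetative biomass reaction.
#'
#' Required roles: `co2_uptake`, `photon_uptake` (one or more reactions),
#' `n2_uptake`, `o2_uptake_hc`, `biomass_vc`, `biomass_hc`,
#' `suc_exchange`, `glu_exchange`, `gln_exchange`, `akg_exchange`.
#'
#' @param model a two-cell `metabolic_model` with role annotations.
#' @param config a [two_cell_config()].
#' @return the constrained model.
#' @export
apply_diazotrophic_constraints <- function(model,
                                           config = two_cell_config()) {
  need <- function(role) {
    ids <- resolve_role(model, role)
    if (length(ids) == 0) stop("no reaction fulfils role '", role, "'")
    ids
  }
  model <- set_bounds(model, need("co2_uptake"), ub = config$co2_uptake_ub)
  model <- set_bounds(model, need("photon_uptake"),
                      ub = config$photon_ub_per_photosystem)
  model <- set_bounds(model, need("n2_uptake"), ub = config$n2_uptake_ub)
  model <- set_bounds(model, need("o2_uptake_hc"),
                      ub = heterocyst_o2_bound(config$culture_o2_uptake,
                                               config$heterocyst_fraction))
  model <- set_bounds(model, need("biomass_hc"),
                      lb = config$heterocyst_biomass_lb_fraction *
                           config$mu_exp)
  model <- set_bounds(model, need("suc_exchange"), ub = Inf)
  model <- set_bounds(model, need("akg_exchange"), ub = Inf)
  if (isTRUE(config$couple_glu_gln)) {
    model <- couple_reaction_fluxes(model, need("glu_exchange"),
                                    need("gln_exchange"))
  }
  model$objective <- list(reaction = need("biomass_vc")[1],
                          direction = "max")
  model
}

# equality coupling of two irreversible fluxes via a massless
# pseudo-metabolite: rxn_a produces it, rxn_b consumes it.
couple_reaction_fluxes <- function(model, rxn_a, rxn_b,
                                   pseudo = "pseudo_couple") {
  stopifnot(length(rxn_a) == 1, length(rxn_b) == 1)
  pid <- make.unique(c(model$metabolites$id, pseudo))[
    nrow(model$metabolites) + 1L]
  model$metabolites <- rbind(
    model$metabolites,
    metabolite(pid, name = paste0("coupling pseudo-species ", rxn_a, "=",
                                  rxn_b),
               formula = "", charge = 0L, compartment = "pseudo",
               super_compartment = "shared-external"))
  model$stoichiometry[[rxn_a]][pid] <- 1
  model$stoichiometry[[rxn_b]][pid] <- -1
  model
}
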