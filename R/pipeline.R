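# End-to-end pipeline commands: file in, TSV out.  These are the
# programmatic equivalents of a command-line interface; a thin Rscript
# wrapper lives in inst/scripts/diazoflux.R.  Every command is
# deterministic (no RNG anywhere in the package) and logs solver status
# and applied bound edits through message().

#' Run configuration for the pipeline commands
#'
#' @param model either a `metabolic_model` or a path readable by
#'   [load_model()]; `"toy"` (default) uses the packaged synthetic
#'   network.
#' @param config a [two_cell_config()].
#' @param out_dir output directory (created if absent).
#' @param watchlist named character vector of reactions for the
#'   simulate command's FVA-minimum table (names are display labels);
#'   `NULL` uses a default toy watchlist.
#' @param scenarios scenario names for [cmd_scenarios()].
#' @param product product name (`"five_aminovalerate"` or
#'   `"adipyl_coa"`) for [cmd_optforce()].
#' @param k intervention budget.
#' @param n_strategies strategies to enumerate via integer cuts.
#' @param yield_frac,biomass_frac overproduction-space fractions.
#' @param extra_knockouts manually added knockout candidates.
#' @param verbose emit progress messages.
#' @return a `run_config` list.
#' @export
run_config <- function(model = "toy", config = two_cell_config(),
                       out_dir = ".", watchlist = NULL,
                       scenarios = SCENARIO_NAMES,
                       product = "five_aminovalerate", k = 2L,
                       n_strategies = 3L, yield_frac = 0.9,
                       biomass_frac = 0.1,
                       extra_knockouts = character(0), verbose = TRUE) {
  structure(list(model = model, config = config, out_dir = out_dir,
                 watchlist = watchlist, scenarios = scenarios,
                 product = product, k = as.integer(k),
                 n_strategies = as.integer(n_strategies),
                 yield_frac = yield_frac, biomass_frac = biomass_frac,
                 extra_knockouts = extra_knockouts, verbose = verbose),
            class = "run_config")
}

resolve_run_model <- function(rc) {
  if (inherits(rc$model, "metabolic_model")) return(rc$model)
  if (identical(rc$model, "toy")) {
    return(make_toy_two_cell(toy_params(config = rc$config))$model)
  }
  model <- load_model(rc$model)
  apply_diazotrophic_constraints(model, rc$config)
}

default_watchlist <- function(model) {
  wl <- c("RuBisCo (vegetative)" = resolve_role(model, "rubisco",
                                                allow_missing = TRUE)[1],
          "Sucrose uptake by heterocyst" =
            resolve_role(model, "suc_exchange")[1],
          "N2ase" = grep("nitrogenase", model$reactions$id,
                         value = TRUE)[1],
          "Glutamate/glutamine exchange" =
            resolve_role(model, "glu_exchange")[1],
          "Heterocyst CO2 evolution" =
            resolve_role(model, "co2_evolution_hc")[1])
  wl[!is.na(wl)]
}

pipe_log <- function(rc, ...) if (isTRUE(rc$verbose)) message(...)

#' Simulate growth and write the flux solution plus an FVA-minimum table
#'
#' Solves FBA under the model's constraint set, writes the full flux
#' distribution (`fluxes.tsv`) and a table of FVA minimum fluxes for the
#' watchlist reactions with growth fixed at its optimum
#' (`watchlist_minima.tsv`).
#'
#' @param rc a [run_config()].
#' @return invisibly, a list with `solution` and `watchlist` results.
#' @export
cmd_simulate <- function(rc = run_config()) {
  model <- resolve_run_model(rc)
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  sol <- fba(model)
  pipe_log(rc, "FBA status: ", sol$status, "; objective = ",
           format(sol$objective_value, digits = 7))
  if (sol$status != "optimal") stop("FBA not optimal: ", sol$status)
  write_fluxes(sol, file.path(rc$out_dir, "fluxes.tsv"))
  wl <- rc$watchlist
  if (is.null(wl)) wl <- default_watchlist(model)
  if (length(wl) > 0) {
    rng <- fva(model, targets = unname(wl), fix_objective = TRUE)
    tab <- data.frame(reaction_of_interest = names(wl),
                      reaction_id = unname(wl),
                      min_flux_for_optimal_growth = rng$ranges$min,
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(reaction_of_interest = character(0),
                      reaction_id = character(0),
                      min_flux_for_optimal_growth = numeric(0))
  }
  utils::write.table(tab, file.path(rc$out_dir, "watchlist_minima.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(solution = sol, watchlist = tab))
}

#' Evaluate the heterocyst energy schemes and write the metrics table
#'
#' One row per scenario: maximum growth, minimum heterocyst sucrose
#' uptake and minimum heterocyst CO2 evolution at that growth.
#'
#' @param rc a [run_config()].
#' @return invisibly, the metrics data.frame (also written to
#'   `scheme_metrics.tsv`).
#' @export
cmd_scenarios <- function(rc = run_config()) {
  model <- resolve_run_model(rc)
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- evaluate_all_schemes(model, rc$scenarios)
  pipe_log(rc, "evaluated ", nrow(tab), " schemes")
  utils::write.table(tab, file.path(rc$out_dir, "scheme_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Run the OptForce strain-design pipeline and write the strategy report
#'
#' Adds the selected production pathway, builds wild-type and
#' overproduction flux spaces, identifies and filters MUST sets, solves
#' the FORCE-set MILP with integer-cut enumeration, and writes a
#' Table-style report (`optforce_<product>.tsv`) with interventions,
#' fold changes, and guaranteed product fluxes.
#'
#' @param rc a [run_config()]; `rc$model` must be `"toy"` or a model the
#'   packaged pathways fit.
#' @param mfa_ranges optional measured flux ranges (default: the toy
#'   fixture from [make_mfa_fixture()]).
#' @return invisibly, a list with `must`, `strategies` and the report
#'   data.frame.
#' @export
cmd_optforce <- function(rc = run_config(), mfa_ranges = NULL) {
  base <- resolve_run_model(rc)
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- make_pathway_fixtures()[[rc$product]]
  if (is.null(spec)) stop("unknown product: ", rc$product)
  model <- add_production_pathway(base, spec)
  if (is.null(mfa_ranges)) mfa_ranges <- make_mfa_fixture(base)
  pipe_log(rc, "wild-type space: ", nrow(mfa_ranges$ranges),
           " measured ranges")
  wt <- wild_type_flux_space(model, mfa_ranges)
  over <- overproduction_flux_space(model, spec$product_exchange,
                                    yield_frac = rc$yield_frac,
                                    biomass_frac = rc$biomass_frac)
  pipe_log(rc, "theoretical yield = ",
           format(over$context$theoretical_yield, digits = 7))
  must <- identify_must_single(wt, over)
  must <- filter_must_sets(must, model)
  pipe_log(rc, "filtered MUST sets: U=", length(must$must_u),
           " L=", length(must$must_l), " X=", length(must$must_x))
  strategies <- solve_force_set(model, must, spec$product_exchange,
                                k = rc$k,
                                extra_knockouts = rc$extra_knockouts,
                                n_strategies = rc$n_strategies)
  if (length(strategies) == 0) {
    report <- data.frame(strategy = integer(0), intervention = character(0),
                         kind = character(0), fold_change = numeric(0),
                         product_flux = numeric(0))
    pipe_log(rc, "no overproduction strategy within budget k=", rc$k)
  } else {
    rows <- lapply(seq_along(strategies), function(i) {
      s <- strategies[[i]]
      if (nrow(s$members) == 0) {
        return(data.frame(strategy = i, intervention = "(none)",
                          kind = "", fold_change = NA_real_,
                          product_flux = s$guaranteed_product_flux))
      }
      fc <- fold_changes(s, wt)
      data.frame(strategy = i, intervention = fc$reaction, kind = fc$kind,
                 fold_change = fc$fold_change,
                 product_flux = s$guaranteed_product_flux)
    })
    report <- do.call(rbind, rows)
  }
  utils::write.table(report,
                     file.path(rc$out_dir,
                               paste0("optforce_", rc$product, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(must = must, strategies = strategies, report = report,
                 wild_type = wt, overproduction = over))
}

#' Write the packaged toy model and fixtures to a directory
#'
#' Emits the synthetic two-cell model in all three dialects, the measured
#' flux-range fixture, the pathway fixtures, and the manifest JSON.
#'
#' @param out_dir output directory.
#' @param params a [toy_params()].
#' @return invisibly, the manifest.
#' @export
cmd_make_toy <- function(out_dir = ".", params = toy_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_two_cell(params)
  write_model(toy$model, file.path(out_dir, "toy_two_cell.tsv"), "tabular")
  write_model(toy$model, file.path(out_dir, "toy_two_cell.json"), "json")
  write_model(toy$model, file.path(out_dir, "toy_two_cell.sbml"), "sbml")
  write_fluxes(make_mfa_fixture(toy$model),
               file.path(out_dir, "toy_mfa_ranges.tsv"))
  paths <- make_pathway_fixtures()
  write_pathway_fixture(paths$five_aminovalerate,
                        file.path(out_dir, "pathway_five_aminovalerate.tsv"))
  write_pathway_fixture(paths$adipyl_coa,
                        file.path(out_dir, "pathway_adipyl_coa.tsv"))
  manifest <- toy$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "toy_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
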