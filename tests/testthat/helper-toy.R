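# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

get_toy <- function() {
  if (is.null(.cache$toy)) .cache$toy <- make_toy_two_cell()
  .cache$toy
}

# OptForce spaces for one product, cached (the FVA over all reactions is
# the expensive step)
get_optforce_setup <- function(product = "five_aminovalerate") {
  key <- paste0("of_", product)
  if (is.null(.cache[[key]])) {
    toy <- get_toy()
    spec <- make_pathway_fixtures()[[product]]
    model <- add_production_pathway(toy$model, spec)
    mfa <- make_mfa_fixture(toy$model)
    wt <- wild_type_flux_space(model, mfa)
    over <- overproduction_flux_space(model, spec$product_exchange)
    must <- filter_must_sets(identify_must_single(wt, over), model)
    .cache[[key]] <- list(model = model, spec = spec, mfa = mfa,
                          wt = wt, over = over, must = must)
  }
  .cache[[key]]
}

# a deliberately tiny single-cell template for builder arithmetic tests:
# a linear chain a -> b -> c with a biomass drain and uptake/secretion
make_mini_template <- function() {
  mets <- rbind(metabolite("a", formula = "C", compartment = "c",
                           super_compartment = "vegetative"),
                metabolite("b", formula = "C", compartment = "c",
                           super_compartment = "vegetative"),
                metabolite("suc", formula = "C", compartment = "c",
                           super_compartment = "vegetative"),
                metabolite("glu", formula = "C", compartment = "c",
                           super_compartment = "vegetative"),
                metabolite("gln", formula = "C", compartment = "c",
                           super_compartment = "vegetative"),
                metabolite("akg", formula = "C", compartment = "c",
                           super_compartment = "vegetative"))
  rxns <- list(
    reaction("up_a", c(a = 1), 0, 10, kind = "exchange"),
    reaction("psii", c(a = -1, b = 1), 0, 10, kind = "enzymatic"),
    reaction("rubisco", c(b = -1, suc = 1), 0, 10, kind = "enzymatic"),
    reaction("gogat", c(suc = -1, glu = 1), 0, 10, kind = "enzymatic"),
    reaction("nitrogenase", c(glu = -1, gln = 1), 0, 10,
             kind = "enzymatic"),
    reaction("drain", c(gln = -1), 0, 10, kind = "exchange"),
    reaction("mk_akg", c(b = -1, akg = 1), 0, 10, kind = "enzymatic"),
    reaction("use_akg", c(akg = -1), 0, 10, kind = "demand"),
    reaction("biomass", c(gln = -1), 0, 10, kind = "biomass"))
  metabolic_model(mets, rxns, objective = "biomass")
}
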