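# Stoichiometric model data structures and consistency checks.
#
# A `metabolic_model` is a plain list with:
#   metabolites : data.frame(id, name, formula, charge, compartment,
#                            super_compartment)
#   reactions   : data.frame(id, name, lower_bound, upper_bound, gpr,
#                            subsystem, kind)
#   stoichiometry : named list, one named numeric vector per reaction
#                   (names are metabolite ids, values signed coefficients)
#   objective   : list(reaction = <id>, direction = "max"/"min")
#   annotations : free-form list; the builders store role aliases here
#                 (annotations$roles maps functional roles such as
#                 "co2_uptake" to reaction ids) so that analyses are
#                 decoupled from any one model's id dialect.
#
# Reaction ids follow the ModelSEED-style convention with a cell suffix:
# template id + "__vc" (vegetative cell) or "__hc" (heterocyst).

REACTION_KINDS <- c("enzymatic", "transport", "exchange", "demand",
                    "biomass", "intercell-exchange", "spontaneous")
CELL_SUFFIX_RE <- "__(vc|hc)$"

#' Construct a metabolite table row
#'
#' @param id metabolite id (compartment-suffixed for cell-specific species).
#' @param name human-readable name.
#' @param formula elemental formula string (e.g. `"C6H12O6P"`); `""` marks a
#'   massless pseudo-species; `NA` means unknown.
#' @param charge integer charge.
#' @param compartment compartment code (e.g. `"c"`, `"e"`).
#' @param super_compartment one of `"vegetative"`, `"heterocyst"`,
#'   `"shared-external"`.
#' @return one-row data.frame suitable for `metabolic_model()`.
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = 0L, compartment = "c",
                       super_compartment = "shared-external") {
  stopifnot(is.character(id), length(id) == 1L)
  super_compartment <- match.arg(super_compartment,
                                 c("vegetative", "heterocyst",
                                   "shared-external"))
  data.frame(id = id, name = name, formula = formula,
             charge = as.integer(charge), compartment = compartment,
             super_compartment = super_compartment,
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id reaction id (template id plus cell suffix for cell-specific
#'   reactions).
#' @param stoichiometry named numeric vector: metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction boolean string (may be `""`).
#' @param subsystem free-text subsystem.
#' @param kind reaction kind; one of `"enzymatic"`, `"transport"`,
#'   `"exchange"`, `"demand"`, `"biomass"`, `"intercell-exchange"`,
#'   `"spontaneous"`.
#' @param name human-readable name.
#' @return list with fields `row` (one-row reaction data.frame) and
#'   `stoichiometry`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, gpr = "", subsystem = "",
                     kind = "enzymatic", name = id) {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  kind <- match.arg(kind, REACTION_KINDS)
  if (lower_bound > upper_bound) {
    stop("reaction ", id, ": lower_bound > upper_bound")
  }
  list(row = data.frame(id = id, name = name,
                        lower_bound = as.numeric(lower_bound),
                        upper_bound = as.numeric(upper_bound),
                        gpr = gpr, subsystem = subsystem, kind = kind,
                        stringsAsFactors = FALSE),
       stoichiometry = stoichiometry)
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites data.frame as produced by rbinding [metabolite()] rows.
#' @param reactions list of [reaction()] objects, or a list with elements
#'   `reactions` (data.frame) and `stoichiometry` (named list).
#' @param objective list(reaction=, direction=) or a reaction id
#'   (direction defaults to `"max"`).
#' @param annotations free-form list.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions,
                            objective = NULL, annotations = list()) {
  if (is.data.frame(reactions)) {
    stop("pass reactions as a list of reaction() objects")
  }
  if (!is.null(reactions$reactions) && !is.null(reactions$stoichiometry)) {
    rxn_df <- reactions$reactions
    stoich <- reactions$stoichiometry
  } else {
    rxn_df <- do.call(rbind, lapply(reactions, `[[`, "row"))
    stoich <- lapply(reactions, `[[`, "stoichiometry")
    names(stoich) <- rxn_df$id
  }
  if (is.character(objective)) {
    objective <- list(reaction = objective, direction = "max")
  }
  model <- structure(list(metabolites = metabolites,
                          reactions = rxn_df,
                          stoichiometry = stoich,
                          objective = objective,
                          annotations = annotations),
                     class = "metabolic_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "))
  }
  if (!setequal(names(model$stoichiometry), rxns$id) ||
      length(model$stoichiometry) != nrow(rxns)) {
    stop("stoichiometry list does not match the reaction table")
  }
  all_met_ids <- unique(unlist(lapply(model$stoichiometry, names)))
  unknown <- setdiff(all_met_ids, mets$id)
  if (length(unknown) > 0) {
    stop("stoichiometry references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  ex <- rxns$kind %in% c("exchange", "demand")
  for (id in rxns$id[ex]) {
    if (length(model$stoichiometry[[id]]) != 1L) {
      stop("exchange/demand reaction ", id,
           " must touch exactly one metabolite")
    }
  }
  if (!is.null(model$objective)) {
    if (!model$objective$reaction %in% rxns$id) {
      stop("objective reaction not in model: ", model$objective$reaction)
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites\n")
  if (!is.null(x$objective)) {
    cat("objective:", x$objective$direction, x$objective$reaction, "\n")
  }
  tab <- table(x$reactions$kind)
  cat("kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  s <- count_unique(object)
  print(object)
  cat("template reactions:", s$n_unique_reactions,
      "| unique metabolites:", s$n_unique_metabolites,
      "| genes:", s$n_genes, "\n")
  cat("vegetative:", s$per_cell[["vegetative"]],
      "heterocyst:", s$per_cell[["heterocyst"]],
      "shared:", s$n_shared, "\n")
  invisible(s)
}

# ---------------------------------------------------------------------------
# accessors / editing helpers

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    S[names(st), j] <- st
  }
  S
}

#' Set flux bounds on one or more reactions
#'
#' @param model a `metabolic_model`.
#' @param id reaction id(s).
#' @param lb,ub new bounds (recycled); `NA` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NA, ub = NA) {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(id[is.na(idx)], collapse = ", "))
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  sel <- !is.na(lb); model$reactions$lower_bound[idx[sel]] <- lb[sel]
  sel <- !is.na(ub); model$reactions$upper_bound[idx[sel]] <- ub[sel]
  bad <- model$reactions$lower_bound[idx] > model$reactions$upper_bound[idx]
  if (any(bad)) stop("lower_bound > upper_bound after edit for: ",
                     paste(id[bad], collapse = ", "))
  model
}

#' Add a reaction to a model
#' @param model a `metabolic_model`.
#' @param rxn a [reaction()] object.
#' @return the modified model.
#' @export
add_reaction <- function(model, rxn) {
  if (rxn$row$id %in% model$reactions$id) {
    stop("reaction already in model: ", rxn$row$id)
  }
  model$reactions <- rbind(model$reactions, rxn$row)
  model$stoichiometry[[rxn$row$id]] <- rxn$stoichiometry
  validate_model(model)
  model
}

#' Remove reactions from a model
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop.
#' @return the modified model.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing) > 0) {
    stop("cannot remove unknown reaction(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

# strip the cell suffix, giving the template id
template_id <- function(id) sub(CELL_SUFFIX_RE, "", id)

# ---------------------------------------------------------------------------
# counting and balance checks

#' Per-super-compartment content summary
#'
#' Collapses cell-specific duplicates by template id (the id with the
#' `__vc`/`__hc` suffix removed) and reports unique reaction/metabolite/gene
#' counts plus the per-cell split and the shared count
#' (vegetative intersect heterocyst, by template id).  Reactions without a
#' cell suffix are counted once, with a warning record in the result.
#'
#' @param model a `metabolic_model`.
#' @return list with `n_unique_reactions`, `n_unique_metabolites`,
#'   `n_genes`, `per_cell` (named vector), `n_shared`, `unsuffixed`
#'   (character vector of reaction ids lacking a cell suffix).
#' @export
count_unique <- function(model) {
  rid <- model$reactions$id
  has_suffix <- grepl(CELL_SUFFIX_RE, rid)
  tmpl <- template_id(rid)
  vc <- unique(tmpl[grepl("__vc$", rid)])
  hc <- unique(tmpl[grepl("__hc$", rid)])
  genes <- unique(unlist(regmatches(model$reactions$gpr,
                                    gregexpr("[A-Za-z0-9_.-]+",
                                             model$reactions$gpr))))
  genes <- setdiff(genes, c("and", "or", "AND", "OR", ""))
  list(n_unique_reactions = length(unique(tmpl)),
       n_unique_metabolites =
         length(unique(template_id(model$metabolites$id))),
       n_genes = length(genes),
       per_cell = c(vegetative = length(vc), heterocyst = length(hc)),
       n_shared = length(intersect(vc, hc)),
       unsuffixed = rid[!has_suffix])
}

#' Parse an elemental formula
#'
#' Accepts element tokens of the form `[A-Z][a-z]*` followed by an optional
#' integer count.  Returns `NULL` for formulas containing polymer/R-group
#' tokens (`R`, `X`, `*`, or a parenthesised repeat unit), which are exempt
#' from balance checking.
#'
#' @param formula formula string; `""` yields an empty (massless) map.
#' @return named integer vector of element counts, or `NULL` if the
#'   formula is not checkable.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula)) return(NULL)
  if (formula == "") return(integer(0))
  if (grepl("[()*]", formula)) return(NULL)
  pieces <- regmatches(formula, gregexpr("[A-Z][a-z]*[0-9]*", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("unparseable formula: ", formula)
  }
  el <- sub("[0-9]+$", "", pieces)
  if (any(el %in% c("R", "X"))) return(NULL)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", pieces)))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Check mass and charge balance of all non-exempt reactions
#'
#' Biomass, exchange and demand reactions are exempt.  A reaction whose
#' metabolites include an unknown (`NA`) formula is reported with
#' element `"unknown"`; metabolites with polymer/R-group formulas exempt
#' the reaction with a warning.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `reaction`, `element` (element symbol,
#'   `"charge"`, or `"unknown"`), `imbalance`; zero rows if fully balanced.
#' @export
check_mass_charge_balance <- function(model) {
  exempt_kinds <- c("biomass", "exchange", "demand")
  out <- list()
  met_idx <- stats::setNames(seq_len(nrow(model$metabolites)),
                             model$metabolites$id)
  parsed <- lapply(model$metabolites$formula, function(f) {
    tryCatch(parse_formula(f), error = function(e) NULL)
  })
  for (i in seq_len(nrow(model$reactions))) {
    if (model$reactions$kind[i] %in% exempt_kinds) next
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    rows <- met_idx[names(st)]
    fmls <- parsed[rows]
    if (any(is.na(model$metabolites$formula[rows]))) {
      out[[length(out) + 1L]] <- data.frame(reaction = rid,
                                            element = "unknown",
                                            imbalance = NA_real_)
      next
    }
    if (any(vapply(fmls, is.null, logical(1)))) {
      warning("reaction ", rid,
              " exempted from balance check (R-group/polymer formula)")
      next
    }
    elements <- unique(unlist(lapply(fmls, names)))
    for (e in elements) {
      counts <- vapply(fmls, function(f) {
        v <- f[e]; if (is.na(v)) 0 else as.numeric(v)
      }, numeric(1))
      imb <- sum(st * counts)
      if (abs(imb) > 1e-9) {
        out[[length(out) + 1L]] <- data.frame(reaction = rid, element = e,
                                              imbalance = imb)
      }
    }
    chg <- sum(st * model$metabolites$charge[rows])
    if (abs(chg) > 1e-9) {
      out[[length(out) + 1L]] <- data.frame(reaction = rid,
                                            element = "charge",
                                            imbalance = chg)
    }
  }
  if (length(out) == 0) {
    return(data.frame(reaction = character(0), element = character(0),
                      imbalance = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
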