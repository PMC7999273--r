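# Model readers and writers: tabular TSV dialect, JSON dump, SBML L3 fbc.
#
# Tabular dialect: UTF-8 tab-separated reaction list with a header row and
# columns id, name, equation, lower_bound, upper_bound, gpr, subsystem,
# kind, objective.  Equation strings use "->" (irreversible) or "<=>"
# (reversible) and compartment-suffixed metabolite ids, e.g.
#   "cpd00027__vc + 2 cpd00002__vc -> cpd00076__vc".
# Reversible reactions default to bounds [-1000, 1000], irreversible to
# [0, 1000]; explicit bound columns override the defaults.  Metabolite
# attributes travel in an optional sidecar "<path>.metabolites.tsv"
# (id, name, formula, charge, compartment, super_compartment); without it
# metabolites are reconstructed from the equations with unknown formulas.

#' Load a metabolic model from disk
#'
#' @param path file path.
#' @param format `"tabular"`, `"json"` or `"sbml"`; default guesses from
#'   the file extension.
#' @return a [metabolic_model()].
#' @seealso [write_model()]
#' @export
load_model <- function(path, format = c("auto", "tabular", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = , txt = "tabular",
                     json = "json",
                     xml = , sbml = "sbml",
                     stop("cannot guess model format from extension: ", path))
  }
  switch(format,
         tabular = read_model_tabular(path),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"tabular"`, `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path,
                        format = c("tabular", "json", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tabular = write_model_tabular(model, path),
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# equation strings

format_equation <- function(st, reversible) {
  side <- function(ids, coefs) {
    if (length(ids) == 0) return("")
    paste(ifelse(abs(coefs) == 1, ids,
                 paste(format(abs(coefs), trim = TRUE, digits = 12), ids)),
          collapse = " + ")
  }
  lhs <- names(st)[st < 0]
  rhs <- names(st)[st > 0]
  arrow <- if (reversible) "<=>" else "->"
  paste(side(lhs, st[st < 0]), arrow, side(rhs, st[st > 0]))
}

parse_equation <- function(eq, line = NA) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  parts <- strsplit(eq, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(parts) > 2L || length(parts) < 1L) {
    stop("cannot parse equation (line ", line, "): ", eq)
  }
  if (length(parts) == 1L) parts <- c(parts, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[terms != ""]
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", t))[[1]]
      if (length(m) == 0) stop("cannot parse equation term (line ", line,
                               "): '", t, "'")
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      out[m[3]] <- (if (is.na(out[m[3]])) 0 else out[m[3]]) + sign * coef
    }
    out
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- parse_side(parts[2], 1)
  st <- c(lhs, rhs)
  # merge duplicated ids across sides
  st <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  list(stoichiometry = st, reversible = rev)
}

# ---------------------------------------------------------------------------
# tabular

metabolite_sidecar_path <- function(path) paste0(path, ".metabolites.tsv")

write_model_tabular <- function(model, path) {
  rx <- model$reactions
  obj <- if (is.null(model$objective)) "" else model$objective$reaction
  eqs <- vapply(rx$id, function(id) {
    format_equation(model$stoichiometry[[id]],
                    rx$lower_bound[match(id, rx$id)] < 0)
  }, character(1))
  df <- data.frame(id = rx$id, name = rx$name, equation = eqs,
                   lower_bound = rx$lower_bound, upper_bound = rx$upper_bound,
                   gpr = rx$gpr, subsystem = rx$subsystem, kind = rx$kind,
                   objective = as.integer(rx$id == obj),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(model$metabolites, metabolite_sidecar_path(path),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_model_tabular <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("parse error in tabular model '", path,
                             "': ", conditionMessage(e)))
  if (!all(c("id", "equation") %in% names(df))) {
    stop("tabular model ", path, " lacks required columns id, equation")
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate reaction id in ", path, ": ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$gpr)) df$gpr <- ""
  if (is.null(df$subsystem)) df$subsystem <- ""
  if (is.null(df$kind)) df$kind <- "enzymatic"
  df$gpr[is.na(df$gpr)] <- ""
  df$subsystem[is.na(df$subsystem)] <- ""
  parsed <- lapply(seq_len(n), function(i) parse_equation(df$equation[i],
                                                          line = i + 1L))
  lb <- if (is.null(df$lower_bound)) rep(NA_real_, n) else df$lower_bound
  ub <- if (is.null(df$upper_bound)) rep(NA_real_, n) else df$upper_bound
  for (i in seq_len(n)) {
    if (is.na(lb[i])) lb[i] <- if (parsed[[i]]$reversible) -1000 else 0
    if (is.na(ub[i])) ub[i] <- 1000
  }
  rxns <- lapply(seq_len(n), function(i) {
    reaction(df$id[i], parsed[[i]]$stoichiometry, lb[i], ub[i],
             gpr = df$gpr[i], subsystem = df$subsystem[i],
             kind = df$kind[i], name = df$name[i])
  })
  side <- metabolite_sidecar_path(path)
  if (file.exists(side)) {
    mets <- utils::read.table(side, sep = "\t", header = TRUE, quote = "",
                              comment.char = "", stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
    mets$formula[is.na(mets$formula)] <- NA_character_
    mets$formula <- as.character(mets$formula)
    mets$formula[is.na(mets$formula)] <- NA_character_
  } else {
    ids <- unique(unlist(lapply(parsed, function(p) names(p$stoichiometry))))
    mets <- do.call(rbind, lapply(ids, metabolite))
  }
  obj <- NULL
  if (!is.null(df$objective) && any(df$objective == 1)) {
    obj <- list(reaction = df$id[which(df$objective == 1)[1]],
                direction = "max")
  }
  metabolic_model(mets, rxns, objective = obj)
}

# ---------------------------------------------------------------------------
# json (one-to-one dump of the typed model)

write_model_json <- function(model, path) {
  rx <- model$reactions
  # bounds as strings so that +/-Inf survive the round trip
  rx$lower_bound <- format(rx$lower_bound, digits = 17, trim = TRUE,
                           scientific = FALSE)
  rx$upper_bound <- format(rx$upper_bound, digits = 17, trim = TRUE,
                           scientific = FALSE)
  x <- list(metabolites = model$metabolites,
            reactions = rx,
            stoichiometry = lapply(model$stoichiometry, as.list),
            objective = model$objective,
            annotations = model$annotations)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = TRUE),
                error = function(e) stop("parse error in JSON model '",
                                         path, "': ", conditionMessage(e)))
  stoich <- lapply(x$stoichiometry, function(s) unlist(s))
  mets <- as.data.frame(x$metabolites, stringsAsFactors = FALSE)
  rxns <- as.data.frame(x$reactions, stringsAsFactors = FALSE)
  if (is.null(mets$formula)) mets$formula <- NA_character_
  rxns$gpr[is.na(rxns$gpr)] <- ""
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  # infinite bounds serialise as the string "Inf"
  rxns$lower_bound <- as.numeric(rxns$lower_bound)
  rxns$upper_bound <- as.numeric(rxns$upper_bound)
  stoich <- lapply(stoich, function(s) {
    stats::setNames(as.numeric(s), names(s))
  })
  ann <- x$annotations
  if (is.null(ann)) ann <- list()
  metabolic_model(mets, list(reactions = rxns, stoichiometry = stoich),
                  objective = x$objective, annotations = ann)
}

# ---------------------------------------------------------------------------
# SBML Level 3 Version 1 with the fbc (version 2) package
#
# Ids are SBML-sanitised on write (prefix M_/R_, "__" cell suffixes kept)
# and de-sanitised on read, so write -> load round-trips the dialect ids.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sanitize <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

write_model_sbml <- function(model, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  mets <- model$metabolites
  rxns <- model$reactions
  comps <- unique(mets$compartment)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            sbml_sanitize(comps)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    extra <- ""
    if (!is.na(mets$formula[i])) {
      extra <- sprintf(' fbc:chemicalFormula="%s"', esc(mets$formula[i]))
    }
    lines <- c(lines, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false" fbc:charge="%d"%s ',
             'sboTerm="SBO:0000247" metaid="M_%s_%s"/>'),
      sbml_sanitize(mets$id[i]), esc(mets$name[i]),
      sbml_sanitize(mets$compartment[i]), mets$charge[i], extra,
      sbml_sanitize(mets$id[i]), sbml_sanitize(mets$super_compartment[i])))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  bnds <- sort(unique(c(rxns$lower_bound, rxns$upper_bound)))
  pid <- function(v) {
    s <- gsub("-", "minus_", gsub("\\.", "_", format(v, digits = 12)))
    paste0("bnd_", s)
  }
  for (v in bnds) {
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pid(v), format(v, digits = 12)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rxns))) {
    id <- rxns$id[i]
    st <- model$stoichiometry[[id]]
    open <- sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s" metaid="R_%s_%s_%s">'),
      sbml_sanitize(id), esc(rxns$name[i]),
      tolower(rxns$lower_bound[i] < 0), pid(rxns$lower_bound[i]),
      pid(rxns$upper_bound[i]), sbml_sanitize(id),
      sbml_sanitize(rxns$kind[i]), sbml_sanitize(rxns$subsystem[i]))
    body <- character(0)
    lhs <- st[st < 0]; rhs <- st[st > 0]
    if (length(lhs) > 0) {
      body <- c(body, '        <listOfReactants>',
                sprintf(paste0('          <speciesReference species="M_%s" ',
                               'stoichiometry="%s" constant="true"/>'),
                        sbml_sanitize(names(lhs)),
                        format(-as.numeric(lhs), digits = 12)),
                '        </listOfReactants>')
    }
    if (length(rhs) > 0) {
      body <- c(body, '        <listOfProducts>',
                sprintf(paste0('          <speciesReference species="M_%s" ',
                               'stoichiometry="%s" constant="true"/>'),
                        sbml_sanitize(names(rhs)),
                        format(as.numeric(rhs), digits = 12)),
                '        </listOfProducts>')
    }
    if (nzchar(rxns$gpr[i])) {
      body <- c(body, '        <fbc:geneProductAssociation>',
                sprintf('          <fbc:annotation text="%s"/>',
                        esc(rxns$gpr[i])),
                '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, open, body, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.null(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      sprintf('      <fbc:objective fbc:id="obj" fbc:type="%simize">',
              model$objective$direction),
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                     'fbc:coefficient="1"/>'),
              sbml_sanitize(model$objective$reaction)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path, useBytes = TRUE)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in SBML file '",
                                           path, "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  params <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  unsan <- function(id, prefix) sub(paste0("^", prefix), "", id)
  meta <- xml2::xml_attr(sp, "metaid")
  sid <- unsan(xml2::xml_attr(sp, "id"), "M_")
  supc <- sub(".*_(vegetative|heterocyst|shared.external)$", "\\1", meta)
  supc[supc == "shared_external"] <- "shared-external"
  supc[!supc %in% c("vegetative", "heterocyst", "shared-external")] <-
    "shared-external"
  fml <- xml2::xml_attr(sp, "chemicalFormula")
  chg <- xml2::xml_attr(sp, "charge")
  mets <- data.frame(id = sid,
                     name = xml2::xml_attr(sp, "name"),
                     formula = fml,
                     charge = ifelse(is.na(chg), 0L, as.integer(chg)),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     super_compartment = supc,
                     stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  if (anyDuplicated(xml2::xml_attr(rx, "id"))) {
    stop("duplicate reaction id in SBML file ", path)
  }
  rxns <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    rid <- unsan(xml2::xml_attr(node, "id"), "R_")
    meta <- xml2::xml_attr(node, "metaid")
    kind_sub <- sub(paste0("^R_", sbml_sanitize(rid), "_"), "", meta)
    kind <- REACTION_KINDS[startsWith(gsub("-", "_", kind_sub),
                                      gsub("-", "_", REACTION_KINDS))][1]
    if (is.na(kind)) kind <- "enzymatic"
    subsystem <- sub(paste0("^", gsub("-", "_", kind), "_?"), "",
                     gsub("-", "_", kind_sub))
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference",
                               ns)
    st <- numeric(0)
    if (length(reac) > 0) {
      ids <- unsan(xml2::xml_attr(reac, "species"), "M_")
      st[ids] <- -as.numeric(xml2::xml_attr(reac, "stoichiometry"))
    }
    if (length(prod) > 0) {
      ids <- unsan(xml2::xml_attr(prod, "species"), "M_")
      v <- as.numeric(xml2::xml_attr(prod, "stoichiometry"))
      for (k in seq_along(ids)) {
        st[ids[k]] <- (if (is.na(st[ids[k]])) 0 else st[ids[k]]) + v[k]
      }
    }
    gnode <- xml2::xml_find_first(
      node, "./fbc:geneProductAssociation/fbc:annotation", ns)
    gpr <- if (inherits(gnode, "xml_missing")) "" else
      xml2::xml_attr(gnode, "text")
    rxns[[i]] <- reaction(
      rid, st,
      lower_bound = pvals[[xml2::xml_attr(node, "lowerFluxBound")]],
      upper_bound = pvals[[xml2::xml_attr(node, "upperFluxBound")]],
      gpr = gpr, subsystem = subsystem, kind = kind,
      name = xml2::xml_attr(node, "name"))
  }
  objn <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  obj <- NULL
  if (!inherits(objn, "xml_missing")) {
    otype <- xml2::xml_attr(xml2::xml_find_first(doc, ".//fbc:objective", ns),
                            "type")
    obj <- list(reaction = unsan(xml2::xml_attr(objn, "reaction"), "R_"),
                direction = sub("imize$", "", otype))
  }
  metabolic_model(mets, rxns, objective = obj)
}
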