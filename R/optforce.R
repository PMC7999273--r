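# OptForce-style strain design.
#
# Pipeline: (1) wild-type flux space -- measured (MFA-style) flux ranges
# imposed on the vegetative compartment, FVA propagates them to the rest
# of the network; (2) overproduction flux space -- product secretion
# forced to >= 90% of theoretical yield and biomass to >= 10% of its
# maximum, FVA again; (3) MUST sets -- reactions (and pairs, via flux sums
# and differences) whose flux must rise (MUST_U), fall (MUST_L) or vanish
# (MUST_X) to move from the wild-type into the overproduction space;
# (4) filtering (no transport/exchange/demand/spontaneous candidates,
# linear pathways collapsed to their first reaction, growth-coupled
# reactions out of MUST_L, essential/low-flux reactions out of MUST_X);
# (5) FORCE set search -- a bi-level program (max over <= k interventions
# of the worst-case product flux) collapsed to a single-level MILP via LP
# duality, with alternative strategies enumerated through integer cuts.
#
# Intervention levels follow the flux-space logic: an upregulation forces
# v >= overproduction-space minimum, a downregulation forces
# v <= overproduction-space maximum, a knockout forces v = 0.

#' Production pathway specification
#'
#' @param name pathway name (e.g. `"five_aminovalerate"`, `"adipyl_coa"`).
#' @param metabolites data.frame of new metabolites ([metabolite()] rows).
#' @param reactions list of [reaction()] objects (pathway steps plus the
#'   product exchange).
#' @param product_exchange id of the product exchange reaction.
#' @return object of class `pathway_spec`.
#' @export
pathway_spec <- function(name, metabolites, reactions, product_exchange) {
  ids <- vapply(reactions, function(r) r$row$id, character(1))
  if (!product_exchange %in% ids) {
    stop("product_exchange must be one of the pathway reactions")
  }
  structure(list(name = name, metabolites = metabolites,
                 reactions = reactions,
                 product_exchange = product_exchange),
            class = "pathway_spec")
}

#' Add a production pathway to a model
#'
#' Appends the pathway's metabolites and reactions.  Every substrate that
#' the pathway does not itself produce must already exist in the model
#' (native precursor check).
#'
#' @param model a `metabolic_model`.
#' @param spec a [pathway_spec()].
#' @return the extended model.
#' @export
add_production_pathway <- function(model, spec) {
  stopifnot(inherits(spec, "pathway_spec"))
  new_ids <- spec$metabolites$id
  produced <- unique(unlist(lapply(spec$reactions, function(r) {
    names(r$stoichiometry)[r$stoichiometry > 0]
  })))
  consumed <- unique(unlist(lapply(spec$reactions, function(r) {
    names(r$stoichiometry)[r$stoichiometry < 0]
  })))
  precursors <- setdiff(consumed, c(new_ids, produced))
  missing <- setdiff(precursors, model$metabolites$id)
  if (length(missing) > 0) {
    stop("pathway ", spec$name, ": precursor(s) absent from model: ",
         paste(missing, collapse = ", "))
  }
  add_mets <- spec$metabolites[!spec$metabolites$id %in%
                               model$metabolites$id, , drop = FALSE]
  model$metabolites <- rbind(model$metabolites, add_mets)
  for (r in spec$reactions) model <- add_reaction(model, r)
  if (is.null(model$annotations$products)) {
    model$annotations$products <- list()
  }
  model$annotations$products[[spec$name]] <- spec$product_exchange
  model
}

#' Wild-type flux space from measured flux ranges
#'
#' Imposes MFA-style flux ranges as bounds and propagates them to every
#' reaction with FVA.
#'
#' @param model a `metabolic_model` (with production pathway, if any).
#' @param mfa_ranges `flux_ranges` or data.frame (`reaction`, `min`,
#'   `max`) of measured ranges; may be empty.
#' @param targets reactions to scan (default: all).
#' @return `flux_ranges`; the bounded model is carried in
#'   `$context$model` for downstream queries.
#' @export
wild_type_flux_space <- function(model, mfa_ranges = NULL, targets = NULL) {
  rng <- if (inherits(mfa_ranges, "flux_ranges")) mfa_ranges$ranges else
    mfa_ranges
  if (!is.null(rng) && nrow(rng) > 0) {
    bad <- setdiff(rng$reaction, model$reactions$id)
    if (length(bad) > 0) {
      stop("MFA range(s) for unknown reaction(s): ",
           paste(bad, collapse = ", "))
    }
    model <- set_bounds(model, rng$reaction, lb = rng$min, ub = rng$max)
  }
  chk <- fba(model)
  if (chk$status == "infeasible") {
    # bisect to name a conflicting range
    culprit <- NULL
    if (!is.null(rng)) {
      for (i in seq_len(nrow(rng))) {
        m2 <- set_bounds(model, rng$reaction[i], lb = -1000, ub = 1000)
        if (fba(m2)$status == "optimal") { culprit <- rng$reaction[i]; break }
      }
    }
    stop("wild-type space infeasible",
         if (!is.null(culprit)) paste0(" (conflicting range on ", culprit,
                                       ")") else "")
  }
  out <- fva(model, targets = targets)
  out$context$model <- model
  out$context$space <- "wild_type"
  out
}

#' Overproduction flux space
#'
#' Theoretical yield is the maximum product flux with the biomass lower
#' bounds released to zero; the overproduction space then requires
#' product >= `yield_frac` x theoretical yield and vegetative biomass >=
#' `biomass_frac` x maximum biomass, and FVA maps the consequences.
#'
#' @param model a `metabolic_model` containing the product exchange.
#' @param product product exchange reaction id.
#' @param yield_frac fraction of theoretical yield enforced (default 0.9).
#' @param biomass_frac fraction of maximum biomass enforced (default 0.1).
#' @param targets reactions to scan (default: all).
#' @return `flux_ranges` with the bounded model in `$context$model` and
#'   `theoretical_yield`/`max_biomass` in the context.
#' @export
overproduction_flux_space <- function(model, product, yield_frac = 0.9,
                                      biomass_frac = 0.1, targets = NULL) {
  if (!product %in% model$reactions$id) {
    stop("unknown product exchange: ", product)
  }
  biomass_ids <- model$reactions$id[model$reactions$kind == "biomass"]
  relaxed <- set_bounds(model, biomass_ids, lb = 0)
  ymod <- relaxed
  ymod$objective <- list(reaction = product, direction = "max")
  ysol <- fba(ymod)
  if (ysol$status != "optimal" || ysol$objective_value <= 1e-9) {
    stop("theoretical yield not positive for product ", product)
  }
  y <- ysol$objective_value
  mu_sol <- fba(model)
  if (mu_sol$status != "optimal") stop("biomass maximisation failed")
  mu_max <- mu_sol$objective_value
  cons <- set_bounds(relaxed, product, lb = yield_frac * y)
  cons <- set_bounds(cons, model$objective$reaction,
                     lb = biomass_frac * mu_max)
  if (fba(cons)$status != "optimal") {
    stop("overproduction space infeasible: product >= ",
         yield_frac * y, " with biomass >= ", biomass_frac * mu_max)
  }
  out <- fva(cons, targets = targets)
  out$context$model <- cons
  out$context$space <- "overproduction"
  out$context$theoretical_yield <- y
  out$context$max_biomass <- mu_max
  out
}

new_must_sets <- function(u = character(0), l = character(0),
                          x = character(0), uu = list(), ll = list(),
                          ul = list(), lu = list(), provenance = list()) {
  structure(list(must_u = u, must_l = l, must_x = x,
                 must_uu = uu, must_ll = ll, must_ul = ul, must_lu = lu,
                 provenance = provenance),
            class = "must_sets")
}

#' @export
print.must_sets <- function(x, ...) {
  cat("MUST sets: U =", length(x$must_u), " L =", length(x$must_l),
      " X =", length(x$must_x),
      " | pairs UU/LL/UL/LU =", length(x$must_uu), length(x$must_ll),
      length(x$must_ul), length(x$must_lu), "\n")
  invisible(x)
}

#' Identify single-reaction MUST sets
#'
#' Contrasts wild-type and overproduction flux ranges with a strict
#' separation rule: a reaction joins MUST_U if its overproduction minimum
#' exceeds the wild-type maximum, MUST_L if its overproduction maximum is
#' below the wild-type minimum, and MUST_X if its overproduction range is
#' \{0\} while the wild-type range excludes zero.
#'
#' @param wt,over `flux_ranges` over the same reaction universe.
#' @param eps separation tolerance (default 1e-6).
#' @return a `must_sets` object (single-reaction part).
#' @export
identify_must_single <- function(wt, over, eps = 1e-6) {
  w <- wt$ranges; o <- over$ranges
  if (!setequal(w$reaction, o$reaction)) {
    stop("wild-type and overproduction ranges cover different reactions")
  }
  o <- o[match(w$reaction, o$reaction), ]
  u <- w$reaction[o$min > w$max + eps]
  l <- w$reaction[o$max < w$min - eps]
  x <- w$reaction[abs(o$min) <= eps & abs(o$max) <= eps &
                  (w$min > eps | w$max < -eps)]
  # a reaction pinned to zero is a knockout candidate, not an up/down
  new_must_sets(u = setdiff(u, x), l = setdiff(l, x), x = x,
                provenance = list(wt = wt, over = over))
}

# range of a linear combination c'v over a flux space (model)
combo_range <- function(model, coefs) {
  lp <- lp_from_model(model)
  c_obj <- numeric(length(lp$rxn_ids))
  c_obj[match(names(coefs), lp$rxn_ids)] <- as.numeric(coefs)
  lo <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = FALSE)
  hi <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = TRUE)
  c(min = lo$objective, max = hi$objective)
}

#' Identify pairwise MUST sets from flux sums and differences
#'
#' For each candidate pair (i, j), the ranges of `v_i + v_j` and
#' `v_i - v_j` are computed by FVA in both spaces and classified with the
#' same strict-separation rule as single reactions: a sum forced upward
#' puts the pair in MUST_UU, a sum forced downward in MUST_LL, a
#' difference forced upward in MUST_UL (i up / j down) and downward in
#' MUST_LU.
#'
#' @param model the unconstrained model (used for the default pair
#'   universe: reaction pairs sharing at least one metabolite).
#' @param wt_space,over_space `flux_ranges` carrying their bounded models
#'   (as produced by [wild_type_flux_space()] /
#'   [overproduction_flux_space()]).
#' @param pairs optional two-column matrix/data.frame of reaction ids;
#'   default: metabolite-sharing pairs of enzymatic reactions.
#' @param eps separation tolerance.
#' @return a `must_sets` object (pairwise part; single sets empty).
#' @export
identify_must_pairs <- function(model, wt_space, over_space, pairs = NULL,
                                eps = 1e-6) {
  wt_model <- wt_space$context$model
  over_model <- over_space$context$model
  if (is.null(wt_model) || is.null(over_model)) {
    stop("flux spaces must carry their bounded models (context$model)")
  }
  if (is.null(pairs)) {
    enz <- model$reactions$id[model$reactions$kind == "enzymatic"]
    by_met <- list()
    for (rid in enz) {
      for (mid in names(model$stoichiometry[[rid]])) {
        by_met[[mid]] <- c(by_met[[mid]], rid)
      }
    }
    pr <- unique(do.call(rbind, lapply(by_met, function(rs) {
      if (length(rs) < 2) return(NULL)
      t(utils::combn(sort(rs), 2))
    })))
    pairs <- pr
  }
  pairs <- as.matrix(pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("empty pair universe; returning empty pairwise MUST sets")
    return(new_must_sets(provenance = list(wt = wt_space,
                                           over = over_space)))
  }
  uu <- ll <- ul <- lu <- list()
  sep_up <- function(w, o) o[["min"]] > w[["max"]] + eps
  sep_dn <- function(w, o) o[["max"]] < w[["min"]] - eps
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    sum_c <- stats::setNames(c(1, 1), p)
    dif_c <- stats::setNames(c(1, -1), p)
    if (p[1] == p[2]) sum_c <- stats::setNames(2, p[1])
    w_sum <- combo_range(wt_model, sum_c)
    o_sum <- combo_range(over_model, sum_c)
    if (sep_up(w_sum, o_sum)) uu[[length(uu) + 1L]] <- p
    if (sep_dn(w_sum, o_sum)) ll[[length(ll) + 1L]] <- p
    if (p[1] != p[2]) {
      w_dif <- combo_range(wt_model, dif_c)
      o_dif <- combo_range(over_model, dif_c)
      if (sep_up(w_dif, o_dif)) ul[[length(ul) + 1L]] <- p
      if (sep_dn(w_dif, o_dif)) lu[[length(lu) + 1L]] <- p
    }
  }
  new_must_sets(uu = uu, ll = ll, ul = ul, lu = lu,
                provenance = list(wt = wt_space, over = over_space))
}

#' Filter MUST sets down to implementable perturbation candidates
#'
#' Applies, in order: (1) transport, exchange, demand, spontaneous,
#' inter-cell exchange and biomass reactions are removed from every set;
#' (2) linear (flux-coupled) pathways -- reactions sharing a metabolite
#' whose wild-type ranges are identical up to a positive scalar -- are
#' collapsed to their first member (model order); (3) growth-coupled
#' reactions are removed from MUST_L; (4) essential and very-low-flux
#' reactions are removed from MUST_X.
#'
#' @param must a `must_sets` with provenance ranges.
#' @param model the model supplying reaction kinds and adjacency.
#' @param essential reaction ids treated as in-vivo essential.
#' @param growth_coupled reaction ids whose flux scales with growth.
#' @param low_flux_eps wild-type |flux| below which a MUST_X candidate is
#'   discarded (default 1e-3 mmol/gDW/h).
#' @return the filtered `must_sets`.
#' @export
filter_must_sets <- function(must, model, essential = character(0),
                             growth_coupled = character(0),
                             low_flux_eps = 1e-3) {
  kinds <- stats::setNames(model$reactions$kind, model$reactions$id)
  keep_kind <- function(ids) ids[kinds[ids] %in% "enzymatic"]
  u <- keep_kind(must$must_u)
  l <- keep_kind(must$must_l)
  x <- keep_kind(must$must_x)

  wt <- must$provenance$wt$ranges
  # producers/consumers per metabolite, over the whole model
  n_prod <- list(); n_cons <- list()
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    for (mid in names(st)) {
      if (st[[mid]] > 0) n_prod[[mid]] <- c(n_prod[[mid]], rid) else
        n_cons[[mid]] <- c(n_cons[[mid]], rid)
    }
  }
  # a -> b is a linear link if a is the sole producer and b the sole
  # consumer of some connecting metabolite (irreversible chain step)
  linear_link <- function(a, b) {
    for (mid in names(model$stoichiometry[[a]])) {
      if (model$stoichiometry[[a]][[mid]] > 0 &&
          identical(n_prod[[mid]], a) && identical(n_cons[[mid]], b)) {
        return(TRUE)
      }
    }
    FALSE
  }
  prop_ranges <- function(a, b) {
    ra <- wt[wt$reaction == a, ]; rb <- wt[wt$reaction == b, ]
    va <- c(ra$min, ra$max); vb <- c(rb$min, rb$max)
    na_ <- max(abs(va)); nb_ <- max(abs(vb))
    if (na_ < 1e-9 || nb_ < 1e-9) return(FALSE)
    isTRUE(all.equal(va / na_, vb / nb_, tolerance = 1e-6))
  }
  collapse_chain <- function(ids) {
    if (length(ids) < 2) return(ids)
    ids <- ids[order(match(ids, model$reactions$id))]
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && linear_link(ids[i], ids[j]) && prop_ranges(ids[i],
                                                               ids[j])) {
        adj[i, j] <- TRUE
      }
    }
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j]) parent[find(j)] <- find(i)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    keep <- logical(n)
    for (g in unique(roots)) {
      members <- which(roots == g)
      # retain the upstream-most member (no incoming link within the
      # group); ties broken by model order
      src <- members[colSums(adj[members, members, drop = FALSE]) == 0]
      keep[if (length(src) > 0) src[1] else members[1]] <- TRUE
    }
    ids[keep]
  }
  u <- collapse_chain(u)
  l <- collapse_chain(l)
  x <- collapse_chain(x)
  l <- setdiff(l, growth_coupled)
  if (length(x) > 0) {
    keepx <- vapply(x, function(id) {
      r <- wt[wt$reaction == id, ]
      !(id %in% essential) &&
        max(abs(r$min), abs(r$max)) >= low_flux_eps
    }, logical(1))
    x <- x[keepx]
  }
  keep_pair <- function(ps) {
    Filter(function(p) all(kinds[p] %in% "enzymatic"), ps)
  }
  new_must_sets(u = u, l = l, x = x,
                uu = keep_pair(must$must_uu), ll = keep_pair(must$must_ll),
                ul = keep_pair(must$must_ul), lu = keep_pair(must$must_lu),
                provenance = must$provenance)
}

# candidate table from filtered MUST sets + extra knockouts
force_candidates <- function(must, extra_knockouts = character(0)) {
  over <- must$provenance$over$ranges
  wt <- must$provenance$wt$ranges
  lvl <- function(ids, col) over[[col]][match(ids, over$reaction)]
  cand <- rbind(
    if (length(must$must_u) > 0)
      data.frame(reaction = must$must_u, kind = "up",
                 level = lvl(must$must_u, "min"),
                 release = lvl(must$must_u, "max"),
                 stringsAsFactors = FALSE),
    if (length(must$must_l) > 0)
      data.frame(reaction = must$must_l, kind = "down",
                 level = lvl(must$must_l, "max"),
                 release = lvl(must$must_l, "min"),
                 stringsAsFactors = FALSE),
    if (length(unique(c(must$must_x, extra_knockouts))) > 0)
      data.frame(reaction = unique(c(must$must_x, extra_knockouts)),
                 kind = "knockout", level = 0, release = 0,
                 stringsAsFactors = FALSE))
  cand
}

# Impose a set of interventions (rows of the candidate table) on a model.
# An engineered reaction is no longer held to the wild-type measured
# range: an upregulation sets lb = level and releases the upper bound to
# at least the overproduction-space maximum; a downregulation sets
# ub = level and releases the lower bound likewise; a knockout pins 0.
impose_interventions <- function(model, cand) {
  for (i in seq_len(nrow(cand))) {
    r <- cand$reaction[i]
    j <- match(r, model$reactions$id)
    switch(cand$kind[i],
           up = {
             ub <- max(model$reactions$upper_bound[j], cand$release[i],
                       cand$level[i])
             model <- set_bounds(model, r, lb = cand$level[i], ub = ub)
           },
           down = {
             lb <- min(model$reactions$lower_bound[j], cand$release[i],
                       cand$level[i])
             model <- set_bounds(model, r, lb = lb, ub = cand$level[i])
           },
           knockout = { model <- set_bounds(model, r, lb = 0, ub = 0) })
  }
  model
}

# worst-case (minimum) product flux over a flux-space model
min_product_flux <- function(model, product) {
  lp <- lp_from_model(model)
  c_obj <- numeric(length(lp$rxn_ids))
  c_obj[match(product, lp$rxn_ids)] <- 1
  res <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = FALSE)
  if (res$status != "optimal") return(NA_real_)
  res$objective
}

#' Brute-force FORCE-set search (enumeration oracle)
#'
#' Evaluates every subset of <= k interventions with an inner LP and
#' returns the best guaranteed product flux.  Exponential; used as the
#' independent check on [solve_force_set()].
#'
#' @param must filtered `must_sets` with provenance.
#' @param product product exchange id.
#' @param k intervention budget.
#' @param extra_knockouts extra knockout candidate ids.
#' @return list(`guaranteed_flux`, `members` data.frame).
#' @export
enumerate_force_sets <- function(must, product, k,
                                 extra_knockouts = character(0)) {
  wt_model <- must$provenance$wt$context$model
  cand <- force_candidates(must, extra_knockouts)
  best <- list(guaranteed_flux = min_product_flux(wt_model, product),
               members = cand[0, , drop = FALSE])
  if (is.null(cand) || k == 0) return(best)
  nc <- nrow(cand)
  for (sz in seq_len(min(k, nc))) {
    for (sub in utils::combn(nc, sz, simplify = FALSE)) {
      m2 <- impose_interventions(wt_model, cand[sub, , drop = FALSE])
      g <- min_product_flux(m2, product)
      if (!is.na(g) && g > best$guaranteed_flux + 1e-9) {
        best <- list(guaranteed_flux = g,
                     members = cand[sub, , drop = FALSE])
      }
    }
  }
  best
}

#' FORCE-set search: bi-level program as a single-level MILP
#'
#' Chooses at most `k` interventions from the filtered MUST sets (plus
#' any extra knockout candidates) so as to maximise the guaranteed
#' (worst-case) product flux over the wild-type flux space with the
#' selected intervention bounds imposed.  The inner minimisation is
#' replaced by its LP dual, giving a single-level MILP whose bilinear
#' dual-times-binary terms are linearised with big-M constraints; every
#' incumbent is verified against the primal inner LP, and alternative
#' strategies are enumerated by adding integer cuts over previously
#' returned FORCE sets.
#'
#' @param model unused except for sanity checks; the inner space is the
#'   wild-type model carried by `must$provenance$wt`.
#' @param must filtered `must_sets` with provenance.
#' @param product product exchange reaction id.
#' @param k intervention budget (>= 0).
#' @param extra_knockouts extra knockout candidates (e.g. manually added
#'   literature candidates).
#' @param n_strategies how many alternative strategies to enumerate.
#' @param big_m big-M constant bounding dual variables.
#' @param min_flux strategies guaranteeing less than this are dropped.
#' @return list of `intervention_strategy` objects (possibly empty), each
#'   with `members` (data.frame reaction/kind/level),
#'   `guaranteed_product_flux` and `k`.
#' @export
solve_force_set <- function(model, must, product, k,
                            extra_knockouts = character(0),
                            n_strategies = 1L, big_m = 1000,
                            min_flux = 1e-6) {
  wt_model <- must$provenance$wt$context$model
  if (is.null(wt_model)) stop("must$provenance$wt lacks its bounded model")
  cand <- force_candidates(must, extra_knockouts)
  if (k == 0 || is.null(cand) || nrow(cand) == 0) {
    g <- min_product_flux(wt_model, product)
    return(list(structure(list(k = k, members = cand[0, , drop = FALSE],
                               guaranteed_product_flux = g,
                               fold_changes = numeric(0)),
                          class = "intervention_strategy")))
  }
  lp <- lp_from_model(wt_model)
  S <- lp$A
  m <- nrow(S); n <- ncol(S)
  rxn_ids <- lp$rxn_ids
  lb0 <- lp$lb; ub0 <- lp$ub
  cj <- match(cand$reaction, rxn_ids)
  nc <- nrow(cand)
  # per candidate: delta_lb (raise of lb when selected), delta_ub (drop of ub)
  dlb <- numeric(nc); dub <- numeric(nc)
  for (i in seq_len(nc)) {
    if (cand$kind[i] == "up") {
      dlb[i] <- cand$level[i] - lb0[cj[i]]
      dub[i] <- ub0[cj[i]] -
        max(ub0[cj[i]], cand$release[i], cand$level[i])   # <= 0: release
    }
    if (cand$kind[i] == "down") {
      dub[i] <- ub0[cj[i]] - cand$level[i]
      dlb[i] <- min(lb0[cj[i]], cand$release[i], cand$level[i]) -
        lb0[cj[i]]                                        # <= 0: release
    }
    if (cand$kind[i] == "knockout") {
      dlb[i] <- 0 - lb0[cj[i]]; dub[i] <- ub0[cj[i]] - 0
    }
  }
  # Single-level MILP: primal feasibility of the intervened wild-type
  # space, dual feasibility of its product-minimisation LP, and a strong
  # duality row tying the two, so that for any selection y the embedded
  # v is an inner OPTIMUM (the guaranteed product flux) and selections
  # with an infeasible inner problem are excluded by construction.
  # variable layout: v(n) | lambda(m) | mu(n) | nu(n) | zmu, znu(nc) | y(nc)
  i_v <- seq_len(n)
  i_lam <- n + seq_len(m)
  i_mu <- n + m + seq_len(n)
  i_nu <- n + m + n + seq_len(n)
  i_zmu <- n + m + 2 * n + seq_len(nc)
  i_znu <- n + m + 2 * n + nc + seq_len(nc)
  i_y <- n + m + 2 * n + 2 * nc + seq_len(nc)
  nv <- n + m + 2 * n + 2 * nc + nc
  jp <- match(product, rxn_ids)

  rows <- list(); rhs <- c(); sense <- c()
  addrow <- function(idx, val, s, b) {
    r <- numeric(nv); r[idx] <- val
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b); sense <<- c(sense, s)
  }
  # primal: S v = 0
  for (i in seq_len(m)) {
    nzj <- which(S[i, ] != 0)
    if (length(nzj) > 0) addrow(i_v[nzj], S[i, nzj], "=", 0)
  }
  # primal intervention bounds (linear in y; static bounds widened below)
  for (i in seq_len(nc)) {
    addrow(c(i_v[cj[i]], i_y[i]), c(-1, dlb[i]), "<", -lb0[cj[i]])
    addrow(c(i_v[cj[i]], i_y[i]), c(1, dub[i]), "<", ub0[cj[i]])
  }
  # dual feasibility: S' lambda + mu - nu = e_p
  for (j in seq_len(n)) {
    nzi <- which(S[, j] != 0)
    addrow(c(i_lam[nzi], i_mu[j], i_nu[j]), c(S[nzi, j], 1, -1), "=",
           as.numeric(j == jp))
  }
  # linearisation of zmu = mu_cand * y and znu = nu_cand * y
  for (i in seq_len(nc)) {
    addrow(c(i_zmu[i], i_y[i]), c(1, -big_m), "<", 0)
    addrow(c(i_zmu[i], i_mu[cj[i]]), c(1, -1), "<", 0)
    addrow(c(i_mu[cj[i]], i_zmu[i], i_y[i]), c(1, -1, big_m), "<", big_m)
    addrow(c(i_znu[i], i_y[i]), c(1, -big_m), "<", 0)
    addrow(c(i_znu[i], i_nu[cj[i]]), c(1, -1), "<", 0)
    addrow(c(i_nu[cj[i]], i_znu[i], i_y[i]), c(1, -1, big_m), "<", big_m)
  }
  addrow(i_y, rep(1, nc), "<", k)                  # budget
  # strong duality: v_p = mu'lb(y) - nu'ub(y)
  dual_idx <- c(i_mu, i_nu, i_zmu, i_znu)
  dual_coef <- c(lb0, -ub0, dlb, dub)
  fin <- is.finite(dual_coef)
  addrow(c(i_v[jp], dual_idx[fin]), c(1, -dual_coef[fin]), "=", 0)

  # static v bounds: widest over y in {0,1}
  vlb <- lb0; vub <- ub0
  for (i in seq_len(nc)) {
    vlb[cj[i]] <- min(vlb[cj[i]], lb0[cj[i]] + dlb[i])
    vub[cj[i]] <- max(vub[cj[i]], ub0[cj[i]] - dub[i])
  }
  obj <- numeric(nv); obj[i_v[jp]] <- 1
  lbv <- c(vlb, rep(-big_m, m), rep(0, 2 * n + 2 * nc), rep(0, nc))
  ubv <- c(vub, rep(big_m, m), rep(big_m, 2 * n + 2 * nc), rep(1, nc))
  # a dual on an infinite primal bound must be zero
  ubv[i_mu][!is.finite(lb0)] <- 0
  ubv[i_nu][!is.finite(ub0)] <- 0

  strategies <- list()
  cuts <- list()
  guard <- 0L
  while (length(strategies) < n_strategies && guard < 50L) {
    guard <- guard + 1L
    A <- do.call(rbind, rows)
    b <- rhs; sn <- sense
    for (cut in cuts) {
      r <- numeric(nv); r[i_y[cut]] <- 1
      A <- rbind(A, r); b <- c(b, length(cut) - 1); sn <- c(sn, "<")
    }
    # slacks for inequality rows
    ineq <- which(sn == "<")
    As <- cbind(A, matrix(0, nrow(A), length(ineq)))
    for (s in seq_along(ineq)) As[ineq[s], nv + s] <- 1
    res <- milp_solve(c(obj, numeric(length(ineq))), As, b,
                      c(lbv, numeric(length(ineq))),
                      c(ubv, rep(Inf, length(ineq))),
                      bin_idx = i_y, maximize = TRUE)
    if (res$status != "optimal") break
    ysel <- which(res$x[i_y] > 0.5)
    if (res$objective < min_flux) break
    # primal verification of the incumbent selection (assertion against
    # big-M loosening of the dual bounds)
    m2 <- impose_interventions(wt_model, cand[ysel, , drop = FALSE])
    g <- min_product_flux(m2, product)
    if (is.na(g) || abs(g - res$objective) >
        1e-4 * (1 + abs(res$objective))) {
      warning("FORCE-set MILP incumbent failed primal verification; ",
              "selection discarded")
      # exact no-good cut on this assignment only
      r <- numeric(nv); r[i_y] <- -1
      if (length(ysel) > 0) r[i_y[ysel]] <- 1
      A <- rbind(A, r)   # not retained across iterations deliberately
      cuts[[length(cuts) + 1L]] <- ysel   # fallback: subset cut
      if (length(ysel) == 0) break
      next
    }
    if (g < min_flux) break
    members <- cand[ysel, , drop = FALSE]
    rownames(members) <- NULL
    strategies[[length(strategies) + 1L]] <-
      structure(list(k = k, members = members,
                     guaranteed_product_flux = g),
                class = "intervention_strategy")
    if (length(ysel) == 0) break
    cuts[[length(cuts) + 1L]] <- ysel
  }
  ord <- order(vapply(strategies, `[[`, numeric(1),
                      "guaranteed_product_flux"), decreasing = TRUE)
  strategies[ord]
}

#' @export
print.intervention_strategy <- function(x, ...) {
  cat("intervention strategy (k =", x$k, "): guaranteed product flux",
      format(x$guaranteed_product_flux, digits = 6), "\n")
  if (nrow(x$members) > 0) {
    mark <- c(up = "up", down = "down", knockout = "KO")
    for (i in seq_len(nrow(x$members))) {
      cat("  ", mark[[x$members$kind[i]]], x$members$reaction[i],
          "level", format(x$members$level[i], digits = 5), "\n")
    }
  } else cat("   (no interventions)\n")
  invisible(x)
}

#' Fold changes of an intervention strategy
#'
#' Overexpression fold change: imposed lower bound divided by the
#' wild-type (MFA-constrained) maximum.  Downregulation: wild-type
#' minimum divided by the imposed upper bound.  Knockouts are reported as
#' `NA` with kind `"knockout"` (a deletion, not a fold change).  Division
#' by zero yields `Inf` rather than an error.
#'
#' @param strategy an `intervention_strategy`.
#' @param wt_space wild-type `flux_ranges`.
#' @return data.frame (`reaction`, `kind`, `fold_change`).
#' @export
fold_changes <- function(strategy, wt_space) {
  wt <- wt_space$ranges
  mem <- strategy$members
  fc <- numeric(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    r <- wt[wt$reaction == mem$reaction[i], ]
    fc[i] <- switch(mem$kind[i],
      up = if (abs(r$max) < 1e-12) Inf else mem$level[i] / r$max,
      down = if (abs(mem$level[i]) < 1e-12) Inf else r$min / mem$level[i],
      knockout = NA_real_)
  }
  data.frame(reaction = mem$reaction, kind = mem$kind, fold_change = fc,
             stringsAsFactors = FALSE)
}

#' Report simple futile cycles through candidate reactions
#'
#' Flags internal reactions that can carry flux with every exchange
#' closed (a necessary condition for participating in a
#' thermodynamically infeasible loop).  Diagnostic only; results are
#' never altered.
#'
#' @param model a `metabolic_model`.
#' @param candidates reaction ids to test (default: all enzymatic).
#' @return character vector of reaction ids that can cycle.
#' @export
report_cycles <- function(model, candidates = NULL) {
  ext <- model$reactions$kind %in% c("exchange", "demand")
  closed <- set_bounds(model, model$reactions$id[ext], lb = 0, ub = 0)
  # release forced fluxes (e.g. biomass turnover floors): only the
  # network's ability to cycle is of interest here
  pos <- closed$reactions$lower_bound > 0
  closed$reactions$lower_bound[pos] <- 0
  if (is.null(candidates)) {
    candidates <- model$reactions$id[model$reactions$kind == "enzymatic"]
  }
  rng <- fva(closed, targets = candidates)
  rng$ranges$reaction[abs(rng$ranges$min) > 1e-6 |
                      abs(rng$ranges$max) > 1e-6]
}
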