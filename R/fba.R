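# Flux balance analysis and derived linear-programming queries.
#
# All queries share one translation: the flux space {v : S v = 0,
# lb <= v <= ub}.  Coupling constraints added by the builders are ordinary
# pseudo-metabolite rows, so nothing here knows about them.
# Numerical conventions: feasibility tolerance 1e-9 inside the simplex;
# FVA and pFBA re-fix the objective at (1 - 1e-9) x optimum on the bound
# side to avoid degenerate-optimum chatter; reported values are raw LP
# solutions (no rounding).

lp_from_model <- function(model) {
  S <- stoichiometric_matrix(model)
  list(A = S, rhs = rep(0, nrow(S)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       rxn_ids = model$reactions$id)
}

objective_vector <- function(model) {
  if (is.null(model$objective)) stop("model has no objective")
  c_obj <- numeric(nrow(model$reactions))
  j <- match(model$objective$reaction, model$reactions$id)
  if (is.na(j)) stop("objective reaction not in model")
  c_obj[j] <- 1
  c_obj
}

new_flux_solution <- function(status, objective = NA_real_,
                              fluxes = numeric(0)) {
  structure(list(objective_value = objective, fluxes = fluxes,
                 status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal") {
    cat(", objective =", format(x$objective_value, digits = 7))
  }
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model objective over the steady-state flux
#' space `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `metabolic_model` with an objective.
#' @return a `flux_solution`: list with `objective_value`, `fluxes` (named
#'   vector, mmol/gDW/h) and `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`).
#' @export
fba <- function(model) {
  lp <- lp_from_model(model)
  res <- lp_solve(objective_vector(model), lp$A, lp$rhs, lp$lb, lp$ub,
                  maximize = model$objective$direction == "max")
  if (res$status != "optimal") return(new_flux_solution(res$status))
  new_flux_solution("optimal", res$objective,
                    stats::setNames(res$x, lp$rxn_ids))
}

#' Parsimonious flux balance analysis
#'
#' Fixes the FBA optimum (within 1e-9 relative) and then minimises the sum
#' of absolute fluxes, by splitting every flux into non-negative forward
#' and reverse parts.
#'
#' @param model a `metabolic_model` with an objective.
#' @return a `flux_solution`; `objective_value` is the FBA optimum and the
#'   attribute `total_flux` carries the minimised sum of absolute fluxes.
#' @export
pfba <- function(model) {
  base <- fba(model)
  if (base$status != "optimal") return(base)
  lp <- lp_from_model(model)
  n <- ncol(lp$A)
  j <- match(model$objective$reaction, lp$rxn_ids)
  opt <- base$objective_value
  lb <- lp$lb; ub <- lp$ub
  eps <- abs(opt) * 1e-9
  if (model$objective$direction == "max") lb[j] <- opt - eps else
    ub[j] <- opt + eps
  # split v = f - r, f, r >= 0; min sum(f + r)
  A2 <- cbind(lp$A, -lp$A)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  obj2 <- rep(-1, 2 * n)                      # maximise -(sum f + sum r)
  res <- lp_solve(obj2, A2, lp$rhs, lb2, ub2, maximize = TRUE)
  if (res$status != "optimal") return(new_flux_solution(res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  out <- new_flux_solution("optimal", v[j],
                           stats::setNames(v, lp$rxn_ids))
  attr(out, "total_flux") <- -res$objective
  out
}

new_flux_ranges <- function(df, context = list()) {
  structure(list(ranges = df, context = context), class = "flux_ranges")
}

#' @export
print.flux_ranges <- function(x, ...) {
  cat("flux_ranges over", nrow(x$ranges), "reactions\n")
  print(utils::head(x$ranges, 10))
  if (nrow(x$ranges) > 10) cat("...\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Computes, for each target reaction, the minimum and maximum flux over
#' the (optionally further constrained) steady-state flux space.
#'
#' @param model a `metabolic_model`.
#' @param fixed optional data.frame of bound edits applied before the
#'   scan: columns `reaction`, `lb`, `ub` (`NA` leaves a bound alone).
#' @param targets reaction ids to scan (default: all).
#' @param fix_objective if `TRUE`, first solve FBA (after `fixed` edits)
#'   and pin the objective flux at `(1 - 1e-9) x optimum` on its bound
#'   side before scanning.
#' @return a `flux_ranges`: `$ranges` is a data.frame
#'   (`reaction`, `min`, `max`), `$context` records the edits.
#' @export
fva <- function(model, fixed = NULL, targets = NULL,
                fix_objective = FALSE) {
  if (!is.null(fixed)) {
    model <- set_bounds(model, fixed$reaction,
                        lb = if (is.null(fixed$lb)) NA else fixed$lb,
                        ub = if (is.null(fixed$ub)) NA else fixed$ub)
  }
  obj_opt <- NA_real_
  if (fix_objective) {
    base <- fba(model)
    if (base$status != "optimal") {
      stop("FVA pre-solve not optimal (", base$status,
           ") under the fixed constraint set")
    }
    obj_opt <- base$objective_value
    j <- model$objective$reaction
    eps <- abs(obj_opt) * 1e-9
    if (model$objective$direction == "max") {
      model <- set_bounds(model, j, lb = obj_opt - eps)
    } else {
      model <- set_bounds(model, j, ub = obj_opt + eps)
    }
  }
  lp <- lp_from_model(model)
  if (is.null(targets)) targets <- lp$rxn_ids
  idx <- match(targets, lp$rxn_ids)
  if (anyNA(idx)) stop("unknown FVA target(s): ",
                       paste(targets[is.na(idx)], collapse = ", "))
  mins <- maxs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    c_obj <- numeric(length(lp$rxn_ids)); c_obj[idx[k]] <- 1
    lo <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = FALSE)
    hi <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("flux space infeasible under the fixed constraint set ",
           "(reaction ", targets[k], ")")
    }
    mins[k] <- if (lo$status == "optimal") lo$objective else -Inf
    maxs[k] <- if (hi$status == "optimal") hi$objective else Inf
  }
  new_flux_ranges(data.frame(reaction = targets, min = mins, max = maxs,
                             stringsAsFactors = FALSE),
                  context = list(fixed = fixed,
                                 fix_objective = fix_objective,
                                 objective_optimum = obj_opt))
}

#' Minimum uptake required for a growth target
#'
#' Minimises the flux of one uptake reaction subject to the model
#' objective (growth) being at least `mu_target`.
#'
#' @param model a `metabolic_model` with a growth objective.
#' @param uptake uptake reaction id.
#' @param mu_target required growth rate, 1/h.
#' @return minimum uptake flux, mmol/gDW/h.
#' @export
min_uptake_for_growth <- function(model, uptake, mu_target) {
  model <- set_bounds(model, model$objective$reaction, lb = mu_target)
  lp <- lp_from_model(model)
  j <- match(uptake, lp$rxn_ids)
  if (is.na(j)) stop("unknown uptake reaction: ", uptake)
  c_obj <- numeric(length(lp$rxn_ids)); c_obj[j] <- 1
  res <- lp_solve(c_obj, lp$A, lp$rhs, lp$lb, lp$ub, maximize = FALSE)
  if (res$status != "optimal") {
    stop("growth target ", mu_target, " infeasible at any uptake")
  }
  res$objective
}

#' Turnover (total production rate) of a metabolite in a flux solution
#'
#' Sums `max(0, coefficient x flux)` over all reactions touching the
#' metabolite: total production, which at steady state equals total
#' consumption.
#'
#' @param model a `metabolic_model`.
#' @param solution an optimal `flux_solution`.
#' @param met metabolite id.
#' @return production rate, mmol/gDW/h.
#' @export
metabolite_turnover <- function(model, solution, met) {
  if (solution$status != "optimal") stop("solution is not optimal")
  if (!met %in% model$metabolites$id) stop("unknown metabolite: ", met)
  tot <- 0
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (met %in% names(st)) {
      tot <- tot + max(0, st[[met]] * solution$fluxes[[rid]])
    }
  }
  tot
}

#' Export a flux solution or flux ranges as TSV/JSON
#' @param x a `flux_solution` or `flux_ranges`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (inherits(x, "flux_solution")) {
    data.frame(reaction = names(x$fluxes), flux = as.numeric(x$fluxes),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "flux_ranges")) {
    x$ranges
  } else stop("unsupported object")
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
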