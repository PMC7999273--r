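# Independent oracles used against the package's own simplex.
#
# oracle_lp(): exhaustive vertex enumeration -- every basis subset with
# every lower/upper assignment of the nonbasic variables -- so it shares
# no code path with the iterative solver.  Only for tiny instances with
# finite bounds.

oracle_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE) {
  verts <- diazoflux:::lp_enumerate_vertices(A, rhs, lb, ub)
  if (length(verts) == 0) return(list(status = "infeasible"))
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  best <- if (maximize) which.max(vals) else which.min(vals)
  list(status = "optimal", objective = vals[best], x = verts[[best]])
}

oracle_fva <- function(A, rhs, lb, ub, j) {
  verts <- diazoflux:::lp_enumerate_vertices(A, rhs, lb, ub)
  stopifnot(length(verts) > 0)
  vals <- vapply(verts, `[`, numeric(1), j)
  c(min = min(vals), max = max(vals))
}

# Brute-force binary MILP oracle: enumerate all 0/1 assignments of the
# binary variables, solve the continuous LP for each, keep the best.
oracle_milp <- function(obj, A, rhs, lb, ub, bin_idx, maximize = TRUE) {
  best <- NULL
  grid <- expand.grid(rep(list(0:1), length(bin_idx)))
  for (g in seq_len(nrow(grid))) {
    lo <- lb; hi <- ub
    lo[bin_idx] <- pmax(lo[bin_idx], as.numeric(grid[g, ]))
    hi[bin_idx] <- pmin(hi[bin_idx], as.numeric(grid[g, ]))
    if (any(lo > hi)) next
    r <- diazoflux:::lp_solve(obj, A, rhs, lo, hi, maximize = maximize)
    if (r$status != "optimal") next
    if (is.null(best) ||
        (maximize && r$objective > best$objective + 1e-9) ||
        (!maximize && r$objective < best$objective - 1e-9)) {
      best <- r
    }
  }
  if (is.null(best)) list(status = "infeasible") else best
}

# random LP generator with a guaranteed-feasible interior point
random_bounded_lp <- function(m, n) {
  A <- matrix(round(stats::rnorm(m * n), 2), m, n)
  lb <- round(stats::runif(n, -4, 0), 2)
  ub <- lb + round(stats::runif(n, 0.5, 6), 2)
  x0 <- lb + stats::runif(n) * (ub - lb)
  list(obj = round(stats::rnorm(n), 2), A = A,
       rhs = as.numeric(A %*% x0), lb = lb, ub = ub)
}
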