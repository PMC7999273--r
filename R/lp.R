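# Linear and mixed-integer programming engine.
#
# All flux computations in the package reduce to LPs of the form
#   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with a dense constraint matrix (metabolite rows x reaction columns).
# The solver below is a two-phase bounded-variable revised simplex with a
# product-form basis-inverse update, periodic refactorisation, and a Bland
# anti-cycling fallback.  Problem sizes in this package are small (tens of
# rows/columns), so a dense implementation is adequate and keeps runs
# bit-reproducible: pivoting is deterministic (Dantzig rule with
# lowest-index tie-break).
#
# The MILP solver is a depth-first branch-and-bound over binary variables
# on top of the LP solver; it is used by the strain-design module.

#' Solve a bounded linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A x = rhs` and
#' `lb <= x <= ub`.  Infinite bounds are allowed.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n); rows are equality constraints.
#' @param rhs right-hand side (length m).
#' @param lb,ub variable bounds (length n); may contain `-Inf`/`Inf`.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (optimal value, `NA` unless optimal) and `x` (primal
#'   solution, length n).
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, rhs, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  # fast configuration first; on numerical breakdown (singular basis)
  # retry with conservative pivoting (Bland's rule, larger pivot
  # threshold, frequent refactorisation) -- deterministic in both modes
  tryCatch(
    lp_solve_core(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                  pivot_tol = 1e-10, bland = FALSE, refac = 200L),
    error = function(e) {
      if (!grepl("singular", conditionMessage(e))) stop(e)
      lp_solve_core(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                    pivot_tol = 1e-7, bland = TRUE, refac = 25L)
    })
}

lp_solve_core <- function(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                          pivot_tol, bland, refac) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  sgn <- if (maximize) 1 else -1
  cvec <- sgn * as.numeric(obj)

  # --- initial nonbasic values: bound nearest zero; free variables at 0 ---
  xN <- numeric(n)
  for (j in seq_len(n)) {
    lo <- lb[j]; hi <- ub[j]
    xN[j] <- if (is.finite(lo) && is.finite(hi)) {
      if (abs(lo) <= abs(hi)) lo else hi
    } else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
  }

  # --- augment with artificial variables (phase 1 basis) ---
  resid <- as.numeric(rhs - A %*% xN)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, nrow = m, ncol = m))
  ntot <- n + m
  x <- c(xN, abs(resid))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))
  Binv <- diag(1 / art_sign, nrow = m, ncol = m)   # inverse of the artificial basis

  c_ph1 <- c(rep(0, n), rep(-1, m))

  refactor <- function(basis) {
    B <- Afull[, basis, drop = FALSE]
    solve(B)
  }
  recompute_xB <- function(basis, x) {
    nb <- setdiff(seq_len(ntot), basis)
    as.numeric(Binv %*% (rhs - Afull[, nb, drop = FALSE] %*% x[nb]))
  }

  iter <- 0L
  degen_run <- 0L
  phase <- 1L
  cc <- c_ph1

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit reached")
    if (iter %% refac == 0L) {
      Binv <- refactor(basis)
      x[basis] <- recompute_xB(basis, x)
    }

    # reduced costs
    cB <- cc[basis]
    yrow <- as.numeric(crossprod(cB, Binv))          # c_B' B^-1
    rc <- cc - as.numeric(yrow %*% Afull)
    rc[basis] <- 0

    # entering variable: improving nonbasic with room to move
    cand <- which(!in_basis & (lbf < ubf - 1e-15))
    improving <- cand[(rc[cand] > tol & x[cand] < ubf[cand] - 1e-15) |
                      (rc[cand] < -tol & x[cand] > lbf[cand] + 1e-15)]
    if (length(improving) == 0L) {
      # phase transition or optimality
      if (phase == 1L) {
        ph1_obj <- -sum(x[n + seq_len(m)])
        if (ph1_obj < -1e-7) {
          return(list(status = "infeasible", objective = NA_real_,
                      x = rep(NA_real_, n)))
        }
        # fix artificials at zero and switch to the true objective
        lbf[n + seq_len(m)] <- 0
        ubf[n + seq_len(m)] <- 0
        x[n + seq_len(m)][!in_basis[n + seq_len(m)]] <- 0
        cc <- c(cvec, rep(0, m))
        phase <- 2L
        degen_run <- 0L
        next
      }
      Binv <- refactor(basis)
      x[basis] <- recompute_xB(basis, x)
      xs <- x[seq_len(n)]
      return(list(status = "optimal",
                  objective = sum(obj * xs),
                  x = xs,
                  iterations = iter))
    }

    if (bland || degen_run > 100L) {
      enter <- min(improving)                        # Bland's rule
    } else {
      enter <- improving[which.max(abs(rc[improving]))]
    }
    dirn <- if (rc[enter] > 0) 1 else -1

    ycol <- as.numeric(Binv %*% Afull[, enter])
    # ratio test: step t >= 0 moving x[enter] by dirn * t.
    # Among (near-)tying blocking rows, leave on the largest pivot for
    # numerical stability of the product-form update.
    delta <- dirn * ycol                             # x_B changes by -delta*t
    tflip <- ubf[enter] - lbf[enter]                 # bound-to-bound flip
    if (!is.finite(tflip)) tflip <- Inf
    ratios <- rep(Inf, m)
    sides <- character(m)
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (delta[i] > pivot_tol) {
        ratios[i] <- max(0, x[bi] - lbf[bi]) / delta[i]
        sides[i] <- "lb"
      } else if (delta[i] < -pivot_tol) {
        room <- ubf[bi] - x[bi]
        if (is.finite(room)) {
          ratios[i] <- max(0, room) / (-delta[i])
          sides[i] <- "ub"
        }
      }
    }
    t_min <- min(ratios, tflip)
    leave <- 0L; leave_to <- NA_character_
    if (t_min < tflip - 1e-12 || (is.finite(t_min) && t_min <= tflip)) {
      near <- which(is.finite(ratios) & ratios <= t_min + 1e-9)
      if (length(near) > 0 && t_min <= tflip) {
        leave <- near[which.max(abs(delta[near]))]
        leave_to <- sides[leave]
      }
    }
    t_best <- if (leave > 0L) ratios[leave] else tflip
    if (!is.finite(t_best)) {
      if (phase == 2L) {
        return(list(status = "unbounded", objective = NA_real_,
                    x = rep(NA_real_, n)))
      }
      stop("phase-1 subproblem unbounded; malformed constraints")
    }
    t_best <- max(t_best, 0)
    degen_run <- if (t_best < 1e-11) degen_run + 1L else 0L

    # apply the step
    x[enter] <- x[enter] + dirn * t_best
    x[basis] <- x[basis] - delta * t_best
    if (leave == 0L) {
      # bound flip, basis unchanged
      next
    }
    bi <- basis[leave]
    x[bi] <- if (leave_to == "lb") lbf[bi] else ubf[bi]
    # product-form update of Binv: row `leave` pivots on ycol[leave]
    piv <- ycol[leave]
    Erow <- Binv[leave, ] / piv
    Binv <- Binv - outer(ycol, Erow)
    Binv[leave, ] <- Erow
    in_basis[bi] <- FALSE
    in_basis[enter] <- TRUE
    basis[leave] <- enter
  }
}

#' Solve a mixed-integer linear program with binary variables
#'
#' Depth-first branch-and-bound over the variables listed in `bin_idx`
#' (bounds must be within \[0, 1\]); all other variables are continuous.
#' Deterministic: branching picks the most fractional binary (lowest index
#' on ties) and explores the rounded-up branch first.
#'
#' @inheritParams lp_solve
#' @param bin_idx integer indices of binary variables.
#' @param int_tol integrality tolerance.
#' @return list with `status` ("optimal" or "infeasible"), `objective`, `x`.
#' @keywords internal
#' @noRd
milp_solve <- function(obj, A, rhs, lb, ub, bin_idx, maximize = TRUE,
                       tol = 1e-9, int_tol = 1e-6, node_limit = 100000L) {
  best <- list(status = "infeasible", objective = -Inf, x = NULL)
  sgn <- if (maximize) 1 else -1
  # node: list(lb, ub)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0L) {
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("branch-and-bound node limit reached")
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(obj, A, rhs, node$lb, node$ub, maximize = maximize,
                    tol = tol)
    if (rel$status != "optimal") next
    if (sgn * rel$objective <= sgn * best$objective + 1e-9 &&
        !is.null(best$x)) next                      # bound pruning
    frac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    if (all(frac <= int_tol)) {
      if (is.null(best$x) || sgn * rel$objective > sgn * best$objective) {
        best <- list(status = "optimal", objective = rel$objective,
                     x = rel$x)
      }
      next
    }
    j <- bin_idx[which.max(frac)]
    lb0 <- node$lb; ub0 <- node$ub
    dn <- node; dn$ub[j] <- floor(rel$x[j])
    up <- node; up$lb[j] <- ceiling(rel$x[j])
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up               # explored first (LIFO)
  }
  if (is.null(best$x)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  best
}

# Exhaustive vertex-enumeration LP oracle.  Enumerates every basis subset
# of the columns together with every lower/upper assignment of the
# nonbasic variables, keeps the feasible basic solutions, and optimises by
# direct comparison.  Exponential: intended only for tiny instances
# (n <= ~12) as an independent check on the simplex.
lp_enumerate_vertices <- function(A, rhs, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(n <= 16, all(is.finite(lb)), all(is.finite(ub)))
  verts <- list()
  basis_sets <- utils::combn(n, min(m, n), simplify = FALSE)
  for (bs in basis_sets) {
    B <- A[, bs, drop = FALSE]
    if (m != length(bs)) next
    qr_B <- qr(B)
    if (qr_B$rank < m) next
    nb <- setdiff(seq_len(n), bs)
    grid <- if (length(nb) > 0) {
      do.call(expand.grid, lapply(nb, function(j) c(lb[j], ub[j])))
    } else {
      data.frame(row.names = 1)
    }
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(nb) > 0) x[nb] <- as.numeric(grid[g, ])
      rb <- rhs - if (length(nb) > 0) A[, nb, drop = FALSE] %*% x[nb] else rhs * 0
      xb <- qr.coef(qr_B, rb)
      x[bs] <- xb
      if (all(x >= lb - tol) && all(x <= ub + tol)) {
        verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
      }
    }
  }
  verts
}
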