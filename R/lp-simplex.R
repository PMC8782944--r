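## Dense two-phase primal simplex with Bland's anti-cycling rule.
## Small metabolic models (tens to a few hundred reactions) make a dense
## tableau entirely adequate, and owning the solver keeps flux results
## bit-reproducible across platforms.

## One simplex phase on an existing tableau.
## Tb: m x (ncol) constraint matrix with rhs as last column, b >= 0
## obj: reduced-cost row (length ncol), maximizing; optimal when all
##      non-basic reduced costs are >= -tol
.simplex_phase <- function(Tb, obj, basis, tol = 1e-9, maxit = 50000L) {
  m <- nrow(Tb); ncols <- ncol(Tb) - 1L
  for (it in seq_len(maxit)) {
    ## Bland: entering = smallest-index column with negative reduced cost
    enter <- 0L
    for (j in seq_len(ncols)) {
      if (obj[j] < -tol && !(j %in% basis)) { enter <- j; break }
    }
    if (enter == 0L) return(list(Tb = Tb, obj = obj, basis = basis,
                                 status = "optimal"))
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tb = Tb, obj = obj, basis = basis,
                                  status = "unbounded"))
    ratio <- Tb[pos, ncols + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    leave <- cand[which.min(basis[cand])]   # Bland tie-break
    ## pivot
    piv <- Tb[leave, enter]
    Tb[leave, ] <- Tb[leave, ] / piv
    other <- setdiff(seq_len(m), leave)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, enter], Tb[leave, ])
    obj <- obj - obj[enter] * Tb[leave, ]
    basis[leave] <- enter
  }
  list(Tb = Tb, obj = obj, basis = basis, status = "maxit")
}

#' Solve a linear program in standard form
#'
#' Maximize `obj . z` subject to `A z = b`, `z >= 0`, by the two-phase
#' primal simplex method with Bland's rule (deterministic, cycle-free).
#'
#' @param obj objective coefficients (length = ncol(A)).
#' @param A constraint matrix.
#' @param b right-hand side.
#' @param tol feasibility/optimality tolerance.
#' @return list(status = "optimal"|"infeasible"|"unbounded", z, objective).
#' @export
simplex_solve <- function(obj, A, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n)
  ## normalize rows so b >= 0
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ## phase I: artificials with identity basis
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ## phase-I reduced costs for max(-sum artificials)
  obj1 <- c(-colSums(A), rep(0, m), -sum(b))
  ph1 <- .simplex_phase(Tb, obj1, basis, tol = tol)
  if (ph1$status != "optimal" || ph1$obj[n + m + 1L] < -1e-7)
    return(list(status = "infeasible", z = NULL, objective = NA_real_))
  Tb <- ph1$Tb; basis <- ph1$basis
  ## drive leftover zero-level artificials out of the basis
  keep_rows <- rep(TRUE, m)
  for (r in which(basis > n)) {
    pivot_col <- which(abs(Tb[r, seq_len(n)]) > tol)[1]
    if (is.na(pivot_col)) { keep_rows[r] <- FALSE; next }   # redundant row
    piv <- Tb[r, pivot_col]
    Tb[r, ] <- Tb[r, ] / piv
    other <- setdiff(seq_len(m), r)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, pivot_col], Tb[r, ])
    basis[r] <- pivot_col
  }
  Tb <- Tb[keep_rows, c(seq_len(n), n + m + 1L), drop = FALSE]
  basis <- basis[keep_rows]
  m2 <- nrow(Tb)
  ## phase II reduced costs: c_B B^-1 A - c
  obj2 <- c(drop(obj[basis] %*% Tb[, seq_len(n), drop = FALSE]) - obj,
            drop(obj[basis] %*% Tb[, n + 1L]))
  ph2 <- .simplex_phase(Tb, obj2, basis, tol = tol)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", z = NULL, objective = Inf))
  if (ph2$status != "optimal")
    return(list(status = "maxit", z = NULL, objective = NA_real_))
  z <- numeric(n)
  z[ph2$basis] <- ph2$Tb[, n + 1L]
  z[z < 0 & z > -1e-7] <- 0
  list(status = "optimal", z = z, objective = sum(obj * z),
       basis = ph2$basis)
}

#' Solve a box-bounded linear program
#'
#' Maximize (or minimize) `obj . v` subject to `S v = rhs` and
#' `lb <= v <= ub` (finite bounds), via conversion to standard form. The
#' returned solution is polished by re-solving the optimal basis against
#' the original constraints, so equality residuals are at machine
#' precision.
#'
#' @param obj objective over the original variables.
#' @param S equality-constraint matrix.
#' @param lb,ub finite bound vectors.
#' @param rhs equality right-hand side (default zero vector).
#' @param maximize logical.
#' @return list(status, v, objective).
#' @export
solve_lp <- function(obj, S, lb, ub, rhs = NULL, maximize = TRUE) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  if (is.null(rhs)) rhs <- numeric(m)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)))
  if (any(lb > ub))
    return(list(status = "infeasible", v = NULL, objective = NA_real_))
  sgn <- if (maximize) 1 else -1
  ## x = v - lb in [0, u]; upper bounds via slack rows
  u <- ub - lb
  b0 <- drop(rhs - S %*% lb)
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(b0, u)
  res <- simplex_solve(c(sgn * obj, rep(0, n)), A, b)
  if (res$status != "optimal")
    return(list(status = res$status, v = NULL,
                objective = if (res$status == "unbounded") sgn * Inf
                            else NA_real_))
  ## polish: exact basis solve against the original system
  z <- res$z
  if (!is.null(res$basis)) {
    B <- A[, res$basis, drop = FALSE]
    ## rows can exceed basis size when redundant constraints were
    ## dropped; the system is consistent, so least squares is exact
    zb <- tryCatch(qr.solve(B, b), error = function(e) NULL)
    if (!is.null(zb) && all(zb > -1e-7) &&
        max(abs(B %*% zb - b)) < 1e-6) {
      z <- numeric(2L * n)
      z[res$basis] <- pmax(zb, 0)
    }
  }
  v <- z[seq_len(n)] + lb
  list(status = "optimal", v = v, objective = sum(obj * v))
}
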