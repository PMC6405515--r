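#' Solve a bounded-variable linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `A %*% x = b` and
#' `lower <= x <= upper`, with a dense two-phase simplex. Variables are
#' shifted to their lower bounds and finite upper bounds become explicit
#' slack rows, so the tableau is the textbook standard form. Bland's rule
#' is used throughout, which makes the solve deterministic and immune to
#' cycling at the cost of some speed; problem sizes in this package
#' (tens of reactions) make that a good trade.
#'
#' This solver exists because the analysis needs exact LP optima
#' (flux-balance maxima and minimum-weighted-total-flux demands) and is
#' deliberately self-contained; it is validated in the test suite against
#' brute-force vertex enumeration of the flux polytope.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A dense or sparse constraint matrix (m x n) of equality rows.
#' @param b right-hand side, length m.
#' @param lower,upper variable bounds, length n, all finite.
#' @param maximize if `TRUE` maximise the objective.
#' @param tol pivot tolerance.
#'
#' @return a list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objval` (objective at the optimum, on the original scale) and `x`
#'   (optimal point, length n).
#' @export
lp_solve <- function(obj, A, b, lower, upper, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("lp_solve requires finite variable bounds")
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))

  cvec <- if (maximize) -obj else obj

  # shift x = lower + y, 0 <= y <= d
  d <- upper - lower
  b2 <- b - as.vector(A %*% lower)

  # structural columns: y (n), slack columns for upper-bound rows (n_ub)
  ub_rows <- which(d > 0)        # rows y_i + s_i = d_i; d == 0 vars are fixed
  n_ub <- length(ub_rows)
  fixed <- which(d <= 0)

  # fixed variables contribute nothing; drop them from the tableau by
  # treating y_i = 0 (already folded into b2 via the shift).
  # Build constraint block:
  #   [ A_y  0   ]  = b2        (m rows, artificials added)
  #   [ E    I   ]  = d[ub]     (n_ub rows, slack basic)
  nvar <- n + n_ub
  ncolT <- nvar + m            # + artificials for the m equality rows
  nrowT <- m + n_ub

  Tm <- matrix(0, nrowT, ncolT + 1)
  Tm[seq_len(m), seq_len(n)] <- A
  if (n_ub > 0) {
    Tm[cbind(m + seq_len(n_ub), ub_rows)] <- 1
    Tm[cbind(m + seq_len(n_ub), n + seq_len(n_ub))] <- 1
    Tm[m + seq_len(n_ub), ncolT + 1] <- d[ub_rows]
  }
  Tm[seq_len(m), ncolT + 1] <- b2
  # make equality RHS nonnegative, then attach artificials
  for (i in seq_len(m)) {
    if (Tm[i, ncolT + 1] < 0) Tm[i, ] <- -Tm[i, ]
    Tm[i, nvar + i] <- 1
  }
  if (length(fixed) > 0) Tm[, fixed] <- 0   # fixed vars removed from play

  basis <- c(nvar + seq_len(m),                       # artificials
             if (n_ub > 0) n + seq_len(n_ub) else integer(0))  # ub slacks

  pivot <- function(Tm, r, pc) {
    Tm[r, ] <- Tm[r, ] / Tm[r, pc]
    other <- setdiff(seq_len(nrow(Tm)), r)
    Tm[other, ] <- Tm[other, ] - outer(Tm[other, pc], Tm[r, ])
    Tm
  }

  run_simplex <- function(Tm, basis, cost, allowed) {
    # cost: length ncolT vector; allowed: columns eligible to enter
    repeat {
      # reduced costs: c_j - c_B %*% B^-1 A_j  (tableau already in B^-1 A form)
      cb <- cost[basis]
      red <- cost[allowed] - as.vector(crossprod(Tm[, allowed, drop = FALSE], cb))
      enter_idx <- which(red < -tol)
      if (length(enter_idx) == 0) return(list(Tm = Tm, basis = basis, status = "optimal"))
      pc <- allowed[min(enter_idx)]                 # Bland: smallest index
      col <- Tm[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(Tm = Tm, basis = basis, status = "unbounded"))
      ratios <- Tm[pos, ncolT + 1] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      r <- cand[which.min(basis[cand])]             # Bland tie-break
      Tm <- pivot(Tm, r, pc)
      basis[r] <- pc
    }
  }

  # ---- phase 1: drive artificials to zero
  cost1 <- c(rep(0, nvar), rep(1, m))
  allowed1 <- setdiff(seq_len(ncolT), fixed)
  res <- run_simplex(Tm, basis, cost1, allowed1)
  if (res$status == "unbounded") stop("internal: phase-1 LP unbounded")
  Tm <- res$Tm; basis <- res$basis
  phase1_obj <- sum(cost1[basis] * Tm[, ncolT + 1])
  if (phase1_obj > 1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))

  # pivot surviving artificials out of the basis (degenerate rows)
  art <- which(basis > nvar)
  for (r in art) {
    row <- Tm[r, seq_len(nvar)]
    cands <- setdiff(which(abs(row) > tol), fixed)
    if (length(cands) > 0) {
      pc <- min(cands)
      Tm <- pivot(Tm, r, pc)
      basis[r] <- pc
    }
    # else: redundant row; harmless to leave (RHS is 0)
  }

  # ---- phase 2
  cost2 <- c(cvec, rep(0, n_ub), rep(Inf, m))  # artificials barred
  allowed2 <- setdiff(seq_len(nvar), fixed)
  cost2[!is.finite(cost2)] <- 0                # never entered: excluded below
  res <- run_simplex(Tm, basis, cost2, allowed2)
  if (res$status == "unbounded")
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, n)))
  Tm <- res$Tm; basis <- res$basis

  y <- numeric(nvar)
  inb <- basis <= nvar
  y[basis[inb]] <- Tm[inb, ncolT + 1]
  x <- lower + y[seq_len(n)]
  objval <- sum(obj * x)
  list(status = "optimal", objval = objval, x = x)
}
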