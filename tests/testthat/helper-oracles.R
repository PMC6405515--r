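# Brute-force oracles, independent of the package's simplex:
# vertex enumeration of the box-bounded flux polytope {S v = 0, lb <= v <= ub}.
# Every LP optimum over a pointed polytope is attained at a vertex, so
# optimising over the enumerated vertex set is an exact (if exponential)
# reference for both the capability LP and, in split space, the demand LP.

enum_vertices <- function(S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  # independent rows
  qrt <- qr(t(S))
  r <- qrt$rank
  if (r > 0) S <- S[qrt$pivot[seq_len(r)], , drop = FALSE]
  if (r == 0) {
    # box only: vertices are the corners
    grid <- as.matrix(expand.grid(lapply(seq_len(n), function(i) c(lb[i], ub[i]))))
    return(unique(grid))
  }
  verts <- list()
  for (Bidx in utils::combn(n, r, simplify = FALSE)) {
    SB <- S[, Bidx, drop = FALSE]
    if (qr(SB)$rank < r) next
    Nidx <- setdiff(seq_len(n), Bidx)
    k <- length(Nidx)
    if (k == 0) {
      VN <- matrix(numeric(0), 1, 0)
      VB <- matrix(0, r, 1)       # S_B v_B = 0 has the unique solution 0
    } else {
      # all 2^k bound assignments of the nonbasic variables, solved at once
      VN <- as.matrix(expand.grid(lapply(Nidx, function(i) c(lb[i], ub[i]))))
      VB <- -solve(SB, S[, Nidx, drop = FALSE] %*% t(VN)) # r x 2^k
    }
    okcol <- apply(VB >= lb[Bidx] - tol & VB <= ub[Bidx] + tol, 2, all)
    for (j in which(okcol)) {
      v <- numeric(n)
      v[Bidx] <- VB[, j]
      v[Nidx] <- VN[j, ]
      verts[[length(verts) + 1]] <- v
    }
  }
  if (length(verts) == 0) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  unique(round(V, 9))
}

# exact LP max of c.v over {S v = 0, lb <= v <= ub}, via vertices
oracle_lp_max <- function(S, lb, ub, cvec) {
  V <- enum_vertices(S, lb, ub)
  if (nrow(V) == 0) return(NA_real_)
  max(as.vector(V %*% cvec))
}

# exact min of sum w|v| subject to S v = 0, bounds, and v[target] >= t:
# linearised by the same forward/reverse split used by the engine, then
# enumerated in split space (only tractable for small n)
oracle_demand_min <- function(S, lb, ub, w, target_idx, t) {
  lb[target_idx] <- max(lb[target_idx], t)
  if (lb[target_idx] > ub[target_idx]) return(NA_real_)
  S2 <- cbind(as.matrix(S), -as.matrix(S))
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  V <- enum_vertices(S2, lo, hi)
  if (nrow(V) == 0) return(NA_real_)
  min(as.vector(V %*% c(w, w)))
}

# random small flux networks with a guaranteed uptake -> ... -> secretion
# spine, used for oracle comparisons
random_small_model <- function(n_rxn = 6, seed = 1) {
  set.seed(seed)
  n_met <- max(2, n_rxn - 2)
  mets <- paste0("m", seq_len(n_met))
  rxns <- list()
  rxns[["EX_in"]] <- list(stoichiometry = stats::setNames(-1, mets[1]),
                          lower_bound = -round(runif(1, 5, 15), 1), upper_bound = 0)
  rxns[["EX_out"]] <- list(stoichiometry = stats::setNames(-1, mets[n_met]),
                           lower_bound = 0, upper_bound = round(runif(1, 5, 20), 1))
  for (j in seq_len(n_rxn - 2)) {
    a <- sample(n_met, 1)
    b <- sample(setdiff(seq_len(n_met), a), 1)
    st <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)), c(mets[a], mets[b]))
    rev <- runif(1) < 0.3
    rxns[[paste0("R", j)]] <- list(stoichiometry = st,
                                   lower_bound = if (rev) -10 else 0,
                                   upper_bound = 10)
  }
  network_model(data.frame(id = mets), rxns, default_bound = 50)
}
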