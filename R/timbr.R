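#' Maximum production capability of a metabolite
#'
#' Solves the flux-balance LP maximising the secretion exchange flux of the
#' target metabolite subject to steady state (`S v = 0`) and the model's
#' bounds. If the metabolite has no exchange reaction, a temporary
#' secretion exchange with bounds `(0, default_bound)` is added for the
#' solve.
#'
#' @param model a `network_model` (typically after [apply_condition]).
#' @param metabolite_id target metabolite id.
#' @return the maximal secretion flux (nonnegative by construction).
#' @export
max_production_capability <- function(model, metabolite_id) {
  pm <- secretion_problem(model, metabolite_id)
  res <- lp_solve(obj = as.numeric(seq_len(ncol(pm$S)) == pm$ex_idx),
                  A = pm$S, b = rep(0, nrow(pm$S)),
                  lower = pm$lb, upper = pm$ub, maximize = TRUE)
  if (res$status != "optimal")
    abort_infeasible(sprintf("capability LP for '%s' not optimal (status: %s)",
                             metabolite_id, res$status),
                     solver_status = res$status)
  max(0, res$objval)
}

# locate (or temporarily add) the secretion exchange for a metabolite and
# return the LP ingredients; exchange sign convention: positive = secretion
secretion_problem <- function(model, metabolite_id) {
  stopifnot(inherits(model, "network_model"))
  i <- match(metabolite_id, model$metabolites$id)
  if (is.na(i)) abort_validation(sprintf("unknown metabolite: %s", metabolite_id))
  S <- model$stoichiometry
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  w <- model$reactions$weight
  ex_cols <- which(model$reactions$is_exchange & S[i, ] != 0)
  if (length(ex_cols) > 0) {
    # prefer an exchange that can carry positive (secretion) flux
    ex_idx <- ex_cols[which.max(ub[ex_cols])]
  } else {
    S <- cbind(S, Matrix::sparseMatrix(i = i, j = 1, x = -1,
                                       dims = c(nrow(S), 1)))
    colnames(S)[ncol(S)] <- paste0("EX_tmp_", metabolite_id)
    lb <- c(lb, 0); ub <- c(ub, model$default_bound); w <- c(w, 1)
    ex_idx <- ncol(S)
  }
  # a secretion exchange consumes the metabolite at positive flux; if the
  # stored coefficient is +1 (uptake-written), flip orientation for scoring
  if (S[i, ex_idx] > 0) {
    S[, ex_idx] <- -S[, ex_idx]
    tmp <- lb[ex_idx]; lb[ex_idx] <- -ub[ex_idx]; ub[ex_idx] <- -tmp
  }
  list(S = S, lb = lb, ub = ub, weights = w, ex_idx = ex_idx)
}

#' Minimum-weighted-total-flux production demand
#'
#' The production demand of a metabolite is the minimum of the weighted sum
#' of absolute fluxes, `sum_j w_j |v_j|`, over steady-state flux vectors
#' that respect the model bounds and secrete the target at a required rate.
#' The absolute values are linearised by splitting each flux into
#' nonnegative forward and reverse parts. The required rate defaults to
#' `v_opt_fraction` times the model's own maximum production capability,
#' but an explicit `target_flux` can be supplied (used by [run_timbr] so
#' both conditions chase the same target).
#'
#' @param model a `network_model` (post [apply_condition]).
#' @param metabolite_id target metabolite id.
#' @param v_opt_fraction fraction in (0, 1] of maximum capability.
#' @param weights optional named vector of nonnegative per-reaction weights
#'   overriding the model's (default all 1).
#' @param target_flux optional explicit required secretion flux; overrides
#'   `v_opt_fraction`.
#' @return a list: `objective` (the demand), `flux` (named optimal flux
#'   vector incl. any temporary exchange), `target` (required secretion
#'   flux), `capability`, and `status` (`"ok"`, `"zero_capability"` or
#'   `"infeasible"`).
#' @export
production_demand <- function(model, metabolite_id, v_opt_fraction = 0.9,
                              weights = NULL, target_flux = NULL) {
  if (v_opt_fraction <= 0 || v_opt_fraction > 1)
    abort_validation("v_opt_fraction must be in (0, 1]")
  pm <- secretion_problem(model, metabolite_id)
  w <- pm$weights
  if (!is.null(weights)) {
    if (any(weights < 0)) abort_validation("reaction weights must be nonnegative")
    idx <- match(names(weights), colnames(pm$S))
    if (anyNA(idx))
      abort_validation(sprintf("weights given for unknown reaction(s): %s",
                               paste(names(weights)[is.na(idx)], collapse = ", ")))
    w[idx] <- unname(weights)
  }

  if (is.null(target_flux)) {
    cap <- max_production_capability(model, metabolite_id)
    if (cap <= 1e-9)
      return(list(objective = NA_real_, flux = NULL, target = 0,
                  capability = cap, status = "zero_capability"))
    target_flux <- v_opt_fraction * cap
  } else {
    cap <- NA_real_
    if (target_flux <= 0)
      return(list(objective = NA_real_, flux = NULL, target = target_flux,
                  capability = cap, status = "zero_capability"))
  }

  n <- ncol(pm$S)
  lb <- pm$lb; ub <- pm$ub
  # required secretion expressed as a bound on the exchange flux
  lb[pm$ex_idx] <- max(lb[pm$ex_idx], target_flux)
  if (lb[pm$ex_idx] > ub[pm$ex_idx] + 1e-9)
    return(list(objective = NA_real_, flux = NULL, target = target_flux,
                capability = cap, status = "infeasible"))

  # split v = f - r with f, r >= 0
  f_lo <- pmax(lb, 0); f_hi <- pmax(ub, 0)
  r_lo <- pmax(-ub, 0); r_hi <- pmax(-lb, 0)
  A <- cbind(pm$S, -pm$S)
  res <- lp_solve(obj = c(w, w), A = A, b = rep(0, nrow(pm$S)),
                  lower = c(f_lo, r_lo), upper = c(f_hi, r_hi))
  if (res$status != "optimal")
    return(list(objective = NA_real_, flux = NULL, target = target_flux,
                capability = cap, status = "infeasible"))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(pm$S)
  list(objective = res$objval, flux = v, target = target_flux,
       capability = cap, status = "ok")
}

#' Raw production score from two condition demands
#'
#' `(X_early - X_late) / (X_early + X_late)`: the normalised difference of
#' the network demands under the early and late conditions. The value lies
#' in `[-1, 1]` and is antisymmetric under swapping the arguments. A
#' positive value means production is cheaper (lower demand) under the
#' late condition, i.e. the metabolite is predicted to rise in plasma.
#'
#' @param x_early,x_late nonnegative demands; their sum must be positive.
#' @return the raw score.
#' @export
raw_score <- function(x_early, x_late) {
  if (any(x_early < 0) || any(x_late < 0))
    abort_validation("demands must be nonnegative")
  s <- x_early + x_late
  if (any(s <= 0))
    abort_validation("raw score undefined when both demands are zero")
  (x_early - x_late) / s
}

#' z-transform raw scores across exchangeable metabolites
#'
#' Centres and scales with the population standard deviation (divisor n),
#' so the output has mean 0 and SD 1 exactly. Order is preserved and the
#' transform is monotone.
#'
#' @param x numeric vector of raw scores (>= 2 values, not all identical).
#' @return a list: `scores` (z-scores), `mu`, `sigma`.
#' @export
z_transform <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) abort_validation("z-transform needs at least 2 scores")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma <= 0)
    abort_validation("degenerate z-transform: all raw scores identical")
  list(scores = (x - mu) / sigma, mu = mu, sigma = sigma)
}

#' Score metabolite production across two fasting conditions
#'
#' For each requested metabolite, computes the maximum production
#' capability under the early and late bound sets, fixes one shared
#' production target (`v_opt_fraction` times the smaller of the two
#' capabilities, so the same secretion rate is demanded of both
#' conditions), solves the minimum-weighted-total-flux demand LP under
#' each condition, forms the raw score and finally z-transforms the raw
#' scores across all metabolites with status `"ok"`. A positive
#' z-transformed score predicts the metabolite rises in plasma between the
#' early and late conditions; a negative score predicts a fall.
#'
#' Metabolites with zero capability under either condition, or whose
#' demand LP is infeasible, are flagged and excluded from the z-transform
#' population.
#'
#' @param model a `network_model` (base bounds).
#' @param cb_early,cb_late `condition_bounds` for the two conditions.
#' @param metabolites metabolite ids to score; defaults to all
#'   exchangeable metabolites.
#' @param v_opt_fraction required fraction of capability (default 0.9).
#' @param weights optional named per-reaction weight vector (default all 1).
#' @param target_mode `"shared"` (one target per metabolite, the default)
#'   or `"per_condition"` (each condition chases its own capability).
#' @return a `timbr_scores` data.frame with columns `metabolite_id`,
#'   `x_early`, `x_late`, `x_raw`, `x_s`, `status`, and attributes `mu`,
#'   `sigma`.
#' @export
run_timbr <- function(model, cb_early, cb_late, metabolites = NULL,
                      v_opt_fraction = 0.9, weights = NULL,
                      target_mode = c("shared", "per_condition")) {
  target_mode <- match.arg(target_mode)
  m_early <- apply_condition(model, cb_early)
  m_late <- apply_condition(model, cb_late)
  if (is.null(metabolites))
    metabolites <- model$metabolites$id[model$metabolites$is_exchangeable]
  if (length(metabolites) == 0) abort_validation("no metabolites to score")

  rows <- lapply(metabolites, function(met) {
    cap_e <- max_production_capability(m_early, met)
    cap_l <- max_production_capability(m_late, met)
    if (min(cap_e, cap_l) <= 1e-9)
      return(data.frame(metabolite_id = met, x_early = NA_real_,
                        x_late = NA_real_, status = "zero_capability"))
    if (target_mode == "shared") {
      tgt <- v_opt_fraction * min(cap_e, cap_l)
      de <- production_demand(m_early, met, weights = weights, target_flux = tgt)
      dl <- production_demand(m_late, met, weights = weights, target_flux = tgt)
    } else {
      de <- production_demand(m_early, met, v_opt_fraction, weights)
      dl <- production_demand(m_late, met, v_opt_fraction, weights)
    }
    if (de$status != "ok" || dl$status != "ok")
      return(data.frame(metabolite_id = met, x_early = NA_real_,
                        x_late = NA_real_, status = "infeasible"))
    data.frame(metabolite_id = met, x_early = de$objective,
               x_late = dl$objective, status = "ok")
  })
  tab <- do.call(rbind, rows)
  tab$x_raw <- NA_real_
  ok <- tab$status == "ok"
  tab$x_raw[ok] <- raw_score(tab$x_early[ok], tab$x_late[ok])
  tab$x_s <- NA_real_
  mu <- sigma <- NA_real_
  if (sum(ok) >= 2) {
    zt <- z_transform(tab$x_raw[ok])
    tab$x_s[ok] <- zt$scores
    mu <- zt$mu; sigma <- zt$sigma
  }
  tab <- tab[, c("metabolite_id", "x_early", "x_late", "x_raw", "x_s", "status")]
  structure(tab, mu = mu, sigma = sigma,
            v_opt_fraction = v_opt_fraction, target_mode = target_mode,
            class = c("timbr_scores", "data.frame"))
}

#' Read / write production score tables
#'
#' TSV dialect: columns `metabolite_id`, `x_early`, `x_late`, `x_raw`,
#' `x_s`, `status`.
#'
#' @param scores a `timbr_scores` object.
#' @param path TSV file path.
#' @export
write_scores <- function(scores, path) {
  write_tsv(as.data.frame(scores), path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_tsv_strict(path, c("metabolite_id", "x_early", "x_late",
                                "x_raw", "x_s", "status"))
  structure(df, class = c("timbr_scores", "data.frame"))
}
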