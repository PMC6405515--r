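test_that("maximum production capability finds the bottleneck", {
  m <- chain3_model(cap = 10)
  expect_equal(max_production_capability(m, "B"), 10)

  # metabolite with no producing reaction
  m2 <- network_model(data.frame(id = c("A", "B")),
                      list(EX_A = list(stoichiometry = c(A = -1),
                                       lower_bound = -10, upper_bound = 0),
                           EX_B = list(stoichiometry = c(B = -1),
                                       lower_bound = 0, upper_bound = 10)))
  expect_equal(max_production_capability(m2, "B"), 0)

  # a metabolite without any exchange gets a temporary secretion route
  m3 <- network_model(data.frame(id = c("A", "B")),
                      list(EX_A = list(stoichiometry = c(A = -1),
                                       lower_bound = -7, upper_bound = 0),
                           CONV = list(stoichiometry = c(A = -1, B = 1),
                                       lower_bound = 0, upper_bound = 1000)))
  expect_equal(max_production_capability(m3, "B"), 7)
})

test_that("capability matches the vertex-enumeration oracle on random networks", {
  for (seed in 1:12) {
    m <- random_small_model(n_rxn = sample(4:8, 1), seed = seed)
    S <- as.matrix(m$stoichiometry)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    target <- match("EX_out", m$reactions$id)
    cvec <- as.numeric(seq_along(lb) == target)
    oracle <- oracle_lp_max(S, lb, ub, cvec)
    met <- names(which(S[, target] != 0))
    expect_equal(max_production_capability(m, met), max(0, oracle),
                 tolerance = 1e-7, info = paste("seed", seed))
  }
})

test_that("production demand solves hand-checked minimum-flux problems", {
  m <- chain3_model(cap = 10)
  # full capability: all three reactions carry 10 -> total |v| = 30
  d <- production_demand(m, "B", v_opt_fraction = 1)
  expect_equal(d$objective, 30, tolerance = 1e-7)
  expect_equal(d$status, "ok")
  # half capability scales linearly on a single path
  d2 <- production_demand(m, "B", v_opt_fraction = 0.5)
  expect_equal(d2$objective, 15, tolerance = 1e-7)
  # explicit target overrides the fraction
  d3 <- production_demand(m, "B", target_flux = 4)
  expect_equal(d3$objective, 12, tolerance = 1e-7)

  # two routes, equal weights: the optimizer takes the shorter one
  tw <- tworoute_model()
  d4 <- production_demand(tw, "B", target_flux = 6)
  expect_equal(d4$objective, 18, tolerance = 1e-7)  # EX_A + DIRECT + EX_B
  expect_equal(unname(d4$flux["DIRECT"]), 6, tolerance = 1e-7)
  expect_equal(unname(d4$flux["DET1"]), 0, tolerance = 1e-7)

  # down-weighting the detour below the direct route flips the choice:
  # direct costs 5/unit, detour costs 1+1 = 2/unit
  d5 <- production_demand(tw, "B", target_flux = 6,
                          weights = c(DIRECT = 5, DET1 = 1, DET2 = 1))
  expect_equal(unname(d5$flux["DIRECT"]), 0, tolerance = 1e-7)
  expect_equal(unname(d5$flux["DET1"]), 6, tolerance = 1e-7)

  # zero capability short-circuits
  m0 <- network_model(data.frame(id = c("A", "B")),
                      list(EX_A = list(stoichiometry = c(A = -1),
                                       lower_bound = -10, upper_bound = 0),
                           EX_B = list(stoichiometry = c(B = -1),
                                       lower_bound = 0, upper_bound = 10)))
  expect_equal(production_demand(m0, "B")$status, "zero_capability")

  # negative weights rejected
  expect_error(production_demand(m, "B", weights = c(CONV = -1)), "nonnegative")
})

test_that("demand equals the split-space vertex oracle on small networks", {
  for (seed in c(1, 3, 5, 7)) {
    m <- random_small_model(n_rxn = 5, seed = seed)
    S <- as.matrix(m$stoichiometry)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    target <- match("EX_out", m$reactions$id)
    cap <- oracle_lp_max(S, lb, ub, as.numeric(seq_along(lb) == target))
    if (is.na(cap) || cap <= 1e-6) next
    t <- 0.9 * cap
    oracle <- oracle_demand_min(S, lb, ub, m$reactions$weight, target, t)
    met <- names(which(S[, target] != 0))
    d <- production_demand(m, met, target_flux = t)
    expect_equal(d$objective, oracle, tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("every demand solution is a steady state within tolerance", {
  net <- make_toy_liver_network()
  me <- apply_condition(net$model, net$cb_early)
  for (met in c("glc_e", "ket_e", "urea_e", "s1_e")) {
    d <- production_demand(me, met, v_opt_fraction = 0.9)
    v <- d$flux[colnames(me$stoichiometry)]
    resid <- max(abs(as.vector(me$stoichiometry %*% v)))
    expect_lt(resid, 1e-6 * max(1, max(abs(v))))
    expect_gte(unname(v[paste0("EX_", sub("_e$", "", met))]), d$target - 1e-7)
  }
})

test_that("no feasible flux beats the reported demand objective", {
  m <- random_small_model(n_rxn = 6, seed = 2)
  S <- as.matrix(m$stoichiometry)
  lb <- m$reactions$lower_bound
  ub <- m$reactions$upper_bound
  target <- match("EX_out", m$reactions$id)
  cap <- oracle_lp_max(S, lb, ub, as.numeric(seq_along(lb) == target))
  skip_if(is.na(cap) || cap <= 1e-6, "random instance cannot produce the target")
  t <- 0.8 * cap
  met <- names(which(S[, target] != 0))
  d <- production_demand(m, met, target_flux = t)
  lb2 <- lb; lb2[target] <- max(lb[target], t)
  V <- enum_vertices(S, lb2, ub)
  set.seed(99)
  for (i in 1:100) {
    wts <- stats::rexp(nrow(V)); wts <- wts / sum(wts)
    v <- as.vector(t(V) %*% wts)   # random point in the constrained polytope
    expect_gte(sum(m$reactions$weight * abs(v)), d$objective - 1e-6)
  }
})

test_that("raw scores are bounded, antisymmetric and error on double zero", {
  expect_equal(raw_score(3, 1), 0.5)
  expect_equal(raw_score(7, 7), 0)
  expect_equal(raw_score(0, 5), -1)
  expect_equal(raw_score(5, 0), 1)
  for (i in 1:20) {
    set.seed(i)
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(raw_score(a, b), -raw_score(b, a))
    expect_true(abs(raw_score(a, b)) <= 1)
  }
  expect_error(raw_score(0, 0), "undefined")
  expect_error(raw_score(-1, 2), "nonnegative")
})

test_that("z-transform centres to mean 0 and population SD 1", {
  zt <- z_transform(c(1, 2, 3))
  expect_equal(zt$scores, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(zt$scores), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(zt$scores^2)), 1, tolerance = 1e-9)

  # affine shifts of the input leave the output unchanged
  set.seed(4)
  x <- rnorm(15)
  expect_equal(z_transform(3 * x + 7)$scores, z_transform(x)$scores,
               tolerance = 1e-9)

  # order preservation
  expect_true(all(diff(z_transform(sort(x))$scores) > 0))

  expect_error(z_transform(rep(2, 5)), "degenerate")
  expect_error(z_transform(1), "at least 2")
})

test_that("weight scaling multiplies demands but leaves scores unchanged", {
  net <- make_toy_liver_network()
  sc1 <- run_timbr(net$model, net$cb_early, net$cb_late,
                   metabolites = c("glc_e", "ket_e", "urea_e", "s1_e"))
  w <- stats::setNames(rep(2.5, nrow(net$model$reactions)), net$model$reactions$id)
  sc2 <- run_timbr(net$model, net$cb_early, net$cb_late,
                   metabolites = c("glc_e", "ket_e", "urea_e", "s1_e"), weights = w)
  ok <- sc1$status == "ok"
  expect_equal(sc2$x_early[ok], 2.5 * sc1$x_early[ok], tolerance = 1e-7)
  expect_equal(sc2$x_late[ok], 2.5 * sc1$x_late[ok], tolerance = 1e-7)
  expect_equal(sc2$x_raw[ok], sc1$x_raw[ok], tolerance = 1e-9)
  expect_equal(sc2$x_s[ok], sc1$x_s[ok], tolerance = 1e-7)
})

test_that("tightening bounds never decreases the demand at a fixed target", {
  m <- tworoute_model()
  d_free <- production_demand(m, "B", target_flux = 6)
  # closing the direct route forces the detour: strictly more total flux
  cb <- condition_bounds("tight", mfa_bounds = data.frame(
    reaction_id = "DIRECT", lower = 0, upper = 0))
  d_tight <- production_demand(apply_condition(m, cb), "B", target_flux = 6)
  expect_gte(d_tight$objective, d_free$objective - 1e-9)
  expect_equal(d_tight$objective, 24, tolerance = 1e-7)  # 4 reactions x 6
})

test_that("run_timbr recovers planted directions and flags degenerate cases", {
  net <- make_toy_liver_network()
  sc <- run_timbr(net$model, net$cb_early, net$cb_late)
  xs <- stats::setNames(sc$x_s, sc$metabolite_id)[net$truth$metabolite_id]
  expect_true(all(ifelse(net$truth$direction == "elevated", xs > 0, xs < 0)))
  # uptake-only metabolites are flagged, not scored
  expect_equal(sc$status[sc$metabolite_id == "glyc_e"], "zero_capability")
  ok <- sc$status == "ok"
  expect_equal(mean(sc$x_s[ok]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(sc$x_s[ok]^2)), 1, tolerance = 1e-9)
  expect_true(all(abs(sc$x_raw[ok]) <= 1))

  # identical conditions: all raw scores equal -> degenerate z-transform
  expect_error(run_timbr(net$model, net$cb_early, net$cb_early,
                         metabolites = c("glc_e", "ket_e", "urea_e")),
               "degenerate")
})
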