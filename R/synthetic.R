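#' Generate a gluconeogenic toy liver network with planted direction truths
#'
#' Builds a small (~30 reaction) carbon-skeleton network of hepatic glucose
#' production — glycogenolysis, gluconeogenesis from glycerol and from
#' lactate/alanine, pyruvate oxidation into the TCA cycle, beta-oxidation
#' feeding ketogenesis, and a urea stub — plus two condition bound sets
#' that reproduce the fasting trajectory: early in the fast, glycogen
#' breakdown supplies ~48% of glucose output; late, ~2%, with
#' gluconeogenic precursors compensating, total glucose output reduced by
#' 30%, and fatty-acid uptake/ketone secretion strongly up-regulated.
#' Gluconeogenic route reactions are lumped and expressed in glucose
#' (hexose) units, so the fractional-contribution bounds apply directly.
#'
#' Planted production-direction truths are constructed, not asserted:
#' glucose output capability falls late (depressed); forced ketogenesis
#' and amino-acid catabolism make ketone-body and urea production free
#' late but costly early (elevated); and optional sentinel metabolites
#' carry route-switch motifs (a short production route open in only one
#' condition, with a longer detour always available) that raise or lower
#' the production cost in a known direction.
#'
#' @param include_pathways character subset of `c("glycogenolysis",
#'   "gluconeogenesis_glycerol", "gluconeogenesis_lactate", "tca",
#'   "ketogenesis", "urea_stub")`. The four glucose-production pathways
#'   are required for the condition bounds to be feasible; the generator
#'   refuses otherwise, naming the violated balance.
#' @param n_extra_exchanges 0–3 sentinel metabolites with route-switch
#'   motifs (default 3: one elevated, two depressed).
#' @param total_output_early,total_output_late glucose output flux under
#'   the two conditions (default 100 and 70: a 30% decline).
#' @param glycogen_fraction_early,glycogen_fraction_late glycogen share of
#'   glucose output (defaults 0.48 and 0.023).
#' @param tolerance_fraction relative half-width of the forced bound
#'   intervals (default 0.1).
#' @return a list: `model` (a [network_model]), `cb_early`, `cb_late`
#'   ([condition_bounds]), and `truth` (data.frame `metabolite_id`,
#'   `direction`).
#' @export
make_toy_liver_network <- function(include_pathways = c("glycogenolysis",
                                                        "gluconeogenesis_glycerol",
                                                        "gluconeogenesis_lactate",
                                                        "tca", "ketogenesis",
                                                        "urea_stub"),
                                   n_extra_exchanges = 3,
                                   total_output_early = 100,
                                   total_output_late = 70,
                                   glycogen_fraction_early = 0.48,
                                   glycogen_fraction_late = 0.023,
                                   tolerance_fraction = 0.1) {
  all_pw <- c("glycogenolysis", "gluconeogenesis_glycerol",
              "gluconeogenesis_lactate", "tca", "ketogenesis", "urea_stub")
  bad <- setdiff(include_pathways, all_pw)
  if (length(bad) > 0)
    abort_validation(sprintf("unknown pathway(s): %s", paste(bad, collapse = ", ")))
  has <- function(p) p %in% include_pathways
  if (has("gluconeogenesis_lactate") && !has("tca"))
    stop("pyruvate carboxylation (GNG_pyr) runs through the TCA cycle; ",
         "gluconeogenesis from lactate is infeasible without 'tca'")
  for (p in c("glycogenolysis", "gluconeogenesis_glycerol",
              "gluconeogenesis_lactate", "tca"))
    if (!has(p))
      stop(sprintf("condition bounds force glucose output that cannot be balanced without '%s': ", p),
           "the three precursor routes together must carry the full output")
  if (n_extra_exchanges < 0 || n_extra_exchanges > 3)
    abort_validation("n_extra_exchanges must be between 0 and 3")
  t <- tolerance_fraction
  if (t < 0 || t >= 1) abort_validation("tolerance_fraction must be in [0, 1)")

  mets <- data.frame(id = character(0), name = character(0),
                     compartment = character(0), stringsAsFactors = FALSE)
  addm <- function(id, name, comp) {
    mets <<- rbind(mets, data.frame(id = id, name = name, compartment = comp,
                                    stringsAsFactors = FALSE))
  }
  rxns <- list()
  addr <- function(id, stoich, lb = -1000, ub = 1000) {
    rxns[[id]] <<- list(stoichiometry = stoich, lower_bound = lb, upper_bound = ub)
  }

  # core: glucose output machinery
  addm("glc_e", "glucose", "e"); addm("glc_c", "glucose", "c")
  addm("g6p_c", "glucose 6-phosphate", "c"); addm("pyr_c", "pyruvate", "c")
  addr("EX_glc", c(glc_e = -1), 0, 1000)
  addr("T_glc", c(glc_c = -1, glc_e = 1), 0, 1000)
  addr("G6PASE", c(g6p_c = -1, glc_c = 1), 0, 1000)
  addr("PK", c(g6p_c = -1, pyr_c = 2), 0, 1000)        # lumped lower glycolysis

  addm("glycogen_c", "glycogen (glucosyl units)", "c")
  addr("EX_glycogen", c(glycogen_c = -1), -1000, 0)    # store mobilisation only
  addr("PYGL", c(glycogen_c = -1, g6p_c = 1), 0, 1000)

  addm("glyc_e", "glycerol", "e"); addm("glyc_c", "glycerol", "c")
  addr("EX_glyc", c(glyc_e = -1), -1000, 0)
  addr("T_glyc", c(glyc_e = -1, glyc_c = 1), 0, 1000)
  addr("GNG_glyc", c(glyc_c = -2, g6p_c = 1), 0, 1000) # glucose units

  addm("lac_e", "lactate", "e"); addm("lac_c", "lactate", "c")
  addm("ala_e", "alanine", "e"); addm("ala_c", "alanine", "c")
  addm("nh4_c", "ammonium", "c")
  addr("EX_lac", c(lac_e = -1), -1000, 1000)
  addr("T_lac", c(lac_e = -1, lac_c = 1), -1000, 1000)
  addr("LDH", c(lac_c = -1, pyr_c = 1), -1000, 1000)
  addr("EX_ala", c(ala_e = -1), -1000, 0)
  addr("T_ala", c(ala_e = -1, ala_c = 1), 0, 1000)
  addr("ALA_DEG", c(ala_c = -1, pyr_c = 1, nh4_c = 1), 0, 1000)
  addr("GNG_pyr", c(pyr_c = -2, g6p_c = 1), 0, 1000)   # PC/PCK lumped, glucose units

  addm("acoa_c", "acetyl-CoA", "c")
  addm("co2_c", "CO2", "c"); addm("co2_e", "CO2", "e")
  addr("PDH", c(pyr_c = -1, acoa_c = 1, co2_c = 1), 0, 1000)
  addr("TCA_OX", c(acoa_c = -1, co2_c = 2), 0, 1000)
  addr("T_co2", c(co2_c = -1, co2_e = 1), 0, 1000)
  addr("EX_co2", c(co2_e = -1), 0, 1000)

  truth <- data.frame(metabolite_id = "glc_e", direction = "depressed",
                      stringsAsFactors = FALSE)

  if (has("ketogenesis")) {
    addm("ffa_e", "fatty acid", "e"); addm("ffa_c", "fatty acid", "c")
    addm("ket_c", "ketone body", "c"); addm("ket_e", "ketone body", "e")
    addr("EX_ffa", c(ffa_e = -1), -1000, 0)
    addr("T_ffa", c(ffa_e = -1, ffa_c = 1), 0, 1000)
    addr("BOX", c(ffa_c = -1, acoa_c = 8), 0, 1000)    # palmitate beta-oxidation
    addr("KETO", c(acoa_c = -2, ket_c = 1), 0, 1000)
    addr("T_ket", c(ket_c = -1, ket_e = 1), 0, 1000)
    addr("EX_ket", c(ket_e = -1), 0, 1000)
    truth <- rbind(truth, data.frame(metabolite_id = "ket_e",
                                     direction = "elevated"))
  }
  if (has("urea_stub")) {
    addm("urea_c", "urea", "c"); addm("urea_e", "urea", "e")
    addr("UREA_SYN", c(nh4_c = -2, urea_c = 1), 0, 1000)
    addr("T_urea", c(urea_c = -1, urea_e = 1), 0, 1000)
    addr("EX_urea", c(urea_e = -1), 0, 1000)
    truth <- rbind(truth, data.frame(metabolite_id = "urea_e",
                                     direction = "elevated"))
  }

  # neutral exchangeables: identical production route under both conditions;
  # they anchor the centre of the z-transform near the common background
  for (aid in c("aux1", "aux2")) {
    addm(paste0(aid, "_c"), paste("auxiliary", aid), "c")
    addm(paste0(aid, "_x_c"), paste("auxiliary", aid, "intermediate"), "c")
    addm(paste0(aid, "_e"), paste("auxiliary", aid), "e")
    addr(paste0(toupper(aid), "_SYN1"),
         stats::setNames(c(-1, 1), c("pyr_c", paste0(aid, "_x_c"))), 0, 1000)
    addr(paste0(toupper(aid), "_SYN2"),
         stats::setNames(c(-1, 1), c(paste0(aid, "_x_c"), paste0(aid, "_c"))), 0, 1000)
    addr(paste0("T_", aid),
         stats::setNames(c(-1, 1), c(paste0(aid, "_c"), paste0(aid, "_e"))), 0, 1000)
    addr(paste0("EX_", aid),
         stats::setNames(-1, paste0(aid, "_e")), 0, 10)
  }

  # sentinel route-switch motifs: a 1-step route open in one condition only,
  # and an always-open detour (5 or 6 steps), so production is markedly
  # cheaper in the condition with the short route
  sentinels <- list(
    list(id = "s1", direction = "elevated", detour = 6, ex_ub = 20),
    list(id = "s2", direction = "depressed", detour = 6, ex_ub = 20),
    list(id = "s3", direction = "depressed", detour = 5, ex_ub = 16))
  used_sent <- sentinels[seq_len(n_extra_exchanges)]
  for (s in used_sent) {
    sid <- s$id
    addm(paste0(sid, "_c"), paste("sentinel", sid), "c")
    addm(paste0(sid, "_e"), paste("sentinel", sid), "e")
    addr(paste0(toupper(sid), "_SHORT"),
         stats::setNames(c(-1, 1), c("pyr_c", paste0(sid, "_c"))), 0, 1000)
    steps <- s$detour
    prev <- "pyr_c"
    for (k in seq_len(steps)) {
      nxt <- if (k == steps) paste0(sid, "_c") else paste0(sid, "_x", k, "_c")
      if (nxt != paste0(sid, "_c")) addm(nxt, paste("sentinel", sid, "intermediate", k), "c")
      addr(paste0(toupper(sid), "_LONG", k),
           stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000)
      prev <- nxt
    }
    addr(paste0("T_", sid),
         stats::setNames(c(-1, 1), c(paste0(sid, "_c"), paste0(sid, "_e"))), 0, 1000)
    addr(paste0("EX_", sid),
         stats::setNames(-1, paste0(sid, "_e")), 0, s$ex_ub)
    truth <- rbind(truth, data.frame(metabolite_id = paste0(sid, "_e"),
                                     direction = s$direction))
  }

  model <- network_model(mets, rxns)

  # ---- condition bound sets (Table-2-style fasting trajectory) ----------
  route_bounds <- function(total, fr_glycogen, fr_glycerol) {
    fr_gng <- 1 - fr_glycogen - fr_glycerol
    data.frame(
      reaction_id = c("PYGL", "GNG_glyc", "GNG_pyr"),
      lower = total * c(fr_glycogen, fr_glycerol, fr_gng) * (1 - t),
      upper = total * c(fr_glycogen, fr_glycerol, fr_gng) * (1 + t),
      stringsAsFactors = FALSE)
  }
  ex_rows <- function(total, ala_uptake, ffa, ket, condition) {
    rows <- data.frame(
      reaction_id = c("EX_glc", "EX_glycogen", "EX_glyc", "EX_lac", "EX_ala"),
      lower = c(total * (1 - t), -60, -45, -120, -ala_uptake[2]),
      upper = c(total * (1 + t), 0, 0, 10, -ala_uptake[1]),
      stringsAsFactors = FALSE)
    if (has("ketogenesis"))
      rows <- rbind(rows, data.frame(
        reaction_id = c("EX_ffa", "EX_ket"),
        lower = c(-ffa[2], ket[1]), upper = c(-ffa[1], ket[2])))
    mfa <- NULL
    for (s in used_sent) {
      # elevated sentinels: short route closed early, open late (production
      # gets cheaper late); depressed sentinels: the mirror image
      closed <- if (s$direction == "elevated") condition == "early"
                else condition == "late"
      mfa <- rbind(mfa, data.frame(
        reaction_id = paste0(toupper(s$id), "_SHORT"),
        lower = 0, upper = if (closed) 0 else 1000, stringsAsFactors = FALSE))
    }
    list(ex = rows, sent = mfa)
  }

  fr_glyc_e <- 0.15; fr_glyc_l <- 0.234
  early <- ex_rows(total_output_early, ala_uptake = c(5, 44),
                   ffa = c(0, 1), ket = c(0, 40), condition = "early")
  late <- ex_rows(total_output_late, ala_uptake = c(35, 44),
                  ffa = c(5, 6), ket = c(18, 45), condition = "late")

  cb_early <- condition_bounds("early_5-7h",
                               exchange_bounds = early$ex,
                               mfa_bounds = rbind(route_bounds(total_output_early,
                                                               glycogen_fraction_early,
                                                               fr_glyc_e),
                                                  early$sent))
  cb_late <- condition_bounds("late_10-13h",
                              exchange_bounds = late$ex,
                              mfa_bounds = rbind(route_bounds(total_output_late,
                                                              glycogen_fraction_late,
                                                              fr_glyc_l),
                                                 late$sent))

  # construction check: both conditions must admit a steady state
  for (cc in list(cb_early, cb_late)) {
    m <- apply_condition(model, cc)
    res <- lp_solve(obj = rep(0, nrow(m$reactions)), A = m$stoichiometry,
                    b = rep(0, nrow(m$metabolites)),
                    lower = m$reactions$lower_bound,
                    upper = m$reactions$upper_bound)
    if (res$status != "optimal")
      stop(sprintf("generated condition '%s' admits no steady state: ",
                   cc$condition_label),
           "precursor route bounds do not balance the forced glucose output")
  }

  list(model = model, cb_early = cb_early, cb_late = cb_late, truth = truth)
}

#' Simulate multi-study MS count tables with planted fold changes
#'
#' Emulates plasma metabolomics count data from several studies, each with
#' an early and a late time point measured in different animals: counts
#' are log-normal around a per-metabolite baseline, with a per-study
#' baseline shift (different vehicles / platforms), a planted late/early
#' fold change per metabolite, and left-censored missingness — entries
#' below a per-study detection floor are masked, which is the regime in
#' which minimum-value imputation is sensible.
#'
#' @param n_metabolites number of metabolites.
#' @param planted_fc named numeric vector (metabolite id -> fold change);
#'   ids must be among `met_1 ... met_n`; unnamed metabolites get fc = 1.
#' @param n_animals per-study animals per time point (default `c(8, 8, 9)`).
#' @param noise_sigma log-normal scale of the within-group noise
#'   (default 0.3).
#' @param study_shift_sigma SD of the per-study baseline log-shift
#'   (default 0.5).
#' @param missing_rate target fraction of entries left-censored below each
#'   study's detection floor (default 0).
#' @param seed integer seed; tables are bit-identical given the seed.
#' @return a list: `counts` (an [ms_counts] long table across all studies)
#'   and `truth` (data.frame `metabolite_id`, `fc`, `direction`,
#'   `fully_censored`).
#' @export
make_ms_counts <- function(n_metabolites = 40, planted_fc = NULL,
                           n_animals = c(8, 8, 9), noise_sigma = 0.3,
                           study_shift_sigma = 0.5, missing_rate = 0,
                           seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    abort_validation("missing_rate must be in [0, 1)")
  mets <- paste0("met_", seq_len(n_metabolites))
  fc <- stats::setNames(rep(1, n_metabolites), mets)
  if (!is.null(planted_fc)) {
    bad <- setdiff(names(planted_fc), mets)
    if (length(bad) > 0)
      abort_validation(sprintf("planted_fc for unknown metabolite(s): %s",
                               paste(bad, collapse = ", ")))
    if (any(planted_fc <= 0)) abort_validation("planted fold changes must be positive")
    fc[names(planted_fc)] <- planted_fc
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  base_mu <- stats::runif(n_metabolites, log(1e4), log(1e6))
  rows <- list()
  for (s in seq_along(n_animals)) {
    n <- n_animals[s]
    shift <- stats::rnorm(1, 0, study_shift_sigma)
    for (tp in c("early", "late")) {
      mu <- base_mu + shift + if (tp == "late") log(fc) else 0
      x <- exp(mu[rep(seq_len(n_metabolites), each = n)] +
                 stats::rnorm(n_metabolites * n, 0, noise_sigma))
      rows[[length(rows) + 1]] <- data.frame(
        study_id = paste0("study_", s), time_point = tp,
        animal_id = paste0("s", s, "_", tp, "_a", rep(seq_len(n), n_metabolites)),
        metabolite_id = rep(mets, each = n), count = x,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  if (missing_rate > 0) {
    for (s in unique(df$study_id)) {
      i <- df$study_id == s
      floor_s <- stats::quantile(df$count[i], missing_rate, type = 7)
      df$count[i & df$count < floor_s] <- NA_real_
    }
  }

  observed <- tapply(!is.na(df$count), df$metabolite_id, any)
  truth <- data.frame(metabolite_id = mets, fc = unname(fc),
                      direction = ifelse(fc > 1, "elevated",
                                         ifelse(fc < 1, "depressed", "unchanged")),
                      fully_censored = !as.vector(observed[mets]),
                      stringsAsFactors = FALSE)
  df <- df[!is.na(df$count), , drop = FALSE]
  rownames(df) <- NULL
  list(counts = ms_counts(df), truth = truth)
}
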