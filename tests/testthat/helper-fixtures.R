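# shared fixtures built in code

# 3-reaction chain: uptake (<= 10) -> conversion -> secretion, 2 metabolites
chain3_model <- function(cap = 10) {
  network_model(
    data.frame(id = c("A", "B")),
    list(EX_A = list(stoichiometry = c(A = -1), lower_bound = -cap, upper_bound = 0),
         CONV = list(stoichiometry = c(A = -1, B = 1), lower_bound = 0, upper_bound = 1000),
         EX_B = list(stoichiometry = c(B = -1), lower_bound = 0, upper_bound = 1000)))
}

# two routes to the same secretion: direct (1 reaction) and detour (2 reactions)
tworoute_model <- function() {
  network_model(
    data.frame(id = c("A", "I", "B")),
    list(EX_A = list(stoichiometry = c(A = -1), lower_bound = -10, upper_bound = 0),
         DIRECT = list(stoichiometry = c(A = -1, B = 1), lower_bound = 0, upper_bound = 1000),
         DET1 = list(stoichiometry = c(A = -1, I = 1), lower_bound = 0, upper_bound = 1000),
         DET2 = list(stoichiometry = c(I = -1, B = 1), lower_bound = 0, upper_bound = 1000),
         EX_B = list(stoichiometry = c(B = -1), lower_bound = 0, upper_bound = 1000)))
}

# long-form count table from per-study early/late matrices (rows = metabolites)
counts_from_matrices <- function(study_id, early, late) {
  stopifnot(nrow(early) == nrow(late))
  mk <- function(m, tp) {
    data.frame(study_id = study_id, time_point = tp,
               animal_id = paste0(study_id, "_", tp, "_a",
                                  rep(seq_len(ncol(m)), each = nrow(m))),
               metabolite_id = rep(rownames(m), ncol(m)),
               count = as.vector(m), stringsAsFactors = FALSE)
  }
  # NA counts are kept: they mark a missing measurement for a known animal
  rbind(mk(early, "early"), mk(late, "late"))
}
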