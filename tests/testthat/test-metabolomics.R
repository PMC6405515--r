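test_that("minimum-value imputation fills gaps within the chosen scope", {
  e1 <- matrix(c(5, NA, 7), 1, 3, dimnames = list("m1", NULL))
  l1 <- matrix(c(6, 8, 9), 1, 3, dimnames = list("m1", NULL))
  cts <- ms_counts(counts_from_matrices("study_1", e1, l1))
  imp <- impute_missing(cts, "per_study")
  got <- imp$count[imp$time_point == "early"]
  expect_equal(sort(got), c(5, 5, 7))

  # no missing values: unchanged
  full <- ms_counts(counts_from_matrices("study_1", l1, l1))
  imp2 <- impute_missing(full, "per_study")
  expect_equal(sort(imp2$count), sort(rep(c(6, 8, 9), 2)))

  # two studies with different floors: per-study minima 3 and 9
  eA <- matrix(c(3, NA, 5), 1, 3, dimnames = list("m1", NULL))
  lA <- matrix(c(4, 6, 7), 1, 3, dimnames = list("m1", NULL))
  eB <- matrix(c(NA, 9, 12), 1, 3, dimnames = list("m1", NULL))
  lB <- matrix(c(10, 11, 13), 1, 3, dimnames = list("m1", NULL))
  cts2 <- ms_counts(rbind(counts_from_matrices("A", eA, lA),
                          counts_from_matrices("B", eB, lB)))
  imp3 <- impute_missing(cts2, "per_study")
  # scan oracle: every filled value equals the study's observed minimum
  expect_equal(sort(imp3$count[imp3$study_id == "A" & imp3$time_point == "early"]),
               c(3, 3, 5))
  expect_equal(sort(imp3$count[imp3$study_id == "B" & imp3$time_point == "early"]),
               c(9, 9, 12))
  # pooled scope uses the global minimum instead
  imp4 <- impute_missing(cts2, "pooled")
  expect_equal(sort(imp4$count[imp4$study_id == "B" & imp4$time_point == "early"]),
               c(3, 9, 12))

  # a metabolite never observed in a study is dropped and recorded
  eC <- matrix(c(NA, NA, NA, 1, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("gone", "kept"), NULL))
  lC <- matrix(c(NA, NA, NA, 2, 3, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("gone", "kept"), NULL))
  imp5 <- impute_missing(ms_counts(counts_from_matrices("C", eC, lC)), "per_study")
  expect_false("gone" %in% imp5$metabolite_id)
  expect_true("gone" %in% attr(imp5, "dropped"))
})

test_that("bootstrap replicates are exact for constant data and reproducible", {
  const <- matrix(rep(42, 8), 1, dimnames = list("m1", NULL))
  studies <- list(s1 = list(early = rep(42, 8), late = rep(42, 8)))
  for (est in c("ratio_of_means", "paired_ratio")) {
    cfg <- bootstrap_config(B = 500, seed = 7, estimator = est)
    reps <- bootstrap_fold_changes(studies, cfg, "m1")
    expect_true(all(reps == 1))
  }

  # late exactly twice early: replicate means concentrate at 2
  set.seed(11)
  e <- exp(rnorm(8, 10, 0.3))
  studies2 <- list(s1 = list(early = e, late = 2 * e))
  cfg <- bootstrap_config(B = 1e4, seed = 3)
  reps2 <- bootstrap_fold_changes(studies2, cfg, "m1")
  expect_true(mean(reps2) > 1.8 && mean(reps2) < 2.2)

  # bit-identical under the same seed, regardless of processing order
  r1 <- bootstrap_fold_changes(studies2, cfg, "metX")
  dummy <- bootstrap_fold_changes(studies2, cfg, "metY")
  r2 <- bootstrap_fold_changes(studies2, cfg, "metX")
  expect_identical(as.numeric(r1), as.numeric(r2))
})

test_that("percentile intervals use linear interpolation", {
  ci <- percentile_ci(1:1000, 0.99)
  expect_equal(ci, c(5.995, 995.005), tolerance = 1e-9)
  expect_equal(percentile_ci(rep(3.3, 50), 0.99), c(3.3, 3.3))
  expect_equal(percentile_ci(c(2, 9, 4, 1), 1.0), c(1, 9))
  expect_error(percentile_ci(numeric(0)), "empty")
})

test_that("direction classification follows the CI-versus-1 rule", {
  expect_equal(classify_direction(1.2, 1.5), "elevated")
  expect_equal(classify_direction(0.7, 0.9), "depressed")
  expect_equal(classify_direction(0.9, 1.1), "unchanged")
  expect_equal(classify_direction(1.0, 1.4), "unchanged")  # touching 1
  expect_equal(classify_direction(0.6, 1.0), "unchanged")
  expect_error(classify_direction(1.5, 1.2), "invalid")
})

test_that("calls are reproducible and respect study membership", {
  sim <- make_ms_counts(n_metabolites = 6,
                        planted_fc = c(met_1 = 2, met_2 = 0.5),
                        n_animals = c(8, 8, 9), seed = 5)
  cfg <- bootstrap_config(B = 2000, seed = 5)
  c1 <- call_fold_changes(sim$counts, cfg)
  c2 <- call_fold_changes(sim$counts, cfg)
  expect_identical(c1, c2)
  expect_equal(c1$direction[c1$metabolite_id == "met_1"], "elevated")
  expect_equal(c1$direction[c1$metabolite_id == "met_2"], "depressed")
  expect_equal(unique(c1$n_studies), 3L)
  expect_true(all(c1$ci_lower <= c1$ci_upper))

  # a metabolite measured in only one study still gets a call from that study
  base_df <- as.data.frame(sim$counts)
  s1_early <- sort(unique(base_df$animal_id[base_df$study_id == "study_1" &
                                              base_df$time_point == "early"]))
  s1_late <- sort(unique(base_df$animal_id[base_df$study_id == "study_1" &
                                             base_df$time_point == "late"]))
  extra <- rbind(base_df,
                 data.frame(study_id = "study_1", time_point = "early",
                            animal_id = s1_early, metabolite_id = "solo",
                            count = c(10, 12, 11, 10.5, 11.5, 12.5, 9.5, 11.2)),
                 data.frame(study_id = "study_1", time_point = "late",
                            animal_id = s1_late, metabolite_id = "solo",
                            count = c(30, 33, 29, 31, 32, 28, 30.5, 33.5)))
  c3 <- call_fold_changes(ms_counts(extra), cfg)
  expect_equal(c3$studies_present[c3$metabolite_id == "solo"], "study_1")
  expect_equal(c3$direction[c3$metabolite_id == "solo"], "elevated")
})

test_that("scaling all late counts up never moves calls toward depressed", {
  sim <- make_ms_counts(n_metabolites = 8, seed = 9)
  cfg <- bootstrap_config(B = 1000, seed = 9)
  base <- call_fold_changes(sim$counts, cfg)
  scaled <- as.data.frame(sim$counts)
  scaled$count[scaled$time_point == "late"] <- 3 * scaled$count[scaled$time_point == "late"]
  up <- call_fold_changes(ms_counts(scaled), cfg)
  rank <- c(depressed = 1, unchanged = 2, elevated = 3)
  expect_true(all(rank[up$direction] >= rank[base$direction]))
})

test_that("zero early counts are redrawn (or rejected if hopeless)", {
  studies <- list(s1 = list(early = c(0, 5, 5, 5), late = c(6, 6, 6, 6)))
  cfg <- bootstrap_config(B = 200, seed = 2, estimator = "paired_ratio")
  reps <- bootstrap_fold_changes(studies, cfg, "m")
  expect_true(all(is.finite(reps)))
  expect_gte(attr(reps, "redraws"), 0)
  hopeless <- list(s1 = list(early = c(0, 0, 0), late = c(1, 1, 1)))
  expect_error(bootstrap_fold_changes(hopeless, cfg, "m"), "impute")
})

test_that("count tables round-trip through TSV", {
  sim <- make_ms_counts(n_metabolites = 4, seed = 3, missing_rate = 0.1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_ms_counts(sim$counts, tmp)
  back <- read_ms_counts(tmp)
  expect_equal(nrow(back), nrow(sim$counts))
  expect_equal(sort(back$count), sort(sim$counts$count), tolerance = 1e-12)
})
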