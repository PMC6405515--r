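#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis. Either give file paths
#' (model + bounds + counts produced elsewhere) or set `simulate = TRUE`
#' to generate both the toy liver network and the count tables from the
#' synthetic-data module. A seed is mandatory whenever any stochastic
#' stage runs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param simulate if `TRUE`, inputs come from [make_toy_liver_network] and
#'   [make_ms_counts]; otherwise `model_path`, `bounds_path` and
#'   `counts_path` must point to existing files.
#' @param model_path,bounds_path,counts_path,pathway_path input files
#'   (`pathway_path` optional).
#' @param v_opt_fraction,B,ci_level,estimator,impute_scope analysis
#'   parameters (see [run_timbr] and [bootstrap_config]).
#' @param sim synthetic-data parameters: a list with any of
#'   `n_metabolites`, `planted_fc`, `n_animals`, `noise_sigma`,
#'   `missing_rate`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = NULL, simulate = TRUE,
                       model_path = NULL, bounds_path = NULL,
                       counts_path = NULL, pathway_path = NULL,
                       v_opt_fraction = 0.9, B = 1e4, ci_level = 0.99,
                       estimator = "ratio_of_means",
                       impute_scope = "per_study", sim = list()) {
  if (is.null(seed) && B > 0)
    abort_validation("a seed is mandatory for any stochastic stage")
  if (!simulate) {
    for (p in c(model_path, bounds_path, counts_path, pathway_path))
      if (!is.null(p) && !file.exists(p) &&
          !file.exists(paste0(p, "_metabolites.tsv")))
        abort_validation(sprintf("configured input does not exist: %s", p))
    if (is.null(model_path) || is.null(bounds_path) || is.null(counts_path))
      abort_validation("without simulate = TRUE, model_path, bounds_path and counts_path are required")
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              model_path = model_path, bounds_path = bounds_path,
              counts_path = counts_path, pathway_path = pathway_path,
              v_opt_fraction = v_opt_fraction, B = B, ci_level = ci_level,
              estimator = estimator, impute_scope = impute_scope, sim = sim)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the same keys.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

config_fingerprint <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  sprintf("%08x", hash_string(s))
}

#' Run the full analysis pipeline
#'
#' Executes the four stages in order — condition bounds, production
#' scoring, fold-change calling, concordance — writing every intermediate
#' table and a run manifest into `cfg$out_dir`. Re-running with an
#' identical config reproduces identical output files.
#'
#' Outputs: `scores.tsv`, `calls.tsv`, `concordance.tsv`,
#' `concordance.json`, `manifest.json`, plus (when simulating)
#' `truth_network.tsv`, `truth_counts.tsv` and the simulated inputs.
#'
#' @param cfg a [run_config] (or path to a YAML config).
#' @return invisibly, a list with `scores`, `calls`, `report`, `accuracy`
#'   and `manifest`.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  op <- function(...) file.path(cfg$out_dir, ...)

  if (cfg$simulate) {
    net <- make_toy_liver_network()
    simargs <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    msc <- do.call(make_ms_counts, simargs)
    model <- net$model; cb_early <- net$cb_early; cb_late <- net$cb_late
    counts <- msc$counts
    save_model(model, op("model"), format = "tsv-triplet")
    write_condition_bounds(list(net$cb_early, net$cb_late), op("bounds.tsv"))
    write_ms_counts(counts, op("counts.tsv"))
    write_tsv(net$truth, op("truth_network.tsv"))
    write_tsv(msc$truth, op("truth_counts.tsv"))
    pathway_map <- NULL
  } else {
    model <- load_model(cfg$model_path)
    cbs <- read_condition_bounds(cfg$bounds_path)
    if (length(cbs) != 2)
      abort_validation("bounds file must define exactly two conditions (early, late)")
    cb_early <- cbs[[1]]; cb_late <- cbs[[2]]
    counts <- read_ms_counts(cfg$counts_path)
    pathway_map <- if (!is.null(cfg$pathway_path)) read_pathway_map(cfg$pathway_path)
  }

  scores <- run_timbr(model, cb_early, cb_late,
                      v_opt_fraction = cfg$v_opt_fraction)
  write_scores(scores, op("scores.tsv"))

  bcfg <- bootstrap_config(B = cfg$B, ci_level = cfg$ci_level, seed = cfg$seed,
                           estimator = cfg$estimator,
                           impute_scope = cfg$impute_scope)
  calls <- call_fold_changes(counts, bcfg)
  write_calls(calls, op("calls.tsv"))

  # when simulating, network scores and count calls describe different
  # synthetic entities; concordance is evaluated against the network truth
  # directions (the study-level question: does the sign recover the
  # planted direction?)
  if (cfg$simulate) {
    obs <- data.frame(metabolite_id = if (is.null(net$truth)) character(0)
                      else net$truth$metabolite_id,
                      direction = net$truth$direction,
                      stringsAsFactors = FALSE)
    report <- compare_concordance(scores, obs)
  } else {
    report <- compare_concordance(scores, calls, pathway_map)
  }
  write_concordance(report, op("concordance.tsv"), op("concordance.json"))
  acc <- accuracy_summary(report)

  manifest <- list(package = "hepaflux",
                   version = as.character(utils::packageVersion("hepaflux")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   config_fingerprint = config_fingerprint(cfg),
                   config = unclass(cfg),
                   stages = c("constraints", "scoring", "fold_changes",
                              "concordance"))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(scores = scores, calls = calls, report = report,
                 accuracy = acc, manifest = manifest))
}
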