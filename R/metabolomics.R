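#' Multi-study MS count tables
#'
#' Plasma metabolomics counts are kept in long form: one row per observed
#' (study, time point, animal, metabolite) measurement. A missing
#' measurement is simply an absent row (or an `NA` count). Each study has
#' an early and a late time point with equal numbers of animals.
#'
#' @param df data.frame with columns `study_id`, `time_point` (`"early"` /
#'   `"late"`), `animal_id`, `metabolite_id`, `count`.
#' @return a validated `ms_counts` data.frame.
#' @export
ms_counts <- function(df) {
  need <- c("study_id", "time_point", "animal_id", "metabolite_id", "count")
  if (!all(need %in% names(df)))
    abort_validation(sprintf("ms_counts needs columns: %s", paste(need, collapse = ", ")))
  df <- as.data.frame(df)[, need]
  bad_tp <- setdiff(unique(df$time_point), c("early", "late"))
  if (length(bad_tp) > 0)
    abort_validation(sprintf("time_point must be 'early' or 'late'; found: %s",
                             paste(bad_tp, collapse = ", ")))
  if (any(df$count < 0, na.rm = TRUE))
    abort_validation("counts must be nonnegative")
  key <- paste(df$study_id, df$time_point, df$animal_id, df$metabolite_id)
  if (anyDuplicated(key))
    abort_validation("duplicate (study, time point, animal, metabolite) rows")
  structure(df, class = c("ms_counts", "data.frame"))
}

#' @rdname ms_counts
#' @param path TSV path (columns as in [ms_counts]).
#' @export
read_ms_counts <- function(path) {
  ms_counts(read_tsv_strict(path, c("study_id", "time_point", "animal_id",
                                    "metabolite_id", "count")))
}

#' @rdname ms_counts
#' @param counts an `ms_counts` object.
#' @export
write_ms_counts <- function(counts, path) {
  write_tsv(as.data.frame(counts), path)
}

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates (default `1e5`; at least 1000
#'   for inference, smaller values are allowed for tests).
#' @param ci_level confidence level in (0, 1); default 0.99.
#' @param seed master integer seed; per-metabolite substreams are derived
#'   from it so that metabolite order cannot change any result.
#' @param estimator `"ratio_of_means"` (default): each replicate resamples
#'   animals within each study and forms the ratio of the resampled late
#'   mean to the resampled early mean, pooled across studies weighted by
#'   study size. `"paired_ratio"`: each replicate forms elementwise
#'   late/early ratios of index-aligned resampled draws (n per study),
#'   pools all ratios across studies and takes their mean. The per-pair
#'   ratios are upward-biased under multiplicative noise (see the methods
#'   vignette), which is why the ratio of means is the default.
#' @param impute_scope `"per_study"` (each study has its own detection
#'   floor) or `"pooled"`.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(B = 1e5, ci_level = 0.99, seed = 1L,
                             estimator = c("ratio_of_means", "paired_ratio"),
                             impute_scope = c("per_study", "pooled")) {
  estimator <- match.arg(estimator)
  impute_scope <- match.arg(impute_scope)
  if (B < 1) abort_validation("B must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) abort_validation("ci_level must be in (0, 1)")
  if (is.null(seed) || is.na(seed)) abort_validation("a seed is mandatory")
  structure(list(B = as.integer(B), ci_level = ci_level, seed = as.integer(seed),
                 estimator = estimator, impute_scope = impute_scope),
            class = "bootstrap_config")
}

#' Impute missing counts with the per-metabolite minimum observed value
#'
#' Missing entries (absent rows or `NA` counts on the full study x time
#' point x animal grid) are replaced by the minimum observed value for the
#' metabolite within the chosen scope: within each study (both time
#' points) for `per_study`, or across all studies for `pooled`. Metabolites
#' with no observed value anywhere in a scope unit are excluded from that
#' unit; ids excluded everywhere are recorded in the `"dropped"` attribute.
#'
#' @param counts an `ms_counts` object.
#' @param scope `"per_study"` or `"pooled"`.
#' @return an `ms_counts` object with no missing entries for retained
#'   metabolites.
#' @export
impute_missing <- function(counts, scope = c("per_study", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(inherits(counts, "ms_counts"))
  df <- as.data.frame(counts)
  observed <- df[!is.na(df$count), , drop = FALSE]
  pooled_min <- tapply(observed$count, observed$metabolite_id, min)

  out <- list(); dropped <- character(0)
  for (sid in unique(df$study_id)) {
    d <- df[df$study_id == sid, , drop = FALSE]
    obs <- d[!is.na(d$count), , drop = FALSE]
    study_min <- tapply(obs$count, obs$metabolite_id, min)
    mets <- if (scope == "per_study") names(study_min) else
      intersect(unique(df$metabolite_id[!is.na(df$count)]), unique(d$metabolite_id))
    # metabolites listed in this study (any row) but never observed in scope
    listed <- unique(d$metabolite_id)
    mets <- intersect(listed, if (scope == "per_study") names(study_min)
                      else names(pooled_min))
    dropped <- c(dropped, setdiff(listed, mets))
    for (tp in c("early", "late")) {
      animals <- sort(unique(d$animal_id[d$time_point == tp]))
      if (length(animals) == 0) next
      grid <- expand.grid(animal_id = animals, metabolite_id = mets,
                          stringsAsFactors = FALSE)
      have <- obs[obs$time_point == tp, c("animal_id", "metabolite_id", "count")]
      grid <- merge(grid, have, by = c("animal_id", "metabolite_id"), all.x = TRUE)
      fill <- if (scope == "per_study") study_min[grid$metabolite_id]
              else pooled_min[grid$metabolite_id]
      grid$count <- ifelse(is.na(grid$count), as.numeric(fill), grid$count)
      out[[length(out) + 1]] <- data.frame(study_id = sid, time_point = tp,
                                           animal_id = grid$animal_id,
                                           metabolite_id = grid$metabolite_id,
                                           count = grid$count,
                                           stringsAsFactors = FALSE)
    }
  }
  res <- ms_counts(do.call(rbind, out))
  res <- res[order(res$study_id, res$time_point, res$metabolite_id, res$animal_id), ]
  rownames(res) <- NULL
  attr(res, "dropped") <- unique(dropped)
  res
}

# internal: per-study early/late value vectors for one metabolite
study_pairs <- function(df, metabolite_id) {
  d <- df[df$metabolite_id == metabolite_id, , drop = FALSE]
  out <- list()
  for (sid in unique(d$study_id)) {
    e <- d$count[d$study_id == sid & d$time_point == "early"]
    l <- d$count[d$study_id == sid & d$time_point == "late"]
    if (length(e) > 0 && length(l) > 0)
      out[[as.character(sid)]] <- list(early = e, late = l)
  }
  out
}

#' Bootstrap the pooled mean fold change of one metabolite
#'
#' For each replicate, animals are resampled with replacement within each
#' study at both time points; the replicate's pooled mean fold change is
#' formed according to the configured estimator (see [bootstrap_config]).
#' Fully reproducible: the RNG substream is derived from the master seed
#' and the metabolite id.
#'
#' @param studies named list (study id -> list(early =, late = numeric
#'   vectors)) as produced internally from an imputed [ms_counts] table.
#' @param cfg a [bootstrap_config].
#' @param metabolite_id id used to derive the RNG substream.
#' @return numeric vector of `B` pooled mean fold changes, with attribute
#'   `"redraws"` counting replicates redrawn due to zero denominators.
#' @export
bootstrap_fold_changes <- function(studies, cfg, metabolite_id = "met") {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(studies) == 0) abort_validation("metabolite present in no study")
  B <- cfg$B
  ns <- vapply(studies, function(s) length(s$early), 0L)
  for (s in studies)
    if (length(s$early) != length(s$late))
      abort_validation("early and late vectors of a study must have equal length")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(cfg$seed, metabolite_id))

  redraws <- 0L
  draw <- function() {
    if (cfg$estimator == "paired_ratio") {
      folds <- matrix(0, B, sum(ns)); col <- 0L
      for (s in studies) {
        n <- length(s$early)
        li <- matrix(sample.int(n, B * n, replace = TRUE), B, n)
        ei <- matrix(sample.int(n, B * n, replace = TRUE), B, n)
        num <- matrix(s$late[li], B, n); den <- matrix(s$early[ei], B, n)
        bad <- which(rowSums(den == 0) > 0)
        attempts <- 0
        while (length(bad) > 0 && attempts < 50) {
          redraws <<- redraws + length(bad)
          for (r in bad) {
            li_r <- sample.int(n, n, replace = TRUE)
            ei_r <- sample.int(n, n, replace = TRUE)
            num[r, ] <- s$late[li_r]; den[r, ] <- s$early[ei_r]
          }
          bad <- which(rowSums(den == 0) > 0)
          attempts <- attempts + 1
        }
        if (length(bad) > 0)
          abort_validation("zero early counts persist after redraws; impute first")
        folds[, (col + 1L):(col + n)] <- num / den
        col <- col + n
      }
      rowMeans(folds)
    } else {
      fcs <- matrix(0, B, length(studies))
      for (j in seq_along(studies)) {
        s <- studies[[j]]; n <- length(s$early)
        li <- matrix(sample.int(n, B * n, replace = TRUE), B, n)
        ei <- matrix(sample.int(n, B * n, replace = TRUE), B, n)
        num <- rowMeans(matrix(s$late[li], B, n))
        den <- rowMeans(matrix(s$early[ei], B, n))
        bad <- which(den == 0)
        attempts <- 0
        while (length(bad) > 0 && attempts < 50) {
          redraws <<- redraws + length(bad)
          for (r in bad) {
            num[r] <- mean(s$late[sample.int(n, n, replace = TRUE)])
            den[r] <- mean(s$early[sample.int(n, n, replace = TRUE)])
          }
          bad <- which(den == 0)
          attempts <- attempts + 1
        }
        if (length(bad) > 0)
          abort_validation("zero early counts persist after redraws; impute first")
        fcs[, j] <- num / den
      }
      as.vector(fcs %*% ns) / sum(ns)
    }
  }
  out <- draw()
  attr(out, "redraws") <- redraws
  out
}

#' Percentile confidence interval
#'
#' Linear-interpolation percentiles (R's default quantile definition,
#' type 7) of the bootstrap replicate vector; for `ci_level = 0.99` the
#' interval runs from the 0.5th to the 99.5th percentile.
#'
#' @param samples numeric vector of replicate statistics (length >= 2,
#'   or >= 1 for `ci_level = 1`).
#' @param ci_level confidence level in (0, 1].
#' @return numeric `c(lower, upper)`.
#' @export
percentile_ci <- function(samples, ci_level = 0.99) {
  if (length(samples) == 0) abort_validation("empty replicate vector")
  alpha <- (1 - ci_level) / 2
  unname(stats::quantile(samples, c(alpha, 1 - alpha), type = 7, names = FALSE))
}

#' Classify the direction of change from a fold-change CI
#'
#' Elevated iff the whole interval lies above 1, depressed iff it lies
#' below 1, otherwise (including intervals touching 1 exactly) unchanged.
#'
#' @param lower,upper CI bounds (either two scalars or `lower` a length-2
#'   vector).
#' @return `"elevated"`, `"depressed"` or `"unchanged"`.
#' @export
classify_direction <- function(lower, upper = NULL) {
  if (is.null(upper)) { upper <- lower[2]; lower <- lower[1] }
  if (is.na(lower) || is.na(upper) || lower > upper)
    abort_validation("invalid confidence interval")
  if (lower > 1) "elevated" else if (upper < 1) "depressed" else "unchanged"
}

#' Call per-metabolite plasma direction from multi-study counts
#'
#' End-to-end direction caller: minimum-value imputation, pooled bootstrap
#' of mean fold changes (late/early), percentile confidence interval, and
#' the CI-versus-1 direction rule.
#'
#' @param counts an `ms_counts` object (raw; imputation is applied here).
#' @param cfg a [bootstrap_config].
#' @return a `fold_change_calls` data.frame: `metabolite_id`, `mean_fc`,
#'   `ci_lower`, `ci_upper`, `direction`, `studies_present`, `n_studies`.
#' @export
call_fold_changes <- function(counts, cfg) {
  stopifnot(inherits(counts, "ms_counts"), inherits(cfg, "bootstrap_config"))
  imp <- impute_missing(counts, cfg$impute_scope)
  df <- as.data.frame(imp)
  mets <- sort(unique(df$metabolite_id))
  rows <- lapply(mets, function(met) {
    studies <- study_pairs(df, met)
    if (length(studies) == 0) return(NULL)
    reps <- bootstrap_fold_changes(studies, cfg, metabolite_id = met)
    ci <- percentile_ci(reps, cfg$ci_level)
    data.frame(metabolite_id = met, mean_fc = mean(reps),
               ci_lower = ci[1], ci_upper = ci[2],
               direction = classify_direction(ci),
               studies_present = paste(names(studies), collapse = ";"),
               n_studies = length(studies), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fold_change_calls", "data.frame"))
}

#' Read / write fold-change call tables
#'
#' TSV dialect: columns `metabolite_id`, `mean_fc`, `ci_lower`, `ci_upper`,
#' `direction`, `studies_present`, `n_studies`.
#'
#' @param calls a `fold_change_calls` data.frame.
#' @param path TSV file path.
#' @export
write_calls <- function(calls, path) write_tsv(as.data.frame(calls), path)

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_tsv_strict(path, c("metabolite_id", "mean_fc", "ci_lower",
                                "ci_upper", "direction"))
  structure(df, class = c("fold_change_calls", "data.frame"))
}
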