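#' Compare production-score signs with observed directions of change
#'
#' A prediction is concordant when the z-transformed production score is
#' positive for an observed elevated metabolite or negative for an
#' observed depressed one. Metabolites whose score is exactly zero or
#' whose scoring status is not `"ok"` carry no prediction; by default they
#' are counted discordant (conservative), or they can be excluded.
#' Only metabolites with an observed direction of `elevated` or
#' `depressed` and a score row are compared; called metabolites absent
#' from the score table are listed in the `unmapped` element and excluded
#' from all counts.
#'
#' @param scores a `timbr_scores` data.frame (needs `metabolite_id`,
#'   `x_s`, `status`).
#' @param calls a `fold_change_calls` data.frame, or any data.frame with
#'   `metabolite_id` and `direction`.
#' @param pathway_map optional data.frame `metabolite_id`, `pathway`.
#' @param no_prediction how to treat score-less metabolites:
#'   `"discordant"` (default) or `"exclude"`.
#' @return a `concordance_report`: list with `per_metabolite` (data.frame
#'   `metabolite_id`, `pathway`, `observed`, `predicted_sign`,
#'   `concordant`), `summary` (confusion counts) and `unmapped`.
#' @export
compare_concordance <- function(scores, calls, pathway_map = NULL,
                                no_prediction = c("discordant", "exclude")) {
  no_prediction <- match.arg(no_prediction)
  sc <- as.data.frame(scores)
  cl <- as.data.frame(calls)
  cl <- cl[cl$direction %in% c("elevated", "depressed"), , drop = FALSE]
  unmapped <- setdiff(cl$metabolite_id, sc$metabolite_id)
  cl <- cl[!cl$metabolite_id %in% unmapped, , drop = FALSE]

  idx <- match(cl$metabolite_id, sc$metabolite_id)
  xs <- sc$x_s[idx]
  ok <- sc$status[idx] == "ok" & !is.na(xs)
  sign_chr <- ifelse(!ok | xs == 0, "none", ifelse(xs > 0, "+", "-"))
  concordant <- (sign_chr == "+" & cl$direction == "elevated") |
                (sign_chr == "-" & cl$direction == "depressed")

  per <- data.frame(metabolite_id = cl$metabolite_id,
                    pathway = rep(NA_character_, nrow(cl)),
                    observed = cl$direction,
                    predicted_sign = sign_chr,
                    concordant = concordant,
                    stringsAsFactors = FALSE)
  if (!is.null(pathway_map)) {
    pm <- as.data.frame(pathway_map)
    per$pathway <- pm$pathway[match(per$metabolite_id, pm$metabolite_id)]
  }
  if (no_prediction == "exclude")
    per <- per[per$predicted_sign != "none", , drop = FALSE]

  n_elev <- sum(per$observed == "elevated")
  n_depr <- sum(per$observed == "depressed")
  summary <- list(
    n_elevated = n_elev,
    n_elevated_concordant = sum(per$concordant & per$observed == "elevated"),
    n_depressed = n_depr,
    n_depressed_concordant = sum(per$concordant & per$observed == "depressed"),
    n_total = n_elev + n_depr,
    n_concordant = sum(per$concordant))
  structure(list(per_metabolite = per, summary = summary, unmapped = unmapped),
            class = "concordance_report")
}

#' Build a concordance report directly from confusion counts
#'
#' Convenience constructor for evaluating published or externally tabulated
#' confusion counts with [accuracy_summary].
#'
#' @param n_elevated,n_elevated_concordant,n_depressed,n_depressed_concordant
#'   confusion counts.
#' @return a `concordance_report` (without per-metabolite rows).
#' @export
concordance_from_counts <- function(n_elevated, n_elevated_concordant,
                                    n_depressed, n_depressed_concordant) {
  if (n_elevated_concordant > n_elevated || n_depressed_concordant > n_depressed)
    abort_validation("concordant counts cannot exceed group totals")
  structure(list(per_metabolite = NULL,
                 summary = list(
                   n_elevated = n_elevated,
                   n_elevated_concordant = n_elevated_concordant,
                   n_depressed = n_depressed,
                   n_depressed_concordant = n_depressed_concordant,
                   n_total = n_elevated + n_depressed,
                   n_concordant = n_elevated_concordant + n_depressed_concordant),
                 unmapped = character(0)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("concordance: %d/%d overall, %d/%d elevated, %d/%d depressed\n",
              s$n_concordant, s$n_total, s$n_elevated_concordant, s$n_elevated,
              s$n_depressed_concordant, s$n_depressed))
  invisible(x)
}

#' Accuracy percentages and exact binomial significance
#'
#' Accuracies are reported both at full precision and rounded to the
#' integer percent. The significance of the overall accuracy is the
#' one-sided exact binomial probability of at least the observed number of
#' concordant predictions under chance (p0 = 0.5); per-pathway accuracies
#' are tested two-sided. Empty groups yield `NA` percents.
#'
#' @param report a `concordance_report`.
#' @param p0 chance success probability (default 0.5).
#' @return a list with `overall`, `elevated`, `depressed` (each holding
#'   `k`, `n`, `accuracy`, `accuracy_pct` and, for overall, `p_value`) and
#'   `pathways` (data.frame with two-sided p-values), when pathway
#'   annotations are present.
#' @export
accuracy_summary <- function(report, p0 = 0.5) {
  stopifnot(inherits(report, "concordance_report"))
  s <- report$summary
  grp <- function(k, n, alternative = NULL) {
    acc <- if (n > 0) 100 * k / n else NA_real_
    out <- list(k = k, n = n, accuracy = acc,
                accuracy_pct = if (is.na(acc)) NA_integer_ else as.integer(round(acc)))
    if (!is.null(alternative) && n > 0)
      out$p_value <- exact_binomial_p(k, n, p0, alternative)
    out
  }
  res <- list(overall = grp(s$n_concordant, s$n_total, "greater"),
              elevated = grp(s$n_elevated_concordant, s$n_elevated),
              depressed = grp(s$n_depressed_concordant, s$n_depressed))
  per <- report$per_metabolite
  if (!is.null(per) && any(!is.na(per$pathway))) {
    pw <- split(per, per$pathway)
    res$pathways <- do.call(rbind, lapply(names(pw), function(p) {
      k <- sum(pw[[p]]$concordant); n <- nrow(pw[[p]])
      data.frame(pathway = p, k = k, n = n,
                 accuracy = 100 * k / n,
                 accuracy_pct = as.integer(round(100 * k / n)),
                 p_value = exact_binomial_p(k, n, p0, "two_sided"),
                 stringsAsFactors = FALSE)
    }))
    rownames(res$pathways) <- NULL
  }
  res
}

#' Exact binomial tail probability
#'
#' `greater`: `P(X >= k)` for `X ~ Binomial(n, p0)`. `two_sided` (intended
#' for `p0 = 0.5`): twice the smaller tail, where the tails are
#' `P(X >= k)` and `P(X <= k)`, capped at 1.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return the p-value.
#' @export
exact_binomial_p <- function(k, n, p0 = 0.5,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
    abort_validation("need integer 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) abort_validation("p0 must be in (0, 1)")
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  if (alternative == "greater") return(upper)
  lower <- stats::pbinom(k, n, p0)                          # P(X <= k)
  min(1, 2 * min(upper, lower))
}

#' Read / write pathway annotation maps
#'
#' TSV dialect: columns `metabolite_id`, `pathway` (the major biochemical
#' pathway groups: amino acid, carbohydrate, cofactors and vitamins, TCA
#' cycle, lipid, nucleotide, peptide).
#'
#' @param path TSV file path.
#' @export
read_pathway_map <- function(path) {
  read_tsv_strict(path, c("metabolite_id", "pathway"))
}

#' Write a concordance report to TSV (per-metabolite rows) and JSON (summary)
#'
#' @param report a `concordance_report`.
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @export
write_concordance <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "concordance_report"))
  if (!is.null(tsv_path) && !is.null(report$per_metabolite))
    write_tsv(report$per_metabolite, tsv_path)
  if (!is.null(json_path)) {
    acc <- accuracy_summary(report)
    jsonlite::write_json(list(summary = report$summary, accuracy = acc,
                              unmapped = report$unmapped),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
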