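#' Per-condition flux bound sets
#'
#' A `condition_bounds` object collects bound overrides for a named
#' physiological condition: exchange-reaction bounds (uptake/secretion
#' rates) and bounds on measured central-carbon reactions (from isotope
#' tracer flux estimates).
#'
#' @param condition_label e.g. `"early_5-7h"` or `"late_10-13h"`.
#' @param exchange_bounds data.frame with columns `reaction_id`, `lower`,
#'   `upper` (may be empty).
#' @param mfa_bounds same shape, for measured internal fluxes.
#' @return an object of class `condition_bounds`.
#' @export
condition_bounds <- function(condition_label, exchange_bounds = NULL,
                             mfa_bounds = NULL) {
  empty <- data.frame(reaction_id = character(0), lower = numeric(0),
                      upper = numeric(0), stringsAsFactors = FALSE)
  norm <- function(b, what) {
    if (is.null(b)) return(empty)
    b <- as.data.frame(b)
    need <- c("reaction_id", "lower", "upper")
    if (!all(need %in% names(b)))
      abort_validation(sprintf("%s needs columns reaction_id, lower, upper", what))
    b <- b[, need]
    if (any(b$lower > b$upper))
      abort_validation(sprintf("%s: lower > upper for reaction(s): %s", what,
                               paste(b$reaction_id[b$lower > b$upper], collapse = ", ")))
    if (anyDuplicated(b$reaction_id))
      abort_validation(sprintf("%s: duplicate reaction id(s)", what))
    b
  }
  structure(list(condition_label = as.character(condition_label),
                 exchange_bounds = norm(exchange_bounds, "exchange_bounds"),
                 mfa_bounds = norm(mfa_bounds, "mfa_bounds")),
            class = "condition_bounds")
}

#' @export
print.condition_bounds <- function(x, ...) {
  cat(sprintf("condition_bounds '%s': %d exchange, %d measured-flux overrides\n",
              x$condition_label, nrow(x$exchange_bounds), nrow(x$mfa_bounds)))
  invisible(x)
}

#' Fractional precursor contributions to glucose output
#'
#' During short-term fasting the liver produces glucose from glycogen
#' breakdown and from gluconeogenesis fed by glycerol, lactate and amino
#' acids; the split between those precursors shifts strongly with fasting
#' duration (glycogen ~48% of output early, ~2% late). This container
#' holds the total output flux and the precursor fractions.
#'
#' @param total_output total glucose output flux (model flux units).
#' @param fractions named numeric vector over precursors (names from
#'   `glycogen`, `glycerol`, `lactate_and_amino_acids`), each in `[0, 1]`,
#'   summing to 1 within 0.01.
#' @return an object of class `precursor_fractions`.
#' @export
precursor_fractions <- function(total_output,
                                fractions = c(glycogen = 0.48, glycerol = 0.15,
                                              lactate_and_amino_acids = 0.37)) {
  if (!is.numeric(total_output) || length(total_output) != 1 || total_output < 0)
    abort_validation("total_output must be a single nonnegative flux")
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    abort_validation("fractions must be a named numeric vector")
  if (any(fractions < 0 | fractions > 1))
    abort_validation(sprintf("fraction outside [0,1]: %s",
                             paste(names(fractions)[fractions < 0 | fractions > 1],
                                   collapse = ", ")))
  if (abs(sum(fractions) - 1) > 0.01)
    abort_validation(sprintf("fractions sum to %.4f; expected 1 within 0.01",
                             sum(fractions)))
  structure(list(total_output = total_output, fractions = fractions),
            class = "precursor_fractions")
}

#' Convert fractional precursor contributions into absolute reaction bounds
#'
#' Each precursor route reaction is bounded at
#' `fraction * total_output * (1 -/+ tolerance_fraction)`, and the glucose
#' output reaction at `total_output` with the same relative tolerance.
#' With `tolerance_fraction = 0` the bounds are point constraints whose
#' sum over precursors equals the total output (to within the tolerance on
#' the fraction sum).
#'
#' @param pf a [precursor_fractions] object.
#' @param mapping named character vector precursor-name -> reaction id; must
#'   cover every precursor present in `pf`. Optionally include the entry
#'   `glucose_output` for the output reaction.
#' @param tolerance_fraction relative half-width of each bound interval.
#' @param condition_label label passed to [condition_bounds].
#' @return a `condition_bounds` object (bounds recorded as measured-flux
#'   bounds, since they constrain internal route reactions).
#' @export
fractions_to_bounds <- function(pf, mapping, tolerance_fraction = 0,
                                condition_label = "condition") {
  stopifnot(inherits(pf, "precursor_fractions"))
  if (tolerance_fraction < 0) abort_validation("tolerance_fraction must be >= 0")
  unknown <- setdiff(names(pf$fractions), names(mapping))
  if (length(unknown) > 0)
    abort_validation(sprintf("mapping missing precursor(s): %s",
                             paste(unknown, collapse = ", ")))
  extra <- setdiff(names(mapping), c(names(pf$fractions), "glucose_output"))
  if (length(extra) > 0)
    abort_validation(sprintf("unknown precursor name(s) in mapping: %s",
                             paste(extra, collapse = ", ")))
  flux <- pf$fractions * pf$total_output
  ids <- unname(mapping[names(pf$fractions)])
  lo <- unname(flux * (1 - tolerance_fraction))
  hi <- unname(flux * (1 + tolerance_fraction))
  if ("glucose_output" %in% names(mapping)) {
    ids <- c(ids, unname(mapping[["glucose_output"]]))
    lo <- c(lo, pf$total_output * (1 - tolerance_fraction))
    hi <- c(hi, pf$total_output * (1 + tolerance_fraction))
  }
  condition_bounds(condition_label,
                   mfa_bounds = data.frame(reaction_id = ids, lower = lo,
                                           upper = hi, stringsAsFactors = FALSE))
}

#' Apply a condition's bound overrides to a model
#'
#' Returns a copy of the model in which every reaction listed in the
#' condition has its bounds replaced by the intersection of the override
#' interval with the model's declared hard bounds (the tighter of the two
#' wins); all other bounds are unchanged. Applying the same condition
#' twice is idempotent.
#'
#' @param model a `network_model`.
#' @param cb a `condition_bounds` object.
#' @return a new `network_model`.
#' @export
apply_condition <- function(model, cb) {
  stopifnot(inherits(model, "network_model"), inherits(cb, "condition_bounds"))
  ov <- rbind(cb$exchange_bounds, cb$mfa_bounds)
  if (nrow(ov) == 0) return(model)
  if (anyDuplicated(ov$reaction_id))
    abort_validation(sprintf("condition '%s' lists reaction(s) twice: %s",
                             cb$condition_label,
                             paste(unique(ov$reaction_id[duplicated(ov$reaction_id)]),
                                   collapse = ", ")))
  idx <- match(ov$reaction_id, model$reactions$id)
  if (anyNA(idx))
    abort_validation(sprintf("condition '%s' references unknown reaction(s): %s",
                             cb$condition_label,
                             paste(ov$reaction_id[is.na(idx)], collapse = ", ")))
  hard <- model$default_bound
  lo <- pmax(ov$lower, -hard)
  hi <- pmin(ov$upper, hard)
  bad <- lo > hi + 1e-12
  if (any(bad))
    abort_infeasible(sprintf("condition '%s': empty bound interval after intersection for: %s",
                             cb$condition_label,
                             paste(ov$reaction_id[bad], collapse = ", ")))
  model$reactions$lower_bound[idx] <- lo
  model$reactions$upper_bound[idx] <- hi
  attr(model, "condition_label") <- cb$condition_label
  model
}

#' Read / write condition bound tables
#'
#' TSV dialect: columns `condition`, `reaction_id`, `lower`, `upper`,
#' `source` (one of `exchange`, `mfa`).
#'
#' @param path TSV file path.
#' @return `read_condition_bounds`: a named list of `condition_bounds`,
#'   one per condition label in the file.
#' @export
read_condition_bounds <- function(path) {
  df <- read_tsv_strict(path, c("condition", "reaction_id", "lower", "upper", "source"))
  bad <- setdiff(unique(df$source), c("exchange", "mfa"))
  if (length(bad) > 0)
    abort_validation(sprintf("%s: unknown source value(s): %s", path,
                             paste(bad, collapse = ", ")))
  out <- lapply(split(df, df$condition), function(d) {
    condition_bounds(d$condition[1],
                     exchange_bounds = d[d$source == "exchange",
                                         c("reaction_id", "lower", "upper")],
                     mfa_bounds = d[d$source == "mfa",
                                    c("reaction_id", "lower", "upper")])
  })
  out[unique(df$condition)]
}

#' @rdname read_condition_bounds
#' @param cbs a `condition_bounds` object or list of them.
#' @export
write_condition_bounds <- function(cbs, path) {
  if (inherits(cbs, "condition_bounds")) cbs <- list(cbs)
  rows <- lapply(cbs, function(cb) {
    rbind(
      if (nrow(cb$exchange_bounds) > 0)
        cbind(condition = cb$condition_label, cb$exchange_bounds, source = "exchange"),
      if (nrow(cb$mfa_bounds) > 0)
        cbind(condition = cb$condition_label, cb$mfa_bounds, source = "mfa"))
  })
  write_tsv(do.call(rbind, rows), path)
}
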