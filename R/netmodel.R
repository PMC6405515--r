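#' Construct a constraint-based metabolic network model
#'
#' A `network_model` holds an ordered metabolite table, an ordered reaction
#' list and the stoichiometric matrix S (rows = metabolites, columns =
#' reactions). Exchange reactions — boundary reactions whose stoichiometry
#' involves exactly one metabolite — follow the usual sign convention:
#' positive flux secretes the metabolite into plasma, negative flux takes
#' it up.
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`
#'   and `compartment`.
#' @param reactions named list; each element has `stoichiometry` (named
#'   numeric vector of metabolite coefficients), and optionally
#'   `lower_bound`, `upper_bound`, `weight` and `name`.
#' @param compartments character vector of declared compartment codes;
#'   defaults to the distinct compartments present.
#' @param default_bound magnitude used for absent bounds (conventionally
#'   1000 in model flux units).
#'
#' @return an object of class `network_model` with elements `metabolites`
#'   (data.frame), `reactions` (data.frame id/name/lower_bound/upper_bound/
#'   weight/is_exchange), `stoichiometry` (sparse `dgCMatrix`), and
#'   `compartments`.
#' @export
network_model <- function(metabolites, reactions, compartments = NULL,
                          default_bound = 1000) {
  if (is.character(metabolites)) metabolites <- data.frame(id = metabolites)
  if (!"id" %in% names(metabolites)) abort_validation("metabolites need an 'id' column")
  metabolites$id <- as.character(metabolites$id)
  if (anyDuplicated(metabolites$id))
    abort_validation(sprintf("duplicate metabolite id(s): %s",
                             paste(unique(metabolites$id[duplicated(metabolites$id)]),
                                   collapse = ", ")))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))
  bad_comp <- setdiff(metabolites$compartment, compartments)
  if (length(bad_comp) > 0)
    abort_validation(sprintf("undeclared compartment(s): %s",
                             paste(bad_comp, collapse = ", ")))

  rxn_ids <- names(reactions)
  if (is.null(rxn_ids) || any(rxn_ids == ""))
    abort_validation("reactions must be a named list (names are reaction ids)")
  if (anyDuplicated(rxn_ids))
    abort_validation(sprintf("duplicate reaction id(s): %s",
                             paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))

  lb <- ub <- w <- numeric(length(reactions))
  nm <- character(length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    s <- r$stoichiometry
    if (is.null(s) || length(s) == 0)
      abort_validation(sprintf("reaction '%s': empty stoichiometry", rxn_ids[j]))
    unknown <- setdiff(names(s), metabolites$id)
    if (length(unknown) > 0)
      abort_validation(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                               rxn_ids[j], paste(unknown, collapse = ", ")))
    lb[j] <- r$lower_bound %||% -default_bound
    ub[j] <- r$upper_bound %||% default_bound
    if (lb[j] > ub[j])
      abort_validation(sprintf("reaction '%s': lower_bound > upper_bound", rxn_ids[j]))
    w[j] <- r$weight %||% 1
    if (w[j] < 0) abort_validation(sprintf("reaction '%s': negative weight", rxn_ids[j]))
    nm[j] <- r$name %||% rxn_ids[j]
  }

  S <- build_stoich_matrix(reactions, metabolites$id)
  is_ex <- Matrix::colSums(S != 0) == 1

  rx <- data.frame(id = rxn_ids, name = nm, lower_bound = lb, upper_bound = ub,
                   weight = w, is_exchange = as.vector(is_ex),
                   stringsAsFactors = FALSE)

  model <- structure(list(metabolites = metabolites, reactions = rx,
                          stoichiometry = S, compartments = compartments,
                          default_bound = default_bound),
                     class = "network_model")
  model$metabolites$is_exchangeable <- exchangeable_metabolites(model)
  model
}

#' Build the stoichiometric matrix from reaction definitions
#'
#' @param reactions named list of reactions, each carrying a named numeric
#'   `stoichiometry` vector (or the named numeric vector itself).
#' @param metabolite_ids character vector giving the row order.
#' @return a sparse `dgCMatrix` with rows = metabolites, columns = reactions;
#'   column j reproduces reaction j's stoichiometry exactly.
#' @export
build_stoich_matrix <- function(reactions, metabolite_ids) {
  metabolite_ids <- as.character(metabolite_ids)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(reactions)) {
    s <- reactions[[j]]
    if (is.list(s)) s <- s$stoichiometry
    idx <- match(names(s), metabolite_ids)
    if (anyNA(idx))
      abort_validation(sprintf("reaction '%s' references unknown metabolite(s): %s",
                               names(reactions)[j] %||% j,
                               paste(names(s)[is.na(idx)], collapse = ", ")))
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(s))); xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(metabolite_ids), length(reactions)),
                       dimnames = list(metabolite_ids,
                                       names(reactions) %||% seq_along(reactions)))
}

#' Identify exchange reactions
#'
#' Exchange (boundary) reactions are exactly those whose stoichiometry
#' involves a single metabolite.
#'
#' @param model a `network_model`.
#' @return character vector of reaction ids, sorted.
#' @export
identify_exchange_reactions <- function(model) {
  stopifnot(inherits(model, "network_model"))
  ids <- model$reactions$id[Matrix::colSums(model$stoichiometry != 0) == 1]
  sort(ids)
}

# metabolites touched by an exchange reaction (directly; extracellular
# counterpart resolution is left to model curation)
exchangeable_metabolites <- function(model) {
  ex <- model$reactions$is_exchange
  if (!any(ex)) return(rep(FALSE, nrow(model$metabolites)))
  touched <- Matrix::rowSums(model$stoichiometry[, ex, drop = FALSE] != 0) > 0
  as.vector(touched)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d metabolites, %d reactions (%d exchange), compartments: %s\n",
              nrow(x$metabolites), nrow(x$reactions), sum(x$reactions$is_exchange),
              paste(x$compartments, collapse = ", ")))
  invisible(x)
}

#' Load a metabolic network model from disk
#'
#' Three dialects are supported: COBRA-style JSON (`metabolites` +
#' `reactions` with `metabolites` coefficient maps and bounds), SBML Level 3
#' with the FBC bounds extension (requires the xml2 package), and a plain
#' TSV triplet (`<stem>_metabolites.tsv`, `<stem>_reactions.tsv`,
#' `<stem>_stoich.tsv`) used for fixtures.
#'
#' @param path file path; for `tsv-triplet`, the stem shared by the three
#'   files (or the path of any one of them).
#' @param format one of `"cobra-json"`, `"sbml"`, `"tsv-triplet"`; guessed
#'   from the file extension when omitted.
#' @param default_bound bound magnitude substituted for absent bounds.
#' @return a `network_model`.
#' @export
load_model <- function(path, format = c("guess", "cobra-json", "sbml", "tsv-triplet"),
                       default_bound = 1000) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra-json"
    else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
    else "tsv-triplet"
  }
  switch(format,
         "cobra-json" = load_model_json(path, default_bound),
         "sbml" = load_model_sbml(path, default_bound),
         "tsv-triplet" = load_model_tsv(path, default_bound))
}

load_model_json <- function(path, default_bound) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    abort_validation(sprintf("JSON parse failure in %s: %s",
                                             path, conditionMessage(e))))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    abort_validation(sprintf("%s: not a COBRA-style model (need 'metabolites' and 'reactions')", path))
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), ""),
    name = vapply(doc$metabolites, function(m) as.character(m$name %||% m$id), ""),
    compartment = vapply(doc$metabolites, function(m) as.character(m$compartment %||% "c"), ""),
    stringsAsFactors = FALSE)
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) abort_validation(sprintf("%s: reaction without id", path))
    list(stoichiometry = unlist(r$metabolites),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         weight = r$weight, name = r$name)
  })
  names(rxns) <- vapply(doc$reactions, function(r) as.character(r$id), "")
  comps <- if (!is.null(doc$compartments)) names(doc$compartments) else NULL
  network_model(mets, rxns, compartments = comps, default_bound = default_bound)
}

load_model_sbml <- function(path, default_bound) {
  if (!requireNamespace("xml2", quietly = TRUE))
    abort_validation("SBML reading requires the 'xml2' package")
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    abort_validation(sprintf("SBML parse failure in %s: %s",
                                             path, conditionMessage(e))))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  # global flux-bound parameters (FBC style)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(r) {
    refs_in <- xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)
    refs_out <- xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(nodes, "species"))
    }
    s <- c(coef(refs_in, -1), coef(refs_out, +1))
    # duplicated species on both sides: sum coefficients
    s <- tapply(s, names(s), sum)
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]]
          else if (rev) NULL else 0
    list(stoichiometry = stats::setNames(as.numeric(s), names(s)),
         lower_bound = lb,
         upper_bound = if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else NULL,
         name = xml2::xml_attr(r, "name"))
  })
  names(rxns) <- xml2::xml_attr(rnodes, "id")
  network_model(mets, rxns, default_bound = default_bound)
}

tsv_triplet_paths <- function(path) {
  stem <- sub("_(metabolites|reactions|stoich)\\.tsv$", "", path)
  list(metabolites = paste0(stem, "_metabolites.tsv"),
       reactions = paste0(stem, "_reactions.tsv"),
       stoich = paste0(stem, "_stoich.tsv"))
}

load_model_tsv <- function(path, default_bound) {
  p <- tsv_triplet_paths(path)
  mets <- read_tsv_strict(p$metabolites, c("id", "name", "compartment"))
  rx <- read_tsv_strict(p$reactions, c("id", "lower_bound", "upper_bound", "weight"))
  st <- read_tsv_strict(p$stoich, c("reaction_id", "metabolite_id", "coefficient"))
  if (anyDuplicated(rx$id))
    abort_validation(sprintf("%s: duplicate reaction id(s): %s", p$reactions,
                             paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")))
  bad <- setdiff(st$reaction_id, rx$id)
  if (length(bad) > 0)
    abort_validation(sprintf("%s: stoichiometry for undeclared reaction(s): %s",
                             p$stoich, paste(unique(bad), collapse = ", ")))
  rxns <- lapply(rx$id, function(rid) {
    rows <- st[st$reaction_id == rid, , drop = FALSE]
    i <- match(rid, rx$id)
    list(stoichiometry = stats::setNames(rows$coefficient, rows$metabolite_id),
         lower_bound = rx$lower_bound[i], upper_bound = rx$upper_bound[i],
         weight = rx$weight[i],
         name = if ("name" %in% names(rx)) rx$name[i] else rid)
  })
  names(rxns) <- rx$id
  network_model(mets, rxns, default_bound = default_bound)
}

#' Save a network model
#'
#' Writes either the TSV triplet dialect (bit-exact round trip) or
#' COBRA-style JSON (round trip to double precision).
#'
#' @param model a `network_model`.
#' @param path output path (TSV: the shared stem; JSON: the file).
#' @param format `"tsv-triplet"` or `"cobra-json"`.
#' @return the path(s) written, invisibly.
#' @export
save_model <- function(model, path, format = c("tsv-triplet", "cobra-json")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "network_model"))
  if (format == "tsv-triplet") {
    p <- tsv_triplet_paths(path)
    write_tsv(model$metabolites[, c("id", "name", "compartment")], p$metabolites)
    rx <- model$reactions[, c("id", "name", "lower_bound", "upper_bound", "weight")]
    write_tsv(rx, p$reactions)
    S <- model$stoichiometry
    idx <- Matrix::which(S != 0, arr.ind = TRUE)
    st <- data.frame(reaction_id = colnames(S)[idx[, 2]],
                     metabolite_id = rownames(S)[idx[, 1]],
                     coefficient = S[idx])
    st <- st[order(match(st$reaction_id, model$reactions$id),
                   match(st$metabolite_id, model$metabolites$id)), ]
    write_tsv(st, p$stoich)
    invisible(unlist(p))
  } else {
    S <- model$stoichiometry
    rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
      nz <- which(S[, j] != 0)
      list(id = model$reactions$id[j], name = model$reactions$name[j],
           metabolites = as.list(stats::setNames(S[nz, j], rownames(S)[nz])),
           lower_bound = model$reactions$lower_bound[j],
           upper_bound = model$reactions$upper_bound[j],
           weight = model$reactions$weight[j])
    })
    mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i], name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])
    })
    doc <- list(metabolites = mets, reactions = rxns,
                compartments = as.list(stats::setNames(model$compartments,
                                                       model$compartments)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
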