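#' Read a genome-scale metabolic model
#'
#' Parses a constraint-based model from COBRA JSON or SBML Level 3 (with
#' the `fbc` flux-bound/objective extension) into a [metabolic_model()].
#' Bounds and objective coefficients are preserved exactly; reaction and
#' metabolite order follow the file.
#'
#' The binary COBRA Toolbox `.mat` dialect is not supported: reading
#' MATLAB files requires a MAT parser which this package deliberately does
#' not bundle. Convert such models to JSON or SBML first.
#'
#' @param path Path to the model file.
#' @param dialect One of `"json"` or `"sbml"`; guessed from the file
#'   extension when missing.
#' @return A [metabolic_model()].
#' @seealso [write_model()]
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml", "mat")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
      json = "json", xml = "sbml", sbml = "sbml", mat = "mat",
      stop("cannot guess model dialect from extension: ", path)
    )
  }
  if (dialect == "mat") {
    stop("the binary COBRA .mat dialect is not supported; ",
         "convert the model to COBRA JSON or SBML L3 FBC")
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(dialect, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @param dialect `"json"` (COBRA JSON) or `"sbml"` (Level 3 + fbc);
#'   guessed from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "json", "sbml")) {
  stopifnot(inherits(model, "metabolic_model"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
      json = "json", xml = "sbml", sbml = "sbml",
      stop("cannot guess model dialect from extension: ", path)
    )
  }
  switch(dialect,
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path)
  )
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed COBRA JSON in ", path, ": ",
                             conditionMessage(e))
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("malformed COBRA JSON: missing 'metabolites' or 'reactions' in ", path)
  }
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed COBRA JSON: metabolite without id")
    m$id
  }, character(1))
  n <- length(doc$reactions)
  m <- length(met_ids)
  S <- matrix(0, m, n)
  rxn_ids <- character(n)
  lb <- ub <- obj <- numeric(n)
  subsys <- gpr <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    if (is.null(r$id)) stop("malformed COBRA JSON: reaction ", j, " without id")
    rxn_ids[j] <- r$id
    lb[j] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[j] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    obj[j] <- if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient
    if (!is.null(r$subsystem) && nzchar(r$subsystem)) subsys[j] <- r$subsystem
    if (!is.null(r$gene_reaction_rule) && nzchar(r$gene_reaction_rule)) {
      gpr[j] <- r$gene_reaction_rule
    }
    for (met in names(r$metabolites)) {
      i <- match(met, met_ids)
      if (is.na(met_i <- i)) {
        stop("malformed COBRA JSON: reaction ", r$id,
             " references unknown metabolite ", met)
      }
      S[met_i, j] <- as.numeric(r$metabolites[[met]])
    }
  }
  metabolic_model(S, met_ids, rxn_ids, lb = lb, ub = ub, objective = obj,
                  subsystem = subsys, gene_rules = gpr,
                  id = if (is.null(doc$id)) "model" else doc$id)
}

write_model_json <- function(model, path) {
  mets <- purrr::map(model$metabolite_ids, function(id) {
    list(id = id, name = id, compartment = "c")
  })
  rxns <- purrr::map(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S[, j] != 0)
    stoich <- as.list(model$S[nz, j])
    names(stoich) <- model$metabolite_ids[nz]
    out <- list(
      id = model$reaction_ids[j],
      name = model$reaction_ids[j],
      metabolites = stoich,
      lower_bound = model$lb[j],
      upper_bound = model$ub[j],
      objective_coefficient = model$objective[j]
    )
    if (!is.na(model$subsystem[j])) out$subsystem <- model$subsystem[j]
    if (!is.na(model$gene_rules[j])) out$gene_reaction_rule <- model$gene_rules[j]
    out
  })
  doc <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = list(), compartments = list(c = "cytosol"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("malformed SBML in ", path, ": ",
                             conditionMessage(e)))
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("malformed SBML: no species found in ", path)
  met_ids <- xml2::xml_attr(sp, "id")
  pars <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("malformed SBML: no reactions found in ", path)
  n <- length(rx)
  m <- length(met_ids)
  S <- matrix(0, m, n)
  rxn_ids <- xml2::xml_attr(rx, "id")
  lb <- ub <- numeric(n)
  rev <- xml2::xml_attr(rx, "reversible") %in% c("true", "1")
  attr_any_ns <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  for (j in seq_len(n)) {
    node <- rx[[j]]
    lbp <- attr_any_ns(node, "lowerFluxBound")
    ubp <- attr_any_ns(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (rev[j]) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    for (ref in xml2::xml_find_all(node, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      i <- match(xml2::xml_attr(ref, "species"), met_ids)
      if (is.na(i)) stop("malformed SBML: reaction ", rxn_ids[j],
                         " references unknown species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      S[i, j] <- S[i, j] - if (is.na(st)) 1 else as.numeric(st)
    }
    for (ref in xml2::xml_find_all(node, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      i <- match(xml2::xml_attr(ref, "species"), met_ids)
      if (is.na(i)) stop("malformed SBML: reaction ", rxn_ids[j],
                         " references unknown species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      S[i, j] <- S[i, j] + if (is.na(st)) 1 else as.numeric(st)
    }
  }
  obj <- rep(0, n)
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  for (node in fo) {
    rid <- attr_any_ns(node, "reaction")
    co <- attr_any_ns(node, "coefficient")
    i <- match(rid, rxn_ids)
    if (!is.na(i)) obj[i] <- as.numeric(co)
  }
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  id <- xml2::xml_attr(mdl, "id")
  metabolic_model(S, met_ids, rxn_ids, lb = lb, ub = ub, objective = obj,
                  reversible = rev, id = if (is.na(id)) "model" else id)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  # element-wise: vector format() pads to a common width, breaking lookups
  num <- function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                 trim = TRUE), character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (id in model$metabolite_ids) {
    w('      <species id="', esc(id),
      '" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  w('    </listOfSpecies>')
  # one shared parameter per distinct bound value
  vals <- sort(unique(c(model$lb, model$ub)))
  pid <- stats::setNames(paste0("par_", seq_along(vals)), num(vals))
  w('    <listOfParameters>')
  for (v in vals) {
    w('      <parameter id="', pid[[num(v)]], '" value="', num(v),
      '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (j in seq_along(model$reaction_ids)) {
    w('      <reaction id="', esc(model$reaction_ids[j]), '" reversible="',
      tolower(model$reversible[j]), '" fast="false" fbc:lowerFluxBound="',
      pid[[num(model$lb[j])]], '" fbc:upperFluxBound="',
      pid[[num(model$ub[j])]], '">')
    sub <- which(model$S[, j] < 0)
    prod <- which(model$S[, j] > 0)
    if (length(sub)) {
      w('        <listOfReactants>')
      for (i in sub) {
        w('          <speciesReference species="', esc(model$metabolite_ids[i]),
          '" stoichiometry="', num(-model$S[i, j]), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (i in prod) {
        w('          <speciesReference species="', esc(model$metabolite_ids[i]),
          '" stoichiometry="', num(model$S[i, j]), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  nz <- which(model$objective != 0)
  if (length(nz)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (j in nz) {
      w('          <fbc:fluxObjective fbc:reaction="',
        esc(model$reaction_ids[j]), '" fbc:coefficient="',
        num(model$objective[j]), '"/>')
    }
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
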