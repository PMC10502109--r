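#' Construct a genome-scale metabolic model
#'
#' The central container of the package: a stoichiometric matrix together
#' with per-reaction flux bounds, reversibility flags and an objective
#' vector. Column order is the reaction order and row order the metabolite
#' order; both are stable across I/O round trips.
#'
#' A reaction is flagged reversible if and only if its lower bound is
#' negative (the convention used by the BIGG model collection). Missing
#' bounds default to +/-1000 mmol/gDW/h.
#'
#' @param S Numeric matrix, metabolites x reactions (stoichiometric
#'   coefficients; negative = consumed, positive = produced).
#' @param metabolite_ids,reaction_ids Character vectors naming the rows and
#'   columns of `S`.
#' @param lb,ub Numeric vectors of lower/upper flux bounds (mmol/gDW/h);
#'   recycled defaults are `-1000 * reversible` and `1000`.
#' @param objective Numeric vector of objective coefficients (usually a
#'   single 1 on the biomass reaction).
#' @param reversible Logical vector; defaults to `lb < 0`.
#' @param subsystem,gene_rules Optional character vectors of per-reaction
#'   pathway labels and gene-association strings (stored, never evaluated).
#' @param id Model identifier string.
#'
#' @return An object of class `metabolic_model`.
#' @export
#' @examples
#' m <- metabolic_model(
#'   S = matrix(c(1, -1, 0, 0, 1, -1), 2, 3),
#'   metabolite_ids = c("A", "B"),
#'   reaction_ids = c("EX_A", "R1", "DM_B"),
#'   lb = c(0, 0, 0), ub = c(5, 1000, 1000),
#'   objective = c(0, 0, 1)
#' )
#' n_reactions(m)
metabolic_model <- function(S, metabolite_ids, reaction_ids,
                            lb = NULL, ub = NULL, objective = NULL,
                            reversible = NULL, subsystem = NULL,
                            gene_rules = NULL, id = "model") {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(length(metabolite_ids) == m, length(reaction_ids) == n)
  if (anyDuplicated(reaction_ids)) stop("duplicated reaction ids")
  if (anyDuplicated(metabolite_ids)) stop("duplicated metabolite ids")
  if (is.null(ub)) ub <- rep(1000, n)
  if (is.null(lb)) {
    lb <- if (is.null(reversible)) rep(0, n) else ifelse(reversible, -1000, 0)
  }
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound for reaction(s): ",
                         paste(reaction_ids[lb > ub], collapse = ", "))
  if (is.null(objective)) objective <- rep(0, n)
  objective <- rep_len(as.numeric(objective), n)
  if (is.null(reversible)) reversible <- lb < 0
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(
    list(
      id = id,
      metabolite_ids = as.character(metabolite_ids),
      reaction_ids = as.character(reaction_ids),
      S = S, lb = lb, ub = ub,
      objective = objective,
      reversible = as.logical(rep_len(reversible, n)),
      subsystem = if (is.null(subsystem)) rep(NA_character_, n) else
        as.character(rep_len(subsystem, n)),
      gene_rules = if (is.null(gene_rules)) rep(NA_character_, n) else
        as.character(rep_len(gene_rules, n))
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", nrow(x$S), " metabolites x ", ncol(x$S), " reactions (",
      sum(x$reversible), " reversible)\n", sep = "")
  obj <- which(x$objective != 0)
  if (length(obj)) {
    cat("  objective:", paste(x$reaction_ids[obj], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname metabolic_model
#' @param model A `metabolic_model`.
#' @export
n_reactions <- function(model) length(model$reaction_ids)

#' @rdname metabolic_model
#' @export
n_metabolites <- function(model) length(model$metabolite_ids)

#' Objective reaction index of a model
#'
#' Resolves the objective column: an explicit reaction id, or the column
#' with a nonzero objective coefficient.
#' @param model A `metabolic_model` or `decoupled_model`.
#' @param objective Optional reaction id overriding the stored objective.
#' @return Integer column index.
#' @keywords internal
objective_index <- function(model, objective = NULL) {
  ids <- if (inherits(model, "decoupled_model")) model$col_ids else model$reaction_ids
  if (!is.null(objective)) {
    i <- match(objective, ids)
    if (is.na(i)) stop("objective reaction not found: ", objective)
    return(i)
  }
  nz <- which(model$objective != 0)
  if (!length(nz)) stop("model declares no objective; pass `objective=`")
  nz
}

#' Reaction table of a model
#'
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: id, bounds, reversibility,
#'   objective coefficient and subsystem.
#' @export
tidy.metabolic_model <- function(x, ...) {
  tibble::tibble(
    reaction_id = x$reaction_ids,
    lb = x$lb, ub = x$ub,
    reversible = x$reversible,
    objective = x$objective,
    subsystem = x$subsystem
  )
}

#' One-row summary of a model
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @export
glance.metabolic_model <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_metabolites = nrow(x$S),
    n_reactions = ncol(x$S),
    n_reversible = sum(x$reversible),
    n_nonzero = sum(x$S != 0)
  )
}
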