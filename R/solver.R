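#' Flux balance analysis
#'
#' Maximizes the objective over the steady-state flux polytope
#' `S v = 0, lb <= v <= ub`. Works on an original [metabolic_model()] and
#' on a [decoupled_model][assemble_decoupled_model()]; in the decoupled
#' case the solution is also recovered to element-reaction space.
#'
#' @param model A `metabolic_model` or `decoupled_model`.
#' @param objective Optional reaction/column id overriding the stored
#'   objective.
#' @param extra_ge Optional list `(A, b)` of additional linear rows
#'   `A v >= b` over the model's columns (used internally for kinetic
#'   constraints and optimum-fixing).
#' @return A `flux_solution`: fields `status`, `objective`, `flux`
#'   (tibble over solved columns), and for decoupled models
#'   `element_flux` (tibble over original reactions).
#' @export
#' @examples
#' net <- synth_network(cycle_lengths = 3, n_chain = 2, seed = 1)
#' sol <- solve_fba(net$model)
#' sol$objective
solve_fba <- function(model, objective = NULL, extra_ge = NULL) {
  prob <- as_lp_data(model, objective)
  res <- solve_lp(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                  A_ge = extra_ge$A, b_ge = extra_ge$b, maximize = TRUE)
  new_flux_solution(res, model, prob)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: fixes the objective at its [solve_fba()] optimum, then
#' minimizes the total absolute flux (L1 norm, split variables). On a
#' decoupled model this is the parsimonious decoupled optimizer.
#'
#' @inheritParams solve_fba
#' @param tol Slack allowed on the fixed optimum (default `1e-9` relative).
#' @return A `flux_solution` with attribute `l1_norm`.
#' @export
solve_pfba <- function(model, objective = NULL, extra_ge = NULL, tol = 1e-9) {
  prob <- as_lp_data(model, objective)
  stage1 <- solve_lp(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                     A_ge = extra_ge$A, b_ge = extra_ge$b, maximize = TRUE)
  if (stage1$status != "optimal") return(new_flux_solution(stage1, model, prob))
  opt <- stage1$objective
  n <- length(prob$obj)
  # vars (vp, vm), v = vp - vm
  S2 <- cbind(prob$S, -prob$S)
  obj2 <- rep(1, 2 * n)
  lo <- rep(0, 2 * n)
  hi <- c(pmax(prob$ub, 0), pmax(-prob$lb, 0))
  slack <- max(tol, abs(opt) * tol)
  A_ge <- rbind(
    c(prob$obj, -prob$obj),        # c'v >= opt - slack
    cbind(diag(n), -diag(n)),      # v >= lb
    cbind(-diag(n), diag(n))       # -v >= -ub
  )
  b_ge <- c(opt - slack, prob$lb, -prob$ub)
  if (!is.null(extra_ge) && length(extra_ge$b)) {
    A_ge <- rbind(A_ge, cbind(extra_ge$A, -extra_ge$A))
    b_ge <- c(b_ge, extra_ge$b)
  }
  res2 <- solve_lp(obj2, S2, rep(0, nrow(S2)), lo, hi,
                   A_ge = A_ge, b_ge = b_ge, maximize = FALSE)
  if (res2$status != "optimal") {
    sol <- new_flux_solution(stage1, model, prob)
    attr(sol, "l1_norm") <- sum(abs(stage1$solution))
    return(sol)
  }
  v <- res2$solution[seq_len(n)] - res2$solution[n + seq_len(n)]
  out <- list(status = "optimal", objective = sum(prob$obj * v), solution = v)
  sol <- new_flux_solution(out, model, prob)
  attr(sol, "l1_norm") <- sum(abs(v))
  sol
}

#' Flux variability analysis
#'
#' Per-column minimum and maximum flux subject to retaining at least
#' `fraction_of_optimum` of the FBA optimum. Two LPs per column.
#'
#' @inheritParams solve_fba
#' @param fraction_of_optimum Fraction in (0, 1] of the optimum to retain
#'   (default 1).
#' @param columns Optional subset of column ids to analyze.
#' @return A tibble with `column_id`, `min_flux`, `max_flux` (class
#'   `fva_result`).
#' @export
run_fva <- function(model, fraction_of_optimum = 1, objective = NULL,
                    columns = NULL, extra_ge = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  prob <- as_lp_data(model, objective)
  base <- solve_lp(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                   A_ge = extra_ge$A, b_ge = extra_ge$b, maximize = TRUE)
  if (base$status != "optimal") {
    stop("FVA: base problem is ", base$status)
  }
  opt <- base$objective
  floor_val <- if (opt >= 0) fraction_of_optimum * opt else opt / fraction_of_optimum
  A_ge <- rbind(extra_ge$A, prob$obj)
  b_ge <- c(extra_ge$b, floor_val)
  ids <- prob$ids
  cols <- if (is.null(columns)) seq_along(ids) else match(columns, ids)
  if (anyNA(cols)) stop("unknown column id in `columns`")
  res <- purrr::map(cols, function(j) {
    e <- rep(0, length(ids)); e[j] <- 1
    lo <- solve_lp(e, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                   A_ge = A_ge, b_ge = b_ge, maximize = FALSE)
    hi <- solve_lp(e, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                   A_ge = A_ge, b_ge = b_ge, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible at fraction ", fraction_of_optimum,
           " for column ", ids[j])
    }
    c(lo$objective, hi$objective)
  })
  out <- tibble::tibble(
    column_id = ids[cols],
    min_flux = purrr::map_dbl(res, 1),
    max_flux = purrr::map_dbl(res, 2)
  )
  class(out) <- c("fva_result", class(out))
  out
}

#' Kinetic-flux-constrained optimization
#'
#' Imposes box constraints `v_kf - delta <= v_j <= v_kf + delta` on
#' selected reactions and solves FBA (or parsimonious FBA). On a decoupled
#' model, a constraint on a coupled element reaction is translated through
#' the cluster basis into a linear row over the LBR columns.
#'
#' @inheritParams solve_fba
#' @param constraints Tibble/data frame with columns `reaction_id`, `v_kf`
#'   and optionally `delta` (default 5 percent of `|v_kf|`).
#' @param parsimonious If `TRUE`, run the two-stage parsimonious optimizer.
#' @return A `flux_solution`.
#' @export
solve_kinetic_fba <- function(model, constraints, objective = NULL,
                              parsimonious = FALSE) {
  constraints <- tibble::as_tibble(constraints)
  stopifnot(all(c("reaction_id", "v_kf") %in% names(constraints)))
  if (!"delta" %in% names(constraints) || all(is.na(constraints$delta))) {
    constraints$delta <- 0.05 * abs(constraints$v_kf)
  }
  if (any(constraints$delta < 0)) stop("negative kinetic tolerance delta")
  prob <- as_lp_data(model, objective)
  n <- length(prob$ids)
  A <- NULL; b <- NULL
  for (i in seq_len(nrow(constraints))) {
    rid <- constraints$reaction_id[i]
    row <- constraint_row(model, prob, rid)
    A <- rbind(A, row, -row)
    b <- c(b, constraints$v_kf[i] - constraints$delta[i],
           -(constraints$v_kf[i] + constraints$delta[i]))
  }
  sol <- if (parsimonious) {
    solve_pfba(model, objective, extra_ge = list(A = A, b = b))
  } else {
    solve_fba(model, objective, extra_ge = list(A = A, b = b))
  }
  if (sol$status == "infeasible") {
    warning("kinetic constraint set infeasible (reactions: ",
            paste(constraints$reaction_id, collapse = ", "), ")")
  }
  sol
}

# linear row over solved columns expressing one original reaction's flux
constraint_row <- function(model, prob, reaction_id) {
  n <- length(prob$ids)
  if (inherits(model, "decoupled_model")) {
    j <- match(reaction_id, prob$ids)
    if (!is.na(j)) {             # non-coupled column
      row <- rep(0, n); row[j] <- 1
      return(row)
    }
    # coupled element reaction: v_j = sum_i N*_ji v_lbr_i
    hit <- model$mapping[model$mapping$element_reaction_id == reaction_id, ]
    if (!nrow(hit)) stop("constraint on unknown reaction: ", reaction_id)
    row <- rep(0, n)
    row[match(hit$lbr_id, prob$ids)] <- hit$coefficient
    row
  } else {
    j <- match(reaction_id, prob$ids)
    if (is.na(j)) stop("constraint on unknown reaction: ", reaction_id)
    row <- rep(0, n); row[j] <- 1
    row
  }
}

# common LP data for both model classes
as_lp_data <- function(model, objective = NULL) {
  if (inherits(model, "decoupled_model")) {
    obj <- model$objective
    if (!is.null(objective)) {
      obj <- rep(0, length(model$col_ids))
      obj[objective_index(model, objective)] <- 1
    } else if (!any(obj != 0)) {
      stop("model declares no objective; pass `objective=`")
    }
    list(S = model$S, lb = model$lb, ub = model$ub, obj = obj,
         ids = model$col_ids, decoupled = TRUE)
  } else if (inherits(model, "metabolic_model")) {
    obj <- model$objective
    if (!is.null(objective)) {
      obj <- rep(0, length(model$reaction_ids))
      obj[objective_index(model, objective)] <- 1
    } else if (!any(obj != 0)) {
      stop("model declares no objective; pass `objective=`")
    }
    list(S = model$S, lb = model$lb, ub = model$ub, obj = obj,
         ids = model$reaction_ids, decoupled = FALSE)
  } else {
    stop("expected a metabolic_model or decoupled_model")
  }
}

new_flux_solution <- function(res, model, prob) {
  flux <- tibble::tibble(column_id = prob$ids, flux = res$solution)
  element <- NULL
  if (res$status == "optimal" && prob$decoupled) {
    element <- recover_element_fluxes(res$solution, model)
  } else if (res$status == "optimal") {
    element <- tibble::tibble(reaction_id = prob$ids, flux = res$solution)
  }
  structure(
    list(status = res$status, objective = res$objective,
         flux = flux, element_flux = element,
         decoupled = prob$decoupled),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective: ", format(x$objective, digits = 8), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Per-reaction fluxes of a solution
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `flux` in original reaction space (for a
#'   decoupled solve, the recovered element fluxes).
#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$element_flux)) {
    return(tibble::tibble(reaction_id = character(), flux = numeric()))
  }
  x$element_flux
}

#' @rdname tidy.flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective = x$objective,
    n_active = if (is.null(x$element_flux)) NA_integer_ else
      sum(abs(x$element_flux$flux) > 1e-6),
    l1_norm = if (is.null(x$element_flux)) NA_real_ else
      sum(abs(x$element_flux$flux))
  )
}

#' Compare predicted against measured fluxes
#'
#' @param predicted Tibble with `reaction_id`, `flux` (e.g.
#'   [tidy.flux_solution()] output).
#' @param measured Tibble with `reaction_id`, `flux` of measured values
#'   (typically from isotope-tracing flux analysis); `NA`s dropped.
#' @param active_tol Absolute flux above which a reaction counts as active
#'   (default `1e-6`).
#' @return One-row tibble: `pearson`, `spearman`, `mse`, `n_shared`,
#'   `n_both_active`.
#' @export
evaluate_predictions <- function(predicted, measured, active_tol = 1e-6) {
  predicted <- tibble::as_tibble(predicted)
  measured <- tibble::as_tibble(measured)
  joined <- dplyr::inner_join(predicted, measured, by = "reaction_id",
                              suffix = c("_pred", "_meas"))
  joined <- joined[stats::complete.cases(joined[, c("flux_pred", "flux_meas")]), ]
  if (nrow(joined) < 3) {
    stop("fewer than 3 shared reactions: correlation metrics undefined")
  }
  tibble::tibble(
    pearson = stats::cor(joined$flux_pred, joined$flux_meas),
    spearman = stats::cor(joined$flux_pred, joined$flux_meas,
                          method = "spearman"),
    mse = mean((joined$flux_pred - joined$flux_meas)^2),
    n_shared = nrow(joined),
    n_both_active = sum(abs(joined$flux_pred) > active_tol &
                          abs(joined$flux_meas) > active_tol)
  )
}

#' Jaccard index of two flux intervals
#'
#' Overlap length divided by union length. Two identical zero-width
#' intervals score 1; disjoint intervals score 0.
#'
#' @param a,b Numeric length-2 vectors `c(min, max)`.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' interval_jaccard(c(0, 2), c(1, 3))  # 1/3
interval_jaccard <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni == 0) {
    return(as.numeric(a[1] == b[1]))
  }
  inter / uni
}

#' Interval agreement between an FVA result and reference intervals
#'
#' @param fva An `fva_result` tibble (`column_id`, `min_flux`, `max_flux`).
#' @param reference Tibble with `column_id` (or `reaction_id`), `min_flux`,
#'   `max_flux`.
#' @return Tibble with per-column `jaccard` plus the inputs.
#' @export
evaluate_fva <- function(fva, reference) {
  reference <- tibble::as_tibble(reference)
  if ("reaction_id" %in% names(reference) && !"column_id" %in% names(reference)) {
    reference <- dplyr::rename(reference, column_id = "reaction_id")
  }
  joined <- dplyr::inner_join(tibble::as_tibble(fva), reference,
                              by = "column_id", suffix = c("", "_ref"))
  joined$jaccard <- purrr::map_dbl(seq_len(nrow(joined)), function(i) {
    interval_jaccard(c(joined$min_flux[i], joined$max_flux[i]),
                     c(joined$min_flux_ref[i], joined$max_flux_ref[i]))
  })
  joined
}
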