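#' Build the stoichiometric submodel of a coupled reaction cluster
#'
#' Restricts the stoichiometric matrix to a cluster's reactions and the
#' metabolites they touch, and appends one artificial exchange column
#' (coefficient -1, reversible, wide bounds) for every metabolite that is
#' also produced or consumed by reactions outside the cluster, so the
#' submodel can carry steady state on its own. The null-space dimension
#' `r_k` is the augmented column count minus the numerical rank (singular
#' values below `1e-9 * sigma_max` treated as zero).
#'
#' @param model A [metabolic_model()].
#' @param cluster Character vector of reaction ids or integer indices.
#' @return An object of class `cluster_submodel` with fields `S` (augmented
#'   submatrix), `lb`, `ub`, `reaction_ids` (cluster reactions then
#'   artificial exchanges), `is_artificial`, `metabolite_ids`, `l_k`, `r_k`,
#'   `rank`, `cluster_idx`.
#' @export
build_cluster_submodel <- function(model, cluster) {
  stopifnot(inherits(model, "metabolic_model"))
  idx <- if (is.character(cluster)) match(cluster, model$reaction_ids) else
    as.integer(cluster)
  if (anyNA(idx) || !length(idx)) stop("cluster reactions not found in model")
  rows <- which(rowSums(model$S[, idx, drop = FALSE] != 0) > 0)
  S_sub <- model$S[rows, idx, drop = FALSE]
  outside <- setdiff(seq_len(ncol(model$S)), idx)
  boundary <- rows[rowSums(model$S[rows, outside, drop = FALSE] != 0) > 0]
  n_art <- length(boundary)
  if (n_art) {
    E <- matrix(0, length(rows), n_art)
    E[cbind(match(boundary, rows), seq_len(n_art))] <- -1
    S_aug <- cbind(S_sub, E)
    art_ids <- paste0("AEX_", model$metabolite_ids[boundary])
  } else {
    S_aug <- S_sub
    art_ids <- character(0)
  }
  lb <- c(model$lb[idx], rep(-1000, n_art))
  ub <- c(model$ub[idx], rep(1000, n_art))
  l_k <- ncol(S_aug)
  sv <- svd(S_aug)$d
  rank <- sum(sv > 1e-9 * max(sv, 0))
  structure(
    list(S = S_aug,
         lb = lb, ub = ub,
         reaction_ids = c(model$reaction_ids[idx], art_ids),
         is_artificial = c(rep(FALSE, length(idx)), rep(TRUE, n_art)),
         metabolite_ids = model$metabolite_ids[rows],
         l_k = l_k, r_k = l_k - rank, rank = rank,
         cluster_idx = idx),
    class = "cluster_submodel"
  )
}

#' @export
print.cluster_submodel <- function(x, ...) {
  cat("<cluster_submodel> ", length(x$cluster_idx), " reactions + ",
      sum(x$is_artificial), " artificial exchanges; r_k = ", x$r_k,
      "\n", sep = "")
  invisible(x)
}

#' Extract a sparse linear basis of a cluster's null space
#'
#' Finds `r_k` minimal-support null-space vectors of the augmented cluster
#' stoichiometry by iterated L1-minimizing linear programs: each vector
#' solves `min sum(x)` subject to `S v = 0`, `-x <= v <= x`,
#' `lb <= v <= ub`, plus a random-projection constraint
#' `|w' P v| >= zeta` that forces linear independence from the vectors
#' already found (`P` projects onto the orthogonal complement of their
#' span). The disjunction is realized as two LP runs (`>= zeta` and
#' `<= -zeta`); when both are feasible the sparser solution is kept, ties
#' going to the positive branch. Columns are rescaled so their largest
#' magnitude is 1 and entries below `1e-7` are truncated to exact zeros.
#'
#' @param sub A [build_cluster_submodel()] result with `r_k >= 1`.
#' @param zeta Independence margin (default `1e-3`).
#' @param seed Seed for the uniform random projection weights (default 17).
#' @return An object of class `sparse_basis`: `N` (`l_k x r_k`), `N_star`
#'   (artificial-exchange rows removed), `support` (list of element
#'   reaction ids per column), `element_ids`, `cluster_idx`.
#' @export
sparsify_nullspace <- function(sub, zeta = 1e-3, seed = 17) {
  stopifnot(inherits(sub, "cluster_submodel"))
  l <- sub$l_k
  r_k <- sub$r_k
  if (r_k < 1) {
    N <- matrix(0, l, 0)
    return(new_sparse_basis(N, sub))
  }
  set.seed(seed)
  xmax <- pmax(abs(sub$lb), abs(sub$ub))
  A_eq <- cbind(sub$S, matrix(0, nrow(sub$S), l))   # vars (v, x)
  b_eq <- rep(0, nrow(sub$S))
  # x - v >= 0 and x + v >= 0
  A_abs <- rbind(cbind(-diag(l), diag(l)), cbind(diag(l), diag(l)))
  b_abs <- rep(0, 2 * l)
  obj <- c(rep(0, l), rep(1, l))
  lo <- c(sub$lb, rep(0, l))
  hi <- c(sub$ub, xmax)
  N <- matrix(0, l, 0)
  for (m_i in seq_len(r_k)) {
    P <- if (ncol(N)) {
      Q <- qr.Q(qr(N))
      diag(l) - Q %*% t(Q)
    } else diag(l)
    w <- stats::runif(l)
    wP <- as.numeric(t(w) %*% P)
    sols <- list()
    for (sgn in c(1, -1)) {
      A_ge <- rbind(A_abs, c(sgn * wP, rep(0, l)))
      b_ge <- c(b_abs, zeta)
      res <- solve_lp(obj, A_eq, b_eq, lo, hi, A_ge = A_ge, b_ge = b_ge,
                      maximize = FALSE)
      if (res$status == "optimal") sols[[length(sols) + 1]] <- res
    }
    if (!length(sols)) {
      stop("sparse-basis extraction failed for cluster (reactions ",
           paste(utils::head(sub$reaction_ids, 3), collapse = ", "),
           " ...): both independence branches infeasible")
    }
    vs <- purrr::map(sols, function(s) clean_basis_column(s$solution[seq_len(l)]))
    nnz <- purrr::map_int(vs, ~ sum(.x != 0))
    v <- vs[[which.min(nnz)]]   # which.min takes first on ties (+ branch)
    N <- cbind(N, v)
  }
  resid <- max(abs(sub$S %*% N))
  scale <- max(abs(sub$S))
  if (resid > 1e-9 * max(1, scale) * 100) {
    warning("sparse basis residual ", format(resid), " above tolerance")
  }
  new_sparse_basis(N, sub)
}

# rescale so max |v| = 1 and truncate numerically-zero entries
clean_basis_column <- function(v, tol = 1e-7) {
  mx <- max(abs(v))
  if (mx == 0) return(v)
  v <- v / mx
  v[abs(v) < tol] <- 0
  v
}

new_sparse_basis <- function(N, sub) {
  colnames(N) <- if (ncol(N)) paste0("SLB", seq_len(ncol(N))) else character(0)
  rownames(N) <- sub$reaction_ids
  N_star <- N[!sub$is_artificial, , drop = FALSE]
  support <- purrr::map(seq_len(ncol(N_star)), function(i) {
    rownames(N_star)[N_star[, i] != 0]
  })
  structure(
    list(N = N, N_star = N_star, support = support,
         element_ids = rownames(N_star), cluster_idx = sub$cluster_idx),
    class = "sparse_basis"
  )
}

#' @export
print.sparse_basis <- function(x, ...) {
  cat("<sparse_basis> ", ncol(x$N), " vectors over ", nrow(x$N_star),
      " element reactions\n", sep = "")
  invisible(x)
}

#' Assemble the decoupled model from cluster bases
#'
#' Replaces each coupled cluster's columns by its linear basis reactions
#' (LBRs): the stoichiometric columns `S[, C_k] %*% N_star_k`, with bounds
#' obtained by intersecting the element-reaction bound intervals divided by
#' the basis coefficients over the support (bounds swap for negative
#' coefficients). Non-coupled reactions and clusters with an empty basis
#' pass through unchanged. The objective is mapped consistently, so the
#' optimum of the decoupled model is comparable with the original.
#'
#' @param model A [metabolic_model()].
#' @param clusters A `reaction_clusters` object (or tibble with
#'   `reaction_id`, `cluster`).
#' @param bases List of [sparsify_nullspace()] results, one per cluster id
#'   in `sort(unique(cluster))`; built automatically when `NULL`.
#' @param zeta,seed Passed to [sparsify_nullspace()] when bases are built
#'   here.
#' @return An object of class `decoupled_model`.
#' @export
#' @examples
#' net <- synth_network(cycle_lengths = c(3, 4), n_chain = 3, seed = 1)
#' dm <- decouple_model(net$model)
#' dm
assemble_decoupled_model <- function(model, clusters, bases = NULL,
                                     zeta = 1e-3, seed = 17) {
  stopifnot(inherits(model, "metabolic_model"))
  tab <- if (inherits(clusters, "reaction_clusters")) clusters$assignment else
    tibble::as_tibble(clusters)
  tab <- tab[match(model$reaction_ids, tab$reaction_id), ]
  if (anyNA(tab$reaction_id)) stop("cluster table does not cover the model")
  kids <- sort(unique(stats::na.omit(tab$cluster)))
  cluster_sets <- purrr::map(kids, function(k) {
    which(!is.na(tab$cluster) & tab$cluster == k)
  })
  if (is.null(bases)) {
    bases <- purrr::map(cluster_sets, function(idx) {
      sparsify_nullspace(build_cluster_submodel(model, idx),
                         zeta = zeta, seed = seed)
    })
  }
  stopifnot(length(bases) == length(cluster_sets))

  nc_idx <- which(is.na(tab$cluster))
  keep <- vapply(bases, function(b) ncol(b$N_star) > 0, logical(1))
  # clusters with r_k = 0 pass through as non-coupled columns
  for (k in which(!keep)) nc_idx <- c(nc_idx, cluster_sets[[k]])
  nc_idx <- sort(nc_idx)
  cluster_sets <- cluster_sets[keep]
  bases <- bases[keep]
  kids <- kids[keep]

  S_cols <- list(model$S[, nc_idx, drop = FALSE])
  lb <- model$lb[nc_idx]
  ub <- model$ub[nc_idx]
  obj <- model$objective[nc_idx]
  col_ids <- model$reaction_ids[nc_idx]
  col_type <- rep("nc", length(nc_idx))
  mapping <- list()

  for (k in seq_along(cluster_sets)) {
    idx <- cluster_sets[[k]]
    Nk <- bases[[k]]$N_star
    # align basis rows to cluster columns
    ord <- match(model$reaction_ids[idx], rownames(Nk))
    if (anyNA(ord)) stop("basis rows do not match cluster reactions")
    Nk <- Nk[ord, , drop = FALSE]
    S_cols[[length(S_cols) + 1]] <- model$S[, idx, drop = FALSE] %*% Nk
    for (i in seq_len(ncol(Nk))) {
      lbr_id <- paste0("LBR_", kids[k], "_", i)
      bounds <- lbr_bounds(Nk[, i], model$lb[idx], model$ub[idx])
      if (bounds[1] > bounds[2] + 1e-12) {
        stop("empty bound interval for ", lbr_id,
             " [", bounds[1], ", ", bounds[2], "]")
      }
      lb <- c(lb, bounds[1]); ub <- c(ub, bounds[2])
      obj <- c(obj, sum(Nk[, i] * model$objective[idx]))
      col_ids <- c(col_ids, lbr_id)
      col_type <- c(col_type, "lbr")
      nz <- which(Nk[, i] != 0)
      mapping[[length(mapping) + 1]] <- tibble::tibble(
        lbr_id = lbr_id, cluster = kids[k],
        element_reaction_id = model$reaction_ids[idx][nz],
        coefficient = Nk[nz, i]
      )
    }
  }
  S_IR <- do.call(cbind, S_cols)
  colnames(S_IR) <- col_ids
  structure(
    list(S = S_IR, lb = lb, ub = ub, objective = obj,
         col_ids = col_ids, col_type = col_type,
         nc_idx = nc_idx, cluster_sets = cluster_sets,
         cluster_ids = kids,
         bases = bases,
         mapping = if (length(mapping)) dplyr::bind_rows(mapping) else
           tibble::tibble(lbr_id = character(), cluster = integer(),
                          element_reaction_id = character(),
                          coefficient = numeric()),
         model = model),
    class = "decoupled_model"
  )
}

# intersect element bound intervals scaled by basis coefficients
lbr_bounds <- function(coefs, lb, ub) {
  nz <- which(coefs != 0)
  if (!length(nz)) return(c(0, 0))
  lows <- ifelse(coefs[nz] > 0, lb[nz] / coefs[nz], ub[nz] / coefs[nz])
  highs <- ifelse(coefs[nz] > 0, ub[nz] / coefs[nz], lb[nz] / coefs[nz])
  c(max(lows), min(highs))
}

#' One-call decoupling pipeline
#'
#' Convenience wrapper chaining [coupling_graph()], [cycle_similarity()],
#' [best_wcut_cluster()] and [assemble_decoupled_model()].
#'
#' @param model A [metabolic_model()].
#' @param max_cycle_len Cycle length cap for [cycle_similarity()].
#' @param k_range,seed,min_size Passed to [best_wcut_cluster()].
#' @param zeta Passed to [sparsify_nullspace()].
#' @return A `decoupled_model`.
#' @export
decouple_model <- function(model, max_cycle_len = 12, k_range = 2:8,
                           seed = 17, min_size = 2, zeta = 1e-3) {
  g <- coupling_graph(model)
  A <- cycle_similarity(g, max_cycle_len = max_cycle_len)
  cl <- best_wcut_cluster(A, k_range = k_range, seed = seed,
                          min_size = min_size)
  assemble_decoupled_model(model, cl, zeta = zeta, seed = seed)
}

#' @export
print.decoupled_model <- function(x, ...) {
  cat("<decoupled_model> ", nrow(x$S), " metabolites x ", ncol(x$S),
      " columns (", sum(x$col_type == "nc"), " non-coupled + ",
      sum(x$col_type == "lbr"), " LBRs from ", length(x$cluster_sets),
      " clusters)\n", sep = "")
  invisible(x)
}

#' @rdname assemble_decoupled_model
#' @param x A `decoupled_model`.
#' @param ... Unused.
#' @export
tidy.decoupled_model <- function(x, ...) {
  tibble::tibble(column_id = x$col_ids, type = x$col_type,
                 lb = x$lb, ub = x$ub, objective = x$objective)
}

#' @rdname assemble_decoupled_model
#' @export
glance.decoupled_model <- function(x, ...) {
  tibble::tibble(n_columns = ncol(x$S),
                 n_noncoupled = sum(x$col_type == "nc"),
                 n_lbr = sum(x$col_type == "lbr"),
                 n_clusters = length(x$cluster_sets))
}

#' Recover element-reaction fluxes from a decoupled solution
#'
#' Maps a flux vector over the decoupled columns back to the original
#' reactions: non-coupled fluxes are copied, coupled fluxes are
#' `N_star %*% v_lbr` per cluster. The result is a steady-state vector of
#' the original stoichiometric matrix.
#'
#' @param solution Numeric vector over the decoupled model's columns (in
#'   `col_ids` order).
#' @param dmodel A `decoupled_model`.
#' @return Tibble with `reaction_id` and `flux` in the original model's
#'   reaction order.
#' @export
recover_element_fluxes <- function(solution, dmodel) {
  stopifnot(inherits(dmodel, "decoupled_model"))
  if (inherits(solution, "flux_solution")) {
    solution <- solution$flux$flux
  }
  if (length(solution) != ncol(dmodel$S)) {
    stop("solution length ", length(solution), " does not match the ",
         ncol(dmodel$S), " decoupled columns")
  }
  v <- rep(0, ncol(dmodel$model$S))
  v[dmodel$nc_idx] <- solution[dmodel$col_type == "nc"]
  pos <- sum(dmodel$col_type == "nc")
  for (k in seq_along(dmodel$cluster_sets)) {
    idx <- dmodel$cluster_sets[[k]]
    Nk <- dmodel$bases[[k]]$N_star
    Nk <- Nk[match(dmodel$model$reaction_ids[idx], rownames(Nk)), ,
             drop = FALSE]
    r_k <- ncol(Nk)
    v[idx] <- as.numeric(Nk %*% solution[pos + seq_len(r_k)])
    pos <- pos + r_k
  }
  tibble::tibble(reaction_id = dmodel$model$reaction_ids, flux = v)
}
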