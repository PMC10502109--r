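#' Bipartite metabolite-reaction coupling graph
#'
#' Builds the directed bipartite graph of a metabolic network: substrate
#' metabolites point into their reaction node, the reaction node points to
#' its product metabolites. A reversible reaction additionally contributes
#' both arcs in the reverse orientation. Arc orientation (forward vs
#' reverse use of a reaction) is recorded so that cycle enumeration can
#' require every reaction on a cycle to be traversed in a single direction.
#'
#' @param model A [metabolic_model()].
#' @return An object of class `coupling_graph` wrapping an [igraph][igraph::graph]
#'   with vertex attributes `kind` (`"met"`/`"rxn"`) and `name`, and edge
#'   attribute `dir` (+1 forward, -1 reverse).
#' @export
#' @examples
#' m <- synth_network(cycle_lengths = 3, n_chain = 0, seed = 1)$model
#' g <- coupling_graph(m)
#' g
coupling_graph <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- nrow(model$S)
  n <- ncol(model$S)
  if (m == 0 || n == 0) stop("empty model")
  from <- integer(0); to <- integer(0); dir <- integer(0)
  for (j in seq_len(n)) {
    rj <- m + j
    sub <- which(model$S[, j] < 0)
    prod <- which(model$S[, j] > 0)
    from <- c(from, sub, rep(rj, length(prod)))
    to <- c(to, rep(rj, length(sub)), prod)
    dir <- c(dir, rep(1L, length(sub) + length(prod)))
    if (model$reversible[j]) {
      from <- c(from, prod, rep(rj, length(sub)))
      to <- c(to, rep(rj, length(prod)), sub)
      dir <- c(dir, rep(-1L, length(sub) + length(prod)))
    }
  }
  g <- igraph::make_empty_graph(n = m + n, directed = TRUE)
  igraph::V(g)$kind <- rep(c("met", "rxn"), c(m, n))
  igraph::V(g)$name <- c(model$metabolite_ids, model$reaction_ids)
  g <- igraph::add_edges(g, rbind(from, to), dir = dir)
  structure(
    list(graph = g, n_met = m, n_rxn = n,
         metabolite_ids = model$metabolite_ids,
         reaction_ids = model$reaction_ids),
    class = "coupling_graph"
  )
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("<coupling_graph> ", x$n_met, " metabolite + ", x$n_rxn,
      " reaction nodes, ", igraph::ecount(x$graph), " arcs\n", sep = "")
  invisible(x)
}

#' Simple-cycle coupling similarity between reactions
#'
#' Counts, for every pair of reaction nodes, the simple directed cycles of
#' the bipartite graph that pass through both, up to `max_cycle_len`
#' reaction nodes per cycle. The count is exhaustive (a bounded
#' Johnson-style backtracking search anchored at the smallest metabolite
#' node of each cycle, so each directed cycle is enumerated exactly once).
#' Cycles that traverse the same reaction in both directions (the trivial
#' back-and-forth through a reversible reaction) are excluded by requiring
#' a consistent orientation at every reaction node.
#'
#' The diagonal entry `A[i, i]` is the number of cycles through reaction
#' `i`; the matrix is symmetric and entrywise nondecreasing in
#' `max_cycle_len`.
#'
#' @param graph A [coupling_graph()].
#' @param max_cycle_len Cap on the number of reaction nodes per cycle
#'   (default 12); must be at least 2 for any off-diagonal count.
#' @return A symmetric integer matrix with reaction ids as dimnames, class
#'   `similarity_matrix`.
#' @export
cycle_similarity <- function(graph, max_cycle_len = 12) {
  stopifnot(inherits(graph, "coupling_graph"))
  if (max_cycle_len < 2) {
    warning("max_cycle_len < 2: no cycle can couple two reactions; ",
            "off-diagonal counts will be zero")
  }
  cycles <- enumerate_cycles(graph, max_cycle_len)
  n <- graph$n_rxn
  A <- matrix(0L, n, n, dimnames = list(graph$reaction_ids, graph$reaction_ids))
  for (rxns in cycles) {
    A[rxns, rxns] <- A[rxns, rxns] + 1L
  }
  class(A) <- c("similarity_matrix", class(A))
  A
}

# Enumerate orientation-consistent simple directed cycles of the bipartite
# graph. Returns a list of integer vectors of reaction indices (1..n_rxn).
# Each cycle is anchored at its minimal metabolite node and hence listed
# exactly once. Pure R backtracking; intended for networks up to a few
# hundred nodes, which covers the coupled substructures this package
# clusters.
enumerate_cycles <- function(graph, max_cycle_len) {
  g <- graph$graph
  m <- graph$n_met
  nv <- m + graph$n_rxn
  el <- igraph::as_edgelist(g, names = FALSE)
  dir <- igraph::E(g)$dir
  # adjacency: per node, matrix of (target, dir)
  adj <- vector("list", nv)
  ord <- order(el[, 1])
  for (idx in ord) {
    f <- el[idx, 1]
    adj[[f]] <- rbind(adj[[f]], c(el[idx, 2], dir[idx]))
  }
  cycles <- list()
  visited <- rep(FALSE, nv)

  # depth-first walk: at a metabolite, step to a reaction and immediately
  # onward to a product metabolite, keeping the reaction's orientation
  # consistent; metabolites below the anchor are forbidden.
  for (start in seq_len(m)) {
    if (is.null(adj[[start]])) next
    path_rxn <- integer(0)

    walk <- function(v_met, n_rxn_used) {
      outs <- adj[[v_met]]
      if (is.null(outs)) return()
      for (a in seq_len(nrow(outs))) {
        r <- outs[a, 1]
        d_in <- outs[a, 2]
        if (visited[r]) next
        if (n_rxn_used + 1L > max_cycle_len) next
        router <- adj[[r]]
        if (is.null(router)) next
        for (b in seq_len(nrow(router))) {
          if (router[b, 2] != d_in) next      # orientation consistency
          nxt <- router[b, 1]
          if (nxt == start) {
            cycles[[length(cycles) + 1L]] <<- c(path_rxn, r - m)
          } else if (nxt > start && nxt <= m && !visited[nxt]) {
            visited[r] <<- TRUE; visited[nxt] <<- TRUE
            path_rxn[length(path_rxn) + 1L] <<- r - m
            walk(nxt, n_rxn_used + 1L)
            path_rxn <<- path_rxn[-length(path_rxn)]
            visited[r] <<- FALSE; visited[nxt] <<- FALSE
          }
        }
      }
    }
    walk(start, 0L)
  }
  cycles
}

#' Generalized weighted cut of a reaction clustering
#'
#' For clusters `C_1..C_K` over the coupled reactions, computes
#' `sum_k Cut(C_k, complement of C_k) / D_k`, where the cut weight is the
#' summed cycle similarity between a cluster and all reactions outside it
#' and `D_k` is the cluster degree (sum of row degrees `D_i` of its
#' members). Zero exactly when no cycle crosses a cluster boundary.
#'
#' @param clusters A `reaction_clusters` object (see [best_wcut_cluster()])
#'   or a tibble/data frame with columns `reaction_id` and `cluster`
#'   (`NA` = non-coupled).
#' @param A Similarity matrix from [cycle_similarity()].
#' @return Nonnegative scalar.
#' @export
wcut <- function(clusters, A) {
  tab <- if (inherits(clusters, "reaction_clusters")) clusters$assignment else
    tibble::as_tibble(clusters)
  stopifnot(all(c("reaction_id", "cluster") %in% names(tab)))
  idx <- match(tab$reaction_id, rownames(A))
  if (anyNA(idx)) stop("reaction ids not found in similarity matrix")
  D <- rowSums(A)
  total <- 0
  for (k in unique(stats::na.omit(tab$cluster))) {
    members <- idx[!is.na(tab$cluster) & tab$cluster == k]
    Dk <- sum(D[members])
    if (Dk == 0) stop("cluster ", k, " has zero cycle weight: WCut undefined")
    cut_k <- sum(A[members, -members, drop = FALSE])
    total <- total + cut_k / Dk
  }
  total
}

#' Cluster coupled reactions by minimizing the weighted cut
#'
#' Reactions with zero total cycle weight are set aside as non-coupled
#' (`cluster = NA`). The remaining reactions are embedded with the top
#' eigenvectors of the symmetrically normalized similarity matrix, grouped
#' by k-means, and the assignment is refined by greedy single-reaction
#' moves that lower the weighted cut. The number of clusters is chosen
#' within `k_range` by minimum [wcut()]; ties are broken toward more
#' clusters, so a disjoint union of cycle blocks is recovered as its blocks
#' rather than merged.
#'
#' @param A Similarity matrix from [cycle_similarity()].
#' @param k_range Integer vector of candidate cluster counts (default
#'   `2:8`).
#' @param seed RNG seed for the k-means starts (default 17).
#' @param min_size Minimum cluster size (default 2); smaller clusters are
#'   merged into their most connected neighbor.
#' @return An object of class `reaction_clusters`: list with `assignment`
#'   (tibble `reaction_id`, `cluster`, `degree`), `wcut`, `K`.
#' @export
best_wcut_cluster <- function(A, k_range = 2:8, seed = 17, min_size = 2) {
  D <- rowSums(A)
  coupled <- which(D > 0)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(A)))
  if (!length(coupled)) {
    warning("no coupled reactions (no cycles): empty clustering")
    out <- tibble::tibble(reaction_id = ids,
                          cluster = NA_integer_, degree = D)
    return(structure(list(assignment = out, wcut = 0, K = 0L),
                     class = "reaction_clusters"))
  }
  Ac <- A[coupled, coupled, drop = FALSE]
  nc <- length(coupled)
  k_range <- k_range[k_range >= 1 & k_range <= floor(nc / max(1, min_size))]
  if (!length(k_range)) k_range <- 1L

  d <- rowSums(Ac)
  Lsym <- Ac / sqrt(d %o% d)
  eig <- eigen(Lsym, symmetric = TRUE)

  best <- NULL
  for (K in sort(k_range)) {
    memb <- if (K == 1 || nc == K) {
      if (nc == K) seq_len(nc) else rep(1L, nc)
    } else {
      emb <- eig$vectors[, seq_len(K), drop = FALSE]
      nrm <- sqrt(rowSums(emb^2)); nrm[nrm == 0] <- 1
      emb <- emb / nrm
      set.seed(seed + K)
      stats::kmeans(emb, centers = K, nstart = 20, iter.max = 100)$cluster
    }
    memb <- enforce_min_size(memb, Ac, min_size)
    memb <- refine_wcut(memb, Ac)
    val <- wcut_memb(memb, Ac)
    Keff <- length(unique(memb))
    if (is.null(best) || val < best$val - 1e-12 ||
        (abs(val - best$val) <= 1e-12 && Keff > best$Keff)) {
      best <- list(memb = memb, val = val, Keff = Keff)
    }
  }
  cluster_full <- rep(NA_integer_, nrow(A))
  cluster_full[coupled] <- match(best$memb, sort(unique(best$memb)))
  structure(
    list(assignment = tibble::tibble(reaction_id = ids,
                                     cluster = cluster_full, degree = D),
         wcut = best$val, K = best$Keff),
    class = "reaction_clusters"
  )
}

# WCut for an integer membership over a coupled-only similarity matrix
wcut_memb <- function(memb, Ac) {
  D <- rowSums(Ac)
  total <- 0
  for (k in unique(memb)) {
    members <- which(memb == k)
    Dk <- sum(D[members])
    if (Dk == 0) next
    total <- total + sum(Ac[members, -members, drop = FALSE]) / Dk
  }
  total
}

# merge clusters below the minimum size into the neighbor with the
# heaviest connecting similarity (fallback: heaviest cluster)
enforce_min_size <- function(memb, Ac, min_size) {
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1) break
    k <- small[1]
    members <- which(memb == k)
    others <- unique(memb[memb != k])
    link <- vapply(others, function(o) {
      sum(Ac[members, memb == o, drop = FALSE])
    }, numeric(1))
    target <- if (any(link > 0)) others[which.max(link)] else others[1]
    memb[members] <- target
  }
  memb
}

# greedy single-node moves lowering WCut; ties keep the incumbent
refine_wcut <- function(memb, Ac, max_pass = 20) {
  if (length(unique(memb)) < 2) return(memb)
  cur <- wcut_memb(memb, Ac)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_along(memb)) {
      for (k in setdiff(unique(memb), memb[i])) {
        if (sum(memb == memb[i]) <= 1) next
        cand <- memb
        cand[i] <- k
        val <- wcut_memb(cand, Ac)
        if (val < cur - 1e-12) {
          memb <- cand
          cur <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  memb
}

#' @export
print.reaction_clusters <- function(x, ...) {
  cat("<reaction_clusters> K = ", x$K, ", WCut = ",
      format(x$wcut, digits = 6), "\n", sep = "")
  cat("  coupled:", sum(!is.na(x$assignment$cluster)),
      " non-coupled:", sum(is.na(x$assignment$cluster)), "\n")
  invisible(x)
}

#' @rdname best_wcut_cluster
#' @param x A `reaction_clusters` object.
#' @param ... Unused.
#' @export
tidy.reaction_clusters <- function(x, ...) x$assignment

#' @rdname best_wcut_cluster
#' @export
glance.reaction_clusters <- function(x, ...) {
  tibble::tibble(K = x$K, wcut = x$wcut,
                 n_coupled = sum(!is.na(x$assignment$cluster)),
                 n_noncoupled = sum(is.na(x$assignment$cluster)))
}
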