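# Independent oracles used by the property-based tests. These deliberately
# use different algorithms from the package implementations.

# Exhaustive cycle-count oracle. Splits every reaction node into a forward
# and a reverse copy (so orientation consistency is structural), then
# enumerates simple cycles with igraph::all_simple_paths anchored at the
# minimal metabolite node of each cycle. Cycles using both copies of one
# reaction (the trivial reversible back-and-forth) are discarded, matching
# the package's definition. Returns the reaction-pair count matrix.
oracle_cycle_similarity <- function(model, max_cycle_len = 12) {
  m <- nrow(model$S)
  n <- ncol(model$S)
  # split-graph nodes: 1..m metabolites, m+j forward copy, m+n+j reverse copy
  from <- integer(0); to <- integer(0)
  for (j in seq_len(n)) {
    sub <- which(model$S[, j] < 0)
    prod <- which(model$S[, j] > 0)
    from <- c(from, sub, rep(m + j, length(prod)))
    to <- c(to, rep(m + j, length(sub)), prod)
    if (model$reversible[j]) {
      from <- c(from, prod, rep(m + n + j, length(sub)))
      to <- c(to, rep(m + n + j, length(prod)), sub)
    }
  }
  g <- igraph::make_empty_graph(n = m + 2 * n, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  A <- matrix(0L, n, n,
              dimnames = list(model$reaction_ids, model$reaction_ids))
  rxn_of <- function(v) ifelse(v <= m, NA_integer_, (v - m - 1) %% n + 1)
  for (s in seq_len(m)) {
    # cycles anchored at s: only metabolites >= s allowed
    drop_met <- seq_len(m)[seq_len(m) < s]
    keep <- setdiff(seq_len(m + 2 * n), drop_met)
    sg <- igraph::induced_subgraph(g, keep)
    old_id <- keep
    s_new <- match(s, old_id)
    preds <- igraph::neighbors(sg, s_new, mode = "in")
    if (!length(preds)) next
    # path length cap: cycle with L reactions alternates met,rxn -> path
    # s .. pred has at most 2L nodes
    paths <- igraph::all_simple_paths(sg, from = s_new, to = preds,
                                      mode = "out",
                                      cutoff = 2 * max_cycle_len)
    for (p in paths) {
      v_old <- old_id[as.integer(p)]
      rx <- rxn_of(v_old)
      rx <- rx[!is.na(rx)]
      if (!length(rx)) next
      if (length(rx) > max_cycle_len) next
      if (anyDuplicated(rx)) next     # both copies of one reaction
      # must close with an edge pred -> s, guaranteed by construction;
      # path must end at a reaction copy (preds of a metabolite are rxns)
      A[rx, rx] <- A[rx, rx] + 1L
    }
  }
  A
}

# Brute-force minimal-support null-space basis: support sizes of a basis
# built by scanning column subsets in increasing size and greedily taking
# linearly independent null vectors. Only for small matrices.
oracle_minimal_support_sizes <- function(S, tol = 1e-9) {
  l <- ncol(S)
  sv <- svd(S)$d
  r_k <- l - sum(sv > tol * max(sv, 0))
  if (r_k == 0) return(integer(0))
  chosen <- matrix(0, l, 0)
  sizes <- integer(0)
  for (size in seq_len(l)) {
    combs <- utils::combn(l, size)
    for (ci in seq_len(ncol(combs))) {
      T_ <- combs[, ci]
      ST <- S[, T_, drop = FALSE]
      dec <- svd(ST, nu = 0, nv = size)
      null_dim <- sum(dec$d < tol * max(dec$d, 1)) + (size - length(dec$d))
      if (size > nrow(ST)) null_dim <- max(null_dim, size - nrow(ST))
      if (null_dim < 1) next
      V <- dec$v[, (size - null_dim + 1):size, drop = FALSE]
      for (vi in seq_len(ncol(V))) {
        v_full <- rep(0, l)
        v_full[T_] <- V[, vi]
        cand <- cbind(chosen, v_full)
        if (qr(cand)$rank == ncol(cand)) {
          chosen <- cand
          sizes <- c(sizes, sum(abs(v_full) > 1e-7))
          if (ncol(chosen) == r_k) return(sort(sizes))
        }
      }
    }
  }
  sort(sizes)
}

# Small random acyclic (cluster-free) toy model: a chain with random side
# branches, one uptake, one objective drain. Always feasible.
acyclic_toy_model <- function(seed) {
  set.seed(seed)
  n_chain <- sample(3:6, 1)
  mets <- paste0("X", seq_len(n_chain))
  rxn <- list()
  add <- function(id, st, lb = 0, ub = 1000, obj = 0) {
    rxn[[length(rxn) + 1]] <<- list(id = id, st = st, lb = lb, ub = ub,
                                    obj = obj)
  }
  up <- stats::runif(1, 2, 10)
  add("EX_up", c(X1 = 1), ub = up)
  for (i in seq_len(n_chain - 1)) {
    add(paste0("CH", i), stats::setNames(c(-1, 1), mets[c(i, i + 1)]),
        ub = stats::runif(1, 5, 20))
  }
  # random side drains (never create cycles)
  for (i in sample(seq_len(n_chain), sample(0:2, 1))) {
    add(paste0("DR", i), stats::setNames(-1, mets[i]),
        ub = stats::runif(1, 0.5, 3))
  }
  add("DM_biomass", stats::setNames(-1, mets[n_chain]), obj = 1)
  ids <- vapply(rxn, function(r) r$id, character(1))
  S <- matrix(0, n_chain, length(rxn), dimnames = list(mets, ids))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$st), j] <- rxn[[j]]$st
  metabolic_model(S, mets, ids,
                  lb = vapply(rxn, function(r) r$lb, numeric(1)),
                  ub = vapply(rxn, function(r) r$ub, numeric(1)),
                  objective = vapply(rxn, function(r) r$obj, numeric(1)),
                  id = paste0("acyclic", seed))
}
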