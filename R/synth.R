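#' Generate a toy metabolic network with planted coupled cycles
#'
#' Builds a feasible toy model consisting of closed reaction cycles (the
#' planted coupled substructures), a linear uptake-to-biomass chain, and
#' optional bridge reactions that let flux pass through a cycle. Every
#' planted cycle is a closed loop `M1 -> M2 -> ... -> M1`, so its
#' stoichiometric block has a one-dimensional null space spanned by the
#' all-ones vector - the ground-truth sparse basis returned alongside the
#' model.
#'
#' @param cycle_lengths Integer vector; one closed cycle per entry
#'   (lengths >= 3). Use `integer(0)` for a chain-only model.
#' @param n_chain Number of internal chain reactions between uptake and
#'   the biomass drain (default 4).
#' @param n_bridge Number of cycles additionally wired into the chain via
#'   an in/out bridge pair (default 0; bridges never create new cycles).
#' @param rev_fraction Fraction of cycle reactions made reversible
#'   (default 0).
#' @param bound Upper flux bound for internal reactions (default 10).
#' @param uptake Uptake bound on the exchange reaction (default 10).
#' @param seed RNG seed (reversibility draws).
#' @return List with `model` (a [metabolic_model()]), and `truth`: list
#'   with `clusters` (list of reaction-id vectors, one per cycle),
#'   `slb_support` (same sets; each cycle's minimal basis support) and
#'   `basis` (the all-ones vector per cycle).
#' @export
#' @examples
#' net <- synth_network(cycle_lengths = c(3, 3), n_chain = 4, seed = 1)
#' net$truth$clusters
synth_network <- function(cycle_lengths = c(3, 4), n_chain = 4,
                          n_bridge = 0, rev_fraction = 0,
                          bound = 10, uptake = 10, seed = 1) {
  if (length(cycle_lengths) && any(cycle_lengths < 3)) {
    stop("cycle lengths must be >= 3")
  }
  if (n_bridge > length(cycle_lengths)) stop("more bridges than cycles")
  if (n_chain < 1) n_chain <- 1
  set.seed(seed)
  mets <- character(0)
  rxns <- list()   # each: list(id, stoich = named vector, lb, ub, obj)
  add_rxn <- function(id, stoich, lb = 0, ub = bound, obj = 0) {
    rxns[[length(rxns) + 1]] <<- list(id = id, stoich = stoich,
                                      lb = lb, ub = ub, obj = obj)
  }
  chain_mets <- paste0("X", seq_len(n_chain))
  mets <- c(mets, chain_mets)
  add_rxn("EX_up", c(X1 = 1), lb = 0, ub = uptake)
  if (n_chain > 1) {
    for (i in seq_len(n_chain - 1)) {
      st <- stats::setNames(c(-1, 1), chain_mets[c(i, i + 1)])
      add_rxn(paste0("CH", i), st, ub = 1000)
    }
  }
  add_rxn("DM_biomass", stats::setNames(-1, chain_mets[n_chain]),
          ub = 1000, obj = 1)

  truth_clusters <- list()
  for (c_i in seq_along(cycle_lengths)) {
    L <- cycle_lengths[c_i]
    cmets <- paste0("C", c_i, "_", seq_len(L))
    mets <- c(mets, cmets)
    ids <- paste0("CYC", c_i, "_", seq_len(L))
    nrev <- round(rev_fraction * L)
    rev_pick <- if (nrev > 0) sample(L, nrev) else integer(0)
    for (i in seq_len(L)) {
      st <- stats::setNames(c(-1, 1), c(cmets[i], cmets[i %% L + 1]))
      lb_i <- if (i %in% rev_pick) -bound else 0
      add_rxn(ids[i], st, lb = lb_i, ub = bound)
    }
    truth_clusters[[c_i]] <- ids
    if (c_i <= n_bridge) {
      # feed the cycle from the chain head and return downstream:
      # X1 -> C_1, C_2 -> X_last; acyclic by construction
      add_rxn(paste0("BRin", c_i),
              stats::setNames(c(-1, 1), c(chain_mets[1], cmets[1])),
              ub = bound)
      add_rxn(paste0("BRout", c_i),
              stats::setNames(c(-1, 1), c(cmets[2], chain_mets[n_chain])),
              ub = bound)
    }
  }
  ids <- vapply(rxns, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, ids))
  for (j in seq_along(rxns)) {
    S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich
  }
  model <- metabolic_model(
    S, mets, ids,
    lb = vapply(rxns, function(r) r$lb, numeric(1)),
    ub = vapply(rxns, function(r) r$ub, numeric(1)),
    objective = vapply(rxns, function(r) r$obj, numeric(1)),
    id = paste0("synth_seed", seed)
  )
  list(model = model,
       truth = list(clusters = truth_clusters,
                    slb_support = truth_clusters,
                    basis = purrr::map(cycle_lengths, ~ rep(1, .x))))
}

#' Generate a random bipartite toy network
#'
#' Random sparse stoichiometry for property testing of the cycle-count
#' machinery: each reaction converts one or two random substrates into one
#' or two random products; a fraction of reactions is reversible.
#'
#' @param n_met,n_rxn Numbers of metabolites and reactions.
#' @param rev_prob Probability a reaction is reversible (default 0.3).
#' @param seed RNG seed.
#' @return A [metabolic_model()] (no objective; topology only).
#' @export
synth_random_network <- function(n_met = 6, n_rxn = 8, rev_prob = 0.3,
                                 seed = 1) {
  set.seed(seed)
  S <- matrix(0, n_met, n_rxn)
  for (j in seq_len(n_rxn)) {
    ns <- sample(1:2, 1)
    np <- sample(1:2, 1)
    subs <- sample(n_met, ns)
    prods <- sample(setdiff(seq_len(n_met), subs), min(np, n_met - ns))
    S[subs, j] <- -1
    S[prods, j] <- 1
  }
  rev <- stats::runif(n_rxn) < rev_prob
  metabolic_model(S, paste0("M", seq_len(n_met)), paste0("R", seq_len(n_rxn)),
                  lb = ifelse(rev, -10, 0), ub = rep(10, n_rxn),
                  id = paste0("rand_seed", seed))
}

#' Generate multi-omics tables from the generative regulation and kinetics
#'
#' Simulates a strain panel from the package's own regulatory model:
#' biomass-constituent (BG) and precursor (PG) metabolite concentrations
#' are log-normal; growth rate follows the multiplicative biomass law
#' `R = lambda * prod_j (1 + M_bj / K_mj)^theta_j`; regulated genes follow
#' the growth-coupled log-linear law
#' `log E = alpha_g * sum_j theta_j log M_bj + b_g + noise` while
#' non-regulated genes are driven by the PG block; and for each kinetic
#' reaction a flux is produced from the full reversible rate law
#' (saturation numerator, thermodynamic term, denominator) evaluated at
#' sampled substrate/product concentrations with `[S] >= K_m`.
#'
#' @param n_strains Number of strains (default 24, a knockout-panel-sized
#'   design).
#' @param n_bg,n_pg Numbers of biomass and precursor metabolites.
#' @param n_genes Total genes; the first `n_regulated` are globally
#'   regulated.
#' @param n_regulated Number of regulated genes.
#' @param noise_sd Gaussian noise SD on log expression and log flux
#'   (default 0.1).
#' @param kinetic_reactions Character vector of reaction ids to simulate
#'   fluxes for (default one, `"VKIN1"`).
#' @param delta_g0 Standard Gibbs energy used for every kinetic reaction
#'   (kJ/mol, default 5).
#' @param seed RNG seed.
#' @return List with `omics` (an [omics_dataset()]) and `truth` (theta,
#'   alpha, regulated gene ids, bg/pg ids, kinetic parameters).
#' @export
synth_omics <- function(n_strains = 24, n_bg = 6, n_pg = 6, n_genes = 20,
                        n_regulated = 8, noise_sd = 0.1,
                        kinetic_reactions = "VKIN1", delta_g0 = 5,
                        seed = 1) {
  set.seed(seed)
  RT <- 8.314462618e-3 * 298.15
  strains <- sprintf("strain%02d", seq_len(n_strains))
  bg_ids <- paste0("BG", seq_len(n_bg))
  pg_ids <- paste0("PG", seq_len(n_pg))
  Mb <- exp(matrix(stats::rnorm(n_strains * n_bg, 1, 0.5), n_strains, n_bg,
                   dimnames = list(strains, bg_ids)))
  Mp <- exp(matrix(stats::rnorm(n_strains * n_pg, 1, 0.5), n_strains, n_pg,
                   dimnames = list(strains, pg_ids)))
  theta <- stats::runif(n_bg, 0.2, 1)
  Km <- exp(stats::rnorm(n_bg, 0.5, 0.3))
  lambda <- 0.5
  growth <- lambda * apply(sweep(1 + sweep(Mb, 2, Km, "/"), 2, theta, "^"),
                           1, prod)
  bio_index <- as.numeric(log(Mb) %*% theta)   # sum_j theta_j log M_bj
  genes <- paste0("g", seq_len(n_genes))
  regulated <- genes[seq_len(n_regulated)]
  alpha <- stats::runif(n_genes, 0.5, 1.5)
  beta <- matrix(stats::runif(n_genes * n_pg, -0.5, 0.5), n_genes, n_pg)
  logE <- matrix(0, n_strains, n_genes, dimnames = list(strains, genes))
  for (g in seq_len(n_genes)) {
    mu <- if (g <= n_regulated) alpha[g] * bio_index else
      as.numeric(log(Mp) %*% beta[g, ])
    logE[, g] <- mu + stats::rnorm(n_strains, 0, noise_sd)
  }
  conc <- cbind(Mb, Mp)
  kin_truth <- list()
  flux_tab <- NULL
  for (r in kinetic_reactions) {
    s_id <- paste0("S_", r)
    p_id <- paste0("P_", r)
    km_s <- exp(stats::rnorm(1, -0.5, 0.2))
    km_p <- exp(stats::rnorm(1, -0.5, 0.2))
    # substrate held above its affinity constant, the regime in which the
    # log-linearization is accurate in central metabolism
    Sc <- km_s * exp(stats::rnorm(n_strains, log(5), 0.5))
    k_eq <- exp(-delta_g0 / RT)
    # products sampled to stay clearly below equilibrium
    ratio <- stats::runif(n_strains, 0.05, 0.5) / k_eq *
      exp(stats::rnorm(n_strains, 0, 0.2))
    ratio <- pmin(ratio, 0.9 / k_eq)
    Pc <- ratio * Sc
    kplus <- 10
    E <- exp(alpha[1] * bio_index)   # catalyzed by the first regulated gene
    v <- (E * kplus) * (Sc / km_s) * (1 - (Pc / Sc) * k_eq) /
      (1 + Sc / km_s + Pc / km_p)
    v <- v * exp(stats::rnorm(n_strains, 0, noise_sd))
    conc <- cbind(conc, stats::setNames(data.frame(Sc, Pc),
                                        c(s_id, p_id)))
    if (is.null(flux_tab)) flux_tab <- tibble::tibble(strain = strains)
    flux_tab[[r]] <- v
    kin_truth[[r]] <- list(km_s = km_s, km_p = km_p, k_eq = k_eq,
                           kplus = kplus, delta_g0 = delta_g0,
                           substrate = s_id, product = p_id)
  }
  omics <- omics_dataset(
    metabolite_conc = dplyr::bind_cols(tibble::tibble(strain = strains),
                                       tibble::as_tibble(as.data.frame(conc))),
    gene_expr = dplyr::bind_cols(tibble::tibble(strain = strains),
                                 tibble::as_tibble(as.data.frame(logE))),
    measured_flux = flux_tab,
    growth_rate = tibble::tibble(strain = strains,
                                 growth_rate = unname(growth))
  )
  list(omics = omics,
       truth = list(theta = theta, alpha = alpha, lambda = lambda,
                    Km = Km, regulated_genes = regulated,
                    bg = bg_ids, pg = pg_ids, kinetics = kin_truth,
                    bio_index = bio_index))
}
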