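test_that("cluster submodel augments boundary metabolites", {
  net <- synth_network(cycle_lengths = 3, n_chain = 3, n_bridge = 1, seed = 1)
  sub <- build_cluster_submodel(net$model, paste0("CYC1_", 1:3))
  # bridge touches C1_1 (in) and C1_2 (out): two artificial exchanges
  expect_equal(sum(sub$is_artificial), 2)
  expect_equal(sub$l_k, 5)
  expect_equal(sub$r_k, sub$l_k - sub$rank)
  # a fully internal cycle needs no artificial exchange
  net2 <- synth_network(cycle_lengths = 3, n_chain = 2, seed = 1)
  sub2 <- build_cluster_submodel(net2$model, paste0("CYC1_", 1:3))
  expect_equal(sum(sub2$is_artificial), 0)
  expect_equal(sub2$r_k, 1)
})

test_that("closed 3-cycle basis is the all-ones vector", {
  net <- synth_network(cycle_lengths = 3, n_chain = 2, seed = 1)
  sub <- build_cluster_submodel(net$model, paste0("CYC1_", 1:3))
  b <- sparsify_nullspace(sub)
  expect_equal(ncol(b$N_star), 1)
  expect_equal(unname(b$N_star[, 1]), c(1, 1, 1))
  expect_equal(sort(b$support[[1]]), paste0("CYC1_", 1:3))
})

test_that("two independent 2-reaction chains give disjoint supports", {
  # S = [[1,-1,0,0],[0,0,1,-1]]: null space dim 2, minimal supports {1,2},{3,4}
  S <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 2, 4, byrow = TRUE)
  m <- metabolic_model(S, c("A", "B"), paste0("R", 1:4),
                       lb = rep(-10, 4), ub = rep(10, 4))
  sub <- build_cluster_submodel(m, 1:4)
  expect_equal(sub$r_k, 2)
  b <- sparsify_nullspace(sub)
  supports <- lapply(b$support, sort)
  expect_setequal(supports, list(c("R1", "R2"), c("R3", "R4")))
  # basis columns scaled to max |v| = 1
  expect_equal(apply(abs(b$N), 2, max), c(SLB1 = 1, SLB2 = 1))
})

test_that("basis columns satisfy the null-space equation", {
  for (sd in 1:4) {
    net <- synth_network(cycle_lengths = 3 + sd %% 3, n_chain = 3,
                         n_bridge = 1, rev_fraction = 0.3, seed = sd)
    sub <- build_cluster_submodel(net$model, net$truth$clusters[[1]])
    b <- sparsify_nullspace(sub)
    expect_lt(max(abs(sub$S %*% b$N)), 1e-9)
    expect_equal(qr(b$N)$rank, sub$r_k)
  }
})

test_that("support sizes match the brute-force minimal-support oracle", {
  set.seed(9)
  for (sd in 1:6) {
    net <- synth_network(cycle_lengths = sample(3:5, 1), n_chain = 3,
                         n_bridge = 1, seed = sd)
    sub <- build_cluster_submodel(net$model, net$truth$clusters[[1]])
    b <- sparsify_nullspace(sub)
    expect_equal(sort(colSums(b$N != 0)),
                 oracle_minimal_support_sizes(sub$S),
                 ignore_attr = TRUE)
  }
})

test_that("LBR bounds intersect element intervals with sign swap", {
  lbr_bounds <- decoupleFBA:::lbr_bounds
  # all-positive coefficients: plain interval intersection after division
  expect_equal(lbr_bounds(c(1, 1, 1), lb = c(0, 0, 0), ub = c(10, 5, 8)),
               c(0, 5))
  # coefficient 2 halves the interval
  expect_equal(lbr_bounds(c(1, 2), lb = c(0, 0), ub = c(10, 5)), c(0, 2.5))
  # negative coefficient swaps the element interval
  expect_equal(lbr_bounds(c(1, -1), lb = c(0, -4), ub = c(10, 0)), c(0, 4))
  # zero coefficients are ignored
  expect_equal(lbr_bounds(c(1, 0), lb = c(-2, 5), ub = c(3, 6)), c(-2, 3))
})

test_that("decoupled model assembly maps stoichiometry and objective", {
  net <- synth_network(cycle_lengths = c(3, 4), n_chain = 4, n_bridge = 1,
                       seed = 1)
  dm <- decouple_model(net$model)
  expect_s3_class(dm, "decoupled_model")
  expect_equal(sum(dm$col_type == "lbr"), 3)  # 1 for C1 (+bridge) + ...
  # every LBR column equals S[, C_k] %*% basis column
  for (i in which(dm$col_type == "lbr")) {
    lbr <- dm$col_ids[i]
    map <- dm$mapping[dm$mapping$lbr_id == lbr, ]
    recon <- net$model$S[, map$element_reaction_id, drop = FALSE] %*%
      map$coefficient
    expect_equal(unname(dm$S[, i]), as.numeric(recon))
  }
  # objective columns map consistently: optimum is preserved
  expect_equal(solve_fba(dm)$objective, solve_fba(net$model)$objective)
  gl <- glance(dm)
  expect_equal(gl$n_lbr + gl$n_noncoupled, ncol(dm$S))
})

test_that("recover_element_fluxes returns a steady-state vector", {
  net <- synth_network(cycle_lengths = c(3, 4), n_chain = 4, n_bridge = 1,
                       rev_fraction = 0.25, seed = 3)
  dm <- decouple_model(net$model)
  sol <- solve_fba(dm)
  expect_equal(sol$status, "optimal")
  v <- recover_element_fluxes(sol, dm)
  expect_equal(v$reaction_id, net$model$reaction_ids)
  expect_lt(max(abs(net$model$S %*% v$flux)), 1e-6)
  # element fluxes respect the original bounds
  expect_true(all(v$flux >= net$model$lb - 1e-6))
  expect_true(all(v$flux <= net$model$ub + 1e-6))
  # length mismatch is caught
  expect_error(recover_element_fluxes(c(1, 2), dm), "does not match")
})

test_that("cluster with r_k = 0 passes through unchanged", {
  # cluster {R1} where metabolite A is internal to the cluster: the
  # augmented submatrix [[-1, 0], [1, -1]] has full column rank, r_k = 0
  S <- rbind(A = c(-1, 0, 0), B = c(1, -1, 0), X = c(0, 1, -1))
  m <- metabolic_model(S, c("A", "B", "X"), c("R1", "R2", "DM"),
                       lb = rep(0, 3), ub = rep(10, 3),
                       objective = c(0, 0, 1))
  fake <- tibble::tibble(reaction_id = c("R1", "R2", "DM"),
                         cluster = c(1L, NA, NA))
  sub <- build_cluster_submodel(m, "R1")
  expect_equal(sub$r_k, 0)
  dm <- assemble_decoupled_model(m, fake)
  expect_equal(sum(dm$col_type == "lbr"), 0)
  expect_equal(ncol(dm$S), n_reactions(m))
  expect_equal(solve_fba(dm)$objective, solve_fba(m)$objective)
})
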