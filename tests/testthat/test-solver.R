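test_that("FBA on the linear chain attains the uptake bound", {
  net <- synth_network(cycle_lengths = integer(0), n_chain = 3, uptake = 5,
                       seed = 1)
  sol <- solve_fba(net$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  td <- tidy(sol)
  expect_equal(td$flux[td$reaction_id == "EX_up"], 5)
  expect_equal(td$flux[td$reaction_id == "DM_biomass"], 5)
})

test_that("objective override and missing objective error", {
  net <- synth_network(cycle_lengths = integer(0), n_chain = 3, uptake = 5,
                       seed = 1)
  sol <- solve_fba(net$model, objective = "EX_up")
  expect_equal(sol$objective, 5)
  m <- synth_random_network(seed = 1)   # no objective declared
  expect_error(solve_fba(m), "no objective")
  expect_error(solve_fba(net$model, objective = "nope"), "not found")
})

test_that("pFBA keeps the optimum and minimizes total flux", {
  # two routes to biomass: direct chain vs a detour through a cycle;
  # pFBA must not use the cycle's internal circulation
  net <- synth_network(cycle_lengths = 3, n_chain = 3, n_bridge = 1, seed = 1)
  fba <- solve_fba(net$model)
  pfba <- solve_pfba(net$model)
  expect_equal(pfba$objective, fba$objective, tolerance = 1e-8)
  expect_lte(attr(pfba, "l1_norm"),
             sum(abs(tidy(fba)$flux)) + 1e-8)
  # internal cycle flux adds L1 without adding objective: must be zero
  td <- tidy(pfba)
  expect_lt(max(abs(td$flux[grepl("^CYC", td$reaction_id)])), 1e-7)
})

test_that("FVA brackets the pFBA point and respects the optimum floor", {
  net <- synth_network(cycle_lengths = 3, n_chain = 3, n_bridge = 1, seed = 1)
  fva <- run_fva(net$model, fraction_of_optimum = 1)
  expect_s3_class(fva, "fva_result")
  expect_true(all(fva$min_flux <= fva$max_flux + 1e-9))
  sol <- tidy(solve_pfba(net$model))
  j <- match(fva$column_id, sol$reaction_id)
  expect_true(all(sol$flux[j] >= fva$min_flux - 1e-6))
  expect_true(all(sol$flux[j] <= fva$max_flux + 1e-6))
  # at full optimum the biomass flux has zero width
  bio <- fva[fva$column_id == "DM_biomass", ]
  expect_equal(bio$min_flux, bio$max_flux, tolerance = 1e-7)
  # relaxing the floor can only widen intervals
  fva90 <- run_fva(net$model, fraction_of_optimum = 0.9)
  expect_true(all(fva90$min_flux <= fva$min_flux + 1e-7))
  expect_true(all(fva90$max_flux >= fva$max_flux - 1e-7))
  expect_error(run_fva(net$model, fraction_of_optimum = 0), "fraction")
})

test_that("decoupled FBA/pFBA/FVA agree with the original model", {
  net <- synth_network(cycle_lengths = c(3, 4), n_chain = 4, n_bridge = 1,
                       seed = 1)
  dm <- decouple_model(net$model)
  expect_equal(solve_fba(dm)$objective, solve_fba(net$model)$objective,
               tolerance = 1e-9)
  p1 <- solve_pfba(net$model)
  p2 <- solve_pfba(dm)
  expect_equal(p2$objective, p1$objective, tolerance = 1e-8)
  # FVA over the biomass column matches
  f1 <- run_fva(net$model, columns = "DM_biomass")
  f2 <- run_fva(dm, columns = "DM_biomass")
  expect_equal(f2$min_flux, f1$min_flux, tolerance = 1e-7)
  expect_equal(f2$max_flux, f1$max_flux, tolerance = 1e-7)
})

test_that("kinetic constraints box the targeted reaction", {
  net <- synth_network(cycle_lengths = c(3, 4), n_chain = 4, n_bridge = 1,
                       seed = 1)
  dm <- decouple_model(net$model)
  kf <- tibble::tibble(reaction_id = "CYC2_1", v_kf = 2, delta = 0.1)
  sol <- solve_kinetic_fba(dm, kf)
  expect_equal(sol$status, "optimal")
  v <- tidy(sol)
  got <- v$flux[v$reaction_id == "CYC2_1"]
  expect_gte(got, 1.9 - 1e-7)
  expect_lte(got, 2.1 + 1e-7)
  # delta = 0 pins the flux exactly
  kf0 <- tibble::tibble(reaction_id = "CYC2_1", v_kf = 3, delta = 0)
  v0 <- tidy(solve_kinetic_fba(dm, kf0))
  expect_equal(v0$flux[v0$reaction_id == "CYC2_1"], 3, tolerance = 1e-7)
  # the same constraint on the element model gives the same objective
  sol_el <- solve_kinetic_fba(net$model, kf)
  expect_equal(sol$objective, sol_el$objective, tolerance = 1e-7)
})

test_that("kinetic constraint validation and infeasibility", {
  net <- synth_network(cycle_lengths = 3, n_chain = 3, seed = 1)
  expect_error(
    solve_kinetic_fba(net$model, tibble::tibble(reaction_id = "EX_up")),
    "v_kf"
  )
  expect_error(
    solve_kinetic_fba(net$model,
                      tibble::tibble(reaction_id = "EX_up", v_kf = 1,
                                     delta = -1)),
    "negative"
  )
  expect_error(
    solve_kinetic_fba(net$model,
                      tibble::tibble(reaction_id = "ghost", v_kf = 1)),
    "unknown reaction"
  )
  # box outside the feasible range: warning + infeasible status
  expect_warning(
    sol <- solve_kinetic_fba(net$model,
                             tibble::tibble(reaction_id = "EX_up",
                                            v_kf = 50, delta = 0.1)),
    "infeasible"
  )
  expect_equal(sol$status, "infeasible")
})

test_that("default kinetic tolerance is 5 percent", {
  net <- synth_network(cycle_lengths = integer(0), n_chain = 3, uptake = 5,
                       seed = 1)
  # v_kf = 4 with default delta: flux constrained to [3.8, 4.2]
  sol <- solve_kinetic_fba(net$model,
                           tibble::tibble(reaction_id = "EX_up", v_kf = 4))
  v <- tidy(sol)
  got <- v$flux[v$reaction_id == "EX_up"]
  expect_gte(got, 3.8 - 1e-7)
  expect_lte(got, 4.2 + 1e-7)
})

test_that("evaluate_predictions computes the agreed metrics", {
  pred <- tibble::tibble(reaction_id = c("a", "b", "c", "d"),
                         flux = c(1, 2, 3, 0))
  meas <- tibble::tibble(reaction_id = c("a", "b", "c", "d"),
                         flux = c(1.1, 1.9, 3.2, 0))
  ev <- evaluate_predictions(pred, meas)
  expect_equal(ev$n_shared, 4)
  expect_equal(ev$n_both_active, 3)
  expect_equal(ev$pearson, stats::cor(pred$flux, meas$flux))
  expect_equal(ev$mse, mean((pred$flux - meas$flux)^2))
  expect_error(
    evaluate_predictions(pred[1:2, ], meas),
    "fewer than 3"
  )
})

test_that("interval Jaccard handles overlap, disjoint and degenerate cases", {
  expect_equal(interval_jaccard(c(0, 2), c(1, 3)), 1 / 3)
  expect_equal(interval_jaccard(c(0, 1), c(2, 3)), 0)
  expect_equal(interval_jaccard(c(1, 1), c(1, 1)), 1)
  expect_equal(interval_jaccard(c(1, 1), c(2, 2)), 0)
  expect_equal(interval_jaccard(c(0, 4), c(0, 4)), 1)
  expect_error(interval_jaccard(c(2, 1), c(0, 1)))
})

test_that("evaluate_fva joins on column ids and scores agreement", {
  net <- synth_network(cycle_lengths = integer(0), n_chain = 3, seed = 1)
  fva <- run_fva(net$model)
  ev <- evaluate_fva(fva, fva)
  expect_true(all(ev$jaccard == 1))
})
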