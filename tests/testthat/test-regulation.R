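test_that("exact linear growth drivers are classified as BG", {
  # half the candidates drive expression and growth exactly; the others
  # are independent noise
  set.seed(21)
  n <- 30
  bg <- paste0("B", 1:3)
  pg <- paste0("P", 1:3)
  logM_bg <- matrix(rnorm(n * 3), n, 3)
  logM_pg <- matrix(rnorm(n * 3), n, 3)
  drive <- rowSums(logM_bg)
  genes <- sapply(runif(8, 0.5, 2), function(a) a * drive)
  colnames(genes) <- paste0("g", 1:8)
  conc <- tibble::tibble(strain = paste0("s", 1:n))
  for (i in 1:3) conc[[bg[i]]] <- exp(logM_bg[, i])
  for (i in 1:3) conc[[pg[i]]] <- exp(logM_pg[, i])
  expr <- dplyr::bind_cols(tibble::tibble(strain = conc$strain),
                           tibble::as_tibble(genes))
  growth <- tibble::tibble(strain = conc$strain, growth_rate = exp(drive))
  om <- omics_dataset(conc, expr, growth_rate = growth)
  grp <- classify_regulators(om, c(bg, pg))
  expect_setequal(grp$bg, bg)
  expect_setequal(grp$pg, pg)
  expect_s3_class(grp$tree, "hclust")
})

test_that("classify_regulators validates inputs and supports bg_hint", {
  so <- synth_omics(n_strains = 12, seed = 2)
  cand <- c(so$truth$bg, so$truth$pg)
  expect_error(classify_regulators(so$omics, "BG1"), "at least 2")
  expect_error(classify_regulators(so$omics, c("BG1", "nope")), "not in")
  # strip growth rates: labeling needs a hint
  om <- omics_dataset(so$omics$metabolite_conc, so$omics$gene_expr)
  expect_error(classify_regulators(om, cand), "bg_hint")
  grp <- classify_regulators(om, cand, bg_hint = so$truth$bg[1])
  expect_true(so$truth$bg[1] %in% grp$bg)
})

test_that("PLSR reproduces an exact linear relationship with r = 1", {
  set.seed(3)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  B <- matrix(c(1, -2, 0.5, 0.3, 1, -1), 3, 2)
  Y <- X %*% B
  colnames(Y) <- c("gA", "gB")
  fit <- fit_plsr(X, Y = Y, n_components = 3)
  expect_equal(fit$per_gene$r_total, c(1, 1), tolerance = 1e-8)
})

test_that("PLSR on pure noise gives weak correlations", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- matrix(rnorm(n * 6), n, 6)
  fit <- fit_plsr(X, Y = Y, n_components = 1)
  expect_lt(max(abs(fit$per_gene$r_total)), 0.5)
  expect_lt(mean(abs(fit$per_gene$r_total)), 0.3)
})

test_that("gene selection is monotone in both thresholds", {
  so <- synth_omics(n_strains = 24, seed = 5)
  fit <- fit_plsr(so$omics, metabolites = so$truth$bg)
  grid <- seq(0, 1, by = 0.2)
  prev <- Inf
  for (t in grid) {
    sel <- select_regulated_genes(fit, r_total_min = t, r_pc1_min = 0)
    expect_lte(length(sel), prev)
    prev <- length(sel)
  }
  prev <- Inf
  for (t in grid) {
    sel <- select_regulated_genes(fit, r_total_min = 0, r_pc1_min = t)
    expect_lte(length(sel), prev)
    prev <- length(sel)
  }
  # impossible thresholds yield the empty set
  expect_length(select_regulated_genes(fit, 1.1, 1.1), 0)
})

test_that("kinetic design matrix matches its generative definition", {
  so <- synth_omics(n_strains = 12, seed = 6)
  kin <- so$truth$kinetics$VKIN1
  des <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                              bg = so$truth$bg, delta_g0 = kin$delta_g0)
  conc <- so$omics$metabolite_conc
  keep <- match(des$strain, conc$strain)
  S <- conc[[kin$substrate]][keep]
  P <- conc[[kin$product]][keep]
  RT <- 8.314462618e-3 * 298.15
  k_eq <- exp(-kin$delta_g0 / RT)
  expect_equal(attr(des, "k_eq"), k_eq, tolerance = 1e-12)
  expect_equal(des$saturation, unname(log(1 - (P / S) * k_eq)),
               tolerance = 1e-12)
  expect_equal(des$mass_action, unname((P / S) / k_eq), tolerance = 1e-12)
  for (b in so$truth$bg) {
    expect_equal(des[[paste0("log_", b)]], unname(log(conc[[b]][keep])),
                 tolerance = 1e-12)
  }
  # activator adds a reciprocal column
  des2 <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                               bg = so$truth$bg, activators = "PG1",
                               k_eq = k_eq)
  expect_equal(des2$inv_PG1,
               unname(1 / conc$PG1[match(des2$strain, conc$strain)]),
               tolerance = 1e-12)
  # thermodynamic constant is mandatory
  expect_error(
    build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                         bg = so$truth$bg),
    "delta_g0 or k_eq"
  )
})

test_that("strains at or beyond equilibrium are excluded and reported", {
  conc <- tibble::tibble(strain = c("s1", "s2", "s3", "s4"),
                         S_R = c(1, 1, 1, 1),
                         P_R = c(0.1, 0.2, 5, 0.3),
                         BG1 = c(1, 2, 3, 4))
  expr <- tibble::tibble(strain = conc$strain, g1 = 1:4)
  om <- omics_dataset(conc, expr)
  # k_eq = 1: strain s3 has P/S = 5 -> saturation argument negative
  des <- build_kinetic_design(om, "R", "S_R", "P_R", bg = "BG1", k_eq = 1)
  expect_equal(attr(des, "excluded"), "s3")
  expect_equal(des$strain, c("s1", "s2", "s4"))
})

test_that("noise-free linearized kinetics is recovered exactly", {
  # generate log flux exactly from the linear model, check coefficients
  set.seed(7)
  so <- synth_omics(n_strains = 30, noise_sd = 0, seed = 7)
  kin <- so$truth$kinetics$VKIN1
  des <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                              bg = so$truth$bg, delta_g0 = kin$delta_g0)
  terms <- setdiff(names(des), "strain")
  X <- as.matrix(des[, terms])
  beta <- c(0.4, stats::runif(length(terms), -0.5, 0.5))
  logv <- as.numeric(cbind(1, X) %*% beta)
  flux <- tibble::tibble(strain = des$strain, flux = exp(logv))
  fit <- fit_linear_kinetics(des, flux)
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-8)
  expect_equal(fit$r_train, 1, tolerance = 1e-9)
  expect_equal(fit$r_test, 1, tolerance = 1e-9)
  pred <- predict_kinetic_flux(fit, des)
  expect_equal(pred$v_kf, flux$flux, tolerance = 1e-8)
  expect_equal(pred$delta, 0.05 * abs(pred$v_kf), tolerance = 1e-12)
})

test_that("linearization fits the full nonlinear rate law well", {
  so <- synth_omics(n_strains = 60, noise_sd = 0.05, seed = 8)
  kin <- so$truth$kinetics$VKIN1
  des <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                              bg = so$truth$bg, delta_g0 = kin$delta_g0)
  flux <- so$omics$measured_flux
  fit <- fit_linear_kinetics(des, tibble::tibble(strain = flux$strain,
                                                 flux = flux$VKIN1))
  expect_gt(fit$r_train, 0.95)
  expect_gt(fit$r_test, 0.9)
})

test_that("nonpositive fluxes are excluded; tiny panels fall back to ridge", {
  so <- synth_omics(n_strains = 24, seed = 9)
  kin <- so$truth$kinetics$VKIN1
  des <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                              bg = so$truth$bg[1:2], delta_g0 = kin$delta_g0)
  flux <- tibble::tibble(strain = des$strain,
                         flux = c(-1, rep(2, nrow(des) - 1)))
  fit <- fit_linear_kinetics(des, flux)
  expect_equal(fit$excluded_strains, des$strain[1])
  # 5 strains, 4 regressors + intercept -> ridge fallback with warning
  expect_warning(
    fit2 <- fit_linear_kinetics(des[1:5, ], flux[1:5, ]),
    "ridge"
  )
  expect_true(fit2$ridge)
})

test_that("sampling significance: planted selection is significant", {
  so <- synth_omics(n_strains = 24, seed = 2)
  cand <- c(so$truth$bg, so$truth$pg)
  sig <- sampling_significance(so$omics, so$truth$bg, cand, n_draws = 300,
                               genes = so$truth$regulated_genes, seed = 1)
  expect_lte(sig$p_value, 0.01)
  expect_length(sig$null, 300)
  expect_error(
    sampling_significance(so$omics, "not_a_candidate", cand, n_draws = 100),
    "candidate pool"
  )
  expect_warning(
    sampling_significance(so$omics, so$truth$bg[1:3], cand, n_draws = 50,
                          genes = so$truth$regulated_genes, seed = 1),
    "coarse"
  )
})

test_that("tidy/glance methods for regulation fits", {
  so <- synth_omics(n_strains = 12, seed = 10)
  fit <- fit_plsr(so$omics, metabolites = so$truth$bg, n_components = 2)
  expect_named(tidy(fit), c("gene", "r_total", "r_pc1"))
  expect_equal(glance(fit)$n_components, 2)
  kin <- so$truth$kinetics$VKIN1
  des <- build_kinetic_design(so$omics, "VKIN1", kin$substrate, kin$product,
                              bg = so$truth$bg, delta_g0 = kin$delta_g0)
  flux <- so$omics$measured_flux
  kfit <- suppressWarnings(
    fit_linear_kinetics(des, tibble::tibble(strain = flux$strain,
                                            flux = flux$VKIN1))
  )
  expect_named(tidy(kfit), c("term", "estimate"))
  expect_equal(glance(kfit)$reaction, "VKIN1")
})
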