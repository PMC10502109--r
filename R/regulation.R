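#' Split candidate regulator metabolites into biomass and precursor groups
#'
#' Candidate metabolites are clustered (average-linkage hierarchical
#' clustering, Euclidean distance) on their pattern of correlation with
#' the gene-expression block across strains, and cut into two groups. The
#' group whose concentrations correlate more strongly (in absolute mean)
#' with the growth rate is labeled the biomass-constituent group (BG), the
#' other the precursor/regulator group (PG). Without growth rates the
#' labeling follows `bg_hint` (a metabolite known to be in BG).
#'
#' @param omics An [omics_dataset()].
#' @param candidates Character vector of candidate metabolite ids (columns
#'   of the concentration block).
#' @param bg_hint Optional metabolite id anchoring the BG label when no
#'   growth rates are available.
#' @return List with `bg`, `pg` (character vectors) and `tree` (the
#'   [hclust][stats::hclust] object).
#' @export
classify_regulators <- function(omics, candidates, bg_hint = NULL) {
  stopifnot(inherits(omics, "omics_dataset"))
  if (length(candidates) < 2) stop("need at least 2 candidate metabolites")
  conc <- omics_matrix(omics$metabolite_conc)
  missing <- setdiff(candidates, colnames(conc))
  if (length(missing)) {
    stop("candidate metabolite(s) not in concentration table: ",
         paste(missing, collapse = ", "))
  }
  expr <- omics_matrix(omics$gene_expr)
  logc <- apply(conc[, candidates, drop = FALSE], 2, log_floor)
  # profile of each metabolite = correlations with every gene; Euclidean
  # distance between profiles keeps the magnitude signal (growth-coupled
  # metabolites have uniformly strong gene correlations, precursors weak
  # ones), which per-profile rescaling would erase
  prof <- stats::cor(logc, expr)
  d <- stats::dist(prof)
  tree <- stats::hclust(d, method = "average")
  grp <- stats::cutree(tree, k = 2)
  g1 <- candidates[grp == 1]
  g2 <- candidates[grp == 2]
  if (!is.null(omics$growth_rate)) {
    gr <- log_floor(omics$growth_rate$growth_rate)
    sc1 <- mean(abs(stats::cor(logc[, g1, drop = FALSE], gr)))
    sc2 <- mean(abs(stats::cor(logc[, g2, drop = FALSE], gr)))
    if (sc1 >= sc2) list(bg = g1, pg = g2, tree = tree)
    else list(bg = g2, pg = g1, tree = tree)
  } else if (!is.null(bg_hint)) {
    if (bg_hint %in% g1) list(bg = g1, pg = g2, tree = tree)
    else list(bg = g2, pg = g1, tree = tree)
  } else {
    stop("no growth rates and no bg_hint: cannot label the two clusters")
  }
}

#' Partial least squares regression of expression on concentrations
#'
#' Fits a covariance-maximizing bilinear decomposition (`X = T P' + E`,
#' `Y = U Q' + F`) of log metabolite concentrations against log gene
#' expression, and reports for each gene the correlation between fitted
#' and observed expression (total regression correlation) and the
#' correlation achieved by the first component alone.
#'
#' The number of components defaults to the value maximizing leave-one-out
#' predictive R-squared (capped at `max_components`).
#'
#' @param omics An [omics_dataset()], or a numeric strain-by-metabolite
#'   matrix `X`.
#' @param metabolites Metabolite columns to use as predictors (default all).
#' @param genes Gene columns to model (default all).
#' @param n_components Fixed component count; `NULL` picks by LOO.
#' @param max_components Upper cap when selecting (default 8).
#' @param Y When `omics` is a matrix: the response matrix.
#' @return An object of class `plsr_fit` with `per_gene` tibble (columns
#'   `gene`, `r_total`, `r_pc1`), `n_components`, and the underlying
#'   mixOmics fit.
#' @export
fit_plsr <- function(omics, metabolites = NULL, genes = NULL,
                     n_components = NULL, max_components = 8, Y = NULL) {
  if (inherits(omics, "omics_dataset")) {
    X <- apply(omics_matrix(omics$metabolite_conc), 2, log_floor)
    Yy <- omics_matrix(omics$gene_expr)
    if (!is.null(metabolites)) X <- X[, metabolites, drop = FALSE]
    if (!is.null(genes)) Yy <- Yy[, genes, drop = FALSE]
  } else {
    X <- as.matrix(omics)
    if (is.null(Y)) stop("supply Y when passing a predictor matrix")
    Yy <- as.matrix(Y)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(colnames(Yy))) colnames(Yy) <- paste0("y", seq_len(ncol(Yy)))
  }
  n <- nrow(X)
  if (n < 3) stop("need at least 3 strains for PLSR")
  if (ncol(X) < 3) {
    stop("need at least 3 predictor metabolites for PLSR (got ", ncol(X), ")")
  }
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance predictor column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  cap <- min(max_components, n - 2, ncol(X))
  cap <- max(cap, 1)
  ncomp <- n_components
  if (!is.null(ncomp) && ncomp > cap) {
    warning("n_components reduced to ", cap, " (rank limit)")
    ncomp <- cap
  }
  if (is.null(ncomp)) ncomp <- choose_ncomp_loo(X, Yy, cap)
  fit <- mixOmics::pls(X, Yy, ncomp = ncomp, mode = "regression")
  pred <- stats::predict(fit, X)$predict
  per_gene <- tibble::tibble(
    gene = colnames(Yy),
    r_total = vapply(seq_len(ncol(Yy)), function(g) {
      suppressWarnings(stats::cor(pred[, g, ncomp], Yy[, g]))
    }, numeric(1)),
    r_pc1 = vapply(seq_len(ncol(Yy)), function(g) {
      suppressWarnings(stats::cor(pred[, g, 1], Yy[, g]))
    }, numeric(1))
  )
  structure(
    list(fit = fit, per_gene = per_gene, n_components = ncomp,
         X = X, Y = Yy),
    class = "plsr_fit"
  )
}

# leave-one-out predictive R^2 over candidate component counts
choose_ncomp_loo <- function(X, Y, cap) {
  n <- nrow(X)
  press <- matrix(0, n, cap)
  for (i in seq_len(n)) {
    f <- mixOmics::pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                       ncomp = cap, mode = "regression")
    p <- stats::predict(f, X[i, , drop = FALSE])$predict
    for (k in seq_len(cap)) {
      press[i, k] <- sum((p[1, , k] - Y[i, ])^2)
    }
  }
  which.min(colSums(press))
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("<plsr_fit> ", nrow(x$X), " strains, ", ncol(x$X), " metabolites -> ",
      ncol(x$Y), " genes, ", x$n_components, " components\n", sep = "")
  invisible(x)
}

#' @rdname fit_plsr
#' @param x A `plsr_fit`.
#' @param ... Unused.
#' @export
tidy.plsr_fit <- function(x, ...) x$per_gene

#' @rdname fit_plsr
#' @export
glance.plsr_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_genes = ncol(x$Y), n_metabolites = ncol(x$X),
                 mean_r_total = mean(x$per_gene$r_total))
}

#' Select globally regulated genes from a PLSR fit
#'
#' A gene is selected when its total regression correlation and its
#' first-component correlation both exceed their thresholds. The defaults
#' (0.84 and 0.38) are the stringent combined cutoffs used for the
#' 24-strain knockout panel analysis.
#'
#' @param fit A [fit_plsr()] result.
#' @param r_total_min Threshold on the total regression correlation
#'   (default 0.84).
#' @param r_pc1_min Threshold on the first-component correlation
#'   (default 0.38).
#' @return Character vector of gene ids.
#' @export
select_regulated_genes <- function(fit, r_total_min = 0.84, r_pc1_min = 0.38) {
  stopifnot(inherits(fit, "plsr_fit"))
  with(fit$per_gene, gene[r_total > r_total_min & r_pc1 > r_pc1_min])
}

#' Random-subset significance of a regulator selection
#'
#' Empirical one-sided test: the observed statistic is the mean per-gene
#' correlation between PLSR-predicted and measured expression using the
#' selected metabolites as predictors; the null draws random same-size
#' subsets from the candidate pool and recomputes it. The p-value is
#' `(1 + #{draws >= observed}) / (n_draws + 1)`.
#'
#' @param omics An [omics_dataset()].
#' @param selected Character vector of selected metabolite ids.
#' @param candidates Candidate pool (superset of `selected`).
#' @param n_draws Number of random subsets (default 10000).
#' @param n_components PLSR components for every fit (default 2).
#' @param genes Optional gene subset over which the statistic is averaged
#'   (typically the regulated genes the metabolites were selected for;
#'   default all genes).
#' @param seed RNG seed.
#' @return List with `p_value`, `observed`, `null` (numeric vector of null
#'   statistics).
#' @export
sampling_significance <- function(omics, selected, candidates,
                                  n_draws = 10000, n_components = 2,
                                  genes = NULL, seed = 1) {
  stopifnot(inherits(omics, "omics_dataset"))
  if (!all(selected %in% candidates)) {
    stop("selected metabolites must come from the candidate pool")
  }
  if (n_draws < 100) warning("n_draws < 100: p-value will be coarse")
  set.seed(seed)
  stat <- function(mets) {
    f <- fit_plsr(omics, metabolites = mets, genes = genes,
                  n_components = min(n_components, length(mets)))
    mean(f$per_gene$r_total)
  }
  observed <- stat(selected)
  k <- length(selected)
  null <- vapply(seq_len(n_draws), function(i) {
    stat(sample(candidates, k))
  }, numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (n_draws + 1),
       observed = observed, null = null)
}

#' Design matrix for the linearized reversible kinetic model
#'
#' Builds, per strain, the regressors of the log-linearized reversible
#' rate law: the log concentrations of the biomass-constituent metabolites
#' (carrying the growth-coupled enzyme-expression term), the saturation
#' term `log(1 - ([P]/[S]) * exp(-dG0/RT))`, the mass-action ratio
#' `([P]/[S]) / k_eq`, and one reciprocal term `1/[A]` per activator.
#' Strains where the saturation argument is not positive (at or beyond
#' equilibrium) are excluded and reported in the `excluded` attribute.
#'
#' @param omics An [omics_dataset()].
#' @param reaction Reaction id (used to label predictions).
#' @param substrate,product Metabolite ids of the substrate and product
#'   concentration columns.
#' @param bg Character vector of biomass-constituent metabolite ids.
#' @param activators Optional activator metabolite ids.
#' @param delta_g0 Standard reaction Gibbs energy (kJ/mol); equivalently
#'   supply `k_eq`.
#' @param k_eq Equilibrium constant; computed from `delta_g0` when absent.
#' @param temperature Temperature in K (default 298.15; RT = 2.4789
#'   kJ/mol).
#' @return A tibble (one row per retained strain) with attributes
#'   `excluded` (strain ids) and `reaction`.
#' @export
build_kinetic_design <- function(omics, reaction, substrate, product,
                                 bg, activators = character(),
                                 delta_g0 = NULL, k_eq = NULL,
                                 temperature = 298.15) {
  stopifnot(inherits(omics, "omics_dataset"))
  RT <- 8.314462618e-3 * temperature
  if (is.null(k_eq)) {
    if (is.null(delta_g0)) stop("supply delta_g0 or k_eq for reaction ", reaction)
    k_eq <- exp(-delta_g0 / RT)
  }
  conc <- omics_matrix(omics$metabolite_conc)
  need <- c(substrate, product, bg, activators)
  missing <- setdiff(need, colnames(conc))
  if (length(missing)) {
    stop("metabolite(s) missing from concentration table: ",
         paste(missing, collapse = ", "))
  }
  S <- unname(conc[, substrate])
  P <- unname(conc[, product])
  ratio <- ifelse(S > 0, P / S, Inf)
  sat_arg <- 1 - ratio * k_eq
  keep <- is.finite(sat_arg) & sat_arg > 0 & S > 0
  excluded <- omics$strains[!keep]
  des <- tibble::tibble(strain = omics$strains[keep])
  for (b in bg) des[[paste0("log_", b)]] <- unname(log_floor(conc[keep, b]))
  des$saturation <- log(sat_arg[keep])
  des$mass_action <- ratio[keep] / k_eq
  for (a in activators) des[[paste0("inv_", a)]] <- unname(1 / conc[keep, a])
  attr(des, "excluded") <- excluded
  attr(des, "reaction") <- reaction
  attr(des, "k_eq") <- k_eq
  des
}

#' Fit the linearized kinetic flux model
#'
#' Ordinary least squares of log flux on the kinetic design matrix with a
#' train/test split. Strains with nonpositive flux (incompatible with the
#' log transform) are excluded and reported. When the training set is
#' smaller than twice the number of regressors, a small ridge penalty is
#' used instead, with a warning.
#'
#' @param design A [build_kinetic_design()] tibble.
#' @param flux Tibble with `strain` and `flux` columns (measured fluxes,
#'   mmol/gDW/h) or a named numeric vector.
#' @param split Training fraction (default 0.8).
#' @param seed RNG seed for the split.
#' @return An object of class `kinetic_fit` with coefficients, train/test
#'   correlations and the training design ranges.
#' @export
fit_linear_kinetics <- function(design, flux, split = 0.8, seed = 1) {
  if (!is.data.frame(flux)) {
    flux <- tibble::tibble(strain = names(flux), flux = as.numeric(flux))
  }
  dat <- dplyr::inner_join(tibble::as_tibble(design), flux, by = "strain")
  bad <- dat$strain[!is.finite(dat$flux) | dat$flux <= 0]
  dat <- dat[is.finite(dat$flux) & dat$flux > 0, ]
  if (nrow(dat) < 2) stop("need at least 2 strains with positive flux")
  dat$log_flux <- log(dat$flux)
  set.seed(seed)
  n <- nrow(dat)
  n_train <- max(2, round(split * n))
  train_idx <- sort(sample(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  terms <- setdiff(names(dat), c("strain", "flux", "log_flux"))
  Xtr <- as.matrix(dat[train_idx, terms])
  ytr <- dat$log_flux[train_idx]
  p <- ncol(Xtr) + 1
  ridge <- n_train < 2 * p
  if (ridge) {
    warning("training set smaller than twice the regressor count: ",
            "falling back to ridge regression")
    Xd <- cbind(1, Xtr)
    lambda <- 1e-3
    beta <- solve(crossprod(Xd) + lambda * diag(p), crossprod(Xd, ytr))
    coefs <- stats::setNames(as.numeric(beta), c("(Intercept)", terms))
  } else {
    fitlm <- stats::lm.fit(cbind(`(Intercept)` = 1, Xtr), ytr)
    coefs <- fitlm$coefficients
    coefs[is.na(coefs)] <- 0
  }
  predict_log <- function(idx) {
    X <- cbind(1, as.matrix(dat[idx, terms]))
    as.numeric(X %*% coefs)
  }
  r_train <- suppressWarnings(stats::cor(predict_log(train_idx), ytr))
  r_test <- if (length(test_idx) >= 3) {
    suppressWarnings(stats::cor(predict_log(test_idx),
                                dat$log_flux[test_idx]))
  } else NA_real_
  structure(
    list(coefficients = coefs, terms = terms,
         r_train = r_train, r_test = r_test,
         reaction = attr(design, "reaction"),
         excluded_strains = bad,
         train_strains = dat$strain[train_idx],
         test_strains = dat$strain[test_idx],
         ridge = ridge,
         train_range = apply(as.matrix(dat[train_idx, terms]), 2, range)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> ", if (!is.null(x$reaction)) x$reaction else "",
      "  r_train = ", format(x$r_train, digits = 3),
      ", r_test = ", format(x$r_test, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_linear_kinetics
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @rdname fit_linear_kinetics
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(reaction = x$reaction %||% NA_character_,
                 r_train = x$r_train, r_test = x$r_test,
                 n_train = length(x$train_strains),
                 n_test = length(x$test_strains),
                 ridge = x$ridge)
}

#' Predict kinetic fluxes for new strains
#'
#' Evaluates the fitted linearized rate law on a design matrix and
#' exponentiates back to flux units, attaching the tolerance used by
#' [solve_kinetic_fba()]. Strains whose regressors fall beyond ten times
#' the training range are flagged as extrapolations.
#'
#' @param fit A [fit_linear_kinetics()] result.
#' @param design A [build_kinetic_design()] tibble for the strains to
#'   predict.
#' @param delta Kinetic tolerance; default 5 percent of each predicted
#'   flux.
#' @return Tibble `reaction_id`, `strain`, `v_kf`, `delta`, `extrapolated`.
#' @export
predict_kinetic_flux <- function(fit, design, delta = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  des <- tibble::as_tibble(design)
  X <- as.matrix(des[, fit$terms])
  v <- exp(as.numeric(cbind(1, X) %*% fit$coefficients))
  extrap <- vapply(seq_len(nrow(X)), function(i) {
    any(abs(X[i, ]) > 10 * pmax(abs(fit$train_range[1, ]),
                                abs(fit$train_range[2, ])))
  }, logical(1))
  if (any(extrap)) {
    warning("prediction(s) beyond 10x the training concentration range")
  }
  if (is.null(delta)) delta <- 0.05 * abs(v)
  tibble::tibble(
    reaction_id = fit$reaction %||% NA_character_,
    strain = des$strain,
    v_kf = v,
    delta = rep_len(delta, length(v)),
    extrapolated = extrap
  )
}
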