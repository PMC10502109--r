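#' Run the full decoupling pipeline from a configuration file
#'
#' Chains the pipeline stages - model loading (or synthetic generation),
#' cycle-similarity clustering, sparse-basis decoupling, flux solving and,
#' when omics tables are configured, regulator classification, PLSR gene
#' selection and kinetic-constrained solving - and writes the stage
#' outputs plus a JSON run manifest (config digest, seeds, package
#' version, timestamps) into `out_dir`. Re-running with an identical
#' configuration reproduces the deterministic outputs bit-exactly.
#'
#' The YAML configuration supports:
#' \describe{
#'   \item{model}{path to a model file, or `synthetic: true` with
#'     `cycle_lengths`, `n_chain`, `n_bridge`.}
#'   \item{cluster}{`max_cycle_len`, `k_min`, `k_max`, `min_size`.}
#'   \item{decompose}{`zeta`.}
#'   \item{solve}{`method` (fba, pfba, fva), `fraction_of_optimum`.}
#'   \item{omics}{paths `metabolite_file`, `expression_file`, optional
#'     `flux_file`, `growth_file`; `candidates`; thresholds `r_total`,
#'     `r_pc1`.}
#'   \item{seed}{global seed.}
#' }
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.
#' @param out_dir Output directory (default `"pipeline_out"`).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = "pipeline_out") {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop("configuration invalid:\n  - ", paste(errs, collapse = "\n  - "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 17
  t0 <- Sys.time()

  # stage: model
  model <- if (isTRUE(cfg$model$synthetic)) {
    synth_network(
      cycle_lengths = unlist(cfg$model$cycle_lengths) %||% c(3, 4),
      n_chain = cfg$model$n_chain %||% 4,
      n_bridge = cfg$model$n_bridge %||% 0,
      seed = seed
    )$model
  } else {
    read_model(cfg$model$path)
  }

  # stage: cluster
  g <- coupling_graph(model)
  A <- cycle_similarity(g, max_cycle_len = cfg$cluster$max_cycle_len %||% 12)
  k_range <- seq(cfg$cluster$k_min %||% 2, cfg$cluster$k_max %||% 8)
  clusters <- best_wcut_cluster(A, k_range = k_range, seed = seed,
                                min_size = cfg$cluster$min_size %||% 2)
  readr::write_tsv(clusters$assignment, file.path(out_dir, "clusters.tsv"))
  message("clustering: K = ", clusters$K, ", WCut = ",
          format(clusters$wcut, digits = 6))

  # stage: decompose
  dmodel <- assemble_decoupled_model(model, clusters,
                                     zeta = cfg$decompose$zeta %||% 1e-3,
                                     seed = seed)
  readr::write_tsv(dmodel$mapping, file.path(out_dir, "lbr_mapping.tsv"))
  message("decoupling: ", sum(dmodel$col_type == "lbr"), " LBRs")

  # stage: solve
  method <- cfg$solve$method %||% "fba"
  sol <- switch(method,
    fba = solve_fba(dmodel),
    pfba = solve_pfba(dmodel),
    fva = NULL,
    stop("unknown solve method: ", method)
  )
  if (method == "fva") {
    fva <- run_fva(dmodel,
                   fraction_of_optimum = cfg$solve$fraction_of_optimum %||% 1)
    readr::write_tsv(fva, file.path(out_dir, "fva.tsv"))
  } else {
    if (sol$status != "optimal") stop("LP stage failed: status ", sol$status)
    readr::write_tsv(tidy(sol), file.path(out_dir, "fluxes.tsv"))
    message("solve (", method, "): objective = ",
            format(sol$objective, digits = 8))
  }

  regulation <- NULL
  if (!is.null(cfg$omics)) {
    omics <- read_omics(cfg$omics$metabolite_file, cfg$omics$expression_file,
                        cfg$omics$flux_file, cfg$omics$growth_file)
    groups <- classify_regulators(omics, unlist(cfg$omics$candidates))
    plsr <- fit_plsr(omics, metabolites = groups$bg)
    genes <- select_regulated_genes(plsr,
                                    r_total_min = cfg$omics$r_total %||% 0.84,
                                    r_pc1_min = cfg$omics$r_pc1 %||% 0.38)
    readr::write_tsv(tidy(plsr), file.path(out_dir, "plsr_genes.tsv"))
    writeLines(genes, file.path(out_dir, "regulated_genes.txt"))
    regulation <- list(groups = groups, plsr = plsr, genes = genes)
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("decoupleFBA")),
    seed = seed,
    config_digest = unname(config_digest(cfg)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(
      cluster = list(K = clusters$K, wcut = clusters$wcut),
      decompose = list(n_lbr = sum(dmodel$col_type == "lbr")),
      solve = list(method = method,
                   objective = if (!is.null(sol)) sol$objective else NA)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, clusters = clusters, dmodel = dmodel,
                 solution = sol, regulation = regulation,
                 manifest = manifest))
}

validate_config <- function(cfg) {
  errs <- character(0)
  if (!is.list(cfg)) return("configuration must be a list / YAML mapping")
  if (is.null(cfg$model)) {
    errs <- c(errs, "missing 'model' section")
  } else if (!isTRUE(cfg$model$synthetic)) {
    if (is.null(cfg$model$path)) {
      errs <- c(errs, "model: need 'path' or 'synthetic: true'")
    } else if (!file.exists(cfg$model$path)) {
      errs <- c(errs, paste0("model path does not exist: ", cfg$model$path))
    }
  }
  if (!is.null(cfg$solve$method) &&
      !cfg$solve$method %in% c("fba", "pfba", "fva")) {
    errs <- c(errs, paste0("unknown solve method: ", cfg$solve$method))
  }
  if (!is.null(cfg$omics)) {
    for (f in c("metabolite_file", "expression_file")) {
      if (is.null(cfg$omics[[f]])) {
        errs <- c(errs, paste0("omics: missing ", f))
      }
    }
  }
  errs
}

# stable digest of the configuration (serialization-based, no extra deps)
config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  as.character(tools::md5sum(tmp))
}
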