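#' Assemble a multi-strain omics dataset
#'
#' Aligns metabolite-concentration, gene-expression, measured-flux and
#' growth-rate tables on a shared `strain` key. All blocks are stored as
#' tibbles in a common strain order; missing blocks stay `NULL` and missing
#' entries stay `NA` (never silently zeroed).
#'
#' @param metabolite_conc Data frame with a `strain` column and one column
#'   per metabolite (concentrations, strictly positive where observed).
#' @param gene_expr Data frame with a `strain` column and one column per
#'   gene (expression; a log scale is permitted).
#' @param measured_flux Optional data frame, `strain` column plus one column
#'   per reaction (mmol/gDW/h, `NA` allowed).
#' @param growth_rate Optional data frame with columns `strain` and
#'   `growth_rate` (1/h).
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(metabolite_conc, gene_expr,
                          measured_flux = NULL, growth_rate = NULL) {
  blocks <- list(metabolite_conc = metabolite_conc, gene_expr = gene_expr,
                 measured_flux = measured_flux, growth_rate = growth_rate)
  blocks <- purrr::compact(blocks)
  blocks <- purrr::map(blocks, function(b) {
    b <- tibble::as_tibble(b)
    if (!"strain" %in% names(b)) stop("every omics table needs a 'strain' column")
    b$strain <- as.character(b$strain)
    b
  })
  strains <- Reduce(intersect, purrr::map(blocks, "strain"))
  if (!length(strains)) stop("omics tables share no strains: alignment failed")
  for (nm in names(blocks)) {
    extra <- setdiff(blocks[[nm]]$strain, strains)
    if (length(extra)) {
      stop("strain(s) in '", nm, "' absent from other blocks: ",
           paste(extra, collapse = ", "))
    }
  }
  blocks <- purrr::map(blocks, function(b) b[match(strains, b$strain), ])
  conc <- blocks$metabolite_conc
  num <- dplyr::select(conc, -"strain")
  if (any(num < 0, na.rm = TRUE)) {
    stop("negative metabolite concentrations are not allowed before log transform")
  }
  structure(
    list(
      strains = strains,
      metabolite_conc = conc,
      gene_expr = blocks$gene_expr,
      measured_flux = blocks$measured_flux,
      growth_rate = blocks$growth_rate
    ),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("<omics_dataset> ", length(x$strains), " strains\n", sep = "")
  cat("  metabolites:", ncol(x$metabolite_conc) - 1,
      " genes:", ncol(x$gene_expr) - 1, "\n")
  if (!is.null(x$measured_flux)) {
    cat("  measured fluxes:", ncol(x$measured_flux) - 1, "reactions\n")
  }
  if (!is.null(x$growth_rate)) cat("  growth rates present\n")
  invisible(x)
}

#' Read omics tables from delimited text files
#'
#' @param metabolite_file,expression_file Paths to delimited tables with a
#'   `strain` column (concentrations, expression).
#' @param flux_file,growth_file Optional paths for measured fluxes and
#'   growth rates.
#' @param delim Field delimiter (default `","`).
#' @return An [omics_dataset()].
#' @export
read_omics <- function(metabolite_file, expression_file,
                       flux_file = NULL, growth_file = NULL, delim = ",") {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    readr::read_delim(p, delim = delim, show_col_types = FALSE, progress = FALSE)
  }
  omics_dataset(rd(metabolite_file), rd(expression_file),
                rd(flux_file), rd(growth_file))
}

#' Write an omics dataset as delimited text files
#'
#' Writes one CSV per block (`metabolite_conc.csv`, `gene_expr.csv`, and
#' when present `measured_flux.csv`, `growth_rate.csv`) into `dir`.
#'
#' @param omics An [omics_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_omics <- function(omics, dir) {
  stopifnot(inherits(omics, "omics_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("metabolite_conc", "gene_expr", "measured_flux", "growth_rate")) {
    if (!is.null(omics[[nm]])) {
      readr::write_csv(omics[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  invisible(dir)
}

# strain x variable numeric matrix from a block, strains as rownames
omics_matrix <- function(block) {
  m <- as.matrix(dplyr::select(block, -"strain"))
  rownames(m) <- block$strain
  storage.mode(m) <- "double"
  m
}

# log with flooring of zeros at half the smallest positive observed value
log_floor <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (!length(pos)) stop("no positive values to log-transform")
  floor_val <- min(pos) / 2
  x[is.finite(x) & x <= 0] <- floor_val
  log(x)
}
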