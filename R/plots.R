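#' Plot the largest fluxes of a solution
#'
#' @param object A `flux_solution`.
#' @param n_top Number of reactions shown (by absolute flux, default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_solution <- function(object, n_top = 20, ...) {
  dat <- tidy(object)
  dat <- dplyr::slice_max(dat, abs(.data$flux), n = n_top, with_ties = FALSE)
  dat$reaction_id <- stats::reorder(dat$reaction_id, abs(dat$flux))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$flux, y = .data$reaction_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot flux variability intervals
#'
#' @param object An `fva_result` tibble.
#' @param ... Unused.
#' @return A ggplot object showing each column's `[min, max]` interval.
#' @export
autoplot.fva_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$column_id <- stats::reorder(dat$column_id,
                                  dat$max_flux - dat$min_flux)
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$column_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_flux,
                                       xend = .data$max_flux,
                                       yend = .data$column_id)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$min_flux), size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$max_flux), size = 1) +
    ggplot2::labs(x = "flux range (mmol/gDW/h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster sizes of a weighted-cut clustering
#'
#' @param object A `reaction_clusters` object.
#' @param ... Unused.
#' @return A ggplot bar chart of cluster sizes (non-coupled shown as NC).
#' @export
autoplot.reaction_clusters <- function(object, ...) {
  dat <- object$assignment
  dat$label <- ifelse(is.na(dat$cluster), "NC", paste0("C", dat$cluster))
  counts <- dplyr::count(dat, .data$label)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "reactions") +
    ggplot2::theme_minimal()
}

#' Observed vs fitted expression for a PLSR fit
#'
#' @param object A `plsr_fit`.
#' @param ... Unused.
#' @return A ggplot of per-gene total and first-component correlations.
#' @export
autoplot.plsr_fit <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$per_gene, c("r_total", "r_pc1"),
                             names_to = "metric", values_to = "r")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, fill = .data$metric)) +
    ggplot2::geom_histogram(bins = 20, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "correlation", y = "genes") +
    ggplot2::theme_minimal()
}
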