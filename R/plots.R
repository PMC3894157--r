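# ggplot2 views of the main result types.

#' Plot raw growth curves
#'
#' @param reads Long tibble `time_h`, `well`, `od`.
#' @param map Optional plate map (`well`, `strain`) used to colour wells.
#' @return A ggplot object (OD vs time, one line per well).
#' @export
plot_growth_curves <- function(reads, map = NULL) {
  reads <- as_tibble(reads)
  if (!is.null(map)) {
    reads <- left_join(reads, as_tibble(map)[, c("well", "strain")],
                       by = "well")
  } else {
    reads$strain <- "well"
  }
  ggplot2::ggplot(reads, ggplot2::aes(x = .data$time_h, y = .data$od,
                                      group = .data$well,
                                      colour = .data$strain)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (h)", y = "OD600", colour = NULL)
}

#' Heatmap of the phenotype matrix
#'
#' Strains (rows, ordered by amino acid / family) against condition x
#' parameter columns; cell colour is the sigma score, lethal cells drawn
#' black and missing cells grey.
#'
#' @param object A `phenotype_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot phenotype_matrix
autoplot.phenotype_matrix <- function(object, ...) {
  m <- as_tibble(object) |>
    mutate(col = paste(.data$condition, .data$parameter, sep = "\n"),
           strain = factor(.data$strain, levels = rev(unique(.data$strain))))
  lim <- max(abs(m$sigma), 3, na.rm = TRUE)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$col, y = .data$strain)) +
    ggplot2::geom_tile(data = dplyr::filter(m, .data$status == "scored"),
                       ggplot2::aes(fill = .data$sigma)) +
    ggplot2::geom_tile(data = dplyr::filter(m, .data$status == "lethal"),
                       fill = "black") +
    ggplot2::geom_tile(data = dplyr::filter(m, .data$status == "missing"),
                       fill = "grey70") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim), oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "sigma")
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Epistasis estimates with error bars
#'
#' @param object An `epistasis_fit`.
#' @param ... Unused.
#' @return A ggplot object: epsilon per pair, mean with t-based 95% CI.
#' @exportS3Method ggplot2::autoplot epistasis_fit
autoplot.epistasis_fit <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(pair = paste(.data$gene_a, .data$gene_b, sep = " : "))
  aes_fill <- if ("parameter" %in% names(d)) {
    ggplot2::aes(fill = .data$parameter)
  } else {
    NULL
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$epsilon))
  p <- if (is.null(aes_fill)) {
    p + ggplot2::geom_col(position = "dodge")
  } else {
    p + ggplot2::geom_col(aes_fill, position = "dodge")
  }
  p +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi,
                                        group = if ("parameter" %in% names(d))
                                          .data$parameter else 1),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "epistasis (epsilon)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Windowed motif-scan profile
#'
#' @param object A `motif_scan`.
#' @param ... Unused.
#' @return A ggplot object: log10 E-value of the best motif per window
#'   start.
#' @exportS3Method ggplot2::autoplot motif_scan
autoplot.motif_scan <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$available,
                     is.finite(.data$log10_e))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start, y = .data$log10_e)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = log10(0.05), linetype = 2) +
    ggplot2::labs(x = "window start (bp upstream of position 0)",
                  y = "log10 E-value of best motif")
}

#' Element-enrichment heat map
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object: -log10 hypergeometric p per element x class.
#' @exportS3Method ggplot2::autoplot enrichment_result
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$element_id, y = .data$gene_class,
                               fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(x = "element", y = "phenotype class",
                  fill = "-log10 p")
}
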