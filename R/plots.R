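#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` tibble.
#' @param fc_min,adjp_max Thresholds used to color DEG status (defaults
#'   match the MAQC-style filter).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, fc_min = 1.25, adjp_max = 0.05, ...) {
  df <- mutate(as_tibble(object),
               status = dplyr::case_when(
                 .data$adj_p < adjp_max & 2^.data$log2FC > fc_min ~ "up",
                 .data$adj_p < adjp_max & 2^.data$log2FC < 1 / fc_min ~ "down",
                 TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC, -log10(.data$adj_p),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(adjp_max), linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = paste("Contrast", attr(object, "contrast") %||% ""))
}

#' Disease-versus-treatment signature scatter
#'
#' Plots each shared gene's treatment score against its disease score; a
#' cloud falling along the negative diagonal is the visual face of
#' signature reversal.
#'
#' @param disease,treatment `signature_tbl` tibbles.
#' @return A ggplot object.
#' @export
plot_reversal <- function(disease, treatment) {
  shared <- intersect(disease$gene_id, treatment$gene_id)
  df <- tibble(
    disease = disease$score[match(shared, disease$gene_id)],
    treatment = treatment$score[match(shared, treatment$gene_id)])
  cs <- cosine_reversal(disease, treatment)
  ggplot2::ggplot(df, ggplot2::aes(.data$disease, .data$treatment)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "disease score (moderated t)",
                  y = "treatment score (moderated t)",
                  title = sprintf("cosine = %.3f over %d genes",
                                  cs$cosine, cs$n_shared))
}

#' Bar chart of normalized enrichment scores
#'
#' @param object An `enrichment_result` tibble.
#' @param alpha FDR threshold used for the fill color.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- filter(as_tibble(object), .data$testable)
  df <- mutate(df, signif = .data$adj_p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$set, .data$nes),
                                   .data$nes, fill = .data$signif)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = paste("adj p <", alpha)) +
    ggplot2::labs(x = NULL, y = "normalized enrichment score")
}
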