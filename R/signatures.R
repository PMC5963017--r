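new_signature <- function(df, contrast = NA_character_,
                          provenance = "single-study") {
  df <- as_tibble(df)
  if (anyDuplicated(df$gene_id)) {
    abort("A signature may not contain duplicate genes.",
          class = "revsig_format_error")
  }
  if (any(!is.finite(df$score))) {
    abort("All signature scores must be finite.", class = "revsig_format_error")
  }
  attr(df, "contrast") <- contrast
  attr(df, "provenance") <- provenance
  class(df) <- c("signature_tbl", setdiff(class(df), "signature_tbl"))
  df
}

#' Extract a signed signature from a differential-expression result
#'
#' A signature is the per-gene vector of moderated t-statistics for one
#' contrast — the ranking statistic used both for preranked enrichment and
#' for cosine reversal scoring.
#'
#' @param de A `de_result` tibble from [run_contrast()].
#' @return A `signature_tbl` tibble: `gene_id`, `score` (moderated t), `p`.
#' @export
as_signature <- function(de) {
  new_signature(tibble(gene_id = de$gene_id, score = de$t_mod, p = de$p),
                contrast = attr(de, "contrast") %||% NA_character_,
                provenance = "single-study")
}

#' Select differentially expressed genes by fold-change and FDR thresholds
#'
#' The MAQC-style filter: a gene is called up if its linear fold change
#' `2^log2FC` exceeds `fc_min` and its BH-adjusted p-value is below
#' `adjp_max`; down if the linear fold change is below `1/fc_min` at the
#' same FDR threshold.  Both thresholds are strict inequalities.
#'
#' @param de A `de_result` tibble.
#' @param fc_min Minimum absolute linear fold change (> 1; default 1.25).
#' @param adjp_max Maximum adjusted p-value (default 0.05).
#' @return A `deg_list`: list with `up`, `down` (character vectors),
#'   `fc_min`, `adjp_max`, `contrast`.
#' @export
select_degs <- function(de, fc_min = 1.25, adjp_max = 0.05) {
  if (fc_min <= 1) {
    abort("`fc_min` is a linear fold-change threshold and must exceed 1.",
          class = "revsig_config_error")
  }
  fc <- 2^de$log2FC
  sig <- de$adj_p < adjp_max
  structure(list(up = de$gene_id[sig & fc > fc_min],
                 down = de$gene_id[sig & fc < 1 / fc_min],
                 fc_min = fc_min, adjp_max = adjp_max,
                 contrast = attr(de, "contrast") %||% NA_character_),
            class = "deg_list")
}

#' @export
print.deg_list <- function(x, ...) {
  cat(sprintf("<deg_list> contrast %s: %d up, %d down (|FC| > %.3g, adj p < %.3g)\n",
              x$contrast, length(x$up), length(x$down), x$fc_min, x$adjp_max))
  invisible(x)
}

#' Combine two studies' signatures by Stouffer meta-analysis
#'
#' Per shared gene, each study's two-sided p-value and score sign are
#' converted to a signed normal deviate `z = sign(score) * qnorm(1 - p/2)`
#' and combined as a weighted Stouffer sum
#' `(w_a z_a + w_b z_b) / sqrt(w_a^2 + w_b^2)` (unweighted by default).
#' Working on signed z rather than effect sizes keeps the combination
#' platform-agnostic (e.g. one microarray and one RNA-seq cohort).  Genes
#' absent from either study are excluded.
#'
#' @param sig_a,sig_b `signature_tbl` tibbles carrying a `p` column.
#' @param w_a,w_b Optional study weights (e.g. sqrt of sample sizes).
#' @param label Contrast label of the combined signature.
#' @return A `signature_tbl` with `score` = combined z, `p` = two-sided
#'   normal p, provenance `"meta"`.
#' @export
meta_signature <- function(sig_a, sig_b, w_a = 1, w_b = 1, label = "meta") {
  shared <- intersect(sig_a$gene_id, sig_b$gene_id)
  if (length(shared) == 0L) {
    abort("The two signatures share no genes.", class = "revsig_config_error")
  }
  if (length(shared) < 100L) {
    warn(sprintf("Only %d shared genes; meta-analysis may be unstable.",
                 length(shared)))
  }
  za <- signed_z(sig_a)[shared]
  zb <- signed_z(sig_b)[shared]
  z <- unname((w_a * za + w_b * zb) / sqrt(w_a^2 + w_b^2))
  new_signature(tibble(gene_id = shared, score = z,
                       p = 2 * pnorm(-abs(z))),
                contrast = label, provenance = "meta")
}

signed_z <- function(sig) {
  if (!"p" %in% names(sig)) {
    abort("Signature lacks the `p` column needed for meta-analysis.",
          class = "revsig_config_error")
  }
  p <- pmin(pmax(sig$p, 1e-300), 1)
  setNames(sign(sig$score) * qnorm(1 - p / 2), sig$gene_id)
}

#' Build directional reversal gene sets from a DEG list
#'
#' Packages a disease contrast's up- and down-regulated genes as two
#' direction-tagged gene sets (`<label>_UP`, `<label>_DOWN`).  Querying
#' these against a treatment ranking asks the reversal question: disease-up
#' genes should fall at the bottom of the treatment ranking and
#' disease-down genes at the top.
#'
#' @param degs A `deg_list` from [select_degs()].
#' @param label Stem for the set names (default the DEG list's contrast).
#' @return A `gene_sets` tibble with up to two directional sets.
#' @export
make_reversal_sets <- function(degs, label = NULL) {
  label <- label %||% degs$contrast %||% "SIG"
  rows <- list()
  if (length(degs$up) > 0L) {
    rows <- c(rows, list(tibble(set = paste0(label, "_UP"), description = ".",
                                direction = "up", genes = list(degs$up))))
  } else {
    warn("No up-regulated genes; _UP set omitted.")
  }
  if (length(degs$down) > 0L) {
    rows <- c(rows, list(tibble(set = paste0(label, "_DOWN"), description = ".",
                                direction = "down", genes = list(degs$down))))
  } else {
    warn("No down-regulated genes; _DOWN set omitted.")
  }
  if (length(rows) == 0L) {
    abort("Both directions empty; nothing to build.",
          class = "revsig_config_error")
  }
  gene_sets(bind_rows(rows))
}
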