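#' Construct a feature-level count table
#'
#' Exon/junction counts nested under genes, as produced by counting reads
#' against a flattened annotation.
#'
#' @param features Tibble with `gene_id`, `feature_id`, `feature_type`
#'   (`"exon"` or `"junction"`); `feature_id` unique within gene.
#' @param counts Integer matrix, rows matching `features$feature_id`.
#' @param samples Sample tibble with `sample_id` and a `condition` column.
#' @return A `feature_counts` object.
#' @export
feature_counts <- function(features, counts, samples) {
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  if (anyDuplicated(paste(features$gene_id, features$feature_id))) {
    abort("`feature_id` must be unique within gene.",
          class = "revsig_format_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Feature counts must be non-negative integers.",
          class = "revsig_format_error")
  }
  if (!identical(rownames(counts), features$feature_id)) {
    counts <- counts[match(features$feature_id, rownames(counts)), , drop = FALSE]
  }
  storage.mode(counts) <- "integer"
  structure(list(features = features, counts = counts, samples = samples),
            class = "feature_counts")
}

#' Read/write feature-level counts as TSV
#'
#' Layout: columns `gene_id`, `feature_id`, `feature_type`, then one column
#' per sample; the sample sheet travels as `<stem>.sample_sheet.tsv`.
#'
#' @param path TSV path.
#' @param samples Sample sheet (data frame or TSV path); `NULL` reads the
#'   sidecar sheet.
#' @return A `feature_counts` object.
#' @export
read_feature_counts <- function(path, samples = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("gene_id", "feature_id", "feature_type")
  if (!all(meta_cols %in% names(df))) {
    abort("Feature count TSV needs columns gene_id, feature_id, feature_type.",
          class = "revsig_format_error")
  }
  cts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(cts) <- df$feature_id
  if (is.null(samples)) {
    samples <- read.delim(paste0(sub("\\.tsv$", "", path), ".sample_sheet.tsv"),
                          stringsAsFactors = FALSE)
  } else if (is.character(samples) && length(samples) == 1L) {
    samples <- read.delim(samples, stringsAsFactors = FALSE)
  }
  feature_counts(df[, meta_cols], cts, samples)
}

#' @rdname read_feature_counts
#' @param x A `feature_counts` object.
#' @export
write_feature_counts <- function(x, path) {
  df <- data.frame(x$features, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, paste0(sub("\\.tsv$", "", path), ".sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential usage of exons and splice junctions (DUEJ)
#'
#' Detects features whose expression changes between two conditions
#' relative to their gene's overall expression.  For each feature, the
#' counts of the feature and of the rest of its gene are modeled jointly by
#' a negative-binomial log-linear model with sample effects (absorbing
#' library size and gene-level expression), a feature-vs-rest term, and a
#' feature-by-condition interaction; the interaction is tested by a 1-df
#' likelihood-ratio test.  This feature-vs-rest formulation is a
#' deliberately simplified stand-in for full multi-feature GLMs: it keeps
#' each test 1-df and auditable.  Dispersion is estimated per feature by
#' method of moments from a Poisson fit (floored at 1e-8, no trend
#' shrinkage).  P-values are BH-adjusted across all tested features; a gene
#' is called positive if any of its features passes `alpha`.
#'
#' @param fct A `feature_counts` object whose sample table has a
#'   two-level `condition` column.
#' @param alpha Per-feature FDR threshold for the gene-level call.
#' @param min_mean_count Features with mean count below this are excluded
#'   from testing (default 5).
#' @return A `duej_result` list: `features` tibble (`gene_id`,
#'   `feature_id`, `usage_log2fc`, `lrt`, `df`, `p`, `adj_p`), `genes`
#'   tibble (`gene_id`, `min_adj_p`, `significant`), and `skipped` counts
#'   (single-feature genes, low-count or all-zero features).
#' @export
duej_test <- function(fct, alpha = 0.05, min_mean_count = 5) {
  stopifnot(inherits(fct, "feature_counts"))
  cond <- fct$samples$condition
  if (length(unique(cond)) != 2L) {
    abort("`condition` must have exactly two levels.",
          class = "revsig_design_error")
  }
  cond_ind <- as.integer(cond == sort(unique(cond))[2L])
  if (min(table(cond)) < 2L) {
    abort("Need >= 2 samples per condition.", class = "revsig_design_error")
  }
  n_samp <- ncol(fct$counts)
  genes <- split(seq_len(nrow(fct$features)), fct$features$gene_id)

  n_single <- 0L
  n_low <- 0L
  rows <- list()
  sample_mm <- model.matrix(~ 0 + factor(seq_len(n_samp)))
  for (g in names(genes)) {
    idx <- genes[[g]]
    if (length(idx) < 2L) {
      n_single <- n_single + 1L
      next
    }
    sub <- fct$counts[idx, , drop = FALSE]
    gene_tot <- colSums(sub)
    for (j in seq_along(idx)) {
      y1 <- sub[j, ]
      mean_ct <- mean(y1)
      if (all(y1 == 0) || mean_ct < min_mean_count) {
        n_low <- n_low + 1L
        next
      }
      y0 <- gene_tot - y1
      fit <- duej_fit_one(y1, y0, cond_ind, sample_mm)
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = g, feature_id = fct$features$feature_id[idx[j]],
        usage_log2fc = fit$coef / log(2), lrt = fit$lrt, df = 1L, p = fit$p)
    }
  }
  if (length(rows) == 0L) {
    abort("No testable features after filtering.", class = "revsig_filter_error")
  }
  feats <- bind_rows(rows)
  feats$adj_p <- bh_adjust(feats$p)
  gene_tab <- feats %>%
    group_by(.data$gene_id) %>%
    summarise(min_adj_p = min(.data$adj_p), .groups = "drop") %>%
    mutate(significant = .data$min_adj_p < alpha)
  structure(list(features = feats, genes = gene_tab,
                 skipped = c(single_feature_genes = n_single,
                             low_count_features = n_low),
                 alpha = alpha),
            class = "duej_result")
}

# One feature-vs-rest NB LRT.  y1/y0: feature and rest-of-gene counts per
# sample; the design has per-sample intercepts, a part term, and the
# part x condition interaction under test.
duej_fit_one <- function(y1, y0, cond_ind, sample_mm) {
  y <- c(y1, y0)
  part <- rep(c(1, 0), each = length(y1))
  X_red <- cbind(rbind(sample_mm, sample_mm), part = part)
  X_full <- cbind(X_red, inter = part * rep(cond_ind, 2L))
  pois <- suppressWarnings(stats::glm.fit(X_full, y, family = stats::poisson()))
  mu <- pois$fitted.values
  # dispersion from the tested feature's own observations: the rest-of-gene
  # counts are larger and relatively less overdispersed, so pooling them
  # underestimates the feature's usage noise (anti-conservative).  Squared
  # residuals are deflated by the model's leverage (many sample intercepts
  # for few observations), so each is rescaled by 1/(1 - h_i).
  this <- part == 1
  h <- pmin(rowSums(qr.Q(pois$qr)^2), 0.95)
  phi <- sum((y[this] - mu[this])^2 / (1 - h[this]) - mu[this]) /
    sum(mu[this]^2)
  phi <- max(phi, 1e-8)
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  full <- suppressWarnings(stats::glm.fit(X_full, y, family = fam))
  red <- suppressWarnings(stats::glm.fit(X_red, y, family = fam))
  lrt <- max(red$deviance - full$deviance, 0)
  list(coef = full$coefficients[["inter"]],
       lrt = lrt, p = pchisq(lrt, df = 1L, lower.tail = FALSE))
}

#' @export
print.duej_result <- function(x, ...) {
  cat(sprintf("<duej_result> %d features tested in %d genes; %d genes significant at adj p < %g\n",
              nrow(x$features), nrow(x$genes), sum(x$genes$significant),
              x$alpha))
  cat(sprintf("  skipped: %d single-feature genes, %d low-count features\n",
              x$skipped[["single_feature_genes"]],
              x$skipped[["low_count_features"]]))
  invisible(x)
}

#' @method tidy duej_result
#' @export
tidy.duej_result <- function(x, ...) x$features

#' @method glance duej_result
#' @export
glance.duej_result <- function(x, ...) {
  tibble(n_features = nrow(x$features), n_genes = nrow(x$genes),
         n_signif_genes = sum(x$genes$significant), alpha = x$alpha)
}

#' Genes whose disease usage shift is reversed by treatment
#'
#' Returns genes with a significant usage change in the disease contrast
#' whose treatment-contrast interaction coefficient has the opposite sign
#' for the matching feature, and is itself significant.
#'
#' @param disease,treatment `duej_result` objects over a shared gene
#'   universe.
#' @param alpha FDR threshold applied to both results (default 0.05).
#' @return Character vector of reversed gene ids.
#' @export
duej_reversal <- function(disease, treatment, alpha = 0.05) {
  shared <- intersect(disease$features$gene_id, treatment$features$gene_id)
  if (length(shared) == 0L) {
    abort("The two results share no genes.", class = "revsig_config_error")
  }
  j <- dplyr::inner_join(disease$features, treatment$features,
                         by = c("gene_id", "feature_id"),
                         suffix = c("_dis", "_trt"))
  hit <- j$adj_p_dis < alpha & j$adj_p_trt < alpha &
    sign(j$usage_log2fc_dis) * sign(j$usage_log2fc_trt) < 0
  sort(unique(j$gene_id[hit]))
}
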