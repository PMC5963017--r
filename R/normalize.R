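#' Remove genes with low average counts
#'
#' Genes with fewer than `min_mean` reads on average across all samples of
#' the matrix are filtered out before normalization and modeling; a gene
#' whose mean equals the threshold exactly is kept.
#'
#' @param cm A [count_matrix()].
#' @param min_mean Minimum mean raw count (default 10).
#' @return A [count_matrix()] with the same samples and the surviving genes.
#' @export
filter_low_count <- function(cm, min_mean = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowMeans(cm$counts) >= min_mean
  if (!any(keep)) {
    abort("All genes removed by the low-count filter; nothing to analyze.",
          class = "revsig_filter_error")
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors from the standard TMM procedure: the
#' reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean of those; for every sample, gene-wise log2 ratios of
#' count fractions against the reference (M) and average log2 abundances
#' (A) are computed over genes nonzero in both, doubly trimmed (`trim_m` on
#' M, `trim_a` on A), and combined by a precision-weighted mean with
#' binomial delta-method weights.  Factors are rescaled to geometric
#' mean 1, so effective library size = library size x factor.
#'
#' @param cm A [count_matrix()] with at least two samples.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return A `norm_factors` tibble: `sample_id`, `lib_size`, `tmm_factor`,
#'   `eff_lib_size`.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts
  if (ncol(x) < 2L) {
    abort("TMM needs at least two samples.", class = "revsig_config_error")
  }
  lib <- colSums(x)
  if (any(lib <= 0)) {
    abort("Every sample must have a positive total count.",
          class = "revsig_config_error")
  }
  f75 <- apply(x, 2L, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(x)), function(i) {
    tmm_pair_factor(x[, i], x[, ref], lib[i], lib[ref], trim_m, trim_a,
                    sample_id = colnames(x)[i])
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  structure(tibble(sample_id = colnames(x), lib_size = lib,
                   tmm_factor = fac, eff_lib_size = lib * fac),
            class = c("norm_factors", class(tibble())))
}

# TMM factor of one sample against the reference (both raw count vectors).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a,
                            sample_id = "?") {
  keep0 <- obs > 0 & ref > 0
  if (!any(keep0)) {
    warn(sprintf("Sample '%s' shares no nonzero genes with the reference; factor set to 1.",
                 sample_id))
    return(1)
  }
  p_obs <- obs[keep0] / n_obs
  p_ref <- ref[keep0] / n_ref
  m <- log2(p_obs / p_ref)
  a <- (log2(p_obs) + log2(p_ref)) / 2
  v <- (n_obs - obs[keep0]) / (n_obs * obs[keep0]) +
       (n_ref - ref[keep0]) / (n_ref * ref[keep0])
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  f <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  if (!is.finite(f)) 1 else f
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective library size + 1) * 1e6)`, the
#' standard transform of counts to log2-CPM with a prior count guarding
#' zeros.
#'
#' @param cm A [count_matrix()].
#' @param nf A `norm_factors` tibble from [tmm_factors()]; `NULL` computes
#'   TMM factors internally.
#' @param prior Prior count added to every entry (default 0.5).
#' @return A numeric matrix, genes x samples.
#' @export
log_cpm <- function(cm, nf = NULL, prior = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(nf)) nf <- tmm_factors(cm)
  if (!setequal(nf$sample_id, colnames(cm$counts)) ||
      nrow(nf) != ncol(cm$counts)) {
    abort("Normalization factors do not match the count matrix samples.",
          class = "revsig_config_error")
  }
  eff <- nf$eff_lib_size[match(colnames(cm$counts), nf$sample_id)]
  t(log2(t(cm$counts + prior) / (eff + 1) * 1e6))
}
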