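#' Construct a validated count matrix
#'
#' The central container of the pipeline: an integer gene-by-sample count
#' matrix together with a per-sample annotation table.  Gene and sample
#' identifiers are opaque strings matched exactly and case-sensitively;
#' identifier harmonization (symbol mapping, orthologs) is the caller's
#' responsibility.
#'
#' @param counts Integer matrix (genes in rows, samples in columns) with
#'   unique, non-empty dimnames.  Values must be non-negative whole numbers.
#' @param samples Data frame of per-sample annotations with columns
#'   `sample_id`, `genotype`, `dose`, `tissue` and optionally `study_id`.
#'   Every column of `counts` must appear exactly once.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `samples` (tibble).
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.", class = "revsig_format_error")
  }
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid)) {
    abort("`counts` must have row (gene) and column (sample) names.",
          class = "revsig_format_error")
  }
  if (anyDuplicated(gid)) {
    abort(paste0("Duplicate gene identifiers: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")),
          class = "revsig_format_error")
  }
  if (anyDuplicated(sid)) {
    abort(paste0("Duplicate sample identifiers: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")),
          class = "revsig_format_error")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    abort(sprintf(
      "Counts must be non-negative integers; offending value %s at gene '%s', sample '%s'.",
      format(counts[b[1L], b[2L]]), gid[b[1L]], sid[b[2L]]),
      class = "revsig_format_error")
  }
  samples <- as_tibble(samples)
  req <- c("sample_id", "genotype", "dose", "tissue")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0L) {
    abort(paste0("Sample table missing column(s): ", paste(miss, collapse = ", ")),
          class = "revsig_format_error")
  }
  absent <- setdiff(sid, samples$sample_id)
  extra  <- setdiff(samples$sample_id, sid)
  if (length(absent) > 0L || length(extra) > 0L) {
    abort(paste0(
      "Sample sheet mismatch.",
      if (length(absent)) paste0(" Missing from sheet: ", paste(absent, collapse = ", "), ".") else "",
      if (length(extra))  paste0(" Not in matrix: ", paste(extra, collapse = ", "), ".") else ""),
      class = "revsig_format_error")
  }
  samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- table(paste(x$samples$genotype, x$samples$dose, sep = "."))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#'
#' @param x A `count_matrix`.
#' @param genes,samples Character vectors or logical/integer indices; `NULL`
#'   keeps everything.
#' @return A `count_matrix`.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  if (!is.null(genes)) cts <- cts[genes, , drop = FALSE]
  if (!is.null(samples)) cts <- cts[, samples, drop = FALSE]
  count_matrix(cts, x$samples[x$samples$sample_id %in% colnames(cts), ])
}

#' Convert a count matrix to a long tibble
#'
#' One row per (gene, sample) pair, joined with the sample annotations, for
#' tidyverse-style exploration and plotting.
#'
#' @param x A `count_matrix`.
#' @return A tibble with columns `gene_id`, `sample_id`, `count` and the
#'   sample annotation columns.
#' @export
counts_tidy <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  long <- tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  left_join(long, x$samples, by = "sample_id")
}
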