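#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV dialect: tab-separated with a header row whose first column is
#' literally `gene_id`; remaining columns are samples.  MatrixMarket input
#' is the `.mtx` file plus two sidecar index files `<stem>.genes.txt` and
#' `<stem>.samples.txt` (one identifier per line).  Counts must be complete
#' non-negative integers; missing values are not permitted.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param samples Sample annotation table: a data frame or a path to a TSV
#'   with columns `sample_id`, `genotype`, `dose`, `tissue` (optionally
#'   `study_id`).  If `NULL` a skeleton sheet with `NA` annotations is built.
#' @param format `"tsv"` or `"mtx"`; guessed from the file extension by
#'   default.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, samples = NULL, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "revsig_format_error")
  }
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1L] != "gene_id") {
      abort("First column of a count TSV must be named 'gene_id'.",
            class = "revsig_format_error")
    }
    if (anyNA(df)) {
      abort("Missing values are not permitted in count files.",
            class = "revsig_format_error")
    }
    cts <- as.matrix(df[, -1L, drop = FALSE])
    rownames(cts) <- df$gene_id
  } else {
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      abort(paste0("Malformed MatrixMarket file ", path, ": ",
                   conditionMessage(e)), class = "revsig_format_error")
    })
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    sfile <- paste0(stem, ".samples.txt")
    for (f in c(gfile, sfile)) {
      if (!file.exists(f)) {
        abort(paste0("Missing MTX index file: ", f), class = "revsig_format_error")
      }
    }
    gid <- readLines(gfile)
    sid <- readLines(sfile)
    if (length(gid) != nrow(m) || length(sid) != ncol(m)) {
      abort("MTX dimensions do not match the index files.",
            class = "revsig_format_error")
    }
    cts <- as.matrix(m)
    dimnames(cts) <- list(gid, sid)
  }
  if (is.null(samples)) {
    samples <- tibble(sample_id = colnames(cts),
                      genotype = NA_character_, dose = NA_character_,
                      tissue = NA_character_)
  } else if (is.character(samples) && length(samples) == 1L) {
    samples <- read.delim(samples, stringsAsFactors = FALSE)
  }
  count_matrix(cts, samples)
}

#' Write a count matrix to disk
#'
#' Writes the counts as TSV (or MatrixMarket triplets with sidecar index
#' files) and the sample sheet as `<stem>.sample_sheet.tsv`.
#'
#' @param x A [count_matrix()].
#' @param path Output path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "mtx")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    stem <- sub("\\.tsv$", "", path)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(x$counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(x$counts), paste0(stem, ".samples.txt"))
  }
  write.table(x$samples, paste0(stem, ".sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.  Duplicate genes within a set are removed.  A name
#' ending in `_UP` or `_DOWN` is given the corresponding direction tag,
#' used by the directional reversal test.
#'
#' @param path Path to a GMT file.  An empty file yields an empty
#'   collection.
#' @return A `gene_sets` tibble with columns `set`, `description`,
#'   `direction` (`"up"`, `"down"` or `"none"`) and list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "revsig_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(gene_sets(tibble(set = character(), description = character(),
                            direction = character(), genes = list())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    abort(sprintf("GMT line %d has %d field(s); at least 3 required.",
                  which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]),
          class = "revsig_format_error")
  }
  out <- tibble(
    set = vapply(parts, `[[`, character(1), 1L),
    description = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  )
  out$direction <- ifelse(grepl("_UP$", out$set), "up",
                          ifelse(grepl("_DOWN$", out$set), "down", "none"))
  gene_sets(out[, c("set", "description", "direction", "genes")])
}

#' Construct a gene-set collection
#'
#' @param x A tibble/data frame with columns `set`, `genes` (list-column of
#'   character vectors) and optionally `description` and `direction`.
#' @return A `gene_sets` tibble.
#' @export
gene_sets <- function(x) {
  x <- as_tibble(x)
  if (!all(c("set", "genes") %in% names(x))) {
    abort("A gene-set collection needs columns `set` and `genes`.",
          class = "revsig_format_error")
  }
  if (!"description" %in% names(x)) x$description <- "."
  if (!"direction" %in% names(x)) x$direction <- "none"
  if (anyDuplicated(x$set)) {
    abort("Gene-set names must be unique.", class = "revsig_format_error")
  }
  if (nrow(x) > 0L && any(lengths(x$genes) == 0L)) {
    abort("Every gene set must be non-empty.", class = "revsig_format_error")
  }
  x$genes <- lapply(x$genes, unique)
  x <- x[, c("set", "description", "direction", "genes")]
  class(x) <- c("gene_sets", class(x))
  x
}

#' Write a gene-set collection to GMT
#'
#' @param x A `gene_sets` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$set[i], x$description[i], x$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a signature as two-column TSV
#'
#' Signatures are stored as `gene_id`, `score` (and `p` when available).
#'
#' @param path TSV path.
#' @return A signature tibble.
#' @export
read_signature <- function(path) {
  df <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("gene_id", "score") %in% names(df))) {
    abort("A signature TSV needs columns `gene_id` and `score`.",
          class = "revsig_format_error")
  }
  new_signature(df, contrast = attr(df, "contrast") %||% NA_character_,
                provenance = "file")
}

#' @rdname read_signature
#' @param x A signature tibble.
#' @export
write_signature <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
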