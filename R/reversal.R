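#' Cosine similarity between a disease and a treatment signature
#'
#' The headline reversal statistic: the cosine of the angle between the two
#' signatures' moderated-t vectors over their shared genes.  A negative
#' cosine means genes pushed up in disease are pushed down by treatment and
#' vice versa — signature reversal.
#'
#' @param disease,treatment `signature_tbl` tibbles.
#' @param min_shared Minimum number of shared genes (default 10; fewer is
#'   numerically unstable and refused).
#' @return A list: `cosine` in `[-1, 1]`, `n_shared`.
#' @export
cosine_reversal <- function(disease, treatment, min_shared = 10) {
  shared <- intersect(disease$gene_id, treatment$gene_id)
  if (length(shared) < min_shared) {
    abort(sprintf("Only %d shared genes (need >= %d).",
                  length(shared), min_shared),
          class = "revsig_config_error")
  }
  d <- disease$score[match(shared, disease$gene_id)]
  t_ <- treatment$score[match(shared, treatment$gene_id)]
  list(cosine = sum(d * t_) / (sqrt(sum(d^2)) * sqrt(sum(t_^2))),
       n_shared = length(shared))
}

#' Gene-permutation null for the reversal cosine
#'
#' Permutes the treatment signature's gene-to-score assignment `n_perm`
#' times and compares the permuted cosines with the observed one.  The
#' default alternative is one-sided toward reversal (permuted cosine at
#' least as negative as observed); `"two.sided"` compares absolute values.
#'
#' @param disease,treatment `signature_tbl` tibbles.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"reversal"` (one-sided, default) or `"two.sided"`.
#' @return A list: `cosine`, `n_shared`, `perm_p` (floor `1/(n_perm+1)`).
#' @export
cosine_null <- function(disease, treatment, n_perm = 10000, seed = 1,
                        alternative = c("reversal", "two.sided")) {
  alternative <- match.arg(alternative)
  obs <- cosine_reversal(disease, treatment)
  shared <- intersect(disease$gene_id, treatment$gene_id)
  d <- disease$score[match(shared, disease$gene_id)]
  t_ <- treatment$score[match(shared, treatment$gene_id)]
  du <- d / sqrt(sum(d^2))
  tu <- t_ / sqrt(sum(t_^2))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sum(du * tu[sample.int(length(tu))]),
           numeric(1))
  })
  hits <- if (alternative == "reversal") {
    sum(perm <= obs$cosine)
  } else {
    sum(abs(perm) >= abs(obs$cosine))
  }
  list(cosine = obs$cosine, n_shared = obs$n_shared,
       perm_p = (1 + hits) / (n_perm + 1))
}

#' Directional enrichment test of disease up/down sets in a treatment
#' ranking
#'
#' Runs the preranked enrichment of each direction-tagged disease gene set
#' in the treatment signature and BH-adjusts across the tested family.
#' Reversal requires the disease-up set to be negatively enriched (its
#' genes sink to the bottom of the treatment ranking) AND the disease-down
#' set positively enriched, both at the stated FDR threshold.
#'
#' @param sets A `gene_sets` collection with `direction` tags, typically
#'   from [make_reversal_sets()].
#' @param treatment A `signature_tbl`.
#' @param n_perm Permutations for the enrichment null (default 1000).
#' @param seed Integer seed.
#' @param alpha FDR threshold for the verdict (default 0.05).
#' @return An `enrichment_result` tibble with attribute `reversed`
#'   (logical verdict).
#' @export
directional_reversal <- function(sets, treatment, n_perm = 1000, seed = 1,
                                 alpha = 0.05) {
  res <- preranked_test(treatment, sets, n_perm = n_perm, seed = seed)
  ok <- res$testable
  up_ok <- any(ok & res$direction == "up" & res$es < 0 & res$adj_p < alpha)
  down_ok <- any(ok & res$direction == "down" & res$es > 0 & res$adj_p < alpha)
  attr(res, "reversed") <- up_ok && down_ok
  res
}

#' Full reversal assessment of a treatment signature against a disease
#' signature
#'
#' Combines the cosine statistic with its gene-permutation null and the
#' directional enrichment of the disease DEG sets in the treatment ranking.
#'
#' @param disease A `signature_tbl` for the disease contrast.
#' @param treatment A `signature_tbl` for the treatment contrast.
#' @param sets Directional `gene_sets` built from the disease DEGs.
#' @param n_perm Permutations for both nulls (default 1000).
#' @param seed Integer seed.
#' @param alpha FDR threshold for the directional verdict.
#' @return A `reversal_result` list: `cosine`, `n_shared`, `perm_p`,
#'   `sets` (enrichment tibble), `reversed`.
#' @export
reversal_test <- function(disease, treatment, sets, n_perm = 1000, seed = 1,
                          alpha = 0.05) {
  cn <- cosine_null(disease, treatment, n_perm = n_perm, seed = seed)
  dr <- directional_reversal(sets, treatment, n_perm = n_perm,
                             seed = seed + 1L, alpha = alpha)
  structure(list(cosine = cn$cosine, n_shared = cn$n_shared,
                 perm_p = cn$perm_p, sets = dr,
                 reversed = attr(dr, "reversed")),
            class = "reversal_result")
}

#' @export
print.reversal_result <- function(x, ...) {
  cat(sprintf("<reversal_result> cosine = %.3f over %d genes (perm p = %.3g)\n",
              x$cosine, x$n_shared, x$perm_p))
  cat(sprintf("  directional verdict: %s\n",
              if (isTRUE(x$reversed)) "REVERSED" else "not reversed"))
  invisible(x)
}

#' @method tidy reversal_result
#' @export
tidy.reversal_result <- function(x, ...) {
  out <- x$sets
  class(out) <- setdiff(class(out), "enrichment_result")
  out$leading_edge <- NULL
  out
}

#' @method glance reversal_result
#' @export
glance.reversal_result <- function(x, ...) {
  tibble(cosine = x$cosine, n_shared = x$n_shared, perm_p = x$perm_p,
         reversed = x$reversed)
}
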