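# Order a signature into a ranked list: decreasing score, ties broken by
# gene id (lexicographic) for determinism.
rank_signature <- function(sig) {
  o <- order(-sig$score, sig$gene_id)
  list(genes = sig$gene_id[o], scores = sig$score[o])
}

#' Weighted running-sum enrichment score of a gene set in a ranking
#'
#' Walks the score-ranked gene list: each gene-set hit at position i adds
#' `|score_i|^p / sum(|score_hits|^p)` to the running sum, each miss
#' subtracts `1/(N - n_hits)`.  The enrichment score (ES) is the running
#' sum's signed maximal deviation from zero; the leading edge is the set
#' members at or before the extremum (at or after, for negative ES).
#'
#' @param sig A `signature_tbl` (or tibble with `gene_id`, `score`).
#' @param geneset Character vector of member gene ids.
#' @param weight_p Score weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @return A list: `es` in `[-1, 1]`, `n_hits`, `leading_edge`.
#' @export
enrichment_score <- function(sig, geneset, weight_p = 1) {
  rk <- rank_signature(sig)
  hit <- rk$genes %in% geneset
  n <- length(rk$genes)
  nh <- sum(hit)
  if (nh == 0L || nh == n) {
    abort("Gene set covers none or all of the ranked genes.",
          class = "revsig_config_error")
  }
  es_running(rk$scores, hit, weight_p, rk$genes)
}

# Core running-sum computation on a precomputed hit indicator.
es_running <- function(scores, hit, weight_p, genes = NULL) {
  n <- length(hit)
  nh <- sum(hit)
  wts <- abs(scores)^weight_p
  inc <- numeric(n)
  denom <- sum(wts[hit])
  inc[hit] <- if (denom > 0) wts[hit] / denom else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  # first position within float tolerance of the maximal deviation, so an
  # exactly tied +e/-e pair resolves deterministically to the earlier one
  i_ext <- which(abs(rs) >= max(abs(rs)) - 1e-9)[1L]
  es <- rs[i_ext]
  le <- if (is.null(genes)) NULL else if (es >= 0) {
    genes[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    genes[i_ext:n][hit[i_ext:n]]
  }
  list(es = es, n_hits = nh, leading_edge = le)
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For every set, computes the running-sum enrichment score in the ranked
#' signature and compares it with the scores of `n_perm` random same-size
#' gene sets (gene-tag permutation — preranked input has no sample labels
#' to permute).  NES is the ES divided by the mean absolute null ES of
#' matching sign; the permutation p-value is one-sided within the matching
#' sign class with add-one smoothing, and BH-adjusted across the sets
#' tested in the call.
#'
#' @param sig A `signature_tbl`.
#' @param sets A `gene_sets` collection.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation null.
#' @param weight_p Score weight exponent (default 1).
#' @return An `enrichment_result` tibble: `set`, `direction`, `es`, `nes`,
#'   `n_hits`, `perm_p`, `adj_p`, list-column `leading_edge`.
#' @export
preranked_test <- function(sig, sets, n_perm = 1000, seed = 1,
                           weight_p = 1) {
  if (n_perm < 100) {
    warn("Fewer than 100 permutations gives a coarse p-value floor.")
  }
  rk <- rank_signature(sig)
  n <- length(rk$genes)
  res <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(sets)), function(i) {
      members <- intersect(sets$genes[[i]], rk$genes)
      nh <- length(members)
      if (nh == 0L || nh == n) {
        return(tibble(set = sets$set[i], direction = sets$direction[i],
                      es = NA_real_, nes = NA_real_, n_hits = nh,
                      perm_p = NA_real_, leading_edge = list(character(0)),
                      testable = FALSE))
      }
      hit <- rk$genes %in% members
      obs <- es_running(rk$scores, hit, weight_p, rk$genes)
      null_es <- vapply(seq_len(n_perm), function(b) {
        h <- logical(n)
        h[sample.int(n, nh)] <- TRUE
        es_running(rk$scores, h, weight_p)$es
      }, numeric(1))
      same <- null_es * sign(obs$es) >= 0
      nes_denom <- if (any(same)) mean(abs(null_es[same])) else mean(abs(null_es))
      nes <- if (nes_denom > 0) obs$es / nes_denom else 0
      pp <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
      tibble(set = sets$set[i], direction = sets$direction[i],
             es = obs$es, nes = nes, n_hits = nh, perm_p = pp,
             leading_edge = list(obs$leading_edge), testable = TRUE)
    })
  })
  res$adj_p <- NA_real_
  if (any(res$testable)) {
    res$adj_p[res$testable] <- bh_adjust(res$perm_p[res$testable])
  }
  res <- res[, c("set", "direction", "es", "nes", "n_hits", "perm_p",
                 "adj_p", "leading_edge", "testable")]
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Hypergeometric over-representation of gene sets in a DEG list
#'
#' A local replacement for web-service enrichment tools: for each set, the
#' one-sided hypergeometric tail probability of observing at least the
#' actual overlap between the differentially expressed genes and the set,
#' given the gene universe, with BH adjustment across sets.
#'
#' @param deg Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector: all genes that could have been
#'   selected (e.g. all genes surviving the count filter).
#' @param sets A `gene_sets` collection (intersected with the universe).
#' @return A tibble: `set`, `n_set`, `n_overlap`, `expected`, `odds_ratio`,
#'   `p`, `adj_p`.
#' @export
overrep_test <- function(deg, universe, sets) {
  deg <- unique(deg)
  universe <- unique(universe)
  if (length(setdiff(deg, universe)) > 0L) {
    abort("`deg` must be a subset of `universe`.",
          class = "revsig_config_error")
  }
  n_u <- length(universe)
  n_d <- length(deg)
  out <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    memb <- intersect(sets$genes[[i]], universe)
    k <- length(intersect(deg, memb))
    m <- length(memb)
    p <- if (m == 0L) 1 else phyper(k - 1, m, n_u - m, n_d, lower.tail = FALSE)
    or <- {
      a <- k; b <- n_d - k; c_ <- m - k; d <- n_u - m - n_d + k
      if (b * c_ == 0) Inf else (a * d) / (b * c_)
    }
    tibble(set = sets$set[i], n_set = m, n_overlap = k,
           expected = n_d * m / n_u, odds_ratio = or, p = p)
  })
  out$adj_p <- bh_adjust(out$p)
  out
}
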