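# Independent brute-force oracles, written straight from the definitions
# and kept deliberately naive so they share no code with the package.

# BH step-up: adj_i = min over j with p_j >= p_i of min(1, m p_j / rank_j).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / rank(p, ties.method = "max")[cand]))
  }, numeric(1))
}

# Running-sum enrichment score by explicit single-step walk.
oracle_es <- function(scores, is_hit, weight_p) {
  n <- length(scores)
  nh <- sum(is_hit)
  denom <- sum(abs(scores[is_hit])^weight_p)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      running <- running + if (denom > 0) abs(scores[i])^weight_p / denom else 1 / nh
    } else {
      running <- running - 1 / (n - nh)
    }
    # strictly-greater with a float-noise guard: at a mathematically exact
    # tie of the extrema the first one is the ES
    if (abs(running) > abs(best) + 1e-9) best <- running
  }
  best
}

# TMM factors by explicit enumeration of the doubly trimmed gene set.
oracle_tmm <- function(x, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(x)
  f75 <- sapply(seq_len(ncol(x)), function(j) {
    unname(quantile(x[, j], 0.75)) / lib[j]
  })
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(x)), function(j) {
    ok <- x[, j] > 0 & x[, ref] > 0
    if (!any(ok)) return(1)
    po <- x[ok, j] / lib[j]
    pr <- x[ok, ref] / lib[ref]
    m <- log2(po / pr)
    a <- (log2(po) + log2(pr)) / 2
    v <- (lib[j] - x[ok, j]) / (lib[j] * x[ok, j]) +
         (lib[ref] - x[ok, ref]) / (lib[ref] * x[ok, ref])
    fin <- is.finite(m) & is.finite(a)
    m <- m[fin]; a <- a[fin]; v <- v[fin]
    if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    keep <- rep(TRUE, n)
    lo <- floor(n * trim_m) + 1
    hi <- n + 1 - lo
    keep <- keep & rank(m) >= lo & rank(m) <= hi
    lo <- floor(n * trim_a) + 1
    hi <- n + 1 - lo
    keep <- keep & rank(a) >= lo & rank(a) <= hi
    if (!any(keep)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  })
  fac / exp(mean(log(fac)))
}

# Ordinary least squares straight from the normal equations.
oracle_ols <- function(y, X) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  list(coef = drop(b), s2 = sum(r^2) / (nrow(X) - ncol(X)))
}

# Small random count matrix with a standard sample sheet.
random_cm <- function(n_genes = 50, n_samp = 6, lambda = 60, seed = 1) {
  withr::with_seed(seed, {
    cts <- matrix(rpois(n_genes * n_samp, lambda), n_genes,
                  dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                  sprintf("s%02d", seq_len(n_samp))))
    count_matrix(cts, data.frame(
      sample_id = colnames(cts),
      genotype = rep(c("WT", "disease"), length.out = n_samp),
      dose = "veh", tissue = "striatum"))
  })
}

# Minimal de_result tibble for the signature-level operations.
fake_de <- function(gene_id, log2FC, adj_p, t_mod = log2FC, p = adj_p,
                    contrast = "A") {
  out <- tibble::tibble(gene_id = gene_id, log2FC = log2FC,
                        avg_expr = 0, s2 = 1, df_resid = 10,
                        t_ord = t_mod, t_mod = t_mod, p = p, adj_p = adj_p)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", class(out))
  out
}

sig_tbl <- function(gene_id, score, p = NULL) {
  df <- tibble::tibble(gene_id = gene_id, score = score)
  if (!is.null(p)) df$p <- p
  revsig:::new_signature(df)
}
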