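# deterministic two-feature fixture: proportions exactly equal across
# conditions unless shifted
make_fct <- function(ctrl1, ctrl2, treat1, treat2) {
  cts <- rbind(`gX:f1` = c(ctrl1, treat1), `gX:f2` = c(ctrl2, treat2))
  n <- ncol(cts)
  colnames(cts) <- sprintf("s%02d", seq_len(n))
  feature_counts(
    tibble::tibble(gene_id = "gX", feature_id = rownames(cts),
                   feature_type = c("exon", "junction")),
    cts,
    tibble::tibble(sample_id = colnames(cts),
                   condition = rep(c("ctrl", "treat"), c(length(ctrl1),
                                                         length(treat1)))))
}

test_that("pure expression change without usage change is not flagged", {
  # treated samples express the gene 4x higher with identical usage split
  fct <- make_fct(ctrl1 = c(20L, 24L, 18L, 22L), ctrl2 = c(80L, 96L, 72L, 88L),
                  treat1 = c(80L, 96L, 72L, 88L), treat2 = c(320L, 384L, 288L, 352L))
  res <- duej_test(fct, min_mean_count = 1)
  expect_true(all(res$features$lrt < 1e-4))
  expect_false(any(res$genes$significant))
})

test_that("a strong usage flip is detected and coefficients carry its sign", {
  fct <- make_fct(ctrl1 = c(20L, 24L, 18L, 22L), ctrl2 = c(80L, 96L, 72L, 88L),
                  treat1 = c(80L, 96L, 72L, 88L), treat2 = c(20L, 24L, 18L, 22L))
  res <- duej_test(fct, min_mean_count = 1)
  f1 <- res$features[res$features$feature_id == "gX:f1", ]
  f2 <- res$features[res$features$feature_id == "gX:f2", ]
  expect_gt(f1$usage_log2fc, 0)
  expect_lt(f2$usage_log2fc, 0)
  expect_true(all(res$features$adj_p < 0.01))
  expect_true(all(res$features$lrt >= 0))
  expect_true(all(res$features$adj_p >= res$features$p))
})

test_that("statistics are invariant to sample order and to library rescaling", {
  cfg <- sim_config(n_genes = 25, n_per_group = 6,
                    libsize_meanlog = log(3e5), seed = 13)
  fs <- simulate_feature_counts(cfg, features_per_gene = 3,
                                usage_shift_frac = 0.2, usage_shift_delta = 1.5)
  res <- duej_test(fs$features)

  perm <- c(3, 1, 2, 6, 5, 4, 9, 8, 7, 12, 11, 10)  # within-condition shuffle
  fct2 <- feature_counts(fs$features$features,
                         fs$features$counts[, perm],
                         fs$features$samples[perm, ])
  res2 <- duej_test(fct2)
  expect_equal(res$features$lrt, res2$features$lrt, tolerance = 1e-8)

  # doubling one sample's counts is absorbed by its sample effect
  fct3 <- fs$features
  fct3$counts[, 1] <- fct3$counts[, 1] * 2L
  res3 <- duej_test(feature_counts(fct3$features, fct3$counts, fct3$samples))
  expect_equal(res$features$usage_log2fc, res3$features$usage_log2fc,
               tolerance = 0.25)
})

test_that("single-feature genes are skipped with an accounting entry", {
  cts <- rbind(`g1:f1` = c(30L, 31L, 29L, 30L),
               `g2:f1` = c(40L, 42L, 38L, 41L),
               `g2:f2` = c(60L, 63L, 57L, 61L))
  colnames(cts) <- paste0("s", 1:4)
  fct <- feature_counts(
    tibble::tibble(gene_id = c("g1", "g2", "g2"),
                   feature_id = rownames(cts),
                   feature_type = "exon"),
    cts,
    tibble::tibble(sample_id = colnames(cts),
                   condition = c("ctrl", "ctrl", "treat", "treat")))
  res <- duej_test(fct, min_mean_count = 1)
  expect_equal(unname(res$skipped["single_feature_genes"]), 1)
  expect_false("g1" %in% res$features$gene_id)
})

test_that("usage reversal returns exactly the sign-flipped significant genes", {
  feats <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    feature_id = paste0(gene_id, ":f", rep(1:2, 3)),
    usage_log2fc = c(2, -2, 1.5, -1.5, 0.2, -0.2),
    lrt = 10, df = 1L,
    p = c(1e-5, 1e-5, 1e-4, 1e-4, 0.5, 0.5),
    adj_p = c(1e-4, 1e-4, 1e-3, 1e-3, 0.7, 0.7))
  mk <- function(f) {
    genes <- f %>% dplyr::group_by(gene_id) %>%
      dplyr::summarise(min_adj_p = min(adj_p), .groups = "drop") %>%
      dplyr::mutate(significant = min_adj_p < 0.05)
    structure(list(features = f, genes = genes,
                   skipped = c(single_feature_genes = 0L,
                               low_count_features = 0L), alpha = 0.05),
              class = "duej_result")
  }
  disease <- mk(feats)
  flipped <- feats
  flipped$usage_log2fc <- -flipped$usage_log2fc
  expect_identical(duej_reversal(disease, mk(flipped)), c("g1", "g2"))

  null_t <- feats
  null_t$adj_p <- 0.9
  expect_length(duej_reversal(disease, mk(null_t)), 0)

  none_sig <- mk(dplyr::mutate(feats, adj_p = 0.9))
  expect_length(duej_reversal(none_sig, mk(flipped)), 0)

  other <- mk(dplyr::mutate(feats, gene_id = paste0("zz", gene_id)))
  expect_error(duej_reversal(disease, other), class = "revsig_config_error")
})
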