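test_that("simulation is deterministic and respects the no-effect config", {
  cfg <- sim_config(n_genes = 200, n_per_group = 3,
                    libsize_meanlog = log(2e5), seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  null_cfg <- sim_config(n_genes = 100, n_per_group = 3, frac_disease = 0,
                         libsize_meanlog = log(2e5), seed = 2)
  s <- simulate_counts(null_cfg)
  expect_length(s$truth$disease_genes, 0)
  expect_length(s$truth$reversed_genes, 0)

  expect_error(sim_config(n_genes = 0), class = "revsig_config_error")
  expect_error(sim_config(frac_disease = 1.2), class = "revsig_config_error")
  expect_error(sim_config(kappa_by_dose = c(veh = 0, high = 1.5)),
               class = "revsig_config_error")
})

test_that("reversed genes' empirical treatment effect matches -kappa x disease lfc", {
  cfg <- sim_config(n_genes = 2000, n_per_group = 8, frac_disease = 0.1,
                    disease_lfc_sd = 1,
                    kappa_by_dose = c(veh = 0, low = 0.3, high = 0.8),
                    seed = 42)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  expect_true(all(tr$reversed_genes %in% tr$disease_genes))

  cpm <- sweep(sim$counts$counts, 2, colSums(sim$counts$counts), "/") * 1e6
  grp <- paste(sim$counts$samples$genotype, sim$counts$samples$dose, sep = ".")
  gm <- function(g) rowMeans(cpm[, grp == g, drop = FALSE])
  emp_lfc <- log2(gm("disease.high")[tr$reversed_genes] /
                  gm("disease.veh")[tr$reversed_genes])
  planted <- tr$disease_lfc[tr$reversed_genes]
  # treated-vs-vehicle planted effect is -kappa_high * lfc per gene
  fit <- stats::lm(emp_lfc ~ 0 + planted)
  expect_equal(unname(coef(fit)), -0.8, tolerance = 0.05)
  expect_equal(mean(emp_lfc), -0.8 * mean(planted), tolerance = 0.1)
})

test_that("planted effects are recoverable by the DE chain (slope ~ 1, AUC)", {
  cfg <- sim_config(n_genes = 1500, n_per_group = 8, frac_disease = 0.1,
                    disease_lfc_sd = 1, kappa_by_dose = c(veh = 0), seed = 7)
  sim <- simulate_counts(cfg)
  de <- run_contrast(sim$counts, "A")
  j <- de[de$gene_id %in% sim$truth$disease_genes, ]
  planted <- sim$truth$disease_lfc[j$gene_id]
  slope <- unname(coef(stats::lm(j$log2FC ~ 0 + planted)))
  expect_equal(slope, 1, tolerance = 0.1)

  lab <- de$gene_id %in% sim$truth$disease_genes
  r <- rank(abs(de$t_mod))
  auc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  # N(0,1) planted effects include many sub-detectable ones; an established
  # reference chain (voom/lmFit/eBayes) attains the same AUC on this data
  expect_gt(auc, 0.75)
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  dge <- edgeR::calcNormFactors(edgeR::DGEList(de_counts <- filter_low_count(sim$counts)$counts))
  grp <- factor(paste(filter_low_count(sim$counts)$samples$genotype,
                      filter_low_count(sim$counts)$samples$dose, sep = "."))
  des <- stats::model.matrix(~ 0 + grp)
  colnames(des) <- levels(grp)
  v <- limma::voom(dge, des)
  lfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(v, des),
    limma::makeContrasts(disease.veh - WT.veh, levels = des)))
  lab2 <- rownames(de_counts) %in% sim$truth$disease_genes
  r2 <- rank(abs(lfit$t[, 1]))
  auc_limma <- (sum(r2[lab2]) - sum(lab2) * (sum(lab2) + 1) / 2) /
    (sum(lab2) * sum(!lab2))
  expect_equal(auc, auc_limma, tolerance = 0.02)
})

test_that("two-study simulation controls the effect correlation", {
  cfg <- sim_config(n_genes = 800, n_per_group = 4, frac_disease = 0.25,
                    libsize_meanlog = log(5e5), seed = 5)
  s1 <- simulate_two_studies(cfg, shared_effect_corr = 1)
  expect_identical(s1$truth$disease_lfc, s1$truth$disease_lfc2)
  expect_identical(unique(s1$study1$samples$study_id), "study1")
  expect_identical(unique(s1$study2$samples$study_id), "study2")

  s0 <- simulate_two_studies(cfg, shared_effect_corr = 0)
  expect_lt(abs(cor(s0$truth$disease_lfc, s0$truth$disease_lfc2)), 0.15)

  s2 <- simulate_two_studies(cfg, shared_effect_corr = 0.5, n_per_group2 = 6)
  expect_equal(ncol(s2$study1$counts), 8)
  expect_equal(ncol(s2$study2$counts), 12)

  expect_error(simulate_two_studies(cfg, shared_effect_corr = 1.3),
               class = "revsig_config_error")
})

test_that("feature-level simulation plants logit usage shifts without moving totals", {
  cfg <- sim_config(n_genes = 150, n_per_group = 10,
                    libsize_meanlog = log(3e5), seed = 9)
  fs <- simulate_feature_counts(cfg, features_per_gene = 4,
                                usage_shift_frac = 0.2, usage_shift_delta = 1.5)
  tr <- fs$truth
  expect_gt(length(tr$usage_shift_genes), 0)
  fct <- fs$features
  cond <- fct$samples$condition

  # gene totals equal in expectation across conditions
  tot <- rowsum(fct$counts, fct$features$gene_id)
  cpm_tot <- sweep(tot, 2, colSums(fct$counts), "/")
  ratio <- rowMeans(cpm_tot[tr$usage_shift_genes, cond == "treat"]) /
           rowMeans(cpm_tot[tr$usage_shift_genes, cond == "ctrl"])
  expect_equal(mean(log2(ratio)), 0, tolerance = 0.15)

  # shifted feature's usage proportion moved by ~ the inverse-logit shift
  obs_delta <- exp_delta <- numeric(0)
  for (i in seq_along(tr$usage_shift_genes)) {
    g <- tr$usage_shift_genes[i]
    f <- tr$shift_features[i]
    rows <- fct$features$gene_id == g
    prop <- fct$counts[fct$features$feature_id == f, ] /
      pmax(colSums(fct$counts[rows, , drop = FALSE]), 1)
    p_ctrl <- mean(prop[cond == "ctrl"])
    obs_delta <- c(obs_delta, mean(prop[cond == "treat"]) - p_ctrl)
    exp_delta <- c(exp_delta,
                   stats::plogis(stats::qlogis(p_ctrl) + 1.5) - p_ctrl)
  }
  expect_equal(mean(obs_delta), mean(exp_delta), tolerance = 0.05)
  expect_gt(mean(obs_delta), 0.1)

  # no shift requested -> no shift genes recorded
  f0 <- simulate_feature_counts(cfg, features_per_gene = 3,
                                usage_shift_frac = 0)
  expect_length(f0$truth$usage_shift_genes, 0)

  # single-feature genes cannot carry a shift
  expect_warning(
    f1 <- simulate_feature_counts(sim_config(n_genes = 20, n_per_group = 3,
                                             libsize_meanlog = log(1e5),
                                             seed = 3),
                                  features_per_gene = 1,
                                  usage_shift_frac = 0.5),
    "single-feature")
  expect_length(f1$truth$usage_shift_genes, 0)
})

test_that("an independent cohort can reuse planted ground truth", {
  cfg <- sim_config(n_genes = 300, n_per_group = 4, seed = 21,
                    libsize_meanlog = log(3e5))
  a <- simulate_counts(cfg)
  cfg2 <- cfg
  cfg2$seed <- 22L
  b <- simulate_counts(cfg2, truth = a$truth)
  expect_identical(a$truth$disease_lfc, b$truth$disease_lfc)
  expect_false(identical(a$counts$counts, b$counts$counts))
})
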