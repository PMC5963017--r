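#' Simulation configuration
#'
#' Collects every knob of the negative-binomial count simulator.  The
#' experimental layout mirrors a transgenic Huntington-disease mouse study:
#' two genotypes (`WT`, `disease`) crossed with three treatment doses
#' (`veh`, `low`, `high`), `n_per_group` animals per cell, one tissue.
#'
#' Counts for gene g in sample i are NB with mean
#' `lib_i * mu_g * 2^lfc_gi / sum(mu)` and variance `mu + phi_g mu^2`.
#' A fraction `frac_disease` of genes carries a disease log2 fold change
#' drawn from N(0, `disease_lfc_sd`^2), applied in all disease-genotype
#' samples.  A fraction `reversal_frac` of those genes is reversed by
#' treatment: under dose d the planted effect shrinks to
#' `lfc * (1 - kappa_d)`, so `kappa = 1` is full reversal and `kappa = 0`
#' none.  Gene-wise dispersions are lognormal, library sizes lognormal.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per genotype-by-dose cell (the motivating
#'   study used 9 disease vs 6 control animals; the default 8 gives a
#'   balanced design of comparable size).
#' @param baseline_mean_log Log-mean of the lognormal law for per-gene
#'   relative expression (natural log).
#' @param baseline_sd_log Log-sd of the same law.
#' @param disp_meanlog,disp_sdlog Lognormal law for gene-wise NB
#'   dispersions phi (defaults give a typical bulk RNA-seq range,
#'   median phi ~ 0.22).
#' @param libsize_meanlog Log of the median library size (default 1e7
#'   reads, a standard bulk sequencing depth).
#' @param libsize_sigma Lognormal spread of library sizes.
#' @param frac_disease Fraction of genes in `[0,1]` given a disease effect.
#' @param disease_lfc_sd SD of the planted disease log2 fold changes.
#' @param reversal_frac Fraction of disease genes in `[0,1]` reversed by
#'   treatment.
#' @param kappa_by_dose Named numeric vector mapping dose labels to
#'   reversal coefficients in `[0,1]`.
#' @param tissue Tissue label recorded in the sample annotations.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_per_group = 8L,
                       baseline_mean_log = log(100),
                       baseline_sd_log = 1.5,
                       disp_meanlog = -1.5,
                       disp_sdlog = 0.5,
                       libsize_meanlog = log(1e7),
                       libsize_sigma = 0.3,
                       frac_disease = 0.1,
                       disease_lfc_sd = 1,
                       reversal_frac = 0.8,
                       kappa_by_dose = c(veh = 0, low = 0.3, high = 0.8),
                       tissue = "striatum",
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
              baseline_mean_log = baseline_mean_log,
              baseline_sd_log = baseline_sd_log,
              disp_meanlog = disp_meanlog, disp_sdlog = disp_sdlog,
              libsize_meanlog = libsize_meanlog, libsize_sigma = libsize_sigma,
              frac_disease = frac_disease, disease_lfc_sd = disease_lfc_sd,
              reversal_frac = reversal_frac, kappa_by_dose = kappa_by_dose,
              tissue = tissue, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_per_group < 1L) {
    abort("`n_genes` and `n_per_group` must be positive integers.",
          class = "revsig_config_error")
  }
  fr <- c(frac_disease = cfg$frac_disease, reversal_frac = cfg$reversal_frac)
  if (any(fr < 0 | fr > 1)) {
    abort("Fractions must lie in [0, 1].", class = "revsig_config_error")
  }
  if (any(cfg$kappa_by_dose < 0 | cfg$kappa_by_dose > 1)) {
    abort("All reversal coefficients kappa must lie in [0, 1].",
          class = "revsig_config_error")
  }
  sc <- c(cfg$baseline_sd_log, cfg$disp_sdlog, cfg$libsize_sigma,
          cfg$disease_lfc_sd)
  if (any(sc <= 0)) {
    abort("Scale parameters must be > 0.", class = "revsig_config_error")
  }
  invisible(cfg)
}

# Draw per-gene baseline relative expression and NB dispersions.
draw_gene_params <- function(cfg) {
  list(mu = rlnorm(cfg$n_genes, cfg$baseline_mean_log, cfg$baseline_sd_log),
       phi = rlnorm(cfg$n_genes, cfg$disp_meanlog, cfg$disp_sdlog))
}

# NB draws for a mean matrix with gene-wise dispersion (rows = genes).
rnbinom_matrix <- function(mu, phi) {
  n <- ncol(mu)
  cts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                        size = rep(1 / phi, times = n)),
                nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(cts) <- "integer"
  cts
}

#' Simulate a count matrix with planted disease and reversal effects
#'
#' @param config A [sim_config()].
#' @param truth Optional `ground_truth` from a previous call: reuse its
#'   planted disease genes, effects and reversal set so that an independent
#'   cohort (fresh noise, baselines and library sizes) measures the same
#'   biology — the setting in which a disease signature from one study is
#'   queried against a treatment signature from another.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (a `ground_truth` list: `disease_genes`, `disease_lfc`,
#'   `reversed_genes`, `usage_shift_genes`).
#' @export
simulate_counts <- function(config, truth = NULL) {
  validate_sim_config(config)
  if (is.null(truth)) {
    with_seed(config$seed, simulate_counts_impl(config))
  } else {
    with_seed(config$seed, simulate_counts_impl(
      config, lfc = truth$disease_lfc,
      disease_genes = truth$disease_genes,
      reversed_genes = truth$reversed_genes))
  }
}

simulate_counts_impl <- function(config, genotypes = c("WT", "disease"),
                                 doses = names(config$kappa_by_dose),
                                 study_id = NA_character_,
                                 lfc = NULL, disease_genes = NULL,
                                 reversed_genes = NULL) {
  cfg <- config
  gid <- sprintf("g%04d", seq_len(cfg$n_genes))
  gp <- draw_gene_params(cfg)

  if (is.null(disease_genes)) {
    n_dis <- round(cfg$frac_disease * cfg$n_genes)
    disease_genes <- sort(sample(gid, n_dis))
    lfc <- setNames(rnorm(n_dis, 0, cfg$disease_lfc_sd), disease_genes)
    reversed_genes <- sort(sample(disease_genes,
                                  round(cfg$reversal_frac * n_dis)))
  }

  cells <- expand.grid(dose = doses, genotype = genotypes,
                       stringsAsFactors = FALSE)[, c("genotype", "dose")]
  samples <- tibble(
    genotype = rep(cells$genotype, each = cfg$n_per_group),
    dose = rep(cells$dose, each = cfg$n_per_group),
    tissue = cfg$tissue
  )
  samples$sample_id <- sprintf("%s_%s_%02d", samples$genotype, samples$dose,
                               stats::ave(seq_len(nrow(samples)),
                                          paste(samples$genotype, samples$dose),
                                          FUN = seq_along))
  if (!is.na(study_id)) samples$study_id <- study_id
  samples <- samples[, c("sample_id", "genotype", "dose", "tissue",
                         intersect("study_id", names(samples)))]

  n_samp <- nrow(samples)
  lib <- rlnorm(n_samp, cfg$libsize_meanlog, cfg$libsize_sigma)

  # Per-gene, per-sample log2 fold change relative to baseline.
  lfc_mat <- matrix(0, cfg$n_genes, n_samp, dimnames = list(gid, samples$sample_id))
  if (length(disease_genes) > 0L) {
    is_dis_sample <- samples$genotype == "disease"
    lfc_mat[disease_genes, is_dis_sample] <- lfc[disease_genes]
    for (d in doses) {
      kap <- cfg$kappa_by_dose[[d]]
      idx <- which(is_dis_sample & samples$dose == d)
      if (kap > 0 && length(idx) > 0L && length(reversed_genes) > 0L) {
        lfc_mat[reversed_genes, idx] <- lfc[reversed_genes] * (1 - kap)
      }
    }
  }

  mu <- (gp$mu / sum(gp$mu)) * 2^lfc_mat
  mu <- sweep(mu, 2L, lib, `*`)
  cts <- rnbinom_matrix(mu, gp$phi)

  truth <- structure(list(disease_genes = disease_genes,
                          disease_lfc = lfc,
                          reversed_genes = reversed_genes,
                          usage_shift_genes = character(0)),
                     class = "ground_truth")
  list(counts = count_matrix(cts, samples), truth = truth)
}

#' Simulate two independent studies of one disease effect
#'
#' Emulates a meta-analysis setting: two case-control cohorts (genotype
#' `disease` vs `WT`, vehicle only) measure the same disease genes, whose
#' per-study log2 fold changes are draws from a bivariate normal with the
#' given correlation.  Noise, library sizes and baseline expression are
#' independent between studies.
#'
#' @param config A [sim_config()].
#' @param shared_effect_corr Correlation in `[0, 1]` of the two studies'
#'   planted log2 fold changes.
#' @param n_per_group2 Optional sample size per group for the second study
#'   (defaults to the first study's).
#' @return A list with `study1`, `study2` (count matrices) and `truth`; the
#'   ground truth records per-study effects in `disease_lfc` (study 1) and
#'   `disease_lfc2` (study 2).
#' @export
simulate_two_studies <- function(config, shared_effect_corr,
                                 n_per_group2 = NULL) {
  validate_sim_config(config)
  if (!is.numeric(shared_effect_corr) || length(shared_effect_corr) != 1L ||
      shared_effect_corr < 0 || shared_effect_corr > 1) {
    abort("`shared_effect_corr` must be a single value in [0, 1].",
          class = "revsig_config_error")
  }
  with_seed(config$seed, {
    cfg <- config
    gid <- sprintf("g%04d", seq_len(cfg$n_genes))
    n_dis <- round(cfg$frac_disease * cfg$n_genes)
    disease_genes <- sort(sample(gid, n_dis))
    z1 <- rnorm(n_dis)
    z2 <- rnorm(n_dis)
    rho <- shared_effect_corr
    lfc1 <- setNames(cfg$disease_lfc_sd * z1, disease_genes)
    lfc2 <- setNames(cfg$disease_lfc_sd * (rho * z1 + sqrt(1 - rho^2) * z2),
                     disease_genes)
    if (rho == 1) lfc2 <- lfc1  # exact equality, not up to rounding

    cfg2 <- cfg
    if (!is.null(n_per_group2)) cfg2$n_per_group <- as.integer(n_per_group2)
    s1 <- simulate_counts_impl(cfg, doses = "veh", study_id = "study1",
                               lfc = lfc1, disease_genes = disease_genes,
                               reversed_genes = character(0))
    s2 <- simulate_counts_impl(cfg2, doses = "veh", study_id = "study2",
                               lfc = lfc2, disease_genes = disease_genes,
                               reversed_genes = character(0))
    truth <- structure(list(disease_genes = disease_genes,
                            disease_lfc = lfc1, disease_lfc2 = lfc2,
                            reversed_genes = character(0),
                            usage_shift_genes = character(0)),
                       class = "ground_truth")
    list(study1 = s1$counts, study2 = s2$counts, truth = truth)
  })
}

#' Simulate exon/junction-level counts with planted usage shifts
#'
#' Generates a two-condition feature-level count table of the kind produced
#' by flattened-annotation exon/junction counting.  Gene totals are NB with
#' equal means in both conditions; each gene's total is split across its
#' features by a Dirichlet-multinomial.  For usage-shift genes, one
#' randomly chosen feature's expected proportion is shifted by
#' `usage_shift_delta` on the logit scale in the `treat` condition, with
#' the remaining features rescaled, so gene-level totals are unchanged in
#' expectation while relative usage moves.
#'
#' @param config A [sim_config()]; `n_genes`, `n_per_group`, the baseline
#'   and dispersion laws, the library-size law and `seed` are used.
#' @param features_per_gene Integer (scalar or per-gene vector, >= 1):
#'   number of exon/junction features per gene.
#' @param usage_shift_frac Fraction of genes given a usage shift.
#' @param usage_shift_delta Logit-scale shift applied to one feature's
#'   usage proportion in the treated condition.
#' @param dirichlet_conc Dirichlet concentration controlling
#'   sample-to-sample usage overdispersion (larger = closer to
#'   multinomial).
#' @return A list with `features` (a `feature_counts` object: `features`
#'   tibble, integer `counts` matrix, `samples` tibble with a `condition`
#'   column) and `truth` (usage-shift genes plus the shifted feature and
#'   its logit delta).
#' @export
simulate_feature_counts <- function(config, features_per_gene = 4L,
                                    usage_shift_frac = 0.1,
                                    usage_shift_delta = 1,
                                    dirichlet_conc = 50) {
  validate_sim_config(config)
  if (usage_shift_frac < 0 || usage_shift_frac > 1) {
    abort("`usage_shift_frac` must lie in [0, 1].", class = "revsig_config_error")
  }
  with_seed(config$seed, {
    cfg <- config
    gid <- sprintf("g%04d", seq_len(cfg$n_genes))
    k <- rep_len(as.integer(features_per_gene), cfg$n_genes)
    if (any(k < 1L)) {
      abort("`features_per_gene` must be >= 1.", class = "revsig_config_error")
    }
    gp <- draw_gene_params(cfg)

    n_per <- cfg$n_per_group
    samples <- tibble(
      sample_id = sprintf("%s_%02d", rep(c("ctrl", "treat"), each = n_per),
                          rep(seq_len(n_per), 2L)),
      condition = rep(c("ctrl", "treat"), each = n_per),
      genotype = rep(c("WT", "disease"), each = n_per),
      dose = rep(c("veh", "high"), each = n_per),
      tissue = cfg$tissue
    )
    n_samp <- nrow(samples)
    lib <- rlnorm(n_samp, cfg$libsize_meanlog, cfg$libsize_sigma)
    mu <- outer(gp$mu / sum(gp$mu), lib)
    totals <- rnbinom_matrix(matrix(mu, cfg$n_genes, n_samp,
                                    dimnames = list(gid, samples$sample_id)),
                             gp$phi)

    # select shift genes among multi-feature genes only
    n_shift <- round(usage_shift_frac * cfg$n_genes)
    eligible <- gid[k >= 2L]
    if (n_shift > 0L && length(eligible) < n_shift) {
      warn(sprintf(
        "Only %d of %d requested usage-shift genes have >= 2 features; single-feature genes excluded.",
        length(eligible), n_shift))
      n_shift <- length(eligible)
    }
    shift_genes <- if (n_shift > 0L) sort(sample(eligible, n_shift)) else character(0)

    feat_rows <- list()
    cts_rows <- list()
    shift_feature <- character(0)
    for (g in seq_len(cfg$n_genes)) {
      kg <- k[g]
      fid <- sprintf("%s:f%02d", gid[g], seq_len(kg))
      ftype <- rep(c("exon", "junction"), length.out = kg)
      # baseline usage proportions, moderately uneven
      base_p <- as.vector(rdirichlet_one(rep(5, kg)))
      p_by_cond <- list(ctrl = base_p, treat = base_p)
      if (gid[g] %in% shift_genes) {
        j <- sample.int(kg, 1L)
        shift_feature <- c(shift_feature, fid[j])
        pj <- stats::plogis(stats::qlogis(base_p[j]) + usage_shift_delta)
        p_t <- base_p * (1 - pj) / (1 - base_p[j])
        p_t[j] <- pj
        p_by_cond$treat <- p_t
      }
      cts_g <- matrix(0L, kg, n_samp)
      for (s in seq_len(n_samp)) {
        p <- p_by_cond[[samples$condition[s]]]
        ps <- if (kg == 1L) 1 else as.vector(rdirichlet_one(dirichlet_conc * p))
        cts_g[, s] <- if (kg == 1L) totals[g, s] else
          as.vector(rmultinom(1L, totals[g, s], ps))
      }
      feat_rows[[g]] <- tibble(gene_id = gid[g], feature_id = fid,
                               feature_type = ftype)
      cts_rows[[g]] <- cts_g
    }
    features <- bind_rows(feat_rows)
    cts <- do.call(rbind, cts_rows)
    dimnames(cts) <- list(features$feature_id, samples$sample_id)
    storage.mode(cts) <- "integer"
    fct <- structure(list(features = features, counts = cts, samples = samples),
                     class = "feature_counts")
    truth <- structure(list(disease_genes = character(0),
                            disease_lfc = setNames(numeric(0), character(0)),
                            reversed_genes = character(0),
                            usage_shift_genes = shift_genes,
                            shift_features = shift_feature,
                            usage_shift_delta = usage_shift_delta),
                       class = "ground_truth")
    list(features = fct, truth = truth)
  })
}

# One Dirichlet draw via normalized gammas.
rdirichlet_one <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("<feature_counts> %d features in %d genes x %d samples\n",
              nrow(x$counts), length(unique(x$features$gene_id)),
              ncol(x$counts)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d disease genes (%d reversed), %d usage-shift genes\n",
              length(x$disease_genes), length(x$reversed_genes),
              length(x$usage_shift_genes)))
  invisible(x)
}
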