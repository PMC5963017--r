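test_that("voom-style weights are positive, finite and trend-decreasing", {
  cfg <- sim_config(n_genes = 600, n_per_group = 5, frac_disease = 0,
                    disp_meanlog = -6, disp_sdlog = 0.01,  # near-Poisson
                    libsize_meanlog = log(5e5), kappa_by_dose = c(veh = 0),
                    seed = 4)
  sim <- simulate_counts(cfg)
  cm <- filter_low_count(sim$counts, 1)
  nf <- tmm_factors(cm)
  l <- log_cpm(cm, nf)
  d <- build_design(cm$samples)$design
  eff <- nf$eff_lib_size
  w <- voom_weights(l, eff, d)
  expect_true(all(is.finite(w) & w > 0))

  # near-Poisson counts: sd of log-CPM falls with abundance, so weights rise
  a <- rowMeans(l)
  lo_bin <- a < quantile(a, 0.3)
  hi_bin <- a > quantile(a, 0.7)
  expect_gt(mean(w[hi_bin, ]), mean(w[lo_bin, ]))

  # constant gene: zero residual sd floored, weights finite
  l2 <- rbind(l, const = rep(3, ncol(l)))
  w2 <- voom_weights(l2, eff, d)
  expect_true(all(is.finite(w2["const", ])))
})

test_that("weighted least squares matches closed forms and the OLS oracle", {
  withr::with_seed(8, {
    n <- 8
    X <- cbind(a = rep(c(1, 0), each = 4), b = rep(c(0, 1), each = 4))
    y <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    fit <- fit_linear(y, X)
    # group-means design: coefficients are the group means
    expect_equal(fit$coefficients[, "a"], rowMeans(y[, 1:4]))
    expect_equal(fit$coefficients[, "b"], rowMeans(y[, 5:8]))
    for (i in 1:5) {
      o <- oracle_ols(y[i, ], X)
      expect_equal(unname(fit$coefficients[i, ]), unname(o$coef))
      expect_equal(fit$s2[i], o$s2)
    }
    # random weights against a weighted oracle via transformed OLS
    w <- matrix(runif(5 * n, 0.2, 3), 5, n)
    fw <- fit_linear(y, X, weights = w)
    for (i in 1:5) {
      o <- oracle_ols(y[i, ] * sqrt(w[i, ]), X * sqrt(w[i, ]))
      expect_equal(unname(fw$coefficients[i, ]), unname(o$coef))
    }
    Xbad <- cbind(X, a2 = X[, "a"])
    expect_error(fit_linear(y, Xbad), "a2", class = "revsig_design_error")
  })
})

test_that("moderated t has the exact d0 -> 0 and d0 -> Inf limits", {
  withr::with_seed(1, {
    g <- 50
    coef <- rnorm(g)
    se_u <- runif(g, 0.2, 1)
    s2 <- rchisq(g, 5) / 5
    df <- 6
    t_ord <- coef / (se_u * sqrt(s2))
    m0 <- moderate_t(coef, se_u, s2, df, d0 = 0, s0_sq = 0.7)
    expect_equal(m0$t_mod, t_ord)
    expect_equal(m0$s2_post, s2)
    mInf <- moderate_t(coef, se_u, s2, df, d0 = Inf, s0_sq = 0.7)
    expect_equal(mInf$s2_post, rep(0.7, g))
    expect_equal(mInf$t_mod, coef / (se_u * sqrt(0.7)))
  })
})

test_that("eBayes moment estimation recovers known hyperparameters", {
  withr::with_seed(3, {
    df <- 10
    s2 <- 0.25 * stats::rf(5000, df1 = df, df2 = 4)
    eb <- ebayes_moderate(s2, df)
    expect_lt(abs(eb$d0 - 4) / 4, 0.2)
    expect_lt(abs(eb$s0_sq - 0.25) / 0.25, 0.1)
  })
  expect_error(ebayes_moderate(rep(1, 5), 4), class = "revsig_config_error")
})

test_that("eBayes prior agrees with limma's squeezeVar on real fits", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_genes = 400, n_per_group = 5, kappa_by_dose = c(veh = 0),
                    libsize_meanlog = log(5e5), seed = 6)
  sim <- simulate_counts(cfg)
  cm <- filter_low_count(sim$counts)
  l <- log_cpm(cm, tmm_factors(cm))
  fit <- fit_linear(l, build_design(cm$samples)$design)
  eb <- ebayes_moderate(fit$s2, fit$df_resid)
  sq <- limma::squeezeVar(fit$s2, fit$df_resid)
  expect_equal(eb$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(eb$s0_sq, sq$var.prior, tolerance = 0.01)
  expect_equal(eb$s2_post, sq$var.post, tolerance = 0.01)
})

test_that("BH adjustment matches hand examples and preserves ordering", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 7)), rep(0.04, 7))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696)
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), class = "revsig_config_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "revsig_config_error")
})

test_that("run_contrast is antisymmetric under label swap and deterministic", {
  cfg <- sim_config(n_genes = 300, n_per_group = 4, kappa_by_dose = c(veh = 0),
                    libsize_meanlog = log(5e5), seed = 10)
  sim <- simulate_counts(cfg)
  de1 <- run_contrast(sim$counts, "A")
  de2 <- run_contrast(sim$counts, "WT.veh - disease.veh")
  expect_equal(de1$log2FC, -de2$log2FC)
  expect_equal(de1$t_mod, -de2$t_mod)
  expect_equal(de1$adj_p, de2$adj_p)
  expect_identical(sign(de1$t_mod), sign(de1$log2FC))
  expect_true(all(de1$adj_p >= de1$p))
  expect_identical(de1$log2FC, run_contrast(sim$counts, "A")$log2FC)
  expect_error(run_contrast(sim$counts, "B"), class = "revsig_design_error")
  expect_error(run_contrast(sim$counts, "A", tissue = "cortex"),
               class = "revsig_design_error")
})

test_that("PCA screening flags a corrupted sample and respects ordering", {
  withr::with_seed(12, {
    l <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
    expect_length(pca_outlier_screen(l), 0)
    l[, 4] <- l[, 4] + 8          # gross library-scale corruption
    flagged <- pca_outlier_screen(l)
    expect_true("s4" %in% flagged)
    perm <- sample(10)
    expect_identical(pca_outlier_screen(l[, perm]), flagged)
    same <- matrix(5, 30, 4, dimnames = list(NULL, paste0("s", 1:4)))
    expect_length(pca_outlier_screen(same), 0)
  })
})
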