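#' Build a group-means design matrix from sample annotations
#'
#' Encodes each genotype-by-dose cell as its own column (a group-means
#' parameterization, so contrasts are differences of cell means), with
#' optional additional covariate columns taken from the sample table.
#'
#' @param samples Sample annotation tibble with `genotype` and `dose`.
#' @param covariates Optional character vector of extra sample columns to
#'   adjust for (added as main-effect terms).
#' @return A list with `design` (matrix, rows = samples) and `groups`
#'   (per-sample group labels `genotype.dose`).
#' @export
build_design <- function(samples, covariates = NULL) {
  groups <- paste(samples$genotype, samples$dose, sep = ".")
  gf <- factor(groups, levels = unique(groups))
  design <- model.matrix(~ 0 + gf)
  colnames(design) <- levels(gf)
  if (!is.null(covariates)) {
    for (cv in covariates) {
      if (!cv %in% names(samples)) {
        abort(paste0("Covariate column not found: ", cv),
              class = "revsig_config_error")
      }
      v <- samples[[cv]]
      mm <- if (is.numeric(v)) matrix(v, ncol = 1, dimnames = list(NULL, cv))
            else model.matrix(~ factor(v))[, -1, drop = FALSE]
      design <- cbind(design, mm)
    }
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    abort(paste0("Design matrix is not full rank; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "revsig_design_error")
  }
  list(design = design, groups = groups)
}

# The study's named contrasts as group-difference expressions.
named_contrasts <- c(
  A = "disease.veh - WT.veh",
  B = "disease.high - disease.veh",
  C = "disease.low - disease.veh",
  D = "WT.high - WT.veh",
  E = "WT.high - WT.veh"  # blood tissue instance of the same comparison
)

# Parse "grpX - grpY" into a numeric contrast vector over design columns.
contrast_vector <- function(design, contrast) {
  expr <- if (contrast %in% names(named_contrasts)) {
    named_contrasts[[contrast]]
  } else {
    contrast
  }
  parts <- strsplit(expr, "\\s*-\\s*")[[1]]
  if (length(parts) != 2L) {
    abort(paste0("Cannot parse contrast '", contrast,
                 "'; expected 'groupA - groupB'."),
          class = "revsig_design_error")
  }
  miss <- setdiff(parts, colnames(design))
  if (length(miss) > 0L) {
    abort(paste0("Contrast '", contrast, "' involves absent group(s): ",
                 paste(miss, collapse = ", ")),
          class = "revsig_design_error")
  }
  cv <- setNames(numeric(ncol(design)), colnames(design))
  cv[parts[1L]] <- 1
  cv[parts[2L]] <- -1
  cv
}

#' Precision weights from the log-CPM mean-variance trend
#'
#' Fits unweighted gene-wise linear models, smooths the square-root
#' residual standard deviation against average log2 count with a locally
#' weighted regression, and converts each observation's predicted standard
#' deviation (at its own fitted log-count) into an inverse fourth-power
#' precision weight.  Zero residual standard deviations (constant genes)
#' are floored at a small positive constant so weights stay finite.
#'
#' @param logcpm Numeric matrix of log2-CPM values (genes x samples).
#' @param eff_lib Effective library sizes, one per sample (library size x
#'   TMM factor).
#' @param design Design matrix (rows = samples).
#' @param span Span of the lowess smoother (default 0.5).
#' @return A positive weight matrix with the dimensions of `logcpm`.
#' @export
voom_weights <- function(logcpm, eff_lib, design, span = 0.5) {
  n <- ncol(logcpm)
  p <- ncol(design)
  if (n - p < 1L) {
    abort("Fewer than one residual degree of freedom.",
          class = "revsig_design_error")
  }
  qrX <- qr(design)
  coef <- t(qr.coef(qrX, t(logcpm)))
  fitted <- coef %*% t(design)
  res <- logcpm - fitted
  s <- sqrt(rowSums(res^2) / (n - p))
  s <- pmax(s, 1e-4)

  # mean log2 count of each gene, and per-observation fitted log2 count
  off <- log2(eff_lib + 1) - log2(1e6)
  sx <- rowMeans(logcpm) + mean(off)
  sy <- sqrt(s)
  lo <- lowess(sx, sy, f = span)
  fitted_logcount <- sweep(fitted, 2L, off, `+`)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted_logcount), rule = 2,
                 ties = "ordered")$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(pred^-4, nrow = nrow(logcpm), dimnames = dimnames(logcpm))
  w
}

#' Gene-wise weighted least squares
#'
#' Fits the same design to every gene with gene-specific observation
#' weights, returning coefficients, residual variances and the unscaled
#' covariance factors needed for contrast standard errors.
#'
#' @param y Response matrix (genes x samples), e.g. log2-CPM.
#' @param design Design matrix (samples x coefficients), full rank.
#' @param weights Positive weight matrix matching `y`, or `NULL` for
#'   ordinary least squares.
#' @return A `de_fit` list: `coefficients` (genes x p), `s2`, `df_resid`,
#'   `cov_unscaled` (p x p x genes array), `design`.
#' @export
fit_linear <- function(y, design, weights = NULL) {
  n <- ncol(y)
  p <- ncol(design)
  qrX <- qr(design)
  if (qrX$rank < p) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Design matrix is not full rank; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "revsig_design_error")
  }
  if (n <= p) {
    abort("Need more samples than design columns.",
          class = "revsig_design_error")
  }
  g <- nrow(y)
  coefs <- matrix(NA_real_, g, p, dimnames = list(rownames(y), colnames(design)))
  s2 <- numeric(g)
  covu <- array(NA_real_, c(p, p, g))
  for (i in seq_len(g)) {
    w <- if (is.null(weights)) rep(1, n) else weights[i, ]
    sw <- sqrt(w)
    Xw <- design * sw
    yw <- y[i, ] * sw
    xtx <- crossprod(Xw)
    xtxinv <- chol2inv(chol(xtx))
    b <- drop(xtxinv %*% crossprod(Xw, yw))
    r <- yw - drop(Xw %*% b)
    coefs[i, ] <- b
    s2[i] <- sum(r^2) / (n - p)
    covu[, , i] <- xtxinv
  }
  structure(list(coefficients = coefs, s2 = s2, df_resid = n - p,
                 cov_unscaled = covu, design = design),
            class = "de_fit")
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of a scaled-F model for the gene-wise residual variances by matching
#' moments of `log(s2)` (digamma/trigamma inversion), and shrinks each
#' variance to the posterior `(d0 s0_sq + df s2) / (d0 + df)`.  If the
#' variances are less dispersed than the sampling law allows, `d0` is
#' infinite and every posterior variance equals `s0_sq`.
#'
#' @param s2 Gene-wise residual variances (length >= 10).
#' @param df_resid Residual degrees of freedom (scalar).
#' @return A list: `d0`, `s0_sq`, `s2_post`, `df_total` (= `df_resid + d0`).
#' @export
ebayes_moderate <- function(s2, df_resid) {
  if (length(s2) < 10L) {
    abort("Empirical-Bayes moment estimation needs >= 10 genes.",
          class = "revsig_config_error")
  }
  s2f <- pmax(s2, 1e-8)  # guard exact zeros before taking logs
  df <- df_resid
  z <- log(s2f)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2f)) else
    (d0 * s0_sq + df * s2f) / (d0 + df)
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, df_total = df + d0)
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) {
    warn("Trigamma inversion did not converge; using complete shrinkage (d0 = Inf).")
    return(Inf)
  }
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated and ordinary t-statistics from a fitted contrast
#'
#' Applies the empirical-Bayes shrinkage to a contrast's standard errors:
#' the posterior variance `(d0 s0_sq + df s2) / (d0 + df)` replaces the
#' gene-wise `s2`, and the moderated t is referred to a t distribution with
#' `df + d0` degrees of freedom.  `d0 = 0` recovers the ordinary t exactly;
#' `d0 = Inf` gives the s0-based z-like statistic.
#'
#' @param coef Contrast estimates, one per gene.
#' @param se_unscaled Unscaled standard errors `sqrt(c' (X'WX)^-1 c)`.
#' @param s2 Gene-wise residual variances.
#' @param df_resid Residual degrees of freedom (scalar).
#' @param d0,s0_sq Prior degrees of freedom and prior variance (e.g. from
#'   [ebayes_moderate()]).
#' @return A list: `t_mod`, `p`, `s2_post`.
#' @export
moderate_t <- function(coef, se_unscaled, s2, df_resid, d0, s0_sq) {
  s2f <- pmax(s2, 1e-8)
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2f)) else
    (d0 * s0_sq + df_resid * s2f) / (d0 + df_resid)
  t_mod <- coef / (se_unscaled * sqrt(s2_post))
  p <- 2 * pt(-abs(t_mod), df = df_resid + d0)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(t_mod = t_mod, p = p, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up procedure controlling the false discovery rate:
#' `adj_p_i = min over j with p_j >= p_i of min(1, m p_j / rank_j)`.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort("All p-values must lie in (0, 1].", class = "revsig_config_error")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Screen for outlying samples in principal-component space
#'
#' Projects samples onto the first two principal components of the log-CPM
#' matrix and flags those farther than `k_sd` robust standard deviations
#' (median absolute deviation) from the centroid on either component.
#' Screening only: nothing is removed.
#'
#' @param logcpm Numeric matrix (genes x samples), >= 4 samples.
#' @param k_sd Robust-SD multiplier (default 3).
#' @return Sorted character vector of flagged sample ids (possibly empty).
#' @export
pca_outlier_screen <- function(logcpm, k_sd = 3) {
  if (ncol(logcpm) < 4L) {
    abort("PCA screening needs at least 4 samples.",
          class = "revsig_config_error")
  }
  keep <- apply(logcpm, 1L, function(r) stats::sd(r) > 0)
  if (!any(keep)) return(character(0))
  pc <- prcomp(t(logcpm[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  flagged <- rep(FALSE, ncol(logcpm))
  for (j in seq_len(k)) {
    v <- pc$x[, j]
    s <- mad(v)
    if (s > 0) flagged <- flagged | abs(v - median(v)) > k_sd * s
  }
  sort(colnames(logcpm)[flagged])
}

#' Run one named differential-expression contrast end to end
#'
#' Composes the full chain on a count matrix: low-count filter, TMM
#' normalization, log2-CPM, mean-variance precision weights, gene-wise
#' weighted least squares, empirical-Bayes moderated t-statistics, and
#' Benjamini-Hochberg FDR adjustment.
#'
#' @param cm A [count_matrix()].
#' @param contrast One of the named contrasts `"A"`-`"E"` (disease vs
#'   control; each dose vs vehicle in disease; high dose vs vehicle in
#'   control) or an explicit `"group1 - group2"` expression over
#'   `genotype.dose` labels.
#' @param tissue Optional tissue to subset to before analysis.
#' @param min_mean Low-count filter threshold (default 10 mean reads).
#' @param span Lowess span for the mean-variance trend (default 0.5).
#' @param covariates Optional sample columns to adjust for.
#' @return A `de_result` tibble with one row per retained gene: `gene_id`,
#'   `log2FC`, `avg_expr`, `s2`, `df_resid`, `t_ord`, `t_mod`, `p`,
#'   `adj_p`; attributes `contrast`, `prior` (`d0`, `s0_sq`) and
#'   `df_total`.
#' @export
run_contrast <- function(cm, contrast, tissue = NULL, min_mean = 10,
                         span = 0.5, covariates = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(tissue)) {
    keep <- cm$samples$tissue == tissue
    if (!any(keep)) {
      abort(paste0("No samples in tissue '", tissue, "'."),
            class = "revsig_design_error")
    }
    cm <- subset_counts(cm, samples = cm$samples$sample_id[keep])
  }
  cm <- filter_low_count(cm, min_mean = min_mean)
  nf <- tmm_factors(cm)
  lcpm <- log_cpm(cm, nf)
  ds <- build_design(cm$samples, covariates = covariates)
  cv <- contrast_vector(ds$design, contrast)
  eff <- nf$eff_lib_size[match(colnames(cm$counts), nf$sample_id)]
  w <- voom_weights(lcpm, eff, ds$design, span = span)
  fit <- fit_linear(lcpm, ds$design, weights = w)
  eb <- ebayes_moderate(fit$s2, fit$df_resid)

  coef_c <- drop(fit$coefficients %*% cv)
  se_u <- sqrt(vapply(seq_len(nrow(lcpm)), function(i) {
    drop(t(cv) %*% fit$cov_unscaled[, , i] %*% cv)
  }, numeric(1)))
  s2f <- pmax(fit$s2, 1e-8)
  t_ord <- coef_c / (se_u * sqrt(s2f))
  mod <- moderate_t(coef_c, se_u, fit$s2, fit$df_resid, eb$d0, eb$s0_sq)
  t_mod <- mod$t_mod
  p <- mod$p

  out <- tibble(
    gene_id = rownames(lcpm),
    log2FC = coef_c,
    avg_expr = rowMeans(lcpm),
    s2 = fit$s2,
    df_resid = fit$df_resid,
    t_ord = t_ord,
    t_mod = t_mod,
    p = p,
    adj_p = bh_adjust(p)
  )
  attr(out, "contrast") <- contrast
  attr(out, "prior") <- list(d0 = eb$d0, s0_sq = eb$s0_sq)
  attr(out, "df_total") <- eb$df_total
  class(out) <- c("de_result", class(out))
  out
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  pr <- attr(x, "prior")
  tibble(contrast = attr(x, "contrast") %||% NA_character_,
         n_genes = nrow(x),
         d0 = pr$d0, s0_sq = pr$s0_sq,
         df_resid = x$df_resid[1],
         n_signif = sum(x$adj_p < 0.05))
}
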