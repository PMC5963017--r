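#' Pipeline configuration
#'
#' One object holding every threshold and seed of the end-to-end synthetic
#' run: simulation settings, the contrasts per tissue, the MAQC-style DEG
#' filter, permutation counts and the usage-test settings.  Defaults quote
#' the standard preprocessing choices (mean count >= 10, |linear FC| >
#' 1.25, adjusted p < 0.05).
#'
#' @param sim A [sim_config()]; its seed drives all simulation randomness.
#' @param tissues Tissues to simulate and analyze.
#' @param contrasts Named contrasts to run per tissue.
#' @param min_mean,fc_min,adjp_max,duej_alpha Thresholds.
#' @param n_perm Permutations for reversal/enrichment nulls.
#' @param run_usage Whether to include the exon/junction usage stage.
#' @param usage_n_genes Genes in the feature-level simulation (kept small;
#'   the per-feature GLMs dominate run time).
#' @param seed Master seed for all permutation nulls.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            tissues = "striatum",
                            contrasts = c("A", "B", "C", "D"),
                            min_mean = 10, fc_min = 1.25, adjp_max = 0.05,
                            duej_alpha = 0.05, n_perm = 1000,
                            run_usage = TRUE, usage_n_genes = 150L,
                            seed = 1L) {
  structure(list(sim = sim, tissues = tissues, contrasts = contrasts,
                 min_mean = min_mean, fc_min = fc_min, adjp_max = adjp_max,
                 duej_alpha = duej_alpha, n_perm = n_perm,
                 run_usage = run_usage, usage_n_genes = as.integer(usage_n_genes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic reversal pipeline
#'
#' Simulates counts with planted disease and dose-dependent reversal
#' effects, runs every configured differential-expression contrast per
#' tissue, assembles the disease signature and its directional DEG sets,
#' scores reversal of each treatment contrast against the disease
#' signature, and (optionally) runs the exon/junction usage stage on a
#' matched feature-level simulation.  All randomness flows from the seeds
#' in the config, so two runs with an identical config give byte-identical
#' reports.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, per-stage TSVs and a JSON
#'   `report.json` are written there.
#' @return A `pipeline_report` list: `params`, per-tissue `deg_counts`,
#'   `reversal` (cosine, permutation p, directional verdict per treatment
#'   contrast), `usage` (DUEJ gene counts), and `truth` summaries.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  report <- list(params = list(
    thresholds = list(min_mean = config$min_mean, fc_min = config$fc_min,
                      adjp_max = config$adjp_max,
                      duej_alpha = config$duej_alpha),
    n_perm = config$n_perm,
    sim_seed = config$sim$seed, seed = config$seed))

  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)),
            class = "revsig_pipeline_error")
    })
  }

  tissue_reports <- list()
  for (ti in seq_along(config$tissues)) {
    tissue <- config$tissues[[ti]]
    cfg <- config$sim
    cfg$tissue <- tissue
    cfg$seed <- cfg$seed + (ti - 1L) * 1000L
    sim <- run_stage("simulate", simulate_counts(cfg))

    de <- list()
    for (ct in config$contrasts) {
      de[[ct]] <- run_stage(paste0("de_", ct),
        run_contrast(sim$counts, ct, min_mean = config$min_mean))
    }
    deg <- lapply(de, select_degs, fc_min = config$fc_min,
                  adjp_max = config$adjp_max)
    deg_counts <- lapply(deg, function(d)
      list(up = length(d$up), down = length(d$down),
           total = length(d$up) + length(d$down)))

    rev_rep <- list()
    if ("A" %in% config$contrasts &&
        (length(deg$A$up) > 0L || length(deg$A$down) > 0L)) {
      disease_sig <- as_signature(de$A)
      sets <- run_stage("reversal_sets",
                        make_reversal_sets(deg$A, label = "DISEASE"))
      for (ct in intersect(c("B", "C"), config$contrasts)) {
        rv <- run_stage(paste0("reversal_", ct),
          reversal_test(disease_sig, as_signature(de[[ct]]), sets,
                        n_perm = config$n_perm,
                        seed = config$seed + ti * 100L +
                          match(ct, c("B", "C"))))
        rev_rep[[ct]] <- list(cosine = rv$cosine, n_shared = rv$n_shared,
                              perm_p = rv$perm_p, reversed = rv$reversed)
      }
    }

    usage_rep <- NULL
    if (isTRUE(config$run_usage)) {
      ucfg <- cfg
      ucfg$n_genes <- config$usage_n_genes
      ucfg$seed <- cfg$seed + 7L
      fsim <- run_stage("simulate_features", simulate_feature_counts(ucfg))
      du <- run_stage("duej", duej_test(fsim$features,
                                        alpha = config$duej_alpha))
      usage_rep <- list(n_genes_tested = nrow(du$genes),
                        n_signif = sum(du$genes$significant))
      stages[[paste0(tissue, "_duej")]] <- du
    }

    tissue_reports[[tissue]] <- list(
      deg_counts = deg_counts, reversal = rev_rep, usage = usage_rep,
      truth = list(n_disease = length(sim$truth$disease_genes),
                   n_reversed = length(sim$truth$reversed_genes)))
    stages[[paste0(tissue, "_de")]] <- de
    stages[[paste0(tissue, "_counts")]] <- sim$counts
  }
  report$tissues <- tissue_reports

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (tissue in config$tissues) {
      write_counts(stages[[paste0(tissue, "_counts")]],
                   file.path(outdir, paste0("counts_", tissue, ".tsv")))
      for (ct in names(stages[[paste0(tissue, "_de")]])) {
        write.table(as.data.frame(stages[[paste0(tissue, "_de")]][[ct]]),
                    file.path(outdir, sprintf("de_%s_%s.tsv", tissue, ct)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(c(report, list(objects = stages)), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (tissue in names(x$tissues)) {
    tr <- x$tissues[[tissue]]
    cat(sprintf("  %s: DEGs %s", tissue,
                paste(names(tr$deg_counts),
                      vapply(tr$deg_counts, function(d) d$total, numeric(1)),
                      sep = "=", collapse = ", ")))
    if (length(tr$reversal) > 0L) {
      cat("; reversal:",
          paste(names(tr$reversal),
                vapply(tr$reversal, function(r)
                  sprintf("cos=%.2f %s", r$cosine,
                          if (isTRUE(r$reversed)) "REV" else "-"),
                  character(1)),
                sep = " ", collapse = ", "))
    }
    cat("\n")
  }
  invisible(x)
}
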