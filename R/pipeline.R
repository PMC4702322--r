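#' Run workflow preparation plus differential expression
#'
#' Convenience wrapper tying [apply_workflow()] to the two DE engines while
#' honoring each workflow's stage order: NB dispersions are estimated on
#' the workflow's *estimation* matrix (all genes in workflow 1, the
#' filtered re-normalized genes in workflow 2) and carried over to the
#' filtered test matrix.
#'
#' @inheritParams run_pipeline
#' @param terms optional subset of term names to test (passed through).
#' @return A list: `de` (`de_table_set`), `prep` (the [apply_workflow()]
#'   result), `dispersions` (`NULL` for the ln-ANOVA engine).
#' @export
workflow_de <- function(config, counts, intergenic, features, design,
                        engine = c("nbglm", "lnanova"), terms = NULL) {
  engine <- match.arg(engine)
  prep <- apply_workflow(counts, intergenic, features, config)
  if (engine == "lnanova") {
    de <- ln_anova(prep$matrix, design, fdr_level = config$fdr_level)
    if (!is.null(terms)) de <- structure(de[terms], class = "de_table_set")
    return(list(de = de, prep = prep, dispersions = NULL))
  }
  est_counts <- rounded_view(prep$estimation)
  dat <- design[match(colnames(est_counts), design$sample_id), ]
  disp <- estimate_dispersions(est_counts, dat,
                               mode = config$dispersion_mode)
  de <- test_terms(rounded_view(prep$matrix), design,
                   approach = config$interaction_approach,
                   dispersions = disp$final,
                   fdr_level = config$fdr_level, terms = terms)
  list(de = de, prep = prep, dispersions = disp)
}

#' Run the full analysis pipeline and write results to disk
#'
#' Chains the stages of the framework for one configuration: workflow
#' filtering + normalization, differential expression with the configured
#' engine inputs, and BH-flagged per-term tables, writing everything as TSV
#' plus a JSON run manifest. With the same inputs and seed the output files
#' are byte-identical across reruns.
#'
#' @param config an [analysis_config()].
#' @param counts genic (+ spike-in) `count_matrix`.
#' @param intergenic intergenic `count_matrix` (may be `NULL` for
#'   workflow 3).
#' @param features a `feature_table`.
#' @param design a `sample_design`.
#' @param out_dir output directory (created if needed).
#' @param engine `"nbglm"` or `"lnanova"`.
#' @return Invisibly, a list: `de` (`de_table_set`), `prepared` (the
#'   workflow output), `manifest` (written to `manifest.json`).
#' @export
run_pipeline <- function(config, counts, intergenic, features, design,
                         out_dir, engine = c("nbglm", "lnanova")) {
  stopifnot(inherits(config, "analysis_config"))
  engine <- match.arg(engine)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[countbench] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$rng_seed)
  prep <- stage("workflow", apply_workflow(counts, intergenic, features,
                                           config))
  stage("write_normalized", {
    nm <- prep$matrix
    df <- data.frame(gene_id = rownames(nm$values), nm$values,
                     check.names = FALSE)
    write_result_table(df, file.path(out_dir, "normalized.tsv"))
    if (!is.null(prep$threshold)) {
      thr <- prep$threshold
      write_result_table(
        data.frame(method = thr$method, threshold = thr$threshold,
                   percentile = thr$percentile,
                   n_intergenic = thr$n_intergenic,
                   n_genes_removed = length(prep$removed)),
        file.path(out_dir, "threshold.tsv"))
    }
  })
  de <- stage("differential_expression", {
    if (engine == "nbglm") {
      if (config$count_input_mode == "rounded") {
        workflow_de(config, counts, intergenic, features, design,
                    engine = "nbglm")$de
      } else {
        f <- prep$matrix$factors
        if (is.null(f))
          stop("offset mode requires a per-sample scaling method")
        keep <- rownames(prep$matrix$values)
        raw <- subset_counts(counts, genes = keep)
        test_terms(raw$counts, design,
                   approach = config$interaction_approach,
                   dispersion_mode = config$dispersion_mode,
                   offsets = log(f[raw$sample_ids]),
                   fdr_level = config$fdr_level)
      }
    } else {
      ln_anova(prep$matrix, design, fdr_level = config$fdr_level)
    }
  })
  stage("write_de_tables", {
    for (tm in names(de))
      write_result_table(de[[tm]],
                         file.path(out_dir, paste0("de_", tm, ".tsv")))
  })
  manifest <- list(
    package = "countbench",
    config = unclass(config), engine = engine,
    n_genes_in = nrow(counts$counts), n_samples = ncol(counts$counts),
    n_genes_tested = nrow(prep$matrix$values),
    n_removed = length(prep$removed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(de = de, prepared = prep, manifest = manifest))
}
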