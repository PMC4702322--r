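#' Empirical low-expression threshold from intergenic background
#'
#' Genic and intergenic rows are pooled into one matrix and normalized
#' together by the requested method; the threshold is then a percentile
#' (default 95th) of the pooled intergenic values on the
#' `log2(normalized + 1)` scale. Intergenic features shorter than the read
#' length cannot receive uniquely mapped reads and must be excluded before
#' calling this function (see [feature_table()]'s `valid_intergenic` flag).
#'
#' @param genic a `count_matrix` of genic rows.
#' @param intergenic a `count_matrix` of intergenic rows over the same
#'   samples.
#' @param method normalization method name.
#' @param percentile percentile of the intergenic distribution (default 95).
#' @param features `feature_table` (needed for RPKM).
#' @return A list of class `threshold_result`: `method`, `threshold` (on
#'   log2(normalized + 1)), `percentile`, `n_intergenic`.
#' @export
empirical_threshold <- function(genic, intergenic, method, percentile = 95,
                                features = NULL) {
  stopifnot(inherits(genic, "count_matrix"),
            inherits(intergenic, "count_matrix"))
  if (nrow(intergenic$counts) == 0L) stop("no intergenic features supplied")
  if (!identical(genic$sample_ids, intergenic$sample_ids))
    stop("genic and intergenic matrices cover different samples")
  pooled <- count_matrix(rbind(genic$counts, intergenic$counts),
                         library_sizes = genic$library_sizes)
  nm <- normalize_counts(pooled, method, features = features)
  iv <- nm$values[intergenic$gene_ids, , drop = FALSE]
  thr <- quantile7(log2(as.vector(iv) + 1), percentile / 100)
  structure(list(method = method, threshold = thr, percentile = percentile,
                 n_intergenic = nrow(intergenic$counts)),
            class = "threshold_result")
}

#' @exportS3Method base::print
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result (%s): %.4g log2(normalized+1) at the %gth percentile of %d intergenic features\n",
    x$method, x$threshold, x$percentile, x$n_intergenic))
  invisible(x)
}

#' Remove genes below the detection threshold in every sample
#'
#' A gene is kept if its `log2(normalized value + 1)` reaches the threshold
#' in at least one sample; a gene above threshold in a single individual is
#' retained. Filtering with the same threshold twice removes nothing the
#' second time.
#'
#' @param nm a `normalized_matrix` on the same normalization scale as the
#'   threshold.
#' @param threshold a `threshold_result` (its `method` must match
#'   `nm$method`).
#' @return A list: `matrix` (filtered `normalized_matrix`), `removed`
#'   (gene ids), `n_removed`.
#' @export
filter_low_expression <- function(nm, threshold) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(threshold, "threshold_result"))
  if (!identical(nm$method, threshold$method))
    stop("scale mismatch: threshold derived under ", threshold$method,
         " but matrix is ", nm$method, "-normalized")
  keep <- apply(log2(nm$values + 1), 1L, max) >= threshold$threshold
  out <- nm
  out$values <- nm$values[keep, , drop = FALSE]
  list(matrix = out, removed = rownames(nm$values)[!keep],
       n_removed = sum(!keep))
}

#' Remove non-protein-coding features from a matrix
#'
#' @param m a matrix, `count_matrix` or `normalized_matrix`.
#' @param features a `feature_table` with `coding_class`.
#' @return Same class as the input, restricted to protein-coding rows, with
#'   attribute `"removed"` listing the dropped feature ids.
#' @export
filter_noncoding <- function(m, features) {
  stopifnot(inherits(features, "feature_table"))
  ids <- if (inherits(m, "count_matrix")) m$gene_ids
         else if (inherits(m, "normalized_matrix")) rownames(m$values)
         else rownames(m)
  cc <- features$coding_class[match(ids, features$feature_id)]
  keep <- !is.na(cc) & cc == "protein_coding"
  removed <- ids[!keep]
  out <- if (inherits(m, "count_matrix")) subset_counts(m, genes = keep)
         else if (inherits(m, "normalized_matrix")) {
           m$values <- m$values[keep, , drop = FALSE]; m
         } else m[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Apply a filtering workflow to produce the DE input matrix
#'
#' Workflow 1: normalize genic + intergenic jointly, derive the threshold,
#' then drop low-expressed genes from the already-normalized genic matrix.
#' Workflow 2: derive the threshold the same way, drop the low genes from
#' the *raw* counts, then re-normalize the remaining genic counts (library
#' sizes stay frozen at their pre-filter values). Workflow 3: normalize
#' genic counts only, no filtering. Intergenic rows never enter the DE
#' input.
#'
#' @param counts genic `count_matrix`.
#' @param intergenic intergenic `count_matrix` (`NULL` allowed for
#'   workflow 3).
#' @param features `feature_table` (RPKM lengths, intergenic validity).
#' @param config an [analysis_config()].
#' @return A list: `matrix` (`normalized_matrix` ready for DE),
#'   `estimation` (`normalized_matrix` on which distribution parameters
#'   such as NB dispersions are to be estimated: the pre-filter matrix in
#'   workflow 1, the re-normalized post-filter matrix in workflow 2),
#'   `threshold` (`threshold_result` or `NULL`), `removed` (gene ids
#'   dropped).
#' @export
apply_workflow <- function(counts, intergenic, features, config) {
  stopifnot(inherits(config, "analysis_config"))
  method <- config$normalization_method
  wf <- config$workflow
  if (wf == 3L) {
    nm <- normalize_counts(counts, method, features = features)
    return(list(matrix = nm, estimation = nm, threshold = NULL,
                removed = character(0)))
  }
  if (is.null(intergenic))
    stop("workflows 1 and 2 require intergenic features for thresholding")
  thr <- empirical_threshold(counts, intergenic, method,
                             percentile = config$threshold_percentile,
                             features = features)
  if (wf == 1L) {
    # normalize and estimate on all genes; filtering happens after
    nm <- normalize_counts(counts, method, features = features)
    fl <- filter_low_expression(nm, thr)
    return(list(matrix = fl$matrix, estimation = nm, threshold = thr,
                removed = fl$removed))
  }
  # workflow 2: filter raw counts first, then re-normalize the survivors;
  # estimation also happens on the filtered, re-normalized data
  nm0 <- normalize_counts(counts, method, features = features)
  fl <- filter_low_expression(nm0, thr)
  keep <- setdiff(counts$gene_ids, fl$removed)
  refit <- subset_counts(counts, genes = keep)   # library sizes frozen
  nm2 <- normalize_counts(refit, method, features = features)
  list(matrix = nm2, estimation = nm2, threshold = thr, removed = fl$removed)
}
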