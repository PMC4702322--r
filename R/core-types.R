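#' Construct a count matrix container
#'
#' Bundles a genes-by-samples matrix of non-negative integer read counts with
#' per-sample library sizes. Library sizes default to the column sums of the
#' matrix at construction time and are deliberately *frozen* thereafter: a
#' downstream filtering step never changes them, so workflows that filter
#' before or after normalization see the same sequencing-depth denominator
#' (normalization is against total mapped reads, not post-filter sums).
#'
#' @param counts numeric matrix, genes in rows, samples in columns. Entries
#'   must be non-negative integers (integer-valued doubles are accepted).
#' @param gene_ids,sample_ids optional character vectors; default to the
#'   dimnames of `counts`, or `gene_1..`/`sample_1..` when absent.
#' @param library_sizes optional positive numeric vector of per-sample mapped
#'   read totals; defaults to `colSums(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (named integer-valued matrix), `gene_ids`, `sample_ids`,
#'   `library_sizes`.
#' @export
count_matrix <- function(counts, gene_ids = NULL, sample_ids = NULL,
                         library_sizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("count matrix contains NA/NaN entries")
  if (any(counts < 0)) stop("count matrix contains negative entries")
  if (any(counts != round(counts)))
    stop("count matrix contains non-integer entries")
  if (is.null(gene_ids))
    gene_ids <- rownames(counts) %||% paste0("gene_", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- colnames(counts) %||% paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("gene_ids are not unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids are not unique")
  stopifnot(length(gene_ids) == nrow(counts),
            length(sample_ids) == ncol(counts))
  dimnames(counts) <- list(gene_ids, sample_ids)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes length must equal the number of samples")
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  names(library_sizes) <- sample_ids
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids,
         library_sizes = library_sizes),
    class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; library sizes %s..%s\n",
              nrow(x$counts), ncol(x$counts),
              format(min(x$library_sizes), big.mark = ","),
              format(max(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a count matrix by gene and/or sample
#'
#' Library sizes are carried over for the retained samples, not recomputed
#' from the retained genes (see [count_matrix()] for why).
#'
#' @param x a `count_matrix`.
#' @param genes,samples index vectors (logical, integer or character).
#' @return A `count_matrix`.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  g <- genes %||% seq_len(nrow(x$counts))
  s <- samples %||% seq_len(ncol(x$counts))
  m <- x$counts[g, s, drop = FALSE]
  count_matrix(m, gene_ids = rownames(m), sample_ids = colnames(m),
               library_sizes = x$library_sizes[colnames(m)])
}

#' Construct a feature annotation table
#'
#' @param feature_id character identifiers.
#' @param chrom,start,end coordinates, 0-based half-open (`length = end -
#'   start`).
#' @param strand one of `+`, `-`, `*`.
#' @param region_class `"genic"` or `"intergenic"`.
#' @param coding_class `"protein_coding"` or `"non_coding"`; `NA` allowed for
#'   intergenic features.
#' @param read_length intergenic features shorter than this cannot receive a
#'   uniquely mapped read and are flagged invalid for thresholding
#'   (default 76).
#' @return A `data.frame` of class `feature_table` with columns
#'   `feature_id, chrom, start, end, strand, length_bp, region_class,
#'   coding_class, valid_intergenic`.
#' @export
feature_table <- function(feature_id, chrom, start, end, strand = "*",
                          region_class = "genic",
                          coding_class = "protein_coding",
                          read_length = 76L) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start))
    stop("features with end <= start: ",
         paste(feature_id[end <= start], collapse = ", "))
  strand <- rep_len(as.character(strand), length(feature_id))
  if (!all(strand %in% c("+", "-", "*")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(strand, c("+", "-", "*"))), collapse = ", "))
  region_class <- rep_len(region_class, length(feature_id))
  if (!all(region_class %in% c("genic", "intergenic")))
    stop("region_class must be 'genic' or 'intergenic'")
  coding_class <- rep_len(coding_class, length(feature_id))
  bad <- !is.na(coding_class) &
    !coding_class %in% c("protein_coding", "non_coding")
  if (any(bad)) stop("coding_class must be 'protein_coding' or 'non_coding'")
  len <- end - start
  ft <- data.frame(
    feature_id = as.character(feature_id), chrom = as.character(chrom),
    start = start, end = end, strand = strand, length_bp = len,
    region_class = region_class, coding_class = coding_class,
    valid_intergenic = region_class == "intergenic" & len >= read_length,
    stringsAsFactors = FALSE)
  if (anyDuplicated(ft$feature_id)) stop("feature_id values are not unique")
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Construct a sample design table
#'
#' Each sample (library) maps to exactly one genotype x environment x sex
#' cell. Duplicate libraries of the same individual share `individual_id` and
#' differ in `library_id`.
#'
#' @param sample_id,genotype,environment,sex,replicate_index,library_id,individual_id
#'   vectors of equal length; `library_id` defaults to `sample_id`,
#'   `individual_id` to `sample_id` (no duplicates).
#' @return A `data.frame` of class `sample_design`.
#' @export
sample_design <- function(sample_id, genotype, environment, sex,
                          replicate_index = NA_integer_,
                          library_id = sample_id,
                          individual_id = sample_id) {
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample_id in design: ", paste(dup, collapse = ", "))
  }
  d <- data.frame(
    sample_id = as.character(sample_id),
    genotype = factor(genotype), environment = factor(environment),
    sex = factor(sex),
    replicate_index = rep_len(as.integer(replicate_index), length(sample_id)),
    library_id = rep_len(as.character(library_id), length(sample_id)),
    individual_id = rep_len(as.character(individual_id), length(sample_id)),
    stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Report whether a design is balanced
#'
#' @param design a `sample_design`.
#' @return A list with `balanced` (logical), `cell_counts` (table of samples
#'   per genotype x environment x sex cell) and `n_per_cell` (the common cell
#'   size when balanced, otherwise `NA`).
#' @export
design_balance <- function(design) {
  tab <- table(design$genotype, design$environment, design$sex)
  bal <- length(unique(as.vector(tab))) == 1L
  list(balanced = bal, cell_counts = tab,
       n_per_cell = if (bal) unique(as.vector(tab)) else NA_integer_)
}

#' Build a validated analysis configuration
#'
#' @param normalization_method one of `TC, UQ, Med, TMM, DESeq, Q, RPKM, RC`.
#' @param workflow filtering workflow: 1 (normalize, threshold, then filter),
#'   2 (threshold and filter first, then re-normalize), 3 (no filtering).
#' @param threshold_percentile percentile of the intergenic distribution used
#'   as the detection threshold (default 95).
#' @param fdr_level Benjamini-Hochberg FDR cutoff for calling differential
#'   expression (default 0.05).
#' @param dispersion_mode `"trend_max"` (per-gene estimate or fitted trend,
#'   whichever is greater) or `"eb_shrink"` (empirical-Bayes shrink toward
#'   the trend).
#' @param interaction_approach how first-order interactions are tested:
#'   `"sequential"`, `"add_one"` or `"drop_one"`.
#' @param count_input_mode `"rounded"` (normalized counts rounded
#'   half-to-even fed to the NB engine) or `"offset"` (raw counts with
#'   log-scaling-factor offsets).
#' @param rng_seed integer seed recorded in the run manifest.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(normalization_method = "DESeq", workflow = 1L,
                            threshold_percentile = 95, fdr_level = 0.05,
                            dispersion_mode = c("trend_max", "eb_shrink"),
                            interaction_approach = c("sequential", "add_one",
                                                     "drop_one"),
                            count_input_mode = c("rounded", "offset"),
                            rng_seed = 1L) {
  normalization_method <- match.arg(normalization_method, norm_methods())
  if (!workflow %in% 1:3) stop("workflow must be 1, 2 or 3")
  stopifnot(threshold_percentile >= 0, threshold_percentile <= 100,
            fdr_level > 0, fdr_level < 1)
  structure(
    list(normalization_method = normalization_method,
         workflow = as.integer(workflow),
         threshold_percentile = threshold_percentile,
         fdr_level = fdr_level,
         dispersion_mode = match.arg(dispersion_mode),
         interaction_approach = match.arg(interaction_approach),
         count_input_mode = match.arg(count_input_mode),
         rng_seed = as.integer(rng_seed)),
    class = "analysis_config")
}
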