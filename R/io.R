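#' Read a count matrix from TSV or Matrix Market files
#'
#' TSV layout: gene rows by sample columns with a header line; the first
#' column holds gene identifiers. MTX layout: a triplet `.mtx` file plus
#' sidecar row/column label files (one identifier per line), by default
#' `<stem>.rows.txt` and `<stem>.cols.txt`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_file,col_file label files for `format = "mtx"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              row_file = NULL, col_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed count TSV (need id column + samples): ",
                            path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1L, drop = FALSE], 2L,
                         function(col) any(is.na(suppressWarnings(as.numeric(col))))))
      stop("non-numeric count entries in column(s): ",
           paste(names(bad), collapse = ", "))
    }
    rownames(m) <- ids
  } else {
    stem <- sub("\\.mtx$", "", path)
    row_file <- row_file %||% paste0(stem, ".rows.txt")
    col_file <- col_file %||% paste0(stem, ".cols.txt")
    if (!file.exists(row_file) || !file.exists(col_file))
      stop("MTX label files not found: ", row_file, ", ", col_file)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_file)
    colnames(m) <- readLines(col_file)
  }
  count_matrix(m)  # validates non-negativity / integrality
}

#' Write a count matrix as TSV (plus library-size sidecar)
#'
#' @param x a `count_matrix`.
#' @param path output TSV path; library sizes go to `<path>.libsizes.tsv`.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ls_df <- data.frame(sample_id = x$sample_ids,
                      library_size = format(x$library_sizes, scientific = FALSE,
                                            trim = TRUE))
  utils::write.table(ls_df, paste0(path, ".libsizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read feature annotation from GFF3 or BED
#'
#' Coordinates are stored 0-based half-open internally; GFF3 (1-based closed)
#' is converted on read, so a GFF3 feature `101..300` and a BED line
#' `chr 100 300` describe the same 200 bp interval. The region class
#' (genic/intergenic) is taken from a GFF3 attribute (default
#' `region_class`), from the GFF3 `type` column value `intergenic_region`,
#' or everything in the file is genic and intergenic features come from a
#' separate file read with `region_class = "intergenic"`.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param region_class default class for features without an explicit class
#'   attribute.
#' @param coding_attr GFF3 attribute naming the coding class (values
#'   `protein_coding`/`non_coding`); absent means `protein_coding` for genic
#'   features.
#' @param read_length minimum usable intergenic feature length (default 76).
#' @return A [feature_table()].
#' @export
read_annotation <- function(path, format = c("gff3", "bed"),
                            region_class = "genic",
                            coding_attr = "coding_class",
                            read_length = 76L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading annotation requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  md <- as.data.frame(gr)
  ids <- md$ID %||% md$Name %||% md$name %||% md$gene_id
  if (is.null(ids)) ids <- paste0("feat_", seq_along(gr))
  ids <- as.character(ids)
  rc <- if (!is.null(md$region_class)) as.character(md$region_class)
        else if (!is.null(md$type))
          ifelse(as.character(md$type) == "intergenic_region",
                 "intergenic", region_class)
        else region_class
  cc <- if (!is.null(md[[coding_attr]])) as.character(md[[coding_attr]])
        else ifelse(rc == "genic", "protein_coding", NA_character_)
  # GenomicRanges keeps 1-based closed starts; convert to 0-based half-open
  feature_table(feature_id = ids, chrom = as.character(md$seqnames),
                start = md$start - 1L, end = md$end,
                strand = as.character(md$strand),
                region_class = rc, coding_class = cc,
                read_length = read_length)
}

#' Write a feature table as GFF3
#'
#' The inverse of [read_annotation()]: internal 0-based half-open
#' coordinates are emitted as 1-based closed GFF3, so read-write-read
#' round-trips exactly.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @export
write_annotation_gff3 <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  attrs <- sprintf("ID=%s;region_class=%s%s", ft$feature_id, ft$region_class,
                   ifelse(is.na(ft$coding_class), "",
                          paste0(";coding_class=", ft$coding_class)))
  lines <- sprintf("%s\tcountbench\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ft$chrom,
                   ifelse(ft$region_class == "intergenic",
                          "intergenic_region", "gene"),
                   as.integer(ft$start) + 1L, as.integer(ft$end), ft$strand,
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Required columns: `sample_id, genotype, environment, sex`. Optional:
#' `replicate_index, library_id, individual_id`.
#'
#' @param path TSV path.
#' @param counts optional `count_matrix`; when given, every count sample must
#'   appear in the design.
#' @return A [sample_design()]; balance is available via [design_balance()].
#' @export
read_design <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "environment", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("design table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- sample_design(
    sample_id = df$sample_id, genotype = df$genotype,
    environment = df$environment, sex = df$sex,
    replicate_index = df$replicate_index %||% NA_integer_,
    library_id = df$library_id %||% df$sample_id,
    individual_id = df$individual_id %||% df$sample_id)
  if (!is.null(counts)) {
    orphan <- setdiff(counts$sample_ids, d$sample_id)
    if (length(orphan))
      stop("samples present in counts but absent from design: ",
           paste(orphan, collapse = ", "))
  }
  d
}

#' Write a sample design table as TSV
#' @param design a `sample_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with stable float formatting
#'
#' Floats are serialized at full (17 significant digit) precision so that
#' re-running a pipeline with the same seed produces byte-identical files
#' and round-tripping preserves values to machine precision.
#'
#' @param df a data.frame.
#' @param path output path.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
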