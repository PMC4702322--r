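#' Verify sample genotypes against reference-line SNP calls
#'
#' For sample i and line j, `r_ij = D_ij / M_ij` where `D_ij` counts
#' mismatched and `M_ij` matched SNP sites over sites with a call in both;
#' `R_ij = 1 - (r_ij - min_j r_i.) / (max_j r_i. - min_j r_i.)` rescales
#' each sample's row to `[0, 1]`. A sample is assigned to the line with
#' `R = 1` and passes when its `r` to that line is at most `r_threshold`.
#'
#' @param calls sites x samples character matrix of base calls (`NA` =
#'   missing).
#' @param line_table sites x lines character matrix of reference calls.
#' @param r_threshold maximum acceptable mismatch proportion to the assigned
#'   line (default 0.10).
#' @return A list of class `genotype_qc`: matrices `r`, `R`, `D`, `M`
#'   (samples x lines), `assigned` (line name per sample), `pass`
#'   (logical), `tie` (logical: more than one line at `R = 1`).
#' @export
genotype_verify <- function(calls, line_table, r_threshold = 0.10) {
  if (ncol(line_table) < 2L) stop("need at least 2 candidate lines")
  common <- intersect(rownames(calls), rownames(line_table))
  if (length(common) == 0L) stop("no shared SNP sites")
  calls <- calls[common, , drop = FALSE]
  line_table <- line_table[common, , drop = FALSE]
  ns <- ncol(calls); nl <- ncol(line_table)
  D <- M <- matrix(0L, ns, nl,
                   dimnames = list(colnames(calls), colnames(line_table)))
  for (j in seq_len(nl)) {
    ref <- line_table[, j]
    cmp <- !is.na(calls) & !is.na(ref)          # site x sample comparability
    eq <- calls == ref & cmp
    M[, j] <- colSums(eq)
    D[, j] <- colSums(cmp & !eq)
  }
  r <- D / M
  r[M == 0] <- NA                                # incomparable pairs
  rmin <- apply(r, 1L, min, na.rm = TRUE)
  rmax <- apply(r, 1L, max, na.rm = TRUE)
  R <- 1 - (r - rmin) / (rmax - rmin)
  R[rmax == rmin, ] <- 1                         # degenerate: all lines equal
  best <- apply(R, 1L, function(z) which(!is.na(z) & z == 1)[1L])
  tie <- apply(R, 1L, function(z) sum(!is.na(z) & z == 1) > 1L)
  assigned <- colnames(line_table)[best]
  r_best <- r[cbind(seq_len(ns), best)]
  structure(list(r = r, R = R, D = D, M = M, assigned = assigned,
                 pass = r_best <= r_threshold, tie = tie,
                 r_threshold = r_threshold),
            class = "genotype_qc")
}

#' Verify sample sex from dimorphic expression
#'
#' A sex standard is the per-gene median of normalized counts across the
#' samples labeled with that sex (by default computed leave-one-out, so a
#' sample never contributes to the standard it is compared against). Each
#' sample's Spearman rank correlation to both standards is computed; a
#' sample passes when its correlation with its same-sex standard reaches
#' `correlation_threshold`.
#'
#' @param nm a `normalized_matrix` (or plain matrix of normalized counts).
#' @param design a `sample_design` with a `sex` column.
#' @param correlation_threshold default 0.795.
#' @param leave_one_out exclude each sample from its own standard
#'   (default `TRUE`; with hundreds of samples per sex the difference is
#'   negligible, at small synthetic scale it avoids self-correlation bias).
#' @return A list of class `sex_qc`: `cor_same`, `cor_other`, `pass`,
#'   `standards` (genes x sexes medians over all samples).
#' @export
sex_verify <- function(nm, design, correlation_threshold = 0.795,
                       leave_one_out = TRUE) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  sex <- design$sex[match(colnames(v), design$sample_id)]
  if (anyNA(sex)) stop("samples missing from design: ",
                       paste(colnames(v)[is.na(sex)], collapse = ", "))
  sexes <- levels(droplevels(sex))
  if (length(sexes) < 2L) stop("both sexes must be present")
  std <- sapply(sexes, function(s)
    apply(v[, sex == s, drop = FALSE], 1L, stats::median))
  ns <- ncol(v)
  cor_same <- cor_other <- numeric(ns)
  for (i in seq_len(ns)) {
    own <- as.character(sex[i])
    other <- setdiff(sexes, own)[1L]
    own_std <- if (leave_one_out) {
      peers <- which(sex == own); peers <- setdiff(peers, i)
      if (length(peers) == 0L) stop("sex ", own, " has a single sample; ",
                                    "cannot form a leave-one-out standard")
      apply(v[, peers, drop = FALSE], 1L, stats::median)
    } else std[, own]
    cor_same[i] <- stats::cor(v[, i], own_std, method = "spearman")
    cor_other[i] <- stats::cor(v[, i], std[, other], method = "spearman")
  }
  structure(list(cor_same = stats::setNames(cor_same, colnames(v)),
                 cor_other = stats::setNames(cor_other, colnames(v)),
                 pass = stats::setNames(cor_same >= correlation_threshold,
                                        colnames(v)),
                 standards = std,
                 correlation_threshold = correlation_threshold),
            class = "sex_qc")
}

#' Flag samples below a minimum mapped-read total
#'
#' @param x a `count_matrix`.
#' @param min_mapped minimum library size, inclusive (default 2.5 million).
#' @return Character vector of retained sample ids; excluded ids in
#'   attribute `"excluded"`.
#' @export
min_reads_filter <- function(x, min_mapped = 2.5e6) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$library_sizes >= min_mapped
  out <- x$sample_ids[keep]
  attr(out, "excluded") <- x$sample_ids[!keep]
  out
}

#' Quantify technical variation between duplicate libraries
#'
#' Restricted to individuals sequenced twice, fits the per-gene NB GLM
#' `log(mu) = b0 + F` with the individual (fly) as the only factor and
#' duplicate libraries as replicates within it, and tests F by likelihood
#' ratio against the intercept-only model. Spike-in controls, which carry
#' no biology, are summarized separately: under a well-behaved library
#' protocol none should be differentially expressed. Also emits each
#' fly's per-gene absolute difference in raw counts between its two
#' libraries.
#'
#' @param x a `count_matrix` containing the duplicate-library columns.
#' @param design a `sample_design`; duplicates share `individual_id`.
#' @param spikein_ids character vector of spike-in control rows.
#' @param fdr_level BH FDR cutoff (default 0.05).
#' @return A list of class `techrep_result`: `de` (per-gene stat/p/q),
#'   `n_sig_genic`, `n_sig_spikein`, `abs_diff` (genes x flies matrix of
#'   `|library1 - library2|`).
#' @export
technical_replicate_test <- function(x, design, spikein_ids = character(0),
                                     fdr_level = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  d <- design[match(x$sample_ids, design$sample_id), ]
  dup_ind <- names(which(table(d$individual_id) >= 2L))
  if (length(dup_ind) < 2L)
    stop("need duplicate libraries for at least 2 individuals")
  keep <- d$individual_id %in% dup_ind
  xd <- subset_counts(x, samples = keep)
  fly <- factor(d$individual_id[keep])
  X_full <- stats::model.matrix(~fly)
  X_null <- X_full[, 1L, drop = FALSE]
  disp <- estimate_dispersions(xd$counts, data.frame(cell = fly),
                               cell_formula = ~cell)
  dev_f <- nb_fit_matrix(xd$counts, X_full, disp$final)$deviance
  dev_0 <- nb_fit_matrix(xd$counts, X_null, disp$final)$deviance
  stat <- pmax(dev_0 - dev_f, 0)
  df <- qr(X_full)$rank - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  allzero <- rowSums(xd$counts) == 0
  p[allzero] <- 1
  q <- bh_adjust(p)
  de <- data.frame(gene = xd$gene_ids, stat = stat, df = df, p = p, q = q,
                   significant = q < fdr_level,
                   spikein = xd$gene_ids %in% spikein_ids)
  pair_diff <- sapply(dup_ind, function(f) {
    cols <- which(fly == f)[1:2]
    abs(xd$counts[, cols[1L]] - xd$counts[, cols[2L]])
  })
  structure(list(de = de,
                 n_sig_genic = sum(de$significant & !de$spikein),
                 n_sig_spikein = sum(de$significant & de$spikein),
                 abs_diff = pair_diff),
            class = "techrep_result")
}
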