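#' @title Count normalization methods
#' @description The seven normalization methods compared by the framework,
#'   plus raw counts (RC) and a minimal RUVg factor construction. TC, UQ and
#'   Med divide each sample by a ratio built from a per-sample summary over
#'   its mean across samples; DESeq uses median-of-ratios size factors; TMM
#'   uses a trimmed weighted mean of M-values against a reference sample; Q
#'   equalizes the count distribution across samples by rank; RPKM rescales
#'   by gene length and sequencing depth.
#' @name normalization
NULL

norm_methods <- function() c("TC", "UQ", "Med", "TMM", "DESeq", "Q", "RPKM", "RC")

#' Sample quantile, type 7
#'
#' Linear interpolation between order statistics (the default convention of
#' most statistical software); isolated here so every quantile in the
#' package uses one documented rule.
#' @param x numeric vector.
#' @param p probability in `[0, 1]`.
#' @return The interpolated quantile.
#' @keywords internal
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7))

new_normalized_matrix <- function(values, method, factors = NULL,
                                  reference = NULL) {
  structure(
    list(values = values, method = method, factors = factors,
         reference = reference),
    class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d samples\n", x$method,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Integer view of a normalized matrix for count-based engines
#'
#' Rounds normalized values half-to-even to integers, the form in which
#' normalized data are fed back into a negative-binomial count engine.
#' @param nm a `normalized_matrix` (or plain matrix).
#' @return An integer-valued matrix, elementwise `>= 0`.
#' @export
rounded_view <- function(nm) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  round(v)  # round() is round-half-to-even in R
}

ratio_normalize <- function(x, per_sample_stat, method) {
  stat <- apply(x$counts, 2L, per_sample_stat)
  if (any(stat <= 0))
    stop(method, ": zero/negative per-sample statistic for sample(s): ",
         paste(x$sample_ids[stat <= 0], collapse = ", "))
  ratio <- stat / mean(stat)
  values <- sweep(x$counts, 2L, ratio, "/")
  new_normalized_matrix(values, method,
                        factors = stats::setNames(ratio, x$sample_ids))
}

#' Total-count (TC) normalization
#'
#' Divides each sample by the ratio of its total mapped reads to the mean
#' total mapped reads across samples. Uses the frozen `library_sizes` of the
#' count matrix, not post-filter column sums.
#' @param x a `count_matrix`.
#' @return A `normalized_matrix` with per-sample `factors` (the ratios).
#' @export
normalize_tc <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  N <- x$library_sizes
  ratio <- N / mean(N)
  new_normalized_matrix(sweep(x$counts, 2L, ratio, "/"), "TC",
                        factors = ratio)
}

# Per-sample summaries for UQ/Med are computed after dropping genes that are
# zero in every sample; those genes stay in the output matrix.
nonzero_rows <- function(m) m[rowSums(m) > 0, , drop = FALSE]

#' Upper-quartile (UQ) normalization
#'
#' Divides each sample by the ratio of its 75th-percentile count (over genes
#' with a nonzero count in at least one sample) to the mean upper quartile
#' across samples.
#' @inheritParams normalize_tc
#' @return A `normalized_matrix`.
#' @export
normalize_uq <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  nz <- nonzero_rows(x$counts)
  if (nrow(nz) == 0L) stop("UQ: all genes are zero in every sample")
  uq <- apply(nz, 2L, quantile7, p = 0.75)
  if (any(uq == 0))
    stop("UQ: zero upper quartile for sample(s): ",
         paste(x$sample_ids[uq == 0], collapse = ", "))
  ratio <- uq / mean(uq)
  new_normalized_matrix(sweep(x$counts, 2L, ratio, "/"), "UQ",
                        factors = stats::setNames(ratio, x$sample_ids))
}

#' Median (Med) normalization
#'
#' As UQ with the per-sample median in place of the upper quartile.
#' @inheritParams normalize_tc
#' @return A `normalized_matrix`.
#' @export
normalize_med <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  nz <- nonzero_rows(x$counts)
  if (nrow(nz) == 0L) stop("Med: all genes are zero in every sample")
  med <- apply(nz, 2L, stats::median)
  if (any(med == 0))
    stop("Med: zero median for sample(s): ",
         paste(x$sample_ids[med == 0], collapse = ", "))
  ratio <- med / mean(med)
  new_normalized_matrix(sweep(x$counts, 2L, ratio, "/"), "Med",
                        factors = stats::setNames(ratio, x$sample_ids))
}

#' Choose the TMM reference sample
#'
#' The sample whose upper-quartile count is closest to the mean upper
#' quartile across samples; ties broken by lowest sample index.
#' @inheritParams normalize_tc
#' @return The reference `sample_id`.
#' @export
tmm_reference <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 2L) stop("TMM reference needs >= 2 samples")
  nz <- nonzero_rows(x$counts)
  uq <- apply(nz, 2L, quantile7, p = 0.75)
  x$sample_ids[which.min(abs(uq - mean(uq)))]
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' For each sample k against a reference r, per-gene M-values
#' \eqn{M = \log_2\{(x_{ik}/N_k)/(x_{ir}/N_r)\}} and A-values
#' \eqn{A = \frac12\{\log_2(x_{ik}/N_k) + \log_2(x_{ir}/N_r)\}} are computed
#' over genes nonzero in both sample and reference. Genes in the middle
#' `1 - trim_M` of M and the middle `1 - trim_A` of A form the retained set;
#' the normalization factor is `2^(weighted mean of M)` with inverse
#' approximate-asymptotic-variance weights
#' \eqn{w = (N_k - x_{ik})/(N_k x_{ik}) + (N_r - x_{ir})/(N_r x_{ir})}{^-1}.
#' Normalized values are `x / (factor * N)` rescaled by the mean normalized
#' library size so they stay on a count-like scale.
#'
#' @param x a `count_matrix`.
#' @param trim_M per-tail trim fraction on M-values; default 0.30 keeps the
#'   middle 40 %.
#' @param trim_A per-tail trim fraction on A-values; default 0.05 keeps the
#'   middle 90 %.
#' @param reference reference sample id; default [tmm_reference()].
#' @param renorm_geomean if `TRUE` (default), rescale factors so their
#'   geometric mean is 1 before applying, stabilizing cross-sample scale.
#' @return A `normalized_matrix`; `$factors` holds the TMM factors and
#'   `$intermediate` the per-sample M/A/weight tables and retained gene sets.
#' @export
normalize_tmm <- function(x, trim_M = 0.30, trim_A = 0.05,
                          reference = NULL, renorm_geomean = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  ref <- reference %||% tmm_reference(x)
  if (!ref %in% x$sample_ids) stop("unknown reference sample: ", ref)
  N <- x$library_sizes
  xr <- x$counts[, ref]
  Nr <- N[[ref]]
  f <- stats::setNames(rep(1, ncol(x$counts)), x$sample_ids)
  inter <- vector("list", ncol(x$counts))
  names(inter) <- x$sample_ids
  for (k in x$sample_ids) {
    if (k == ref) next
    xk <- x$counts[, k]
    ok <- xk > 0 & xr > 0
    if (!any(ok)) stop("TMM: no gene nonzero in both ", k, " and reference")
    Nk <- N[[k]]
    M <- log2((xk[ok] / Nk) / (xr[ok] / Nr))
    A <- 0.5 * (log2(xk[ok] / Nk) + log2(xr[ok] / Nr))
    w <- 1 / ((Nk - xk[ok]) / (Nk * xk[ok]) + (Nr - xr[ok]) / (Nr * xr[ok]))
    keepM <- M >= quantile7(M, trim_M) & M <= quantile7(M, 1 - trim_M)
    keepA <- A >= quantile7(A, trim_A) & A <= quantile7(A, 1 - trim_A)
    Gstar <- keepM & keepA
    if (!any(Gstar))
      stop("TMM: trimmed gene set empty for sample ", k,
           "; try smaller trim fractions")
    f[[k]] <- 2^(sum(w[Gstar] * M[Gstar]) / sum(w[Gstar]))
    inter[[k]] <- list(M = M, A = A, w = w, Gstar = which(ok)[Gstar])
  }
  if (renorm_geomean) f <- f / exp(mean(log(f)))
  eff <- f * N                      # effective (normalized) library sizes
  values <- sweep(x$counts, 2L, eff, "/") * mean(eff)
  out <- new_normalized_matrix(values, "TMM", factors = f, reference = ref)
  out$intermediate <- inter
  out
}

#' Median-of-ratios (DESeq-style) size factors
#'
#' The reference pseudo-sample is the per-gene geometric mean of counts
#' across samples; each sample's size factor is the median over genes with a
#' positive geometric mean of the ratio of its count to the reference.
#' @inheritParams normalize_tc
#' @return Named numeric vector of size factors.
#' @export
deseq_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  logg <- rowMeans(log(x$counts))   # -Inf for genes with any zero
  use <- is.finite(logg)
  if (!any(use))
    stop("size factors undefined: no gene has positive counts in all samples")
  s <- apply(x$counts[use, , drop = FALSE], 2L, function(col)
    stats::median(exp(log(col) - logg[use])))
  stats::setNames(s, x$sample_ids)
}

#' Normalize by median-of-ratios size factors
#' @inheritParams normalize_tc
#' @return A `normalized_matrix` with values `x / s_k`.
#' @export
normalize_deseq <- function(x) {
  s <- deseq_size_factors(x)
  new_normalized_matrix(sweep(x$counts, 2L, s, "/"), "DESeq", factors = s)
}

#' Full quantile (Q) normalization
#'
#' Every sample's sorted count profile is replaced by the mean sorted
#' profile; ties within a sample receive the mean of the values they would
#' jointly occupy, so the result is deterministic and independent of input
#' order.
#' @inheritParams normalize_tc
#' @return A `normalized_matrix` (no per-sample factors).
#' @export
normalize_quantile <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  target <- rowMeans(apply(m, 2L, sort))
  values <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "min")      # start position of each tie run
    runlen <- table(r)
    # mean of target values each tie block spans
    blockmean <- vapply(names(runlen), function(start) {
      i <- as.integer(start)
      mean(target[i:(i + runlen[[start]] - 1L)])
    }, numeric(1))
    unname(blockmean[as.character(r)])
  })
  dimnames(values) <- dimnames(m)
  new_normalized_matrix(values, "Q")
}

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `x * 1e9 / (N_k * length_bp)`.
#' @param x a `count_matrix`.
#' @param features a `feature_table` supplying `length_bp` for every gene.
#' @return A `normalized_matrix`.
#' @export
normalize_rpkm <- function(x, features) {
  stopifnot(inherits(x, "count_matrix"), inherits(features, "feature_table"))
  len <- features$length_bp[match(x$gene_ids, features$feature_id)]
  if (anyNA(len))
    stop("missing gene length for: ",
         paste(utils::head(x$gene_ids[is.na(len)], 10), collapse = ", "))
  values <- x$counts * 1e9 / outer(len, x$library_sizes)
  dimnames(values) <- dimnames(x$counts)
  new_normalized_matrix(values, "RPKM")
}

#' Minimal RUVg factor construction from negative-control genes
#'
#' Extracts `k` unwanted-variation factors as the leading right-singular
#' vectors of the row-centered `log(x + 1)` submatrix of negative-control
#' genes (ERCC spike-ins). The factors are returned for use as covariates in
#' a differential-expression model, not applied to the counts.
#' @param x a `count_matrix`.
#' @param control_gene_ids identifiers of the negative-control rows.
#' @param k number of factors (default 1).
#' @return samples x k matrix `W`, with singular values as attribute `"d"`.
#' @export
ruvg_factors <- function(x, control_gene_ids, k = 1L) {
  stopifnot(inherits(x, "count_matrix"))
  miss <- setdiff(control_gene_ids, x$gene_ids)
  if (length(miss)) stop("control genes absent from matrix: ",
                         paste(miss, collapse = ", "))
  if (k >= length(control_gene_ids))
    stop("k must be smaller than the number of control genes")
  Z <- log(x$counts[control_gene_ids, , drop = FALSE] + 1)
  Z <- Z - rowMeans(Z)
  sv <- svd(Z, nu = 0, nv = k)
  W <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(W) <- list(x$sample_ids, paste0("W", seq_len(k)))
  attr(W, "d") <- sv$d
  W
}

#' Normalize a count matrix by a named method
#'
#' Dispatch over `TC, UQ, Med, TMM, DESeq, Q, RPKM, RC`; `RC` returns the
#' raw counts unchanged (factors all 1).
#' @param x a `count_matrix`.
#' @param method method name.
#' @param features `feature_table`, required for RPKM.
#' @param ... passed to the method (e.g. TMM trims).
#' @return A `normalized_matrix`.
#' @export
normalize_counts <- function(x, method, features = NULL, ...) {
  if (!method %in% norm_methods())
    stop("unknown normalization method: ", method)
  switch(method,
    TC = normalize_tc(x),
    UQ = normalize_uq(x),
    Med = normalize_med(x),
    TMM = normalize_tmm(x, ...),
    DESeq = normalize_deseq(x),
    Q = normalize_quantile(x),
    RPKM = {
      if (is.null(features)) stop("RPKM requires a feature_table")
      normalize_rpkm(x, features)
    },
    RC = new_normalized_matrix(
      x$counts, "RC",
      factors = stats::setNames(rep(1, ncol(x$counts)), x$sample_ids)))
}
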