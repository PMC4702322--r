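#' Agreement between two differentially-expressed gene sets
#'
#' Reports three percentages: `jaccard = 100 |A n B| / |A u B|` (the
#' headline agreement), and the directed recalls
#' `recall_a = 100 |A n B| / |A|`, `recall_b = 100 |A n B| / |B|`. Two
#' empty sets agree perfectly by convention (two null results), giving 100
#' on all metrics.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return A list of class `agreement_result`: `jaccard, recall_a,
#'   recall_b, n_a, n_b, n_common`.
#' @export
agreement <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  common <- length(intersect(a, b))
  uni <- length(union(a, b))
  res <- if (uni == 0L) list(jaccard = 100, recall_a = 100, recall_b = 100)
         else list(
           jaccard = 100 * common / uni,
           recall_a = if (length(a) == 0L) 100 else 100 * common / length(a),
           recall_b = if (length(b) == 0L) 100 else 100 * common / length(b))
  structure(c(res, list(n_a = length(a), n_b = length(b),
                        n_common = common)),
            class = "agreement_result")
}

#' Intersection across many DE gene sets
#'
#' @param sets named list of >= 2 character vectors.
#' @param exclude optional name of one condition to drop for a second
#'   intersection count (e.g. the un-normalized condition).
#' @return A list: `n_common`, `common` (ids), `sizes`, and when `exclude`
#'   is given, `n_common_excluding` / `common_excluding`.
#' @export
overlap_across_conditions <- function(sets, exclude = NULL) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  common <- Reduce(intersect, sets)
  out <- list(n_common = length(common), common = common,
              sizes = vapply(sets, function(s) length(unique(s)), integer(1)))
  if (!is.null(exclude)) {
    if (!exclude %in% names(sets)) stop("unknown condition: ", exclude)
    ce <- Reduce(intersect, sets[setdiff(names(sets), exclude)])
    out$n_common_excluding <- length(ce)
    out$common_excluding <- ce
  }
  out
}

#' Agreement grid between two registries of DE runs
#'
#' Both registries are named lists (e.g. by normalization method) of
#' `de_table_set` objects sharing a gene universe; the grid reports the
#' agreement of significant sets per condition and term.
#'
#' @param runs_a,runs_b named lists of `de_table_set` objects with common
#'   names.
#' @param terms term names to compare (default all shared terms).
#' @param metric `"jaccard"`, `"recall_a"` or `"recall_b"`.
#' @return A matrix (terms x conditions) of agreement percentages.
#' @export
comparison_grid <- function(runs_a, runs_b, terms = NULL,
                            metric = c("jaccard", "recall_a", "recall_b")) {
  metric <- match.arg(metric)
  conds <- intersect(names(runs_a), names(runs_b))
  if (length(conds) == 0L) stop("run registries share no condition names")
  terms <- terms %||% Reduce(intersect, lapply(c(runs_a[conds], runs_b[conds]),
                                               names))
  m <- matrix(NA_real_, length(terms), length(conds),
              dimnames = list(terms, conds))
  for (cond in conds) {
    ga <- runs_a[[cond]]; gb <- runs_b[[cond]]
    ua <- ga[[1L]]$gene; ub <- gb[[1L]]$gene
    if (!setequal(ua, ub))
      stop("gene universes differ for condition ", cond)
    for (tm in terms)
      m[tm, cond] <- agreement(significant_genes(ga, tm),
                               significant_genes(gb, tm))[[metric]]
  }
  m
}

#' PCA diagnostic of a normalized matrix
#'
#' Principal components of the samples on centered `log2(normalized + 1)`
#' values, with percent variance explained and (when a design is supplied)
#' a silhouette score for the separation of the sexes along PC1.
#'
#' @param nm a `normalized_matrix` or genes x samples matrix.
#' @param design optional `sample_design` for the sex silhouette.
#' @param n_components number of components to report (default 2).
#' @return A list of class `pca_diagnostic`: `scores` (samples x
#'   components), `percent_var`, `pc1_sex_silhouette` (or `NA`).
#' @export
pca_diagnostic <- function(nm, design = NULL, n_components = 2L) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  if (ncol(v) < 3L) stop("PCA diagnostic needs at least 3 samples")
  Y <- t(log2(v + 1))
  if (all(apply(Y, 2L, stats::var) == 0)) stop("constant matrix")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  sil <- NA_real_
  if (!is.null(design)) {
    sex <- design$sex[match(colnames(v), design$sample_id)]
    if (nlevels(droplevels(factor(sex))) == 2L)
      sil <- silhouette_1d(pc$x[, 1L], factor(sex))
  }
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 percent_var = pv[seq_len(k)],
                 pc1_sex_silhouette = sil),
            class = "pca_diagnostic")
}

# Mean silhouette width for a 1-d embedding with two groups.
silhouette_1d <- function(x, group) {
  group <- droplevels(factor(group))
  stopifnot(nlevels(group) == 2L)
  s <- vapply(seq_along(x), function(i) {
    own <- group == group[i]
    own[i] <- FALSE
    a <- mean(abs(x[i] - x[own]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
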