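#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1; `m` is the number of
#' non-missing p-values and missing values propagate as missing. Ties are
#' handled stably (equal p-values receive equal q-values).
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0L) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
  }
  q
}

# ---- negative-binomial GLM at fixed dispersion ------------------------------

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  pos <- y > 0
  t1 <- numeric(length(y))
  t1[pos] <- y[pos] * log(y[pos] / mu[pos])
  if (phi > 0) {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  } else {
    2 * sum(t1 - (y - mu))
  }
}

#' Fit a negative-binomial GLM with log link at fixed dispersion
#'
#' Iteratively reweighted least squares maximizing the NB log-likelihood in
#' the mean for a single gene, with the dispersion `phi` held fixed
#' (variance `mu + mu^2 phi`; `phi = 0` is the Poisson limit). Returns the
#' deviance relative to the saturated model, so differences between nested
#' fits are likelihood-ratio statistics.
#'
#' @param y integer response vector (counts).
#' @param X design matrix (must be full column rank).
#' @param phi fixed dispersion (>= 0).
#' @param offset optional log-scale offset vector.
#' @param tol,max_iter convergence tolerance on the relative deviance change
#'   and iteration cap.
#' @return A list: `coef`, `mu`, `deviance`, `df_residual`, `converged`,
#'   `iter`.
#' @export
fit_nb_glm <- function(y, X, phi, offset = NULL, tol = 1e-10,
                       max_iter = 50L) {
  n <- length(y)
  o <- offset %||% numeric(n)
  if (all(y == 0)) {
    return(list(coef = rep(NA_real_, ncol(X)), mu = rep(1e-10, n),
                deviance = 0, df_residual = n - ncol(X), converged = TRUE,
                iter = 0L, degenerate = TRUE))
  }
  mu <- pmax(y, mean(y) / 10, 1e-3)
  eta <- log(mu) - o
  dev <- nb_deviance(y, mu, phi)
  beta <- NULL
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu
    wX <- X * sqrt(w)
    fit <- tryCatch(solve(crossprod(wX), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) {          # near-singular weighted system
      fit <- qr.coef(qr(wX), sqrt(w) * z)
      fit[is.na(fit)] <- 0
      fit <- matrix(fit, ncol = 1L)
    }
    beta <- drop(fit)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- pmax(exp(eta + o), 1e-10)
    dev_new <- nb_deviance(y, mu, phi)
    if (abs(dev_new - dev) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new; conv <- TRUE; break
    }
    dev <- dev_new
  }
  list(coef = beta, mu = mu, deviance = dev, df_residual = n - ncol(X),
       converged = conv, iter = it, degenerate = FALSE)
}

# Fit every row of a count matrix against one design matrix; returns the
# per-gene deviance vector (the workhorse behind the model ladder).
nb_fit_matrix <- function(Y, X, phi, offset = NULL) {
  ng <- nrow(Y)
  dev <- numeric(ng)
  conv <- logical(ng)
  for (g in seq_len(ng)) {
    f <- fit_nb_glm(Y[g, ], X, phi[g], offset = offset)
    dev[g] <- f$deviance
    conv[g] <- f$converged
  }
  list(deviance = dev, converged = conv)
}

#' Likelihood-ratio test between two nested NB fits
#'
#' The statistic is the deviance of the reduced model minus the deviance of
#' the full model (both at the same fixed per-gene dispersion), referred to
#' a chi-square distribution with `df` equal to the difference in estimated
#' coefficients.
#'
#' @param fit_full,fit_reduced results of [fit_nb_glm()] on nested designs
#'   for the same gene and dispersion.
#' @return A list: `stat`, `df`, `p`.
#' @export
nb_lrt <- function(fit_full, fit_reduced) {
  stat <- fit_reduced$deviance - fit_full$deviance
  if (stat < -1e-6)
    stop("negative LRT statistic (", format(stat),
         "): nested fits inconsistent")
  stat <- max(stat, 0)
  df <- fit_reduced$df_residual - fit_full$df_residual
  if (df < 0L) stop("models are not nested (reduced has more parameters)")
  if (df == 0L) return(list(stat = 0, df = 0L, p = 1))  # same model twice
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- dispersion estimation --------------------------------------------------

#' Estimate per-gene NB dispersions
#'
#' Raw per-gene estimates come from the method of moments on within-cell
#' replicates: with cell means `m_c` and variances `v_c`,
#' `phi_raw = max(0, sum (n_c - 1)(v_c - m_c) / sum (n_c - 1) m_c^2)`.
#' A mean-dispersion trend `phi(mu) = a0 + a1 / mu` is fitted by robust
#' regression through the positive raw estimates. The final value is either
#' the greater of the raw estimate and the fitted trend value
#' (`mode = "trend_max"`) or an empirical-Bayes weighted shrink of the raw
#' estimate toward the trend (`mode = "eb_shrink"`, weight
#' `prior_n / (prior_n + residual df)` on the trend).
#'
#' @param counts genes x samples matrix of (integer) counts.
#' @param design data.frame of factors defining the replicate cells.
#' @param cell_formula one-sided formula whose interaction defines the cells
#'   (default `~ genotype * environment * sex`).
#' @param mode `"trend_max"` or `"eb_shrink"`.
#' @param prior_n prior weight (in residual-df units) for `eb_shrink`
#'   (default 10).
#' @return A list of class `dispersion_estimates`: `raw`, `fitted`, `final`,
#'   `mode`, `trend_coef`, `mean` (per-gene mean count).
#' @export
estimate_dispersions <- function(counts, design,
                                 cell_formula = ~ genotype * environment * sex,
                                 mode = c("trend_max", "eb_shrink"),
                                 prior_n = 10) {
  mode <- match.arg(mode)
  mf <- stats::model.frame(cell_formula, design)
  cell <- interaction(mf, drop = TRUE)
  if (!any(table(cell) >= 2L))
    stop("dispersion unidentifiable: no design cell has >= 2 replicates")
  cells <- levels(cell)
  idx <- lapply(cells, function(cl) which(cell == cl))
  nrep <- lengths(idx)
  use_cell <- nrep >= 2L
  ng <- nrow(counts)
  num <- den <- numeric(ng)
  for (ci in which(use_cell)) {
    sub <- counts[, idx[[ci]], drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    w <- nrep[ci] - 1L
    num <- num + w * (v - m)
    den <- den + w * m^2
  }
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  mu <- rowMeans(counts)
  pos <- raw > 0 & mu > 0
  trend_coef <- c(a0 = 0, a1 = 0)
  fitted <- rep(0, ng)
  if (sum(pos) >= 10L) {
    fit <- tryCatch(MASS::rlm(raw[pos] ~ I(1 / mu[pos]), maxit = 50),
                    error = function(e) stats::lm(raw[pos] ~ I(1 / mu[pos])))
    trend_coef <- c(a0 = unname(stats::coef(fit)[1L]),
                    a1 = unname(stats::coef(fit)[2L]))
    fitted <- pmax(0, trend_coef[["a0"]] + trend_coef[["a1"]] / pmax(mu, 1e-8))
  } else if (any(pos)) {
    fitted <- rep(stats::median(raw[pos]), ng)
    trend_coef <- c(a0 = fitted[1L], a1 = 0)
  }
  df_resid <- sum(nrep[use_cell]) - sum(use_cell)
  final <- switch(mode,
    trend_max = pmax(raw, fitted),
    eb_shrink = {
      w <- prior_n / (prior_n + df_resid)
      pmax(0, w * fitted + (1 - w) * raw)
    })
  if (!is.null(rownames(counts)))
    names(raw) <- names(fitted) <- names(final) <- names(mu) <-
      rownames(counts)
  structure(list(raw = raw, fitted = fitted, final = final, mode = mode,
                 trend_coef = trend_coef, mean = mu),
            class = "dispersion_estimates")
}

# ---- the model-testing ladder ----------------------------------------------

ladder_formulas <- function() {
  list(
    m1_noS  = ~ genotype + environment,
    m1_noG  = ~ sex + environment,
    m1_noE  = ~ sex + genotype,
    m1      = ~ sex + genotype + environment,
    m2a     = ~ sex + genotype + environment + genotype:environment,
    m2b     = ~ sex + genotype + environment + genotype:environment +
                genotype:sex,
    m1_GxS  = ~ sex + genotype + environment + genotype:sex,
    m1_ExS  = ~ sex + genotype + environment + environment:sex,
    m2      = ~ sex + genotype + environment + genotype:environment +
                genotype:sex + environment:sex,
    m2_noGxE = ~ sex + genotype + environment + genotype:sex +
                 environment:sex,
    m2_noGxS = ~ sex + genotype + environment + genotype:environment +
                 environment:sex,
    full    = ~ sex * genotype * environment)
}

ladder_pairs <- function(approach) {
  mains <- list(S = c("m1", "m1_noS"), G = c("m1", "m1_noG"),
                E = c("m1", "m1_noE"))
  inter <- switch(approach,
    sequential = list(GxE = c("m2a", "m1"), GxS = c("m2b", "m2a"),
                      ExS = c("m2", "m2b")),
    add_one    = list(GxE = c("m2a", "m1"), GxS = c("m1_GxS", "m1"),
                      ExS = c("m1_ExS", "m1")),
    drop_one   = list(GxE = c("m2", "m2_noGxE"), GxS = c("m2", "m2_noGxS"),
                      ExS = c("m2", "m2b")))
  c(mains, inter, list(GxExS = c("full", "m2")))
}

#' Test all model terms of the factorial NB GLM
#'
#' Fits the nested model ladder
#' `log(mu) = b0 + S + G + E + GxE + GxS + ExS + GxExS` per gene at fixed
#' per-gene dispersion and reports a likelihood-ratio test per term. Main
#' effects are always tested by dropping each from the main-effects model.
#' First-order interactions follow the chosen `approach`: `"sequential"`
#' adds GxE, then GxS, then ExS, testing each addition against the previous
#' model; `"add_one"` adds each interaction alone to the main-effects
#' model; `"drop_one"` removes each interaction in turn from the model
#' containing all three. The three-way term is always the full model
#' against the all-first-order model. BH adjustment is applied within term
#' across genes.
#'
#' @param counts genes x samples matrix of integer counts (raw, or
#'   normalized and rounded).
#' @param design a `sample_design` (columns `sex, genotype, environment`).
#' @param approach `"sequential"`, `"add_one"` or `"drop_one"`.
#' @param dispersion_mode passed to [estimate_dispersions()].
#' @param dispersions optional precomputed dispersions (skips estimation):
#'   a `dispersion_estimates` object, or a numeric vector of final
#'   per-gene values named by gene id (e.g. estimated on a pre-filter
#'   matrix and subset to the tested genes).
#' @param offsets optional per-sample log-scale offsets (e.g. log size
#'   factors when testing raw counts).
#' @param fdr_level BH significance cutoff (default 0.05).
#' @param terms optional subset of term names to test (default: all seven);
#'   restricting the set skips the model fits only those terms need.
#' @return A list of class `de_table_set`: one data.frame per term
#'   (`gene, stat, df, p, q, significant`), plus attributes `approach` and
#'   `dispersions`.
#' @export
test_terms <- function(counts, design,
                       approach = c("sequential", "add_one", "drop_one"),
                       dispersion_mode = "trend_max", dispersions = NULL,
                       offsets = NULL, fdr_level = 0.05, terms = NULL) {
  approach <- match.arg(approach)
  d <- design[match(colnames(counts), design$sample_id), ]
  if (anyNA(d$sample_id)) stop("count columns missing from design")
  dat <- data.frame(sex = droplevels(d$sex), genotype = droplevels(d$genotype),
                    environment = droplevels(d$environment))
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, dat, mode = dispersion_mode)
  phi <- if (is.numeric(dispersions)) {
    if (is.null(names(dispersions)))
      stop("a dispersion vector must be named by gene id")
    miss <- setdiff(rownames(counts), names(dispersions))
    if (length(miss)) stop("missing dispersions for: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    unname(dispersions[rownames(counts)])
  } else dispersions$final
  forms <- ladder_formulas()
  pairs <- ladder_pairs(approach)
  if (!is.null(terms)) {
    unknown <- setdiff(terms, names(pairs))
    if (length(unknown)) stop("unknown term(s): ",
                              paste(unknown, collapse = ", "))
    pairs <- pairs[terms]
  }
  needed <- unique(unlist(pairs))
  Xs <- lapply(forms[needed], function(f) {
    X <- stats::model.matrix(f, dat)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))             # drop aliased columns (empty cells)
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    X
  })
  ranks <- vapply(Xs, ncol, integer(1))
  off <- offsets
  devs <- lapply(Xs, function(X) nb_fit_matrix(counts, X, phi, offset = off))
  allzero <- rowSums(counts) == 0
  out <- lapply(pairs, function(pr) {
    full <- pr[1L]; red <- pr[2L]
    df <- ranks[[full]] - ranks[[red]]
    if (df < 1L) {
      return(data.frame(gene = rownames(counts), stat = NA_real_,
                        df = 0L, p = NA_real_, q = NA_real_,
                        significant = NA))
    }
    stat <- pmax(devs[[red]]$deviance - devs[[full]]$deviance, 0)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    p[allzero] <- 1
    q <- bh_adjust(p)
    data.frame(gene = rownames(counts), stat = stat, df = df, p = p, q = q,
               significant = q < fdr_level)
  })
  structure(out, class = "de_table_set", approach = approach,
            dispersions = dispersions)
}

# ---- ln & ANOVA engine ------------------------------------------------------

#' Per-gene factorial ANOVA on ln-transformed normalized counts
#'
#' Fits `ln(normalized count + 1) = b0 + S + G + E + GxE + GxS + ExS +
#' GxExS + e` by least squares for every gene simultaneously and tests each
#' term with a partial (Type III) F test under sum-to-zero contrasts; in a
#' balanced design this coincides with the sequential decomposition. Genes
#' with zero residual variance (e.g. identical values in all samples) get
#' `p = 1` by contract.
#'
#' @param nm a `normalized_matrix` or plain genes x samples matrix of
#'   normalized counts.
#' @param design a `sample_design`.
#' @param fdr_level BH cutoff (default 0.05).
#' @return A `de_table_set`: one data.frame per term
#'   (`gene, stat, df, p, q, significant`); `stat` is the F statistic.
#' @export
ln_anova <- function(nm, design, fdr_level = 0.05) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  d <- design[match(colnames(v), design$sample_id), ]
  dat <- data.frame(sex = droplevels(d$sex), genotype = droplevels(d$genotype),
                    environment = droplevels(d$environment))
  Y <- t(log(v + 1))                              # samples x genes
  n <- nrow(Y)
  ctr <- list(sex = "contr.sum", genotype = "contr.sum",
              environment = "contr.sum")
  X <- stats::model.matrix(~ sex * genotype * environment, dat,
                           contrasts.arg = ctr)
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, keep, drop = FALSE]; asgn <- asgn[keep]
  }
  term_labels <- attr(stats::terms(~ sex * genotype * environment),
                      "term.labels")
  term_map <- c(sex = "S", genotype = "G", environment = "E",
                "sex:genotype" = "GxS", "sex:environment" = "ExS",
                "genotype:environment" = "GxE",
                "sex:genotype:environment" = "GxExS")
  rss <- function(Xm) {
    qx <- qr(Xm)
    r <- qx$rank
    qty <- qr.qty(qx, Y)
    tot <- colSums(Y^2)
    pmax(tot - colSums(qty[seq_len(r), , drop = FALSE]^2), 0)
  }
  rss_full <- rss(X)
  df_err <- n - qr(X)$rank
  if (df_err < 1L) stop("no residual degrees of freedom for the full model")
  tot_var <- apply(Y, 2L, stats::var)
  degenerate <- rss_full <= 1e-10 * pmax(colSums(Y^2), 1) | tot_var == 0
  out <- list()
  for (i in seq_along(term_labels)) {
    cols <- which(asgn == i)
    df_t <- length(cols)
    Xr <- X[, -cols, drop = FALSE]
    rss_r <- rss(Xr)
    Fstat <- ((rss_r - rss_full) / df_t) / (rss_full / df_err)
    p <- stats::pf(Fstat, df_t, df_err, lower.tail = FALSE)
    p[degenerate] <- 1
    Fstat[degenerate] <- NA_real_
    q <- bh_adjust(p)
    out[[term_map[[term_labels[i]]]]] <-
      data.frame(gene = rownames(v), stat = Fstat, df = df_t, p = p, q = q,
                 significant = q < fdr_level)
  }
  out <- out[c("S", "G", "E", "GxE", "GxS", "ExS", "GxExS")]
  structure(out, class = "de_table_set", approach = "ln_anova")
}

#' Significant gene set of a DE table
#' @param de_set a `de_table_set`.
#' @param term term name (`S, G, E, GxE, GxS, ExS, GxExS`).
#' @param fdr_level optional override of the stored significance flag.
#' @return Character vector of significant gene ids.
#' @export
significant_genes <- function(de_set, term, fdr_level = NULL) {
  tab <- de_set[[term]]
  if (is.null(tab)) stop("unknown term: ", term)
  if (is.null(fdr_level)) tab$gene[which(tab$significant)]
  else tab$gene[which(tab$q < fdr_level)]
}
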