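#' Noncentrality parameter for the three-way interaction F test
#'
#' For a balanced a x b x c fixed-effects ANOVA with n replicates per cell
#' and interaction deviations `(abc)_ijk` (the part of each cell mean not
#' accounted for by main effects and two-way interactions),
#' `lambda = n * sum (abc)_ijk^2 / sigma^2`; the alternative form is
#' `phi^2 = lambda / ((a-1)(b-1)(c-1) + 1)`.
#'
#' @param effects numeric array (a x b x c) or vector of interaction
#'   deviations; must sum to zero over every margin (tolerance 1e-8).
#' @param sigma2 error variance on the ln scale (> 0).
#' @param n replicates per cell.
#' @param dims `c(a, b, c)`; required when `effects` is not an array.
#' @return A list: `lambda`, `phi2`.
#' @export
noncentrality <- function(effects, sigma2, n, dims = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  arr <- if (is.array(effects) && length(dim(effects)) == 3L) effects
         else {
           if (is.null(dims)) stop("dims = c(a, b, c) required for a vector")
           array(effects, dim = dims)
         }
  margins <- c(apply(arr, c(1, 2), sum), apply(arr, c(1, 3), sum),
               apply(arr, c(2, 3), sum))
  if (max(abs(margins)) > 1e-8 * max(1, max(abs(arr))))
    stop("effects are not in the three-way interaction subspace ",
         "(margins do not sum to zero)")
  lambda <- n * sum(arr^2) / sigma2
  dm <- dim(arr)
  list(lambda = lambda,
       phi2 = lambda / ((dm[1] - 1) * (dm[2] - 1) * (dm[3] - 1) + 1))
}

#' Minimum noncentrality for a given standardized fold-change
#'
#' Over all interaction-effect patterns whose cell means have range
#' `D = d * sigma`, the noncentrality is minimized by two cells at
#' `+D/2` and `-D/2` with the rest at zero, giving `lambda_min = n d^2 / 2`.
#' Using it makes a power estimate conservative.
#'
#' @param n replicates per cell.
#' @param d standardized fold-change `D / sigma` (ln scale).
#' @return `n * d^2 / 2`.
#' @export
lambda_min <- function(n, d) {
  stopifnot(n >= 1, d >= 0)
  n * d^2 / 2
}

#' Power of a (noncentral) F test
#'
#' `P[F'(df1, df2, lambda) > F_crit(alpha; df1, df2)]`; at `lambda = 0`
#' this is exactly `alpha`.
#'
#' @param lambda noncentrality (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_f <- function(lambda, df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

power_dfs <- function(a, b, c, n, term = c("three_way", "first_order")) {
  term <- match.arg(term)
  df1 <- if (term == "three_way") (a - 1) * (b - 1) * (c - 1)
         else (a - 1) * (b - 1)
  list(df1 = df1, df2 = a * b * c * (n - 1))
}

#' Smallest detectable fold-change at a target power
#'
#' Solves `power_f(n_eff * (D / sigma)^2 / 2, df1, df2, alpha) =
#' target_power` for the ln-scale fold-change `D` by bracketed
#' root-finding. The conservative minimum noncentrality is used, so the
#' returned `D` is an upper bound on what the design can detect. For the
#' three-way interaction the per-pattern replication is `n`
#' (`df1 = (a-1)(b-1)(c-1)`); for a first-order interaction of the first
#' two factors each interaction cell is replicated over the `c` levels of
#' the third factor, so the effective replication is `c * n` and
#' `df1 = (a-1)(b-1)`.
#'
#' @param n replicates per cell.
#' @param target_power desired power (default 0.80), must exceed `alpha`.
#' @param sigma2 ln-scale error variance.
#' @param a,b,c factor level counts (defaults 16, 3, 2).
#' @param alpha significance level (default 0.05).
#' @param term `"three_way"` or `"first_order"`.
#' @return A list: `D` (ln scale), `fold_change` (`exp(D)`), `lambda`,
#'   `df1`, `df2`.
#' @export
detectable_fold_change <- function(n, target_power = 0.80, sigma2 = 1,
                                   a = 16, b = 3, c = 2, alpha = 0.05,
                                   term = c("three_way", "first_order")) {
  term <- match.arg(term)
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)")
  if (n < 2) stop("need n >= 2 for a nonzero error df")
  dfs <- power_dfs(a, b, c, n, term)
  n_eff <- if (term == "three_way") n else c * n
  pw <- function(D) power_f(n_eff * D^2 / (2 * sigma2), dfs$df1, dfs$df2,
                            alpha) - target_power
  hi <- sqrt(sigma2)
  while (pw(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (pw(hi) < 0) stop("no root found: target power unreachable")
  D <- stats::uniroot(pw, c(0, hi), tol = 1e-10)$root
  list(D = D, fold_change = exp(D), lambda = n_eff * D^2 / (2 * sigma2),
       df1 = dfs$df1, df2 = dfs$df2)
}

#' Detectable fold-change curve over replicate numbers
#'
#' @param n_range replicate counts (default 2:8).
#' @inheritParams detectable_fold_change
#' @return A data.frame: `n, D, fold_change` (D strictly decreasing in n).
#' @export
power_curve <- function(n_range = 2:8, target_power = 0.80, sigma2 = 1,
                        a = 16, b = 3, c = 2, alpha = 0.05,
                        term = "three_way") {
  rows <- lapply(n_range, function(n)
    c(n = n, D = detectable_fold_change(n, target_power, sigma2, a, b, c,
                                        alpha, term)$D))
  df <- as.data.frame(do.call(rbind, rows))
  df$fold_change <- exp(df$D)
  df
}

#' Monte-Carlo power of the three-way interaction F test
#'
#' Simulates a balanced three-factor Gaussian ANOVA with the given
#' interaction effects and counts rejections of the three-way term;
#' independent check of the closed-form noncentral-F power.
#'
#' @param effects a x b x c array of interaction deviations.
#' @param sigma2 error variance.
#' @param n replicates per cell.
#' @param alpha significance level.
#' @param n_rep Monte-Carlo replicates.
#' @param seed integer seed.
#' @return Estimated power (rejection fraction).
#' @export
mc_anova_power <- function(effects, sigma2, n, alpha = 0.05, n_rep = 1e4,
                           seed = 1L) {
  set.seed(seed)
  dm <- dim(effects)
  a <- dm[1]; b <- dm[2]; c <- dm[3]
  ncell <- a * b * c
  df1 <- (a - 1) * (b - 1) * (c - 1)
  df2 <- ncell * (n - 1)
  crit <- stats::qf(1 - alpha, df1, df2)
  mu <- as.vector(effects)
  # three-way interaction projector on cell means
  Ja <- diag(a) - 1 / a; Jb <- diag(b) - 1 / b; Jc <- diag(c) - 1 / c
  P <- kronecker(Jc, kronecker(Jb, Ja))   # cells ordered a fastest
  rej <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_rep) {
    m <- min(chunk, n_rep - done)
    # cell means over n replicates and residual SS, simulated directly
    cellbar <- matrix(stats::rnorm(ncell * m, mean = mu,
                                   sd = sqrt(sigma2 / n)), ncell, m)
    ss_err <- sigma2 * stats::rchisq(m, df2)
    eff_hat <- P %*% cellbar
    ss_int <- n * colSums(eff_hat^2)
    Fstat <- (ss_int / df1) / (ss_err / df2)
    rej <- rej + sum(Fstat > crit)
    done <- done + m
  }
  rej / n_rep
}

#' Empirical power by subsampling a full study
#'
#' Draws `n_sub` individuals per genotype x environment x sex cell without
#' replacement, reruns the differential-expression analysis on the
#' subsample, and reports per term and per FDR threshold the percentage of
#' the full-data significant genes recovered.
#'
#' @param full_de a `de_table_set` from the full data.
#' @param counts the matrix analysed for `full_de` (integer counts for the
#'   NB engine, normalized values for `engine = "lnanova"`).
#' @param design a `sample_design`.
#' @param n_sub replicates per cell to keep (must not exceed the smallest
#'   cell).
#' @param fdr_grid FDR thresholds to evaluate (default
#'   `c(0.01, 0.05, 0.1)`).
#' @param engine `"nbglm"` or `"lnanova"`.
#' @param seed integer seed for the subsample draw.
#' @param ... passed to [test_terms()] / [ln_anova()].
#' @return A data.frame: `term, fdr, n_sub, n_full_sig, n_recovered,
#'   overlap_pct`.
#' @export
empirical_subsample_power <- function(full_de, counts, design, n_sub,
                                      fdr_grid = c(0.01, 0.05, 0.1),
                                      engine = c("nbglm", "lnanova"),
                                      seed = 1L, ...) {
  engine <- match.arg(engine)
  d <- design[match(colnames(counts), design$sample_id), ]
  cell <- interaction(d$genotype, d$environment, d$sex, drop = TRUE)
  if (n_sub > min(table(cell)))
    stop("n_sub exceeds the smallest design cell (",
         min(table(cell)), ")")
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(cell), cell), function(ix)
    if (length(ix) == n_sub) ix else sample(ix, n_sub)))
  keep <- sort(keep)
  sub_counts <- counts[, keep, drop = FALSE]
  sub_de <- if (engine == "nbglm") test_terms(sub_counts, design, ...)
            else ln_anova(sub_counts, design, ...)
  terms <- names(full_de)
  rows <- list()
  for (tm in terms) {
    for (fdr in fdr_grid) {
      full_sig <- significant_genes(full_de, tm, fdr_level = fdr)
      sub_sig <- significant_genes(sub_de, tm, fdr_level = fdr)
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, fdr = fdr, n_sub = n_sub,
        n_full_sig = length(full_sig),
        n_recovered = length(intersect(full_sig, sub_sig)),
        overlap_pct = if (length(full_sig) == 0) NA_real_
                      else 100 * length(intersect(full_sig, sub_sig)) /
                           length(full_sig))
    }
  }
  do.call(rbind, rows)
}
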