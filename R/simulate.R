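#' Simulation configuration for a factorial single-individual RNA-Seq study
#'
#' The defaults emulate the structure of a large factorial fly study: 16
#' genotypes x 3 environments x 2 sexes with up to 8 individuals per cell,
#' a heavy-tailed baseline expression distribution (a small set of genes
#' carries most reads), negative-binomial overdispersion with a log-normal
#' dispersion distribution, low-rate intergenic background reads, 32
#' spike-in control genes whose means do not depend on the biology, a
#' subset of individuals sequenced as duplicate libraries, and 76 bp reads.
#'
#' @param n_genes number of genic features.
#' @param n_intergenic number of intergenic background features.
#' @param a,b,c genotype / environment / sex level counts (defaults 16, 3, 2).
#' @param n_per_cell individuals per cell (default 8).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for the
#'   baseline per-gene mean; `sdlog = 2` gives the heavy right tail.
#' @param phi_meanlog,phi_sdlog log-normal parameters for the per-gene NB
#'   dispersion `phi_i` (defaults centre phi near 0.1). `phi_sdlog = 0`
#'   with `phi_meanlog = -Inf` yields the Poisson limit.
#' @param de_fraction named numeric: fraction of genes differentially
#'   expressed for each model term (`S, G, E, GxE, GxS, ExS, GxExS`).
#' @param effect_size named numeric: natural-log effect (max - min of the
#'   term's level offsets) for DE genes of each term.
#' @param sigma_fly standard deviation of a per-individual log-scale random
#'   effect shared by a fly's duplicate libraries (technical-replicate
#'   structure); 0 disables it.
#' @param libsize_sdlog spread of the per-sample library-size factor
#'   (log-normal, mean 1).
#' @param n_spikeins number of spike-in control rows (default 32).
#' @param duplicate_library_fraction fraction of individuals sequenced twice.
#' @param intergenic_rate mean of the exponential distribution that draws
#'   per-feature intergenic background rates (counts per library at unit
#'   depth factor).
#' @param read_length read length in bp (default 76).
#' @param rng_seed integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_intergenic = 500L,
                              a = 16L, b = 3L, c = 2L, n_per_cell = 8L,
                              baseline_meanlog = 3, baseline_sdlog = 2,
                              phi_meanlog = log(0.1), phi_sdlog = 0.5,
                              de_fraction = c(S = 0.2, G = 0.1, E = 0.05,
                                              GxE = 0.05, GxS = 0.05,
                                              ExS = 0.05, GxExS = 0.03),
                              effect_size = c(S = 1.5, G = 1, E = 1,
                                              GxE = 1, GxS = 1, ExS = 1,
                                              GxExS = 1),
                              sigma_fly = 0.1,
                              libsize_sdlog = 0.25,
                              n_spikeins = 32L,
                              duplicate_library_fraction = 0,
                              intergenic_rate = 2,
                              read_length = 76L,
                              rng_seed = 1L) {
  terms <- c("S", "G", "E", "GxE", "GxS", "ExS", "GxExS")
  de_fraction <- de_fraction[terms]; de_fraction[is.na(de_fraction)] <- 0
  names(de_fraction) <- terms
  effect_size <- effect_size[terms]; effect_size[is.na(effect_size)] <- 0
  names(effect_size) <- terms
  if (n_genes < 1L || n_per_cell < 1L || a < 2L || c < 2L)
    stop("degenerate simulation config (need genes, replicates and >= 2 ",
         "genotype and sex levels)")
  if (any(de_fraction < 0 | de_fraction > 1))
    stop("de_fraction entries must lie in [0, 1]")
  if (any(!is.finite(effect_size)))
    stop("effect sizes must be finite")
  structure(as.list(environment()), class = "simulation_config")
}

# Split a gene's term effect over the term's level combinations: a random
# half of the combinations get +e/2, the rest -e/2, so max - min equals the
# stated effect on the ln scale.
term_offsets <- function(n_levels, effect) {
  pos <- sample.int(n_levels, n_levels %/% 2)
  off <- rep(-effect / 2, n_levels)
  off[pos] <- effect / 2
  off
}

#' Simulate a complete factorial RNA-Seq study with known truth
#'
#' Genic counts are drawn as gamma-Poisson (negative binomial) with mean
#' `s_k * exp(log baseline + term effects + fly effect)` and variance
#' `mu + mu^2 * phi_i`, so the mean-variance law holds by construction.
#' Intergenic features get Poisson background counts with per-feature
#' exponential rates; spike-in rows depend only on the depth factor `s_k`;
#' duplicate libraries share all biology (including the fly effect) and
#' resample only the counting noise.
#'
#' @param config a [simulation_config()].
#' @return A list: `counts` (genic + spike-in `count_matrix`), `intergenic`
#'   (`count_matrix`), `features` (`feature_table` covering genic,
#'   spike-in and intergenic rows), `design` (`sample_design`), `truth`
#'   (list: `de_genes` per term, `size_factors`, `phi`, `cell_means`,
#'   `spikein_ids`, `sex`, `genotype`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$rng_seed)
  G <- factor(rep(seq_len(cf$a), each = cf$b * cf$c * cf$n_per_cell))
  E <- factor(rep(rep(seq_len(cf$b), each = cf$c * cf$n_per_cell), cf$a))
  S <- factor(rep(rep(seq_len(cf$c), each = cf$n_per_cell), cf$a * cf$b))
  n_ind <- length(G)
  ind_id <- sprintf("fly_%03d", seq_len(n_ind))

  # duplicate libraries: chosen individuals contribute two columns
  dup <- if (cf$duplicate_library_fraction > 0)
    sort(sample.int(n_ind, max(2L, round(cf$duplicate_library_fraction * n_ind))))
  else integer(0)
  col_ind <- c(seq_len(n_ind), dup)            # individual behind each column
  lib_no <- c(rep(1L, n_ind), rep(2L, length(dup)))
  ord <- order(col_ind, lib_no)
  col_ind <- col_ind[ord]; lib_no <- lib_no[ord]
  n_samp <- length(col_ind)
  sample_id <- sprintf("%s_L%d", ind_id[col_ind], lib_no)

  design <- sample_design(
    sample_id = sample_id, genotype = paste0("G", G[col_ind]),
    environment = paste0("E", E[col_ind]), sex = c("M", "F")[S[col_ind]],
    replicate_index = stats::ave(seq_len(n_samp),
                                 paste(G[col_ind], E[col_ind], S[col_ind]),
                                 FUN = seq_along),
    library_id = sample_id, individual_id = ind_id[col_ind])

  gene_ids <- sprintf("gene_%04d", seq_len(cf$n_genes))
  base <- stats::rlnorm(cf$n_genes, cf$baseline_meanlog, cf$baseline_sdlog)
  phi <- if (is.finite(cf$phi_meanlog))
    stats::rlnorm(cf$n_genes, cf$phi_meanlog, cf$phi_sdlog)
  else rep(0, cf$n_genes)

  # per-term DE truth and log-scale offsets per design cell
  terms <- names(cf$de_fraction)
  n_lev <- c(S = cf$c, G = cf$a, E = cf$b, GxE = cf$a * cf$b,
             GxS = cf$a * cf$c, ExS = cf$b * cf$c, GxExS = cf$a * cf$b * cf$c)
  cellG <- rep(seq_len(cf$a), each = cf$b * cf$c)
  cellE <- rep(rep(seq_len(cf$b), each = cf$c), cf$a)
  cellS <- rep(seq_len(cf$c), cf$a * cf$b)
  term_index <- list(
    S = cellS, G = cellG, E = cellE,
    GxE = (cellG - 1L) * cf$b + cellE,
    GxS = (cellG - 1L) * cf$c + cellS,
    ExS = (cellE - 1L) * cf$c + cellS,
    GxExS = seq_len(cf$a * cf$b * cf$c))
  n_cells <- cf$a * cf$b * cf$c
  log_cell <- matrix(log(base), cf$n_genes, n_cells)   # genes x cells
  de_genes <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) {
    n_de <- round(cf$de_fraction[[tm]] * cf$n_genes)
    de <- if (n_de > 0) sort(sample.int(cf$n_genes, n_de)) else integer(0)
    de_genes[[tm]] <- gene_ids[de]
    for (g in de) {
      off <- term_offsets(n_lev[[tm]], cf$effect_size[[tm]])
      log_cell[g, ] <- log_cell[g, ] + off[term_index[[tm]]]
    }
  }

  s_k <- stats::rlnorm(n_samp, 0, cf$libsize_sdlog)
  names(s_k) <- sample_id
  fly_eff <- if (cf$sigma_fly > 0) stats::rnorm(n_ind, 0, cf$sigma_fly)
             else rep(0, n_ind)

  cell_of_col <- (as.integer(G[col_ind]) - 1L) * cf$b * cf$c +
    (as.integer(E[col_ind]) - 1L) * cf$c + as.integer(S[col_ind])
  mu <- exp(log_cell)[, cell_of_col, drop = FALSE] *
    rep(exp(fly_eff[col_ind]), each = cf$n_genes)
  mu <- sweep(mu, 2L, s_k, "*")

  counts <- matrix(0, cf$n_genes, n_samp)
  pois <- phi == 0
  if (any(pois))
    counts[pois, ] <- stats::rpois(sum(pois) * n_samp, mu[pois, ])
  if (any(!pois)) {
    shape <- 1 / phi[!pois]
    lam <- mu[!pois, , drop = FALSE] *
      matrix(stats::rgamma(sum(!pois) * n_samp, shape = shape, rate = shape),
             sum(!pois), n_samp)
    counts[!pois, ] <- stats::rpois(sum(!pois) * n_samp, lam)
  }

  spike_ids <- if (cf$n_spikeins > 0) sprintf("ERCC_%02d", seq_len(cf$n_spikeins))
               else character(0)
  if (cf$n_spikeins > 0) {
    spike_base <- stats::rlnorm(cf$n_spikeins, cf$baseline_meanlog,
                                cf$baseline_sdlog / 2)
    spike_mu <- outer(spike_base, s_k)
    spike_counts <- matrix(stats::rpois(cf$n_spikeins * n_samp, spike_mu),
                           cf$n_spikeins, n_samp)
    counts <- rbind(counts, spike_counts)
  }
  rownames(counts) <- c(gene_ids, spike_ids)
  colnames(counts) <- sample_id

  ig_ids <- sprintf("intergenic_%04d", seq_len(cf$n_intergenic))
  ig_rate <- stats::rexp(cf$n_intergenic, rate = 1 / cf$intergenic_rate)
  ig_counts <- matrix(stats::rpois(cf$n_intergenic * n_samp,
                                   outer(ig_rate, s_k)),
                      cf$n_intergenic, n_samp,
                      dimnames = list(ig_ids, sample_id))

  cm <- count_matrix(counts)
  igm <- count_matrix(ig_counts + 0L, library_sizes = cm$library_sizes)

  # annotation: tile features along one synthetic contig
  n_feat <- nrow(counts) + cf$n_intergenic
  glen <- pmax(200L, round(stats::rlnorm(nrow(counts), log(1500), 0.6)))
  # intergenic lengths: gene-scale gaps with a long right tail and an
  # occasional fragment below the read length
  ilen <- pmax(10L, round(stats::rlnorm(cf$n_intergenic, log(1500), 1.3)))
  lens <- c(glen, ilen)
  starts <- cumsum(c(0, lens[-n_feat] + 100L))
  noncoding <- rep(FALSE, nrow(counts))
  noncoding[sample.int(cf$n_genes, round(0.05 * cf$n_genes))] <- TRUE
  features <- feature_table(
    feature_id = c(rownames(counts), ig_ids),
    chrom = "chrSim", start = starts, end = starts + lens, strand = "+",
    region_class = rep(c("genic", "intergenic"),
                       c(nrow(counts), cf$n_intergenic)),
    coding_class = c(ifelse(noncoding, "non_coding", "protein_coding"),
                     rep(NA_character_, cf$n_intergenic)),
    read_length = cf$read_length)

  truth <- list(de_genes = de_genes, size_factors = s_k, phi = phi,
                cell_means = exp(log_cell), spikein_ids = spike_ids,
                sex = stats::setNames(design$sex, design$sample_id),
                genotype = stats::setNames(design$genotype, design$sample_id),
                fly_effect = stats::setNames(fly_eff, ind_id))
  list(counts = cm, intergenic = igm, features = features, design = design,
       truth = truth)
}

#' Simulate SNP base calls for genotype verification
#'
#' Each of `a_lines` reference lines gets a base call at every site; each
#' sample copies its true line's calls, flipping each to a different base
#' independently with probability `error_rate` and dropping it to missing
#' with probability `missing_rate`.
#'
#' @param a_lines number of reference lines (>= 2).
#' @param n_sites number of informative SNP sites (default 1000).
#' @param n_samples number of samples.
#' @param error_rate per-site base-call error probability (< 0.5).
#' @param missing_rate per-site dropout probability.
#' @param seed integer seed.
#' @return A list: `calls` (sites x samples character matrix, `NA` =
#'   missing), `line_table` (sites x lines), `true_line` (named integer
#'   vector of each sample's line index).
#' @export
simulate_snp_data <- function(a_lines, n_sites = 1000L, n_samples = 50L,
                              error_rate = 0.02, missing_rate = 0.05,
                              seed = 1L) {
  if (a_lines < 2L) stop("need at least 2 reference lines")
  if (error_rate >= 0.5) stop("error_rate must be < 0.5")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  line_table <- matrix(sample(bases, n_sites * a_lines, replace = TRUE),
                       n_sites, a_lines,
                       dimnames = list(sprintf("site_%04d", seq_len(n_sites)),
                                       sprintf("line_%02d", seq_len(a_lines))))
  true_line <- sample.int(a_lines, n_samples, replace = TRUE)
  names(true_line) <- sprintf("sample_%03d", seq_len(n_samples))
  calls <- line_table[, true_line, drop = FALSE]
  colnames(calls) <- names(true_line)
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n_sites * n_samples) < error_rate,
                   n_sites, n_samples)
    if (any(flip)) {
      calls[flip] <- vapply(calls[flip],
                            function(bcall) sample(setdiff(bases, bcall), 1L),
                            character(1))
    }
  }
  if (missing_rate > 0)
    calls[matrix(stats::runif(n_sites * n_samples) < missing_rate,
                 n_sites, n_samples)] <- NA_character_
  list(calls = calls, line_table = line_table, true_line = true_line)
}
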