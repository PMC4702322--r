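test_that("TC normalization matches the ratio formula and hand example", {
  # two samples, N = (1e6, 3e6), gene counts (10, 30) -> normalized (20, 20)
  cm <- count_matrix(matrix(c(10, 30), 1, 2), gene_ids = "g",
                     library_sizes = c(1e6, 3e6))
  nm <- normalize_tc(cm)
  expect_equal(unname(nm$factors), c(0.5, 1.5))
  expect_equal(unname(nm$values[1, ]), c(20, 20))

  cm2 <- toy_counts()
  expect_equal(unname(normalize_tc(cm2)$values),
               unname(oracle_tc(cm2$counts)), tolerance = 1e-12)

  eq <- count_matrix(matrix(c(5, 7, 5, 7), 2, 2))
  expect_equal(normalize_tc(eq)$values, eq$counts)   # equal depths: identity
})

test_that("UQ and Med normalization ignore all-zero genes and match oracles", {
  cm <- toy_counts()
  expect_equal(unname(normalize_uq(cm)$factors),
               oracle_uq_factors(cm$counts), tolerance = 1e-12)
  expect_equal(unname(normalize_med(cm)$factors),
               oracle_med_factors(cm$counts), tolerance = 1e-12)

  # adding an all-zero gene row leaves the factors unchanged
  m2 <- rbind(cm$counts, zero = rep(0, 6))
  cm2 <- count_matrix(m2)
  expect_equal(unname(normalize_uq(cm2)$factors),
               unname(normalize_uq(cm)$factors))
  expect_equal(unname(normalize_med(cm2)$factors),
               unname(normalize_med(cm)$factors))

  ident <- count_matrix(matrix(rep(c(3, 9, 27), 3), 3, 3))
  expect_equal(normalize_uq(ident)$values, ident$counts)
  expect_equal(normalize_med(ident)$values, ident$counts)
})

test_that("DESeq size factors reproduce the worked example and the oracle", {
  # gene rows (2,8) and (8,32): geomeans (4,16); s = (0.5, 2)
  cm <- count_matrix(matrix(c(2, 8, 8, 32), 2, 2))
  s <- deseq_size_factors(cm)
  expect_equal(unname(s), c(0.5, 2))
  nm <- normalize_deseq(cm)
  expect_equal(unname(nm$values[, 1]), c(4, 16))
  expect_equal(unname(nm$values[, 2]), c(4, 16))

  cm2 <- toy_counts()
  expect_equal(unname(deseq_size_factors(cm2)),
               oracle_deseq_factors(cm2$counts), tolerance = 1e-12)

  # identical samples -> all factors 1; scaling one sample scales its factor
  # relative to the others by the same constant
  ident <- count_matrix(matrix(rep(c(3, 9, 27), 3), 3, 3))
  expect_equal(unname(deseq_size_factors(ident)), rep(1, 3))
  scaled <- count_matrix(cbind(cm2$counts[, 1:5], 3 * cm2$counts[, 6]))
  s0 <- unname(deseq_size_factors(cm2)); s1 <- unname(deseq_size_factors(scaled))
  expect_equal(s1[6] / s1[1], 3 * s0[6] / s0[1], tolerance = 1e-12)
})

test_that("DESeq size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  # odd number of all-positive genes: the median needs no interpolation, so
  # the ratio-scale median and the reference log-scale median coincide
  set.seed(19)
  m <- matrix(rnbinom(11 * 5, mu = 60, size = 8) + 1, 11, 5,
              dimnames = list(paste0("g", 1:11), paste0("s", 1:5)))
  cm <- count_matrix(m)
  expect_equal(unname(deseq_size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cm$counts)),
               tolerance = 1e-10)
})

test_that("quantile normalization equalizes sorted columns and averages ties", {
  # columns (1,2,3) and (2,4,6) -> both (1.5, 3, 4.5)
  cm <- count_matrix(matrix(c(1, 2, 3, 2, 4, 6), 3, 2))
  nm <- normalize_quantile(cm)
  expect_equal(unname(nm$values[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(nm$values[, 2]), c(1.5, 3, 4.5))

  cm2 <- toy_counts()   # has tied values: matches the tie-averaging oracle
  q <- normalize_quantile(cm2)
  expect_equal(unname(q$values), unname(oracle_quantile(cm2$counts)),
               tolerance = 1e-12)

  # on tie-free columns the sorted profiles are exactly equal
  set.seed(6)
  mt <- matrix(sample.int(1e6, 40), 10, 4)
  qt <- normalize_quantile(count_matrix(mt))
  sorted <- apply(qt$values, 2, sort)
  for (k in 2:ncol(sorted))
    expect_equal(sorted[, k], sorted[, 1], tolerance = 1e-12)
})

test_that("RPKM matches the direct formula and its invariances", {
  ft <- feature_table("g1", "chr1", 0, 2000)
  cm <- count_matrix(matrix(100, 1, 1), gene_ids = "g1",
                     library_sizes = 1e7)
  expect_equal(unname(normalize_rpkm(cm, ft)$values[1, 1]), 5)
  cm2 <- count_matrix(matrix(c(200L), 1, 1), gene_ids = "g1",
                      library_sizes = 2e7)
  expect_equal(normalize_rpkm(cm2, ft)$values[1, 1],
               normalize_rpkm(cm, ft)$values[1, 1])  # homogeneity
  cm0 <- count_matrix(matrix(0, 1, 1), gene_ids = "g1", library_sizes = 1e7)
  expect_equal(unname(normalize_rpkm(cm0, ft)$values[1, 1]), 0)
  ft_wrong <- feature_table("other", "chr1", 0, 100)
  expect_error(normalize_rpkm(cm, ft_wrong), "missing gene length")
})

test_that("TMM reference picks the sample closest to the mean upper quartile", {
  m <- matrix(c(rep(10, 5), rep(20, 5), rep(30, 5)), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(tmm_reference(count_matrix(m)), "s2")
  # tie: equidistant -> first by index
  m2 <- matrix(c(rep(10, 5), rep(30, 5)), 5, 2,
               dimnames = list(paste0("g", 1:5), c("sA", "sB")))
  expect_equal(tmm_reference(count_matrix(m2)), "sA")
})

test_that("TMM factors match the trimmed weighted-mean oracle", {
  cm <- toy_counts()
  ref <- tmm_reference(cm)
  nm <- normalize_tmm(cm, renorm_geomean = FALSE)
  for (k in setdiff(cm$sample_ids, ref)) {
    expect_equal(unname(nm$factors[[k]]),
                 oracle_tmm_factor(cm$counts[, k], cm$counts[, ref],
                                   cm$library_sizes[[k]],
                                   cm$library_sizes[[ref]]),
                 tolerance = 1e-12)
  }
  # sample identical to reference -> all M = 0 -> factor 1
  expect_equal(unname(nm$factors[[ref]]), 1)

  # sample = 2x reference with N = 2N_r -> M all zero -> factor 1
  base <- cm$counts[, ref]
  m2 <- cbind(ref = base, dbl = 2 * base)
  cm2 <- count_matrix(m2, library_sizes = c(sum(base), 2 * sum(base)))
  nm2 <- normalize_tmm(cm2, reference = "ref", renorm_geomean = FALSE)
  expect_equal(unname(nm2$factors[["dbl"]]), 1, tolerance = 1e-12)
})

test_that("the M-trim absorbs a single strong outlier gene", {
  set.seed(11)
  base <- rpois(20, 200) + 1
  out <- base + rpois(20, 5)
  out[7] <- out[7] * 8                      # 8-fold outlier in one gene
  N <- c(1e5, 1e5)                          # equal depths: isolate the trim
  cmo <- count_matrix(cbind(r = base, k = out), library_sizes = N)
  f_with <- normalize_tmm(cmo, reference = "r",
                          renorm_geomean = FALSE)$factors[["k"]]
  no_out <- out; no_out[7] <- base[7]
  cmn <- count_matrix(cbind(r = base, k = no_out), library_sizes = N)
  f_wo <- normalize_tmm(cmn, reference = "r",
                        renorm_geomean = FALSE)$factors[["k"]]
  expect_lt(abs(f_with - f_wo) / f_wo, 0.01)
})

test_that("RUVg factors recover a per-sample shift from control genes", {
  set.seed(5)
  shift <- c(-0.6, -0.2, 0.1, 0.3, 0.4)
  ctrl <- exp(outer(rnorm(12, 5, 0.4), shift, "+"))
  m <- rbind(round(ctrl), matrix(rpois(20 * 5, 50), 20, 5))
  rownames(m) <- c(paste0("ctl", 1:12), paste0("g", 1:20))
  cm <- count_matrix(m)
  W <- ruvg_factors(cm, paste0("ctl", 1:12), k = 1)
  expect_gt(abs(cor(W[, 1], shift)), 0.999)

  # constant controls -> near-zero factor structure
  mc <- rbind(matrix(7, 4, 5, dimnames = list(paste0("c", 1:4), NULL)),
              matrix(rpois(10 * 5, 30), 10, 5,
                     dimnames = list(paste0("g", 1:10), NULL)))
  Wc <- ruvg_factors(count_matrix(mc), paste0("c", 1:4), k = 1)
  expect_lt(attr(Wc, "d")[1], 1e-10)

  # k = 2 on (near) rank-1 controls: second factor explains ~0 variance
  W2 <- ruvg_factors(cm, paste0("ctl", 1:12), k = 2)
  d <- attr(W2, "d")
  expect_lt(d[2]^2 / sum(d^2), 0.05)
  expect_error(ruvg_factors(cm, paste0("ctl", 1:2), k = 2), "smaller")
})

test_that("dispatch covers all methods, RC identity, unknown method errors", {
  cm <- toy_counts()
  ft <- feature_table(cm$gene_ids, "chr1", seq(0, 9000, 1000),
                      seq(1000, 10000, 1000))
  for (m in c("TC", "UQ", "Med", "TMM", "DESeq", "Q", "RPKM", "RC")) {
    nm <- normalize_counts(cm, m, features = ft)
    expect_s3_class(nm, "normalized_matrix")
    expect_identical(nm$method, m)
    expect_true(all(nm$values >= 0))
  }
  expect_identical(normalize_counts(cm, "RC")$values, cm$counts)
  expect_error(normalize_counts(cm, "CPM"), "unknown normalization")
})

test_that("per-sample scaling methods preserve within-sample rank order", {
  cm <- small_study()$counts
  rk <- apply(cm$counts, 2, rank)
  for (m in c("TC", "UQ", "Med", "TMM", "DESeq")) {
    nm <- normalize_counts(cm, m)
    expect_equal(apply(nm$values, 2, rank), rk, info = m)
  }
})

test_that("size-factor recovery on synthetic data with known truth", {
  cf <- simulation_config(n_genes = 2000, a = 4, b = 2, c = 2, n_per_cell = 2,
                          phi_meanlog = log(0.1), libsize_sdlog = 0.3,
                          de_fraction = c(S = 0), sigma_fly = 0,
                          n_spikeins = 0, rng_seed = 33)
  sim <- simulate_experiment(cf)
  s_hat <- deseq_size_factors(sim$counts)
  s_true <- sim$truth$size_factors
  # size factors are defined up to a common scale
  ratio <- s_hat / s_true
  rel_err <- abs(ratio / median(ratio) - 1)
  expect_lt(median(rel_err), 0.05)
})

test_that("TMM/DESeq factors resist extreme-count genes better than TC", {
  set.seed(71)
  m <- matrix(rnbinom(400 * 4, mu = 80, size = 10), 400, 4,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  cm <- count_matrix(m)
  # add 5 % extreme genes blowing up sample 1 only
  extra <- matrix(5, 20, 4, dimnames = list(paste0("x", 1:20), colnames(m)))
  extra[, 1] <- 5000
  cme <- count_matrix(rbind(m, extra))
  # perturbation of the normalized values of the original genes
  shared <- rownames(m)
  perturb <- function(v0, v1)
    max(abs(log(v1[shared, ] / pmax(v0[shared, ], 0.5))))
  d_tc <- perturb(normalize_tc(cm)$values, normalize_tc(cme)$values)
  d_ds <- perturb(normalize_deseq(cm)$values, normalize_deseq(cme)$values)
  ref <- tmm_reference(cm)
  d_tmm <- perturb(normalize_tmm(cm, reference = ref)$values,
                   normalize_tmm(cme, reference = ref)$values)
  expect_lt(d_ds, d_tc)
  expect_lt(d_tmm, d_tc)
})
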