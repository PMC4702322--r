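test_that("threshold is the type-7 percentile of pooled intergenic log2 values", {
  # intergenic log2(x+1) values 1..20 in one sample: 95th pct = 19.05
  ig_counts <- matrix(round(2^(1:20) - 1), 20, 1,
                      dimnames = list(paste0("ig", 1:20), "s1"))
  genic <- count_matrix(matrix(1000, 2, 1,
                               dimnames = list(c("g1", "g2"), "s1")))
  ig <- count_matrix(ig_counts, library_sizes = genic$library_sizes)
  thr <- empirical_threshold(genic, ig, "RC")
  expect_equal(thr$threshold, 19.05, tolerance = 1e-10)

  # all intergenic zero -> threshold 0; higher percentile never lowers it
  ig0 <- count_matrix(matrix(0, 5, 1, dimnames = list(paste0("z", 1:5), "s1")),
                      library_sizes = genic$library_sizes)
  expect_equal(empirical_threshold(genic, ig0, "RC")$threshold, 0)
  t90 <- empirical_threshold(genic, ig, "RC", percentile = 90)$threshold
  expect_lte(t90, thr$threshold)

  # permutation invariance over samples
  sim <- small_study()
  perm <- sample(sim$counts$sample_ids)
  t1 <- empirical_threshold(sim$counts, sim$intergenic, "TC")
  t2 <- empirical_threshold(subset_counts(sim$counts, samples = perm),
                            subset_counts(sim$intergenic, samples = perm),
                            "TC")
  expect_equal(t1$threshold, t2$threshold, tolerance = 1e-12)
})

test_that("low-expression filter keeps any gene detected in one sample", {
  vals <- rbind(lowall = c(1, 1, 1), once = c(1, 1, 200), high = c(300, 310, 290))
  nm <- structure(list(values = vals, method = "RC", factors = NULL),
                  class = "normalized_matrix")
  thr <- structure(list(method = "RC", threshold = 5, percentile = 95,
                        n_intergenic = 10), class = "threshold_result")
  fl <- filter_low_expression(nm, thr)
  expect_setequal(rownames(fl$matrix$values), c("once", "high"))
  expect_equal(fl$removed, "lowall")

  # idempotence: a second pass removes nothing
  fl2 <- filter_low_expression(fl$matrix, thr)
  expect_equal(fl2$n_removed, 0)

  # threshold 0 removes nothing
  thr0 <- structure(list(method = "RC", threshold = 0, percentile = 95,
                         n_intergenic = 10), class = "threshold_result")
  expect_equal(filter_low_expression(nm, thr0)$n_removed, 0)

  # scale mismatch is an error
  thr_tc <- structure(list(method = "TC", threshold = 5, percentile = 95,
                           n_intergenic = 10), class = "threshold_result")
  expect_error(filter_low_expression(nm, thr_tc), "mismatch")
})

test_that("non-coding removal drops exactly the flagged rows", {
  sim <- small_study()
  ft <- sim$features
  out <- filter_noncoding(sim$counts, ft)
  removed <- attr(out, "removed")
  nc <- ft$feature_id[!is.na(ft$coding_class) & ft$coding_class == "non_coding"]
  expect_setequal(removed, intersect(sim$counts$gene_ids, nc))
  expect_equal(nrow(out$counts) + length(removed), nrow(sim$counts$counts))

  # removal then re-normalization changes DESeq size factors
  s_before <- deseq_size_factors(sim$counts)
  s_after <- deseq_size_factors(count_matrix(out$counts))
  expect_false(isTRUE(all.equal(unname(s_before), unname(s_after))))

  # all-coding input is untouched
  all_pc <- feature_table(sim$counts$gene_ids, "chr1",
                          seq_len(nrow(sim$counts$counts)) * 10,
                          seq_len(nrow(sim$counts$counts)) * 10 + 500)
  expect_equal(nrow(filter_noncoding(sim$counts, all_pc)$counts),
               nrow(sim$counts$counts))
})

test_that("workflows differ exactly where re-normalization is sensitive", {
  sim <- small_study()
  mk <- function(wf, method) {
    cfg <- analysis_config(normalization_method = method, workflow = wf)
    apply_workflow(sim$counts, sim$intergenic, sim$features, cfg)
  }
  # TC: frozen library sizes -> workflow 1 and 2 agree on shared genes
  w1 <- mk(1, "TC"); w2 <- mk(2, "TC")
  shared <- intersect(rownames(w1$matrix$values), rownames(w2$matrix$values))
  expect_equal(w1$matrix$values[shared, ], w2$matrix$values[shared, ],
               tolerance = 1e-12)
  # Med: the median moves after removal -> matrices differ
  m1 <- mk(1, "Med"); m2 <- mk(2, "Med")
  sharedm <- intersect(rownames(m1$matrix$values), rownames(m2$matrix$values))
  expect_gt(max(abs(m1$matrix$values[sharedm, ] - m2$matrix$values[sharedm, ])),
            1e-6)
  # workflow 3 keeps every gene
  w3 <- mk(3, "DESeq")
  expect_equal(nrow(w3$matrix$values), nrow(sim$counts$counts))
  expect_null(w3$threshold)

  # no gene below threshold -> workflows coincide
  high <- count_matrix(sim$counts$counts + 10000L)
  ig0 <- count_matrix(matrix(0L, 3, ncol(high$counts),
                             dimnames = list(paste0("z", 1:3),
                                             high$sample_ids)),
                      library_sizes = high$library_sizes)
  cfg <- analysis_config(normalization_method = "TC", workflow = 1)
  a1 <- apply_workflow(high, ig0, sim$features, cfg)
  cfg2 <- analysis_config(normalization_method = "TC", workflow = 2)
  a2 <- apply_workflow(high, ig0, sim$features, cfg2)
  expect_equal(a1$matrix$values, a2$matrix$values, tolerance = 1e-12)
  expect_equal(length(a1$removed), 0)
})
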