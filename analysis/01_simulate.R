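#!/usr/bin/env Rscript
# Generate the synthetic factorial single-fly study used by the downstream
# analysis steps, and write it to results/data/ in plain-text formats.
#
# The design mirrors the structure of a large factorial expression study of
# individual flies — genotype x environment x sex with replicates, ERCC-style
# spike-in controls, intergenic background features, a subset of individuals
# sequenced as duplicate libraries, and informative SNP sites for genotype
# verification — at a desk-scale size (6 genotypes, 2000 genes).

library(countbench)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cf <- simulation_config(
  n_genes = 2000, n_intergenic = 500,
  a = 6, b = 3, c = 2, n_per_cell = 4,
  duplicate_library_fraction = 0.1, sigma_fly = 0.15,
  rng_seed = 20260101)
sim <- simulate_experiment(cf)

write_count_matrix(sim$counts, file.path(out, "counts_genic.tsv"))
write_count_matrix(sim$intergenic, file.path(out, "counts_intergenic.tsv"))
write_annotation_gff3(sim$features, file.path(out, "features.gff3"))
write_design(sim$design, file.path(out, "design.tsv"))

snp <- simulate_snp_data(a_lines = 6, n_sites = 1000,
                         n_samples = ncol(sim$counts$counts),
                         error_rate = 0.02, missing_rate = 0.05,
                         seed = 20260102)
write.table(data.frame(site_id = rownames(snp$calls), snp$calls),
            file.path(out, "snp_calls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(site_id = rownames(snp$line_table), snp$line_table),
            file.path(out, "snp_lines.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(config = cf, truth = sim$truth, snp_truth = snp$true_line),
        file.path(out, "truth.rds"))  # scratch object for later steps

bal <- design_balance(sim$design)
tot <- rowSums(sim$counts$counts)
top_share <- sum(sort(tot, decreasing = TRUE)[1:50]) / sum(tot)
cat(sprintf(
  "simulated %d genic + %d spike-in + %d intergenic features x %d libraries\n",
  cf$n_genes, cf$n_spikeins, cf$n_intergenic, ncol(sim$counts$counts)))
cat(sprintf("balanced design: %s; top 50 genes carry %.1f%% of reads\n",
            bal$balanced, 100 * top_share))
cat(sprintf("duplicate libraries: %d individuals\n",
            sum(table(sim$design$individual_id) == 2)))
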