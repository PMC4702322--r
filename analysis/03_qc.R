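#!/usr/bin/env Rscript
# Sample-identity quality control: verify each library's genotype against
# the reference-line SNP table, verify sex against dimorphic expression
# standards, apply the minimum mapped-read filter, and quantify technical
# variation between duplicate libraries.

library(countbench)

dat <- "results/data"
counts <- read_count_matrix(file.path(dat, "counts_genic.tsv"))
design <- read_design(file.path(dat, "design.tsv"), counts = counts)
truth <- readRDS(file.path(dat, "truth.rds"))

snp_calls <- read.delim(file.path(dat, "snp_calls.tsv"), row.names = 1,
                        check.names = FALSE)
snp_lines <- read.delim(file.path(dat, "snp_lines.tsv"), row.names = 1,
                        check.names = FALSE)
gq <- genotype_verify(as.matrix(snp_calls), as.matrix(snp_lines))
acc <- mean(gq$assigned == colnames(snp_lines)[truth$snp_truth])
cat(sprintf("genotype verification: %.1f%% of libraries assigned to their true line (%d ties)\n",
            100 * acc, sum(gq$tie)))

nm <- normalize_counts(counts, "DESeq")
sq <- sex_verify(nm, design)
cat(sprintf("sex verification: %d/%d libraries pass at same-sex correlation >= %.3f\n",
            sum(sq$pass), length(sq$pass), sq$correlation_threshold))

kept <- min_reads_filter(counts, min_mapped = 1000)  # desk-scale depth
cat(sprintf("mapped-read filter: %d kept, %d excluded\n",
            length(kept), length(attr(kept, "excluded"))))

tr <- technical_replicate_test(counts, design,
                               spikein_ids = truth$truth$spikein_ids)
cat(sprintf("duplicate-library fly-factor test: %d genic and %d spike-in genes significant (FDR < 0.05)\n",
            tr$n_sig_genic, tr$n_sig_spikein))

qc <- data.frame(sample_id = colnames(as.matrix(snp_calls)),
                 assigned_line = gq$assigned, genotype_pass = gq$pass,
                 sex_cor_same = sq$cor_same[colnames(as.matrix(snp_calls))],
                 sex_pass = sq$pass[colnames(as.matrix(snp_calls))])
write_result_table(qc, "results/qc_report.tsv")

pc <- pca_diagnostic(nm, design)
cat(sprintf("PCA: PC1 explains %.1f%% of variance; sex silhouette on PC1 = %.2f\n",
            pc$percent_var[1], pc$pc1_sex_silhouette))
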