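#!/usr/bin/env Rscript
# Stage 4: male vs female differential expression within the replicate-
# matched total RNA samples (negative-binomial exact-style test,
# median-of-ratios size factors, BH adjustment, 10% FDR).

source("analysis/00_config.R")

ann <- generate_annotation(run_config)
reads <- simulate_read_starts(ann, run_config, run_design)
cm <- count_reads(reads, ann)
gt <- gene_table(ann)
locus <- setNames(sprintf("%s:%d-%d", gt$contig, gt$start, gt$end),
                  rownames(gt))

tot <- run_design[run_design$protocol == "totRNA", ]
counts <- cm$counts[, tot$sample_id]
sf <- size_factors(counts)
cond <- factor(tot$sex, levels = c("M", "F"))
disp <- estimate_dispersions(counts, sf, groups = as.character(cond))
print(disp)

res <- nb_test(counts, sf, disp, cond, locus = locus)
write.table(res[order(res$padj),
                c("gene_id", "locus", "baseMean", "baseMeanA", "baseMeanB",
                  "FC", "log2FC", "pval", "padj")],
            file.path(results_dir, "de_sex.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bcv_summary(disp, counts, sf),
            file.path(results_dir, "bcv_totrna.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- de_genes(res, 0.10)
message(sprintf("%d genes differ between the sexes at 10%% FDR:", nrow(sig)))
for (i in seq_len(nrow(sig)))
  message(sprintf("  %-8s log2FC %6.1f  padj %.2g", sig$gene_id[i],
                  sig$log2FC[i], sig$padj[i]))
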