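#!/usr/bin/env Rscript
# Expression stage: median-of-ratios normalization, replicate QC, the
# NFR-vs-no-NFR expression contrast and row z-scores for the TF genes.
# Writes results/expression.

source("analysis/00_common.R")
truth <- load_truth()
out <- file.path(RESULTS, "expression"); dir.create(out, showWarnings = FALSE)

ct <- as.data.frame(data.table::fread(file.path(DATA_DIR, "counts.tsv")))
counts <- as.matrix(ct[, -1]); rownames(counts) <- ct[[1]]
em <- normalize_counts(counts)
sl <- truth_seqlens(truth)
prom <- regland:::promoter_windows(truth$annotation$tss, 200, sl)

rows <- list()
for (ph in PHENOS) {
  samp <- grep(paste0("^", ph), colnames(counts), value = TRUE)
  rho <- suppressWarnings(replicate_correlation(log(counts[, samp[1]] + 1),
                                                log(counts[, samp[2]] + 1)))
  nfr <- read_bed(file.path(RESULTS, "atac", paste0("nfr_", ph, ".narrowPeak")))
  genes <- truth$annotation$genes
  has <- regland:::iv_overlap_any(genes, nfr) |
    genes$id %in% truth$annotation$tss$gene_id[regland:::iv_overlap_any(prom, nfr)]
  lg <- log(rowMeans(em$normalized[, samp]) + 1)
  tst <- nfr_expression_test(lg, has)
  cat(sprintf(
    "%s: replicate rho = %.3f; %.1f%% of genes contain an NFR; NFR vs other p = %.3g (medians %.2f vs %.2f)\n",
    ph, rho, 100 * mean(has), tst$p_value, tst$median_nfr, tst$median_other))
  rows[[ph]] <- data.frame(phenotype = ph, replicate_rho = rho,
                           pct_genes_with_nfr = 100 * mean(has),
                           U = tst$U, p_value = tst$p_value)
}
data.table::fwrite(do.call(rbind, rows), file.path(out, "nfr_tests.tsv"),
                   sep = "\t")

z <- row_zscore_log(em$normalized, intersect(truth$tf_gene_map$gene_id,
                                             rownames(em$normalized)))
data.table::fwrite(data.frame(gene_id = rownames(z), z, check.names = FALSE),
                   file.path(out, "tf_zscores.tsv"), sep = "\t")
cat("TF gene z-score matrix:", nrow(z), "genes x", ncol(z), "samples\n")
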