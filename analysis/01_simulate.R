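#!/usr/bin/env Rscript
# Generates the synthetic three-phenotype dataset under results/data:
# a 2 Mb genome with 200 genes, planted NFRs / chromatin states / TF
# footprints / network edges, tri-modal ATAC fragments (2 replicates x
# Q, W, D), four histone-mark ChIP peak sets per phenotype, and an
# expression count table with a +1 log2 shift for NFR-containing genes.

source("analysis/00_common.R")

truth <- generate_genome(sim_config(), seed = SEED, dir = DATA_DIR)
cat("genome:", sum(truth$chrom_len), "bp over", length(truth$chrom_len),
    "chromosomes;", nrow(truth$annotation$genes), "genes\n")
cat("planted:", nrow(truth$nfrs), "NFRs (",
    sum(truth$nfrs$kind == "tss"), "TSS,",
    sum(truth$nfrs$kind == "intron"), "intronic ),",
    nrow(truth$states), "chromatin-state intervals,",
    nrow(truth$sites), "motif sites,", nrow(truth$edges), "TF-TF edges\n")

for (ph in PHENOS) for (r in 1:2) {
  fr <- simulate_fragments(truth, ph, r, seed = regland:::seed_for(SEED, paste0("f", ph, r)),
                           path = file.path(DATA_DIR, sprintf("fragments_%s%d.tsv", ph, r)))
  cat(sprintf("fragments %s rep %d: %d (%.1f%% NFR-sized)\n", ph, r, nrow(fr),
              100 * mean(fr$length <= 100)))
}

for (ph in PHENOS) for (mk in c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3")) {
  reps <- simulate_chip_peaks(truth, mk, ph,
                              seed = regland:::seed_for(SEED, paste0("c", mk, ph)))
  for (r in 1:2)
    write_intervals(reps[[r]],
                    file.path(DATA_DIR, sprintf("chip_%s_%s_rep%d.bed", mk, ph, r)),
                    "bed3")
}

counts <- simulate_expression(truth, seed = regland:::seed_for(SEED, "expr"),
                              path = file.path(DATA_DIR, "counts.tsv"))
cat("expression table:", nrow(counts), "genes x", ncol(counts), "samples\n")
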