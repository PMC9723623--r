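#!/usr/bin/env Rscript
# Chromatin-state stage: replicate-consensus ChIP peaks per mark,
# disjoint-segment (UpSet) decomposition, feature enrichment, TSS/non-TSS
# partition of NFRs, NFR-by-state tables and the H3K4me3/H3K27ac
# co-occurrence test.  Writes results/states.

source("analysis/00_common.R")
truth <- load_truth()
out <- file.path(RESULTS, "states"); dir.create(out, showWarnings = FALSE)
MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3")

for (ph in PHENOS) {
  cons <- lapply(stats::setNames(nm = MARKS), function(mk)
    consensus_peaks(
      read_bed(file.path(DATA_DIR, sprintf("chip_%s_%s_rep1.bed", mk, ph))),
      read_bed(file.path(DATA_DIR, sprintf("chip_%s_%s_rep2.bed", mk, ph)))))
  segs <- flatten_state_segments(cons)
  data.table::fwrite(as.data.frame(segs),
                     file.path(out, paste0("segments_", ph, ".tsv")), sep = "\t")
  data.table::fwrite(attr(segs, "pct_segments"),
                     file.path(out, paste0("upset_segments_", ph, ".tsv")),
                     sep = "\t")
  data.table::fwrite(attr(segs, "pct_bp"),
                     file.path(out, paste0("upset_bp_", ph, ".tsv")), sep = "\t")
  enr <- state_feature_enrichment(segs, truth$annotation)
  data.table::fwrite(data.frame(state = rownames(enr), enr),
                     file.path(out, paste0("feature_enrichment_", ph, ".tsv")),
                     sep = "\t")
  top_intron <- rownames(enr)[which.max(enr[, "intron"])]
  cat(sprintf("%s: %d segments in %d states; most intron-enriched state: %s\n",
              ph, nrow(segs), length(unique(segs$state)), top_intron))

  nfr <- read_bed(file.path(RESULTS, "atac", paste0("nfr_", ph, ".narrowPeak")))
  nfr$tss_class <- classify_nfr_tss(nfr, truth$annotation)
  tab <- nfr_state_overlap(nfr, segs)
  data.table::fwrite(tab, file.path(out, paste0("nfr_states_", ph, ".tsv")),
                     sep = "\t")
  hasA <- grepl("H3K4me3", tab$state, fixed = TRUE)
  hasB <- grepl("H3K27ac", tab$state, fixed = TRUE)
  fi <- fisher_cooccurrence(sum(tab$n[hasA & hasB]), sum(tab$n[hasA & !hasB]),
                            sum(tab$n[!hasA & hasB]), sum(tab$n[!hasA & !hasB]))
  cat(sprintf("%s: H3K4me3/H3K27ac co-occurrence OR = %.2f (p = %.3g)\n",
              ph, fi$odds_ratio, fi$p_value))
}
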