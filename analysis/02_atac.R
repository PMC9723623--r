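#!/usr/bin/env Rscript
# ATAC stage: fragment-size classes, per-replicate NFR peak calling,
# replicate consensus, TSS metaprofiles and pairwise differential
# accessibility.  Writes results/atac.

source("analysis/00_common.R")
truth <- load_truth()
sl <- truth_seqlens(truth)
out <- file.path(RESULTS, "atac"); dir.create(out, showWarnings = FALSE)

nfr_peaks <- list(); nfr_frag <- list()
for (ph in PHENOS) {
  reps <- lapply(1:2, function(r) classify_fragments(load_fragments(ph, r)))
  cls <- table(reps[[1]]$class)
  cat(sprintf("%s rep1 classes: nfr %d, mono %d, di %d, unassigned %d\n",
              ph, cls["nfr"], cls["mono"], cls["di"], cls["unassigned"]))
  pk <- lapply(reps, function(fc) call_peaks(fc[fc$class == "nfr", ], sl))
  nfr_peaks[[ph]] <- consensus_peaks(pk[[1]], pk[[2]])
  nfr_frag[[paste0(ph, 1)]] <- reps[[1]][reps[[1]]$class == "nfr", ]
  nfr_frag[[paste0(ph, 2)]] <- reps[[2]][reps[[2]]$class == "nfr", ]
  write_intervals(nfr_peaks[[ph]],
                  file.path(out, paste0("nfr_", ph, ".narrowPeak")), "narrowPeak")
  cat(sprintf("%s: %d consensus NFR peaks\n", ph, nrow(nfr_peaks[[ph]])))
}

# metaprofiles: NFR signal peaks at the TSS, mono-nucleosome phased downstream
meta <- lapply(PHENOS, function(ph) {
  pooled <- rbind(classify_fragments(load_fragments(ph, 1)),
                  classify_fragments(load_fragments(ph, 2)))
  sapply(c("nfr", "mono"), function(cl)
    tss_metaprofile(coverage_track <- regland:::coverage_track(
      pooled[pooled$class == cl, ], sl), truth$annotation))
})
names(meta) <- PHENOS
mdf <- data.frame(position = -1000:1000,
                  do.call(cbind, lapply(meta, function(m)
                    setNames(as.data.frame(m), c("nfr", "mono")))))
data.table::fwrite(mdf, file.path(out, "tss_metaprofile.tsv"), sep = "\t")

# pairwise differential accessibility over the union peak set
union_pk <- regland:::as_peaks(regland:::iv_reduce(
  do.call(rbind, lapply(nfr_peaks, function(x) x[, c("chrom", "start", "end")]))))
union_pk$name <- paste0("u", seq_len(nrow(union_pk)))
cnt <- count_fragments_in_peaks(union_pk, nfr_frag)
for (pr in list(c("Q", "W"), c("W", "D"), c("D", "Q"))) {
  samp <- grepl(paste0("^[", pr[1], pr[2], "]"), colnames(cnt))
  da <- differential_accessibility(cnt[, samp], substr(colnames(cnt)[samp], 1, 1))
  cat(sprintf("%s vs %s: %d regions at FDR <= 0.05\n", pr[1], pr[2],
              sum(da$q_value <= 0.05)))
  data.table::fwrite(da, file.path(out, sprintf("diff_%s_%s.tsv", pr[1], pr[2])),
                     sep = "\t")
}
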