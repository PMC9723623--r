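#!/usr/bin/env Rscript
# Footprinting stage: PWM scan over the NFR peaks, k-mer bias correction of
# the cut-site track, footprint scores, Otsu bound calling, per-motif
# occupancy and pairwise differential occupancy.  Writes results/footprint.

source("analysis/00_common.R")
truth <- load_truth()
sl <- truth_seqlens(truth)
out <- file.path(RESULTS, "footprint"); dir.create(out, showWarnings = FALSE)

nfr <- lapply(stats::setNames(nm = PHENOS), function(ph)
  read_bed(file.path(RESULTS, "atac", paste0("nfr_", ph, ".narrowPeak"))))
union_pk <- regland:::iv_reduce(do.call(rbind, lapply(nfr, function(x)
  x[, c("chrom", "start", "end")])))

codes <- regland:::dna_codes(truth$genome)
kidx <- genome_kmer_index(truth$genome, 6, codes = codes)
sites <- scan_motifs(truth$genome, truth$motifs, union_pk, codes = codes)
cat("scanned", nrow(sites), "motif sites in", nrow(union_pk), "NFR regions\n")

scored <- list()
for (ph in PHENOS) {
  pooled <- rbind(load_fragments(ph, 1), load_fragments(ph, 2))
  track <- cut_site_track(pooled, sl)
  bias <- fit_bias_model(track, truth$genome, kidx = kidx)
  corr <- correct_cuts(track, bias, truth$genome, kidx = kidx)
  sc <- call_bound(footprint_score(corr, sites))
  sc$phenotype <- ph
  scored[[ph]] <- sc
  occ <- occupancy_table(sc, nfr[[ph]])
  data.table::fwrite(sc, file.path(out, paste0("sites_", ph, ".tsv")), sep = "\t")
  data.table::fwrite(occ, file.path(out, paste0("occupancy_", ph, ".tsv")),
                     sep = "\t")
  cat(sprintf("%s: tau = %.2f; %d/%d sites bound; top occupied motif %s (%.0f%%)\n",
              ph, attr(sc, "tau"), sum(sc$bound), nrow(sc),
              occ$motif_id[1], occ$occupancy_pct[1]))
}

for (pr in list(c("Q", "W"), c("W", "D"), c("D", "Q"))) {
  dd <- differential_occupancy(scored[[pr[1]]], scored[[pr[2]]],
                               seed = regland:::seed_for(SEED, paste0("do", pr[1], pr[2])))
  data.table::fwrite(dd, file.path(out, sprintf("diff_occ_%s_%s.tsv", pr[1], pr[2])),
                     sep = "\t")
  cat(sprintf("%s vs %s: top differential motifs: %s\n", pr[1], pr[2],
              paste(utils::head(dd$motif_id, 3), collapse = ", ")))
}
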