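# PWM scanning, bias model, footprint scores, bound calling, occupancy and
# differential occupancy.

ac_motif <- function() {
  m <- list(id = "M_AC", name = "acTF",
            pfm = matrix(c(4, 0, 0, 0,
                           0, 4, 0, 0), nrow = 4,
                         dimnames = list(c("A", "C", "G", "T"), NULL)),
            pseudocount = 1, background = rep(0.25, 4))
  class(m) <- "motif"
  m
}

test_that("PWM log-odds match the hand-evaluated pseudocount scheme", {
  pwm <- regland:::motif_pwm(ac_motif())
  # per matching base: log2(((4 + 0.25)/(4 + 1))/0.25) = log2(3.4)
  expect_equal(unname(pwm["A", 1]), log2(3.4), tolerance = 1e-12)
  expect_equal(unname(pwm["C", 2]), log2(3.4), tolerance = 1e-12)
  g <- Biostrings::DNAStringSet(c(chr1 = "TTACGGTT"))
  hits <- scan_motifs(g, ac_motif(), data.frame(chrom = "chr1", start = 0,
                                                end = 8))
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 2)
  expect_equal(plus$score, 2 * log2(3.4), tolerance = 1e-9)
})

test_that("reverse-strand hits mirror forward hits with identical score", {
  # GT on the forward strand is AC on the reverse
  g <- Biostrings::DNAStringSet(c(chr1 = "TTGTAATT"))
  hits <- scan_motifs(g, ac_motif(), data.frame(chrom = "chr1", start = 0,
                                                end = 8), dedupe = FALSE)
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$start, 2)
  expect_equal(minus$score, 2 * log2(3.4), tolerance = 1e-9)
})

test_that("scanner equals the all-windows oracle on random sequence", {
  tr <- default_truth()
  set.seed(51)
  seq_str <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  # embed two consensus copies of a real motif
  m <- tr$motifs[[3]]
  cons <- paste(c("A", "C", "G", "T")[apply(m$pfm, 2, which.max)],
                collapse = "")
  substr(seq_str, 301, 300 + nchar(cons)) <- cons
  substr(seq_str, 1201, 1200 + nchar(cons)) <- cons
  g <- Biostrings::DNAStringSet(c(chr1 = seq_str))
  got <- scan_motifs(g, m, data.frame(chrom = "chr1", start = 0, end = 2000),
                     dedupe = FALSE)
  orc <- oracle_scan(seq_str, m)
  orc <- orc[order(orc$start, orc$strand), ]
  got <- got[order(got$start, got$strand), ]
  expect_equal(nrow(got), nrow(orc))
  expect_equal(got$start, orc$start)
  expect_equal(got$strand, orc$strand)
  expect_equal(got$score, orc$score, tolerance = 1e-9)
  expect_gte(nrow(got), 2)
})

test_that("scanner rejects out-of-bounds regions and skips short ones", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(scan_motifs(g, ac_motif(),
                           data.frame(chrom = "chr1", start = 0, end = 50)),
               "outside genome bounds")
  none <- scan_motifs(g, ac_motif(),
                      data.frame(chrom = "chr1", start = 0, end = 1))
  expect_equal(nrow(none), 0L)
})

test_that("bias model is flat on unbiased cuts and scale-invariant", {
  tr <- default_truth()
  sl <- truth_seqlengths()
  set.seed(52)
  # unbiased: uniform random cut positions
  n <- 2e5
  pos <- floor(runif(n) * sl[["chr1"]])
  track <- structure(list(chr1 = as.numeric(tabulate(pos + 1,
                                                     nbins = sl[["chr1"]]))),
                     class = "signal_track")
  codes1 <- truth_codes()["chr1"]
  bm <- fit_bias_model(track, tr$genome[1], codes = codes1)
  usable <- !is.na(bm$rates)
  expect_lt(abs(stats::median(bm$rates[usable]) - 1), 0.2)
  # doubling all cuts leaves the model unchanged
  track2 <- structure(list(chr1 = 2 * track$chr1), class = "signal_track")
  bm2 <- fit_bias_model(track2, tr$genome[1], codes = codes1)
  expect_equal(bm$rates, bm2$rates, tolerance = 1e-12)
  # correction of unbiased data is close to identity up to the global scale
  corr <- correct_cuts(track, bm, tr$genome[1], codes = codes1)
  nz <- track$chr1 > 0 & corr$chr1 > 0
  expect_lt(abs(stats::median(corr$chr1[nz] / track$chr1[nz]) - 1), 0.25)
})

test_that("a planted 2x k-mer rate is recovered", {
  tr <- default_truth()
  sl <- truth_seqlengths()
  codes1 <- truth_codes()["chr1"]
  kidx1 <- truth_kidx()["chr1"]
  set.seed(53)
  target <- which(kidx1$chr1 == 1)          # all positions carrying "AAAAAA"
  target <- target[!is.na(target)]
  base_p <- rep(1, sl[["chr1"]])
  base_p[target] <- 2                       # doubled rate on one k-mer
  n <- 3e5
  pos <- sample.int(sl[["chr1"]], n, replace = TRUE, prob = base_p)
  track <- structure(list(chr1 = as.numeric(tabulate(pos, nbins = sl[["chr1"]]))),
                     class = "signal_track")
  bm <- fit_bias_model(track, tr$genome[1], kidx = kidx1)
  expect_equal(unname(bm$rates["AAAAAA"]), 2, tolerance = 0.1)
})

test_that("footprint score is the flank/core log ratio with its properties", {
  track <- structure(list(chr1 = c(rep(8, 20), rep(2, 10), rep(8, 20))),
                     class = "signal_track")
  site <- data.frame(motif_id = "m", chrom = "chr1", start = 20, end = 30,
                     strand = "+", score = 1)
  fs <- footprint_score(track, site, flank_bp = 20)$fs
  expect_equal(fs, log2(8.1 / 2.1), tolerance = 1e-12)
  flat <- structure(list(chr1 = rep(4, 50)), class = "signal_track")
  expect_equal(footprint_score(flat, site)$fs, 0)
  # deeper core depletion strictly increases FS
  deeper <- structure(list(chr1 = c(rep(8, 20), rep(0.5, 10), rep(8, 20))),
                      class = "signal_track")
  expect_gt(footprint_score(deeper, site)$fs, fs)
  # flank leaving the chromosome -> NA with warning
  edge <- data.frame(motif_id = "m", chrom = "chr1", start = 2, end = 12,
                     strand = "+", score = 1)
  expect_warning(out <- footprint_score(track, edge), "skipped")
  expect_true(is.na(out$fs))
})

test_that("Otsu bound calling separates a bimodal score distribution", {
  set.seed(54)
  truth_bound <- rep(c(FALSE, TRUE), each = 300)
  calls <- data.frame(motif_id = "m", chrom = "chr1",
                      start = seq_len(600) * 100, strand = "+",
                      fs = c(rnorm(300, 0, 0.25), rnorm(300, 2, 0.25)))
  calls$end <- calls$start + 10
  out <- call_bound(calls)
  tau <- attr(out, "tau")
  expect_gt(tau, 0.5); expect_lt(tau, 1.5)
  expect_gte(mean(out$bound == truth_bound), 0.99)
  # manual tau bypasses estimation
  out2 <- call_bound(calls, tau = 1)
  expect_equal(attr(out2, "tau"), 1)
  expect_error(call_bound(transform(calls, fs = 1)), "no threshold")
  expect_error(call_bound(calls[1:10, ]), "supply tau")
})

test_that("occupancy is the bound fraction, ranked, within NFRs", {
  calls <- data.frame(motif_id = rep(c("m1", "m2"), c(10, 5)),
                      chrom = "chr1", start = seq_len(15) * 100, strand = "+",
                      fs = 1)
  calls$end <- calls$start + 10
  calls$bound <- c(rep(c(TRUE, FALSE), c(3, 7)), rep(TRUE, 5))
  tab <- occupancy_table(calls)
  expect_equal(tab$occupancy_pct[tab$motif_id == "m1"], 30)
  expect_equal(tab$motif_id[1], "m2")   # 100% ranks first
  expect_true(all(tab$occupancy_pct >= 0 & tab$occupancy_pct <= 100))
  # restriction to NFR peaks drops outside sites
  nfr <- data.frame(chrom = "chr1", start = 0, end = 550)
  tab2 <- occupancy_table(calls, nfr)
  expect_equal(sum(tab2$n_sites), 5L)
})

test_that("differential occupancy has null identity and antisymmetry", {
  set.seed(55)
  calls <- data.frame(motif_id = rep(sprintf("m%d", 1:4), each = 25),
                      chrom = "chr1", start = seq_len(100) * 60, strand = "+",
                      fs = rnorm(100, 1, 0.4))
  calls$end <- calls$start + 10
  d0 <- differential_occupancy(calls, calls, seed = 9)
  expect_true(all(d0$delta_fs == 0))
  expect_false(any(d0$q_value <= 0.05))

  other <- calls; other$fs <- rnorm(100, 1, 0.4)
  dab <- differential_occupancy(calls, other, seed = 9)
  dba <- differential_occupancy(other, calls, seed = 9)
  expect_equal(dab$delta_fs[order(dab$motif_id)],
               -dba$delta_fs[order(dba$motif_id)], tolerance = 1e-12)
  # motifs absent from one side are excluded with a note
  extra <- rbind(calls, transform(calls[1, ], motif_id = "m9"))
  dx <- differential_occupancy(extra, calls, seed = 9)
  expect_false("m9" %in% dx$motif_id)
  expect_equal(attr(dx, "n_excluded"), 1L)
})
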