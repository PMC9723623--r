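# Chromatin-state decomposition, feature annotation/enrichment, TSS
# partition of NFRs and the Fisher co-occurrence test.

test_that("two overlapping mark sets decompose into the hand-enumerated segments", {
  segs <- flatten_state_segments(list(
    H3K27ac = data.frame(chrom = "chr1", start = 0, end = 100),
    H3K4me3 = data.frame(chrom = "chr1", start = 50, end = 150)))
  expect_equal(segs$start, c(0, 50, 100))
  expect_equal(segs$end, c(50, 100, 150))
  expect_equal(segs$state, c("H3K27ac", "H3K4me3+H3K27ac", "H3K4me3"))
})

test_that("degenerate decompositions behave", {
  one <- flatten_state_segments(list(
    H3K27ac = data.frame(chrom = "chr1", start = c(10, 300), end = c(50, 400))))
  expect_true(all(one$state == "H3K27ac"))

  four <- flatten_state_segments(lapply(
    setNames(nm = regland:::HISTONE_MARKS),
    function(m) data.frame(chrom = "chr1", start = 100, end = 300)))
  expect_equal(nrow(four), 1L)
  expect_equal(four$state, "H3K4me1+H3K4me3+H3K27ac+H3K27me3")
})

test_that("segment decomposition matches the per-bp oracle and is order-invariant", {
  set.seed(21)
  L <- 5000
  mk <- lapply(setNames(nm = regland:::HISTONE_MARKS), function(m) {
    s <- sort(sample(0:(L - 300), 6))
    iv <- data.frame(chrom = "chr1", start = s, end = s + sample(80:300, 6, TRUE))
    regland:::iv_reduce(iv)
  })
  segs <- flatten_state_segments(mk)
  # reconstruct the per-bp labels the segments imply
  lab_impl <- character(L)
  for (i in seq_len(nrow(segs)))
    lab_impl[(segs$start[i] + 1):segs$end[i]] <- segs$state[i]
  lab_oracle <- oracle_state_labels(mk, L)
  expect_equal(lab_impl, lab_oracle)
  # union of segments equals union of inputs; segments pairwise disjoint
  expect_equal(sum(segs$end - segs$start),
               regland:::iv_covered_bp(do.call(rbind, mk)))
  o <- order(segs$start)
  expect_true(all(segs$start[o][-1] >= segs$end[o][-nrow(segs)]))
  # input order invariance
  segs_rev <- flatten_state_segments(rev(mk))
  expect_equal(segs[, c("chrom", "start", "end", "state")],
               segs_rev[, c("chrom", "start", "end", "state")],
               ignore_attr = TRUE)
})

test_that("feature annotation follows the priority rule at the midpoint", {
  ann <- tiny_annotation()
  # midpoint inside intron 1 of geneA ([1500,2000))
  expect_equal(annotate_feature(data.frame(chrom = "chr1", start = 1600,
                                           end = 1800), ann), "intron")
  # promoter beats 5'UTR: midpoint in geneA promoter [800,1000)
  expect_equal(annotate_feature(data.frame(chrom = "chr1", start = 850,
                                           end = 950), ann), "promoter")
  # outside everything
  expect_equal(annotate_feature(data.frame(chrom = "chr1", start = 9500,
                                           end = 9600), ann), "intergenic")
  # 5'UTR beats exon at geneA 5'UTR [1000,1150)
  expect_equal(annotate_feature(data.frame(chrom = "chr1", start = 1010,
                                           end = 1100), ann), "five_prime_utr")
})

test_that("state-feature enrichment evaluates the log-ratio formula", {
  # annotation where introns are exactly 25% of a 10 kb genome
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 10000",
               "chr1\tt\tgene\t1001\t5000\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1001\t5000\t.\t+\t.\tID=r1;Parent=g1",
               "chr1\tt\texon\t1001\t1750\t.\t+\t.\tID=e1;Parent=r1",
               "chr1\tt\texon\t4251\t5000\t.\t+\t.\tID=e2;Parent=r1"), f)
  ann <- read_gff3(f)
  expect_equal(sum(ann$introns$end - ann$introns$start), 2500)
  seg <- structure(data.frame(chrom = "chr1", start = 2000, end = 3000,
                              state = "H3K27ac"),
                   class = c("state_segments", "data.frame"))
  e <- state_feature_enrichment(seg, ann)
  # state entirely intronic, introns 25% of genome -> log2(1/0.25) = 2
  expect_equal(e["H3K27ac", "intron"], 2, tolerance = 2e-3)
  expect_lt(e["H3K27ac", "intergenic"], 0)
})

test_that("TSS/non-TSS NFR classification is a strand-symmetric window rule", {
  ann <- tiny_annotation()
  pks <- regland:::as_peaks(data.frame(
    chrom = "chr1",
    start = c(950, 1500, 8850, 9600),
    end = c(1050, 1600, 8950, 9700)))
  cls <- classify_nfr_tss(pks, ann, window = 200)
  # peak 1 overlaps TSS(1000)+-200; peak 2 is 300 bp downstream; peak 3
  # overlaps the minus-strand TSS (8999)+-200; peak 4 is past it
  expect_equal(cls, c("tss", "non_tss", "tss", "non_tss"))

  # invariance under strand flip + coordinate mirroring
  L <- 10000
  annM <- ann
  annM$tss$pos <- L - 1 - ann$tss$pos
  annM$tss$strand <- ifelse(ann$tss$strand == "+", "-", "+")
  pksM <- pks
  pksM$start <- L - pks$end
  pksM$end <- L - pks$start
  expect_equal(classify_nfr_tss(pksM, annM, window = 200), cls)
})

test_that("NFR state table uses the summit and sums to 100 per class", {
  segs <- flatten_state_segments(list(
    H3K27ac = data.frame(chrom = "chr1", start = 0, end = 100)))
  nfrs <- regland:::as_peaks(data.frame(
    chrom = "chr1", start = c(40, 500, 700), end = c(240, 600, 800),
    summit = c(10, NA, NA)))
  nfrs$tss_class <- c("tss", "tss", "non_tss")
  tab <- nfr_state_overlap(nfrs, segs)
  # summit of peak 1 at abs position 50 -> inside the H3K27ac segment
  expect_equal(tab$pct[tab$tss_class == "tss" & tab$state == "H3K27ac"], 50)
  expect_equal(tab$pct[tab$tss_class == "non_tss" & tab$state == "unmarked"], 100)
  sums <- tapply(tab$pct, tab$tss_class, sum)
  expect_equal(as.numeric(sums), c(100, 100))

  none <- nfr_state_overlap(nfrs, segs[0, ])
  expect_true(all(none$state == "unmarked"))
})

test_that("Fisher co-occurrence: odds ratio arithmetic and exact p", {
  f <- fisher_cooccurrence(10, 2, 3, 15)
  expect_equal(f$odds_ratio, 25)        # (10*15)/(2*3)
  f0 <- fisher_cooccurrence(5, 5, 5, 5)
  expect_equal(f0$odds_ratio, 1)
  expect_equal(f0$p_value, 1)
  expect_equal(fisher_cooccurrence(4, 0, 0, 4)$odds_ratio, Inf)
  expect_error(fisher_cooccurrence(0, 0, 0, 0), "all-zero")
})

test_that("Fisher p matches the hypergeometric reference for totals <= 40", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    if (sum(cells) == 0) next
    ours <- fisher_cooccurrence(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9,
                 label = paste("table", paste(cells, collapse = ",")))
  }
})

test_that("gene mark enrichment flags >3-fold genes with finite ratios", {
  ann <- tiny_annotation()
  L <- 10000
  input <- structure(list(chr1 = rep(1, L)), class = "signal_track")
  ip_eq <- structure(list(chr1 = rep(1, L)), class = "signal_track")
  ip_4x <- structure(list(chr1 = rep(1, L)), class = "signal_track")
  ip_4x$chr1[1001:4000] <- 4    # 4x over geneA only
  res <- gene_mark_enrichment(list(H3K27ac = ip_eq), input, ann)
  expect_false(any(res$flag_H3K27ac))
  expect_equal(res$ratio_H3K27ac, c(1, 1), tolerance = 1e-6)
  res4 <- gene_mark_enrichment(list(H3K27ac = ip_4x), input, ann)
  expect_true(res4$flag_H3K27ac[res4$gene_id == "geneA"])
  expect_false(res4$flag_H3K27ac[res4$gene_id == "geneB"])
  expect_true(res4$any_mark[res4$gene_id == "geneA"])
  # zero input stays finite through the epsilon regularizer
  zero_in <- structure(list(chr1 = rep(0, L)), class = "signal_track")
  rz <- gene_mark_enrichment(list(m = ip_eq), zero_in, ann)
  expect_true(all(is.finite(rz$ratio_m)))
})
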