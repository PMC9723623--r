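# Fragment classification, cut tracks, the local-Poisson peak caller and
# differential accessibility.

test_that("fragment classes follow the printed inclusive bounds", {
  fr <- data.frame(length = c(85, 200, 120, 473, 100, 101, 149, 150, 247,
                              248, 314, 315, 474, 1))
  cl <- as.character(classify_fragments(fr)$class)
  expect_equal(cl, c("nfr", "mono", "unassigned", "di", "nfr", "unassigned",
                     "unassigned", "mono", "mono", "unassigned", "unassigned",
                     "di", "unassigned", "nfr"))
})

test_that("fragment classification is a total partition", {
  set.seed(1)
  fr <- data.frame(length = sample(1:600, 500, replace = TRUE))
  cl <- classify_fragments(fr)$class
  expect_equal(sum(table(cl)), 500L)
  expect_false(any(is.na(cl)))
})

test_that("cut_site_track applies Tn5 offsets and conserves counts", {
  sl <- c(chr1 = 1000)
  fr <- data.frame(chrom = "chr1", start = 10, end = 200, length = 190)
  tr <- cut_site_track(fr, sl)
  expect_equal(which(tr$chr1 > 0) - 1, c(14, 194))  # start+4, end-1-5
  expect_equal(sum(tr$chr1), 2)

  set.seed(2)
  n <- 200
  fr <- data.frame(chrom = "chr1", start = s <- sample(0:900, n, TRUE),
                   end = s + 50)
  tr <- cut_site_track(fr, sl)
  expect_lte(sum(tr$chr1), 2 * n)
  expect_equal(sum(tr$chr1) + attr(tr, "clipped"), 2 * n)

  tr0 <- cut_site_track(fr[0, ], sl)
  expect_equal(sum(tr0$chr1), 0)
})

test_that("peak calling matches the brute-force window oracle on a toy genome", {
  # 50 kb genome, one strongly enriched 500 bp region over uniform background
  sl <- c(chrA = 50000)
  set.seed(11)
  bg <- data.frame(start = s <- sort(round(runif(800, 0, 49900))))
  enr <- data.frame(start = s <- round(runif(220, 20000, 19500 + 1000)))
  fr <- data.frame(chrom = "chrA", start = c(bg$start, enr$start))
  fr$end <- fr$start + 80
  fr$length <- 80

  pk <- call_peaks(fr, sl)
  orc <- oracle_call_peaks(fr, sl)
  expect_equal(pk[, c("chrom", "start", "end")], orc,
               ignore_attr = TRUE)
  expect_gt(nrow(pk), 0)
  # the planted region is recovered
  expect_true(any(pk$start < 20500 & pk$end > 20000))
})

test_that("peak calling under the uniform null yields no peaks almost always", {
  sl <- c(chrA = 50000)
  zero <- vapply(1:20, function(r) {
    set.seed(100 + r)
    fr <- data.frame(chrom = "chrA", start = s <- round(runif(1000, 0, 49900)))
    fr$end <- fr$start + 80; fr$length <- 80
    nrow(call_peaks(fr, sl)) == 0
  }, TRUE)
  expect_gte(sum(zero), 19)
})

test_that("peak calling is monotone in added local fragments", {
  sl <- c(chrA = 20000)
  set.seed(5)
  fr <- data.frame(chrom = "chrA", start = s <- round(runif(300, 0, 19900)))
  fr$end <- fr$start + 80; fr$length <- 80
  extra <- data.frame(chrom = "chrA", start = s <- round(runif(150, 5000, 5400)))
  extra$end <- extra$start + 80; extra$length <- 80
  pk1 <- call_peaks(rbind(fr, extra), sl)
  expect_true(any(pk1$start < 5500 & pk1$end > 5000))
  more <- data.frame(chrom = "chrA", start = s <- round(runif(100, 5100, 5300)))
  more$end <- more$start + 80; more$length <- 80
  pk2 <- call_peaks(rbind(fr, extra, more), sl)
  expect_true(any(pk2$start < 5500 & pk2$end > 5000))
})

test_that("empty input gives an empty peak list, not an error", {
  fr <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   length = numeric())
  expect_equal(nrow(call_peaks(fr, c(chr1 = 1000))), 0L)
})

test_that("consensus keeps replicate-supported peaks and merges their span", {
  a <- regland:::as_peaks(data.frame(chrom = "chr1", start = c(100, 1000),
                                     end = c(200, 1100)))
  b <- regland:::as_peaks(data.frame(chrom = "chr1", start = 150, end = 250))
  cons <- consensus_peaks(a, b)
  expect_equal(nrow(cons), 1L)          # peak at 1000 present only in rep A
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 250)           # union of the overlap group
  # idempotence on identical inputs
  cons2 <- consensus_peaks(a, a)
  expect_equal(cons2[, c("chrom", "start", "end")],
               as.data.frame(a)[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("tss_metaprofile aligns, averages and strand-flips", {
  ann <- tiny_annotation()
  sl <- c(chr1 = 10000)
  flat <- structure(list(chr1 = rep(3, 10000)), class = "signal_track")
  mp <- tss_metaprofile(flat, ann, halfwidth = 100)
  expect_equal(unname(mp), rep(3, 201), ignore_attr = TRUE)

  # delta at the + gene TSS (pos 1000) appears at the center
  tr <- structure(list(chr1 = numeric(10000)), class = "signal_track")
  tr$chr1[1001] <- 10
  annA <- ann; annA$tss <- ann$tss[ann$tss$gene_id == "geneA", ]
  mpA <- tss_metaprofile(tr, annA, halfwidth = 50)
  expect_equal(unname(which(mpA > 0)), 51L)

  # same offset downstream of the - gene lands at the same profile position
  trB <- structure(list(chr1 = numeric(10000)), class = "signal_track")
  trB$chr1[9000 - 10] <- 10   # 10 bp downstream of TSS 8999 on minus strand
  annB <- ann; annB$tss <- ann$tss[ann$tss$gene_id == "geneB", ]
  mpB <- tss_metaprofile(trB, annB, halfwidth = 50)
  trA <- structure(list(chr1 = numeric(10000)), class = "signal_track")
  trA$chr1[1001 + 10] <- 10
  mpA2 <- tss_metaprofile(trA, annA, halfwidth = 50)
  expect_equal(mpB, mpA2, ignore_attr = TRUE)
})

test_that("differential accessibility has null identity and antisymmetry", {
  set.seed(3)
  m <- matrix(rpois(400, 60), ncol = 4,
              dimnames = list(paste0("p", 1:100), c("A1", "A2", "B1", "B2")))
  same <- cbind(m[, 1:2], m[, 1:2])
  colnames(same) <- c("A1", "A2", "B1", "B2")
  da0 <- differential_accessibility(same, c("A", "A", "B", "B"))
  expect_true(all(da0$log2fc == 0))
  expect_false(any(da0$q_value <= 0.05))

  da <- differential_accessibility(m, c("A", "A", "B", "B"))
  db <- differential_accessibility(m, c("B", "B", "A", "A"))
  expect_equal(da$log2fc, -db$log2fc)
  expect_equal(da$p_value, db$p_value, tolerance = 1e-12)
  # q monotone non-decreasing in p rank
  expect_true(all(diff(da$q_value[order(da$p_value)]) >= -1e-12))

  expect_error(differential_accessibility(m[, 1:3], c("A", "A", "B")),
               ">= 2 replicates")
})

test_that("a 4x differential peak at default depth is detected nearly always", {
  # per-peak counts emulate the default synthetic depth (~800 NFR fragments
  # per consensus peak per sample); one peak is 4x down in group B
  hit <- vapply(1:100, function(r) {
    set.seed(r)
    m <- cbind(A1 = rpois(50, 800), A2 = rpois(50, 800),
               B1 = rpois(50, 800), B2 = rpois(50, 800))
    m[1, c("B1", "B2")] <- rpois(2, 200)
    rownames(m) <- paste0("p", 1:50)
    da <- differential_accessibility(m, c("A", "A", "B", "B"))
    da$q_value[da$unit == "p1"] <= 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})
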