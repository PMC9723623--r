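# Shared fixtures: one default-config synthetic dataset per test session,
# plus small hand-built genomes/annotations and independent oracles used by
# the oracle-equivalence tests.

.fixture_env <- new.env(parent = emptyenv())

# default study-conditions truth, generated once and reused
default_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    dir <- file.path(tempdir(), "regland_truth_42")
    .fixture_env$truth <- generate_genome(sim_config(), seed = 42, dir = dir)
  }
  .fixture_env$truth
}

truth_seqlengths <- function(truth = default_truth()) {
  stats::setNames(as.numeric(Biostrings::width(truth$genome)),
                  names(truth$genome))
}

truth_codes <- function() {
  if (is.null(.fixture_env$codes))
    .fixture_env$codes <- regland:::dna_codes(default_truth()$genome)
  .fixture_env$codes
}

truth_kidx <- function(k = 6) {
  key <- paste0("kidx", k)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- genome_kmer_index(default_truth()$genome, k,
                                             codes = truth_codes())
  .fixture_env[[key]]
}

# a tiny two-gene annotation written as GFF3 and parsed back
# chr1 is 10 kb; geneA: + strand 1001..4000, geneB: - strand 6001..9000
# exons geneA: 1001..1500, 2001..2500, 3501..4000 (1-based, inclusive)
tiny_annotation <- function(promoter_width = 200) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\ttest\tgene\t1001\t4000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t1001\t4000\t.\t+\t.\tID=rnaA;Parent=geneA",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=rnaA.e1;Parent=rnaA",
    "chr1\ttest\texon\t2001\t2500\t.\t+\t.\tID=rnaA.e2;Parent=rnaA",
    "chr1\ttest\texon\t3501\t4000\t.\t+\t.\tID=rnaA.e3;Parent=rnaA",
    "chr1\ttest\tfive_prime_UTR\t1001\t1150\t.\t+\t.\tID=rnaA.u5;Parent=rnaA",
    "chr1\ttest\tthree_prime_UTR\t3851\t4000\t.\t+\t.\tID=rnaA.u3;Parent=rnaA",
    "chr1\ttest\tgene\t6001\t9000\t.\t-\t.\tID=geneB",
    "chr1\ttest\tmRNA\t6001\t9000\t.\t-\t.\tID=rnaB;Parent=geneB",
    "chr1\ttest\texon\t6001\t7000\t.\t-\t.\tID=rnaB.e1;Parent=rnaB",
    "chr1\ttest\texon\t8001\t9000\t.\t-\t.\tID=rnaB.e2;Parent=rnaB",
    "chr1\ttest\tfive_prime_UTR\t8851\t9000\t.\t-\t.\tID=rnaB.u5;Parent=rnaB",
    "chr1\ttest\tthree_prime_UTR\t6001\t6150\t.\t-\t.\tID=rnaB.u3;Parent=rnaB"
  ), path)
  read_gff3(path, promoter_width = promoter_width)
}

# ---- independent oracles ---------------------------------------------------

# brute-force windowed Poisson peak caller: enumerates every window and bp
# from first principles, sharing no code with call_peaks()
oracle_call_peaks <- function(fragments, seqlengths, window = 200, step = 50,
                              q_threshold = 0.05) {
  rate_genome <- nrow(fragments) / sum(seqlengths)
  rows <- list()
  for (ch in names(seqlengths)) {
    L <- seqlengths[[ch]]
    fr <- fragments[fragments$chrom == ch, ]
    mids <- floor((fr$start + fr$end) / 2)
    for (ws in seq(0, L - window, by = step)) {
      cnt <- sum(mids >= ws & mids < ws + window)
      ctr <- ws + window %/% 2
      loc <- function(h) {
        a <- max(ctr - h, 0); b <- min(ctr + h, L)
        sum(mids >= a & mids < b) / (b - a) * window
      }
      lambda <- max(rate_genome * window, loc(500), loc(5000))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = ws, end = ws + window,
        p = 1 - stats::ppois(cnt - 1, lambda), count = cnt)
    }
  }
  win <- do.call(rbind, rows)
  win$q <- stats::p.adjust(win$p, "BH")
  sig <- win[win$q <= q_threshold & win$count > 0, ]
  if (nrow(sig) == 0) return(sig[, c("chrom", "start", "end")])
  # merge overlapping/touching significant windows by sweep
  sig <- sig[order(sig$chrom, sig$start), ]
  out <- sig[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(sig))[-1]) {
    last <- nrow(out)
    if (sig$chrom[i] == out$chrom[last] && sig$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], sig$end[i])
    } else out <- rbind(out, sig[i, c("chrom", "start", "end")])
  }
  rownames(out) <- NULL
  out
}

# per-bp chromatin-state labeling oracle
oracle_state_labels <- function(mark_peaks, L, chrom = "chr1") {
  marks <- names(mark_peaks)
  cov <- sapply(marks, function(mk) {
    v <- logical(L)
    p <- mark_peaks[[mk]]
    p <- p[p$chrom == chrom, ]
    for (i in seq_len(nrow(p))) v[(p$start[i] + 1):p$end[i]] <- TRUE
    v
  })
  if (is.null(dim(cov))) cov <- matrix(cov, ncol = length(marks))
  apply(cov, 1, function(z)
    paste(intersect(regland:::HISTONE_MARKS, marks[z]), collapse = "+"))
}

# naive all-windows motif scorer on a plain character sequence
oracle_scan <- function(seq_string, motif, min_score_frac = 0.8) {
  pc <- motif$pseudocount; bg <- motif$background
  pfm <- motif$pfm
  prob <- sweep(pfm + pc * bg, 2, colSums(pfm) + pc, "/")
  pwm <- log2(prob / bg)
  L <- ncol(pwm)
  thr <- min_score_frac * sum(apply(pwm, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_string, "")[[1]]
  hits <- list()
  for (s in seq_len(nchar(seq_string) - L + 1)) {
    w <- chars[s:(s + L - 1)]
    for (str in c("+", "-")) {
      ww <- if (str == "+") w else rev(unname(comp[w]))
      sc <- sum(vapply(seq_len(L), function(j) pwm[ww[j], j], 0))
      if (sc >= thr)
        hits[[length(hits) + 1]] <- data.frame(
          start = s - 1, end = s - 1 + L, strand = str, score = sc)
    }
  }
  if (!length(hits)) return(data.frame(start = numeric(), end = numeric(),
                                       strand = character(), score = numeric()))
  do.call(rbind, hits)
}

# exact Mann-Whitney p by full enumeration of rank assignments
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) {
    xx <- all_v[ix]; yy <- all_v[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  list(U = u_obs, p = mean(us >= u_obs))
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
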