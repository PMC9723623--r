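# TF footprinting: PWM motif scanning over NFR regions, k-mer cut-bias
# estimation and correction, flank-vs-core footprint scores, bound/unbound
# calling by Otsu thresholding, per-motif occupancy and phenotype-
# differential occupancy against a motif-label-blind background null.

BASES <- c("A", "C", "G", "T")

# log2-odds PWM from a motif's PFM: log2(((count + pc*bg) / (coltotal + pc)) / bg)
motif_pwm <- function(motif) {
  pfm <- motif$pfm
  bg <- motif$background
  pc <- motif$pseudocount
  tot <- colSums(pfm)
  prob <- sweep(pfm + pc * bg, 2, tot + pc, "/")
  log2(prob / bg)
}

max_pwm_bits <- function(pwm) sum(apply(pwm, 2, max))

# reverse-complement PWM: complement rows, reverse columns
pwm_revcomp <- function(pwm) pwm[c(4, 3, 2, 1), ncol(pwm):1, drop = FALSE]

#' Scan regions for PWM motif hits
#'
#' Scores every window of every region on both strands with the log2-odds
#' PWM and reports hits at or above the threshold.  Overlapping hits of the
#' same motif are deduplicated greedily, keeping the higher score (ties:
#' leftmost, then + strand).
#'
#' @param genome `DNAStringSet` or a path to a FASTA file.
#' @param motifs list of `motif` objects (or a single one).
#' @param regions interval data.frame to scan (typically NFR peaks).
#' @param min_score_frac threshold as a fraction of each motif's maximum
#'   attainable bits (default 0.8).
#' @param min_score_bits absolute threshold in bits, overrides
#'   `min_score_frac` when given.
#' @param dedupe drop lower-scoring overlapping self-hits (default TRUE).
#' @param codes precomputed `dna_codes(genome)` (optional, for speed).
#' @return data.frame of class `motif_sites`: `motif_id`, `chrom`, `start`,
#'   `end`, `strand`, `score` (bits), sorted by coordinate.
#' @export
scan_motifs <- function(genome, motifs, regions, min_score_frac = 0.8,
                        min_score_bits = NULL, dedupe = TRUE, codes = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (is.null(codes)) codes <- dna_codes(genome)
  glen <- vapply(codes, length, 0L)
  if (nrow(regions) > 0L) {
    bad <- which(!(regions$chrom %in% names(glen)) |
                   regions$start < 0 |
                   regions$end > glen[match(regions$chrom, names(glen))])
    if (length(bad))
      stop("region outside genome bounds (row ", bad[1], ")")
  }
  out <- list()
  for (m in motifs) {
    pwm <- motif_pwm(m)
    L <- ncol(pwm)
    thr <- if (!is.null(min_score_bits)) min_score_bits
           else min_score_frac * max_pwm_bits(pwm)
    pwm_rc <- pwm_revcomp(pwm)
    hits <- list()
    for (r in seq_len(nrow(regions))) {
      rs <- regions$start[r]; re <- regions$end[r]
      if (re - rs < L) next    # motif longer than region
      v <- codes[[regions$chrom[r]]][(rs + 1):re]
      n <- length(v) - L + 1L
      sc_f <- numeric(n); sc_r <- numeric(n)
      for (j in seq_len(L)) {
        b <- v[j:(j + n - 1L)]
        sc_f <- sc_f + pwm[, j][b]
        sc_r <- sc_r + pwm_rc[, j][b]
      }
      for (str in c("+", "-")) {
        sc <- if (str == "+") sc_f else sc_r
        w <- which(!is.na(sc) & sc >= thr)
        if (length(w))
          hits[[length(hits) + 1L]] <-
            data.frame(motif_id = m$id, chrom = regions$chrom[r],
                       start = rs + w - 1L, end = rs + w - 1L + L,
                       strand = str, score = sc[w], stringsAsFactors = FALSE)
      }
    }
    if (length(hits) == 0L) next
    h <- do.call(rbind, hits)
    h <- h[!duplicated(h[, c("chrom", "start", "strand")]), , drop = FALSE]
    if (dedupe && nrow(h) > 1L) h <- dedupe_hits(h)
    out[[m$id]] <- h
  }
  if (length(out) == 0L)
    return(structure(data.frame(motif_id = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                strand = character(), score = numeric()),
                     class = c("motif_sites", "data.frame")))
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$chrom, sites$start, sites$motif_id, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("motif_sites", "data.frame")
  sites
}

# greedy per-motif, per-chrom dedup of overlapping hits: best score first
dedupe_hits <- function(h) {
  ord <- order(-h$score, h$start, h$strand)
  h <- h[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  taken <- list()
  for (i in seq_len(nrow(h))) {
    ch <- h$chrom[i]
    iv <- taken[[ch]]
    s <- h$start[i]; e <- h$end[i]
    if (is.null(iv) || !any(s < iv[, 2] & e > iv[, 1])) {
      keep[i] <- TRUE
      taken[[ch]] <- rbind(iv, c(s, e))
    }
  }
  h[keep, , drop = FALSE]
}

#' Fit a k-mer Tn5 cut-bias model
#'
#' Estimates a relative cut rate per k-mer as (cuts observed on positions
#' carrying the k-mer) / (genomic frequency of the k-mer), normalized so the
#' frequency-weighted mean rate over the genome is 1.  The k-mer window at a
#' cut position `p` spans `[p - floor(k/2), p + ceiling(k/2))`.  Positions
#' whose window leaves the chromosome or contains a non-ACGT base are
#' excluded from both fitting and correction.
#'
#' @param cut_track `signal_track` of per-bp cut counts.
#' @param genome `DNAStringSet` or FASTA path.
#' @param k k-mer length (default 6).
#' @param codes precomputed `dna_codes(genome)` (optional).
#' @param kidx precomputed per-chromosome k-mer indices from
#'   [genome_kmer_index()] (optional, for repeated fits on one genome).
#' @return object of class `bias_model`: `k`, `rates` (named by k-mer,
#'   length `4^k`, NA for unobserved k-mers), `n_positions`, `n_cuts`.
#' @export
fit_bias_model <- function(cut_track, genome, k = 6L, codes = NULL,
                           kidx = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(codes) && is.null(kidx)) codes <- dna_codes(genome)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 10L)
  if (is.null(kidx)) kidx <- lapply(codes, kmer_index, k = k)
  nk <- 4L^k
  freq <- numeric(nk)
  cuts <- numeric(nk)
  for (ch in names(kidx)) {
    idx <- kidx[[ch]]
    ok <- !is.na(idx)
    freq <- freq + tabulate(idx[ok], nbins = nk)
    tr <- cut_track[[ch]]
    if (!is.null(tr) && any(tr > 0)) {
      w <- which(ok & tr > 0)
      if (length(w)) {
        agg <- rowsum(tr[w], idx[w])
        cuts[as.integer(rownames(agg))] <- cuts[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  rate <- ifelse(freq > 0, cuts / freq, NA_real_)
  overall <- sum(cuts) / sum(freq)
  if (overall <= 0) stop("no cuts observed; cannot fit bias model")
  rate <- rate / overall
  names(rate) <- kmer_names(k)
  structure(list(k = k, rates = rate, n_positions = sum(freq),
                 n_cuts = sum(cuts)),
            class = "bias_model")
}

# k-mer index (1..4^k) per position; NA when window leaves chrom or hits non-ACGT
kmer_index <- function(code, k) {
  n <- length(code)
  off <- -(k %/% 2L)
  idx <- numeric(n)
  valid <- rep(TRUE, n)
  pow <- 4^((k - 1L):0L)
  for (j in seq_len(k)) {
    shift <- off + j - 1L
    pos <- seq_len(n) + shift
    b <- rep(NA_integer_, n)
    inb <- pos >= 1L & pos <= n
    b[inb] <- code[pos[inb]]
    valid <- valid & !is.na(b)
    b[is.na(b)] <- 1L
    idx <- idx + (b - 1L) * pow[j]
  }
  out <- idx + 1L
  out[!valid] <- NA
  out
}

#' Precompute per-chromosome k-mer indices for a genome
#'
#' Convenience cache for repeated [fit_bias_model()] / [correct_cuts()] calls
#' on one genome.
#' @param genome `DNAStringSet` or FASTA path.
#' @param k k-mer length.
#' @param codes precomputed `dna_codes(genome)` (optional).
#' @return named list of integer vectors.
#' @export
genome_kmer_index <- function(genome, k = 6L, codes = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(codes)) codes <- dna_codes(genome)
  lapply(codes, kmer_index, k = as.integer(k))
}

kmer_names <- function(k) {
  idx <- 0:(4L^k - 1L)
  cols <- lapply(seq_len(k), function(j) BASES[(idx %/% 4^(k - j)) %% 4 + 1])
  do.call(paste0, cols)
}

#' Correct a cut track for k-mer bias
#'
#' Corrected value at each position = observed / (expected + eps), where the
#' expected value is the bias model's relative rate for the position's k-mer.
#' Excluded positions (edge or non-ACGT k-mers, unseen k-mers) are set to 0.
#'
#' @param cut_track `signal_track`.
#' @param model `bias_model`.
#' @param genome `DNAStringSet` or FASTA path.
#' @param eps regularizer added to the expected rate (default 0.01).
#' @param codes precomputed `dna_codes(genome)` (optional).
#' @param kidx precomputed indices from [genome_kmer_index()] (optional).
#' @return corrected `signal_track`.
#' @export
correct_cuts <- function(cut_track, model, genome, eps = 0.01, codes = NULL,
                         kidx = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(codes) && is.null(kidx)) codes <- dna_codes(genome)
  if (is.null(kidx)) kidx <- lapply(codes, kmer_index, k = model$k)
  out <- list()
  for (ch in names(cut_track)) {
    idx <- kidx[[ch]]
    expected <- model$rates[idx]
    v <- cut_track[[ch]] / (expected + eps)
    v[is.na(v)] <- 0
    out[[ch]] <- v
  }
  structure(out, class = "signal_track")
}

#' Footprint score of motif sites
#'
#' `FS = log2((mean corrected signal over both flanks + eps) /
#' (mean over the motif core + eps))`: positive when cuts are depleted in the
#' core relative to the flanks, the signature of a bound TF.
#'
#' @param corrected_track `signal_track` (bias-corrected cuts).
#' @param sites `motif_sites` data.frame.
#' @param flank_bp flank width on each side (default 20).
#' @param eps regularizer (default 0.1).
#' @return `sites` with an added `fs` column; sites whose flank leaves the
#'   chromosome get `NA` with a warning.
#' @export
footprint_score <- function(corrected_track, sites, flank_bp = 20L, eps = 0.1) {
  n <- nrow(sites)
  fs <- rep(NA_real_, n)
  cums <- lapply(corrected_track, function(v) c(0, cumsum(v)))
  rsum <- function(ch, a, b) cums[[ch]][b + 1L] - cums[[ch]][a + 1L]  # [a,b)
  skipped <- 0L
  for (ch in unique(sites$chrom)) {
    v <- corrected_track[[ch]]
    i <- which(sites$chrom == ch)
    s <- sites$start[i]; e <- sites$end[i]
    ok <- s - flank_bp >= 0 & e + flank_bp <= length(v)
    skipped <- skipped + sum(!ok)
    io <- i[ok]
    if (!length(io)) next
    s <- sites$start[io]; e <- sites$end[io]
    core <- rsum(ch, s, e) / (e - s)
    fl <- (rsum(ch, s - flank_bp, s) + rsum(ch, e, e + flank_bp)) / (2 * flank_bp)
    fs[io] <- log2((fl + eps) / (core + eps))
  }
  if (skipped) warning(skipped, " sites skipped (flank outside chromosome)")
  sites$fs <- fs
  sites
}

# Otsu's threshold: maximize between-class variance over a binned histogram
otsu_threshold <- function(x, bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) stop("all scores equal: no threshold")
  br <- seq(r[1], r[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-(bins + 1L)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  kk <- which.max(sigma_b)
  br[kk + 1L]
}

#' Call bound sites from footprint scores
#'
#' Thresholds the footprint-score distribution; the default threshold is
#' Otsu's between-class variance maximizer (suited to the bimodal
#' bound/unbound mixture), or a quantile, or a manual `tau`.
#'
#' @param calls `motif_sites` data.frame with an `fs` column.
#' @param method `"otsu"` or `"quantile"`.
#' @param tau manual threshold; bypasses estimation when given.
#' @param quantile quantile used by `method = "quantile"` (default 0.75).
#' @param min_sites minimum number of scored sites for estimation (default 50).
#' @return `calls` with a logical `bound` column (`fs >= tau`) and attribute
#'   `tau`.
#' @export
call_bound <- function(calls, method = c("otsu", "quantile"), tau = NULL,
                       quantile = 0.75, min_sites = 50L) {
  method <- match.arg(method)
  fs <- calls$fs[!is.na(calls$fs)]
  if (is.null(tau)) {
    if (length(fs) < min_sites)
      stop("only ", length(fs), " scored sites (< ", min_sites,
           "); supply tau explicitly")
    tau <- if (method == "otsu") otsu_threshold(fs)
           else stats::quantile(fs, quantile, names = FALSE)
  }
  calls$bound <- !is.na(calls$fs) & calls$fs >= tau
  attr(calls, "tau") <- tau
  calls
}

#' Per-motif occupancy table
#'
#' Occupancy of a motif = 100 * bound sites / total sites, restricted to
#' sites inside NFR peaks when supplied; motifs with zero sites are excluded.
#' Optionally also reports the fraction of NFRs containing >= 1 bound site.
#'
#' @param calls `motif_sites` with `bound` flags.
#' @param nfr_peaks optional `peaks` data.frame to restrict to.
#' @param top_k return only the top k motifs by occupancy (default all).
#' @return data.frame `motif_id`, `n_sites`, `n_bound`, `occupancy_pct`
#'   (and `pct_nfrs_bound` when `nfr_peaks` given), sorted by descending
#'   occupancy (ties: motif id).
#' @export
occupancy_table <- function(calls, nfr_peaks = NULL, top_k = Inf) {
  stopifnot(!is.null(calls$bound))
  if (!is.null(nfr_peaks))
    calls <- calls[iv_overlap_any(calls, nfr_peaks), , drop = FALSE]
  if (nrow(calls) == 0L)
    return(data.frame(motif_id = character(), n_sites = integer(),
                      n_bound = integer(), occupancy_pct = numeric()))
  sp <- split(seq_len(nrow(calls)), calls$motif_id)
  tab <- data.frame(motif_id = names(sp),
                    n_sites = lengths(sp),
                    n_bound = vapply(sp, function(i) sum(calls$bound[i]), 0L),
                    stringsAsFactors = FALSE)
  tab$occupancy_pct <- 100 * tab$n_bound / tab$n_sites
  if (!is.null(nfr_peaks) && nrow(nfr_peaks) > 0L) {
    tab$pct_nfrs_bound <- vapply(sp, function(i) {
      b <- calls[i, , drop = FALSE]
      b <- b[b$bound, , drop = FALSE]
      100 * sum(iv_overlap_any(nfr_peaks, b)) / nrow(nfr_peaks)
    }, 0)
  }
  tab <- tab[order(-tab$occupancy_pct, tab$motif_id), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Differential TF occupancy between two phenotypes
#'
#' Both phenotypes must be scored over the same site set.  Per motif,
#' `delta_fs` is the mean footprint-score difference (a minus b) over its
#' sites; the null distribution is built from `n_background_draws` random
#' same-size site subsets drawn motif-blind across all shared sites, giving a
#' z-score and a two-sided normal p-value, BH-corrected over motifs.
#'
#' @param calls_a,calls_b `motif_sites` with `fs`, scored over a shared site
#'   set (matched on motif, position and strand).
#' @param n_background_draws background subsets per motif (default 100).
#' @param seed integer seed for the background draws.
#' @return data.frame `motif_id`, `n_sites`, `delta_fs`, `z`, `p_value`,
#'   `q_value`, sorted by p.  Motifs present in only one input are excluded
#'   (attribute `n_excluded`).
#' @export
differential_occupancy <- function(calls_a, calls_b, n_background_draws = 100L,
                                   seed = 1L) {
  key <- function(d) paste(d$motif_id, d$chrom, d$start, d$end, d$strand)
  ka <- key(calls_a); kb <- key(calls_b)
  shared <- intersect(ka, kb)
  a <- calls_a[match(shared, ka), , drop = FALSE]
  b <- calls_b[match(shared, kb), , drop = FALSE]
  ok <- !is.na(a$fs) & !is.na(b$fs)
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  motifs_a <- unique(calls_a$motif_id); motifs_b <- unique(calls_b$motif_id)
  excluded <- length(union(motifs_a, motifs_b)) -
    length(unique(a$motif_id))
  if (nrow(a) == 0L) stop("no shared scored sites")
  d <- a$fs - b$fs
  sp <- split(seq_along(d), a$motif_id)
  sizes <- lengths(sp)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  null_by_size <- lapply(unique(sizes), function(n) {
    draws <- vapply(seq_len(n_background_draws), function(i)
      mean(d[sample.int(length(d), n, replace = length(d) < n)]), 0)
    c(mean = mean(draws), sd = stats::sd(draws))
  })
  names(null_by_size) <- as.character(unique(sizes))
  delta <- vapply(sp, function(i) mean(d[i]), 0)
  nm <- vapply(names(sp), function(m) null_by_size[[as.character(sizes[m])]]["mean"], 0)
  ns <- vapply(names(sp), function(m) null_by_size[[as.character(sizes[m])]]["sd"], 0)
  z <- ifelse(ns > 0, (delta - nm) / ns, 0)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(motif_id = names(sp), n_sites = as.integer(sizes),
                    delta_fs = unname(delta), z = unname(z),
                    p_value = unname(p),
                    q_value = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
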