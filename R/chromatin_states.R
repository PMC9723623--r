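# Combinatorial chromatin states from histone-mark consensus peak sets:
# disjoint-segment (UpSet-style) decomposition, feature annotation and
# enrichment, TSS/non-TSS partition of NFRs, NFR-by-state tables and the
# Fisher co-occurrence test.

HISTONE_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3")

FEATURE_PRIORITY <- c("promoter", "five_prime_utr", "exon", "intron",
                      "three_prime_utr", "intergenic")

#' Disjoint chromatin-state segments from per-mark peak sets
#'
#' Cuts the union of all input consensus peaks at every peak boundary and
#' labels each resulting disjoint segment with the exact subset of marks
#' covering it (the bp-resolved analogue of an UpSet decomposition).
#' Overlapping peaks within one mark are merged first (with a warning).
#'
#' @param mark_peaks named list (mark -> `peaks`/interval data.frame), 1-4
#'   entries.
#' @return data.frame of class `state_segments`: `chrom`, `start`, `end`,
#'   `state` (marks joined by `+`, in `HISTONE_MARKS` order), plus one logical
#'   column per input mark.  Attributes `pct_segments` and `pct_bp` hold the
#'   per-state percentage tables over segment count and bp.
#' @export
flatten_state_segments <- function(mark_peaks) {
  stopifnot(length(mark_peaks) >= 1L, !is.null(names(mark_peaks)))
  marks <- names(mark_peaks)
  merged <- lapply(mark_peaks, function(p) {
    p <- as.data.frame(p)
    r <- iv_reduce(p)
    if (nrow(r) < nrow(p)) warning("overlapping peaks within one mark set merged")
    r
  })
  all_iv <- do.call(rbind, lapply(merged, function(m) m[, c("chrom", "start", "end")]))
  if (nrow(all_iv) == 0L) {
    seg <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character())
    class(seg) <- c("state_segments", "data.frame")
    return(seg)
  }
  dj <- GenomicRanges::disjoin(iv_to_gr(all_iv), ignore.strand = TRUE)
  seg <- gr_to_iv(dj)[, c("chrom", "start", "end")]
  cover <- sapply(marks, function(mk) iv_overlap_any(seg, merged[[mk]]))
  if (is.null(dim(cover))) cover <- matrix(cover, nrow = nrow(seg))
  colnames(cover) <- marks
  ord <- intersect(HISTONE_MARKS, marks)
  ord <- c(ord, setdiff(marks, ord))
  seg$state <- apply(cover, 1, function(z) paste(ord[ord %in% marks[z]],
                                                 collapse = "+"))
  seg <- cbind(seg, as.data.frame(cover))
  seg <- seg[rowSums(cover) > 0, , drop = FALSE]
  seg <- iv_sort(seg)
  rownames(seg) <- NULL
  bp <- seg$end - seg$start
  pct_segments <- 100 * table(seg$state) / nrow(seg)
  pct_bp <- 100 * tapply(bp, seg$state, sum) / sum(bp)
  attr(seg, "pct_segments") <- as.data.frame(pct_segments,
                                             responseName = "pct_segments")
  attr(seg, "pct_bp") <- data.frame(state = names(pct_bp),
                                    pct_bp = as.numeric(pct_bp))
  class(seg) <- c("state_segments", "data.frame")
  seg
}

#' Annotate intervals with their genomic feature
#'
#' Assigns each interval the highest-priority feature overlapping its
#' midpoint, with priority promoter > 5'UTR > exon > intron > 3'UTR and
#' intergenic as the fallback.  The midpoint rule guarantees a unique label.
#'
#' @param query interval data.frame.
#' @param annotation `genome_annotation`.
#' @return character vector of feature labels, one per row of `query`.
#' @export
annotate_feature <- function(query, annotation) {
  n <- nrow(query)
  if (n == 0L) return(character())
  mid <- floor((query$start + query$end) / 2)
  mp <- data.frame(chrom = query$chrom, start = mid, end = mid + 1)
  lab <- rep("intergenic", n)
  for (f in rev(setdiff(FEATURE_PRIORITY, "intergenic"))) {
    fv <- annotation$features[[f]]
    if (is.null(fv) || nrow(fv) == 0L) next
    lab[iv_overlap_any(mp, fv)] <- f
  }
  lab
}

# bp covered by each feature class (intergenic = genome minus the rest)
feature_bp_table <- function(annotation) {
  genome_bp <- sum(annotation$seqlengths)
  feats <- setdiff(FEATURE_PRIORITY, "intergenic")
  bp <- vapply(feats, function(f) {
    fv <- annotation$features[[f]]
    if (is.null(fv) || nrow(fv) == 0L) 0 else iv_covered_bp(fv)
  }, 0)
  covered <- do.call(rbind, lapply(feats, function(f) {
    fv <- annotation$features[[f]]
    if (is.null(fv) || nrow(fv) == 0L) NULL else fv[, c("chrom", "start", "end")]
  }))
  non_intergenic <- if (is.null(covered)) 0 else iv_covered_bp(covered)
  c(bp, intergenic = genome_bp - non_intergenic)
}

#' State-by-feature enrichment matrix
#'
#' For every chromatin state and genomic feature computes
#' `log2( (state bp in feature / state bp) / (feature bp / genome bp) )`
#' with a 1 bp pseudocount on the observed overlap.
#'
#' @param segments `state_segments`.
#' @param annotation `genome_annotation`.
#' @return numeric matrix states x features.
#' @export
state_feature_enrichment <- function(segments, annotation) {
  genome_bp <- sum(annotation$seqlengths)
  if (genome_bp <= 0) stop("zero-length genome")
  stopifnot(nrow(segments) >= 1L)
  states <- sort(unique(segments$state))
  fbp <- feature_bp_table(annotation)
  mat <- matrix(NA_real_, length(states), length(FEATURE_PRIORITY),
                dimnames = list(states, FEATURE_PRIORITY))
  for (st in states) {
    seg <- segments[segments$state == st, , drop = FALSE]
    state_bp <- sum(seg$end - seg$start)
    for (f in FEATURE_PRIORITY) {
      if (f == "intergenic") {
        others <- do.call(rbind, lapply(setdiff(FEATURE_PRIORITY, "intergenic"),
          function(g) {
            fv <- annotation$features[[g]]
            if (is.null(fv) || nrow(fv) == 0L) NULL
            else fv[, c("chrom", "start", "end")]
          }))
        obs <- state_bp - if (is.null(others)) 0 else iv_intersect_bp(seg, others)
      } else {
        fv <- annotation$features[[f]]
        obs <- if (is.null(fv) || nrow(fv) == 0L) 0 else iv_intersect_bp(seg, fv)
      }
      mat[st, f] <- log2(((obs + 1) / state_bp) / (fbp[[f]] / genome_bp))
    }
  }
  mat
}

#' Classify NFR peaks as TSS or non-TSS
#'
#' A peak is `tss` when it overlaps (>= 1 bp) the window from `window` bp
#' upstream to `window` bp downstream of any annotated TSS (strand-oriented;
#' the window is symmetric so the orientation matters only for reporting),
#' otherwise `non_tss`.
#'
#' @param nfr_peaks `peaks` data.frame.
#' @param annotation `genome_annotation`.
#' @param window bp on each side of the TSS (default 200).
#' @return character vector `"tss"`/`"non_tss"` per peak.
#' @export
classify_nfr_tss <- function(nfr_peaks, annotation, window = 200L) {
  if (nrow(nfr_peaks) == 0L) return(character())
  tss <- annotation$tss
  win <- data.frame(chrom = tss$chrom,
                    start = pmax(tss$pos - window, 0),
                    end = tss$pos + window + 1)
  ifelse(iv_overlap_any(nfr_peaks, win), "tss", "non_tss")
}

#' NFR-by-state percentage table
#'
#' Assigns each NFR the mark subset of the state segment covering its summit
#' (midpoint when no summit is recorded; `unmarked` when no segment covers
#' it) and tabulates the percentage of NFRs per state within each TSS class.
#'
#' @param nfrs `peaks` data.frame with a `tss_class` column
#'   (`"tss"`/`"non_tss"`).
#' @param segments `state_segments`.
#' @return data.frame `tss_class`, `state`, `n`, `pct`; percentages sum to
#'   100 within each class.
#' @export
nfr_state_overlap <- function(nfrs, segments) {
  stopifnot(!is.null(nfrs$tss_class))
  if (nrow(nfrs) == 0L)
    return(data.frame(tss_class = character(), state = character(),
                      n = integer(), pct = numeric()))
  pos <- ifelse(is.na(nfrs$summit), floor((nfrs$start + nfrs$end) / 2),
                nfrs$start + nfrs$summit)
  pt <- data.frame(chrom = nfrs$chrom, start = pos, end = pos + 1)
  state <- rep("unmarked", nrow(nfrs))
  if (nrow(segments) > 0L) {
    h <- iv_overlaps(pt, segments)
    state[h$query] <- segments$state[h$subject]
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(nfrs)), nfrs$tss_class),
    function(idx) {
      tb <- table(state[idx])
      data.frame(tss_class = nfrs$tss_class[idx[1]], state = names(tb),
                 n = as.integer(tb), pct = 100 * as.integer(tb) / length(idx),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Fisher exact test of mark co-occurrence
#'
#' Two-sided Fisher exact test on a 2x2 table by hypergeometric enumeration,
#' with the sample odds ratio `(n11 * n00) / (n10 * n01)` (infinite when a
#' denominator cell is 0 and the numerator cells are positive).
#'
#' @param n11,n10,n01,n00 non-negative integer cell counts (rows: mark A
#'   present/absent; columns: mark B present/absent).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_cooccurrence <- function(n11, n10, n01, n00) {
  cells <- c(n11, n10, n01, n00)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  if (sum(cells) == 0) stop("all-zero table")
  or <- if (n10 * n01 == 0) {
    if (n11 * n00 > 0) Inf else NaN
  } else (n11 * n00) / (n10 * n01)
  # hypergeometric enumeration with fixed margins
  m <- n11 + n10          # row-1 total
  nn <- n01 + n00         # row-2 total
  k <- n11 + n01          # column-1 total
  lo <- max(0, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(n11, m, nn, k)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Per-gene histone-mark enrichment over input
#'
#' Computes, per gene, the ratio of mean IP to mean input signal density with
#' a small regularizer `eps = 0.5 / gene length`, and flags genes exceeding a
#' fold threshold (default 3-fold over input).
#'
#' @param ip_tracks named list of `signal_track`s (one per mark) or a single
#'   track.
#' @param input_track `signal_track` of the input/control.
#' @param annotation `genome_annotation`.
#' @param fold enrichment threshold (default 3).
#' @return data.frame `gene_id`, one `ratio_<mark>` and `flag_<mark>` column
#'   per mark, and `any_mark` (TRUE when any mark exceeds `fold`).
#' @export
gene_mark_enrichment <- function(ip_tracks, input_track, annotation, fold = 3) {
  if (inherits(ip_tracks, "signal_track")) ip_tracks <- list(mark = ip_tracks)
  genes <- annotation$genes
  keep <- genes$end > genes$start
  if (any(!keep)) warning(sum(!keep), " zero-length genes skipped")
  genes <- genes[keep, , drop = FALSE]
  out <- data.frame(gene_id = genes$id, stringsAsFactors = FALSE)
  flags <- matrix(FALSE, nrow(genes), length(ip_tracks))
  for (j in seq_along(ip_tracks)) {
    mk <- names(ip_tracks)[j]
    ratio <- numeric(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      idx <- (genes$start[i] + 1):genes$end[i]
      eps <- 0.5 / (genes$end[i] - genes$start[i])
      ip <- mean(ip_tracks[[j]][[genes$chrom[i]]][idx])
      ins <- mean(input_track[[genes$chrom[i]]][idx])
      ratio[i] <- (ip + eps) / (ins + eps)
    }
    out[[paste0("ratio_", mk)]] <- ratio
    flags[, j] <- ratio > fold
    out[[paste0("flag_", mk)]] <- flags[, j]
  }
  out$any_mark <- rowSums(flags) > 0
  out
}
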