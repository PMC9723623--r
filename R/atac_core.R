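# ATAC fragment-level analysis: size-class partition, Tn5 cut-site tracks,
# windowed local-Poisson NFR peak calling, replicate consensus, TSS
# metaprofiles and differential accessibility.

# Inclusive fragment-length bounds of the three nucleosomal classes.
FRAGMENT_CLASS_BOUNDS <- list(nfr = c(0L, 100L), mono = c(150L, 247L),
                              di = c(315L, 473L))

#' Classify ATAC fragments by length
#'
#' Partitions fragments into nucleosome-free (0-100 bp), mono-nucleosome
#' (150-247 bp) and di-nucleosome (315-473 bp) classes by inclusive bounds;
#' lengths falling in the gaps (101-149, 248-314) or above 473 are
#' `unassigned`.  Every fragment receives exactly one label.
#'
#' @param fragments `fragments` data.frame (needs a `length` column).
#' @return the input with an added factor column `class` with levels
#'   `nfr`, `mono`, `di`, `unassigned`.
#' @export
classify_fragments <- function(fragments) {
  len <- fragments$length
  cls <- rep("unassigned", length(len))
  for (nm in names(FRAGMENT_CLASS_BOUNDS)) {
    b <- FRAGMENT_CLASS_BOUNDS[[nm]]
    cls[len >= b[1] & len <= b[2]] <- nm
  }
  fragments$class <- factor(cls, levels = c("nfr", "mono", "di", "unassigned"))
  fragments
}

#' Per-bp Tn5 cut-site track
#'
#' Each fragment contributes two cut counts, at `start + shift_plus` and
#' `end - 1 + shift_minus` (defaults +4/-5, the standard Tn5 offset
#' correction).  Cuts falling outside a chromosome are clipped and counted.
#'
#' @param fragments `fragments` data.frame.
#' @param seqlengths named numeric vector of chromosome lengths.
#' @param shift_plus,shift_minus integer offsets applied to the left and right
#'   fragment ends.
#' @return object of class `signal_track`: named list of per-bp numeric
#'   vectors with attribute `clipped` (number of out-of-bounds cuts dropped).
#' @export
cut_site_track <- function(fragments, seqlengths, shift_plus = 4L,
                           shift_minus = -5L) {
  stopifnot(shift_plus == as.integer(shift_plus),
            shift_minus == as.integer(shift_minus))
  track <- lapply(seqlengths, function(L) numeric(L))
  clipped <- 0L
  for (ch in names(seqlengths)) {
    L <- as.integer(seqlengths[[ch]])
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) next
    cuts <- c(fr$start + shift_plus, fr$end - 1L + shift_minus)
    inside <- cuts >= 0 & cuts < L
    clipped <- clipped + sum(!inside)
    if (any(inside))
      track[[ch]] <- as.numeric(tabulate(cuts[inside] + 1L, nbins = L))
  }
  structure(track, clipped = clipped, class = "signal_track")
}

# per-bp fragment coverage track
coverage_track <- function(fragments, seqlengths) {
  track <- lapply(seqlengths, function(L) numeric(L))
  for (ch in names(seqlengths)) {
    L <- as.integer(seqlengths[[ch]])
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) next
    s <- pmax(as.integer(fr$start), 0L) + 1L
    e <- pmin(as.integer(fr$end), L) + 1L
    ok <- s <= L & e > 1L & s < e
    # difference-array coverage: +1 at start, -1 at end, cumulative sum
    ds <- tabulate(s[ok], nbins = L + 1L)
    de <- tabulate(e[ok], nbins = L + 1L)
    track[[ch]] <- cumsum(ds - de)[1:L]
  }
  structure(track, class = "signal_track")
}

#' Call peaks from fragments with a windowed local-Poisson scan
#'
#' Slides a window along each chromosome, counts fragment midpoints per
#' window, and tests each count against a Poisson null whose rate is the
#' maximum of the genome-wide rate and local rates estimated in 1 kb and
#' 10 kb windows centred on the window (the local-lambda idea of
#' MACS-family callers, re-derived here in closed form).  Benjamini-Hochberg
#' correction is applied over all windows; significant windows that overlap
#' or touch are merged into peaks, and each peak's summit is the bp of
#' maximal fragment coverage.
#'
#' @param fragments `fragments` data.frame (typically the NFR class).
#' @param seqlengths named chromosome lengths; the effective genome size is
#'   their sum unless overridden.
#' @param effective_genome_size effective genome size used for the
#'   genome-wide rate (default `sum(seqlengths)`; 2.7e8 is the value used for
#'   real honey-bee data).
#' @param window,step window width and step in bp (defaults 200/50).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @return `peaks` data.frame; empty when no fragments are supplied.
#' @export
call_peaks <- function(fragments, seqlengths, effective_genome_size = NULL,
                       window = 200L, step = 50L, q_threshold = 0.05) {
  if (nrow(fragments) == 0L) return(empty_peaks())
  if (is.null(effective_genome_size)) effective_genome_size <- sum(seqlengths)
  stopifnot(effective_genome_size > 0, window > 0, step > 0)
  n_total <- nrow(fragments)
  rate_genome <- n_total / effective_genome_size

  res <- list()
  for (ch in names(seqlengths)) {
    L <- as.integer(seqlengths[[ch]])
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    starts <- seq.int(0L, max(L - window, 0L), by = step)
    if (nrow(fr) == 0L || length(starts) == 0L) next
    mid <- floor((fr$start + fr$end) / 2)
    mid <- mid[mid >= 0 & mid < L]
    cum <- c(0, cumsum(tabulate(mid + 1L, nbins = L)))
    cnt_in <- function(a, b) {      # midpoints in [a, b), clipped
      a <- pmax(a, 0L); b <- pmin(b, L)
      cum[pmax(b, a) + 1L] - cum[a + 1L]
    }
    cnt <- cnt_in(starts, starts + window)
    centre <- starts + window %/% 2L
    lam1 <- cnt_in(centre - 500L, centre + 500L) /
      (pmin(centre + 500L, L) - pmax(centre - 500L, 0L)) * window
    lam10 <- cnt_in(centre - 5000L, centre + 5000L) /
      (pmin(centre + 5000L, L) - pmax(centre - 5000L, 0L)) * window
    lambda <- pmax(rate_genome * window, lam1, lam10)
    p <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + window,
                            count = cnt, p_value = p, stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty_peaks())
  win <- do.call(rbind, res)
  win$q_value <- stats::p.adjust(win$p_value, method = "BH")
  sig <- win[win$q_value <= q_threshold & win$count > 0, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty_peaks())
  merged <- iv_reduce(sig, min_gapwidth = 1L)

  cov <- coverage_track(fragments, seqlengths)
  h <- iv_overlaps(merged, sig)
  pk <- merged
  pk$score <- 0; pk$p_value <- 1; pk$q_value <- 1; pk$summit <- NA_real_
  for (i in seq_len(nrow(merged))) {
    members <- h$subject[h$query == i]
    pk$p_value[i] <- min(sig$p_value[members])
    pk$q_value[i] <- min(sig$q_value[members])
    pk$score[i] <- max(sig$count[members])
    v <- cov[[pk$chrom[i]]][(pk$start[i] + 1):pk$end[i]]
    pk$summit[i] <- which.max(v) - 1
  }
  pk$name <- paste0("peak_", seq_len(nrow(pk)))
  pk$strand <- "."
  as_peaks(pk)
}

#' Replicate-consensus peaks
#'
#' Keeps peaks that overlap (>= 1 bp) a peak called in the other replicate
#' and merges each overlapping group into one interval spanning its union.
#'
#' @param rep_a,rep_b `peaks` data.frames from two replicates.
#' @return `peaks` data.frame of merged consensus intervals.
#' @export
consensus_peaks <- function(rep_a, rep_b) {
  keep_a <- rep_a[iv_overlap_any(rep_a, rep_b), , drop = FALSE]
  keep_b <- rep_b[iv_overlap_any(rep_b, rep_a), , drop = FALSE]
  both <- rbind(keep_a[, c("chrom", "start", "end")],
                keep_b[, c("chrom", "start", "end")])
  if (nrow(both) == 0L) return(empty_peaks())
  merged <- iv_reduce(both)
  merged <- iv_sort(merged)
  rownames(merged) <- NULL
  merged$name <- paste0("consensus_", seq_len(nrow(merged)))
  as_peaks(merged)
}

#' TSS metaprofile of a signal track
#'
#' Averages a per-bp signal over windows of +/- `halfwidth` bp around every
#' usable TSS; minus-strand genes are orientation-flipped before averaging so
#' that positive x is always downstream.
#'
#' @param track `signal_track`.
#' @param annotation `genome_annotation`.
#' @param halfwidth half window size in bp (default 1000).
#' @return numeric vector of length `2 * halfwidth + 1` named by position
#'   relative to the TSS, with attribute `n_skipped` (TSSs too close to a
#'   chromosome edge).
#' @export
tss_metaprofile <- function(track, annotation, halfwidth = 1000L) {
  tss <- annotation$tss
  acc <- numeric(2L * halfwidth + 1L)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(tss))) {
    v <- track[[tss$chrom[i]]]
    if (is.null(v)) { skipped <- skipped + 1L; next }
    p <- tss$pos[i]
    if (p - halfwidth < 0 || p + halfwidth >= length(v)) {
      skipped <- skipped + 1L; next
    }
    w <- v[(p - halfwidth + 1):(p + halfwidth + 1)]
    if (tss$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TSS within chromosome bounds")
  out <- acc / used
  names(out) <- as.character(seq(-halfwidth, halfwidth))
  attr(out, "n_skipped") <- skipped
  out
}

#' Count fragments overlapping each peak
#'
#' @param peaks `peaks` data.frame.
#' @param fragment_sets named list of `fragments` data.frames (one per sample).
#' @return integer matrix peaks x samples (midpoint-in-peak counts).
#' @export
count_fragments_in_peaks <- function(peaks, fragment_sets) {
  m <- matrix(0L, nrow = nrow(peaks), ncol = length(fragment_sets),
              dimnames = list(peaks$name, names(fragment_sets)))
  gp <- iv_to_gr(peaks)
  for (j in seq_along(fragment_sets)) {
    fr <- fragment_sets[[j]]
    mid <- floor((fr$start + fr$end) / 2)
    gm <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    m[, j] <- GenomicRanges::countOverlaps(gp, gm, ignore.strand = TRUE)
  }
  m
}

#' Differential accessibility between two groups of samples
#'
#' Normalizes a per-peak count matrix by median-of-ratios size factors and
#' tests each peak with a two-sided z-test on log2 normalized counts using a
#' pooled variance with a dispersion floor, followed by Benjamini-Hochberg
#' correction.  The significant set is `q <= 0.05` by convention.
#'
#' @param counts_matrix integer matrix, peaks x samples.
#' @param groups character/factor of length `ncol(counts_matrix)` with exactly
#'   two levels, each with >= 2 replicates.
#' @param var_floor minimum pooled variance on the log2 scale (default 0.01).
#' @return data.frame with `unit`, `log2fc` (first level over second),
#'   `statistic`, `p_value`, `q_value`.
#' @export
differential_accessibility <- function(counts_matrix, groups, var_floor = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required")
  if (any(table(groups) < 2L))
    stop("each group needs >= 2 replicates")
  sf <- size_factors(counts_matrix)
  norm <- sweep(counts_matrix, 2, sf, "/")
  lg <- log2(norm + 0.5)
  a <- lg[, groups == levels(groups)[1], drop = FALSE]
  b <- lg[, groups == levels(groups)[2], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  pooled <- pmax(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2), var_floor)
  z <- (ma - mb) / sqrt(pooled * (1 / na + 1 / nb))
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(unit = rownames(counts_matrix) %||% as.character(seq_len(nrow(lg))),
             log2fc = ma - mb, statistic = z, p_value = p, q_value = q,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
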