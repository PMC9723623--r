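# Genomic intervals are plain data.frames with columns chrom, start, end and
# optionally strand, using 0-based half-open coordinates throughout the
# package.  GenomicRanges does the heavy interval arithmetic behind this
# surface; conversion to its 1-based closed convention happens only here.

#' Construct an interval table
#'
#' Builds and validates the package's universal coordinate unit: a data.frame
#' of 0-based half-open genomic intervals.
#'
#' @param chrom character vector of sequence names (non-empty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, ": need 0 <= start < end (first offender row ", bad[1], ")")
  if (!is.null(df$strand) && any(!df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(df)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
iv_to_gr <- function(df) {
  s <- if (is.null(df$strand)) "*" else ifelse(df$strand == ".", "*", df$strand)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = s)
}

gr_to_iv <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = ifelse(s == "*", ".", s),
             stringsAsFactors = FALSE)
}

# indices of rows in `a` overlapping >= 1 bp with any row of `b`
iv_overlap_any <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(logical(nrow(a)))
  GenomicRanges::countOverlaps(iv_to_gr(a), iv_to_gr(b), ignore.strand = TRUE) > 0
}

# hits data.frame (query, subject) of >=1 bp overlaps
iv_overlaps <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  h <- GenomicRanges::findOverlaps(iv_to_gr(a), iv_to_gr(b), ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

# union/merge of possibly-overlapping intervals (strand ignored)
iv_reduce <- function(df, min_gapwidth = 0L) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(iv_to_gr(df), ignore.strand = TRUE,
                              min.gapwidth = min_gapwidth)
  gr_to_iv(gr)[, c("chrom", "start", "end")]
}

# total bp covered after merging
iv_covered_bp <- function(df) {
  if (nrow(df) == 0L) return(0)
  r <- iv_reduce(df)
  sum(r$end - r$start)
}

# bp of intersection between two interval sets (each merged first)
iv_intersect_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  gi <- GenomicRanges::intersect(
    GenomicRanges::reduce(iv_to_gr(a), ignore.strand = TRUE),
    GenomicRanges::reduce(iv_to_gr(b), ignore.strand = TRUE))
  sum(GenomicRanges::width(gi))
}

iv_sort <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
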