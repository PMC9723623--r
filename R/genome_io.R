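# Readers and writers for the standard formats the pipeline touches:
# BED/narrowPeak, GFF3 gene annotation, fragment TSV/BEDPE, JASPAR PFM text
# and FASTA.  All coordinates are converted to 0-based half-open at the
# boundary; GFF3 (1-based inclusive) and GRanges conversions happen here only.

#' Read a BED or narrowPeak file as a peak table
#'
#' Accepts BED3/4/5/6 and the 10-column narrowPeak dialect.  narrowPeak
#' `-log10` p/q columns are converted to linear probabilities on read;
#' missing values (`-1`) become 1.  Input order is preserved.
#'
#' @param path path to a tab-separated BED-family file.
#' @return data.frame of class `peaks` with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `p_value`, `q_value`, `summit` (0-based offset
#'   within the peak, `NA` when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (length(keep) == 0L) return(empty_peaks())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nc <- lengths(fields)
  badn <- which(!nc %in% c(3L, 4L, 5L, 6L, 10L))
  if (length(badn))
    stop("line ", keep[badn[1]], ": unsupported column count ", nc[badn[1]],
         " (expected 3, 4, 5, 6 or 10)")
  n <- length(fields)
  col <- function(j, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= j) f[j] else default, "")
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  badc <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(badc))
    stop("line ", keep[badc[1]], ": malformed coordinates (need 0 <= start < end)")
  name <- ifelse(nc >= 4L, col(4), NA_character_)
  strand <- ifelse(nc >= 6L, col(6), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  score <- rep(0, n)
  p <- rep(1, n)
  q <- rep(1, n)
  summit <- rep(NA_real_, n)
  if (any(nc == 5L | nc == 6L)) {
    i <- nc %in% c(5L, 6L)
    score[i] <- suppressWarnings(as.numeric(col(5)))[i]
  }
  if (any(nc == 10L)) {
    i <- nc == 10L
    sv <- suppressWarnings(as.numeric(col(7)))
    lp <- suppressWarnings(as.numeric(col(8)))
    lq <- suppressWarnings(as.numeric(col(9)))
    sm <- suppressWarnings(as.numeric(col(10)))
    score[i] <- sv[i]
    p[i] <- ifelse(lp[i] < 0, 1, 10^(-lp[i]))
    q[i] <- ifelse(lq[i] < 0, 1, 10^(-lq[i]))
    summit[i] <- ifelse(sm[i] < 0, NA_real_, sm[i])
  }
  score[is.na(score)] <- 0
  bads <- which(!is.na(summit) & (summit < 0 | summit >= end - start))
  if (length(bads))
    stop("line ", keep[bads[1]], ": summit outside peak")
  pk <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, p_value = p, q_value = q,
                   summit = summit, stringsAsFactors = FALSE)
  class(pk) <- c("peaks", "data.frame")
  pk
}

empty_peaks <- function() {
  pk <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   name = character(), score = numeric(), strand = character(),
                   p_value = numeric(), q_value = numeric(), summit = numeric(),
                   stringsAsFactors = FALSE)
  class(pk) <- c("peaks", "data.frame")
  pk
}

as_peaks <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$name)) df$name <- NA_character_
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$p_value)) df$p_value <- 1
  if (is.null(df$q_value)) df$q_value <- 1
  if (is.null(df$summit)) df$summit <- NA_real_
  df <- df[, c("chrom", "start", "end", "name", "score", "strand",
               "p_value", "q_value", "summit")]
  validate_intervals(df, "peak")
  class(df) <- c("peaks", "data.frame")
  df
}

#' Write intervals or peaks to disk
#'
#' @param items interval or peak data.frame.
#' @param path output path.
#' @param dialect `"bed3"`, `"narrowPeak"` or `"tsv"`.  `tsv` writes every
#'   column verbatim and round-trips losslessly; `narrowPeak` converts p/q back
#'   to `-log10`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(items, path, dialect = c("bed3", "narrowPeak", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(items)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (dialect == "bed3") {
    out <- if (nrow(df)) paste(df$chrom, format_num(df$start), format_num(df$end),
                               sep = "\t") else character()
    writeLines(out, path)
  } else if (dialect == "narrowPeak") {
    df <- as_peaks(df)
    nm <- ifelse(is.na(df$name), paste0("peak_", seq_len(nrow(df))), df$name)
    if (nrow(df) == 0L) nm <- character()
    out <- if (nrow(df)) paste(df$chrom, format_num(df$start), format_num(df$end),
                               nm, "0", df$strand,
                               format_num(df$score),
                               format_num(-log10(pmax(df$p_value, 1e-300))),
                               format_num(-log10(pmax(df$q_value, 1e-300))),
                               format_num(ifelse(is.na(df$summit), -1, df$summit)),
                               sep = "\t") else character()
    writeLines(out, path)
  } else {
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  }
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 2^52, sprintf("%.0f", x),
         format(x, scientific = FALSE, trim = TRUE, digits = 10))
}

#' Read ATAC fragments
#'
#' Accepts a >=3-column fragment TSV (`chrom start end`, 0-based half-open) or
#' 10-column BEDPE, in which case the fragment is the outermost span of the two
#' mates.  Output is sorted by `(chrom, start)`.
#'
#' @param path fragment file path.
#' @return data.frame of class `fragments` with columns `chrom`, `start`,
#'   `end`, `length`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    fr <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     length = numeric())
    class(fr) <- c("fragments", "data.frame")
    return(fr)
  }
  if (ncol(dt) < 3L) stop("fragment file needs >= 3 columns")
  is_bedpe <- ncol(dt) >= 6L && is.character(dt[[4]]) &&
    is.numeric(dt[[5]]) && is.numeric(dt[[6]])
  if (is_bedpe) {
    chrom <- dt[[1]]
    start <- pmin(dt[[2]], dt[[5]])
    end <- pmax(dt[[3]], dt[[6]])
  } else {
    chrom <- dt[[1]]
    start <- as.numeric(dt[[2]])
    end <- as.numeric(dt[[3]])
  }
  bad <- which(is.na(start) | is.na(end) | end - start <= 0)
  if (length(bad))
    stop("line ", bad[1], ": non-positive fragment length")
  fr <- data.frame(chrom = chrom, start = start, end = end,
                   length = end - start, stringsAsFactors = FALSE)
  fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
  rownames(fr) <- NULL
  class(fr) <- c("fragments", "data.frame")
  fr
}

#' Read a GFF3 gene annotation
#'
#' Parses gene/mRNA/exon/UTR features, converts 1-based inclusive GFF3
#' coordinates to 0-based half-open, derives introns as the gaps between a
#' transcript's sorted exons and strand-aware TSS positions, and materialises
#' the derived feature sets (promoter, 5'UTR, exon, intron, 3'UTR) used for
#' element annotation.
#'
#' @param path GFF3 file.
#' @param promoter_width bp upstream of the TSS treated as promoter (default
#'   200, matching the TSS-proximal window used for element classification).
#' @return object of class `genome_annotation`: list with `genes`,
#'   `transcripts`, `exons`, `introns`, `tss`, `features` (list of interval
#'   data.frames), `seqlengths`, `promoter_width`.
#' @export
read_gff3 <- function(path, promoter_width = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  # chromosome lengths from ##sequence-region pragmas, falling back to seqinfo
  pr <- grep("^##sequence-region", readLines(path, n = 5000), value = TRUE)
  sl <- GenomeInfoDb::seqlengths(gr)
  if (length(pr)) {
    parts <- strsplit(trimws(pr), "[ \t]+")
    sl <- setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                   vapply(parts, function(p) p[2], ""))
  }
  gdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = as.numeric(GenomicRanges::end(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    type = type,
                    id = if (!is.null(gr$ID)) as.character(gr$ID) else
                      rep(NA_character_, length(gr)),
                    parent = vapply(if (!is.null(gr$Parent)) gr$Parent else
                      vector("list", length(gr)),
                      function(p) if (length(p)) p[[1]] else NA_character_, ""),
                    stringsAsFactors = FALSE)
  genes <- gdf[gdf$type == "gene", , drop = FALSE]
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene without strand in ", path)
  tx <- gdf[gdf$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- gdf[gdf$type == "exon", , drop = FALSE]
  utr5 <- gdf[gdf$type == "five_prime_UTR", , drop = FALSE]
  utr3 <- gdf[gdf$type == "three_prime_UTR", , drop = FALSE]
  # exons must lie inside their parent transcript span
  if (nrow(ex)) {
    sp <- match(ex$parent, tx$id)
    bad <- which(!is.na(sp) & (ex$start < tx$start[sp] | ex$end > tx$end[sp]))
    if (length(bad))
      stop("exon outside parent transcript span: ", ex$parent[bad[1]])
  }
  # introns: per transcript, gaps between sorted exons
  introns <- if (nrow(ex)) {
    do.call(rbind, lapply(split(ex, ex$parent), function(e) {
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) < 2L) return(NULL)
      data.frame(chrom = e$chrom[-1], start = e$end[-nrow(e)], end = e$start[-1],
                 strand = e$strand[-1], transcript_id = e$parent[-1],
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(introns))
    introns <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                          strand = character(), transcript_id = character())
  introns <- introns[introns$end > introns$start, , drop = FALSE]
  rownames(introns) <- NULL
  tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  tss <- data.frame(gene_id = genes$id, chrom = genes$chrom, pos = tss_pos,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if (length(sl) == 0L || all(is.na(sl))) {
    sl <- tapply(gdf$end, gdf$chrom, max)
    sl <- setNames(as.numeric(sl), names(sl))
  } else sl <- sl[!is.na(sl)]
  promoter <- promoter_windows(tss, promoter_width, sl)
  features <- list(
    promoter = promoter,
    five_prime_utr = utr5[, c("chrom", "start", "end", "strand")],
    exon = ex[, c("chrom", "start", "end", "strand")],
    intron = introns[, c("chrom", "start", "end", "strand")],
    three_prime_utr = utr3[, c("chrom", "start", "end", "strand")]
  )
  ann <- list(genes = genes[, c("id", "chrom", "start", "end", "strand")],
              transcripts = tx[, c("id", "parent", "chrom", "start", "end", "strand")],
              exons = ex[, c("parent", "chrom", "start", "end", "strand")],
              introns = introns,
              tss = tss,
              features = features,
              seqlengths = sl,
              promoter_width = promoter_width)
  names(ann$transcripts)[2] <- "gene_id"
  names(ann$exons)[1] <- "transcript_id"
  class(ann) <- "genome_annotation"
  ann
}

# strand-aware upstream windows [tss-w, tss) on + / (tss, tss+w] on -
promoter_windows <- function(tss, width, seqlengths) {
  if (nrow(tss) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character()))
  start <- ifelse(tss$strand == "+", tss$pos - width, tss$pos + 1)
  end <- ifelse(tss$strand == "+", tss$pos, tss$pos + 1 + width)
  sl <- seqlengths[tss$chrom]
  start <- pmax(start, 0)
  end <- pmin(end, ifelse(is.na(sl), Inf, sl))
  keep <- end > start
  data.frame(chrom = tss$chrom[keep], start = start[keep], end = end[keep],
             strand = tss$strand[keep], stringsAsFactors = FALSE)
}

#' Read motifs from JASPAR PFM text
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four
#' bracketed count rows in A, C, G, T order.
#'
#' @param path JASPAR-format motif file.
#' @param pseudocount total pseudocount added per column, split by the
#'   background (default 0.8, the JASPAR convention).
#' @param background length-4 base composition summing to 1 (default uniform).
#' @return list of `motif` objects: `id`, `name`, `pfm` (4 x L count matrix,
#'   rows A/C/G/T), `pseudocount`, `background`.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-8,
            pseudocount > 0)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no '>' motif headers in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  motifs <- lapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("motif block ", i, ": expected 4 rows, got ", length(block))
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[", "", ln)
      ln <- gsub("\\]", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
      if (any(is.na(vals))) stop("motif block ", i, ": non-numeric count")
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif block ", i, ": rows of unequal length")
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    h <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1]]
    m <- list(id = h[1], name = if (length(h) > 1) h[2] else h[1],
              pfm = pfm, pseudocount = pseudocount, background = background)
    class(m) <- "motif"
    m
  })
  motifs
}

#' Write motifs in JASPAR PFM text format
#' @param motifs list of `motif` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  out <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$id, " ", m$name),
      vapply(1:4, function(r)
        paste0(c("A", "C", "G", "T")[r], "  [ ",
               paste(format_num(m$pfm[r, ]), collapse = " "), " ]"), ""))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Load a genome FASTA
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("[ \t].*$", "", names(g))
  g
}

# genome -> list of integer vectors (A=1 C=2 G=3 T=4, NA otherwise)
dna_codes <- function(genome) {
  lapply(as.character(genome), function(s) {
    v <- utf8ToInt(s)
    code <- rep(NA_integer_, length(v))
    code[v == 65L | v == 97L] <- 1L
    code[v == 67L | v == 99L] <- 2L
    code[v == 71L | v == 103L] <- 3L
    code[v == 84L | v == 116L] <- 4L
    code
  })
}
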