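# Synthetic three-phenotype dataset with planted ground truth: a random
# genome with genes, planted NFRs (TSS, intronic, exonic, intergenic),
# chromatin-state intervals, embedded motif sites with per-phenotype bound
# flags, a planted TF-TF edge set, tri-modal ATAC fragments with footprint
# depletion, jittered ChIP peak replicates and NFR-shifted expression counts.

#' Simulation configuration
#'
#' Defaults define the study conditions every planted-truth test runs under:
#' a 2 Mb genome over 4 chromosomes, 200 genes, 12 motifs, 4e5 fragments per
#' replicate with the tri-modal fragment-length mixture
#' (N(55,18) truncated > 0 / N(200,25) / N(400,35), weights 0.50/0.35/0.15),
#' two replicates of three phenotypes (Q, W, D), 20% phenotype-specific NFRs
#' and two phenotype-specific motifs, footprint cut depletion to 0.25x and a
#' +1 log2 expression shift for NFR-containing genes.
#'
#' @param ... overrides of the defaults listed above (unknown keys error).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_size = 2e6,
    n_chroms = 4L,
    n_genes = 200L,
    n_motifs = 12L,
    n_fragments = 4e5,
    frag_weights = c(nfr = 0.50, mono = 0.35, di = 0.15),
    frag_means = c(nfr = 55, mono = 200, di = 400),
    frag_sds = c(nfr = 18, mono = 25, di = 35),
    replicates = 2L,
    phenotypes = c("Q", "W", "D"),
    n_nfrs = 150L,
    nfr_width = c(250, 400),
    frac_tss_nfrs = 0.4,
    frac_specific = 0.2,
    n_specific_motifs = 2L,
    nfr_enrichment = 0.55,
    mono_phasing = 0.3,
    depletion = 0.25,
    sites_per_motif = 24L,
    top_motif_bound_frac = 0.9,
    other_bound_frac = c(0.25, 0.6),
    n_states = 100L,
    state_width = c(400, 1200),
    chip_jitter = 20,
    chip_false_rate = 8,
    expression_effect = 1,
    dispersion = 0.1,
    expression_base_log2 = 7
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(abs(sum(cfg$frag_weights) - 1) < 1e-8,
            cfg$frag_means["nfr"] < cfg$frag_means["mono"],
            cfg$frag_means["mono"] < cfg$frag_means["di"],
            cfg$n_chroms >= 1, cfg$genome_size > 0)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage substream of a root seed
seed_for <- function(root, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 104729L
  as.integer((as.numeric(root) * 7919 + h * 131) %% 2147483629)
}

#' Generate a synthetic genome with planted regulatory truth
#'
#' Writes `genome.fa`, `annotation.gff3`, `motifs.jaspar`, `tf_map.tsv`,
#' `truth_manifest.txt` and `config.yaml` under `dir` and returns the
#' in-memory objects.  Deterministic for a fixed `(config, seed)`.  At least
#' 60% of planted non-TSS NFRs are intronic; motif consensus sequences are
#' embedded in the genome at the planted sites; a planted TF-TF edge set is
#' derived from the planted bound sites by a direct (site x gene) double
#' loop.
#'
#' @param config `sim_config`.
#' @param seed integer root seed.
#' @param dir output directory.
#' @return list of class `sim_truth`: `genome` (DNAStringSet), `annotation`,
#'   `motifs`, `tf_gene_map`, `nfrs`, `states`, `sites`, `edges`, `config`,
#'   `seed`, `dir`, `paths`.
#' @export
generate_genome <- function(config = sim_config(), seed = 1L, dir = tempfile("sim")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed_for(seed, "genome"))
  n_chroms <- config$n_chroms
  chrom_len <- rep(floor(config$genome_size / n_chroms), n_chroms)
  names(chrom_len) <- paste0("chr", seq_len(n_chroms))

  ## --- genes -----------------------------------------------------------
  margin <- 3000; min_gap <- 2300; max_gap <- 3000
  genes <- list(); exons <- list()
  if (config$n_genes > 0L) {
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chroms + 1)))
    gid <- 0L
    for (ci in seq_len(n_chroms)) {
      ch <- names(chrom_len)[ci]
      cursor <- margin
      for (g in seq_len(per_chrom[ci])) {
        ex_len <- c(sample(300:600, 1), sample(200:500, 1), sample(300:600, 1))
        in_len <- c(sample(500:1500, 1), sample(500:1500, 1))
        glen <- sum(ex_len, in_len)
        if (cursor + glen > chrom_len[ci] - margin)
          stop("genome too small to place requested genes; need >= ",
               (config$n_genes / n_chroms) * (glen + max_gap) + 2 * margin,
               " bp per chromosome")
        gid <- gid + 1L
        id <- sprintf("gene%03d", gid)
        strand <- sample(c("+", "-"), 1)
        gs <- cursor
        b <- gs + cumsum(c(0, ex_len[1], in_len[1], ex_len[2], in_len[2], ex_len[3]))
        genes[[gid]] <- data.frame(id = id, chrom = ch, start = gs, end = b[6],
                                   strand = strand, stringsAsFactors = FALSE)
        exons[[gid]] <- data.frame(gene_id = id, chrom = ch,
                                   start = b[c(1, 3, 5)], end = b[c(2, 4, 6)],
                                   strand = strand, stringsAsFactors = FALSE)
        cursor <- b[6] + sample(min_gap:max_gap, 1)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character())
  exons_df <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character())

  ## --- motifs ----------------------------------------------------------
  motifs <- lapply(seq_len(config$n_motifs), function(i) {
    L <- sample(8:12, 1)
    cons <- sample(1:4, L, replace = TRUE)
    pfm <- matrix(5, 4, L, dimnames = list(BASES, NULL))
    pfm[cbind(cons, seq_len(L))] <- 85
    m <- list(id = sprintf("MS%04d", i), name = sprintf("TF%02d", i),
              pfm = pfm, pseudocount = 0.8, background = rep(0.25, 4))
    class(m) <- "motif"
    m
  })
  motif_ids <- vapply(motifs, `[[`, "", "id")
  motif_names <- vapply(motifs, `[[`, "", "name")
  consensus <- lapply(motifs, function(m) apply(m$pfm, 2, which.max))

  ## --- TF gene map -----------------------------------------------------
  n_tf <- min(config$n_motifs, nrow(genes))
  tf_gene_idx <- if (n_tf > 0)
    round(seq(1, nrow(genes), length.out = n_tf)) else integer()
  tf_gene_map <- data.frame(motif_id = motif_ids[seq_len(n_tf)],
                            gene_id = genes$id[tf_gene_idx],
                            stringsAsFactors = FALSE)

  ## --- NFRs ------------------------------------------------------------
  tss_pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  introns_of <- function(gi) {
    e <- exons_df[exons_df$gene_id == genes$id[gi], , drop = FALSE]
    e <- e[order(e$start), ]
    data.frame(chrom = e$chrom[-1], start = e$end[-nrow(e)], end = e$start[-1])
  }
  nfr_w <- function(n) round(runif(n, config$nfr_width[1], config$nfr_width[2]))
  nfrs <- list()
  add_nfr <- function(chrom, start, end, kind, gene = NA_character_) {
    nfrs[[length(nfrs) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, kind = kind, gene = gene,
      stringsAsFactors = FALSE)
  }
  if (nrow(genes) > 0L) {
    # every TF gene gets a TSS NFR and an intronic NFR (edge substrate)
    for (gi in tf_gene_idx) {
      w <- nfr_w(1)
      add_nfr(genes$chrom[gi], tss_pos[gi] - w %/% 2, tss_pos[gi] - w %/% 2 + w,
              "tss", genes$id[gi])
      intr <- introns_of(gi)
      # the intron farther from the TSS keeps sites clear of the -2kb..+200 window
      pick <- if (genes$strand[gi] == "+") nrow(intr) else 1L
      w <- nfr_w(1)
      c0 <- floor((intr$start[pick] + intr$end[pick]) / 2)
      add_nfr(genes$chrom[gi], c0 - w %/% 2, c0 - w %/% 2 + w,
              "intron", genes$id[gi])
    }
    n_tss_total <- round(config$frac_tss_nfrs * config$n_nfrs)
    other_genes <- setdiff(seq_len(nrow(genes)), tf_gene_idx)
    extra_tss <- sample(other_genes, max(n_tss_total - n_tf, 0))
    for (gi in extra_tss) {
      w <- nfr_w(1)
      add_nfr(genes$chrom[gi], tss_pos[gi] - w %/% 2, tss_pos[gi] - w %/% 2 + w,
              "tss", genes$id[gi])
    }
    n_nontss <- config$n_nfrs - n_tss_total
    n_intronic <- max(round(0.72 * n_nontss) - n_tf, 0)
    n_exonic <- max(round(0.12 * n_nontss), 0)
    pool <- setdiff(other_genes, extra_tss)
    intronic_genes <- sample(pool, min(n_intronic, length(pool)))
    for (gi in intronic_genes) {
      intr <- introns_of(gi)
      pick <- which.max(intr$end - intr$start)
      w <- min(nfr_w(1), intr$end[pick] - intr$start[pick] - 40)
      c0 <- floor((intr$start[pick] + intr$end[pick]) / 2)
      add_nfr(genes$chrom[gi], c0 - w %/% 2, c0 - w %/% 2 + w,
              "intron", genes$id[gi])
    }
    pool <- setdiff(pool, intronic_genes)
    exonic_genes <- sample(pool, min(n_exonic, length(pool)))
    for (gi in exonic_genes) {
      e <- exons_df[exons_df$gene_id == genes$id[gi], , drop = FALSE]
      # last exon, away from the TSS-side windows
      pick <- if (genes$strand[gi] == "+") which.max(e$start) else which.min(e$start)
      w <- nfr_w(1)
      c0 <- floor((e$start[pick] + e$end[pick]) / 2)
      add_nfr(genes$chrom[gi], c0 - w %/% 2, c0 - w %/% 2 + w,
              "exon", genes$id[gi])
    }
  }
  # intergenic NFRs in the gene-free chromosome tails
  n_sofar <- length(nfrs)
  n_intergenic <- max(config$n_nfrs - n_sofar, if (nrow(genes)) 0L else config$n_nfrs)
  if (n_intergenic > 0) {
    per <- diff(round(seq(0, n_intergenic, length.out = n_chroms + 1)))
    for (ci in seq_len(n_chroms)) {
      if (per[ci] == 0) next
      lo <- if (nrow(genes)) max(genes$end[genes$chrom == names(chrom_len)[ci]],
                                 margin) + 5000 else margin
      hi <- chrom_len[ci] - margin
      centers <- round(seq(lo + 1000, hi - 1000, length.out = per[ci]))
      w <- nfr_w(per[ci])
      for (k in seq_len(per[ci]))
        add_nfr(names(chrom_len)[ci], centers[k] - w[k] %/% 2,
                centers[k] - w[k] %/% 2 + w[k], "intergenic")
    }
  }
  nfrs <- do.call(rbind, nfrs)
  nfrs <- nfrs[nfrs$start >= 0, , drop = FALSE]
  rownames(nfrs) <- NULL
  # phenotype assignment: TF-gene NFRs stay shared; 20% of the rest specific
  nfrs$phenotypes <- paste(config$phenotypes, collapse = ",")
  protected <- !is.na(nfrs$gene) & nfrs$gene %in% tf_gene_map$gene_id
  free_idx <- which(!protected)
  n_spec <- round(config$frac_specific * nrow(nfrs))
  n_spec <- min(n_spec, length(free_idx))
  spec_idx <- sample(free_idx, n_spec)
  ph_cycle <- rep_len(config$phenotypes, n_spec)
  nfrs$phenotypes[spec_idx] <- ph_cycle

  ## --- chromatin states -------------------------------------------------
  tss_states <- list(c("H3K4me3", "H3K27ac"), "H3K4me3",
                     c("H3K4me3", "H3K27ac"), "H3K27ac")
  nontss_states <- list("H3K27ac", c("H3K4me1", "H3K27ac"), "H3K27me3",
                        c("H3K4me1", "H3K27me3"), "H3K4me1",
                        c("H3K4me1", "H3K27ac", "H3K27me3"), "H3K27ac")
  states <- list()
  n_on_nfr <- min(round(0.7 * config$n_states), nrow(nfrs))
  on_idx <- if (n_on_nfr > 0) sample(seq_len(nrow(nfrs)), n_on_nfr) else integer()
  for (i in on_idx) {
    w <- round(runif(1, max(config$state_width[1],
                            nfrs$end[i] - nfrs$start[i] + 100),
                     config$state_width[2]))
    c0 <- floor((nfrs$start[i] + nfrs$end[i]) / 2)
    pool <- if (nfrs$kind[i] == "tss") tss_states else nontss_states
    mk <- pool[[sample(length(pool), 1)]]
    states[[length(states) + 1L]] <- data.frame(
      chrom = nfrs$chrom[i], start = max(c0 - w %/% 2, 0), end = c0 - w %/% 2 + w,
      marks = paste(mk, collapse = "+"), stringsAsFactors = FALSE)
  }
  n_off <- config$n_states - length(states)
  if (n_off > 0) {
    per <- diff(round(seq(0, n_off, length.out = n_chroms + 1)))
    for (ci in seq_len(n_chroms)) {
      if (per[ci] == 0) next
      lo <- chrom_len[ci] - 60000
      centers <- round(seq(lo, chrom_len[ci] - margin - 2000,
                           length.out = per[ci]))
      for (k in seq_len(per[ci])) {
        w <- round(runif(1, config$state_width[1], config$state_width[2]))
        mk <- nontss_states[[sample(length(nontss_states), 1)]]
        states[[length(states) + 1L]] <- data.frame(
          chrom = names(chrom_len)[ci], start = centers[k] - w %/% 2,
          end = centers[k] - w %/% 2 + w, marks = paste(mk, collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
  }
  states <- do.call(rbind, states)
  # enforce pairwise separation >= 150 bp (drop later-placed offenders)
  states <- iv_sort(states)
  keep <- rep(TRUE, nrow(states))
  last_end <- -Inf; last_ch <- ""
  for (i in seq_len(nrow(states))) {
    if (states$chrom[i] == last_ch && states$start[i] < last_end + 150) {
      keep[i] <- FALSE
    } else {
      last_end <- states$end[i]; last_ch <- states$chrom[i]
    }
  }
  states <- states[keep, , drop = FALSE]
  rownames(states) <- NULL

  ## --- planted motif sites and network edges ---------------------------
  planted_edges <- if (n_tf >= 12) data.frame(
    src = c(1, 1, 1, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10),
    tgt = c(2, 3, 4, 5, 6, 7, 8, 8, 9, 10, 11, 12, 1),
    where = c("tss", "tss", "tss", "intron", "tss", "intron", "tss", "intron",
              "tss", "tss", "intron", "tss", "tss"),
    stringsAsFactors = FALSE) else
    data.frame(src = integer(), tgt = integer(), where = character())

  site_rows <- list()
  slot_of_nfr <- function(i, used) {
    # non-overlapping slots inside NFR i: offsets 30, 80, 130, ...
    w <- nfrs$end[i] - nfrs$start[i]
    offs <- seq(30, w - 42, by = 50)
    offs <- setdiff(offs, used)
    if (!length(offs)) return(NA)
    offs[1]
  }
  used_slots <- vector("list", nrow(nfrs))
  place_site <- function(motif_idx, nfr_i, bound_map) {
    off <- slot_of_nfr(nfr_i, unlist(used_slots[[nfr_i]]))
    if (is.na(off)) return(FALSE)
    used_slots[[nfr_i]] <<- c(used_slots[[nfr_i]], off)
    L <- length(consensus[[motif_idx]])
    s <- nfrs$start[nfr_i] + off
    strand <- sample(c("+", "-"), 1)
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      motif_id = motif_ids[motif_idx], chrom = nfrs$chrom[nfr_i],
      start = s, end = s + L, strand = strand,
      bound_Q = bound_map["Q"], bound_W = bound_map["W"], bound_D = bound_map["D"],
      nfr = nfr_i, stringsAsFactors = FALSE)
    TRUE
  }
  all_b <- c(Q = TRUE, W = TRUE, D = TRUE)
  if (nrow(planted_edges)) {
    for (r in seq_len(nrow(planted_edges))) {
      tgt_gene <- tf_gene_map$gene_id[planted_edges$tgt[r]]
      cand <- which(nfrs$gene %in% tgt_gene &
                      nfrs$kind == ifelse(planted_edges$where[r] == "tss",
                                          "tss", "intron"))
      place_site(planted_edges$src[r], cand[1], all_b)
    }
  }
  # remaining sites: free NFRs only (outside TF genes), truth bound fractions
  free_nfrs <- which(!protected)
  bound_frac <- runif(config$n_motifs, config$other_bound_frac[1],
                      config$other_bound_frac[2])
  bound_frac[1] <- config$top_motif_bound_frac
  specific_motifs <- if (config$n_specific_motifs > 0 && config$n_motifs >= 2)
    seq(config$n_motifs, by = -1, length.out = min(config$n_specific_motifs,
                                                   config$n_motifs - 1)) else integer()
  specific_pheno <- rep_len(config$phenotypes[seq_len(max(1, length(config$phenotypes) - 1))],
                            length(specific_motifs))
  n_placed <- table(factor(vapply(site_rows, function(s) s$motif_id, ""),
                           levels = motif_ids))
  for (mi in seq_len(config$n_motifs)) {
    todo <- config$sites_per_motif - n_placed[motif_ids[mi]]
    placed <- 0
    for (nf in sample(rep(free_nfrs, 4))) {
      if (placed >= todo) break
      is_bound <- runif(1) < bound_frac[mi]
      bm <- all_b
      if (mi %in% specific_motifs) {
        ph <- specific_pheno[match(mi, specific_motifs)]
        bm[] <- FALSE
        bm[ph] <- is_bound
      } else bm[] <- is_bound
      # a site can only be bound in phenotypes where its host NFR is active
      act <- strsplit(nfrs$phenotypes[nf], ",", fixed = TRUE)[[1]]
      bm[setdiff(names(bm), act)] <- FALSE
      if (place_site(mi, nf, bm)) placed <- placed + 1
    }
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL

  ## --- genome sequence with embedded motif instances -------------------
  seqs <- lapply(chrom_len, function(L)
    sample(BASES, L, replace = TRUE))
  for (i in seq_len(nrow(sites))) {
    mi <- match(sites$motif_id[i], motif_ids)
    cons <- consensus[[mi]]
    bases <- BASES[cons]
    if (sites$strand[i] == "-")
      bases <- rev(c(A = "T", C = "G", G = "C", T = "A")[bases])
    seqs[[sites$chrom[i]]][(sites$start[i] + 1):sites$end[i]] <- bases
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  names(genome) <- names(chrom_len)

  ## --- derived planted edge table (direct double loop over truth) ------
  edges <- derive_truth_edges(sites, genes, tss_pos, tf_gene_map,
                              tss_window = c(-2000, 200))

  ## --- write everything -------------------------------------------------
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "annotation.gff3"),
                motifs = file.path(dir, "motifs.jaspar"),
                tf_map = file.path(dir, "tf_map.tsv"),
                manifest = file.path(dir, "truth_manifest.txt"),
                config = file.path(dir, "config.yaml"))
  Biostrings::writeXStringSet(genome, paths$fasta)
  write_gff3(genes, exons_df, chrom_len, paths$gff3)
  write_jaspar_pfm(motifs, paths$motifs)
  data.table::fwrite(tf_gene_map, paths$tf_map, sep = "\t", quote = FALSE)
  writeLines(yaml::as.yaml(unclass(config)), paths$config)

  truth <- list(genome = genome,
                annotation = read_gff3(paths$gff3),
                motifs = motifs, tf_gene_map = tf_gene_map,
                nfrs = nfrs, states = states, sites = sites, edges = edges,
                chrom_len = chrom_len,
                config = config, seed = seed, dir = dir, paths = paths)
  class(truth) <- "sim_truth"
  write_truth_manifest(truth, paths$manifest)
  truth
}

# planted edge set by brute-force loop over (bound site x TF gene)
derive_truth_edges <- function(sites, genes, tss_pos, tf_gene_map, tss_window) {
  if (nrow(tf_gene_map) == 0L || is.null(sites) || nrow(sites) == 0L)
    return(data.frame(source_tf = character(), target_tf = character(),
                      target_gene = character(), edge_class = character(),
                      phenotypes = character(), stringsAsFactors = FALSE))
  out <- list()
  for (gi in which(genes$id %in% tf_gene_map$gene_id)) {
    tssp <- tss_pos[gi]
    if (genes$strand[gi] == "+") {
      ws <- tssp + tss_window[1]; we <- tssp + tss_window[2] + 1
    } else {
      ws <- tssp - tss_window[2]; we <- tssp - tss_window[1] + 1
    }
    for (si in seq_len(nrow(sites))) {
      b <- c(Q = sites$bound_Q[si], W = sites$bound_W[si], D = sites$bound_D[si])
      if (!any(b)) next
      if (sites$chrom[si] != genes$chrom[gi]) next
      in_win <- sites$start[si] < we && sites$end[si] > ws
      in_gene <- sites$start[si] < genes$end[gi] && sites$end[si] > genes$start[gi]
      if (!in_win && !in_gene) next
      out[[length(out) + 1L]] <- data.frame(
        source_tf = sites$motif_id[si], target_gene = genes$id[gi],
        in_win = in_win, phenos = paste(names(b)[b], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(source_tf = character(), target_tf = character(),
                      target_gene = character(), edge_class = character(),
                      phenotypes = character(), stringsAsFactors = FALSE))
  rows <- do.call(rbind, out)
  g2m <- vapply(split(tf_gene_map$motif_id, tf_gene_map$gene_id),
                function(x) paste(sort(unique(x)), collapse = ","), "")
  agg <- do.call(rbind, lapply(split(rows, paste(rows$source_tf, rows$target_gene)),
    function(r) {
      cls <- if (all(r$in_win)) "tss" else if (!any(r$in_win)) "non_tss" else "both"
      ph <- sort(unique(unlist(strsplit(r$phenos, ","))))
      data.frame(source_tf = r$source_tf[1], target_tf = g2m[r$target_gene[1]],
                 target_gene = r$target_gene[1], edge_class = cls,
                 phenotypes = paste(ph, collapse = ","), stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$source_tf, agg$target_gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

write_gff3 <- function(genes, exons, chrom_len, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(chrom_len),
                     as.integer(chrom_len)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- sub("^gene", "rna", g$id)
    lines <- c(lines,
      sprintf("%s\tregland\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1, g$end, g$strand, g$id),
      sprintf("%s\tregland\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start + 1, g$end, g$strand, tid, g$id))
    e <- exons[exons$gene_id == g$id, , drop = FALSE]
    e <- e[order(e$start), ]
    for (j in seq_len(nrow(e)))
      lines <- c(lines,
        sprintf("%s\tregland\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                g$chrom, e$start[j] + 1, e$end[j], g$strand, tid, j, tid))
    # UTRs: 150 bp at each end of the mRNA, strand-aware
    if (g$strand == "+") {
      u5 <- c(e$start[1], e$start[1] + 150); u3 <- c(g$end - 150, g$end)
    } else {
      u5 <- c(g$end - 150, g$end); u3 <- c(e$start[1], e$start[1] + 150)
    }
    lines <- c(lines,
      sprintf("%s\tregland\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.u5;Parent=%s",
              g$chrom, u5[1] + 1, u5[2], g$strand, tid, tid),
      sprintf("%s\tregland\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tID=%s.u3;Parent=%s",
              g$chrom, u3[1] + 1, u3[2], g$strand, tid, tid))
  }
  writeLines(lines, path)
}

#' Simulate one replicate of ATAC fragments for a phenotype
#'
#' Fragment lengths follow the configured tri-modal mixture.  NFR-class
#' fragments are concentrated on planted NFRs active in the phenotype;
#' mono-nucleosome fragments are partially phased ~200 bp downstream of
#' TSSs; cut sites falling in bound motif cores are depleted by repositioning
#' with probability `1 - depletion`.
#'
#' @param truth `sim_truth`.
#' @param phenotype one of the configured phenotypes.
#' @param replicate replicate number (only distinguishes the output file).
#' @param seed integer seed for this draw.
#' @param path optional output fragment TSV path (written when given).
#' @return `fragments` data.frame (sorted), invisibly carrying `path` as an
#'   attribute when written.
#' @export
simulate_fragments <- function(truth, phenotype, replicate = 1L, seed = 1L,
                               path = NULL) {
  cfg <- truth$config
  if (!phenotype %in% cfg$phenotypes)
    stop("unknown phenotype '", phenotype, "'")
  set.seed(seed_for(seed, paste0("frags_", phenotype, "_", replicate)))
  n <- cfg$n_fragments
  chrom_len <- truth$chrom_len
  compi <- sample.int(3L, n, replace = TRUE, prob = cfg$frag_weights)
  comp <- names(cfg$frag_weights)[compi]
  mu <- unname(cfg$frag_means)[compi]; sg <- unname(cfg$frag_sds)[compi]
  len <- round(rnorm(n, mu, sg))
  while (any(len < 5)) {   # truncation at > 0 (resample, preserving the mixture)
    i <- which(len < 5)
    len[i] <- round(rnorm(length(i), mu[i], sg[i]))
  }

  active <- truth$nfrs[vapply(strsplit(truth$nfrs$phenotypes, ",", fixed = TRUE),
                              function(p) phenotype %in% p, TRUE), , drop = FALSE]
  bound_col <- paste0("bound_", phenotype)
  cores <- truth$sites[truth$sites[[bound_col]], , drop = FALSE]
  core_mask <- lapply(chrom_len, function(L) logical(L))
  if (!is.null(cores) && nrow(cores))
    for (i in seq_len(nrow(cores)))
      core_mask[[cores$chrom[i]]][(cores$start[i] + 1):cores$end[i]] <- TRUE

  chroms <- names(chrom_len)
  clv <- as.numeric(chrom_len)
  cum_len <- c(0, cumsum(clv))
  # positions are tracked as (chromosome index, centre); names attach at the end
  draw_uniform <- function(m) {
    gpos <- runif(m) * cum_len[length(cum_len)]
    ci <- findInterval(gpos, cum_len, rightmost.closed = TRUE)
    ci[ci > length(chroms)] <- length(chroms)
    list(ci = ci, center = floor(gpos - cum_len[ci]))
  }
  nfr_widths <- active$end - active$start
  nfr_ci <- match(active$chrom, chroms)
  draw_on_nfr <- function(m) {
    if (nrow(active) == 0L) return(draw_uniform(m))
    i <- sample.int(nrow(active), m, replace = TRUE, prob = nfr_widths)
    list(ci = nfr_ci[i],
         center = active$start[i] + floor(runif(m) * nfr_widths[i]))
  }
  ci <- integer(n); center <- numeric(n)

  i_nfr <- which(comp == "nfr")
  on <- runif(length(i_nfr)) < cfg$nfr_enrichment
  d <- draw_on_nfr(sum(on)); ci[i_nfr[on]] <- d$ci; center[i_nfr[on]] <- d$center
  d <- draw_uniform(sum(!on)); ci[i_nfr[!on]] <- d$ci; center[i_nfr[!on]] <- d$center

  i_mono <- which(comp == "mono")
  tss <- truth$annotation$tss
  tss_ci <- match(tss$chrom, chroms)
  ph <- nrow(tss) > 0 & runif(length(i_mono)) < cfg$mono_phasing
  if (any(ph)) {
    gi <- sample.int(nrow(tss), sum(ph), replace = TRUE)
    off <- ifelse(tss$strand[gi] == "+", 200, -200) + round(rnorm(sum(ph), 0, 20))
    ci[i_mono[ph]] <- tss_ci[gi]
    center[i_mono[ph]] <- tss$pos[gi] + off
  }
  d <- draw_uniform(sum(!ph))
  ci[i_mono[!ph]] <- d$ci; center[i_mono[!ph]] <- d$center

  i_di <- which(comp == "di")
  d <- draw_uniform(length(i_di)); ci[i_di] <- d$ci; center[i_di] <- d$center

  # footprint depletion: cuts landing in a bound core are repositioned with
  # probability 1 - depletion (up to 4 attempts), conserving lengths
  flat_mask <- unlist(core_mask, use.names = FALSE)
  for (attempt in 1:4) {
    start <- center - len %/% 2
    start <- pmax(pmin(start, clv[ci] - len), 0)
    cut1 <- start + 4; cut2 <- start + len - 6
    off <- cum_len[ci]
    g1 <- pmin(pmax(off + cut1, 0), length(flat_mask) - 1) + 1
    g2 <- pmin(pmax(off + cut2, 0), length(flat_mask) - 1) + 1
    in_core <- flat_mask[g1] | flat_mask[g2]
    redraw <- in_core & runif(n) < (1 - cfg$depletion)
    if (!any(redraw)) break
    was_on_nfr <- logical(n); was_on_nfr[i_nfr[on]] <- TRUE
    rd_on <- redraw & was_on_nfr
    if (any(rd_on)) {
      d <- draw_on_nfr(sum(rd_on))
      ci[rd_on] <- d$ci; center[rd_on] <- d$center
    }
    rd_off <- redraw & !was_on_nfr
    if (any(rd_off)) {
      d <- draw_uniform(sum(rd_off))
      ci[rd_off] <- d$ci; center[rd_off] <- d$center
    }
  }
  start <- center - len %/% 2
  start <- pmax(pmin(start, clv[ci] - len), 0)
  ord <- order(ci, start)   # integer sort before chrom names attach
  fr <- data.frame(chrom = chroms[ci[ord]], start = start[ord],
                   end = start[ord] + len[ord], length = len[ord],
                   stringsAsFactors = FALSE)
  class(fr) <- c("fragments", "data.frame")
  if (!is.null(path)) {
    data.table::fwrite(fr[, c("chrom", "start", "end")], path, sep = "\t",
                       col.names = FALSE)
    attr(fr, "path") <- path
  }
  fr
}

#' Simulate two replicate ChIP peak sets for one histone mark
#'
#' Every planted state interval carrying the mark emits a peak in both
#' replicates with boundaries jittered by up to `chip_jitter` bp; false
#' peaks are added per replicate at rate `chip_false_rate` (Poisson), so they
#' appear in one replicate only and are removed by the consensus step.
#'
#' @param truth `sim_truth`.
#' @param mark one of H3K4me1, H3K4me3, H3K27ac, H3K27me3.
#' @param phenotype phenotype label (recorded; planted states are shared).
#' @param seed integer seed.
#' @param jitter,false_rate override the config's `chip_jitter` /
#'   `chip_false_rate`.
#' @return list of two `peaks` data.frames (replicates).
#' @export
simulate_chip_peaks <- function(truth, mark, phenotype = "Q", seed = 1L,
                                jitter = NULL, false_rate = NULL) {
  if (!mark %in% HISTONE_MARKS)
    stop("unknown mark '", mark, "' (expected one of ",
         paste(HISTONE_MARKS, collapse = ", "), ")")
  cfg <- truth$config
  if (is.null(jitter)) jitter <- cfg$chip_jitter
  if (is.null(false_rate)) false_rate <- cfg$chip_false_rate
  set.seed(seed_for(seed, paste0("chip_", mark, "_", phenotype)))
  has <- vapply(strsplit(truth$states$marks, "+", fixed = TRUE),
                function(m) mark %in% m, TRUE)
  base <- truth$states[has, , drop = FALSE]
  lapply(1:2, function(rep_i) {
    if (nrow(base)) {
      s <- base$start + if (jitter > 0) round(runif(nrow(base), -jitter, jitter)) else 0
      e <- base$end + if (jitter > 0) round(runif(nrow(base), -jitter, jitter)) else 0
      pk <- data.frame(chrom = base$chrom, start = pmax(s, 0),
                       end = pmax(e, pmax(s, 0) + 50), stringsAsFactors = FALSE)
    } else pk <- data.frame(chrom = character(), start = numeric(), end = numeric())
    n_false <- stats::rpois(1, false_rate)
    if (n_false > 0) {
      ci <- sample(names(truth$chrom_len), n_false, replace = TRUE)
      w <- round(runif(n_false, 200, 400))
      # false peaks live in the gene-free margin below coord 3000, in a
      # replicate-private zone so they never overlap across replicates
      zone_lo <- 100 + (rep_i - 1) * 1200
      s <- round(runif(n_false, zone_lo, zone_lo + 700))
      pk <- rbind(pk, data.frame(chrom = ci, start = s, end = s + w))
    }
    as_peaks(iv_sort(pk))
  })
}

#' Simulate an expression count table
#'
#' Negative-binomial counts for genes x (phenotype x replicate) samples.
#' Genes overlapping a planted NFR active in a phenotype (gene span plus the
#' 200 bp promoter window) have their mean shifted by `expression_effect`
#' log2 units in that phenotype's samples.
#'
#' @param truth `sim_truth`.
#' @param seed integer seed.
#' @param path optional output TSV (genes x samples with header).
#' @return matrix of counts with attribute `gene_has_nfr` (per-phenotype
#'   logical matrix).
#' @export
simulate_expression <- function(truth, seed = 1L, path = NULL) {
  cfg <- truth$config
  set.seed(seed_for(seed, "expression"))
  genes <- truth$annotation$genes
  if (nrow(genes) == 0L) stop("no genes in truth")
  samples <- as.vector(t(outer(cfg$phenotypes, seq_len(cfg$replicates),
                               paste0)))
  base_mu <- 2^rnorm(nrow(genes), cfg$expression_base_log2, 1.2)
  prom <- promoter_windows(truth$annotation$tss, 200, truth$chrom_len)
  span <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end)
  has_nfr <- sapply(cfg$phenotypes, function(ph) {
    act <- truth$nfrs[vapply(strsplit(truth$nfrs$phenotypes, ",", fixed = TRUE),
                             function(p) ph %in% p, TRUE), , drop = FALSE]
    iv_overlap_any(span, act) |
      genes$id %in% truth$annotation$tss$gene_id[iv_overlap_any(prom, act)]
  })
  colnames(has_nfr) <- cfg$phenotypes
  size <- 1 / cfg$dispersion
  counts <- matrix(0L, nrow(genes), length(samples),
                   dimnames = list(genes$id, samples))
  for (j in seq_along(samples)) {
    ph <- substr(samples[j], 1, 1)
    mu <- base_mu * 2^(cfg$expression_effect * has_nfr[, ph])
    counts[, j] <- stats::rnbinom(nrow(genes), mu = mu, size = size)
  }
  if (!is.null(path)) {
    out <- data.table::data.table(gene_id = rownames(counts))
    for (s in samples) out[[s]] <- counts[, s]
    data.table::fwrite(out, path, sep = "\t")
  }
  attr(counts, "gene_has_nfr") <- has_nfr
  counts
}

#' Write the ground-truth manifest
#' @param truth `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# regland truth manifest")
  wl("seed: ", truth$seed)
  tab <- function(name, df) {
    wl("[", name, "]")
    if (nrow(df)) {
      wl(paste(names(df), collapse = "\t"))
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else wl(paste(names(df), collapse = "\t"))
  }
  wl("[config]")
  writeLines(yaml::as.yaml(unclass(truth$config)), con)
  tab("nfrs", truth$nfrs)
  tab("states", truth$states)
  tab("sites", truth$sites)
  tab("edges", truth$edges)
  tab("tf_gene_map", truth$tf_gene_map)
  invisible(path)
}

#' Read a truth manifest written by [write_truth_manifest()]
#'
#' Restores the planted tables and config; genome sequence and annotation
#' are reloaded from the sibling files when `dir` contains them.
#'
#' @param path manifest path.
#' @return `sim_truth`-like list (without the genome unless found on disk).
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\[", lines)
  get_block <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    if (!length(i)) return(NULL)
    nxt <- hdr[hdr > i]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    lines[(i + 1):end]
  }
  cfgl <- get_block("config")
  config <- yaml::yaml.load(paste(cfgl, collapse = "\n"))
  # YAML serialisation drops vector names; component order is canonical
  config$frag_weights <- setNames(unlist(config$frag_weights),
                                  c("nfr", "mono", "di"))
  config$frag_means <- setNames(unlist(config$frag_means),
                                c("nfr", "mono", "di"))
  config$frag_sds <- setNames(unlist(config$frag_sds), c("nfr", "mono", "di"))
  config$phenotypes <- unlist(config$phenotypes)
  for (nm in c("nfr_width", "other_bound_frac", "state_width"))
    config[[nm]] <- unlist(config[[nm]])
  class(config) <- "sim_config"
  read_tab <- function(name) {
    b <- get_block(name)
    b <- b[nzchar(b)]
    if (length(b) <= 1)
      return(utils::read.table(text = b, header = TRUE, sep = "\t"))
    utils::read.table(text = paste(b, collapse = "\n"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  }
  seed <- as.integer(sub("^seed: *", "", lines[startsWith(lines, "seed:")][1]))
  truth <- list(config = config, seed = seed,
                nfrs = read_tab("nfrs"), states = read_tab("states"),
                sites = read_tab("sites"), edges = read_tab("edges"),
                tf_gene_map = read_tab("tf_gene_map"))
  dir <- dirname(path)
  fa <- file.path(dir, "genome.fa"); gff <- file.path(dir, "annotation.gff3")
  if (file.exists(fa)) {
    truth$genome <- read_genome(fa)
    truth$chrom_len <- setNames(Biostrings::width(truth$genome),
                                names(truth$genome))
  }
  if (file.exists(gff)) truth$annotation <- read_gff3(gff)
  mf <- file.path(dir, "motifs.jaspar")
  if (file.exists(mf)) truth$motifs <- read_jaspar_pfm(mf)
  truth$dir <- dir
  class(truth) <- "sim_truth"
  truth
}
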