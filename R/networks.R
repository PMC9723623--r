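# Directed TF-TF regulatory network: an edge A -> B exists when a bound site
# of motif A lies in the gene encoding TF B or in its promoter window, with
# the edge classed by where its supporting sites fall (TSS window vs gene
# body).

#' Build the directed TF-TF network from bound sites
#'
#' Creates an edge A -> B whenever >= 1 bound site of motif A lies within
#' gene B's span or its TSS window (default -2000..+200 bp around the TSS,
#' strand-oriented).  The edge class is `tss` when every supporting site is
#' inside the TSS window, `non_tss` when every site is elsewhere within the
#' gene, and `both` otherwise.  Self-loops are allowed and flagged.
#'
#' @param bound_calls `motif_sites` with `bound` flags (only bound sites are
#'   used); an optional `phenotype` column is aggregated into the edge's
#'   phenotype set.
#' @param annotation `genome_annotation`.
#' @param tf_gene_map data.frame with columns `motif_id`, `gene_id` mapping
#'   each TF motif to the gene encoding that TF.
#' @param tss_window length-2 numeric, bp upstream (negative) and downstream
#'   (positive) of the TSS defining the promoter window (default
#'   `c(-2000, 200)`).
#' @return data.frame of class `network_edges`: `source_tf`, `target_tf`,
#'   `target_gene`, `edge_class`, `n_supporting_sites`, `phenotypes`,
#'   `self_loop`.  Attribute `n_unmapped_sites` counts bound sites whose
#'   motif has no gene mapping.
#' @export
build_tf_network <- function(bound_calls, annotation, tf_gene_map,
                             tss_window = c(-2000, 200)) {
  stopifnot(all(c("motif_id", "gene_id") %in% names(tf_gene_map)))
  if (nrow(tf_gene_map) == 0L) stop("empty tf_gene_map")
  sites <- bound_calls[bound_calls$bound %||% TRUE, , drop = FALSE]
  if (is.null(sites$phenotype)) sites$phenotype <- NA_character_
  n_unmapped <- sum(!sites$motif_id %in% tf_gene_map$motif_id)

  tf_genes <- annotation$genes[annotation$genes$id %in% tf_gene_map$gene_id, ,
                               drop = FALSE]
  tss <- annotation$tss[match(tf_genes$id, annotation$tss$gene_id), ]
  # strand-oriented TSS window in absolute coordinates (0-based half-open)
  win_start <- ifelse(tss$strand == "+", tss$pos + tss_window[1],
                      tss$pos - tss_window[2])
  win_end <- ifelse(tss$strand == "+", tss$pos + tss_window[2] + 1,
                    tss$pos - tss_window[1] + 1)
  win <- data.frame(chrom = tss$chrom, start = pmax(win_start, 0), end = win_end)
  gene_iv <- tf_genes[, c("chrom", "start", "end")]
  # target extent = gene span union TSS window
  ext <- data.frame(chrom = gene_iv$chrom,
                    start = pmin(gene_iv$start, win$start),
                    end = pmax(gene_iv$end, win$end))

  h <- iv_overlaps(sites, ext)
  if (nrow(h) == 0L)
    return(empty_edges(n_unmapped))
  in_tss <- iv_overlaps(sites, win)
  tss_pair <- paste(in_tss$query, in_tss$subject)
  rows <- data.frame(
    source_tf = sites$motif_id[h$query],
    target_gene = tf_genes$id[h$subject],
    phenotype = sites$phenotype[h$query],
    in_tss_window = paste(h$query, h$subject) %in% tss_pair,
    stringsAsFactors = FALSE)
  # a supporting site must be in the TSS window or within the gene proper
  in_gene <- iv_overlaps(sites, gene_iv)
  gene_pair <- paste(in_gene$query, in_gene$subject)
  rows <- rows[rows$in_tss_window | paste(h$query, h$subject) %in% gene_pair, ,
               drop = FALSE]
  if (nrow(rows) == 0L) return(empty_edges(n_unmapped))
  # motifs of the target gene (paralog motifs sharing a gene collapse here)
  gene_to_tf <- vapply(split(tf_gene_map$motif_id, tf_gene_map$gene_id),
                       function(x) paste(sort(unique(x)), collapse = ","), "")
  rows$target_tf <- gene_to_tf[rows$target_gene]
  sp <- split(seq_len(nrow(rows)),
              paste(rows$source_tf, rows$target_gene, sep = "\r"))
  edges <- do.call(rbind, lapply(sp, function(i) {
    r <- rows[i, , drop = FALSE]
    cls <- if (all(r$in_tss_window)) "tss"
           else if (!any(r$in_tss_window)) "non_tss" else "both"
    ph <- sort(unique(r$phenotype[!is.na(r$phenotype)]))
    data.frame(source_tf = r$source_tf[1], target_tf = r$target_tf[1],
               target_gene = r$target_gene[1], edge_class = cls,
               n_supporting_sites = nrow(r),
               phenotypes = paste(ph, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  edges$self_loop <- mapply(function(s, t)
    s %in% strsplit(t, ",", fixed = TRUE)[[1]],
    edges$source_tf, edges$target_tf)
  edges <- edges[order(edges$source_tf, edges$target_tf), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_unmapped_sites") <- n_unmapped
  class(edges) <- c("network_edges", "data.frame")
  edges
}

empty_edges <- function(n_unmapped = 0L) {
  e <- data.frame(source_tf = character(), target_tf = character(),
                  target_gene = character(), edge_class = character(),
                  n_supporting_sites = integer(), phenotypes = character(),
                  self_loop = logical(), stringsAsFactors = FALSE)
  attr(e, "n_unmapped_sites") <- n_unmapped
  class(e) <- c("network_edges", "data.frame")
  e
}

#' Root-anchored subnetwork
#'
#' Breadth-first closure following edge direction from a root TF, with
#' deterministic ordering (by depth, then lexically).  Cycles terminate via a
#' visited set; each edge is reported once.
#'
#' @param edges `network_edges`.
#' @param root_tf root TF name (matched against source/target TF labels,
#'   including comma-joined paralog labels).
#' @param max_depth maximum BFS depth (default unlimited).
#' @return `network_edges` subset reachable from the root, with attribute
#'   `nodes` (visited node labels including the root).
#' @export
subnetwork_from_root <- function(edges, root_tf, max_depth = Inf) {
  node_has <- function(label, tf)
    tf %in% strsplit(label, ",", fixed = TRUE)[[1]] || label == tf
  all_nodes <- unique(c(edges$source_tf, edges$target_tf))
  root <- all_nodes[vapply(all_nodes, node_has, TRUE, tf = root_tf)]
  if (length(root) == 0L)
    stop("root '", root_tf, "' not in network; available TFs: ",
         paste(sort(all_nodes), collapse = ", "))
  visited <- character()
  frontier <- sort(root)
  picked <- logical(nrow(edges))
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    visited <- c(visited, frontier)
    out_e <- which(edges$source_tf %in% frontier & !picked)
    picked[out_e] <- TRUE
    nxt <- sort(setdiff(unique(edges$target_tf[out_e]), c(visited, frontier)))
    frontier <- nxt
    depth <- depth + 1
  }
  visited <- unique(c(visited, frontier))
  sub <- edges[picked, , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "nodes") <- visited
  class(sub) <- c("network_edges", "data.frame")
  sub
}

#' Export a network to TSV or DOT
#'
#' @param edges `network_edges`.
#' @param path output path.
#' @param dialect `"tsv"` (columns source, target, gene, class, n_sites,
#'   phenotypes) or `"dot"` (edges coloured by class).
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, dialect = c("tsv", "dot")) {
  dialect <- match.arg(dialect)
  e <- edges[order(edges$source_tf, edges$target_tf), , drop = FALSE]
  if (dialect == "tsv") {
    out <- data.frame(source = e$source_tf, target = e$target_tf,
                      gene = e$target_gene, class = e$edge_class,
                      n_sites = e$n_supporting_sites,
                      phenotypes = e$phenotypes, stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  } else {
    col <- c(tss = "aquamarine3", non_tss = "purple", both = "gray50")
    lines <- c("digraph tf_network {",
               sprintf("  \"%s\" -> \"%s\" [color=%s];",
                       e$source_tf, e$target_tf, col[e$edge_class]),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a network TSV written by [export_network()]
#' @param path TSV path.
#' @return `network_edges` data.frame.
#' @export
read_network <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         colClasses = list(character = "phenotypes"))
  e <- data.frame(source_tf = d$source, target_tf = d$target,
                  target_gene = d$gene, edge_class = d$class,
                  n_supporting_sites = d$n_sites,
                  phenotypes = as.character(d$phenotypes),
                  stringsAsFactors = FALSE)
  e$self_loop <- mapply(function(s, t)
    s %in% strsplit(t, ",", fixed = TRUE)[[1]], e$source_tf, e$target_tf)
  class(e) <- c("network_edges", "data.frame")
  e
}
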