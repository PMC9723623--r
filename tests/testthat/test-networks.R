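# TF-TF network construction, root subnetworks, export round-trips and the
# noiseless planted-edge recovery.

toy_net_fixture <- function() {
  # geneA (+, TSS 1000) encodes TF_B target; geneB (-, TSS 8999) second target
  ann <- tiny_annotation()
  map <- data.frame(motif_id = c("TF_A", "TF_B"),
                    gene_id = c("geneA", "geneB"), stringsAsFactors = FALSE)
  list(ann = ann, map = map)
}

test_that("edge classes follow the -2kb..+200bp promoter window rule", {
  fx <- toy_net_fixture()
  mk_call <- function(id, start, end) data.frame(
    motif_id = id, chrom = "chr1", start = start, end = end, strand = "+",
    fs = 2, bound = TRUE, phenotype = "Q", stringsAsFactors = FALSE)
  # bound site of TF_B at TSS-500 of geneA -> edge TF_B -> TF_A, class tss
  net <- build_tf_network(mk_call("TF_B", 490, 500), fx$ann, fx$map)
  expect_equal(nrow(net), 1L)
  expect_equal(net$source_tf, "TF_B")
  expect_equal(net$target_gene, "geneA")
  expect_equal(net$edge_class, "tss")
  # site in geneA's second intron ([2500,3500)), outside the window -> non_tss
  net2 <- build_tf_network(mk_call("TF_B", 3000, 3010), fx$ann, fx$map)
  expect_equal(net2$edge_class, "non_tss")
  # one site of each kind -> both
  net3 <- build_tf_network(rbind(mk_call("TF_B", 490, 500),
                                 mk_call("TF_B", 3000, 3010)), fx$ann, fx$map)
  expect_equal(net3$edge_class, "both")
  expect_equal(net3$n_supporting_sites, 2L)
  # minus-strand target: upstream window extends to higher coordinates
  net4 <- build_tf_network(mk_call("TF_A", 9500, 9510), fx$ann, fx$map)
  expect_equal(net4$target_gene, "geneB")
  expect_equal(net4$edge_class, "tss")
  # unmapped motifs are counted, not fatal; empty map errors
  net5 <- build_tf_network(mk_call("TF_X", 490, 500), fx$ann, fx$map)
  expect_equal(nrow(net5), 1L)
  expect_equal(attr(net5, "n_unmapped_sites"), 1L)
  expect_error(build_tf_network(mk_call("TF_A", 1, 10), fx$ann, fx$map[0, ]),
               "empty tf_gene_map")
})

test_that("network equals a brute-force (site x gene) double loop", {
  fx <- toy_net_fixture()
  set.seed(71)
  calls <- data.frame(motif_id = sample(c("TF_A", "TF_B"), 40, TRUE),
                      chrom = "chr1",
                      start = s <- sample(0:9900, 40), end = s + 10,
                      strand = "+", fs = 1, bound = TRUE,
                      phenotype = "Q", stringsAsFactors = FALSE)
  net <- build_tf_network(calls, fx$ann, fx$map)
  # independent brute force
  genes <- fx$ann$genes
  tssd <- fx$ann$tss
  exp_rows <- list()
  for (si in seq_len(nrow(calls))) for (gi in seq_len(nrow(genes))) {
    tp <- tssd$pos[tssd$gene_id == genes$id[gi]]
    if (genes$strand[gi] == "+") { ws <- tp - 2000; we <- tp + 201 }
    else { ws <- tp - 200; we <- tp + 2001 }
    in_win <- calls$start[si] < we && calls$end[si] > ws
    in_gene <- calls$start[si] < genes$end[gi] && calls$end[si] > genes$start[gi]
    if (in_win || in_gene)
      exp_rows[[length(exp_rows) + 1]] <- data.frame(
        src = calls$motif_id[si], gene = genes$id[gi], win = in_win)
  }
  exp_rows <- do.call(rbind, exp_rows)
  exp_edges <- do.call(rbind, lapply(
    split(exp_rows, paste(exp_rows$src, exp_rows$gene)), function(r)
      data.frame(src = r$src[1], gene = r$gene[1],
                 class = if (all(r$win)) "tss"
                         else if (!any(r$win)) "non_tss" else "both",
                 n = nrow(r))))
  exp_edges <- exp_edges[order(exp_edges$src, exp_edges$gene), ]
  expect_equal(net$source_tf, exp_edges$src)
  expect_equal(net$target_gene, exp_edges$gene)
  expect_equal(net$edge_class, exp_edges$class)
  expect_equal(net$n_supporting_sites, exp_edges$n)
})

chain_edges <- function() {
  e <- data.frame(source_tf = c("A", "B", "B", "D"),
                  target_tf = c("B", "C", "A", "E"),
                  target_gene = c("gB", "gC", "gA", "gE"),
                  edge_class = "tss", n_supporting_sites = 1L,
                  phenotypes = "Q", self_loop = FALSE,
                  stringsAsFactors = FALSE)
  class(e) <- c("network_edges", "data.frame")
  e
}

test_that("root subnetworks follow direction, terminate cycles, stay subsets", {
  e <- chain_edges()
  sub <- subnetwork_from_root(e, "A")
  expect_setequal(paste(sub$source_tf, sub$target_tf),
                  c("A B", "B C", "B A"))      # cycle A->B->A terminates
  expect_false("D E" %in% paste(sub$source_tf, sub$target_tf))
  # subset + idempotence
  sub2 <- subnetwork_from_root(sub, "A")
  expect_equal(sub[order(sub$source_tf), ], sub2[order(sub2$source_tf), ],
               ignore_attr = TRUE)
  # root with no outgoing edges
  subC <- subnetwork_from_root(e, "C")
  expect_equal(nrow(subC), 0L)
  expect_true("C" %in% attr(subC, "nodes"))
  expect_error(subnetwork_from_root(e, "Z"), "available TFs")
  # depth limit
  sub1 <- subnetwork_from_root(e, "A", max_depth = 1)
  expect_equal(paste(sub1$source_tf, sub1$target_tf), "A B")
})

test_that("network export round-trips TSV and writes valid DOT", {
  e <- chain_edges()
  f <- tempfile()
  export_network(e, f, "tsv")
  back <- read_network(f)
  expect_setequal(paste(back$source_tf, back$target_tf, back$edge_class),
                  paste(e$source_tf, e$target_tf, e$edge_class))
  fd <- tempfile()
  export_network(e, fd, "dot")
  dot <- readLines(fd)
  expect_equal(dot[1], "digraph tf_network {")
  expect_equal(dot[length(dot)], "}")
  body <- dot[-c(1, length(dot))]
  expect_true(all(grepl('^  "[^"]+" -> "[^"]+" \\[color=[a-z0-9]+\\];$', body)))
  expect_equal(length(body), nrow(e))
})

test_that("noiseless truth bound sites reproduce the planted edge set exactly", {
  tr <- default_truth()
  calls <- do.call(rbind, lapply(c("Q", "W", "D"), function(ph) {
    b <- tr$sites[tr$sites[[paste0("bound_", ph)]], , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    data.frame(motif_id = b$motif_id, chrom = b$chrom, start = b$start,
               end = b$end, strand = b$strand, bound = TRUE, phenotype = ph,
               stringsAsFactors = FALSE)
  }))
  net <- build_tf_network(calls, tr$annotation, tr$tf_gene_map)
  key <- function(d) sort(paste(d$source_tf, d$target_gene, d$edge_class,
                                d$phenotypes))
  expect_equal(key(net), key(tr$edges))
})
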