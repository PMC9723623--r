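#!/usr/bin/env Rscript
# Network stage: directed TF-TF network from the bound sites of all three
# phenotypes, with TSS (-2 kb..+200 bp) vs gene-body edge classes, and the
# subnetwork rooted at the hub TF.  Writes results/network.

source("analysis/00_common.R")
truth <- load_truth()
out <- file.path(RESULTS, "network"); dir.create(out, showWarnings = FALSE)

bound <- do.call(rbind, lapply(PHENOS, function(ph) {
  sc <- as.data.frame(data.table::fread(
    file.path(RESULTS, "footprint", paste0("sites_", ph, ".tsv"))))
  sc[sc$bound, , drop = FALSE]
}))
net <- build_tf_network(bound, truth$annotation, truth$tf_gene_map)
export_network(net, file.path(out, "tf_network.tsv"), "tsv")
export_network(net, file.path(out, "tf_network.dot"), "dot")
cat("network:", nrow(net), "edges over",
    length(unique(c(net$source_tf, net$target_tf))), "nodes; classes:",
    paste(names(table(net$edge_class)), table(net$edge_class),
          collapse = ", "), "\n")

root <- truth$motifs[[1]]$id
sub <- subnetwork_from_root(net, root)
export_network(sub, file.path(out, "subnetwork.tsv"), "tsv")
cat("subnetwork from", root, ":", nrow(sub), "edges,",
    length(attr(sub, "nodes")), "nodes\n")

# recovery against the planted edge set
key <- function(d) paste(d$source_tf, d$target_gene, d$edge_class)
cat(sprintf("planted-edge recall %.0f%%, precision %.0f%%\n",
            100 * mean(key(truth$edges) %in% key(net)),
            100 * mean(key(net) %in% key(truth$edges))))
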