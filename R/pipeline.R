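# Pipeline orchestration: a single structured config drives
# simulate -> atac -> states -> expression -> footprint -> network -> report.
# All randomness flows from one root seed through named per-stage
# substreams, so reruns with the same config are byte-identical.

pipeline_param_defaults <- function() list(
  tss_window = 200,
  network_window = c(-2000, 200),
  q_threshold = 0.05,
  peak_window = 200,
  peak_step = 50,
  flank_bp = 20,
  bias_k = 6,
  min_score_frac = 0.8,
  tau_method = "otsu",
  top_k = 10,
  root_tf = NULL
)

#' Validate a pipeline configuration
#'
#' Reads a YAML config, rejects unknown keys, enforces that exactly one of a
#' `simulate` block and an `inputs` block is present, checks referenced files
#' exist, and fills parameter defaults.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return list of class `pipeline_config` with `simulate` or `inputs`,
#'   `params`, `output_dir`, `seed`, `skip_expression`, and a
#'   `resolved` character vector echoing every resolved parameter.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  allowed <- c("simulate", "inputs", "params", "output_dir", "seed",
               "skip_expression")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_sim <- !is.null(raw$simulate)
  has_inp <- !is.null(raw$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' and 'inputs'")
  params <- pipeline_param_defaults()
  if (!is.null(raw$params)) {
    unknown <- setdiff(names(raw$params), names(params))
    if (length(unknown))
      stop("unknown params key(s): ", paste(unknown, collapse = ", "))
    params[names(raw$params)] <- raw$params
  }
  if (has_sim) {
    sim_keys <- setdiff(names(raw$simulate), c("config", "seed"))
    if (length(sim_keys))
      stop("unknown simulate key(s): ", paste(sim_keys, collapse = ", "))
    sim_cfg <- do.call(sim_config, as.list(raw$simulate$config))
  } else {
    need <- c("fragments", "chip", "gff3", "fasta", "motifs", "tf_map")
    unknown <- setdiff(names(raw$inputs), c(need, "counts"))
    if (length(unknown))
      stop("unknown inputs key(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(need, names(raw$inputs))
    if (length(missing))
      stop("inputs block missing: ", paste(missing, collapse = ", "))
    flat <- unlist(raw$inputs[c("gff3", "fasta", "motifs", "tf_map", "counts",
                                "fragments", "chip")])
    absent <- flat[!file.exists(flat)]
    if (length(absent)) stop("input file not found: ", absent[1])
    sim_cfg <- NULL
  }
  cfg <- list(
    simulate = if (has_sim) list(config = sim_cfg,
                                 seed = raw$simulate$seed %||% raw$seed %||% 1L),
    inputs = raw$inputs,
    params = params,
    output_dir = raw$output_dir %||% tempfile("regland_run"),
    seed = as.integer(raw$seed %||% raw$simulate$seed %||% 1L),
    skip_expression = isTRUE(raw$skip_expression))
  cfg$resolved <- c(
    sprintf("seed = %d", cfg$seed),
    sprintf("mode = %s", if (has_sim) "simulate" else "real inputs"),
    sprintf("%s = %s", names(params),
            vapply(params, function(p)
              paste(format(p %||% "auto"), collapse = ","), "")))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage from one validated config, writing stage outputs and
#' a machine-readable `report.json` under the output directory.  Identical
#' config + seed reruns produce byte-identical outputs.  With simulated
#' inputs the report also contains planted-truth recovery statistics.
#'
#' @param config `pipeline_config` from [validate_config()], or a path/list
#'   accepted by it.
#' @return the report, invisibly (a nested list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  seed <- config$seed
  log_lines <- c("regland pipeline run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("regland"))),
                 sprintf("seed: %d", seed), "", config$resolved)

  ## ---- stage: inputs / simulation ------------------------------------
  if (!is.null(config$simulate)) {
    truth <- generate_genome(config$simulate$config, seed,
                             dir = file.path(out, "sim"))
    cfg <- truth$config
    phenos <- cfg$phenotypes
    reps <- seq_len(cfg$replicates)
    fragments <- list()
    for (ph in phenos) for (r in reps) {
      fragments[[paste0(ph, r)]] <- simulate_fragments(
        truth, ph, r, seed = seed_for(seed, paste0("f", ph, r)),
        path = file.path(out, "sim", sprintf("fragments_%s%d.tsv", ph, r)))
    }
    chip <- list()
    for (ph in phenos) {
      chip[[ph]] <- list()
      for (mk in HISTONE_MARKS)
        chip[[ph]][[mk]] <- simulate_chip_peaks(
          truth, mk, ph, seed = seed_for(seed, paste0("c", mk, ph)))
    }
    counts <- simulate_expression(truth, seed = seed_for(seed, "expr"),
                                  path = file.path(out, "sim", "counts.tsv"))
    genome <- truth$genome
    annotation <- truth$annotation
    motifs <- truth$motifs
    tf_map <- truth$tf_gene_map
  } else {
    truth <- NULL
    inp <- config$inputs
    genome <- read_genome(inp$fasta)
    annotation <- read_gff3(inp$gff3)
    motifs <- read_jaspar_pfm(inp$motifs)
    tf_map <- as.data.frame(data.table::fread(inp$tf_map))
    phenos <- names(inp$fragments)
    fragments <- list()
    for (ph in phenos)
      for (r in seq_along(inp$fragments[[ph]]))
        fragments[[paste0(ph, r)]] <- read_fragments(inp$fragments[[ph]][[r]])
    reps <- seq_len(length(inp$fragments[[1]]))
    chip <- lapply(phenos, function(ph)
      lapply(inp$chip, function(mk) lapply(mk[[ph]], read_bed)))
    names(chip) <- phenos
    chip <- lapply(chip, function(x) lapply(x, function(r) r))
    counts <- if (!is.null(inp$counts)) {
      ct <- as.data.frame(data.table::fread(inp$counts))
      m <- as.matrix(ct[, -1]); rownames(m) <- ct[[1]]; m
    }
  }
  seqlens <- setNames(as.numeric(Biostrings::width(genome)), names(genome))
  codes <- dna_codes(genome)

  ## ---- stage: atac ----------------------------------------------------
  dir.create(file.path(out, "atac"), showWarnings = FALSE)
  nfr_peaks <- list(); frag_class <- list()
  for (ph in phenos) {
    rep_peaks <- list()
    for (r in reps) {
      fc <- classify_fragments(fragments[[paste0(ph, r)]])
      frag_class[[paste0(ph, r)]] <- fc
      rep_peaks[[r]] <- call_peaks(fc[fc$class == "nfr", ], seqlens,
                                   window = p$peak_window, step = p$peak_step,
                                   q_threshold = p$q_threshold)
    }
    nfr_peaks[[ph]] <- consensus_peaks(rep_peaks[[1]], rep_peaks[[2]])
    write_intervals(nfr_peaks[[ph]],
                    file.path(out, "atac", paste0("nfr_", ph, ".narrowPeak")),
                    "narrowPeak")
  }
  # TSS metaprofiles of NFR and mono coverage (pooled replicates)
  meta <- list()
  for (ph in phenos) {
    pooled <- do.call(rbind, lapply(reps, function(r)
      frag_class[[paste0(ph, r)]]))
    for (cl in c("nfr", "mono")) {
      tr <- coverage_track(pooled[pooled$class == cl, ], seqlens)
      meta[[paste0(ph, "_", cl)]] <- tss_metaprofile(tr, annotation)
    }
  }
  meta_df <- data.frame(position = as.integer(names(meta[[1]])),
                        lapply(meta, as.numeric), check.names = FALSE)
  data.table::fwrite(meta_df, file.path(out, "atac", "tss_metaprofile.tsv"),
                     sep = "\t")
  # differential accessibility over the union peak set, pairwise
  union_peaks <- as_peaks(iv_reduce(do.call(rbind, lapply(nfr_peaks, function(x)
    x[, c("chrom", "start", "end")]))))
  union_peaks$name <- paste0("u", seq_len(nrow(union_peaks)))
  nfr_frag_sets <- lapply(frag_class, function(fc) fc[fc$class == "nfr", ])
  cnt <- count_fragments_in_peaks(union_peaks, nfr_frag_sets)
  pairs <- if (length(phenos) >= 2)
    utils::combn(phenos, 2, simplify = FALSE) else list()
  diff_acc <- lapply(pairs, function(pr) {
    samp <- grepl(paste0("^", pr[1]), colnames(cnt)) |
      grepl(paste0("^", pr[2]), colnames(cnt))
    grp <- substr(colnames(cnt)[samp], 1, 1)
    da <- differential_accessibility(cnt[, samp, drop = FALSE], grp)
    data.table::fwrite(da, file.path(out, "atac",
                                     sprintf("diff_%s_vs_%s.tsv", pr[1], pr[2])),
                       sep = "\t")
    da
  })
  names(diff_acc) <- vapply(pairs, paste, "", collapse = "_vs_")

  ## ---- stage: chromatin states ----------------------------------------
  dir.create(file.path(out, "states"), showWarnings = FALSE)
  segments <- list(); nfr_states <- list(); fisher <- list(); enrich <- list()
  for (ph in phenos) {
    consensus <- lapply(chip[[ph]], function(rr) consensus_peaks(rr[[1]], rr[[2]]))
    segments[[ph]] <- flatten_state_segments(consensus)
    data.table::fwrite(as.data.frame(segments[[ph]]),
                       file.path(out, "states", paste0("segments_", ph, ".tsv")),
                       sep = "\t")
    enrich[[ph]] <- state_feature_enrichment(segments[[ph]], annotation)
    pk <- nfr_peaks[[ph]]
    pk$tss_class <- classify_nfr_tss(pk, annotation, p$tss_window)
    nfr_states[[ph]] <- nfr_state_overlap(pk, segments[[ph]])
    data.table::fwrite(nfr_states[[ph]],
                       file.path(out, "states", paste0("nfr_states_", ph, ".tsv")),
                       sep = "\t")
    # co-occurrence of H3K4me3 and H3K27ac across NFR summit states
    st <- nfr_states[[ph]]
    hasA <- grepl("H3K4me3", st$state, fixed = TRUE)
    hasB <- grepl("H3K27ac", st$state, fixed = TRUE)
    fisher[[ph]] <- fisher_cooccurrence(sum(st$n[hasA & hasB]),
                                        sum(st$n[hasA & !hasB]),
                                        sum(st$n[!hasA & hasB]),
                                        sum(st$n[!hasA & !hasB]))
  }

  ## ---- stage: expression ----------------------------------------------
  expr_res <- NULL
  if (!config$skip_expression && !is.null(counts)) {
    dir.create(file.path(out, "expression"), showWarnings = FALSE)
    em <- normalize_counts(counts)
    expr_res <- list()
    prom <- promoter_windows(annotation$tss, p$tss_window, seqlens)
    for (ph in phenos) {
      samp <- grep(paste0("^", ph), colnames(counts), value = TRUE)
      lg <- log(rowMeans(em$normalized[, samp, drop = FALSE]) + 1)
      gene_iv <- annotation$genes
      has <- iv_overlap_any(gene_iv, nfr_peaks[[ph]]) |
        gene_iv$id %in% annotation$tss$gene_id[iv_overlap_any(prom, nfr_peaks[[ph]])]
      test <- nfr_expression_test(lg, has)
      rho <- replicate_correlation(log(counts[, samp[1]] + 1),
                                   log(counts[, samp[2]] + 1))
      expr_res[[ph]] <- list(pct_genes_with_nfr = 100 * mean(has),
                             nfr_test = test, replicate_rho = rho)
    }
    tf_genes <- intersect(tf_map$gene_id, rownames(em$normalized))
    if (length(tf_genes) >= 1) {
      z <- row_zscore_log(em$normalized, tf_genes)
      data.table::fwrite(data.frame(gene_id = rownames(z), z,
                                    check.names = FALSE),
                         file.path(out, "expression", "tf_zscores.tsv"),
                         sep = "\t")
    }
    stats_df <- data.frame(
      phenotype = phenos,
      pct_genes_with_nfr = vapply(expr_res, `[[`, 0, "pct_genes_with_nfr"),
      nfr_p_value = vapply(expr_res, function(x) x$nfr_test$p_value, 0),
      replicate_rho = vapply(expr_res, `[[`, 0, "replicate_rho"))
    data.table::fwrite(stats_df, file.path(out, "expression", "nfr_tests.tsv"),
                       sep = "\t")
  }

  ## ---- stage: footprints ----------------------------------------------
  dir.create(file.path(out, "footprint"), showWarnings = FALSE)
  sites <- scan_motifs(genome, motifs, union_peaks,
                       min_score_frac = p$min_score_frac, codes = codes)
  fp <- list(); occupancy <- list()
  for (ph in phenos) {
    pooled <- do.call(rbind, lapply(reps, function(r) fragments[[paste0(ph, r)]]))
    track <- cut_site_track(pooled, seqlens)
    bias <- fit_bias_model(track, genome, k = p$bias_k, codes = codes)
    corrected <- correct_cuts(track, bias, genome, codes = codes)
    scored <- footprint_score(corrected, sites, flank_bp = p$flank_bp)
    scored <- call_bound(scored, method = p$tau_method)
    scored$phenotype <- ph
    fp[[ph]] <- scored
    occupancy[[ph]] <- occupancy_table(scored, nfr_peaks[[ph]], top_k = Inf)
    data.table::fwrite(occupancy[[ph]],
                       file.path(out, "footprint", paste0("occupancy_", ph, ".tsv")),
                       sep = "\t")
    data.table::fwrite(scored,
                       file.path(out, "footprint", paste0("sites_", ph, ".tsv")),
                       sep = "\t")
  }
  diff_occ <- lapply(pairs, function(pr)
    differential_occupancy(fp[[pr[1]]], fp[[pr[2]]],
                           seed = seed_for(seed, paste0("do", pr[1], pr[2]))))
  names(diff_occ) <- vapply(pairs, paste, "", collapse = "_vs_")
  for (nm in names(diff_occ))
    data.table::fwrite(diff_occ[[nm]],
                       file.path(out, "footprint", paste0("diff_occ_", nm, ".tsv")),
                       sep = "\t")

  ## ---- stage: network --------------------------------------------------
  dir.create(file.path(out, "network"), showWarnings = FALSE)
  bound_all <- do.call(rbind, lapply(fp, function(x)
    x[x$bound, , drop = FALSE]))
  net <- build_tf_network(bound_all, annotation, tf_map,
                          tss_window = p$network_window)
  export_network(net, file.path(out, "network", "tf_network.tsv"), "tsv")
  export_network(net, file.path(out, "network", "tf_network.dot"), "dot")
  root <- p$root_tf %||% (if (nrow(net)) net$source_tf[1] else NULL)
  subnet <- if (!is.null(root) && nrow(net))
    subnetwork_from_root(net, root) else NULL
  if (!is.null(subnet))
    export_network(subnet, file.path(out, "network", "subnetwork.tsv"), "tsv")

  ## ---- report -----------------------------------------------------------
  report <- list(
    seed = seed,
    phenotypes = phenos,
    atac = list(
      n_nfr_peaks = lapply(nfr_peaks, nrow),
      n_diff_significant = lapply(diff_acc, function(d) sum(d$q_value <= 0.05))),
    states = list(
      n_segments = lapply(segments, nrow),
      fisher_K4me3_K27ac = lapply(fisher, function(f)
        list(odds_ratio = f$odds_ratio, p_value = f$p_value))),
    expression = if (!is.null(expr_res)) lapply(expr_res, function(x)
      list(pct_genes_with_nfr = x$pct_genes_with_nfr,
           nfr_p_value = x$nfr_test$p_value,
           replicate_rho = x$replicate_rho)),
    footprint = list(
      n_sites = nrow(sites),
      tau = lapply(fp, function(x) attr(x, "tau")),
      top10_occupancy = lapply(occupancy, function(o) utils::head(o, p$top_k)),
      n_diff_significant = lapply(diff_occ, function(d) sum(d$q_value <= 0.05))),
    network = list(n_edges = nrow(net),
                   n_nodes = length(unique(c(net$source_tf, net$target_tf)))))

  if (!is.null(truth)) report$truth_recovery <- truth_recovery(
    truth, nfr_peaks, segments, fp, occupancy, diff_occ, net)

  files <- sort(setdiff(list.files(out, recursive = TRUE, full.names = TRUE),
                        file.path(out, c("report.json", "run_log.txt"))))
  report$checksums <- setNames(as.list(unname(tools::md5sum(files))),
                               sub(paste0("^", out, "/?"), "", files))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(report)
}

# planted-truth recovery statistics for the report
truth_recovery <- function(truth, nfr_peaks, segments, fp, occupancy,
                           diff_occ, net) {
  cfg <- truth$config
  phenos <- cfg$phenotypes
  rec <- list()
  # NFR bp recovery per phenotype
  rec$nfr_bp_recovery_pct <- lapply(phenos, function(ph) {
    act <- truth$nfrs[vapply(strsplit(truth$nfrs$phenotypes, ",", fixed = TRUE),
                             function(p) ph %in% p, TRUE), , drop = FALSE]
    100 * iv_intersect_bp(act, nfr_peaks[[ph]]) / sum(act$end - act$start)
  })
  names(rec$nfr_bp_recovery_pct) <- phenos
  # state bp labeling accuracy (marks of the recovered segment must match)
  rec$state_bp_accuracy_pct <- lapply(phenos, function(ph) {
    seg <- segments[[ph]]
    planted <- truth$states
    norm_state <- function(s) vapply(strsplit(s, "+", fixed = TRUE),
      function(z) paste(intersect(HISTONE_MARKS, z), collapse = "+"), "")
    planted$state <- norm_state(planted$marks)
    tot <- sum(planted$end - planted$start)
    ok <- sum(vapply(unique(planted$state), function(st)
      iv_intersect_bp(planted[planted$state == st, , drop = FALSE],
                      seg[seg$state == st, , drop = FALSE]), 0))
    100 * ok / tot
  })
  names(rec$state_bp_accuracy_pct) <- phenos
  # footprint ROC AUC vs planted bound truth, per phenotype
  rec$footprint_auc <- lapply(phenos, function(ph)
    footprint_auc(truth, fp[[ph]], ph))
  names(rec$footprint_auc) <- phenos
  # rank of the planted top-occupancy motif
  top_id <- truth$motifs[[1]]$id
  rec$top_motif_rank <- lapply(phenos, function(ph)
    match(top_id, occupancy[[ph]]$motif_id))
  names(rec$top_motif_rank) <- phenos
  # rank (by p) of the planted differential motifs in their comparison
  if (length(diff_occ)) {
    spec_ids <- vapply(truth$motifs[c(cfg$n_motifs, cfg$n_motifs - 1)],
                       `[[`, "", "id")
    rec$diff_motif_rank <- lapply(names(diff_occ), function(nm)
      min(match(spec_ids, diff_occ[[nm]]$motif_id), na.rm = TRUE))
    names(rec$diff_motif_rank) <- names(diff_occ)
  }
  # network edge recovery (exact source/gene/class triples)
  tr_key <- with(truth$edges, paste(source_tf, target_gene, edge_class))
  nk <- if (nrow(net)) paste(net$source_tf, net$target_gene, net$edge_class)
        else character()
  rec$network_edge_recall_pct <-
    if (length(tr_key)) 100 * mean(tr_key %in% nk) else NA
  rec$network_edge_precision_pct <-
    if (length(nk)) 100 * mean(nk %in% tr_key) else NA
  rec
}

# AUC of footprint score against planted bound truth for a phenotype;
# scanned sites not in the manifest count as unbound
footprint_auc <- function(truth, scored, phenotype) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  tk <- key(truth$sites)
  m <- match(key(scored), tk)
  lab <- !is.na(m) & truth$sites[[paste0("bound_", phenotype)]][m]
  ok <- !is.na(scored$fs)
  lab <- lab[ok]; fs <- scored$fs[ok]
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(fs)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
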