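# Shared setup for the analysis scripts: paths, seed, and lazy access to the
# simulated dataset produced by 01_simulate.R.

suppressPackageStartupMessages(library(regland))

RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
SEED <- as.integer(Sys.getenv("REGLAND_SEED", "1"))

dir.create(RESULTS, showWarnings = FALSE)

load_truth <- function() {
  mf <- file.path(DATA_DIR, "truth_manifest.txt")
  if (!file.exists(mf))
    stop("run analysis/01_simulate.R first (missing ", mf, ")")
  read_truth_manifest(mf)
}

load_fragments <- function(phenotype, replicate) {
  read_fragments(file.path(DATA_DIR,
                           sprintf("fragments_%s%d.tsv", phenotype, replicate)))
}

truth_seqlens <- function(truth)
  stats::setNames(as.numeric(Biostrings::width(truth$genome)),
                  names(truth$genome))

PHENOS <- c("Q", "W", "D")
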