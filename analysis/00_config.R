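# Shared study configuration for the analysis scripts.
# Sourced by each numbered script; everything downstream is determined
# by this one seed.

library(saltmir)

study_config <- pipeline_config(
  synthetic = synthetic_config(
    seed = 1L,
    n_known_mirnas = 60L,     # annotated miRNA loci
    n_novel_mirnas = 20L,     # hairpin-embedded ground-truth novel loci
    n_other_loci = 40L,       # piRNA/snoRNA/Rfam/other decoys
    reads_per_library = 50000L
  )
)

run_dir <- "results/run"
dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
rpath <- function(...) file.path(run_dir, ...)
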