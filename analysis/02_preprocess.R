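#!/usr/bin/env Rscript
# Clean both libraries: quality / 3' adapter / 5' contaminant / insert /
# poly-A / length rules, then collapse to unique tags, and tabulate the
# insert length distribution.

source("analysis/00_config.R")
syn <- study_config$synthetic

for (lib in c("control", "stress")) {
  reads <- read_fastq(rpath(paste0(lib, ".fastq")))
  cl <- clean_reads(reads, adapter = syn$adapter,
                    quality_floor = study_config$quality_floor,
                    min_len = study_config$min_len,
                    max_len = study_config$max_len,
                    primer5 = syn$primer5)
  write.table(cl$tags, rpath(sprintf("tags_%s.tsv", lib)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(rule = names(cl$rejections),
                         reads = as.integer(cl$rejections)),
              rpath(sprintf("rejections_%s.tsv", lib)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  d <- length_distribution(cl$tags)
  write.table(d, rpath(sprintf("lengths_%s.tsv", lib)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mode_len <- d$length[which.max(d$total_count)]
  cat(sprintf(
    "%s: %d raw -> %d clean reads (%.2f%%), %d unique tags; modal length %s nt\n",
    lib, cl$n_raw, cl$n_clean, 100 * cl$n_clean / cl$n_raw,
    nrow(cl$tags), mode_len))
  stopifnot(cl$n_clean + sum(cl$rejections) == cl$n_raw)
}
cat("Wrote tags_*.tsv, rejections_*.tsv, lengths_*.tsv\n")
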