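#!/usr/bin/env Rscript
# Differential expression between the stress and control libraries:
# TPM with the 0.001 zero-count floor, the exact two-library Poisson
# test on raw tag counts, Bonferroni and BH-FDR corrections, and
# up/down calls at FDR <= 0.001, |log2 ratio| >= 1.  Finishes by
# checking direction recovery against the simulation ground truth.

source("analysis/00_config.R")

tc <- read.delim(rpath("tags_control.tsv"))
ts <- read.delim(rpath("tags_stress.tsv"))
assigned <- read.delim(rpath("tag_categories.tsv"))

universe <- merge(tc, ts, by = "sequence", all = TRUE,
                  suffixes = c("_control", "_stress"))
universe$count_control[is.na(universe$count_control)] <- 0L
universe$count_stress[is.na(universe$count_stress)] <- 0L
universe <- universe[order(-(universe$count_control + universe$count_stress),
                           universe$sequence), ]

de <- diff_expression(universe$sequence,
                      universe$count_control, universe$count_stress,
                      sum(tc$count), sum(ts$count),
                      zero_floor = study_config$zero_floor,
                      fdr_threshold = study_config$fdr_threshold,
                      lfc_threshold = study_config$lfc_threshold)
de$locus <- assigned$best_locus[match(de$srna_id, assigned$sequence)]
write.table(de, rpath("de.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

tal <- tally_regulation(de)
cat(sprintf("Tested %d tags: %d up, %d down (%d DES total).\n",
            nrow(de), tal$n_up, tal$n_down, tal$n_total_des))

truth <- read_truth_table(rpath("truth.tsv"))
ann <- read_annotation(rpath("annotation.gff3"))
md <- S4Vectors::mcols(ann)
strong <- truth[abs(truth$true_log2_fc) >= 1 &
                  truth$true_counts_control + truth$true_counts_stress >= 50, ]
if (nrow(strong) > 0) {
  seqs <- md$sequence[match(strong$locus_id, md$locus_id)]
  calls <- de$regulation[match(seqs, de$srna_id)]
  expected <- ifelse(strong$true_log2_fc > 0, "up", "down")
  cat(sprintf("Direction recovery on %d strongly spiked loci: %.1f%%\n",
              nrow(strong), 100 * mean(calls == expected, na.rm = TRUE)))
}
cat("Wrote de.tsv\n")
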