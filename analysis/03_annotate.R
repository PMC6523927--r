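#!/usr/bin/env Rscript
# Map the clean tags to the reference (exact genomic matching, up to two
# mismatches against known miRNA loci) and resolve each tag to a single
# category under the priority rule miRNA > piRNA > snoRNA > Rfam >
# other_sRNA.

source("analysis/00_config.R")

reference <- Biostrings::readDNAStringSet(rpath("reference.fa"))
annotation <- read_annotation(rpath("annotation.gff3"))

tc <- read.delim(rpath("tags_control.tsv"))
ts <- read.delim(rpath("tags_stress.tsv"))
universe <- merge(tc, ts, by = "sequence", all = TRUE,
                  suffixes = c("_control", "_stress"))
universe$count_control[is.na(universe$count_control)] <- 0L
universe$count_stress[is.na(universe$count_stress)] <- 0L
universe$count <- universe$count_control + universe$count_stress
universe <- universe[order(-universe$count, universe$sequence), ]

m <- map_tags(universe, reference, annotation,
              max_mismatch = study_config$max_mismatch,
              mirna_max_mismatch = study_config$mirna_max_mismatch)
write.table(m$annotated, rpath("tag_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(m$alignments, rpath("tag_alignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (lib in c("control", "stress")) {
  a <- m$annotated
  a$count <- universe[[paste0("count_", lib)]][match(a$sequence,
                                                    universe$sequence)]
  clean_total <- sum(a$count)
  cs <- category_summary(a, clean_total)
  write.table(cs, rpath(sprintf("categories_%s.tsv", lib)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mapped <- sum(a$count[a$sequence %in% unique(m$alignments$tag)])
  cat(sprintf("%s: %.2f%% of clean tags genome-mapped; miRNA %.2f%%, unannotated %.2f%%\n",
              lib, 100 * mapped / clean_total,
              cs$percent[cs$category == "miRNA"],
              cs$percent[cs$category == "unannotated"]))
}
cat("Wrote tag_categories.tsv, tag_alignments.tsv, categories_*.tsv\n")
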