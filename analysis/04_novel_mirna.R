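#!/usr/bin/env Rscript
# Novel miRNA candidate detection: excise a +/-80 nt precursor window
# around every well-expressed unannotated mapped tag, fold it by
# weighted base-pair maximization, and apply the hairpin criteria.
# Also scans for siRNA-like duplexes (22-24 nt, 2-nt 3' overhangs).

source("analysis/00_config.R")

reference <- Biostrings::readDNAStringSet(rpath("reference.fa"))
assigned <- read.delim(rpath("tag_categories.tsv"))
aln <- read.delim(rpath("tag_alignments.tsv"))

una_seq <- assigned$sequence[assigned$resolved_category == "unannotated"]
a <- aln[aln$tag %in% una_seq, ]
a <- a[order(a$tag, a$mismatches, a$start), ]
a <- a[!duplicated(a$tag), ]
una <- data.frame(sequence = a$tag,
                  count = assigned$count[match(a$tag, assigned$sequence)],
                  contig = a$contig, start = a$start, end = a$end,
                  strand = a$strand)

cand <- call_novel_mirnas(una, reference,
                          window_flank = study_config$window_flank,
                          min_count = study_config$min_count,
                          thresholds = study_config$hairpin)
write.table(cand, rpath("novel_candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read_truth_table(rpath("truth.tsv"))
ann <- read_annotation(rpath("annotation.gff3"))
md <- S4Vectors::mcols(ann)
novel_truth_seqs <- md$sequence[md$sRNA_class == "novel_truth"]
called <- cand$sequence[cand$verdict]
cat(sprintf("Evaluated %d windows; %d pass the hairpin verdict.\n",
            nrow(cand), length(called)))
cat(sprintf("Ground-truth novel matures recovered: %d / %d expressed above min_count.\n",
            length(intersect(called, novel_truth_seqs)),
            length(intersect(cand$sequence, novel_truth_seqs))))

sirna <- call_sirna_pairs(data.frame(sequence = aln$tag, contig = aln$contig,
                                     start = aln$start, end = aln$end,
                                     strand = aln$strand))
write.table(sirna, rpath("sirna_pairs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("siRNA-like duplexes with 2-nt 3' overhangs: %d\n", nrow(sirna)))
cat("Wrote novel_candidates.tsv, sirna_pairs.tsv\n")
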