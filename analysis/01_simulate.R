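#!/usr/bin/env Rscript
# Simulate the two-condition sRNA-seq study: a reference contig with
# annotated and hairpin-embedded loci, and paired control/stress FASTQ
# libraries with known per-locus fold changes.

source("analysis/00_config.R")
syn <- study_config$synthetic

ref <- generate_reference(syn)
write_reference(ref, rpath("reference.fa"), rpath("annotation.gff3"))
truth <- generate_libraries(syn, ref$reference, ref$annotation,
                            rpath("control.fastq"), rpath("stress.fastq"))
write_truth_table(truth, rpath("truth.tsv"))

cls <- table(S4Vectors::mcols(ref$annotation)$sRNA_class)
cat("Simulated reference:", names(ref$reference),
    sprintf("(%d nt), %d loci\n", nchar(as.character(ref$reference[[1]])),
            length(ref$annotation)))
print(cls)
spiked <- sum(abs(truth$true_log2_fc) > 0)
cat(sprintf("Libraries: 2 x %d reads; %d loci carry a true fold change.\n",
            syn$reads_per_library, spiked))
cat("Wrote reference.fa, annotation.gff3, control/stress.fastq, truth.tsv\n")
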