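#!/usr/bin/env Rscript
# Map differentially expressed miRNAs to target transcripts by the
# penalized-complementarity rule, then test GO-term and KEGG-pathway
# over-representation of the target genes with the hypergeometric test
# and Bonferroni control (corrected p <= 0.05).

source("analysis/00_config.R")

de <- read.delim(rpath("de.tsv"))
cand <- read.delim(rpath("novel_candidates.tsv"))
assigned <- read.delim(rpath("tag_categories.tsv"))
ann <- read_annotation(rpath("annotation.gff3"))
md <- S4Vectors::mcols(ann)

mir_loci <- md$sRNA_class %in% c("miRNA", "novel_truth")
mirnas <- setNames(md$sequence[mir_loci], md$locus_id[mir_loci])
fun <- generate_functional_annotation(study_config$synthetic, mirnas)
write.table(fun$gene2go, rpath("gene2go.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fun$gene2kegg, rpath("gene2kegg.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat_of <- assigned$resolved_category[match(de$srna_id, assigned$sequence)]
des <- de[de$regulation != "ns" &
            (cat_of == "miRNA" | de$srna_id %in% cand$sequence[cand$verdict]), ]
cat(sprintf("%d differentially expressed miRNAs enter target prediction.\n",
            nrow(des)))

des_mirnas <- setNames(des$srna_id,
                       ifelse(is.na(des$locus), des$srna_id, des$locus))
targets_tab <- predict_targets(des_mirnas, fun$transcripts,
                               cutoff = study_config$target_cutoff)
write.table(targets_tab, rpath("targets.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
target_genes <- unique(targets_tab$gene_id)
background <- names(fun$transcripts)
cat(sprintf("%d target genes among %d background transcripts.\n",
            length(target_genes), length(background)))

for (mode in c("go", "kegg")) {
  map <- if (mode == "go") fun$gene2go else fun$gene2kegg
  res <- enrich(map, background, target_genes,
                alpha = study_config$enrichment_alpha)
  write.table(res, rpath(sprintf("enrichment_%s.tsv", mode)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d terms tested, %d significant at corrected p <= %.2f\n",
              toupper(mode), nrow(res), sum(res$significant),
              study_config$enrichment_alpha))
}
cat("Wrote targets.tsv, enrichment_go.tsv, enrichment_kegg.tsv\n")
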