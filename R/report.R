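#' Tally regulation calls
#'
#' @param regulation Character vector of calls (`up` / `down` / `ns`),
#'   or a data.frame with a `regulation` column.
#' @return Named list `n_up`, `n_down`, `n_total_des`
#'   (`n_up + n_down`; `ns` calls are excluded).
#' @export
tally_regulation <- function(regulation) {
  if (is.data.frame(regulation)) regulation <- regulation$regulation
  n_up <- sum(regulation == "up")
  n_down <- sum(regulation == "down")
  list(n_up = n_up, n_down = n_down, n_total_des = n_up + n_down)
}

#' Full pipeline configuration
#'
#' Bundles the synthetic-study design with every stage threshold.  All
#' randomness in a pipeline run flows from the single seed inside
#' `synthetic`.
#'
#' @param synthetic A [synthetic_config()].
#' @param quality_floor Minimum mean Phred score (cleaning).
#' @param min_len,max_len Retained insert length window.
#' @param max_mismatch Genomic mapping mismatches (default 0).
#' @param mirna_max_mismatch Mismatches tolerated for miRNA-locus hits
#'   (default 2).
#' @param window_flank,min_count,hairpin Novel-miRNA stage parameters
#'   (see [call_novel_mirnas()], [hairpin_thresholds()]).
#' @param zero_floor,fdr_threshold,lfc_threshold Differential-expression
#'   parameters.
#' @param target_cutoff Target-prediction penalty cutoff.
#' @param enrichment_alpha Corrected-p threshold for enrichment.
#' @return List of class `saltmir_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            quality_floor = 20,
                            min_len = 18L, max_len = 28L,
                            max_mismatch = 0L, mirna_max_mismatch = 2L,
                            window_flank = 80L, min_count = 5L,
                            hairpin = hairpin_thresholds(),
                            zero_floor = 0.001,
                            fdr_threshold = 0.001, lfc_threshold = 1,
                            target_cutoff = 4,
                            enrichment_alpha = 0.05) {
  cfg <- list(synthetic = synthetic, quality_floor = quality_floor,
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              max_mismatch = as.integer(max_mismatch),
              mirna_max_mismatch = as.integer(mirna_max_mismatch),
              window_flank = as.integer(window_flank),
              min_count = as.integer(min_count),
              hairpin = hairpin, zero_floor = zero_floor,
              fdr_threshold = fdr_threshold,
              lfc_threshold = lfc_threshold,
              target_cutoff = target_cutoff,
              enrichment_alpha = enrichment_alpha)
  class(cfg) <- "saltmir_pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return The path (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  # named vectors must serialize as YAML maps, not sequences
  x$synthetic$insert_length_weights <-
    as.list(x$synthetic$insert_length_weights)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- x$synthetic
  syn$insert_length_weights <- unlist(syn$insert_length_weights)
  synthetic <- do.call(synthetic_config, syn)
  x$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = synthetic), x))
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s stage failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic two-condition pipeline
#'
#' Stages, in order: simulate, preprocess (clean), annotate, novel-miRNA
#' calling, differential expression, enrichment, report.  All outputs
#' are TSV/FASTA/FASTQ/JSON files under `out_dir`; re-running with the
#' same configuration reproduces them byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage timings to stderr.
#' @return Invisibly, a list with the main in-memory results
#'   (`truth`, `summary`, `categories`, `novel`, `de`, `enrichment_go`,
#'   `enrichment_kegg`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "saltmir_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  syn <- config$synthetic

  say("[simulate] generating reference and libraries")
  ref <- .stage("simulate", {
    ref <- generate_reference(syn)
    write_reference(ref, p("reference.fa"), p("annotation.gff3"))
    truth <- generate_libraries(syn, ref$reference, ref$annotation,
                                p("control.fastq"), p("stress.fastq"))
    write_truth_table(truth, p("truth.tsv"))
    c(ref, list(truth = truth))
  })

  say("[preprocess] cleaning and collapsing reads")
  clean <- .stage("preprocess", {
    lapply(c(control = "control.fastq", stress = "stress.fastq"),
           function(f) {
             reads <- read_fastq(p(f))
             clean_reads(reads, adapter = syn$adapter,
                         quality_floor = config$quality_floor,
                         min_len = config$min_len, max_len = config$max_len,
                         primer5 = syn$primer5)
           })
  })
  for (lib in names(clean))
    .write_tsv(clean[[lib]]$tags, p(sprintf("tags_%s.tsv", lib)))
  lengths_tab <- do.call(rbind, lapply(names(clean), function(lib) {
    cbind(library = lib, length_distribution(clean[[lib]]$tags))
  }))
  .write_tsv(lengths_tab, p("lengths.tsv"))

  # combined tag universe with per-library counts
  universe <- merge(clean$control$tags, clean$stress$tags,
                    by = "sequence", all = TRUE,
                    suffixes = c("_control", "_stress"))
  universe$count_control[is.na(universe$count_control)] <- 0L
  universe$count_stress[is.na(universe$count_stress)] <- 0L
  universe$count <- universe$count_control + universe$count_stress
  universe <- universe[order(-universe$count, universe$sequence), ]

  say("[annotate] mapping %d unique tags", nrow(universe))
  ann <- .stage("annotate", {
    map_tags(universe, ref$reference, ref$annotation,
             max_mismatch = config$max_mismatch,
             mirna_max_mismatch = config$mirna_max_mismatch)
  })
  assigned <- ann$annotated
  .write_tsv(assigned, p("tag_categories.tsv"))

  cats <- do.call(rbind, lapply(c("control", "stress"), function(lib) {
    a <- assigned
    a$count <- universe[[paste0("count_", lib)]][
      match(a$sequence, universe$sequence)]
    cbind(library = lib, category_summary(a, clean[[lib]]$n_clean))
  }))
  .write_tsv(cats, p("categories.tsv"))

  mapped <- vapply(c("control", "stress"), function(lib) {
    tags <- clean[[lib]]$tags
    mapped_seqs <- unique(ann$alignments$tag)
    sum(tags$count[tags$sequence %in% mapped_seqs])
  }, 0)
  summary_tab <- cbind(
    library = c("control", "stress"),
    summarize_library(raw_n = vapply(clean, `[[`, 0L, "n_raw"),
                      clean_n = vapply(clean, `[[`, 0L, "n_clean"),
                      mapped_n = mapped))
  .write_tsv(summary_tab, p("summary.tsv"))

  say("[novel] folding precursor windows")
  novel <- .stage("novel", {
    una_seq <- assigned$sequence[assigned$resolved_category == "unannotated"]
    aln <- ann$alignments[ann$alignments$tag %in% una_seq, , drop = FALSE]
    aln <- aln[order(aln$tag, aln$mismatches, aln$contig, aln$start), ]
    aln <- aln[!duplicated(aln$tag), , drop = FALSE]   # best alignment per tag
    una <- data.frame(sequence = aln$tag,
                      count = universe$count[match(aln$tag, universe$sequence)],
                      contig = aln$contig, start = aln$start, end = aln$end,
                      strand = aln$strand, stringsAsFactors = FALSE)
    list(candidates = call_novel_mirnas(una, ref$reference,
                                        window_flank = config$window_flank,
                                        min_count = config$min_count,
                                        thresholds = config$hairpin),
         sirna = call_sirna_pairs(
           data.frame(sequence = ann$alignments$tag,
                      contig = ann$alignments$contig,
                      start = ann$alignments$start,
                      end = ann$alignments$end,
                      strand = ann$alignments$strand,
                      stringsAsFactors = FALSE)),
         pirna = predict_pirnas(universe))
  })
  .write_tsv(novel$candidates, p("novel_candidates.tsv"))
  .write_tsv(novel$sirna, p("sirna_pairs.tsv"))
  if (nrow(novel$candidates) > 0) {
    prec <- Biostrings::DNAStringSet(novel$candidates$window_seq)
    names(prec) <- sprintf("candidate%d_%s", seq_len(nrow(novel$candidates)),
                           ifelse(novel$candidates$verdict, "hairpin", "no"))
    Biostrings::writeXStringSet(prec, p("novel_precursors.fa"))
    writeLines(paste(names(prec), novel$candidates$fold, sep = "\t"),
               p("novel_precursors_fold.tsv"))
  }

  say("[de] testing %d tags", nrow(universe))
  de <- .stage("de", {
    d <- diff_expression(universe$sequence,
                         universe$count_control, universe$count_stress,
                         clean$control$n_clean, clean$stress$n_clean,
                         zero_floor = config$zero_floor,
                         fdr_threshold = config$fdr_threshold,
                         lfc_threshold = config$lfc_threshold)
    d$resolved_category <- assigned$resolved_category[
      match(d$srna_id, assigned$sequence)]
    d$locus <- assigned$best_locus[match(d$srna_id, assigned$sequence)]
    d
  })
  .write_tsv(de, p("de.tsv"))

  say("[enrich] target prediction and GO/KEGG enrichment")
  enr <- .stage("enrich", {
    amd <- S4Vectors::mcols(ref$annotation)
    mir_loci <- amd$sRNA_class %in% c("miRNA", "novel_truth")
    mirnas <- setNames(amd$sequence[mir_loci], amd$locus_id[mir_loci])
    fun <- generate_functional_annotation(syn, mirnas)
    novel_seqs <- novel$candidates$sequence[novel$candidates$verdict]
    des <- de[de$regulation != "ns" &
                (de$resolved_category == "miRNA" |
                   de$srna_id %in% novel_seqs), , drop = FALSE]
    des_mirnas <- setNames(des$srna_id, ifelse(is.na(des$locus),
                                               des$srna_id, des$locus))
    background <- names(fun$transcripts)
    if (length(des_mirnas) > 0) {
      targets_tab <- predict_targets(des_mirnas, fun$transcripts,
                                     cutoff = config$target_cutoff)
      target_genes <- unique(targets_tab$gene_id)
    } else {
      targets_tab <- predict_targets(c(none = "ACGTACGTACGTACGTACGTA"),
                                     fun$transcripts,
                                     cutoff = -1)
      target_genes <- character(0)
    }
    go <- if (length(target_genes))
      enrich(fun$gene2go, background, target_genes,
             alpha = config$enrichment_alpha) else NULL
    kegg <- if (length(target_genes))
      enrich(fun$gene2kegg, background, target_genes,
             alpha = config$enrichment_alpha) else NULL
    list(targets = targets_tab, go = go, kegg = kegg)
  })
  .write_tsv(enr$targets, p("targets.tsv"))
  if (!is.null(enr$go)) .write_tsv(enr$go, p("enrichment_go.tsv"))
  if (!is.null(enr$kegg)) .write_tsv(enr$kegg, p("enrichment_kegg.tsv"))

  say("[report] writing manifest")
  manifest <- .stage("report", {
    outputs <- list.files(out_dir, full.names = FALSE)
    outputs <- setdiff(outputs, "manifest.json")
    hashes <- tools::md5sum(file.path(out_dir, outputs))
    tal <- tally_regulation(de)
    m <- list(
      package = "saltmir",
      version = as.character(utils::packageVersion("saltmir")),
      seed = syn$seed,
      thresholds = list(quality_floor = config$quality_floor,
                        min_len = config$min_len, max_len = config$max_len,
                        max_mismatch = config$max_mismatch,
                        mirna_max_mismatch = config$mirna_max_mismatch,
                        window_flank = config$window_flank,
                        min_count = config$min_count,
                        hairpin = config$hairpin,
                        zero_floor = config$zero_floor,
                        fdr_threshold = config$fdr_threshold,
                        lfc_threshold = config$lfc_threshold,
                        target_cutoff = config$target_cutoff,
                        enrichment_alpha = config$enrichment_alpha),
      regulation = tal,
      stages = c("simulate", "preprocess", "annotate", "novel", "de",
                 "enrich", "report"),
      outputs = as.list(setNames(unname(hashes), outputs)))
    jsonlite::write_json(m, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    m
  })
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(truth = ref$truth, summary = summary_tab, categories = cats,
                 novel = novel, de = de,
                 enrichment_go = enr$go, enrichment_kegg = enr$kegg,
                 manifest = manifest))
}
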