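#' Configuration for the synthetic sRNA-seq study
#'
#' Defines a two-condition (control vs. salt stress) single-end 50 nt
#' sequencing experiment at desk scale.  The generator emulates the
#' statistical structure of plant leaf sRNA libraries: insert lengths of
#' 17--34 nt dominated by the 21 nt and 24 nt species, a fixed 3' adapter
#' appended to every genuine insert, a junk fraction exercising each
#' cleaning rule, loci of known categories plus novel miRNA loci embedded
#' in genomic hairpins, and per-locus Poisson counts whose stress mean is
#' the control mean times a per-locus fold change.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_known_mirnas Number of annotated miRNA loci.
#' @param n_novel_mirnas Number of unannotated loci embedded in hairpins
#'   (the ground-truth novel miRNAs).
#' @param n_other_loci Number of decoy loci split across the piRNA,
#'   snoRNA, Rfam and other_sRNA categories.
#' @param reads_per_library Target reads per library (before Poisson
#'   variation in locus counts).
#' @param adapter 3' adapter sequence appended to inserts.
#' @param primer5 5' primer sequence; used only to synthesize
#'   5'-contaminant junk reads.
#' @param insert_length_weights Named numeric vector over lengths 17--34
#'   giving the insert-length distribution of background reads; must sum
#'   to 1 within 1e-9.  The default is bimodal with modes at 21 and 24 nt.
#' @param base_expression Per-locus mean control count.  Either a single
#'   number, a vector of length `n_known_mirnas + n_novel_mirnas +
#'   n_other_loci`, or `NULL` to draw means log-uniformly from
#'   `base_expression_range`.
#' @param base_expression_range Range for drawn control means.
#' @param fold_changes Per-locus multiplicative stress/control factor
#'   (strictly positive).  Single number, full-length vector, or `NULL`
#'   to spike a fraction `de_fraction` of miRNA loci with log2 fold
#'   changes uniform on `[-3, -1] U [1, 3]` and leave the rest at 1.
#' @param de_fraction Fraction of miRNA loci spiked when `fold_changes`
#'   is `NULL`.
#' @param junk_fraction Fraction of reads drawn from the junk classes
#'   (no adapter, poly-A insert, short insert, 5' contaminant, low
#'   quality).
#' @param n_background_species Number of distinct random background
#'   insert sequences (unannotated, largely unmappable tags).
#' @param noise Count noise model; only `"poisson"` is supported.
#' @return A list of class `saltmir_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_known_mirnas = 60L,
                             n_novel_mirnas = 20L,
                             n_other_loci = 40L,
                             reads_per_library = 50000L,
                             adapter = "AGATCGGAAGAGCACACGTCT",
                             primer5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             insert_length_weights = default_length_weights(),
                             base_expression = NULL,
                             base_expression_range = c(20, 500),
                             fold_changes = NULL,
                             de_fraction = 0.3,
                             junk_fraction = 0.08,
                             n_background_species = 400L,
                             noise = "poisson") {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!identical(noise, "poisson"))
    stop("only 'poisson' count noise is supported")
  if (abs(sum(insert_length_weights) - 1) > 1e-9)
    stop("insert_length_weights must sum to 1 within 1e-9")
  if (is.null(names(insert_length_weights)))
    stop("insert_length_weights must be named by insert length")
  if (!is.null(fold_changes) && any(fold_changes <= 0))
    stop("fold_changes must be strictly positive")
  if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
  cfg <- list(seed = as.integer(seed),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_other_loci = as.integer(n_other_loci),
              reads_per_library = as.integer(reads_per_library),
              adapter = adapter,
              primer5 = primer5,
              insert_length_weights = insert_length_weights,
              base_expression = base_expression,
              base_expression_range = base_expression_range,
              fold_changes = fold_changes,
              de_fraction = de_fraction,
              junk_fraction = junk_fraction,
              n_background_species = as.integer(n_background_species),
              noise = noise)
  class(cfg) <- "saltmir_config"
  cfg
}

#' Default insert-length distribution (17--34 nt, modes at 21 and 24)
#' @return Named numeric vector summing to 1.
#' @export
default_length_weights <- function() {
  len <- 17:34
  w <- 0.35 * exp(-(len - 21)^2 / 2) + 0.45 * exp(-(len - 24)^2 / 2) +
    0.02
  w <- w / sum(w)
  names(w) <- as.character(len)
  w
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate the synthetic reference and locus annotation
#'
#' Builds a single contig containing, in shuffled order and separated by
#' random spacers: known miRNA loci, decoy loci (piRNA / snoRNA / Rfam /
#' other_sRNA), and novel miRNA loci.  Each novel locus is embedded so
#' that the 80 nt flank downstream of the mature is the reverse
#' complement of (part of the upstream flank + the mature), guaranteeing
#' that excising the mature +/- 80 nt and folding it recovers a hairpin
#' with the mature fully paired on one arm.  Per-locus control means and
#' fold changes are drawn here (seed-determined) and stored as annotation
#' metadata.
#'
#' @param config A [synthetic_config()].
#' @return A list with `reference` (a [Biostrings::DNAStringSet] of one
#'   contig) and `annotation` (a [GenomicRanges::GRanges] with metadata
#'   columns `locus_id`, `sRNA_class`, `sequence`, `base_mean`, `fold`).
#'   Novel ground-truth loci carry class `novel_truth` and are excluded
#'   from the known-annotation set fed to the annotation stage.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "saltmir_config"))
  set.seed(config$seed)
  n_known <- config$n_known_mirnas
  n_novel <- config$n_novel_mirnas
  n_other <- config$n_other_loci
  n_loci <- n_known + n_novel + n_other

  mirna_lengths <- c(20L, 21L, 22L, 24L)
  mirna_wts <- c(0.15, 0.45, 0.2, 0.2)

  loci <- data.frame(
    locus_id = character(0), class = character(0), sequence = character(0),
    stringsAsFactors = FALSE)
  if (n_known > 0) {
    len <- sample(mirna_lengths, n_known, replace = TRUE, prob = mirna_wts)
    loci <- rbind(loci, data.frame(
      locus_id = sprintf("known_mir%d", seq_len(n_known)),
      class = "miRNA",
      sequence = vapply(len, .rand_dna, ""),
      stringsAsFactors = FALSE))
  }
  if (n_other > 0) {
    decoy_classes <- rep(c("piRNA", "snoRNA", "Rfam", "other_sRNA"),
                         length.out = n_other)
    len <- sample(18:28, n_other, replace = TRUE)
    loci <- rbind(loci, data.frame(
      locus_id = sprintf("decoy%d", seq_len(n_other)),
      class = decoy_classes,
      sequence = vapply(len, .rand_dna, ""),
      stringsAsFactors = FALSE))
  }
  if (n_novel > 0) {
    len <- sample(mirna_lengths, n_novel, replace = TRUE, prob = mirna_wts)
    loci <- rbind(loci, data.frame(
      locus_id = sprintf("novel_mir%d", seq_len(n_novel)),
      class = "novel_truth",
      sequence = vapply(len, .rand_dna, ""),
      stringsAsFactors = FALSE))
  }

  # per-locus expression parameters
  base <- config$base_expression
  if (is.null(base)) {
    r <- config$base_expression_range
    base <- exp(runif(n_loci, log(r[1]), log(r[2])))
  } else {
    base <- rep_len(base, n_loci)
  }
  fold <- config$fold_changes
  if (is.null(fold)) {
    fold <- rep(1, n_loci)
    is_mirna <- loci$class %in% c("miRNA", "novel_truth")
    spike <- which(is_mirna & runif(n_loci) < config$de_fraction)
    if (length(spike)) {
      lfc <- runif(length(spike), 1, 3) * sample(c(-1, 1), length(spike),
                                                 replace = TRUE)
      fold[spike] <- 2^lfc
    }
  } else {
    fold <- rep_len(fold, n_loci)
  }

  # assemble the contig: spacer, locus segment, spacer, ...
  ord <- sample.int(n_loci)
  parts <- character(0)
  pos <- 0L
  start <- integer(n_loci); end <- integer(n_loci)
  for (i in ord) {
    spacer <- .rand_dna(sample(60:120, 1))
    if (loci$class[i] == "novel_truth") {
      mat <- loci$sequence[i]
      upstream <- .rand_dna(80)
      loop <- .rand_dna(8)
      arm3 <- .revcomp_chr(paste0(substr(upstream, 30, 80), mat))
      seg_pre <- paste0(spacer, upstream)
      start[i] <- pos + nchar(seg_pre) + 1L
      end[i] <- start[i] + nchar(mat) - 1L
      seg <- paste0(seg_pre, mat, loop, arm3)
    } else {
      seg_pre <- spacer
      start[i] <- pos + nchar(seg_pre) + 1L
      end[i] <- start[i] + nchar(loci$sequence[i]) - 1L
      seg <- paste0(seg_pre, loci$sequence[i])
    }
    parts <- c(parts, seg)
    pos <- pos + nchar(seg)
  }
  parts <- c(parts, .rand_dna(100))
  contig <- paste(parts, collapse = "")

  reference <- Biostrings::DNAStringSet(contig)
  names(reference) <- "synth_contig_1"
  if (n_loci > 0 && max(end) > nchar(contig))
    stop("total locus length exceeds contig length")

  annotation <- GenomicRanges::GRanges(
    seqnames = rep("synth_contig_1", n_loci),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = rep("+", n_loci),
    locus_id = loci$locus_id,
    sRNA_class = loci$class,
    sequence = loci$sequence,
    base_mean = base,
    fold = fold)
  annotation <- annotation[order(GenomicRanges::start(annotation))]
  list(reference = reference, annotation = annotation)
}

#' Write reference FASTA and annotation GFF3
#'
#' @param ref Output of [generate_reference()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(ref$reference, fasta_path)
  gr <- ref$annotation
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta_path, gff3_path))
}

#' Read an annotation GFF3 written by [write_reference()]
#' @param path GFF3 path.
#' @return A `GRanges` with the generator's metadata columns.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  for (col in c("base_mean", "fold"))
    if (col %in% names(md)) md[[col]] <- as.numeric(md[[col]])
  S4Vectors::mcols(gr) <- md
  gr
}

.junk_classes <- c("no_adapter", "poly_a", "short_insert",
                   "primer5_contaminant", "low_quality")

#' Generate paired control/stress FASTQ libraries and the truth table
#'
#' Per-locus read counts are drawn Poisson(base_mean) in the control
#' library and Poisson(base_mean * fold) in the stress library.  Each
#' genuine read is the locus (or background) insert with the 3' adapter
#' appended, truncated to 50 nt, at constant quality "I" (Phred 40).
#' A junk fraction of reads is injected in equal parts from five classes
#' that exercise the cleaning rules: no adapter, poly-A insert, insert
#' shorter than 18 nt, 5'-primer contaminant, and low base quality.
#'
#' @param config A [synthetic_config()].
#' @param reference,annotation From [generate_reference()].
#' @param fastq_control,fastq_stress Output FASTQ paths (uncompressed).
#' @return Invisibly, the truth table: a data.frame with columns
#'   `locus_id`, `category` (known_mirna / novel_mirna / rfam / snoRNA /
#'   piRNA / other), `true_counts_control`, `true_counts_stress`,
#'   `true_log2_fc`.
#' @export
generate_libraries <- function(config, reference, annotation,
                               fastq_control, fastq_stress) {
  stopifnot(inherits(config, "saltmir_config"))
  md <- S4Vectors::mcols(annotation)
  need <- c("locus_id", "sRNA_class", "sequence", "base_mean", "fold")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("annotation is missing metadata: ", paste(miss, collapse = ", "))
  bad <- which(is.na(md$base_mean) | is.na(md$fold) |
                 is.na(md$sequence) | md$sequence == "")
  if (length(bad))
    stop("locus without generator metadata: ", md$locus_id[bad[1]])

  set.seed(config$seed + 1L)
  n_loci <- length(annotation)

  counts_c <- rpois(n_loci, md$base_mean)
  counts_s <- rpois(n_loci, md$base_mean * md$fold)

  truth_cat <- c(miRNA = "known_mirna", novel_truth = "novel_mirna",
                 Rfam = "rfam", snoRNA = "snoRNA", piRNA = "piRNA",
                 other_sRNA = "other")[md$sRNA_class]
  truth <- data.frame(locus_id = md$locus_id,
                      category = unname(truth_cat),
                      true_counts_control = counts_c,
                      true_counts_stress = counts_s,
                      true_log2_fc = log2(md$fold),
                      stringsAsFactors = FALSE)

  # shared background species pool (same sequences in both libraries)
  lens <- as.integer(names(config$insert_length_weights))
  bg_len <- sample(lens, config$n_background_species, replace = TRUE,
                   prob = config$insert_length_weights)
  bg_seq <- vapply(bg_len, .rand_dna, "")
  bg_wt <- rexp(config$n_background_species) + 0.1
  bg_wt <- bg_wt / sum(bg_wt)

  write_lib <- function(locus_counts, path, subseed) {
    set.seed(config$seed + subseed)
    n_locus_reads <- sum(locus_counts)
    n_junk <- rbinom(1, config$reads_per_library, config$junk_fraction)
    n_bg <- max(0L, config$reads_per_library - n_junk - n_locus_reads)

    inserts <- rep(md$sequence, locus_counts)
    if (n_bg > 0) {
      idx <- sample.int(length(bg_seq), n_bg, replace = TRUE, prob = bg_wt)
      inserts <- c(inserts, bg_seq[idx])
    }
    reads <- substr(paste0(inserts, config$adapter), 1L, 50L)
    qual <- strrep("I", nchar(reads))

    if (n_junk > 0) {
      jc <- sample(.junk_classes, n_junk, replace = TRUE)
      jr <- character(n_junk); jq <- character(n_junk)
      for (k in seq_len(n_junk)) {
        jr[k] <- switch(jc[k],
          no_adapter = .rand_dna(50),
          poly_a = substr(paste0(strrep("A", sample(19:24, 1)),
                                 config$adapter), 1, 50),
          short_insert = substr(paste0(.rand_dna(sample(5:17, 1)),
                                       config$adapter), 1, 50),
          primer5_contaminant = substr(
            paste0(substr(config$primer5, 1, 10), .rand_dna(21),
                   config$adapter), 1, 50),
          low_quality = substr(paste0(.rand_dna(21), config$adapter), 1, 50))
        jq[k] <- strrep(if (jc[k] == "low_quality") "#" else "I",
                        nchar(jr[k]))
      }
      reads <- c(reads, jr)
      qual <- c(qual, jq)
    }
    ord <- sample.int(length(reads))
    reads <- reads[ord]; qual <- qual[ord]
    ids <- sprintf("read_%07d", seq_along(reads))
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- ids
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
    invisible(NULL)
  }

  write_lib(counts_c, fastq_control, subseed = 2L)
  write_lib(counts_s, fastq_stress, subseed = 3L)
  invisible(truth)
}

#' Write / read the ground-truth table
#' @param truth Truth data.frame from [generate_libraries()].
#' @param path TSV path.
#' @return `write_truth_table` the path invisibly; `read_truth_table`
#'   the data.frame.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Synthetic transcripts and GO/KEGG annotation maps
#'
#' Creates a transcriptome in which each miRNA locus has one target
#' transcript embedding the reverse complement of its mature sequence
#' (possibly with up to one substitution), plus decoy transcripts, and
#' random flat gene-to-GO-term and gene-to-KEGG-pathway maps over that
#' gene universe.  This provides the plumbing needed to exercise target
#' prediction and enrichment end to end; it does not model real GO/KEGG
#' structure.
#'
#' @param config A [synthetic_config()].
#' @param mirna_sequences Named character vector of mature miRNA
#'   sequences (names become part of target gene ids).
#' @param n_decoy_genes Number of transcripts without an embedded site.
#' @param n_go_terms,n_kegg_pathways Number of annotation terms.
#' @return List with `transcripts` (named character), `gene2go` and
#'   `gene2kegg` (data.frames: gene_id, term_id, term_name, namespace).
#' @export
generate_functional_annotation <- function(config, mirna_sequences,
                                           n_decoy_genes = 120L,
                                           n_go_terms = 30L,
                                           n_kegg_pathways = 15L) {
  set.seed(config$seed + 7L)
  n_t <- length(mirna_sequences)
  target_genes <- sprintf("gene_t%03d", seq_len(n_t))
  tx_target <- vapply(seq_len(n_t), function(i) {
    site <- .revcomp_chr(mirna_sequences[[i]])
    if (runif(1) < 0.3) {   # one substitution outside the seed-facing end
      p <- sample(seq_len(max(1, nchar(site) - 13)), 1)
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(site, p, p)), 1)
    }
    paste0(.rand_dna(40), site, .rand_dna(40))
  }, "")
  decoy_genes <- sprintf("gene_d%03d", seq_len(n_decoy_genes))
  tx_decoy <- vapply(rep(100L, n_decoy_genes), .rand_dna, "")
  transcripts <- c(setNames(tx_target, target_genes),
                   setNames(tx_decoy, decoy_genes))
  genes <- names(transcripts)

  flat_map <- function(prefix, n_terms, namespaces) {
    term_id <- sprintf("%s%04d", prefix, seq_len(n_terms))
    ns <- sample(namespaces, n_terms, replace = TRUE)
    rows <- lapply(seq_len(n_terms), function(j) {
      members <- sample(genes, sample(3:25, 1))
      data.frame(gene_id = members, term_id = term_id[j],
                 term_name = paste0("term_", term_id[j]),
                 namespace = ns[j], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  list(transcripts = transcripts,
       gene2go = flat_map("GO:", n_go_terms,
                          c("biological_process", "molecular_function",
                            "cellular_component")),
       gene2kegg = flat_map("ko", n_kegg_pathways,
                            c("Metabolism", "Genetic Information Processing",
                              "Environmental Information Processing")))
}
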