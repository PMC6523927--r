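#' Map tags to the reference and annotated sRNA loci
#'
#' Substitution-only matching: a tag aligns at a genomic position iff it
#' matches the reference there (either strand) with at most
#' `max_mismatch` substitutions and no indels.  A tag hits a locus iff
#' one of its alignments lies entirely within the locus span.  The
#' mapped-tag total counts tags (weighted by their counts) with at least
#' one perfect (0-mismatch) genomic alignment anywhere.
#'
#' @param tags data.frame with `sequence` and `count` columns.
#' @param reference A [Biostrings::DNAStringSet].
#' @param annotation A `GRanges` with `locus_id` and `sRNA_class`
#'   metadata columns (only loci with a category among
#'   [srna_categories()] participate in category resolution; others are
#'   ignored here).
#' @param max_mismatch Maximum substitutions, one of 0, 1, 2.
#' @param mirna_max_mismatch Maximum substitutions accepted for hits to
#'   miRNA loci (defaults to `max_mismatch`); known-miRNA identification
#'   conventionally tolerates up to two mismatches while genomic mapping
#'   of the remaining categories is exact.
#' @return A list:
#'   \describe{
#'     \item{alignments}{data.frame of all genomic alignments with at
#'       most `max_mismatch` substitutions: `tag`, `contig`, `start`,
#'       `end`, `strand`, `mismatches`.}
#'     \item{hits}{data.frame of within-locus hits: `tag`, `locus_id`,
#'       `category`, `mismatches`.}
#'     \item{annotated}{data.frame per tag: `sequence`, `count`,
#'       `resolved_category`, `best_locus`, `best_mismatches`; the
#'       resolved category follows the priority rule, `"unannotated"`
#'       when a tag hits no locus.}
#'     \item{mapped_total}{count-weighted number of tags with at least
#'       one genomic alignment at `max_mismatch`.}
#'   }
#' @export
map_tags <- function(tags, reference, annotation, max_mismatch = 0L,
                     mirna_max_mismatch = max_mismatch) {
  stopifnot(max_mismatch %in% 0:2, mirna_max_mismatch %in% 0:2)
  k <- max(max_mismatch, mirna_max_mismatch)
  aln <- .align_tags(tags$sequence, reference, k)

  known <- annotation[S4Vectors::mcols(annotation)$sRNA_class %in%
                        .srna_categories]
  hits <- data.frame(tag = character(0), locus_id = character(0),
                     category = character(0), mismatches = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(aln) > 0 && length(known) > 0) {
    agr <- GenomicRanges::GRanges(aln$contig,
                                  IRanges::IRanges(aln$start, aln$end))
    ov <- GenomicRanges::findOverlaps(agr, known, type = "within",
                                      ignore.strand = TRUE)
    if (length(ov) > 0) {
      kmd <- S4Vectors::mcols(known)
      hits <- data.frame(
        tag = aln$tag[S4Vectors::queryHits(ov)],
        locus_id = kmd$locus_id[S4Vectors::subjectHits(ov)],
        category = kmd$sRNA_class[S4Vectors::subjectHits(ov)],
        mismatches = aln$mismatches[S4Vectors::queryHits(ov)],
        stringsAsFactors = FALSE)
      hits <- unique(hits)
      keep <- hits$mismatches <= ifelse(hits$category == "miRNA",
                                        mirna_max_mismatch, max_mismatch)
      hits <- hits[keep, , drop = FALSE]
    }
  }

  aln <- aln[aln$mismatches <= max_mismatch, , drop = FALSE]
  annotated <- .resolve_tags(tags, hits)
  mapped <- unique(aln$tag)
  mapped_total <- sum(tags$count[tags$sequence %in% mapped])
  list(alignments = aln, hits = hits, annotated = annotated,
       mapped_total = mapped_total)
}

# all substitution-only alignments of each unique tag on both strands
.align_tags <- function(sequences, reference, max_mismatch) {
  out <- vector("list", length(sequences) * 2L)
  k <- 0L
  for (ci in seq_along(reference)) {
    contig <- reference[[ci]]
    cname <- names(reference)[ci]
    clen <- length(contig)
    for (s in sequences) {
      if (nchar(s) > clen) next
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") s else .revcomp_chr(s)
        m <- Biostrings::matchPattern(pat, contig,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        mm <- Biostrings::neditAt(Biostrings::DNAString(pat), contig,
                                  at = BiocGenerics::start(m))
        k <- k + 1L
        out[[k]] <- data.frame(tag = s, contig = cname,
                               start = BiocGenerics::start(m),
                               end = BiocGenerics::end(m),
                               strand = strand, mismatches = as.integer(mm),
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(tag = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

.resolve_tags <- function(tags, hits) {
  res <- data.frame(sequence = tags$sequence, count = tags$count,
                    resolved_category = "unannotated",
                    best_locus = NA_character_,
                    best_mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(res)
  sp <- split(hits, hits$tag)
  for (tg in names(sp)) {
    h <- sp[[tg]]
    i <- match(tg, res$sequence)
    if (is.na(i)) next
    cat <- resolve_category(h$category)
    res$resolved_category[i] <- cat
    hc <- h[h$category == cat, , drop = FALSE]
    j <- which.min(hc$mismatches)
    res$best_locus[i] <- hc$locus_id[j]
    res$best_mismatches[i] <- hc$mismatches[j]
  }
  res
}

#' Resolve a set of category hits to a single category
#'
#' Applies the single-assignment priority rule
#' miRNA > piRNA > snoRNA > Rfam > other_sRNA; an empty hit set resolves
#' to `"unannotated"`.
#'
#' @param hit_categories Character vector of category labels (possibly
#'   with repeats), each among [srna_categories()].
#' @return A single category label, or `"unannotated"`.
#' @export
resolve_category <- function(hit_categories) {
  if (length(hit_categories) == 0) return("unannotated")
  unknown <- setdiff(unique(hit_categories), .srna_categories)
  if (length(unknown))
    stop("unknown sRNA category: ", paste(unknown, collapse = ", "))
  .srna_categories[min(match(hit_categories, .srna_categories))]
}

#' Category abundance summary
#'
#' Tag-level accounting: each tag contributes its whole count to its
#' single resolved category.  Percentages are over the clean-tag total,
#' rounded to two decimals; the unannotated remainder is reported so the
#' rows partition the library.
#'
#' @param annotated data.frame with `count` and `resolved_category`
#'   columns (as from [map_tags()]).
#' @param clean_total Clean-tag total of the library; must be at least
#'   `sum(annotated$count)`.
#' @return data.frame with `category`, `count`, `percent` rows for each
#'   category plus `unannotated`.
#' @export
category_summary <- function(annotated, clean_total) {
  if (clean_total < sum(annotated$count))
    stop("clean_total must be >= total annotated tag count")
  cats <- c(.srna_categories, "unannotated")
  cnt <- vapply(cats, function(cc)
    sum(annotated$count[annotated$resolved_category == cc]), 0)
  # tags not present in `annotated` (none, normally) are folded into
  # unannotated so the table partitions clean_total
  cnt["unannotated"] <- cnt["unannotated"] + clean_total - sum(cnt)
  data.frame(category = cats, count = as.integer(cnt),
             percent = round(100 * cnt / clean_total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
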