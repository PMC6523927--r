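#' Read a FASTQ file into id/sequence/quality vectors
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the reader's internal coercion discards (empty) mcols with a warning
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- as.character(x)
  quals <- as.character(Biostrings::quality(x))
  data.frame(id = names(x),
             sequence = seqs,
             quality = quals,
             stringsAsFactors = FALSE)
}

.mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

#' Clean raw sRNA reads and collapse them to unique tags
#'
#' Applies, in order: (1) drop reads with mean Phred below
#' `quality_floor`; (2) require a 3' adapter match (exact occurrence of
#' the first `adapter_match_len` nt of the adapter; the insert is the
#' part before the match); (3) drop inserts starting with the 5' primer
#' (5' contaminant); (4) drop empty inserts; (5) drop poly-A inserts
#' (at least `polya_fraction` A); (6) drop inserts outside
#' `[min_len, max_len]`.  Survivors are collapsed by identical insert
#' into tags with counts.
#'
#' @param reads data.frame with `sequence` and optionally `quality`
#'   columns (as from [read_fastq()]), or a character vector of reads.
#' @param adapter 3' adapter sequence (non-empty).
#' @param quality_floor Minimum mean Phred score (default 20).
#' @param min_len,max_len Retained insert length window (default 18--28).
#' @param primer5 5' primer sequence, or `NULL` to skip rule (3).
#' @param adapter_match_len Length of the exact adapter prefix searched
#'   for (default 8).
#' @param polya_fraction Fraction of A at or above which an insert is
#'   called poly-A (default 0.8).
#' @return A list with `tags` (data.frame `sequence`, `count`, sorted by
#'   decreasing count then sequence), `rejections` (named integer vector
#'   over the six rules), `n_raw`, `n_clean` (reads surviving, equal to
#'   `sum(tags$count)`), and `insert_lengths` (lengths of inserts
#'   surviving rules 1--5, before the length filter; used for
#'   figure-style length distributions over a wider axis).
#' @export
clean_reads <- function(reads, adapter, quality_floor = 20,
                        min_len = 18L, max_len = 28L,
                        primer5 = NULL, adapter_match_len = 8L,
                        polya_fraction = 0.8) {
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (is.character(reads)) reads <- data.frame(sequence = reads,
                                               stringsAsFactors = FALSE)
  seqs <- reads$sequence
  quals <- reads$quality
  n_raw <- length(seqs)
  rej <- c(low_quality = 0L, no_adapter = 0L, primer5_contaminant = 0L,
           no_insert = 0L, poly_a = 0L, length_filtered = 0L)
  if (n_raw == 0L) {
    return(list(tags = data.frame(sequence = character(0),
                                  count = integer(0)),
                rejections = rej, n_raw = 0L, n_clean = 0L,
                insert_lengths = integer(0)))
  }

  keep <- rep(TRUE, n_raw)
  if (!is.null(quals)) {
    bad <- .mean_phred(quals) < quality_floor
    rej["low_quality"] <- sum(bad)
    keep[bad] <- FALSE
  }

  probe <- substr(adapter, 1L, adapter_match_len)
  pos <- regexpr(probe, seqs, fixed = TRUE)
  no_ad <- keep & pos < 0L
  rej["no_adapter"] <- sum(no_ad)
  keep[no_ad] <- FALSE

  insert <- substr(seqs, 1L, ifelse(pos > 0L, pos - 1L, 0L))

  if (!is.null(primer5) && nchar(primer5) > 0) {
    p5 <- substr(primer5, 1L, min(8L, nchar(primer5)))
    contam <- keep & startsWith(insert, p5) & nchar(insert) > 0L
    rej["primer5_contaminant"] <- sum(contam)
    keep[contam] <- FALSE
  }

  empty <- keep & nchar(insert) == 0L
  rej["no_insert"] <- sum(empty)
  keep[empty] <- FALSE

  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  polya <- keep & (n_a / pmax(nchar(insert), 1L)) >= polya_fraction
  rej["poly_a"] <- sum(polya)
  keep[polya] <- FALSE

  insert_lengths <- nchar(insert[keep])

  len_bad <- keep & (nchar(insert) < min_len | nchar(insert) > max_len)
  rej["length_filtered"] <- sum(len_bad)
  keep[len_bad] <- FALSE

  surv <- insert[keep]
  tab <- table(surv)
  tags <- data.frame(sequence = names(tab),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, rejections = rej, n_raw = n_raw,
       n_clean = as.integer(sum(tags$count)),
       insert_lengths = insert_lengths)
}

#' Length distribution of tags
#'
#' @param tags data.frame with `sequence` and `count` columns, or an
#'   integer vector of lengths (counts then default to 1 each).
#' @param range Integer vector of lengths to report individually
#'   (default 16:36); lengths outside it are pooled in an `overflow` row.
#' @return data.frame with `length` (character; includes `"overflow"`),
#'   `total_count` and `unique_tags`; the two count columns partition
#'   the input.
#' @export
length_distribution <- function(tags, range = 16:36) {
  if (is.numeric(tags)) tags <- data.frame(sequence = strrep("N", tags),
                                           count = 1L, len = as.integer(tags))
  len <- if ("len" %in% names(tags)) tags$len else nchar(tags$sequence)
  out <- data.frame(length = as.character(range),
                    total_count = 0L, unique_tags = 0L,
                    stringsAsFactors = FALSE)
  inside <- len %in% range
  if (any(inside)) {
    tc <- tapply(tags$count[inside], factor(len[inside], levels = range), sum)
    ut <- tapply(rep(1L, sum(inside)), factor(len[inside], levels = range), sum)
    out$total_count <- as.integer(ifelse(is.na(tc), 0L, tc))
    out$unique_tags <- as.integer(ifelse(is.na(ut), 0L, ut))
  }
  rbind(out, data.frame(length = "overflow",
                        total_count = as.integer(sum(tags$count[!inside])),
                        unique_tags = as.integer(sum(!inside))))
}

#' Library-level sequencing summary
#'
#' Reproduces the arithmetic of a sequencing summary table: the clean
#' percentage is taken over raw reads, the mapped percentage over clean
#' reads, both rounded to two decimals.
#'
#' @param raw_n,clean_n,mapped_n Read counts with
#'   `0 <= mapped_n <= clean_n <= raw_n` and `raw_n > 0`.  Vectorized.
#' @return data.frame with columns `raw_tag_count`, `clean_tag_count`,
#'   `clean_percent`, `mapped_tag_count`, `mapped_percent`.
#' @export
summarize_library <- function(raw_n, clean_n, mapped_n) {
  if (any(raw_n == 0)) stop("raw_n must be positive")
  if (any(mapped_n > clean_n) || any(clean_n > raw_n) || any(mapped_n < 0))
    stop("require 0 <= mapped_n <= clean_n <= raw_n")
  data.frame(raw_tag_count = raw_n,
             clean_tag_count = clean_n,
             clean_percent = round(100 * clean_n / raw_n, 2),
             mapped_tag_count = mapped_n,
             mapped_percent = round(100 * mapped_n / clean_n, 2))
}
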