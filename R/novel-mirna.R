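.pair_weights <- function() {
  w <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  w["G", "C"] <- w["C", "G"] <- 3L
  w["A", "T"] <- w["T", "A"] <- 2L
  w["G", "T"] <- w["T", "G"] <- 1L
  w
}

.encode_dna <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(b, c("A", "C", "G", "T")) - 1L
  if (anyNA(code)) stop("non-ACGT character in sequence")
  code
}

#' Fold a sequence by weighted base-pair maximization
#'
#' A Nussinov-style dynamic program maximizing the total pair weight
#' (G-C = 3, A-T = 2, G-T = 1) over all pseudoknot-free structures whose
#' hairpin loops contain at least `min_loop` unpaired bases.  This is a
#' deliberately simple stand-in for a thermodynamic folding model: the
#' weights order pair stabilities the way stacking energies do, and the
#' score-per-nucleotide serves as the stage's energy proxy.  Traceback
#' is deterministic (a pairing of the 3'-most base is preferred over
#' leaving it unpaired on ties; among tied partners the leftmost wins).
#'
#' @param seq Nucleotide string (A/C/G/T only).
#' @param min_loop Minimum hairpin-loop size (>= 3).
#' @param weights 4x4 integer pair-weight matrix over A/C/G/T (rows and
#'   columns in that order); defaults to G-C = 3, A-T = 2, G-T = 1.
#' @return List with `structure` (dot-bracket string of the same length
#'   as `seq`), `pairs` (two-column matrix of 1-based paired positions,
#'   i < j), `n_pairs`, `score` (total pair weight), `paired_fraction`.
#' @export
fold_max_pairing <- function(seq, min_loop = 3L, weights = NULL) {
  if (nchar(seq) < 1) stop("sequence must be non-empty")
  if (min_loop < 3) stop("min_loop must be >= 3")
  if (is.null(weights)) weights <- .pair_weights()
  code <- .encode_dna(seq)
  res <- fold_nussinov_cpp(code, as.integer(min_loop),
                           matrix(as.integer(weights), 4, 4))
  p <- res$pairs
  n <- length(p)
  db <- rep(".", n)
  i <- which(p > seq_len(n))
  db[i] <- "("
  db[p[i]] <- ")"
  pairs <- cbind(i = i, j = p[i])
  list(structure = paste(db, collapse = ""),
       pairs = pairs,
       n_pairs = length(i),
       score = res$score,
       paired_fraction = if (n > 0) sum(p > 0) / n else 0)
}

#' Default hairpin-verdict thresholds
#'
#' @return Named list: `min_paired_fraction` (0.55, over the excised
#'   window), `min_mature_paired` (16 bases of the mature must pair),
#'   `max_mature_self_pairs` (2; pairs internal to the mature), and
#'   `min_score_per_nt` (1.0; total pair weight per window nucleotide,
#'   the energy proxy).  The last value reflects that a genuine
#'   precursor stem pairs nearly every window base at weight 2 or 3,
#'   so its score is close to or above the window length, whereas the
#'   fragmented maximum-pairing folds of random sequence are pulled
#'   below it by loops and weight-1 G-U pairs.
#' @export
hairpin_thresholds <- function() {
  list(min_paired_fraction = 0.55,
       min_mature_paired = 16L,
       max_mature_self_pairs = 2L,
       min_score_per_nt = 1.0)
}

# evaluate hairpin criteria for a mature occupying positions
# mat_start..mat_end (1-based) of `window_seq`
.evaluate_hairpin <- function(window_seq, mat_start, mat_end,
                              thresholds = hairpin_thresholds(),
                              min_loop = 3L) {
  fold <- fold_max_pairing(window_seq, min_loop)
  n <- nchar(window_seq)
  partner <- integer(n)
  if (nrow(fold$pairs) > 0) {
    partner[fold$pairs[, 1]] <- fold$pairs[, 2]
    partner[fold$pairs[, 2]] <- fold$pairs[, 1]
  }
  mat_idx <- mat_start:mat_end
  mat_partner <- partner[mat_idx]
  paired <- mat_partner > 0
  self <- paired & mat_partner >= mat_start & mat_partner <= mat_end
  outside <- mat_partner[paired & !self]
  one_arm <- length(outside) == 0 ||
    all(outside > mat_end) || all(outside < mat_start)
  arm <- if (length(outside) == 0) NA_character_
         else if (all(outside > mat_end)) "5p" else "3p"
  score_per_nt <- fold$score / n
  verdict <- fold$paired_fraction >= thresholds$min_paired_fraction &&
    sum(paired) >= thresholds$min_mature_paired &&
    sum(self) / 2 <= thresholds$max_mature_self_pairs &&
    one_arm &&
    score_per_nt >= thresholds$min_score_per_nt
  list(fold = fold$structure,
       paired_fraction = fold$paired_fraction,
       mature_paired = sum(paired),
       mature_self_pairs = as.integer(sum(self) / 2),
       one_arm = one_arm,
       mature_arm = arm,
       score_per_nt = score_per_nt,
       star_span = if (length(outside)) range(outside) else c(NA, NA),
       verdict = isTRUE(verdict))
}

#' Call novel miRNA candidates from unannotated mapped tags
#'
#' For each unannotated tag with at least `min_count` reads and a
#' genomic alignment, a precursor window of the tag plus `window_flank`
#' nt on each side (clipped at contig ends) is excised (reverse
#' complemented for minus-strand tags) and folded with
#' [fold_max_pairing()].  The verdict is `TRUE` iff (a) the paired
#' fraction of the window is at least `min_paired_fraction`, (b) at
#' least `min_mature_paired` bases of the mature are paired, (c) the
#' mature lies entirely on one arm — every outside partner of a mature
#' base is on the same side, with at most `max_mature_self_pairs` pairs
#' internal to the mature — and (d) the pair-weight score per window
#' nucleotide is at least `min_score_per_nt`.  Star support is reported
#' when another tag aligns to the partner (star) arm with the 2-nt 3'
#' overhang characteristic of Dicer processing (tolerance 2 nt).
#'
#' @param unannotated data.frame of tags with columns `sequence`,
#'   `count`, `contig`, `start`, `end`, `strand` (genomic alignment of
#'   the tag, as produced by [map_tags()] alignments joined to the
#'   unannotated set).
#' @param reference [Biostrings::DNAStringSet].
#' @param window_flank Flank excised on each side (default 80 nt).
#' @param min_count Minimum tag count to consider (default 5).
#' @param thresholds See [hairpin_thresholds()].
#' @param min_loop Minimum hairpin loop for folding.
#' @return data.frame with one row per evaluated tag: window
#'   coordinates, window sequence, dot-bracket fold, the four criterion
#'   values, `mature_arm`, `star_support`, and `verdict`.
#' @export
call_novel_mirnas <- function(unannotated, reference, window_flank = 80L,
                              min_count = 5L,
                              thresholds = hairpin_thresholds(),
                              min_loop = 3L) {
  cand <- unannotated[unannotated$count >= min_count &
                        !is.na(unannotated$start), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      contig = character(0), window_start = integer(0),
                      window_end = integer(0), strand = character(0),
                      window_seq = character(0), fold = character(0),
                      paired_fraction = numeric(0), mature_paired = integer(0),
                      mature_self_pairs = integer(0), one_arm = logical(0),
                      mature_arm = character(0), score_per_nt = numeric(0),
                      star_support = logical(0), verdict = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    tg <- cand[r, ]
    contig <- reference[[tg$contig]]
    clen <- length(contig)
    ws <- max(1L, tg$start - window_flank)
    we <- min(clen, tg$end + window_flank)
    wseq <- as.character(Biostrings::subseq(contig, ws, we))
    if (identical(tg$strand, "-")) {
      wseq <- .revcomp_chr(wseq)
      mat_start <- we - tg$end + 1L
    } else {
      mat_start <- tg$start - ws + 1L
    }
    mat_end <- mat_start + nchar(tg$sequence) - 1L
    ev <- .evaluate_hairpin(wseq, mat_start, mat_end, thresholds, min_loop)

    star_support <- FALSE
    if (ev$verdict && !anyNA(ev$star_span)) {
      # star arm genomic span (coordinates on the folded window strand)
      if (identical(tg$strand, "-")) {
        star_g_start <- we - (ev$star_span[2] - 1L)
      } else {
        star_g_start <- ws + ev$star_span[1] - 1L
      }
      others <- unannotated[unannotated$sequence != tg$sequence &
                              !is.na(unannotated$start) &
                              unannotated$contig == tg$contig, , drop = FALSE]
      if (nrow(others) > 0) {
        star_support <- any(abs(others$start - star_g_start) <= 2 &
                              nchar(others$sequence) >= 20 &
                              nchar(others$sequence) <= 24)
      }
    }
    rows[[r]] <- data.frame(
      sequence = tg$sequence, count = tg$count, contig = tg$contig,
      window_start = ws, window_end = we, strand = tg$strand,
      window_seq = wseq, fold = ev$fold,
      paired_fraction = ev$paired_fraction,
      mature_paired = ev$mature_paired,
      mature_self_pairs = ev$mature_self_pairs,
      one_arm = ev$one_arm, mature_arm = ev$mature_arm,
      score_per_nt = ev$score_per_nt,
      star_support = star_support, verdict = ev$verdict,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call siRNA-like duplexes from mapped tags
#'
#' Emits pairs of 22--24 nt tags mapping to opposite strands of the same
#' contig whose alignment leaves exactly a 2-nt 3' overhang on each
#' strand (the Dicer signature): with the plus-strand tag at
#' `[s1, e1]` and the minus-strand tag at `[s2, e2]`, this requires
#' `s1 - s2 == 2` and `e1 - e2 == 2`.
#'
#' @param tag_alignments data.frame with `sequence`, `contig`, `start`,
#'   `end`, `strand` (one row per alignment).
#' @return data.frame with `tag_plus`, `tag_minus`, `contig`,
#'   `start_plus`, `start_minus`, `overhang_check` (always `TRUE` for
#'   emitted rows).
#' @export
call_sirna_pairs <- function(tag_alignments) {
  len <- nchar(tag_alignments$sequence)
  ok <- len >= 22L & len <= 24L
  x <- tag_alignments[ok, , drop = FALSE]
  plus <- x[x$strand == "+", , drop = FALSE]
  minus <- x[x$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(plus) > 0 && nrow(minus) > 0) {
    for (i in seq_len(nrow(plus))) {
      m <- minus[minus$contig == plus$contig[i] &
                   plus$start[i] - minus$start == 2L &
                   plus$end[i] - minus$end == 2L, , drop = FALSE]
      if (nrow(m) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          tag_plus = plus$sequence[i], tag_minus = m$sequence,
          contig = plus$contig[i], start_plus = plus$start[i],
          start_minus = m$start, overhang_check = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(tag_plus = character(0), tag_minus = character(0),
                      contig = character(0), start_plus = integer(0),
                      start_minus = integer(0), overhang_check = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict piRNAs (stub)
#'
#' Transposon-interaction-based piRNA classification is intentionally
#' not modeled; this predictor always returns an empty set, so known and
#' novel piRNA counts are reported as zero.
#'
#' @param tags Any tag collection.
#' @return Zero-row data.frame with a `sequence` column.
#' @export
predict_pirnas <- function(tags) {
  data.frame(sequence = character(0), stringsAsFactors = FALSE)
}

#' Dinucleotide shuffle of a sequence
#'
#' Uniform random shuffle preserving the exact dinucleotide composition
#' (Altschul-Erickson Eulerian-path construction); used to build
#' empirical nulls for the hairpin verdict.
#'
#' @param seq Nucleotide string.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 3) return(seq)
  last <- b[n]
  succ <- split(b[-1], b[-n])          # outgoing edge multisets
  verts <- names(succ)
  repeat {
    # pick a candidate final edge for every vertex except the terminal
    # one; accept when these edges form a tree rooted at the terminal
    final_edge <- vapply(verts, function(v) {
      if (v == last) NA_character_ else sample(succ[[v]], 1)
    }, "")
    reaches <- function(v) {
      seen <- character(0)
      while (!is.na(v) && v != last && !(v %in% seen)) {
        seen <- c(seen, v)
        v <- if (v %in% names(final_edge)) final_edge[[v]] else NA_character_
      }
      identical(v, last)
    }
    if (all(vapply(setdiff(verts, last), reaches, TRUE))) break
  }
  # order edges: random permutation per vertex, chosen final edge last
  ordered <- lapply(verts, function(v) {
    e <- succ[[v]]
    if (v == last) return(sample(e))
    fe <- final_edge[[v]]
    e <- e[-match(fe, e)]
    c(if (length(e)) sample(e) else character(0), fe)
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- b[1]
  for (i in 2:n) {
    cur <- out[i - 1]
    out[i] <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
  }
  paste(out, collapse = "")
}
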