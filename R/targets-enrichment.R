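#' Predict miRNA target transcripts by penalized complementarity
#'
#' Slides the reverse complement of each miRNA along each transcript
#' (no indels) and scores every window: a mismatch costs 1 and a G:U
#' wobble (miRNA G opposite target T, or miRNA T opposite target G)
#' costs 0.5, with both costs doubled at positions 2--13 counted from
#' the miRNA 5' end.  The best window per miRNA/transcript pair is
#' emitted when its penalty is at most `cutoff`.
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param cutoff Maximum penalty (default 4).
#' @return data.frame: `mirna_id`, `gene_id`, `penalty_score`,
#'   `position` (1-based start of the target window on the transcript).
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 4) {
  if (length(mirnas) == 0 || length(transcripts) == 0)
    stop("mirnas and transcripts must be non-empty")
  out <- list()
  for (mi in seq_along(mirnas)) {
    m <- mirnas[[mi]]
    mlen <- nchar(m)
    mb <- strsplit(m, "", fixed = TRUE)[[1]]
    # window position k (5'->3' on the transcript) faces miRNA position
    # mlen - k + 1 (miRNA is antiparallel to its site)
    mirna_pos <- mlen:1
    comp <- c(A = "T", C = "G", G = "C", T = "A")[mb[mirna_pos]]
    weight <- ifelse(mirna_pos >= 2 & mirna_pos <= 13, 2, 1)
    m_is_g <- mb[mirna_pos] == "G"
    m_is_t <- mb[mirna_pos] == "T"
    for (ti in seq_along(transcripts)) {
      tx <- transcripts[[ti]]
      nwin <- nchar(tx) - mlen + 1L
      if (nwin < 1L) next
      best <- Inf; best_pos <- NA_integer_
      tb <- strsplit(tx, "", fixed = TRUE)[[1]]
      for (s in seq_len(nwin)) {
        w <- tb[s:(s + mlen - 1L)]
        mismatch <- w != comp
        wobble <- (m_is_g & w == "T") | (m_is_t & w == "G")
        pen <- sum(weight * ifelse(wobble, 0.5, ifelse(mismatch, 1, 0)))
        if (pen < best) { best <- pen; best_pos <- s }
        if (best == 0) break
      }
      if (best <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = names(mirnas)[mi], gene_id = names(transcripts)[ti],
          penalty_score = best, position = best_pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      penalty_score = numeric(0), position = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Upper-tail hypergeometric enrichment probability
#'
#' The probability of drawing at least `m` term genes when `n` genes
#' are drawn without replacement from a universe of `N` genes of which
#' `M` carry the term:
#' `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)`,
#' computed exactly as an upper-tail sum of log-space binomials.
#'
#' @param N Total annotated genes.
#' @param n Target (drawn) genes among `N`.
#' @param M Genes annotated to the term.
#' @param m Target genes among `M`.
#' @return The upper-tail probability.
#' @export
hypergeom_p <- function(N, n, M, m) {
  if (m > min(n, M) || n > N || M > N || any(c(N, n, M, m) < 0))
    stop("invalid hypergeometric input: need m <= min(n, M), n <= N, M <= N")
  if (m == 0) return(1)
  i <- m:min(n, M)
  p <- sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)))
  min(1, max(0, p))
}

#' Hypergeometric term enrichment with Bonferroni control
#'
#' One test per annotation term observed in the target set: with `N`
#' background genes, `n` target genes, `M` background genes carrying
#' the term and `m` target genes among them, the enrichment p-value is
#' [hypergeom_p()].  Bonferroni correction is over the tested terms
#' only (terms with `M = 0` or no target gene are excluded from the
#' denominator, mirroring standard term-finder behavior); a term is
#' significant when its corrected p-value is at most `alpha`.  The GO
#' and KEGG analyses use this identical machinery with different term
#' maps.
#'
#' @param gene2term data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`, `namespace`.
#' @param background Character vector of background gene ids (`N`).
#' @param targets Character vector of target gene ids; must be a subset
#'   of `background`.
#' @param alpha Corrected-p threshold (default 0.05).
#' @param all_terms If `TRUE`, terms with no target gene are also
#'   emitted (with `p_value = 1`, excluded from the Bonferroni
#'   denominator).
#' @return data.frame: `term_id`, `term_name`, `namespace`, `M`, `m`,
#'   `p_value`, `p_corrected`, `significant`, sorted by `p_value`.
#' @export
enrich <- function(gene2term, background, targets, alpha = 0.05,
                   all_terms = FALSE) {
  background <- unique(background)
  targets <- unique(targets)
  if (length(background) == 0) stop("background must be non-empty")
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  ann <- gene2term[gene2term$gene_id %in% background, , drop = FALSE]
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  if (!"namespace" %in% names(ann)) ann$namespace <- NA_character_
  ann <- unique(ann[, c("gene_id", "term_id", "term_name", "namespace")])

  N <- length(background)
  n <- length(targets)
  terms <- unique(ann[, c("term_id", "term_name", "namespace")])
  M <- tapply(ann$gene_id, ann$term_id, function(g) length(unique(g)))
  m <- tapply(ann$gene_id, ann$term_id,
              function(g) length(unique(intersect(g, targets))))
  terms$M <- as.integer(M[terms$term_id])
  terms$m <- as.integer(m[terms$term_id])

  tested <- terms[terms$M > 0 & terms$m > 0, , drop = FALSE]
  tested$p_value <- vapply(seq_len(nrow(tested)), function(i)
    hypergeom_p(N, n, tested$M[i], tested$m[i]), 0)
  tested$p_corrected <- bonferroni(tested$p_value)
  tested$significant <- tested$p_corrected <= alpha

  if (all_terms) {
    rest <- terms[!(terms$M > 0 & terms$m > 0), , drop = FALSE]
    if (nrow(rest) > 0) {
      rest$p_value <- 1
      rest$p_corrected <- 1
      rest$significant <- FALSE
      tested <- rbind(tested, rest)
    }
  }
  tested <- tested[order(tested$p_value, tested$term_id), , drop = FALSE]
  rownames(tested) <- NULL
  tested
}
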