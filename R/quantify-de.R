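#' Transcripts-per-million expression of a tag count
#'
#' `TPM = count * 1e6 / library_total`.  A zero count is floored at
#' `zero_floor` (default 0.001) so that log ratios against a zero side
#' remain finite; this matches the convention of printing 0.001 for
#' zero-count rows in published novel-miRNA expression tables.
#'
#' @param count Tag count(s), non-negative.
#' @param library_total Clean-tag total of the library (> 0).
#' @param zero_floor TPM assigned to zero counts (default 0.001).
#' @return Numeric TPM, vectorized over `count`.
#' @export
tpm <- function(count, library_total, zero_floor = 0.001) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  ifelse(count > 0, count * 1e6 / library_total, zero_floor)
}

#' Log2 expression ratio (condition b over condition a)
#'
#' @param tpm_a,tpm_b Strictly positive TPM values (zero counts must
#'   already be floored via [tpm()]).
#' @return `log2(tpm_b / tpm_a)`, vectorized.
#' @export
log2_ratio <- function(tpm_a, tpm_b) {
  if (any(tpm_a <= 0) || any(tpm_b <= 0))
    stop("TPM values must be strictly positive (apply the zero floor first)")
  log2(tpm_b / tpm_a)
}

#' Poisson probability mass
#'
#' `P(x) = exp(-lambda) * lambda^x / x!`, evaluated in log space.
#'
#' @param x Non-negative integer count(s).
#' @param lambda Expected count (> 0).
#' @return `P(x)`, vectorized.
#' @export
poisson_pmf <- function(x, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(x < 0) || any(x != round(x))) stop("x must be a non-negative integer")
  dpois(x, lambda)
}

#' Two-library conditional count probability
#'
#' The exact probability of observing `y` tags of an sRNA in library 2
#' given `x` tags in library 1 under equal per-tag expression, when the
#' clean-tag totals are `n1` and `n2`.  With `r = n2/n1`:
#' `P(y | x) = r^y * C(x+y, y) * (1+r)^(-(x+y+1))`, evaluated in log
#' space.  For fixed `x` this is a proper distribution over `y`
#' (negative binomial with size `x+1` and success probability
#' `n1/(n1+n2)`).
#'
#' @param y Count(s) in library 2 (vectorized).
#' @param x Count in library 1.
#' @param n1,n2 Clean-tag totals of libraries 1 and 2 (> 0).
#' @return `P(y | x)`, vectorized over `y`.
#' @export
ac_conditional <- function(y, x, n1, n2) {
  stopifnot(length(x) == 1L, x >= 0, n1 > 0, n2 > 0)
  if (any(y < 0)) stop("y must be non-negative")
  logr <- log(n2) - log(n1)
  log1pr <- log1p(exp(logr))
  exp(y * logr + lchoose(x + y, y) - (x + y + 1) * log1pr)
}

#' Two-sided two-library Poisson p-value
#'
#' The doubled tail probability of the observed library-2 count: with
#' `S = sum_{i=0..y} P(i | x)`, the p-value is `2*S` when `S <= 0.5`
#' and `2*(1-S)` otherwise, clamped to `[0, 1]`.  The upper branch is
#' evaluated as a direct sum over `i > y` (not as `1 - S`) so extreme
#' tails retain full relative precision.
#'
#' @param x,y Observed counts in libraries 1 and 2 (scalars or vectors
#'   of equal length).
#' @param n1,n2 Clean-tag totals (> 0).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (length(x) > 1L || length(y) > 1L) {
    k <- max(length(x), length(y))
    x <- rep_len(x, k); y <- rep_len(y, k)
    return(vapply(seq_len(k),
                  function(i) ac_pvalue(x[i], y[i], n1, n2), 0))
  }
  s <- sum(ac_conditional(0:y, x, n1, n2))
  if (s <= 0.5) {
    p <- 2 * s
  } else {
    # upper tail summed directly; the distribution over y is negative
    # binomial with mean (x+1)r and variance (x+1)r(1+r)
    r <- n2 / n1
    mu <- (x + 1) * r
    hi <- max(y, ceiling(mu)) + ceiling(50 * sqrt((x + 1) * r * (1 + r))) + 50L
    p <- 2 * sum(ac_conditional((y + 1):hi, x, n1, n2))
  }
  min(1, max(0, p))
}

#' Bonferroni-corrected p-values
#'
#' `min(1, m * p)` with `m` the number of tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Up/down/not-significant regulation calls
#'
#' An sRNA is called `up` iff its FDR is at or below `fdr_threshold`
#' and its log2 ratio (condition b over a) is at least `lfc_threshold`;
#' `down` iff the FDR gate holds and the log2 ratio is at or below
#' `-lfc_threshold`; `ns` otherwise.  Defaults are the stringent
#' screening thresholds FDR <= 0.001 and |log2 ratio| >= 1.
#'
#' @param log2_ratio,fdr Equal-length numeric vectors.
#' @param fdr_threshold,lfc_threshold Gates (defaults 0.001 and 1).
#' @return Character vector over `c("up", "down", "ns")`.
#' @export
call_regulation <- function(log2_ratio, fdr, fdr_threshold = 0.001,
                            lfc_threshold = 1) {
  out <- rep("ns", length(log2_ratio))
  sig <- fdr <= fdr_threshold
  out[sig & log2_ratio >= lfc_threshold] <- "up"
  out[sig & log2_ratio <= -lfc_threshold] <- "down"
  out
}

#' Differential expression between two libraries
#'
#' Computes per-sRNA TPM in both libraries (with the zero-count floor),
#' the log2 ratio of the floored TPMs, the exact two-library Poisson
#' p-value on the raw counts, Bonferroni-corrected p-values,
#' Benjamini-Hochberg FDR, and the regulation call.
#'
#' @param ids sRNA identifiers.
#' @param count_a,count_b Raw tag counts in libraries a and b.
#' @param n_a,n_b Clean-tag totals of libraries a and b.
#' @param zero_floor TPM floor for zero counts.
#' @param fdr_threshold,lfc_threshold Regulation gates.
#' @return data.frame: `srna_id`, `count_a`, `count_b`, `tpm_a`,
#'   `tpm_b`, `log2_ratio`, `p_value`, `p_bonferroni`, `fdr`,
#'   `regulation`.
#' @export
diff_expression <- function(ids, count_a, count_b, n_a, n_b,
                            zero_floor = 0.001, fdr_threshold = 0.001,
                            lfc_threshold = 1) {
  stopifnot(length(ids) == length(count_a), length(count_a) == length(count_b))
  tpm_a <- tpm(count_a, n_a, zero_floor)
  tpm_b <- tpm(count_b, n_b, zero_floor)
  lfc <- log2_ratio(tpm_a, tpm_b)
  p <- ac_pvalue(count_a, count_b, n_a, n_b)
  q <- fdr_bh(p)
  data.frame(srna_id = ids, count_a = count_a, count_b = count_b,
             tpm_a = tpm_a, tpm_b = tpm_b, log2_ratio = lfc,
             p_value = p, p_bonferroni = bonferroni(p), fdr = q,
             regulation = call_regulation(lfc, q, fdr_threshold,
                                          lfc_threshold),
             stringsAsFactors = FALSE)
}
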