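# shared fixtures and independent oracles

tiny_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_known_mirnas = 8L, n_novel_mirnas = 3L,
                   n_other_loci = 8L, reads_per_library = 3000L,
                   base_expression_range = c(20, 100),
                   n_background_species = 50L, ...)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# a precursor window built the way the generator embeds novel loci:
# 80 nt upstream flank, the mature, an 8 nt loop, and the reverse
# complement of (upstream[30..80] + mature); mature sits at 81..(80+len)
make_hairpin_window <- function(mature = rand_dna(21)) {
  up <- rand_dna(80)
  loop <- rand_dna(8)
  arm3 <- revcomp(paste0(substr(up, 30, 80), mature))
  list(window = paste0(up, mature, loop, arm3),
       mature_start = 81L, mature_end = 80L + nchar(mature))
}

# brute-force maximizer over all non-crossing pairings (uncached plain
# recursion pairing the FIRST position; independent of the DP's
# last-position formulation)
bf_fold_score <- function(seq, min_loop = 3L, gt_weight = 1L) {
  w <- matrix(0L, 4, 4)
  w[3, 2] <- w[2, 3] <- 3L
  w[1, 4] <- w[4, 1] <- 2L
  w[3, 4] <- w[4, 3] <- gt_weight
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  go <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- go(i + 1L, j)                       # i unpaired
    for (k in (i + min_loop + 1L):j) {
      wij <- w[b[i], b[k]]
      if (wij == 0L) next
      best <- max(best, wij + go(i + 1L, k - 1L) + go(k + 1L, j))
    }
    best
  }
  go(1L, length(b))
}

# exhaustive hypergeometric upper tail by enumerating every n-subset of
# an N-element universe whose first M elements carry the term
bf_hypergeom_p <- function(N, n, M, m) {
  if (m == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= M)
  mean(overlap >= m)
}

# plain-arithmetic direct summation of the two-library Poisson p-value
# (term recurrence, no logs; independent of the log-space implementation)
bf_ac_pvalue <- function(x, y, n1, n2) {
  r <- n2 / n1
  t <- (1 + r)^-(x + 1)           # P(0 | x)
  s <- t
  if (y > 0) {
    for (i in seq_len(y)) {
      t <- t * r * (x + i) / (i * (1 + r))
      s <- s + t
    }
  }
  if (s <= 0.5) return(min(1, 2 * s))
  # continue the recurrence into the upper tail for full precision
  tail <- 0
  i <- y
  repeat {
    i <- i + 1L
    t <- t * r * (x + i) / (i * (1 + r))
    tail <- tail + t
    if (t < 1e-25 * max(tail, 1e-300) && i > (x + 1) * r) break
  }
  min(1, 2 * tail)
}
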