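test_that("fold recovers simple stems and respects the loop constraint", {
  f <- fold_max_pairing("GGGAAACCC", min_loop = 3L)
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$n_pairs, 3L)
  expect_equal(f$score, 9L)

  expect_equal(fold_max_pairing("AAAAAA")$n_pairs, 0L)
  # any sequence shorter than min_loop + 2 cannot pair
  for (n in 1:4)
    expect_equal(fold_max_pairing(strrep("G", n), min_loop = 3L)$n_pairs, 0L)
  expect_equal(fold_max_pairing("GAAAC", min_loop = 4L)$n_pairs, 0L)

  expect_error(fold_max_pairing("ACGUN"), "non-ACGT")
})

test_that("fold score equals brute-force maximization on short sequences", {
  set.seed(31)
  for (len in 2:12) {
    for (rep in 1:5) {
      s <- rand_dna(len)
      expect_equal(fold_max_pairing(s)$score, bf_fold_score(s),
                   label = s)
    }
  }
})

test_that("pair count is preserved under reverse complement (canonical pairs)", {
  w <- matrix(0L, 4, 4)
  w[2, 3] <- w[3, 2] <- 3L   # C-G
  w[1, 4] <- w[4, 1] <- 2L   # A-T
  set.seed(32)
  for (rep in 1:20) {
    s <- rand_dna(sample(8:40, 1))
    a <- fold_max_pairing(s, weights = w)
    b <- fold_max_pairing(revcomp(s), weights = w)
    expect_equal(a$n_pairs, b$n_pairs, label = s)
    expect_equal(a$score, b$score, label = s)
  }
})

test_that("constructed precursor windows pass the hairpin verdict", {
  set.seed(33)
  for (rep in 1:5) {
    hp <- make_hairpin_window()
    ev <- saltmir:::.evaluate_hairpin(hp$window, hp$mature_start,
                                      hp$mature_end)
    expect_true(ev$verdict)
    expect_gte(ev$mature_paired, 16L)
    expect_equal(ev$mature_arm, "5p")
  }
})

test_that("shuffled contexts rarely pass the verdict", {
  set.seed(34)
  hp <- make_hairpin_window()
  hits <- vapply(1:100, function(i) {
    s <- dinucleotide_shuffle(hp$window)
    saltmir:::.evaluate_hairpin(s, hp$mature_start, hp$mature_end)$verdict
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("novel calling excises windows around mapped tags and is gated", {
  cfg <- synthetic_config(seed = 35L, n_known_mirnas = 2L,
                          n_novel_mirnas = 3L, n_other_loci = 0L,
                          reads_per_library = 3000L,
                          base_expression = 150,
                          n_background_species = 30L)
  ref <- generate_reference(cfg)
  fq <- withr::local_tempfile()
  generate_libraries(cfg, ref$reference, ref$annotation, fq,
                     withr::local_tempfile())
  cl <- clean_reads(read_fastq(fq), cfg$adapter, primer5 = cfg$primer5)
  m <- map_tags(cl$tags, ref$reference, ref$annotation,
                max_mismatch = 0L, mirna_max_mismatch = 2L)

  una_seq <- m$annotated$sequence[m$annotated$resolved_category ==
                                    "unannotated"]
  aln <- m$alignments[m$alignments$tag %in% una_seq, ]
  aln <- aln[!duplicated(aln$tag), ]
  una <- data.frame(sequence = aln$tag,
                    count = cl$tags$count[match(aln$tag, cl$tags$sequence)],
                    contig = aln$contig, start = aln$start, end = aln$end,
                    strand = aln$strand)
  cand <- call_novel_mirnas(una, ref$reference)

  md <- S4Vectors::mcols(ref$annotation)
  novel_seqs <- md$sequence[md$sRNA_class == "novel_truth"]
  # all embedded novel loci expressed above min_count are called
  called <- cand$sequence[cand$verdict]
  expect_setequal(intersect(novel_seqs, cand$sequence), called)
  expect_gte(length(called), 1L)

  # novel calls and annotated miRNA tags are disjoint sets
  mir_tags <- m$annotated$sequence[m$annotated$resolved_category == "miRNA"]
  expect_length(intersect(called, mir_tags), 0L)
})

test_that("siRNA duplex geometry requires the 2-nt 3' overhangs and 22-24 nt", {
  aln <- data.frame(
    sequence = c(strrep("A", 22), strrep("C", 22)),
    contig = "chr", start = c(101L, 99L), end = c(122L, 120L),
    strand = c("+", "-"))
  got <- call_sirna_pairs(aln)
  expect_equal(nrow(got), 1L)
  expect_true(got$overhang_check)

  # zero offset: blunt ends, no candidate
  aln0 <- aln; aln0$start <- c(101L, 101L); aln0$end <- c(122L, 122L)
  expect_equal(nrow(call_sirna_pairs(aln0)), 0L)

  # 21-mers fail the length gate even with perfect overhangs
  aln21 <- data.frame(
    sequence = c(strrep("A", 21), strrep("C", 21)),
    contig = "chr", start = c(101L, 99L), end = c(121L, 119L),
    strand = c("+", "-"))
  expect_equal(nrow(call_sirna_pairs(aln21)), 0L)
})

test_that("the piRNA predictor is an explicit stub returning none", {
  expect_equal(nrow(predict_pirnas(data.frame(sequence = "ACGT"))), 0L)
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  set.seed(36)
  s <- rand_dna(120)
  dinucs <- function(x) {
    b <- strsplit(x, "")[[1]]
    table(paste0(b[-length(b)], b[-1]))
  }
  for (rep in 1:5) {
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucs(sh), dinucs(s))
  }
})
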