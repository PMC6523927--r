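test_that("generator output is fully determined by the seed", {
  cfg <- tiny_config(seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    ref <- generate_reference(cfg)
    write_reference(ref, file.path(d, "ref.fa"), file.path(d, "ann.gff3"))
    truth <- generate_libraries(cfg, ref$reference, ref$annotation,
                                file.path(d, "c.fastq"), file.path(d, "s.fastq"))
    write_truth_table(truth, file.path(d, "truth.tsv"))
  }
  for (f in c("ref.fa", "ann.gff3", "c.fastq", "s.fastq", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("annotation records count and tag loci as configured", {
  cfg <- synthetic_config(seed = 2L, n_known_mirnas = 5L,
                          n_novel_mirnas = 1L, n_other_loci = 5L,
                          reads_per_library = 100L)
  ref <- generate_reference(cfg)
  cls <- S4Vectors::mcols(ref$annotation)$sRNA_class
  expect_equal(sum(cls %in% srna_categories()), 10L)
  expect_equal(sum(cls == "novel_truth"), 1L)

  # the novel locus carries a reverse-complemented flank: the 72 nt after
  # the 8 nt loop downstream of the mature equal revcomp(flank + mature)
  md <- S4Vectors::mcols(ref$annotation)
  i <- which(md$sRNA_class == "novel_truth")
  st <- GenomicRanges::start(ref$annotation)[i]
  en <- GenomicRanges::end(ref$annotation)[i]
  contig <- as.character(ref$reference[[1]])
  upstream <- substr(contig, st - 80L, st - 1L)
  mature <- substr(contig, st, en)
  expect_identical(md$sequence[i], mature)
  downstream <- substr(contig, en + 9L, en + 8L + 51L + nchar(mature))
  expect_identical(downstream, revcomp(paste0(substr(upstream, 30, 80), mature)))
})

test_that("truth table reflects the count model and links to the annotation", {
  n <- 6L
  cfg <- synthetic_config(seed = 3L, n_known_mirnas = n, n_novel_mirnas = 0L,
                          n_other_loci = 0L, reads_per_library = 2000L,
                          base_expression = c(0, rep(100, n - 1)),
                          fold_changes = c(1, 8, rep(1, n - 2)),
                          n_background_species = 20L)
  ref <- generate_reference(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  truth <- generate_libraries(cfg, ref$reference, ref$annotation, f1, f2)

  expect_equal(nrow(truth), n)
  # every truth locus is recoverable from the annotation by id
  expect_true(all(truth$locus_id %in%
                    S4Vectors::mcols(ref$annotation)$locus_id))
  expect_equal(truth$true_log2_fc[truth$locus_id == "known_mir2"], 3)
  # base mean 0 => no reads for that locus in either library
  expect_equal(truth$true_counts_control[truth$locus_id == "known_mir1"], 0L)
  expect_true(all(truth$true_counts_control >= 0))
})

test_that("generate_libraries rejects annotations missing locus metadata", {
  cfg <- tiny_config(seed = 4L)
  ref <- generate_reference(cfg)
  ann <- ref$annotation
  S4Vectors::mcols(ann)$sequence[3] <- ""
  bad_id <- S4Vectors::mcols(ann)$locus_id[3]
  expect_error(
    generate_libraries(cfg, ref$reference, ann,
                       withr::local_tempfile(), withr::local_tempfile()),
    bad_id, fixed = TRUE)
})

test_that("junk injection matches the requested fraction within binomial error", {
  # background inserts kept to 20-28 nt so every genuine read survives
  # cleaning and the rejection tallies count exactly the junk reads
  cfg <- synthetic_config(seed = 6L, n_known_mirnas = 0L, n_novel_mirnas = 0L,
                          n_other_loci = 0L, reads_per_library = 20000L,
                          junk_fraction = 0.1, n_background_species = 100L,
                          insert_length_weights =
                            setNames(rep(1 / 9, 9), 20:28))
  ref <- generate_reference(cfg)
  fq <- withr::local_tempfile()
  generate_libraries(cfg, ref$reference, ref$annotation, fq,
                     withr::local_tempfile())
  reads <- read_fastq(fq)
  cl <- clean_reads(reads, adapter = cfg$adapter, min_len = 18L, max_len = 34L,
                    primer5 = cfg$primer5)
  junk_seen <- sum(cl$rejections)
  n <- cfg$reads_per_library
  expect_lt(abs(junk_seen / n - 0.1), 4 * sqrt(0.1 * 0.9 / n))
})

test_that("under a global fold of 1, stress/control ratios concentrate near 1", {
  n <- 20L
  cfg <- synthetic_config(seed = 7L, n_known_mirnas = n, n_novel_mirnas = 0L,
                          n_other_loci = 0L, reads_per_library = 10000L,
                          base_expression = 400, fold_changes = 1,
                          junk_fraction = 0, n_background_species = 10L)
  ref <- generate_reference(cfg)
  truth <- generate_libraries(cfg, ref$reference, ref$annotation,
                              withr::local_tempfile(), withr::local_tempfile())
  ratio <- truth$true_counts_stress / truth$true_counts_control
  # each count is Poisson(400); the ratio sd is ~ sqrt(2/400)
  expect_true(all(abs(ratio - 1) < 3 * sqrt(2 / 400) + 0.02))
})
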