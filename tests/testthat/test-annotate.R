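# a hand-built two-locus reference used across the mapping tests
make_mini_reference <- function() {
  mir <- "TGACAGAAGAGAGTGAGCACA"       # 21 nt miRNA locus
  rf  <- "CCGTAACGGTTACCGGTTAACCGG"    # 24 nt Rfam locus
  contig <- paste0(strrep("T", 30), mir, strrep("G", 25), rf, strrep("C", 30))
  reference <- Biostrings::DNAStringSet(contig)
  names(reference) <- "chr"
  annotation <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = c(31L, 31L + 21L + 25L),
                            width = c(21L, 24L)),
    strand = "+",
    locus_id = c("mir1", "rfam1"), sRNA_class = c("miRNA", "Rfam"),
    sequence = c(mir, rf))
  list(reference = reference, annotation = annotation, mir = mir, rf = rf)
}

test_that("priority rule resolves multi-category hits to one category", {
  expect_equal(resolve_category(c("Rfam", "miRNA")), "miRNA")
  expect_equal(resolve_category(c("snoRNA", "piRNA")), "piRNA")
  expect_equal(resolve_category(character(0)), "unannotated")
  expect_error(resolve_category(c("miRNA", "lincRNA")), "unknown")
  # order independence
  set.seed(1)
  cats <- c("other_sRNA", "Rfam", "snoRNA", "miRNA")
  for (i in 1:10)
    expect_equal(resolve_category(sample(cats)), "miRNA")
})

test_that("tags map with the mismatch threshold as an exact boundary", {
  mini <- make_mini_reference()
  tag <- mini$mir
  tag2 <- tag
  substr(tag2, 3, 3) <- "C"; substr(tag2, 10, 10) <- "T"  # 2 substitutions
  tags <- data.frame(sequence = c(tag, tag2), count = c(4L, 2L))

  m0 <- map_tags(tags, mini$reference, mini$annotation, max_mismatch = 0L)
  expect_equal(m0$hits$mismatches[m0$hits$tag == tag], 0L)
  expect_false(tag2 %in% m0$hits$tag)
  expect_equal(m0$mapped_total, 4L)

  m1 <- map_tags(tags, mini$reference, mini$annotation, max_mismatch = 1L)
  expect_false(tag2 %in% m1$hits$tag)

  m2 <- map_tags(tags, mini$reference, mini$annotation, max_mismatch = 2L)
  expect_equal(m2$hits$mismatches[m2$hits$tag == tag2], 2L)
  expect_equal(m2$mapped_total, 6L)

  # the known-miRNA tolerance can exceed the genomic tolerance
  mk <- map_tags(tags, mini$reference, mini$annotation, max_mismatch = 0L,
                 mirna_max_mismatch = 2L)
  expect_equal(mk$annotated$resolved_category[
    mk$annotated$sequence == tag2], "miRNA")
  expect_equal(mk$mapped_total, 4L)  # genomic mapping stays exact
})

test_that("reverse-complement matches are hits", {
  mini <- make_mini_reference()
  tags <- data.frame(sequence = revcomp(mini$rf), count = 1L)
  m <- map_tags(tags, mini$reference, mini$annotation, max_mismatch = 0L)
  expect_equal(m$annotated$resolved_category, "Rfam")
  expect_equal(m$alignments$strand, "-")
})

test_that("a tag longer than every contig is unmapped, not an error", {
  mini <- make_mini_reference()
  tags <- data.frame(sequence = strrep("ACGT", 80), count = 1L)
  m <- map_tags(tags, mini$reference, mini$annotation)
  expect_equal(m$mapped_total, 0L)
  expect_equal(m$annotated$resolved_category, "unannotated")
})

test_that("category summary percentages and conservation", {
  ann <- data.frame(count = c(60L, 25L, 10L),
                    resolved_category = c("miRNA", "Rfam", "unannotated"))
  cs <- category_summary(ann, clean_total = 100L)
  expect_equal(cs$percent[cs$category == "miRNA"], 60)
  expect_equal(sum(cs$count), 100L)
  # unaccounted clean tags fold into the unannotated remainder
  cs2 <- category_summary(ann, clean_total = 120L)
  expect_equal(cs2$count[cs2$category == "unannotated"], 35L)
  # a single category holding everything reports 100%
  cs3 <- category_summary(data.frame(count = 7L,
                                     resolved_category = "miRNA"), 7L)
  expect_equal(cs3$percent[cs3$category == "miRNA"], 100)
  expect_error(category_summary(ann, 50L), "clean_total")
})

test_that("synthetic known-miRNA tags are recovered as miRNA", {
  cfg <- tiny_config(seed = 21L)
  ref <- generate_reference(cfg)
  fq <- withr::local_tempfile()
  generate_libraries(cfg, ref$reference, ref$annotation, fq,
                     withr::local_tempfile())
  cl <- clean_reads(read_fastq(fq), cfg$adapter, primer5 = cfg$primer5)
  m <- map_tags(cl$tags, ref$reference, ref$annotation,
                max_mismatch = 0L, mirna_max_mismatch = 2L)

  md <- S4Vectors::mcols(ref$annotation)
  mir_seqs <- md$sequence[md$sRNA_class == "miRNA"]
  present <- intersect(mir_seqs, cl$tags$sequence)
  res <- m$annotated$resolved_category[match(present, m$annotated$sequence)]
  expect_gte(mean(res == "miRNA"), 0.99)

  # single assignment + conservation over the clean library
  expect_equal(sum(m$annotated$count), cl$n_clean)
  expect_true(all(m$annotated$resolved_category %in%
                    c(srna_categories(), "unannotated")))
})
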