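test_that("target prediction scores complementarity with seed doubling", {
  mir <- "TGACAGAAGAGAGTGAGCACA"   # 21 nt
  site <- revcomp(mir)
  tx_perfect <- paste0(rand_dna(30), site, rand_dna(30))

  # one mismatch facing miRNA position 10 (inside the 2-13 seed window):
  # in the site (written 5'->3' on the transcript) position k faces
  # miRNA position len - k + 1, so k = 12 faces position 10
  site_mm <- site
  mir_b <- strsplit(mir, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  k <- nchar(mir) - 10 + 1
  wrong <- setdiff(c("A", "C", "G", "T"),
                   c(comp[[mir_b[10]]],
                     if (mir_b[10] == "G") "T" else character(0),
                     if (mir_b[10] == "T") "G" else character(0)))[1]
  substr(site_mm, k, k) <- wrong
  tx_mm <- paste0(rand_dna(30), site_mm, rand_dna(30))

  # five mismatches in the seed-facing window
  site_bad <- site
  for (kk in (nchar(mir) - 13 + 1):(nchar(mir) - 9 + 1)) {
    cur <- substr(site_bad, kk, kk)
    mpos <- nchar(mir) - kk + 1
    repl <- setdiff(c("A", "C", "G", "T"),
                    c(comp[[mir_b[mpos]]], cur,
                      if (mir_b[mpos] == "G") "T" else character(0),
                      if (mir_b[mpos] == "T") "G" else character(0)))[1]
    substr(site_bad, kk, kk) <- repl
  }
  tx_bad <- paste0(rand_dna(30), site_bad, rand_dna(30))

  got <- predict_targets(c(mir1 = mir),
                         c(perfect = tx_perfect, one_mm = tx_mm,
                           bad = tx_bad), cutoff = 4)
  expect_setequal(got$gene_id, c("perfect", "one_mm"))
  expect_equal(got$penalty_score[got$gene_id == "perfect"], 0)
  expect_equal(got$penalty_score[got$gene_id == "one_mm"], 2)
  expect_equal(got$position[got$gene_id == "perfect"], 31L)
})

test_that("G:U wobbles cost half a mismatch", {
  mir <- strrep("G", 8)                 # all-G miRNA, site is all C
  tx <- paste0("AAAA", "CCCCCCTC", "AAAA")  # one C -> T: wobble vs miRNA G
  got <- predict_targets(c(m = mir), c(t = tx), cutoff = 4)
  # wobble faces miRNA position 2 (seed): 0.5 * 2 = 1
  expect_equal(got$penalty_score, 1)
})

test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hypergeom_p(100, 10, 20, 0), 1)
  expect_equal(hypergeom_p(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(hypergeom_p(50, 10, 50, 10), 1)   # every gene in the term
  expect_error(hypergeom_p(10, 5, 5, 6), "invalid")
  expect_error(hypergeom_p(10, 12, 5, 2), "invalid")
  # monotonicity: increasing m never increases p
  for (m in 1:4)
    expect_gte(hypergeom_p(40, 10, 8, m), hypergeom_p(40, 10, 8, m + 1))
  # independent library route
  expect_equal(hypergeom_p(200, 30, 25, 7),
               phyper(6, 25, 175, 30, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("enrichment tests each observed term and corrects over tested terms", {
  background <- sprintf("g%03d", 1:100)
  g2t <- data.frame(gene_id = c("g001", "g002", "g003"),
                    term_id = c("GO:1", "GO:2", "GO:2"))
  res <- enrich(g2t, background, targets = "g001")
  expect_equal(nrow(res), 1L)          # only the term with a target gene
  expect_equal(res$p_value, 0.01)
  expect_equal(res$p_corrected, 0.01)  # single tested term
  expect_true(res$significant)

  full <- enrich(g2t, background, targets = "g001", all_terms = TRUE)
  expect_equal(nrow(full), 2L)
  expect_equal(full$p_value[full$term_id == "GO:2"], 1)

  expect_error(enrich(g2t, character(0), "g001"), "background")
  expect_error(enrich(g2t, background, "not_there"), "subset")
})

test_that("random target sets are not spuriously enriched", {
  set.seed(51)
  background <- sprintf("g%03d", 1:100)
  terms <- sprintf("T%02d", 1:20)
  g2t <- do.call(rbind, lapply(terms, function(tm)
    data.frame(gene_id = sample(background, 12), term_id = tm)))
  frac_sig <- replicate(200, {
    res <- enrich(g2t, background, sample(background, 10))
    mean(res$significant)
  })
  expect_lte(mean(frac_sig), 0.05)
})

test_that("GO and KEGG code paths agree on identical term maps", {
  background <- sprintf("g%03d", 1:60)
  set.seed(52)
  map <- do.call(rbind, lapply(1:8, function(i)
    data.frame(gene_id = sample(background, 10),
               term_id = sprintf("X%d", i))))
  go_map <- transform(map, namespace = "biological_process")
  kegg_map <- transform(map, namespace = "Metabolism")
  targets <- sample(background, 12)
  a <- enrich(go_map, background, targets)
  b <- enrich(kegg_map, background, targets)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$p_corrected, b$p_corrected)
  expect_equal(a$term_id, b$term_id)
})
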