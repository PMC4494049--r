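test_that("e-value follows the Karlin-Altschul identities", {
  p <- search_profile("nucleotide")
  m <- 300; n <- 50000
  s1 <- log(p$k * m * n) / p$lambda
  expect_equal(evalue(s1, m, n, p), 1, tolerance = 1e-12)
  expect_equal(evalue(40, m, 2 * n, p), 2 * evalue(40, m, n, p))
  expect_true(all(diff(evalue(seq(10, 80, 5), m, n, p)) < 0))
})

test_that("self-match yields a full-length perfect nucleotide hit", {
  set.seed(31)
  db <- stbl(sprintf("d%d", 1:5),
             vapply(1:5, function(i) random_seq(300), character(1)))
  h <- search_nucleotide(db[2, ], db)
  expect_equal(h$subject_id[1], "d2")
  expect_equal(h$percent_identity[1], 100)
  expect_equal(h$alignment_length[1], 300L)
  expect_equal(c(h$query_start[1], h$query_end[1]), c(1L, 300L))
})

test_that("queries sharing no seed word produce no hits", {
  q <- stbl("q", strrep("AC", 60))
  db <- stbl("s", strrep("GT", 60))   # no shared 11-mer on either strand?
  # AC-repeat reverse complement is GT-repeat, so use a G/C-only subject
  db <- stbl("s", strrep("G", 120))
  expect_equal(nrow(search_nucleotide(q, db)), 0)
  expect_equal(nrow(search_nucleotide(q, db[0, ])), 0)
})

test_that("reverse-strand hits are normalised to forward coordinates", {
  set.seed(32)
  gene <- random_seq(240)
  q <- stbl("q", revcomp(substring(gene, 41, 200)))
  h <- search_nucleotide(q, stbl("g", gene))
  expect_equal(nrow(h), 1)
  expect_equal(h$query_frame, -1L)
  expect_lt(h$query_start, h$query_end)
  expect_equal(c(h$subject_start, h$subject_end), c(41L, 200L))
  expect_equal(h$percent_identity, 100)
})

test_that("built-in top-hit scores equal exhaustive DP (both modes)", {
  set.seed(33)
  pn <- exhaustive_nt_params()
  pt <- exhaustive_tx_params()
  for (i in 1:8) {
    a <- random_seq(sample(60:200, 1))
    b <- random_seq(sample(60:200, 1))
    q <- stbl("q", a); d <- stbl("s", b)
    h <- search_nucleotide(q, d, pn)
    expect_equal(if (nrow(h)) h$raw_score[1] else 0, sw_score_nt(a, b))
    ht <- search_translated(q, d, pt)
    expect_equal(if (nrow(ht)) ht$raw_score[1] else 0, sw_score_tx(a, b))
  }
})

test_that("translated search works at the protein, not nucleotide, level", {
  set.seed(34)
  genes <- generate_reference_transcriptome(3, c(300, 450), seed = 77)
  g <- genes$seq[1]
  # synonymously recode: swap codons for same-aa alternatives where possible
  syn <- c(CTT = "TTG", TCT = "AGC", CGT = "AGA", GGT = "GGC", GCT = "GCC",
           CCT = "CCG", ACT = "ACG", GTT = "GTG", TAT = "TAC", AAA = "AAG")
  codons <- substring(g, seq(1, nchar(g) - 2, 3), seq(3, nchar(g), 3))
  recoded <- ifelse(codons %in% names(syn), syn[codons], codons)
  g2 <- paste(recoded, collapse = "")
  expect_true(any(recoded != codons))
  h <- search_translated(stbl("q", g2), genes)
  expect_equal(h$subject_id[1], genes$id[1])
  expect_equal(h$percent_identity[1], 100)
  hn <- search_nucleotide(stbl("q", g2), genes,
                          exhaustive_nt_params(word_size = 11L))
  expect_lt(hn$percent_identity[1], 100)
})

test_that("reported hits satisfy every active threshold", {
  set.seed(35)
  p <- search_params("nucleotide", e_value_max = 1e-6,
                     min_percent_identity = 90,
                     min_alignment_length = 60L)
  genes <- generate_reference_transcriptome(5, c(300, 600), seed = 3)
  fr <- mutate_and_fragment(genes, divergence = 0.08,
                            n_fragments_per_gene = 4, seed = 4)
  h <- search_nucleotide(fr$fragments, genes, p)
  expect_true(all(h$e_value <= 1e-6))
  expect_true(all(h$percent_identity >= 90))
  expect_true(all(h$alignment_length >= 60))
})

test_that("search results are invariant under database order", {
  set.seed(36)
  genes <- generate_reference_transcriptome(6, c(300, 450), seed = 13)
  fr <- mutate_and_fragment(genes, divergence = 0.03,
                            n_fragments_per_gene = 2, seed = 14)
  h1 <- search_nucleotide(fr$fragments, genes)
  h2 <- search_nucleotide(fr$fragments, genes[sample(nrow(genes)), ])
  expect_equal(h1, h2)
})

test_that("best_match applies the ordered criteria with declared ties", {
  h <- dplyr::bind_rows(
    make_hit("q", "long_weak_e", e_value = 1e-5, alignment_length = 500),
    make_hit("q", "strong_e", e_value = 1e-20, alignment_length = 80))
  expect_equal(best_match(h)$subject_id, "strong_e")

  h2 <- dplyr::bind_rows(
    make_hit("q", "short", e_value = 1e-10, alignment_length = 120),
    make_hit("q", "long", e_value = 1e-10, alignment_length = 300))
  expect_equal(best_match(h2)$subject_id, "long")

  h3 <- dplyr::bind_rows(
    make_hit("q", "geneB"), make_hit("q", "geneA"))
  expect_equal(best_match(h3)$subject_id, "geneA")

  expect_null(best_match(h3[0, ]))
  expect_error(best_match(dplyr::bind_rows(make_hit("q1", "s"),
                                           make_hit("q2", "s"))),
               "single query")
})

test_that("an external engine's tabular output drives downstream modules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # outfmt-6 style file as an external engine would emit (12 columns)
  writeLines(c("q1\tg1\t97.50\t200\t5\t0\t1\t200\t1\t200\t1e-50\t180.1",
               "q1\tg2\t90.00\t150\t15\t0\t1\t150\t1\t150\t1e-20\t90.0",
               "q2\tg2\t95.00\t100\t5\t0\t1\t100\t1\t100\t1e-30\t120.0"),
             f)
  fwd <- read_hits_tabular(f)
  rev <- dplyr::bind_rows(make_hit("g1", "q1", e_value = 1e-48),
                          make_hit("g2", "q2", e_value = 1e-28))
  rb <- find_rbbh(fwd, rev)
  expect_equal(rb$query_id, c("q1", "q2"))
  expect_equal(rb$subject_id, c("g1", "g2"))
})
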