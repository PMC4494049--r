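test_that("exon and flank extraction honours orientation and edges", {
  set.seed(61)
  contig <- random_seq(20000)
  genome <- stbl("chr1", contig)
  ann <- tibble::tibble(
    contig = "chr1",
    start = c(5000L, 8000L, 8600L, 9200L, 201L),
    end = c(5999L, 8199L, 8799L, 9399L, 400L),
    strand = c("+", "-", "-", "-", "+"),
    transcript_id = c("tx1", "tx2", "tx2", "tx2", "tx3"),
    exon_index = c(0L, 2L, 1L, 0L, 0L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, gff)
  ex <- extract_exons_flanks(genome, gff, flank_len = 1000L)

  tx1 <- ex[ex$transcript_id == "tx1", ]
  expect_equal(nchar(tx1$seq[tx1$role == "exon"]), 1000)
  expect_equal(nchar(tx1$seq[tx1$role == "flank5"]), 1000)
  expect_equal(nchar(tx1$seq[tx1$role == "flank3"]), 1000)
  expect_equal(tx1$seq[tx1$role == "exon"], substring(contig, 5000, 5999))
  expect_equal(tx1$seq[tx1$role == "flank5"], substring(contig, 4000, 4999))

  # minus-strand transcript: exons in transcript order, reverse-complemented
  tx2 <- ex[ex$transcript_id == "tx2" & ex$role == "exon", ]
  expect_equal(tx2$exon_index, 0:2)
  expect_equal(tx2$seq[1], revcomp(substring(contig, 9200, 9399)))
  # its 5' flank lies to the right of the span on the genome
  f5 <- ex[ex$transcript_id == "tx2" & ex$role == "flank5", ]
  expect_equal(f5$seq, revcomp(substring(contig, 9400, 10399)))

  # flank truncation at the contig edge
  tx3f5 <- ex[ex$transcript_id == "tx3" & ex$role == "flank5", ]
  expect_equal(nchar(tx3f5$seq), 200)

  # coordinates outside the contig are an error naming the feature
  bad <- ann
  bad$end[1] <- 30000L
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(bad, gff2)
  expect_error(extract_exons_flanks(genome, gff2), "tx1")
})

test_that("projection accepts exact copies and rejects 25% divergence", {
  set.seed(62)
  exon <- random_seq(300)
  target <- stbl("scaf1", paste0(random_seq(500), exon, random_seq(500)))
  exrec <- tibble::tibble(record_id = "tx|exon0", transcript_id = "tx",
                          role = "exon", exon_index = 0L, contig = "ref",
                          start = 1L, end = 300L, strand = "+", seq = exon)
  pe <- project_exons(exrec, target)
  expect_equal(nrow(pe), 1)
  expect_equal(pe$percent_identity, 100)
  expect_equal(c(pe$start, pe$end), c(501L, 800L))
  expect_equal(pe$seq, exon)   # coordinate integrity

  # mutate exactly 25% of positions -> identity below the 80 threshold
  mutated <- exon
  pos <- sample(300, 75)
  for (p in pos) {
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substring(exon, p, p))[1]
  }
  target2 <- stbl("scaf1", paste0(random_seq(500), mutated, random_seq(500)))
  pe2 <- project_exons(exrec, target2, min_match_pct = 80)
  expect_equal(nrow(pe2), 0)
  # projection count is monotone non-increasing in the threshold
  pe2b <- project_exons(exrec, target2, min_match_pct = 60)
  expect_gte(nrow(pe2b), nrow(pe2))
})

test_that("overlapping projections of one transcript merge by union", {
  set.seed(63)
  gene <- random_seq(600)
  target <- stbl("scaf", paste0(random_seq(300), gene, random_seq(300)))
  # two "exons" overlapping by 10 nt on the genome
  exrecs <- tibble::tibble(
    record_id = c("tx|exon0", "tx|exon1"),
    transcript_id = "tx", role = "exon", exon_index = 0:1,
    contig = "ref", start = c(1L, 291L), end = c(300L, 600L),
    strand = "+",
    seq = c(substring(gene, 1, 300), substring(gene, 291, 600)))
  pe <- project_exons(exrecs, target)
  expect_equal(nrow(pe), 1)
  expect_equal(c(pe$start, pe$end), c(301L, 900L))
  expect_equal(pe$n_source_records, 2L)
  expect_equal(pe$seq, gene)
})

test_that("projection + reassembly round trip recovers transcripts exactly", {
  genes <- generate_reference_transcriptome(5, c(450, 900), seed = 64)
  g <- generate_annotated_genome(genes, seed = 65)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(g$annotation, gff)
  ex <- extract_exons_flanks(g$genome, gff, flank_len = 500L)
  pe <- project_exons(ex, g$genome)
  cons <- assemble_projected_transcripts(pe, genes)
  expect_setequal(names(cons), genes$id)
  for (gid in genes$id) {
    z <- cons[[gid]]
    emitted <- strsplit(if (z$kind == "one_to_many") z$anchor_residues else
      z$residues, "")[[1]]
    anchor <- strsplit(genes$seq[genes$id == gid], "")[[1]]
    covered <- emitted != "-"
    expect_true(all(emitted[covered] == anchor[covered]))
    expect_gte(mean(covered), 0.99)
  }
})

test_that("phylogeny filters keep >90 bp consensuses with matching anchors", {
  set.seed(66)
  mk <- function(name, len) {
    anchor <- stbl(name, random_seq(len + 40))
    member <- substring(anchor$seq, 1, len)
    build_consensus(stbl(paste0(name, "_m"), member), anchor,
                    make_hit(paste0(name, "_m"), name,
                             subject_start = 1, subject_end = len))
  }
  cs <- structure(list(GALGA_a = mk("GALGA_a", 90),
                       GALGA_b = mk("GALGA_b", 120),
                       PELSI_c = mk("PELSI_c", 120)),
                  class = "saurannot_consensus_set")
  plain <- filter_phylogeny_genome(cs)
  expect_setequal(names(plain), c("GALGA_b", "PELSI_c"))   # 90 bp removed
  gallus <- filter_phylogeny_genome(cs, require_anchor_prefix = "GALGA")
  expect_setequal(names(gallus), "GALGA_b")
})
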