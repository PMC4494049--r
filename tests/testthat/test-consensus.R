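test_that("grouping by anchor partitions queries", {
  bm <- dplyr::bind_rows(make_hit("q1", "g1"), make_hit("q2", "g1"),
                         make_hit("q3", "g2"))
  g <- group_by_anchor(bm)
  expect_equal(g$anchor_id, c("g1", "g1", "g2"))
  expect_equal(nrow(group_by_anchor(bm[0, ])), 0)

  set.seed(51)
  bm2 <- dplyr::bind_rows(lapply(1:100, function(i)
    make_hit(sprintf("q%03d", i), sprintf("g%02d", sample(12, 1)))))
  g2 <- group_by_anchor(bm2)
  expect_equal(nrow(g2), 100)
  expect_equal(sum(table(g2$anchor_id)), 100)
  expect_error(group_by_anchor(dplyr::bind_rows(make_hit("q", "a"),
                                                make_hit("q", "b"))),
               "one best match")
})

consensus_fixture <- function(anchor_len = 150, members) {
  # members: list of (start, end, seq) placed on the anchor
  anchor <- stbl("anchor1", random_seq(anchor_len))
  recs <- dplyr::bind_rows(lapply(names(members), function(id)
    stbl(id, members[[id]]$seq)))
  hits <- dplyr::bind_rows(lapply(names(members), function(id)
    make_hit(id, "anchor1",
             subject_start = members[[id]]$start,
             subject_end = members[[id]]$end,
             alignment_length = nchar(members[[id]]$seq))))
  list(anchor = anchor, records = recs, hits = hits)
}

test_that("a single member yields a verbatim one-to-one consensus", {
  set.seed(52)
  anchor <- stbl("g1", random_seq(400))
  member <- stbl("m1", substring(anchor$seq, 51, 200))
  h <- make_hit("m1", "g1", subject_start = 51, subject_end = 200)
  cons <- build_consensus(member, anchor, h)
  expect_s3_class(cons, "saurannot_consensus")
  expect_equal(cons$kind, "one_to_one")
  expect_equal(cons$name, "g1")
  expect_identical(cons$residues, member$seq)
  expect_equal(cons$coverage_fraction, 150 / 400)
})

test_that("overlapping members agreeing on the overlap tile the anchor", {
  set.seed(53)
  anchor <- stbl("g1", random_seq(150))
  m1 <- substring(anchor$seq, 1, 100)
  m2 <- substring(anchor$seq, 51, 150)
  recs <- stbl(c("m1", "m2"), c(m1, m2))
  hits <- dplyr::bind_rows(
    make_hit("m1", "g1", subject_start = 1, subject_end = 100),
    make_hit("m2", "g1", subject_start = 51, subject_end = 150))
  cons <- build_consensus(recs, anchor, hits)
  expect_equal(cons$kind, "one_to_many")
  expect_equal(cons$residues, anchor$seq)   # members equal the anchor here
  expect_equal(cons$coverage_fraction, 1)
})

test_that("the majority symbol wins and the anchor never votes", {
  set.seed(54)
  anchor <- stbl("g1", random_seq(120))
  base <- substring(anchor$seq, 1, 120)
  v1 <- base; v2 <- base; v3 <- base
  # column 60: two members vote A, one votes G; the anchor base is made T
  substr(v1, 60, 60) <- "A"; substr(v2, 60, 60) <- "A"
  substr(v3, 60, 60) <- "G"
  a2 <- anchor; substr(a2$seq, 60, 60) <- "T"
  recs <- stbl(c("m1", "m2", "m3"), c(v1, v2, v3))
  hits <- dplyr::bind_rows(lapply(c("m1", "m2", "m3"), function(id)
    make_hit(id, "g1", subject_start = 1, subject_end = 120)))
  cons <- build_consensus(recs, a2, hits)
  expect_equal(substring(cons$residues, 60, 60), "A")
})

test_that("reverse-strand members are oriented before voting", {
  set.seed(55)
  anchor <- stbl("g1", random_seq(200))
  m <- revcomp(substring(anchor$seq, 21, 180))
  recs <- stbl(c("f", "r"), c(substring(anchor$seq, 21, 180), m))
  hits <- dplyr::bind_rows(
    make_hit("f", "g1", subject_start = 21, subject_end = 180),
    make_hit("r", "g1", subject_start = 21, subject_end = 180,
             query_frame = -1L))
  cons <- build_consensus(recs, anchor, hits)
  expect_equal(substring(cons$residues, 21, 180),
               substring(anchor$seq, 21, 180))
})

test_that("per-column majority recount oracle holds on randomized cases", {
  set.seed(56)
  for (case in 1:25) {
    L <- sample(80:200, 1)
    anchor <- stbl("anchor", random_seq(L))
    k <- sample(2:5, 1)
    ivs <- lapply(seq_len(k), function(i) {
      s <- sample.int(L - 40, 1)
      e <- min(L, s + sample(40:120, 1))
      c(s, e)
    })
    seqs <- vapply(ivs, function(iv) {
      s <- substring(anchor$seq, iv[1], iv[2])
      # sprinkle a few substitutions
      n <- nchar(s)
      for (p in sample(n, max(1, n %/% 25))) {
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, character(1))
    ids <- sprintf("m%d", seq_len(k))
    recs <- stbl(ids, seqs)
    hits <- dplyr::bind_rows(lapply(seq_len(k), function(i)
      make_hit(ids[i], "anchor", subject_start = ivs[[i]][1],
               subject_end = ivs[[i]][2],
               e_value = 10^-sample(10:40, 1))))
    cons <- build_consensus(recs, anchor, hits)

    # recount: each emitted symbol must be modal among covering members
    votes <- matrix(NA_character_, nrow = k, ncol = L)
    for (i in seq_len(k)) {
      aln <- saurannot:::cpp_align_banded(
        saurannot:::encode_nt(seqs[i]),
        saurannot:::encode_nt(anchor$seq),
        saurannot:::nt_score_matrix(2L, -3L), 5L, 2L,
        -(nchar(seqs[i]) - 1L), L - 1L, TRUE)
      both <- aln$apos > 0 & aln$bpos > 0
      votes[i, aln$bpos[both]] <-
        strsplit(seqs[i], "")[[1]][aln$apos[both]]
    }
    emitted <- strsplit(cons$anchor_residues, "")[[1]]
    for (col in seq_len(L)) {
      col_votes <- votes[, col]
      col_votes <- col_votes[!is.na(col_votes)]
      if (length(col_votes) == 0) {
        expect_equal(emitted[col], "-")
      } else {
        tab <- table(col_votes)
        expect_true(emitted[col] %in% names(tab)[tab == max(tab)])
      }
    }
    # coverage + gap identity
    expect_equal(cons$coverage_fraction, mean(emitted != "-"))
    st <- coverage_stats(cons)
    n_end <- round(0.3 * L)
    w <- c(n_end, L - 2 * n_end, n_end)
    expect_equal(sum(w), L)
    gap_total <- sum(st$gap5 * w[1], st$gap_mid * w[2], st$gap3 * w[3])
    expect_equal(gap_total / L + cons$coverage_fraction, 1,
                 tolerance = 1e-9)
  }
})

test_that("k identical members reproduce the member on its interval", {
  set.seed(57)
  anchor <- stbl("a", random_seq(300))
  piece <- substring(anchor$seq, 101, 260)
  for (k in 2:4) {
    ids <- sprintf("m%d", 1:k)
    recs <- stbl(ids, rep(piece, k))
    hits <- dplyr::bind_rows(lapply(ids, function(id)
      make_hit(id, "a", subject_start = 101, subject_end = 260)))
    cons <- build_consensus(recs, anchor, hits)
    expect_equal(substring(cons$anchor_residues, 101, 260), piece)
    expect_equal(gsub("-", "", cons$anchor_residues), piece)
  }
})

test_that("region split statistics match direct construction", {
  set.seed(58)
  anchor <- stbl("a", random_seq(100))
  # member covering exactly the middle 40%
  mid <- substring(anchor$seq, 31, 70)
  recs <- stbl(c("m1", "m2"), c(mid, mid))
  hits <- dplyr::bind_rows(
    make_hit("m1", "a", subject_start = 31, subject_end = 70),
    make_hit("m2", "a", subject_start = 31, subject_end = 70))
  cons <- build_consensus(recs, anchor, hits)
  st <- coverage_stats(cons)
  expect_equal(st$gap5, 1)
  expect_equal(st$gap3, 1)
  expect_equal(st$gap_mid, 0)

  # fully covered consensus has no gaps anywhere
  full <- stbl(c("f1", "f2"), c(anchor$seq, anchor$seq))
  hits_f <- dplyr::bind_rows(
    make_hit("f1", "a", subject_start = 1, subject_end = 100),
    make_hit("f2", "a", subject_start = 1, subject_end = 100))
  stf <- coverage_stats(build_consensus(full, anchor, hits_f))
  expect_equal(c(stf$gap5, stf$gap_mid, stf$gap3), c(0, 0, 0))

  # degenerate anchors fall back to a single region with a warning
  tiny_anchor <- stbl("t", "ACG")
  tiny <- build_consensus(stbl("m", "ACG"), tiny_anchor,
                          make_hit("m", "t", subject_start = 1,
                                   subject_end = 3))
  expect_warning(coverage_stats(tiny), "single-region")
})

test_that("consensus sets tidy, glance and export consistently", {
  set.seed(59)
  anchors <- stbl(c("g1", "g2"), c(random_seq(200), random_seq(150)))
  m1 <- substring(anchors$seq[1], 1, 120)
  m2 <- substring(anchors$seq[1], 81, 200)
  m3 <- substring(anchors$seq[2], 1, 150)
  recs <- stbl(c("m1", "m2", "m3"), c(m1, m2, m3))
  bm <- dplyr::bind_rows(
    make_hit("m1", "g1", subject_start = 1, subject_end = 120),
    make_hit("m2", "g1", subject_start = 81, subject_end = 200),
    make_hit("m3", "g2", subject_start = 1, subject_end = 150))
  cs <- build_consensus_set(recs, anchors, bm)
  expect_s3_class(cs, "saurannot_consensus_set")
  td <- tidy(cs)
  expect_equal(nrow(td), 2)
  gl <- glance(cs)
  expect_equal(gl$n_consensus, 2)
  expect_equal(gl$n_one_to_many, 1)

  dir <- withr::local_tempdir()
  write_consensus_set(cs, dir)
  fa <- read_fasta(file.path(dir, "consensus.fasta"))
  expect_setequal(fa$id, c("g1", "g2"))
  expect_false(any(grepl("-", fa$seq, fixed = TRUE)))
  expect_true(file.exists(file.path(dir, "members.tsv")))
  expect_true(file.exists(file.path(dir, "stats.tsv")))
})

test_that("members without a hit against the anchor are a contract error", {
  anchor <- stbl("a", strrep("ACGT", 30))
  expect_error(build_consensus(stbl("m", "ACGTACGTAC"), anchor,
                               make_hit("other", "a")),
               "without a hit")
})
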