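test_that("reciprocal best hits follow the definition", {
  fwd <- dplyr::bind_rows(make_hit("q1", "s1", e_value = 1e-30),
                          make_hit("q2", "s2", e_value = 1e-30))
  rev <- dplyr::bind_rows(make_hit("s1", "q1", e_value = 1e-28),
                          make_hit("s2", "q9", e_value = 1e-28))
  rb <- find_rbbh(fwd, rev)
  expect_equal(rb$query_id, "q1")      # s2's best is q9, so q2 drops out
  expect_equal(rb$subject_id, "s1")
})

test_that("find_rbbh equals brute force on random 20x20 hit sets", {
  set.seed(41)
  qs <- sprintf("q%02d", 1:20)
  ss <- sprintf("s%02d", 1:20)
  mk <- function(a, b) {
    pairs <- expand.grid(x = a, y = b, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < 0.3
    pairs <- pairs[keep, ]
    dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      make_hit(pairs$x[i], pairs$y[i], e_value = 10^-sample(5:40, 1),
               alignment_length = sample(50:300, 1),
               percent_identity = round(stats::runif(1, 70, 100), 1))
    }))
  }
  for (rep in 1:3) {
    fwd <- mk(qs, ss)
    rev <- mk(ss, qs)
    rb <- find_rbbh(fwd, rev)
    # brute force over all 400 pairs
    expected <- list()
    for (q in qs) {
      bq <- best_match(fwd[fwd$query_id == q, ])
      if (is.null(bq)) next
      bs <- best_match(rev[rev$query_id == bq$subject_id, ])
      if (!is.null(bs) && bs$subject_id == q) {
        expected[[q]] <- bq$subject_id
      }
    }
    got <- stats::setNames(rb$subject_id, rb$query_id)
    want <- unlist(expected)
    if (is.null(want)) want <- stats::setNames(character(0), character(0))
    expect_equal(got[order(names(got))], want[order(names(want))])
    # symmetry under dataset swap
    rb_swap <- find_rbbh(rev, fwd)
    expect_setequal(paste(rb$query_id, rb$subject_id),
                    paste(rb_swap$subject_id, rb_swap$query_id))
  }
})

test_that("stage order is respected and early annotations finalise", {
  tp <- tiny_pipeline()
  # a query identical to a mtDNA stretch is classified at stage 0
  mito_seq <- tp$stages[[1]]$db$seq
  queries <- dplyr::bind_rows(
    stbl("mt_frag", substring(mito_seq, 100, 400)),
    tp$fragments[1:4, ],
    stbl("nohit", random_seq(150)))
  ann <- annotate_iterative(queries, tp$stages)
  expect_equal(nrow(ann), nrow(queries))
  expect_equal(ann$category[ann$query_id == "mt_frag"], "mtDNA")
  expect_equal(ann$stage_index[ann$query_id == "mt_frag"], 0L)
  expect_equal(ann$category[ann$query_id == "nohit"], "orphan")
  expect_true(is.na(ann$subject_id[ann$query_id == "nohit"]))
  # gene fragments are annotated against the cDNA stage
  frag_cat <- ann$category[ann$query_id %in% tp$fragments$id[1:4]]
  expect_true(all(frag_cat %in% c("cdna_rbbh", "cdna_hit")))
})

test_that("category counts conserve the input and partition law holds", {
  tp <- tiny_pipeline(orphan_rate = 0.2)
  ann <- annotate_iterative(tp$fragments, tp$stages)
  expect_equal(nrow(ann), nrow(tp$fragments))
  expect_equal(sort(ann$query_id), sort(tp$fragments$id))
  sets <- partition_datasets(ann)
  expect_true(all(sets$phylogeny %in% sets$annotation))
  orphans <- ann$query_id[ann$category == "orphan"]
  expect_length(intersect(sets$annotation, orphans), 0)
  # category <-> set membership examples
  expect_true(all(ann$rbbh[ann$category == "cdna_rbbh"]))
  expect_false(any(ann$rbbh[ann$category == "cdna_hit"]))
  hit_ids <- ann$query_id[ann$category == "cdna_hit"]
  expect_true(all(hit_ids %in% sets$annotation))
  expect_length(intersect(hit_ids, sets$phylogeny), 0)
  mt_ids <- ann$query_id[ann$category == "mtDNA"]
  expect_length(intersect(mt_ids, union(sets$annotation, sets$phylogeny)), 0)
})

test_that("adding a later stage never changes earlier categories", {
  tp <- tiny_pipeline()
  set.seed(45)
  taxon <- stbl("taxon_1", random_seq(500))
  ann1 <- annotate_iterative(tp$fragments, tp$stages)
  ann2 <- annotate_iterative(tp$fragments,
                             c(tp$stages,
                               list(annotation_stage("taxon_mrna",
                                                     "taxon", taxon))))
  non_orphan <- ann1$query_id[ann1$category != "orphan"]
  expect_equal(ann1[ann1$query_id %in% non_orphan, ],
               ann2[ann2$query_id %in% non_orphan, ])
})

test_that("zero-divergence fragments all recover their gene as RBBH or hit", {
  tp <- tiny_pipeline(n_genes = 6, divergence = 0, n_frag = 2)
  ann <- annotate_iterative(tp$fragments, tp$stages)
  truth <- tp$truth
  got <- ann$subject_id[match(truth$fragment_id, ann$query_id)]
  expect_equal(got, truth$true_gene_id)
  expect_true(all(ann$category %in% c("cdna_rbbh", "cdna_hit")))
})

test_that("the repeat hook labels heavily masked queries", {
  tp <- tiny_pipeline(n_genes = 3, n_frag = 1)
  set.seed(46)
  queries <- dplyr::bind_rows(tp$fragments,
                              stbl("repeatish", random_seq(200)))
  masker <- function(recs) ifelse(recs$id == "repeatish", 0.9, 0)
  ann <- annotate_iterative(queries, tp$stages, repeat_masker = masker)
  expect_equal(ann$category[ann$query_id == "repeatish"], "repeat")
})

test_that("invalid stage configurations are rejected", {
  expect_error(annotate_iterative(stbl("q", strrep("A", 100)), list()),
               "non-empty")
  expect_error(annotation_stage("mtDNA", "m", stbl("d", "ACGT"),
                                search_profile("translated")),
               "nucleotide-mode")
  expect_error(annotation_stage("bogus", "b", stbl("d", "ACGT")),
               "unknown stage kind")
})

test_that("cross-dataset comparison links lineage-specific orphans", {
  tp <- tiny_pipeline(n_genes = 4, n_frag = 2, seed = 301)
  # a "lineage-specific" coding gene absent from every reference database
  lineage <- generate_reference_transcriptome(1, c(700, 700), seed = 302)
  fragA <- substring(lineage$seq, 1, 420)
  fragB <- substring(lineage$seq, 281, 700)
  dsA_records <- dplyr::bind_rows(tp$fragments[1:3, ], stbl("A_ls", fragA))
  dsB_records <- dplyr::bind_rows(tp$fragments[4:6, ], stbl("B_ls", fragB))
  annA <- annotate_iterative(dsA_records, tp$stages)
  annB <- annotate_iterative(dsB_records, tp$stages)
  expect_equal(annA$category[annA$query_id == "A_ls"], "orphan")
  datasets <- list(A = list(records = dsA_records, annotations = annA),
                   B = list(records = dsB_records, annotations = annB))
  out <- cross_dataset_compare(datasets)
  a_row <- out$A$annotations[out$A$annotations$query_id == "A_ls", ]
  b_row <- out$B$annotations[out$B$annotations$query_id == "B_ls", ]
  expect_equal(a_row$category, "cross_species")
  expect_equal(b_row$category, "cross_species")
  expect_equal(a_row$subject_id, "B_ls")
  expect_equal(b_row$subject_id, "A_ls")
  expect_equal(a_row$reference_label, "B")
  expect_equal(b_row$reference_label, "A")

  # single dataset: identity
  one <- cross_dataset_compare(datasets["A"])
  expect_equal(one$A$annotations, annA)
})
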