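# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

stbl <- function(ids, seqs) {
  tibble::tibble(id = ids, desc = "", seq = toupper(seqs))
}

# a minimal hit row for ranking / RBBH tests
make_hit <- function(query_id, subject_id, e_value = 1e-10,
                     alignment_length = 100L, percent_identity = 98,
                     query_frame = 1L, subject_frame = 1L,
                     query_start = 1L, query_end = alignment_length,
                     subject_start = 1L, subject_end = alignment_length) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 percent_identity = percent_identity,
                 alignment_length = as.integer(alignment_length),
                 mismatches = 0L, gap_opens = 0L,
                 query_start = as.integer(query_start),
                 query_end = as.integer(query_end),
                 subject_start = as.integer(subject_start),
                 subject_end = as.integer(subject_end),
                 e_value = e_value, bit_score = -log2(e_value),
                 query_frame = as.integer(query_frame),
                 subject_frame = as.integer(subject_frame))
}

# exhaustive engine configurations: full band, no heuristics, permissive
# thresholds (used when comparing against full dynamic programming)
exhaustive_nt_params <- function(word_size = 4L) {
  search_params("nucleotide", e_value_max = 1e12,
                min_alignment_length = NULL, word_size = word_size,
                band_margin = 600L, min_seed_count = 1L)
}

exhaustive_tx_params <- function(word_size = 4L) {
  search_params("translated", e_value_max = 1e12, word_size = word_size,
                band_margin = 600L, min_seed_count = 1L,
                ungapped_gate = NULL)
}

# independent Smith-Waterman oracles via Biostrings::pairwiseAlignment
sw_score_nt <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = TRUE)
  max(0,
      Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = sm,
        gapOpening = 5, gapExtension = 2)),
      Biostrings::score(Biostrings::pairwiseAlignment(
        revcomp(a), b, type = "local", substitutionMatrix = sm,
        gapOpening = 5, gapExtension = 2)))
}

sw_score_tx <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- six_frame_translate(a)
  pb <- six_frame_translate(b)
  best <- 0
  for (fa in 1:6) {
    for (fb in 1:6) {
      if (nchar(pa[fa]) == 0 || nchar(pb[fb]) == 0) next
      s <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(pa[fa]), Biostrings::AAString(pb[fb]),
        type = "local", substitutionMatrix = BLOSUM62,
        gapOpening = 11, gapExtension = 1))
      best <- max(best, s)
    }
  }
  best
}

# identity over the shorter sequence via an independent semi-global
# alignment (pattern = shorter, global in pattern, local in subject)
fit_identity_oracle <- function(x, y) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = TRUE)
  ident <- function(p, s) {
    pa <- Biostrings::pairwiseAlignment(p, s, type = "global-local",
                                        substitutionMatrix = sm,
                                        gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(pa) / nchar(p)
  }
  max(ident(x, y), ident(revcomp(x), y))
}

# ready-made tiny annotation configuration over a synthetic reference set
tiny_pipeline <- function(n_genes = 8, divergence = 0, n_frag = 3,
                          orphan_rate = 0, seed = 101) {
  genes <- generate_reference_transcriptome(n_genes, c(450, 900),
                                            seed = seed)
  fr <- mutate_and_fragment(genes, divergence = divergence,
                            n_fragments_per_gene = n_frag,
                            frag_length_range = c(150L, 400L),
                            orphan_rate = orphan_rate, seed = seed + 1)
  set.seed(seed + 2)
  mito <- stbl("mt_genome", random_seq(800))
  ncrna <- stbl("ncrna_1", random_seq(300))
  stages <- list(
    annotation_stage("mtDNA", "mito", mito),
    annotation_stage("ncRNA", "ncrna_pool", ncrna),
    annotation_stage("cdna", "refA", genes))
  list(genes = genes, fragments = fr$fragments, truth = fr$truth,
       stages = stages)
}
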