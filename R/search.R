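# Built-in homology search engine: exact-word seeding, banded gapped
# extension with affine penalties, Karlin-Altschul e-values. Substitutes
# for an external BLAST-like engine; an outfmt-6 file from any engine can
# be dropped in via read_hits_tabular().

#' Search parameter sets
#'
#' Constructs the parameter bundle consumed by [search_nucleotide()] and
#' [search_translated()]. `lambda` and `k` are the Karlin-Altschul
#' statistical parameters matched to the scoring system; the defaults
#' correspond to +2/-3 with gap open 5 / extend 2 (nucleotide) and
#' BLOSUM62 with gap open 11 / extend 1 (translated).
#'
#' @param mode `"nucleotide"` or `"translated"`.
#' @param e_value_max Maximum e-value reported.
#' @param min_percent_identity Optional identity floor (0-100), or `NULL`.
#' @param min_alignment_length Optional minimum alignment length in
#'   columns (nucleotide columns in nucleotide mode, amino-acid columns in
#'   translated mode), or `NULL`.
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param matrix Protein scoring matrix name (only `"BLOSUM62"` is built in).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length g costs
#'   `gap_open + g * gap_extend`.
#' @param word_size Exact-word seed length in nucleotides. Translated
#'   searches seed on peptide words of `max(1, word_size %/% 3)` residues.
#' @param band_margin Half-width added around each seed diagonal cluster
#'   for the banded extension.
#' @param min_seed_count Minimum number of seeds on a single diagonal of a
#'   band before it is considered (two-hit style heuristic; defaults to 2
#'   in translated mode, 1 otherwise).
#' @param ungapped_gate Raw-score threshold on the best ungapped seed
#'   extension of a band before gapped extension is attempted, or `NULL`
#'   to disable the gate (default 40 in translated mode, disabled in
#'   nucleotide mode).
#' @param xdrop Score drop-off terminating the ungapped extension.
#' @param lambda,k Karlin-Altschul parameters (lambda > 0, K > 0).
#' @return An object of class `saurannot_search_params` (a named list).
#' @export
search_params <- function(mode = c("nucleotide", "translated"),
                          e_value_max = 1e-3,
                          min_percent_identity = NULL,
                          min_alignment_length = NULL,
                          match = 2L, mismatch = -3L,
                          matrix = "BLOSUM62",
                          gap_open = NULL, gap_extend = NULL,
                          word_size = 11L,
                          band_margin = 24L,
                          min_seed_count = NULL,
                          ungapped_gate = if (mode[1] == "translated") 40L else NULL,
                          xdrop = 20L,
                          lambda = NULL, k = NULL) {
  mode <- match.arg(mode)
  nt <- mode == "nucleotide"
  gap_open <- gap_open %||% if (nt) 5L else 11L
  gap_extend <- gap_extend %||% if (nt) 2L else 1L
  lambda <- lambda %||% if (nt) 0.625 else 0.267
  k <- k %||% if (nt) 0.41 else 0.041
  min_seed_count <- min_seed_count %||% if (nt) 1L else 2L
  stopifnot(e_value_max >= 0, lambda > 0, k > 0, word_size >= 1,
            is.null(min_percent_identity) ||
              (min_percent_identity >= 0 && min_percent_identity <= 100),
            is.null(min_alignment_length) || min_alignment_length >= 0)
  if (!identical(matrix, "BLOSUM62")) {
    rlang::abort("only the BLOSUM62 protein matrix is built in")
  }
  structure(list(mode = mode, e_value_max = e_value_max,
                 min_percent_identity = min_percent_identity,
                 min_alignment_length = min_alignment_length,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 band_margin = as.integer(band_margin),
                 min_seed_count = as.integer(min_seed_count),
                 ungapped_gate = if (is.null(ungapped_gate)) NULL else
                   as.integer(ungapped_gate),
                 xdrop = as.integer(xdrop),
                 lambda = lambda, k = k),
            class = "saurannot_search_params")
}

#' Named search profiles
#'
#' The profiles used by the annotation pipeline stages:
#' \describe{
#'   \item{nucleotide}{BLASTn-like stages (mtDNA, ncRNA): e-value 1e-3,
#'     minimum alignment length 50, no identity floor.}
#'   \item{translated}{tBLASTx-like stages (cDNA, UniGene-like, taxon
#'     mRNA, cross-dataset): e-value 1e-3.}
#'   \item{genome_validation}{stringent nucleotide profile: e-value 1e-5,
#'     minimum identity 90.}
#'   \item{projection_reassembly}{nucleotide profile with the minimum
#'     alignment length disabled so even the shortest potential exons
#'     align.}
#'   \item{completeness}{nucleotide profile: e-value 1e-5, no identity
#'     floor.}
#' }
#'
#' @param name Profile name.
#' @return A `saurannot_search_params` object.
#' @export
search_profile <- function(name = c("nucleotide", "translated",
                                    "genome_validation",
                                    "projection_reassembly",
                                    "completeness")) {
  switch(match.arg(name),
    nucleotide = search_params("nucleotide", e_value_max = 1e-3,
                               min_alignment_length = 50L),
    translated = search_params("translated", e_value_max = 1e-3),
    genome_validation = search_params("nucleotide", e_value_max = 1e-5,
                                      min_percent_identity = 90,
                                      min_alignment_length = 50L),
    projection_reassembly = search_params("nucleotide", e_value_max = 1e-3,
                                          min_alignment_length = NULL),
    completeness = search_params("nucleotide", e_value_max = 1e-5,
                                 min_alignment_length = NULL))
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` with raw sequence lengths as the
#' search-space dimensions (no edge-effect correction).
#'
#' @param score Raw alignment score.
#' @param query_len,db_len Query length and total database length.
#' @param params A `saurannot_search_params` object.
#' @return The expected number of chance alignments with score >= `score`.
#' @export
evalue <- function(score, query_len, db_len, params) {
  stopifnot(query_len >= 1, db_len >= 1)
  params$k * query_len * db_len * exp(-params$lambda * score)
}

bit_score <- function(score, params) {
  (params$lambda * score - log(params$k)) / log(2)
}

score_matrix_for <- function(params) {
  if (params$mode == "nucleotide") {
    nt_score_matrix(params$match, params$mismatch)
  } else {
    BLOSUM62_MATRIX
  }
}

# ---- engine ---------------------------------------------------------------

# shared driver: per query x subject, call the compiled seeded search over
# the relevant strand/frame representations, map coordinates back to the
# forward nucleotide strands, apply thresholds, rank.
run_search <- function(queries, database, params, translated) {
  assert_seq_tbl(queries, "queries")
  assert_seq_tbl(database, "database")
  if (nrow(queries) == 0 || nrow(database) == 0) return(empty_hits())
  smat <- score_matrix_for(params)
  seed_alpha <- if (translated) 20L else 4L
  word <- if (translated) max(1L, params$word_size %/% 3L) else params$word_size
  db_len <- sum(nchar(database$seq))

  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  enc_views <- function(s) {
    if (translated) {
      pep <- six_frame_translate(s)
      lapply(pep, encode_aa)
    } else {
      list(encode_nt(s), encode_nt(revcomp(s)))
    }
  }
  q_views <- lapply(queries$seq, enc_views)
  s_views <- lapply(database$seq, function(s) {
    if (translated) enc_views(s) else list(encode_nt(s))
  })
  q_len <- nchar(queries$seq)
  s_len <- nchar(database$seq)

  rows <- vector("list", nrow(queries) * nrow(database))
  nrow_out <- 0L
  for (qi in seq_len(nrow(queries))) {
    for (si in seq_len(nrow(database))) {
      r <- cpp_search_best(q_views[[qi]], s_views[[si]], smat,
                           params$gap_open, params$gap_extend, word,
                           seed_alpha, params$band_margin,
                           params$min_seed_count,
                           params$ungapped_gate %||% -1L, params$xdrop)
      if (!isTRUE(r$found)) next
      if (translated) {
        qf <- frames[r$ai]; sf <- frames[r$bi]
        qc <- pep_to_nt(qf, r$a_start, r$a_end, q_len[qi])
        sc <- pep_to_nt(sf, r$b_start, r$b_end, s_len[si])
      } else {
        qf <- if (r$ai == 1L) 1L else -1L
        sf <- 1L
        qc <- if (qf > 0) c(r$a_start, r$a_end) else
          c(q_len[qi] - r$a_end + 1L, q_len[qi] - r$a_start + 1L)
        sc <- c(r$b_start, r$b_end)
      }
      ev <- evalue(r$score, q_len[qi], db_len, params)
      pid <- 100 * r$matches / r$cols
      if (ev > params$e_value_max) next
      if (!is.null(params$min_percent_identity) &&
          pid < params$min_percent_identity) next
      if (!is.null(params$min_alignment_length) &&
          r$cols < params$min_alignment_length) next
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- list(
        query_id = queries$id[qi], subject_id = database$id[si],
        percent_identity = pid, alignment_length = r$cols,
        mismatches = r$mismatches, gap_opens = r$gap_opens,
        query_start = qc[1], query_end = qc[2],
        subject_start = sc[1], subject_end = sc[2],
        e_value = ev, bit_score = bit_score(r$score, params),
        query_frame = qf, subject_frame = sf, raw_score = r$score)
    }
  }
  if (nrow_out == 0) return(dplyr::mutate(empty_hits(), raw_score = double()))
  hits <- dplyr::bind_rows(rows[seq_len(nrow_out)])
  dplyr::arrange(hits, .data$query_id, .data$e_value,
                 dplyr::desc(.data$alignment_length),
                 dplyr::desc(.data$percent_identity), .data$subject_id)
}

# map 1-based peptide coordinates in a given frame back to 1-based
# inclusive coordinates on the forward nucleotide strand
pep_to_nt <- function(frame, ps, pe, nt_len) {
  f <- abs(frame)
  s <- f + 3L * (ps - 1L)
  e <- f + 3L * pe - 1L
  if (frame > 0) c(s, e) else c(nt_len - e + 1L, nt_len - s + 1L)
}

#' Nucleotide similarity search (BLASTn-like)
#'
#' Seeded local alignment of each query against each database sequence on
#' both strands. One best-scoring hit per query-subject pair is retained;
#' reverse-strand hits are normalised so query coordinates ascend and the
#' strand is carried in `query_frame` (+1/-1). Hits failing the active
#' thresholds in `params` are discarded, and hits are sorted per query by
#' the ordered criteria (e-value, alignment length, percent identity).
#'
#' @param queries,database Sequence tibbles.
#' @param params Search parameters; see [search_profile()].
#' @return A hit tibble (columns of [read_hits_tabular()] plus
#'   `raw_score`).
#' @export
search_nucleotide <- function(queries, database,
                              params = search_profile("nucleotide")) {
  stopifnot(params$mode == "nucleotide")
  run_search(queries, database, params, translated = FALSE)
}

#' Translated similarity search (tBLASTx-like)
#'
#' Compares all 36 pairs of the six conceptual translation frames of each
#' query and database sequence at the protein level (BLOSUM62). The
#' best-scoring frame pair per query-subject pair is reported with
#' coordinates on the forward nucleotide strands and the frames recorded;
#' `percent_identity` and `alignment_length` are at the amino-acid level.
#'
#' @inheritParams search_nucleotide
#' @return A hit tibble.
#' @export
search_translated <- function(queries, database,
                              params = search_profile("translated")) {
  stopifnot(params$mode == "translated")
  run_search(queries, database, params, translated = TRUE)
}

#' Best match under the ordered criteria
#'
#' Ranks the hits of one query lexicographically by smallest e-value, then
#' largest alignment length, then largest percent identity; remaining ties
#' break by `subject_id` ascending.
#'
#' @param hits Hit tibble whose rows share a single `query_id`.
#' @return A one-row tibble, or `NULL` for an empty hit list.
#' @export
best_match <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  if (length(unique(hits$query_id)) > 1) {
    rlang::abort("best_match() expects hits from a single query")
  }
  rank_hits(hits)[1, ]
}

rank_hits <- function(hits) {
  dplyr::arrange(hits, .data$e_value,
                 dplyr::desc(.data$alignment_length),
                 dplyr::desc(.data$percent_identity), .data$subject_id)
}

# best hit per query over a multi-query hit table
best_match_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    rank_hits() |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}
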