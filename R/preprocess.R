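# Preprocessing applied before annotation: short-sequence removal and
# CD-HIT-style greedy redundancy clustering keeping the longest
# representative.

#' Remove short sequences
#'
#' Drops every record of length `<= max_excluded_len` (so the default
#' removes sequences of 90 nucleotides or shorter and keeps 91-nt ones).
#' Input order is preserved.
#'
#' @param records Sequence tibble.
#' @param max_excluded_len Longest excluded length (inclusive).
#' @return The filtered sequence tibble.
#' @export
filter_short <- function(records, max_excluded_len = 90L) {
  assert_seq_tbl(records)
  records[nchar(records$seq) > max_excluded_len, , drop = FALSE]
}

#' Greedy redundancy clustering
#'
#' Incremental clustering in the style of CD-HIT-EST: records are sorted by
#' length (descending, ties by input order) and each record joins the first
#' existing cluster whose representative it matches at
#' `>= identity_threshold`, otherwise it founds a new cluster. Identity is
#' matching columns divided by the length of the shorter sequence, computed
#' from a semi-global alignment (the shorter sequence aligned end-to-end,
#' unaligned ends of the longer sequence free), with both orientations
#' tried. A q-gram prefilter skips alignments that provably cannot reach
#' the threshold: a record sharing fewer than
#' `(Ls - w + 1) - floor((1 - t) * Ls) * w` length-`w` words with a
#' representative (Ls = shorter length, t = threshold) cannot attain
#' identity t, since each mismatch destroys at most `w` words.
#'
#' @param records Sequence tibble (already length-filtered).
#' @param identity_threshold Minimum identity for cluster membership.
#' @param word_size Prefilter word length.
#' @return A list with `retained` (representatives, in input order) and
#'   `clusters` (tibble `representative_id`, `member_id`; members include
#'   the representative).
#' @export
cluster_redundant <- function(records, identity_threshold = 0.95,
                              word_size = 10L) {
  assert_seq_tbl(records)
  n <- nrow(records)
  if (n == 0) {
    return(list(retained = records,
                clusters = tibble::tibble(representative_id = character(),
                                          member_id = character())))
  }
  len <- nchar(records$seq)
  ord <- order(-len)                       # stable: ties keep input order
  smat <- nt_score_matrix(2L, -3L)

  # positional words for the candidate (multiset: repeated words count per
  # position, keeping the skip bound an upper bound on preserved words);
  # unique word sets for representatives
  kmers <- function(s, uniq = FALSE) {
    L <- nchar(s)
    if (L < word_size) return(character())
    starts <- seq_len(L - word_size + 1L)
    w <- substring(s, starts, starts + word_size - 1L)
    if (uniq) unique(w) else w
  }

  rep_idx <- integer(0)
  rep_enc <- list()
  rep_kmers <- list()
  assign_to <- integer(n)                  # index into rep_idx

  for (pos in ord) {
    s <- records$seq[pos]
    Ls <- len[pos]
    enc_f <- encode_nt(s)
    s_r <- revcomp(s)
    enc_r <- NULL
    km_f <- kmers(s)
    km_r <- kmers(s_r)
    thr <- (Ls - word_size + 1L) - floor((1 - identity_threshold) * Ls) * word_size
    placed <- FALSE
    for (ri in seq_along(rep_idx)) {
      if (thr > 0) {
        shared <- max(sum(km_f %in% rep_kmers[[ri]]),
                      sum(km_r %in% rep_kmers[[ri]]))
        if (shared < thr) next
      }
      need <- ceiling(identity_threshold * Ls)
      a_f <- cpp_align_fit(enc_f, rep_enc[[ri]], smat, 5L, 2L)
      ok <- isTRUE(a_f$found) && a_f$matches >= need
      if (!ok) {
        if (is.null(enc_r)) enc_r <- encode_nt(s_r)
        a_r <- cpp_align_fit(enc_r, rep_enc[[ri]], smat, 5L, 2L)
        ok <- isTRUE(a_r$found) && a_r$matches >= need
      }
      if (ok) {
        assign_to[pos] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, pos)
      ri <- length(rep_idx)
      rep_enc[[ri]] <- enc_f
      rep_kmers[[ri]] <- unique(km_f)
      assign_to[pos] <- ri
    }
  }

  keep <- sort(rep_idx)                    # representatives, input order
  clusters <- tibble::tibble(
    representative_id = records$id[rep_idx[assign_to]],
    member_id = records$id) |>
    dplyr::arrange(match(.data$representative_id, records$id[keep]))
  list(retained = records[keep, , drop = FALSE], clusters = clusters)
}
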