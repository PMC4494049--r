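# Anchored majority-rule consensus building. The database (anchor)
# sequence only defines the coordinate frame: it never contributes
# residues or votes.

#' Group queries by their best-match anchor
#'
#' @param best_matches Hit tibble with one (best) row per query.
#' @return A tibble `anchor_id`, `query_id`; each query appears once.
#' @export
group_by_anchor <- function(best_matches) {
  if (is.null(best_matches) || nrow(best_matches) == 0) {
    return(tibble::tibble(anchor_id = character(), query_id = character()))
  }
  if (anyDuplicated(best_matches$query_id)) {
    rlang::abort("group_by_anchor() expects one best match per query")
  }
  tibble::tibble(anchor_id = best_matches$subject_id,
                 query_id = best_matches$query_id)
}

#' Build one consensus sequence on an anchor
#'
#' A single member yields a one-to-one consensus whose residues are the
#' member's own sequence, named after the anchor. With several members,
#' each member is placed on anchor coordinates through its pairwise local
#' alignment to the anchor (members that hit the reverse strand are
#' reverse-complemented first); at every anchor column the consensus emits
#' the majority symbol among covering members, with ties broken in favour
#' of the member whose best match ranks higher under the ordered criteria.
#' Columns covered by no member emit `-`. Member insertions relative to
#' the anchor are retained only when a strict majority of the members
#' covering that junction carry an insertion there, in which case the
#' modal insertion is emitted.
#'
#' @param member_records Sequence tibble of the member queries.
#' @param anchor_record One-row sequence tibble (the anchor).
#' @param member_hits Hit tibble containing one row per member against the
#'   anchor (used for orientation and ranking).
#' @return An object of class `saurannot_consensus`.
#' @export
build_consensus <- function(member_records, anchor_record, member_hits) {
  assert_seq_tbl(member_records, "member_records", require_rows = TRUE)
  stopifnot(nrow(anchor_record) == 1)
  anchor_id <- anchor_record$id
  anchor_seq <- anchor_record$seq
  anchor_len <- nchar(anchor_seq)
  hits <- member_hits[member_hits$subject_id == anchor_id &
                        member_hits$query_id %in% member_records$id, ,
                      drop = FALSE]
  missing <- setdiff(member_records$id, hits$query_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("member(s) without a hit against anchor %s: %s",
                         anchor_id, paste(missing, collapse = ", ")))
  }
  hits <- rank_hits(hits) |> dplyr::distinct(.data$query_id, .keep_all = TRUE)

  if (nrow(member_records) == 1) {
    h <- hits[1, ]
    cov <- (abs(h$subject_end - h$subject_start) + 1) / anchor_len
    members <- tibble::tibble(
      member_id = member_records$id,
      anchor_start = min(h$subject_start, h$subject_end),
      anchor_end = max(h$subject_start, h$subject_end),
      strand = if (hit_strand(h) > 0) "+" else "-")
    return(new_consensus(anchor_id, "one_to_one", members,
                         residues = member_records$seq,
                         anchor_residues = NA_character_,
                         anchor_len = anchor_len,
                         coverage_fraction = cov))
  }

  # rank order of members (1 = best) for tie-breaking
  rank_of <- stats::setNames(seq_len(nrow(hits)), hits$query_id)
  smat <- nt_score_matrix(2L, -3L)
  anchor_enc <- encode_nt(anchor_seq)

  votes <- vector("list", nrow(member_records))    # per-member placements
  members <- vector("list", nrow(member_records))
  insertions <- list()                             # junction -> per member
  for (mi in seq_len(nrow(member_records))) {
    mid <- member_records$id[mi]
    h <- hits[hits$query_id == mid, ]
    strand <- hit_strand(h)
    s <- member_records$seq[mi]
    if (strand < 0) s <- revcomp(s)
    aln <- cpp_align_banded(encode_nt(s), anchor_enc, smat, 5L, 2L,
                            -(nchar(s) - 1L), anchor_len - 1L, TRUE)
    if (!isTRUE(aln$found)) {
      rlang::abort(sprintf("member %s does not align to anchor %s",
                           mid, anchor_id))
    }
    chars <- strsplit(s, "")[[1]]
    apos <- aln$apos; bpos <- aln$bpos
    both <- apos > 0 & bpos > 0
    votes[[mi]] <- list(pos = bpos[both], sym = chars[apos[both]],
                        rank = unname(rank_of[mid]),
                        span = c(aln$b_start, aln$b_end))
    members[[mi]] <- tibble::tibble(
      member_id = mid, anchor_start = aln$b_start, anchor_end = aln$b_end,
      strand = if (strand > 0) "+" else "-")
    # record insertions (member residues between two anchor columns)
    ins_run <- rle(bpos == 0)
    at <- cumsum(ins_run$lengths)
    start_idx <- at - ins_run$lengths + 1L
    for (ri in which(ins_run$values)) {
      i0 <- start_idx[ri]; i1 <- at[ri]
      if (i0 == 1 || i1 == length(bpos)) next     # terminal: not a junction
      junction <- bpos[i0 - 1L]                   # insert after this column
      key <- as.character(junction)
      insertions[[key]] <- c(insertions[[key]], stats::setNames(
        paste(chars[apos[i0:i1]], collapse = ""), mid))
    }
  }

  # per-column majority vote
  col_syms <- rep("-", anchor_len)
  pos_all <- unlist(lapply(votes, `[[`, "pos"))
  sym_all <- unlist(lapply(votes, `[[`, "sym"))
  rank_all <- unlist(lapply(votes, function(v) rep(v$rank, length(v$pos))))
  if (length(pos_all) > 0) {
    o <- order(pos_all, rank_all)
    pos_all <- pos_all[o]; sym_all <- sym_all[o]; rank_all <- rank_all[o]
    split_sym <- split(sym_all, pos_all)
    split_rank <- split(rank_all, pos_all)
    maj <- vapply(seq_along(split_sym), function(ii) {
      syms <- split_sym[[ii]]
      tabs <- table(syms)
      top <- names(tabs)[tabs == max(tabs)]
      if (length(top) == 1) return(top)
      # tie: symbol voted by the best-ranked member among tied symbols
      rk <- split_rank[[ii]]
      cand <- syms %in% top
      syms[cand][which.min(rk[cand])]
    }, character(1))
    col_syms[as.integer(names(split_sym))] <- maj
  }

  # majority-insertion rule per junction
  ins_at <- integer(0); ins_seq <- character(0)
  if (length(insertions) > 0) {
    spans <- do.call(rbind, lapply(votes, `[[`, "span"))
    for (key in names(insertions)) {
      j <- as.integer(key)
      covering <- sum(spans[, 1] <= j & spans[, 2] >= j + 1L)
      ins <- insertions[[key]]
      if (length(ins) * 2L > covering) {
        tabs <- table(ins)
        top <- names(tabs)[tabs == max(tabs)]
        if (length(top) > 1) {
          rk <- vapply(names(ins), function(m) unname(rank_of[m]), numeric(1))
          cand <- ins %in% top
          top <- ins[cand][which.min(rk[cand])]
        }
        ins_at <- c(ins_at, j); ins_seq <- c(ins_seq, top)
      }
    }
  }
  residues <- col_syms
  if (length(ins_at) > 0) {
    o <- order(ins_at, decreasing = TRUE)
    out <- paste(residues, collapse = "")
    for (t in o) {
      out <- paste0(substring(out, 1, ins_at[t]), ins_seq[t],
                    substring(out, ins_at[t] + 1L, nchar(out)))
    }
    residues_str <- out
  } else {
    residues_str <- paste(residues, collapse = "")
  }
  anchor_residues <- paste(col_syms, collapse = "")
  coverage <- sum(col_syms != "-") / anchor_len
  new_consensus(anchor_id, "one_to_many", dplyr::bind_rows(members),
                residues = residues_str, anchor_residues = anchor_residues,
                anchor_len = anchor_len, coverage_fraction = coverage)
}

hit_strand <- function(h) {
  sign(h$query_frame) * sign(h$subject_frame)
}

new_consensus <- function(name, kind, members, residues, anchor_residues,
                          anchor_len, coverage_fraction) {
  structure(list(name = name, kind = kind, members = members,
                 residues = residues, anchor_residues = anchor_residues,
                 anchor_len = anchor_len,
                 coverage_fraction = coverage_fraction),
            class = "saurannot_consensus")
}

#' @export
print.saurannot_consensus <- function(x, ...) {
  cat(sprintf("<consensus %s: %s, %d member(s), coverage %.2f>\n",
              x$name, x$kind, nrow(x$members), x$coverage_fraction))
  invisible(x)
}

#' Build a consensus set from best matches
#'
#' Groups queries by their best-match anchor and builds one consensus per
#' anchor.
#'
#' @param members Sequence tibble of all queries.
#' @param anchors Sequence tibble of the reference (anchor) sequences.
#' @param best_matches Hit tibble with one best row per query (see
#'   [best_match_per_query] semantics; extra hits are reduced to the best
#'   per query).
#' @return An object of class `saurannot_consensus_set` (a list of
#'   consensuses keyed by anchor id).
#' @export
build_consensus_set <- function(members, anchors, best_matches) {
  best <- best_match_per_query(best_matches)
  grouping <- group_by_anchor(best)
  anchors_used <- unique(grouping$anchor_id)
  out <- lapply(anchors_used, function(aid) {
    qids <- grouping$query_id[grouping$anchor_id == aid]
    build_consensus(members[match(qids, members$id), , drop = FALSE],
                    anchors[anchors$id == aid, , drop = FALSE],
                    best[best$query_id %in% qids, , drop = FALSE])
  })
  names(out) <- anchors_used
  structure(out, class = "saurannot_consensus_set")
}

#' Per-region coverage and gap statistics
#'
#' Splits the anchor into the 5' 30%, middle 40% and 3' 30% (first
#' `round(0.3 * L)` positions, last `round(0.3 * L)` positions, and the
#' remainder) and reports the gap fraction per region together with the
#' overall coverage fraction. Anchors shorter than 4 positions fall back
#' to a single region with a warning.
#'
#' @param consensus A `saurannot_consensus` object.
#' @return A one-row tibble: `anchor_id`, `kind`, `n_members`,
#'   `coverage_fraction`, `gap5`, `gap_mid`, `gap3`.
#' @export
coverage_stats <- function(consensus) {
  L <- consensus$anchor_len
  gaps <- if (consensus$kind == "one_to_one") {
    # the sole member covers its hit interval on the anchor
    covered <- logical(L)
    covered[consensus$members$anchor_start:consensus$members$anchor_end] <- TRUE
    !covered
  } else {
    strsplit(consensus$anchor_residues, "")[[1]] == "-"
  }
  if (L < 4) {
    rlang::warn("anchor shorter than 4 positions: single-region fallback")
    g <- mean(gaps)
    return(tibble::tibble(anchor_id = consensus$name, kind = consensus$kind,
                          n_members = nrow(consensus$members),
                          coverage_fraction = consensus$coverage_fraction,
                          gap5 = g, gap_mid = g, gap3 = g))
  }
  n_end <- round(0.3 * L)
  five <- seq_len(n_end)
  three <- seq.int(L - n_end + 1L, L)
  mid <- seq.int(n_end + 1L, L - n_end)
  tibble::tibble(anchor_id = consensus$name, kind = consensus$kind,
                 n_members = nrow(consensus$members),
                 coverage_fraction = consensus$coverage_fraction,
                 gap5 = mean(gaps[five]), gap_mid = mean(gaps[mid]),
                 gap3 = mean(gaps[three]))
}

#' @export
print.saurannot_consensus_set <- function(x, ...) {
  cat(sprintf("<consensus set: %d consensuses (%d one-to-many)>\n",
              length(x), sum(vapply(x, function(z)
                z$kind == "one_to_many", logical(1)))))
  invisible(x)
}

#' Tidy a consensus set into per-anchor statistics
#'
#' @param x A `saurannot_consensus_set`.
#' @param ... Unused.
#' @return A tibble with one row per consensus (see [coverage_stats()]).
#' @export
tidy.saurannot_consensus_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), coverage_stats))
}

#' One-row summary of a consensus set
#'
#' @param x A `saurannot_consensus_set`.
#' @param ... Unused.
#' @return A tibble: counts by kind, mean coverage.
#' @export
glance.saurannot_consensus_set <- function(x, ...) {
  kinds <- vapply(unclass(x), `[[`, character(1), "kind")
  cov <- vapply(unclass(x), `[[`, numeric(1), "coverage_fraction")
  tibble::tibble(n_consensus = length(x),
                 n_one_to_one = sum(kinds == "one_to_one"),
                 n_one_to_many = sum(kinds == "one_to_many"),
                 fraction_one_to_many =
                   if (length(x)) mean(kinds == "one_to_many") else NA_real_,
                 mean_coverage = if (length(x)) mean(cov) else NA_real_)
}

#' Export a consensus set
#'
#' Writes the consensus FASTA (uncovered anchor positions become `N` runs,
#' or are stripped with `strip_gaps = TRUE`), the member placement table
#' and the per-anchor statistics table.
#'
#' @param x A `saurannot_consensus_set`.
#' @param dir Output directory (created if needed).
#' @param strip_gaps Drop gap columns instead of writing `N`.
#' @return `dir`, invisibly.
#' @export
write_consensus_set <- function(x, dir, strip_gaps = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- seq_tbl(
    id = vapply(unclass(x), `[[`, character(1), "name"),
    desc = vapply(unclass(x), function(z)
      sprintf("%s n_members=%d", z$kind, nrow(z$members)), character(1)),
    seq = vapply(unclass(x), function(z) {
      s <- z$residues
      if (strip_gaps) gsub("-", "", s, fixed = TRUE)
      else gsub("-", "N", s, fixed = TRUE)
    }, character(1)))
  write_fasta(fasta, file.path(dir, "consensus.fasta"))
  memb <- dplyr::bind_rows(lapply(unclass(x), function(z)
    dplyr::mutate(z$members, anchor = z$name, .before = 1)))
  readr::write_tsv(memb, file.path(dir, "members.tsv"), progress = FALSE)
  readr::write_tsv(tidy.saurannot_consensus_set(x),
                   file.path(dir, "stats.tsv"), progress = FALSE)
  invisible(dir)
}

# consensus residues as a searchable sequence tibble (gaps -> N)
consensus_seq_tbl <- function(x, strip_gaps = FALSE) {
  seq_tbl(
    id = vapply(unclass(x), `[[`, character(1), "name"),
    seq = vapply(unclass(x), function(z) {
      if (strip_gaps) gsub("-", "", z$residues, fixed = TRUE)
      else gsub("-", "N", z$residues, fixed = TRUE)
    }, character(1)))
}

# non-gap length of a consensus
consensus_nongap_len <- function(z) {
  nchar(gsub("-", "", z$residues, fixed = TRUE))
}
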