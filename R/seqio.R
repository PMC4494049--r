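#' Read a FASTA file into a tibble
#'
#' Parses a (possibly line-wrapped) multi-record nucleotide FASTA file.
#' Residues are uppercased and RNA `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (remainder of the header) and `seq`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">tx1 example", "ACGTACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(seq_tbl())
  line_no <- which(keep)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    rlang::abort(sprintf(
      "malformed FASTA: line %d contains residues before any '>' header",
      line_no[1]))
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste0, character(1), collapse = "")
  seq <- character(length(id))
  seq[as.integer(names(seqs))] <- seqs
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    rlang::abort(sprintf("duplicate FASTA id(s): %s",
                         paste(dup, collapse = ", ")))
  }
  seq_tbl(id = id, desc = desc, seq = chartr("Uu", "Tt", seq))
}

#' Write sequences to a FASTA file
#'
#' @param records Sequence tibble (`id`, optional `desc`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  assert_seq_tbl(records)
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Remove adaptor contamination from sequences
#'
#' Every exact occurrence of an adaptor (in forward or reverse-complement
#' orientation) is excised. Terminal occurrences shorten a record; internal
#' occurrences split it into fragments suffixed `_1`, `_2`, ... Fragments
#' shorter than `min_retained_len` are dropped, so trimming composes with
#' the short-sequence filter applied before annotation.
#'
#' @param records Sequence tibble.
#' @param adaptors Character vector of adaptor sequences (each >= 8 nt).
#' @param min_retained_len Minimum fragment length retained (default 91,
#'   the complement of the <= 90 nt exclusion rule).
#' @return A sequence tibble (possibly empty).
#' @export
trim_adaptors <- function(records, adaptors, min_retained_len = 91L) {
  assert_seq_tbl(records)
  adaptors <- toupper(adaptors)
  if (any(nchar(adaptors) < 8)) {
    rlang::abort("all adaptors must be at least 8 nt long")
  }
  pats <- unique(c(adaptors, revcomp(adaptors)))
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    n <- nchar(s)
    ivs <- list()
    for (p in pats) {
      hits <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (hits[1] != -1L) {
        ivs[[length(ivs) + 1L]] <-
          IRanges::IRanges(as.integer(hits), width = nchar(p))
      }
    }
    if (length(ivs) == 0) {
      out[[i]] <- records[i, ]   # no adaptor: returned unchanged
      next
    }
    cut <- IRanges::reduce(do.call(c, ivs))
    keep <- IRanges::setdiff(IRanges::IRanges(1L, n), cut)
    keep <- keep[IRanges::width(keep) >= min_retained_len]
    if (length(keep) == 0) next
    frag_seq <- substring(s, IRanges::start(keep), IRanges::end(keep))
    frag_id <- if (length(keep) == 1 && IRanges::width(keep)[1] == n) {
      records$id[i]
    } else if (length(keep) == 1) {
      records$id[i]
    } else {
      paste0(records$id[i], "_", seq_along(keep))
    }
    out[[i]] <- seq_tbl(id = frag_id,
                        desc = rep(records$desc[i] %||% "", length(keep)),
                        seq = frag_seq)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) seq_tbl() else res
}

#' Six-frame conceptual translation
#'
#' Translates `residues` in all six reading frames under the standard
#' genetic code. Codons containing `N` translate to `X`; stop codons emit
#' `*` and do not truncate the peptide; a trailing partial codon is
#' dropped. Frames -1..-3 are read off the reverse complement.
#'
#' @param residues A single nucleotide string.
#' @return Named character vector of six peptides
#'   (`"+1" "+2" "+3" "-1" "-2" "-3"`).
#' @export
#' @examples
#' six_frame_translate("ATGAAATGA")
six_frame_translate <- function(residues) {
  stopifnot(length(residues) == 1)
  fwd <- toupper(residues)
  rev <- revcomp(fwd)
  out <- c("+1" = translate_frame(fwd, 1L),
           "+2" = translate_frame(fwd, 2L),
           "+3" = translate_frame(fwd, 3L),
           "-1" = translate_frame(rev, 1L),
           "-2" = translate_frame(rev, 2L),
           "-3" = translate_frame(rev, 3L))
  out
}

translate_frame <- function(s, offset) {
  n <- nchar(s) - offset + 1L
  n_codons <- n %/% 3L
  if (n_codons <= 0) return("")
  starts <- offset + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ---- BLAST tabular (outfmt 6 dialect) interchange ------------------------

HIT_COLS <- c("query_id", "subject_id", "percent_identity",
              "alignment_length", "mismatches", "gap_opens",
              "query_start", "query_end", "subject_start", "subject_end",
              "e_value", "bit_score", "query_frame", "subject_frame")

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 percent_identity = double(), alignment_length = integer(),
                 mismatches = integer(), gap_opens = integer(),
                 query_start = integer(), query_end = integer(),
                 subject_start = integer(), subject_end = integer(),
                 e_value = double(), bit_score = double(),
                 query_frame = integer(), subject_frame = integer())
}

#' Write search hits as BLAST-style tabular output
#'
#' The 12 standard "outfmt 6" columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) are written
#' tab-separated without a header, followed by a documented two-column
#' extension carrying the query and subject frames.
#'
#' @param hits Hit tibble as returned by [search_nucleotide()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tabular <- function(hits, path) {
  df <- as.data.frame(hits)[, HIT_COLS, drop = FALSE]
  df$percent_identity <- sprintf("%.2f", df$percent_identity)
  df$e_value <- sprintf("%.3g", df$e_value)
  df$bit_score <- sprintf("%.1f", df$bit_score)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read BLAST-style tabular hits
#'
#' Accepts the 12-column standard dialect (frames default to +1/+1, as
#' produced by external engines) or the 14-column dialect written by
#' [write_hits_tabular()].
#'
#' @param path Path to a tab-separated hit file.
#' @return A hit tibble.
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(12L, 14L)))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "line %d has %d tab-separated columns; expected 12 or 14",
      bad[1], nf[bad[1]]))
  }
  get <- function(k) vapply(fields, function(f) f[k], character(1))
  tibble::tibble(
    query_id = get(1), subject_id = get(2),
    percent_identity = as.double(get(3)),
    alignment_length = as.integer(get(4)),
    mismatches = as.integer(get(5)), gap_opens = as.integer(get(6)),
    query_start = as.integer(get(7)), query_end = as.integer(get(8)),
    subject_start = as.integer(get(9)), subject_end = as.integer(get(10)),
    e_value = as.double(get(11)), bit_score = as.double(get(12)),
    query_frame = ifelse(nf == 14L,
                         as.integer(vapply(fields, function(f)
                           f[13] %||% NA_character_, character(1))), 1L),
    subject_frame = ifelse(nf == 14L,
                           as.integer(vapply(fields, function(f)
                             f[14] %||% NA_character_, character(1))), 1L))
}
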