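# Exon-projection genome annotation: project reference exons plus 1,000
# base flanks onto an unannotated genome, extract matched segments
# ("potential exons"), and reassemble them into annotated transcript
# consensuses.

#' Extract exons and transcript flanks from a reference annotation
#'
#' For every transcript in the GFF3 annotation: one record per exon in
#' transcript orientation (minus-strand exons reverse-complemented,
#' `exon_index` 0-based 5' to 3'), plus the `flank_len` bases immediately
#' upstream (`flank5`) and downstream (`flank3`) of the transcript span,
#' truncated at contig edges.
#'
#' @param reference_genome Sequence tibble of the reference contigs.
#' @param gff3 Path to a GFF3 file or a `GRanges` of exon features with a
#'   transcript identifier (`Parent` or `transcript_id` attribute).
#' @param flank_len Flank length in bases (default 1000).
#' @return A tibble: `record_id`, `transcript_id`, `role`
#'   (`exon`/`flank5`/`flank3`), `exon_index`, `contig`, `start`, `end`
#'   (1-based inclusive on the contig), `strand`, `seq`.
#' @export
extract_exons_flanks <- function(reference_genome, gff3, flank_len = 1000L) {
  assert_seq_tbl(reference_genome, "reference_genome", require_rows = TRUE)
  gr <- if (is.character(gff3)) rtracklayer::import(gff3) else gff3
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) rlang::abort("no exon features in the annotation")
  meta <- S4Vectors::mcols(gr)
  tx <- if ("Parent" %in% names(meta)) {
    as.character(S4Vectors::unstrsplit(meta$Parent, ","))
  } else if ("transcript_id" %in% names(meta)) {
    as.character(meta$transcript_id)
  } else {
    rlang::abort("exon features carry neither Parent nor transcript_id")
  }
  contig <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  contig_len <- stats::setNames(nchar(reference_genome$seq),
                                reference_genome$id)
  bad <- which(!(contig %in% names(contig_len)) | start < 1 |
                 end > contig_len[contig])
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "exon feature outside its contig: %s:%d-%d (transcript %s)",
      contig[bad[1]], start[bad[1]], end[bad[1]], tx[bad[1]]))
  }
  genome_seq <- stats::setNames(reference_genome$seq, reference_genome$id)

  out <- list()
  for (t in unique(tx)) {
    i <- which(tx == t)
    tc <- contig[i[1]]
    tstrand <- strand[i[1]]
    o <- order(start[i])
    if (tstrand == "-") o <- rev(o)
    i <- i[o]                                # 5' -> 3' in transcript order
    n <- length(i)
    exon_seq <- substring(genome_seq[tc], start[i], end[i])
    if (tstrand == "-") exon_seq <- revcomp(exon_seq)
    rows <- tibble::tibble(
      record_id = sprintf("%s|exon%d", t, seq_len(n) - 1L),
      transcript_id = t, role = "exon", exon_index = seq_len(n) - 1L,
      contig = tc, start = start[i], end = end[i], strand = tstrand,
      seq = unname(exon_seq))
    span <- c(min(start[i]), max(end[i]))
    left <- c(max(1L, span[1] - flank_len), span[1] - 1L)
    right <- c(span[2] + 1L, min(contig_len[[tc]], span[2] + flank_len))
    flank <- function(iv, role) {
      if (iv[2] < iv[1]) return(NULL)
      s <- substring(genome_seq[tc], iv[1], iv[2])
      if (tstrand == "-") s <- revcomp(s)
      tibble::tibble(record_id = sprintf("%s|%s", t, role),
                     transcript_id = t, role = role, exon_index = NA_integer_,
                     contig = tc, start = iv[1], end = iv[2],
                     strand = tstrand, seq = unname(s))
    }
    if (tstrand == "+") {
      rows <- dplyr::bind_rows(flank(left, "flank5"), rows,
                               flank(right, "flank3"))
    } else {
      rows <- dplyr::bind_rows(flank(right, "flank5"), rows,
                               flank(left, "flank3"))
    }
    out[[t]] <- rows
  }
  dplyr::bind_rows(out)
}

#' Project exons and flanks onto a target genome
#'
#' Each exon/flank record is searched (nucleotide mode) against the target
#' genome; the best hit with percent identity `>= min_match_pct` yields a
#' potential exon covering the matched genome interval. Overlapping or
#' abutting projections from different records of the same transcript are
#' merged per contig and strand.
#'
#' @param exon_records Tibble from [extract_exons_flanks()].
#' @param target_genome Sequence tibble of the genome to annotate.
#' @param min_match_pct Minimum percent identity of an accepted
#'   projection (default 80).
#' @param params Nucleotide search parameters.
#' @return A tibble of potential exons: `pe_id`, `transcript_id`,
#'   `contig`, `start`, `end` (1-based inclusive), `strand`,
#'   `percent_identity` (best among merged members), `n_source_records`,
#'   `source_records`, `seq` (forward-strand genome substring).
#' @export
project_exons <- function(exon_records, target_genome, min_match_pct = 80,
                          params = search_profile("projection_reassembly")) {
  assert_seq_tbl(target_genome, "target_genome", require_rows = TRUE)
  queries <- seq_tbl(id = exon_records$record_id, seq = exon_records$seq)
  hits <- search_nucleotide(queries, target_genome, params)
  hits <- hits[hits$percent_identity >= min_match_pct, , drop = FALSE]
  best <- best_match_per_query(hits)
  if (nrow(best) == 0) {
    return(tibble::tibble(pe_id = character(), transcript_id = character(),
                          contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          percent_identity = double(),
                          n_source_records = integer(),
                          source_records = character(), seq = character()))
  }
  best$transcript_id <- exon_records$transcript_id[
    match(best$query_id, exon_records$record_id)]
  best$strand_chr <- ifelse(best$query_frame * best$subject_frame > 0,
                            "+", "-")
  genome_seq <- stats::setNames(target_genome$seq, target_genome$id)

  merged <- best |>
    dplyr::group_by(.data$transcript_id, .data$subject_id,
                    .data$strand_chr) |>
    dplyr::group_modify(function(d, key) {
      red <- IRanges::reduce(IRanges::IRanges(d$subject_start,
                                              d$subject_end))
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(d$subject_start, d$subject_end), red)
      grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
      tibble::tibble(
        start = IRanges::start(red),
        end = IRanges::end(red),
        percent_identity = vapply(seq_along(red), function(g)
          max(d$percent_identity[grp == g]), numeric(1)),
        n_source_records = vapply(seq_along(red), function(g)
          sum(grp == g), integer(1)),
        source_records = vapply(seq_along(red), function(g)
          paste(sort(d$query_id[grp == g]), collapse = ","), character(1)))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(contig = "subject_id", strand = "strand_chr") |>
    dplyr::arrange(.data$transcript_id, .data$contig, .data$start)
  merged$pe_id <- sprintf("pe|%s|%03d", merged$transcript_id,
                          as.integer(stats::ave(seq_len(nrow(merged)),
                                                merged$transcript_id,
                                                FUN = seq_along)))
  merged$seq <- unname(substring(genome_seq[merged$contig], merged$start,
                                 merged$end))
  dplyr::select(merged, "pe_id", "transcript_id", "contig", "start", "end",
                "strand", "percent_identity", "n_source_records",
                "source_records", "seq")
}

#' Assemble potential exons into transcript consensuses
#'
#' Each potential exon is searched against the coding cDNA database(s)
#' with the minimum alignment length disabled; potential exons whose best
#' match shares an anchor cDNA are assembled into an anchored consensus.
#' Potential exons without a cDNA hit are dropped.
#'
#' @param potential_exons Tibble from [project_exons()].
#' @param cdna_db Sequence tibble of reference coding cDNAs (for
#'   dual-reference annotation, bind the databases' rows together with
#'   distinct ids, e.g. prefixed by species).
#' @param params Nucleotide search parameters; `min_alignment_length` must
#'   be disabled.
#' @return A `saurannot_consensus_set`.
#' @export
assemble_projected_transcripts <- function(
    potential_exons, cdna_db,
    params = search_profile("projection_reassembly")) {
  if (!is.null(params$min_alignment_length)) {
    rlang::abort(
      "reassembly requires a profile with min_alignment_length disabled")
  }
  pes <- seq_tbl(id = potential_exons$pe_id, seq = potential_exons$seq)
  if (nrow(pes) == 0) {
    return(structure(list(), class = "saurannot_consensus_set"))
  }
  hits <- search_nucleotide(pes, cdna_db, params)
  build_consensus_set(pes, cdna_db, hits)
}

#' Filter projected consensuses for the phylogeny set
#'
#' Keeps consensuses whose non-gap length exceeds `min_len_exclusive`
#' (so 90-bp consensuses are removed and 91-bp ones kept) and, when
#' `require_anchor_prefix` is given, whose anchor name starts with that
#' prefix.
#'
#' @param consensuses A `saurannot_consensus_set`.
#' @param require_anchor_prefix Anchor-name prefix filter, or `NULL`.
#' @param min_len_exclusive Exclusive minimum non-gap length.
#' @return The filtered `saurannot_consensus_set`.
#' @export
filter_phylogeny_genome <- function(consensuses,
                                    require_anchor_prefix = NULL,
                                    min_len_exclusive = 90L) {
  keep <- vapply(unclass(consensuses), function(z) {
    ok <- consensus_nongap_len(z) > min_len_exclusive
    if (ok && !is.null(require_anchor_prefix)) {
      ok <- startsWith(z$name, require_anchor_prefix)
    }
    ok
  }, logical(1))
  structure(unclass(consensuses)[keep], class = "saurannot_consensus_set")
}

#' Write potential exons as BED
#'
#' 0-based half-open intervals; name is the source transcript, score the
#' projection percent identity.
#'
#' @param potential_exons Tibble from [project_exons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_exons_bed <- function(potential_exons, path) {
  df <- data.frame(chrom = potential_exons$contig,
                   chromStart = potential_exons$start - 1L,
                   chromEnd = potential_exons$end,
                   name = potential_exons$transcript_id,
                   score = round(potential_exons$percent_identity, 1),
                   strand = potential_exons$strand)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
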