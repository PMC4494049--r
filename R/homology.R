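# RBBH detection, the iterative multi-reference annotation driver, and the
# partition into the annotation and phylogeny data sets.

PHYLOGENY_CATEGORIES <- c("cdna_rbbh", "unigene_rbbh")
ANNOTATION_CATEGORIES <- c(PHYLOGENY_CATEGORIES,
                           "cdna_hit", "unigene_hit", "taxon_mrna")
ALL_CATEGORIES <- c("mtDNA", "ncRNA", ANNOTATION_CATEGORIES,
                    "cross_species", "repeat", "orphan")

STAGE_KINDS <- c(mtDNA = "nucleotide", ncRNA = "nucleotide",
                 cdna = "translated", unigene = "translated",
                 taxon_mrna = "translated")

#' Reciprocal best hits
#'
#' A pair `(q, s)` is reciprocal iff `s` is the best match of `q` in the
#' forward search and `q` is the best match of `s` in the reverse search,
#' both under the ordered criteria (e-value, alignment length, percent
#' identity, subject id).
#'
#' @param forward_hits Hits of queries against the database.
#' @param reverse_hits Hits of database sequences against the queries
#'   (same parameter profile).
#' @return A tibble with columns `query_id`, `subject_id` and the forward
#'   best-hit statistics.
#' @export
find_rbbh <- function(forward_hits, reverse_hits) {
  fwd <- best_match_per_query(forward_hits)
  rev <- best_match_per_query(reverse_hits)
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(fwd[0, ])
  rev_best <- stats::setNames(rev$subject_id, rev$query_id)
  keep <- !is.na(rev_best[fwd$subject_id]) &
    rev_best[fwd$subject_id] == fwd$query_id
  fwd[keep, , drop = FALSE]
}

#' Declare an annotation stage
#'
#' @param kind One of `"mtDNA"`, `"ncRNA"`, `"cdna"`, `"unigene"`,
#'   `"taxon_mrna"`. `mtDNA`/`ncRNA` stages search in nucleotide mode,
#'   the others in translated mode; cDNA and UniGene-like stages also run
#'   the reciprocal search.
#' @param label Reference species or collection name recorded in the
#'   annotation output.
#' @param db Reference sequence tibble (non-empty).
#' @param params Optional search parameter override; defaults to the
#'   profile matching the stage kind.
#' @return A stage declaration (named list).
#' @export
annotation_stage <- function(kind, label, db, params = NULL) {
  if (!kind %in% names(STAGE_KINDS)) {
    rlang::abort(sprintf("unknown stage kind '%s'", kind))
  }
  assert_seq_tbl(db, "db", require_rows = TRUE)
  params <- params %||% search_profile(
    if (STAGE_KINDS[[kind]] == "nucleotide") "nucleotide" else "translated")
  if (params$mode != STAGE_KINDS[[kind]]) {
    rlang::abort(sprintf(
      "stage '%s' (%s) requires %s-mode search parameters",
      label, kind, STAGE_KINDS[[kind]]))
  }
  list(kind = kind, label = label, db = db, params = params)
}

empty_annotation <- function() {
  tibble::tibble(query_id = character(), category = character(),
                 stage_index = integer(), reference_label = character(),
                 subject_id = character(), e_value = double(),
                 percent_identity = double(), alignment_length = integer(),
                 subject_start = integer(), subject_end = integer(),
                 query_frame = integer(), subject_frame = integer(),
                 rbbh = logical())
}

annotation_row <- function(query_id, category, stage_index = NA_integer_,
                           reference_label = NA_character_, hit = NULL,
                           rbbh = FALSE) {
  tibble::tibble(
    query_id = query_id, category = category,
    stage_index = as.integer(stage_index),
    reference_label = reference_label,
    subject_id = if (is.null(hit)) NA_character_ else hit$subject_id,
    e_value = if (is.null(hit)) NA_real_ else hit$e_value,
    percent_identity = if (is.null(hit)) NA_real_ else hit$percent_identity,
    alignment_length = if (is.null(hit)) NA_integer_ else hit$alignment_length,
    subject_start = if (is.null(hit)) NA_integer_ else hit$subject_start,
    subject_end = if (is.null(hit)) NA_integer_ else hit$subject_end,
    query_frame = if (is.null(hit)) NA_integer_ else hit$query_frame,
    subject_frame = if (is.null(hit)) NA_integer_ else hit$subject_frame,
    rbbh = rbbh)
}

#' Iterative multi-reference annotation
#'
#' Runs the configured stages in order over preprocessed queries. A query
#' annotated at stage k is excluded from all later stages. Consecutive
#' stages of the same reciprocal kind (cDNA or UniGene-like, one stage per
#' reference species, most closely related first) form one iteration
#' group: a query with a reciprocal best hit at species i finalises
#' immediately and is not searched at species i+1, while a query with only
#' a one-way hit is still tried at the remaining species and finalised at
#' the end of the group with its best-ranked hit (category `*_hit`).
#' Queries exhausting all stages (and the optional repeat-masking hook)
#' are labelled `orphan`.
#'
#' @param queries Sequence tibble (preprocessed with [filter_short()] and
#'   [cluster_redundant()]).
#' @param stages Non-empty list of [annotation_stage()] declarations.
#' @param repeat_masker Optional function taking a sequence tibble and
#'   returning the masked fraction (0-1) per record, in order; records
#'   with masked fraction `>= repeat_threshold` are labelled `repeat`.
#' @param repeat_threshold Masked-fraction threshold for the repeat label.
#' @return One `AnnotationRecord` row per input query: `query_id`,
#'   `category`, `stage_index` (0-based stage order; `NA` for orphans),
#'   `reference_label`, `subject_id`, hit statistics and `rbbh`.
#' @export
annotate_iterative <- function(queries, stages, repeat_masker = NULL,
                               repeat_threshold = 0.5) {
  assert_seq_tbl(queries, "queries")
  if (length(stages) == 0) rlang::abort("the stage list must be non-empty")
  for (st in stages) {
    if (!all(c("kind", "label", "db", "params") %in% names(st))) {
      rlang::abort("each stage must come from annotation_stage()")
    }
  }
  records <- list()
  remaining <- queries

  # group consecutive stages of the same reciprocal kind
  kinds <- vapply(stages, function(s) s$kind, character(1))
  rbbh_kind <- kinds %in% c("cdna", "unigene")
  grp <- cumsum(c(TRUE, kinds[-1] != kinds[-length(kinds)] |
                    !rbbh_kind[-1] | !rbbh_kind[-length(kinds)]))

  for (g in unique(grp)) {
    if (nrow(remaining) == 0) break
    idx <- which(grp == g)
    kind <- kinds[idx[1]]
    if (!rbbh_kind[idx[1]]) {
      st <- stages[[idx[1]]]
      searcher <- if (st$params$mode == "nucleotide") search_nucleotide
                  else search_translated
      hits <- searcher(remaining, st$db, st$params)
      best <- best_match_per_query(hits)
      if (nrow(best) > 0) {
        for (r in seq_len(nrow(best))) {
          records[[length(records) + 1L]] <- annotation_row(
            best$query_id[r],
            category = if (kind == "taxon_mrna") "taxon_mrna" else kind,
            stage_index = idx[1] - 1L, reference_label = st$label,
            hit = best[r, ])
        }
        remaining <- remaining[!remaining$id %in% best$query_id, ,
                               drop = FALSE]
      }
    } else {
      group_remaining <- remaining
      pending <- empty_hits()
      pending$stage_index <- integer()
      pending$reference_label <- character()
      for (i in idx) {
        if (nrow(group_remaining) == 0) break
        st <- stages[[i]]
        fwd <- search_translated(group_remaining, st$db, st$params)
        if (nrow(fwd) == 0) next
        rev <- search_translated(st$db, group_remaining, st$params)
        rb <- find_rbbh(fwd, rev)
        if (nrow(rb) > 0) {
          for (r in seq_len(nrow(rb))) {
            records[[length(records) + 1L]] <- annotation_row(
              rb$query_id[r], category = paste0(kind, "_rbbh"),
              stage_index = i - 1L, reference_label = st$label,
              hit = rb[r, ], rbbh = TRUE)
          }
          group_remaining <- group_remaining[
            !group_remaining$id %in% rb$query_id, , drop = FALSE]
        }
        oneway <- best_match_per_query(fwd)
        oneway <- oneway[!oneway$query_id %in% rb$query_id, , drop = FALSE]
        if (nrow(oneway) > 0) {
          oneway$stage_index <- i - 1L
          oneway$reference_label <- st$label
          pending <- dplyr::bind_rows(pending, oneway)
        }
      }
      pending <- pending[pending$query_id %in% group_remaining$id, ,
                         drop = FALSE]
      if (nrow(pending) > 0) {
        pend_best <- pending |>
          rank_hits() |>
          dplyr::distinct(.data$query_id, .keep_all = TRUE)
        for (r in seq_len(nrow(pend_best))) {
          records[[length(records) + 1L]] <- annotation_row(
            pend_best$query_id[r], category = paste0(kind, "_hit"),
            stage_index = pend_best$stage_index[r],
            reference_label = pend_best$reference_label[r],
            hit = pend_best[r, ])
        }
        group_remaining <- group_remaining[
          !group_remaining$id %in% pend_best$query_id, , drop = FALSE]
      }
      remaining <- group_remaining
    }
  }

  # repeat-masking hook (built-in default: no-op)
  if (!is.null(repeat_masker) && nrow(remaining) > 0) {
    frac <- repeat_masker(remaining)
    stopifnot(length(frac) == nrow(remaining))
    masked <- which(frac >= repeat_threshold)
    for (r in masked) {
      records[[length(records) + 1L]] <- annotation_row(
        remaining$id[r], category = "repeat",
        stage_index = length(stages), reference_label = "repeat_hook")
    }
    if (length(masked) > 0) {
      remaining <- remaining[-masked, , drop = FALSE]
    }
  }

  for (r in seq_len(nrow(remaining))) {
    records[[length(records) + 1L]] <- annotation_row(
      remaining$id[r], category = "orphan")
  }
  out <- dplyr::bind_rows(records)
  out[match(queries$id, out$query_id), , drop = FALSE]
}

#' Compare orphans across datasets
#'
#' Each dataset's orphans are searched in translated mode against every
#' other dataset's annotated and orphan sequences. Orphans with a match
#' are re-categorised `cross_species`, with the partner dataset recorded
#' in `reference_label`; when an orphan's best match is itself an orphan
#' of the partner dataset, the partner record is marked reciprocally, so
#' a pair discovered once is recorded for both.
#'
#' @param datasets Named list; each element a list with `records`
#'   (sequence tibble) and `annotations` (tibble from
#'   [annotate_iterative()]).
#' @param params Translated search parameters.
#' @return The input list with updated `annotations` elements.
#' @export
cross_dataset_compare <- function(datasets,
                                  params = search_profile("translated")) {
  if (length(datasets) < 2) return(datasets)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    rlang::abort("`datasets` must be a named list")
  }
  orphan_ids <- lapply(datasets, function(d) {
    d$annotations$query_id[d$annotations$category == "orphan"]
  })
  annotated_ids <- lapply(datasets, function(d) {
    sets <- partition_datasets(d$annotations)
    sets$annotation
  })
  new_cat <- list()
  for (a in names(datasets)) {
    qa <- datasets[[a]]$records
    qa <- qa[qa$id %in% orphan_ids[[a]], , drop = FALSE]
    if (nrow(qa) == 0) next
    pooled <- list()
    for (b in setdiff(names(datasets), a)) {
      tb <- datasets[[b]]$records
      tb <- tb[tb$id %in% c(annotated_ids[[b]], orphan_ids[[b]]), ,
               drop = FALSE]
      if (nrow(tb) == 0) next
      h <- search_translated(qa, tb, params)
      if (nrow(h) > 0) {
        h$partner <- b
        pooled[[b]] <- h
      }
    }
    if (length(pooled) == 0) next
    best <- dplyr::bind_rows(pooled) |>
      rank_hits() |>
      dplyr::distinct(.data$query_id, .keep_all = TRUE)
    for (r in seq_len(nrow(best))) {
      new_cat[[a]][[best$query_id[r]]] <- list(
        partner = best$partner[r], subject = best$subject_id[r],
        hit = best[r, ])
      # reciprocal bookkeeping for orphan-orphan pairs
      b <- best$partner[r]
      s <- best$subject_id[r]
      if (s %in% orphan_ids[[b]] && is.null(new_cat[[b]][[s]])) {
        new_cat[[b]][[s]] <- list(partner = a, subject = best$query_id[r],
                                  hit = NULL)
      }
    }
  }
  for (a in names(datasets)) {
    upd <- new_cat[[a]]
    if (is.null(upd) || length(upd) == 0) next
    ann <- datasets[[a]]$annotations
    for (qid in names(upd)) {
      i <- which(ann$query_id == qid)
      ann$category[i] <- "cross_species"
      ann$reference_label[i] <- upd[[qid]]$partner
      ann$subject_id[i] <- upd[[qid]]$subject
      h <- upd[[qid]]$hit
      if (!is.null(h)) {
        ann$e_value[i] <- h$e_value
        ann$percent_identity[i] <- h$percent_identity
        ann$alignment_length[i] <- h$alignment_length
      }
    }
    datasets[[a]]$annotations <- ann
  }
  datasets
}

#' Partition annotation records into the annotation and phylogeny sets
#'
#' The phylogeny set holds reciprocal best hits against coding cDNA and
#' UniGene-like databases; the annotation set additionally includes the
#' one-way cDNA/UniGene matches and the taxon mRNA matches. Mitochondrial,
#' ncRNA, cross-species, repeat and orphan records belong to neither.
#'
#' @param records Tibble from [annotate_iterative()].
#' @return A list with character vectors `annotation` and `phylogeny`
#'   (query ids).
#' @export
partition_datasets <- function(records) {
  list(
    annotation = records$query_id[records$category %in% ANNOTATION_CATEGORIES],
    phylogeny = records$query_id[records$category %in% PHYLOGENY_CATEGORIES])
}
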