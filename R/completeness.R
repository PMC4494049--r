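# Completeness assessment against reference gene sets and the
# annotated-vs-orphan comparison.

#' Assess annotation completeness against a reference gene set
#'
#' Each reference sequence is searched (nucleotide mode) against the
#' consensus sequences. A reference is *found* when at least one hit
#' passes the thresholds; its coverage is the union of all its passing
#' hit intervals on the reference divided by the reference length.
#'
#' @param reference Sequence tibble of the reference gene set (non-empty).
#' @param consensuses Sequence tibble of consensus sequences (e.g. from
#'   [write_consensus_set()] output or [read_fasta()]), or a
#'   `saurannot_consensus_set`.
#' @param params Search parameters (default: the stringent completeness
#'   profile, e-value 1e-5).
#' @param label Reference-set label recorded in the report.
#' @return An object of class `saurannot_completeness`: a list with the
#'   one-row `report` tibble (`reference_set`, `n_reference`, `n_found`,
#'   `fraction_found`, `mean_coverage`, `no_hits` flag) and the
#'   per-reference `detail` tibble.
#' @export
assess_completeness <- function(reference, consensuses,
                                params = search_profile("completeness"),
                                label = "reference") {
  assert_seq_tbl(reference, "reference", require_rows = TRUE)
  if (inherits(consensuses, "saurannot_consensus_set")) {
    consensuses <- consensus_seq_tbl(consensuses)
  }
  assert_seq_tbl(consensuses, "consensuses")
  hits <- if (nrow(consensuses) == 0) empty_hits() else
    search_nucleotide(reference, consensuses, params)
  ref_len <- nchar(reference$seq)
  cov <- vapply(seq_len(nrow(reference)), function(i) {
    h <- hits[hits$query_id == reference$id[i], , drop = FALSE]
    if (nrow(h) == 0) return(NA_real_)
    union_width(h$query_start, h$query_end) / ref_len[i]
  }, numeric(1))
  detail <- tibble::tibble(reference_id = reference$id,
                           length = ref_len,
                           found = !is.na(cov),
                           coverage = cov)
  n_found <- sum(detail$found)
  report <- tibble::tibble(
    reference_set = label,
    n_reference = nrow(reference),
    n_found = n_found,
    fraction_found = n_found / nrow(reference),
    mean_coverage = if (n_found > 0) mean(cov, na.rm = TRUE) else 0,
    no_hits = n_found == 0)
  structure(list(report = report, detail = detail),
            class = "saurannot_completeness")
}

#' @export
print.saurannot_completeness <- function(x, ...) {
  cat(sprintf("<completeness %s: %d/%d found (%.1f%%), mean coverage %.2f>\n",
              x$report$reference_set, x$report$n_found,
              x$report$n_reference, 100 * x$report$fraction_found,
              x$report$mean_coverage))
  invisible(x)
}

#' @export
tidy.saurannot_completeness <- function(x, ...) x$detail

#' @export
glance.saurannot_completeness <- function(x, ...) x$report

#' Compare annotated and orphan sequence statistics
#'
#' Welch's unequal-variance two-sample t-test on a per-sequence quality
#' statistic (typically length or coverage) of annotated sequences versus
#' orphans.
#'
#' @param annotated,orphan Numeric vectors (each of length >= 2 with
#'   positive variance).
#' @return A one-row tibble: group means, their difference, `statistic`
#'   (t), `df` (Welch-Satterthwaite), `p.value` (two-sided), confidence
#'   bounds, `method`.
#' @export
compare_annotated_vs_orphans <- function(annotated, orphan) {
  if (length(annotated) < 2 || length(orphan) < 2) {
    rlang::abort("both samples must contain at least two values")
  }
  if (stats::var(annotated) == 0 || stats::var(orphan) == 0) {
    rlang::abort("degenerate (zero) variance in one of the samples")
  }
  tt <- stats::t.test(annotated, orphan, var.equal = FALSE)
  tibble::tibble(mean_annotated = unname(tt$estimate[1]),
                 mean_orphan = unname(tt$estimate[2]),
                 difference = unname(tt$estimate[1] - tt$estimate[2]),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p.value = tt$p.value,
                 conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
                 method = "Welch two-sample t-test")
}
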