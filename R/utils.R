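# Internal sequence helpers shared across modules.

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`. `N` (and any character outside `ACGT`) complements
#' to `N`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ATGCN")
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# 0-based integer encoding for the compiled aligner
encode_nt <- function(s) {
  unname(NT_LOOKUP[utf8ToInt(s) + 1L])
}

encode_aa <- function(s) {
  unname(AA_LOOKUP[utf8ToInt(s) + 1L])
}

# Sequence collections are plain tibbles: id, desc, seq. Construct/validate.
seq_tbl <- function(id = character(), desc = character(), seq = character()) {
  if (length(desc) == 0 && length(id) > 0) desc <- rep("", length(id))
  tibble::tibble(id = as.character(id), desc = as.character(desc),
                 seq = toupper(as.character(seq)))
}

assert_seq_tbl <- function(x, arg = "records", require_rows = FALSE) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    rlang::abort(sprintf(
      "`%s` must be a data frame with at least columns `id` and `seq`.", arg))
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    rlang::abort(sprintf("duplicate sequence id(s) in `%s`: %s", arg,
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (require_rows && nrow(x) == 0) {
    rlang::abort(sprintf("`%s` must contain at least one sequence.", arg))
  }
  invisible(x)
}

# interval union length on one sequence axis (1-based inclusive intervals)
union_width <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
}

`%||%` <- rlang::`%||%`
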