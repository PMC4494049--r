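# Pipeline driver: YAML configuration, the end-to-end annotation run, and
# a reproducible JSON run manifest.

#' Read and validate a pipeline configuration
#'
#' The YAML file declares the ordered annotation stages and optional
#' settings:
#' ```yaml
#' seed: 1
#' min_len: 91
#' identity: 0.95
#' stages:
#'   - kind: mtDNA
#'     label: mito
#'     fasta: refs/mtdna.fasta
#'   - kind: cdna
#'     label: speciesA
#'     fasta: refs/speciesA_cdna.fasta
#' ```
#' Stage kinds and their search modes are fixed as in
#' [annotation_stage()]; per-stage `profile` may name any
#' [search_profile()].
#'
#' @param path Path to a YAML configuration.
#' @return A validated config list (stages carry loaded databases).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$stages) || length(cfg$stages) == 0) {
    rlang::abort("config declares no stages")
  }
  base <- dirname(normalizePath(path))
  stages <- lapply(cfg$stages, function(st) {
    for (field in c("kind", "label", "fasta")) {
      if (is.null(st[[field]])) {
        rlang::abort(sprintf("stage missing required field '%s'", field))
      }
    }
    fa <- st$fasta
    if (!file.exists(fa)) fa <- file.path(base, st$fasta)
    if (!file.exists(fa)) {
      rlang::abort(sprintf("stage '%s': FASTA not found: %s",
                           st$label, st$fasta))
    }
    params <- if (!is.null(st$profile)) search_profile(st$profile) else NULL
    annotation_stage(st$kind, st$label, read_fasta(fa), params)
  })
  list(stages = stages,
       seed = cfg$seed %||% 1L,
       min_len = cfg$min_len %||% 91L,
       identity = cfg$identity %||% 0.95)
}

#' Run the full annotation pipeline
#'
#' Preprocess (short-sequence filter + redundancy clustering), iterative
#' annotation, partition into annotation/phylogeny sets, consensus
#' building per set, coverage statistics, and a machine-readable run
#' manifest. All intermediate artifacts are persisted in their declared
#' text formats so any stage can be re-run from disk.
#'
#' @param config Config list from [read_pipeline_config()], or a list
#'   with elements `stages` (list of [annotation_stage()]), and optional
#'   `seed`, `min_len`, `identity`.
#' @param queries Sequence tibble or path to a query FASTA (non-empty).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `annotations`, `sets`, `consensus`
#'   (per-set consensus objects) and `manifest`.
#' @export
run_annotate <- function(config, queries, out_dir) {
  if (is.character(queries)) queries <- read_fasta(queries)
  assert_seq_tbl(queries, "queries")
  if (nrow(queries) == 0) {
    rlang::abort("validation: empty query set; nothing to annotate")
  }
  if (is.null(config$stages) || length(config$stages) == 0) {
    rlang::abort("validation: config declares no stages")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[saurannot %s] %s",
                    format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
  }

  min_len <- config$min_len %||% 91L
  identity <- config$identity %||% 0.95
  log_stage("preprocess: %d queries", nrow(queries))
  filtered <- filter_short(queries, max_excluded_len = min_len - 1L)
  clustered <- cluster_redundant(filtered, identity_threshold = identity)
  pre <- clustered$retained
  write_fasta(pre, file.path(out_dir, "preprocessed.fasta"))
  readr::write_tsv(clustered$clusters, file.path(out_dir, "clusters.tsv"),
                   progress = FALSE)
  log_stage("preprocess: %d retained (%d short, %d redundant)",
            nrow(pre), nrow(queries) - nrow(filtered),
            nrow(filtered) - nrow(pre))

  ann <- annotate_iterative(pre, config$stages)
  readr::write_tsv(ann, file.path(out_dir, "annotations.tsv"),
                   progress = FALSE)
  counts <- table(factor(ann$category, levels = ALL_CATEGORIES))
  log_stage("annotate: %s",
            paste(sprintf("%s=%d", names(counts), counts), collapse = " "))

  sets <- partition_datasets(ann)
  writeLines(sets$annotation, file.path(out_dir, "annotation_set.txt"))
  writeLines(sets$phylogeny, file.path(out_dir, "phylogeny_set.txt"))

  # consensus per data set, anchored on the matched reference sequences
  all_refs <- dplyr::bind_rows(lapply(config$stages, function(st) st$db))
  all_refs <- all_refs[!duplicated(all_refs$id), , drop = FALSE]
  consensus <- list()
  for (set_name in c("annotation", "phylogeny")) {
    ids <- sets[[set_name]]
    rows <- ann[ann$query_id %in% ids & !is.na(ann$subject_id), ,
                drop = FALSE]
    if (nrow(rows) == 0) {
      consensus[[set_name]] <-
        structure(list(), class = "saurannot_consensus_set")
      next
    }
    pseudo_hits <- tibble::tibble(
      query_id = rows$query_id, subject_id = rows$subject_id,
      percent_identity = rows$percent_identity,
      alignment_length = rows$alignment_length,
      subject_start = rows$subject_start, subject_end = rows$subject_end,
      e_value = rows$e_value,
      query_frame = rows$query_frame, subject_frame = rows$subject_frame)
    cs <- build_consensus_set(pre, all_refs, pseudo_hits)
    consensus[[set_name]] <- cs
    write_consensus_set(cs, file.path(out_dir, set_name))
  }

  manifest <- list(
    tool = "saurannot",
    version = as.character(utils::packageVersion("saurannot")),
    seed = config$seed %||% NA_integer_,
    config_hash = rlang::hash(list(
      min_len = min_len, identity = identity,
      stages = lapply(config$stages, function(st)
        list(kind = st$kind, label = st$label, n_db = nrow(st$db))))),
    n_input = nrow(queries),
    n_short_removed = nrow(queries) - nrow(filtered),
    n_redundant_removed = nrow(filtered) - nrow(pre),
    n_annotated_queries = nrow(pre),
    category_counts = as.list(stats::setNames(as.integer(counts),
                                              names(counts))),
    n_annotation_set = length(sets$annotation),
    n_phylogeny_set = length(sets$phylogeny),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done in %.1fs", manifest$elapsed_sec)
  invisible(list(annotations = ann, sets = sets, consensus = consensus,
                 manifest = manifest))
}
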