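# Deterministic synthetic-data generators with ground-truth tables, so
# every pipeline stage is benchmarkable without external downloads. All
# generators draw from R's RNG under a caller-supplied seed and restore
# the RNG state on exit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample_nt <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a reference transcriptome with forced open reading frames
#'
#' Gene lengths are drawn uniformly from `length_range` and rounded to
#' codon multiples. Every gene starts with `ATG`, ends with a stop codon,
#' and contains no internal stop in frame +1, so translated searches are
#' exercised on realistic coding sequence.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Length range in nucleotides.
#' @param gc Target GC content.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A sequence tibble (`id` = `gene_0001`, ...).
#' @export
generate_reference_transcriptome <- function(n_genes,
                                             length_range = c(600L, 1800L),
                                             gc = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, length_range[1] >= 9,
            length_range[2] >= length_range[1])
  codons <- names(GENETIC_CODE_TABLE)
  sense <- setdiff(codons, STOP_CODONS)
  with_seed(seed, {
    # codon weights from per-base composition at the requested GC
    pbase <- stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
                             c("A", "C", "G", "T"))
    w <- vapply(sense, function(cd) {
      prod(pbase[strsplit(cd, "")[[1]]])
    }, numeric(1))
    lens <- sample(seq.int(length_range[1], length_range[2]), n_genes,
                   replace = TRUE)
    lens <- pmax(9L, (lens %/% 3L) * 3L)
    seqs <- vapply(lens, function(L) {
      n_codons <- L %/% 3L
      body <- sample(sense, n_codons - 2L, replace = TRUE, prob = w)
      paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
    }, character(1))
    seq_tbl(id = sprintf("gene_%04d", seq_len(n_genes)), seq = seqs)
  })
}

# substitute positions of s given 0-based positions; 2:1 transition bias
substitute_positions <- function(s, pos) {
  if (length(pos) == 0) return(s)
  chars <- strsplit(s, "")[[1]]
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (p in pos) {
    b <- chars[p]
    if (!b %in% names(transitions)) next
    chars[p] <- if (stats::runif(1) < 2 / 3) transitions[[b]] else
      sample(transversions[[b]], 1L)
  }
  paste(chars, collapse = "")
}

#' Fragment and mutate genes into a synthetic assembly
#'
#' Emulates the contig/singleton input of an annotation run: fragments
#' sampled uniformly from the genes, per-position substitution with
#' probability `divergence` (transition:transversion 2:1), optional
#' planted adaptors, near-identical redundant duplicates, lineage-specific
#' orphans drawn from fresh random sequence, and random strand. Every
#' choice is recorded in the returned truth table.
#'
#' @param genes Sequence tibble (e.g. from
#'   [generate_reference_transcriptome()]).
#' @param divergence Per-position substitution probability.
#' @param n_fragments_per_gene Fragments sampled per gene.
#' @param frag_length_range Fragment length range (capped at gene length).
#' @param adaptor Adaptor sequence to plant, or `NULL`.
#' @param adaptor_rate Probability a fragment receives one adaptor at a
#'   recorded position.
#' @param redundancy_rate Probability a fragment gains a >= 95% identical
#'   duplicate (2% extra divergence), sharing its redundancy group.
#' @param orphan_rate Number of true-orphan fragments as a fraction of the
#'   gene-derived fragments.
#' @param seed Integer seed.
#' @return A list: `fragments` (sequence tibble) and `truth` (tibble:
#'   `fragment_id`, `true_gene_id` (`NA` for orphans), `gene_start`,
#'   `gene_end`, `strand`, `divergence`, `n_substitutions`,
#'   `adaptor_start` (`NA` if none), `redundancy_group`).
#' @export
mutate_and_fragment <- function(genes, divergence = 0.05,
                                n_fragments_per_gene = 5L,
                                frag_length_range = c(150L, 500L),
                                adaptor = NULL, adaptor_rate = 0,
                                redundancy_rate = 0, orphan_rate = 0,
                                seed = 1L) {
  assert_seq_tbl(genes, "genes", require_rows = TRUE)
  stopifnot(divergence >= 0, divergence <= 1, adaptor_rate >= 0,
            adaptor_rate <= 1, redundancy_rate >= 0, redundancy_rate <= 1,
            orphan_rate >= 0, orphan_rate <= 1)
  with_seed(seed, {
    frag <- list(); truth <- list(); k <- 0L
    add <- function(id, seq, gene, gs, ge, strand, nsub, ads, group) {
      k <<- k + 1L
      frag[[k]] <<- tibble::tibble(id = id, desc = "", seq = seq)
      truth[[k]] <<- tibble::tibble(
        fragment_id = id, true_gene_id = gene, gene_start = gs,
        gene_end = ge, strand = strand, divergence = divergence,
        n_substitutions = nsub, adaptor_start = ads,
        redundancy_group = group)
    }
    glen <- nchar(genes$seq)
    for (gi in seq_len(nrow(genes))) {
      for (fi in seq_len(n_fragments_per_gene)) {
        L <- sample(seq.int(frag_length_range[1], frag_length_range[2]), 1L)
        L <- min(L, glen[gi])
        gs <- sample.int(glen[gi] - L + 1L, 1L)
        ge <- gs + L - 1L
        base <- substring(genes$seq[gi], gs, ge)
        pos <- which(stats::runif(L) < divergence)
        s <- substitute_positions(base, pos)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        if (strand == "-") s <- revcomp(s)
        ads <- NA_integer_
        if (!is.null(adaptor) && stats::runif(1) < adaptor_rate) {
          ads <- sample.int(nchar(s) + 1L, 1L)
          s <- paste0(substring(s, 1, ads - 1L), adaptor,
                      substring(s, ads, nchar(s)))
        }
        fid <- sprintf("frag_%s_%02d", genes$id[gi], fi)
        group <- fid
        add(fid, s, genes$id[gi], gs, ge, strand, length(pos), ads, group)
        if (stats::runif(1) < redundancy_rate) {
          dpos <- which(stats::runif(nchar(s)) < 0.02)
          if (!is.na(ads)) {   # keep the planted adaptor intact
            dpos <- dpos[dpos < ads | dpos >= ads + nchar(adaptor)]
          }
          dup <- substitute_positions(s, dpos)
          add(paste0(fid, "_dup"), dup, genes$id[gi], gs, ge, strand,
              length(pos) + length(dpos), ads, group)
        }
      }
    }
    n_orphans <- round(orphan_rate * nrow(genes) * n_fragments_per_gene)
    for (oi in seq_len(n_orphans)) {
      L <- sample(seq.int(frag_length_range[1], frag_length_range[2]), 1L)
      oid <- sprintf("orphan_%03d", oi)
      add(oid, sample_nt(L), NA_character_, NA_integer_, NA_integer_,
          "+", 0L, NA_integer_, oid)
    }
    list(fragments = dplyr::bind_rows(frag),
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate an annotated genome from a gene set
#'
#' Splits each gene into exons separated by random introns, embeds the
#' gene structures (random strand) in random intergenic sequence on a
#' single contig, and returns the genome together with exact exon
#' coordinates: splicing the annotated exons back out of the genome
#' reconstructs each gene exactly.
#'
#' @param genes Sequence tibble.
#' @param exons_per_gene_range Range of exon counts per gene.
#' @param intron_length_range Range of intron lengths.
#' @param intergenic_length_range Range of intergenic spacer lengths. The
#'   default keeps genes separated by more than the 1,000-base flanks used
#'   in exon projection, as in real vertebrate genomes where intergenic
#'   tracts are typically several kilobases.
#' @param min_exon_len Minimum exon length (breakpoints respect it).
#' @param seed Integer seed.
#' @return A list: `genome` (one-contig sequence tibble), `annotation`
#'   (exon tibble: `contig`, `start`, `end`, `strand`, `transcript_id`,
#'   `exon_index` in transcript order) and `truth` (per-gene strand and
#'   span).
#' @export
generate_annotated_genome <- function(genes,
                                      exons_per_gene_range = c(2L, 5L),
                                      intron_length_range = c(120L, 400L),
                                      intergenic_length_range = c(1500L, 3000L),
                                      min_exon_len = 60L, seed = 1L) {
  assert_seq_tbl(genes, "genes", require_rows = TRUE)
  stopifnot(exons_per_gene_range[1] >= 1, intron_length_range[1] > 0,
            intergenic_length_range[1] > 0)
  with_seed(seed, {
    contig <- "synth_contig_1"
    pieces <- character(0)
    cursor <- 0L
    ann <- list(); truth <- list()
    rint <- function(rng) {
      if (rng[1] == rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
    }
    for (gi in seq_len(nrow(genes))) {
      spacer <- sample_nt(rint(intergenic_length_range))
      pieces <- c(pieces, spacer)
      cursor <- cursor + nchar(spacer)
      L <- nchar(genes$seq[gi])
      kmax <- max(1L, L %/% min_exon_len)
      k <- min(rint(exons_per_gene_range), kmax)
      # breakpoints keeping every exon >= min_exon_len
      if (k > 1) {
        repeat {
          bp <- sort(sample.int(L - 1L, k - 1L))
          widths <- diff(c(0L, bp, L))
          if (all(widths >= min_exon_len)) break
        }
      } else {
        bp <- integer(0)
      }
      bounds <- cbind(c(1L, bp + 1L), c(bp, L))
      exon_seqs <- substring(genes$seq[gi], bounds[, 1], bounds[, 2])
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      # build the gene block in plus-strand genome orientation
      block_exons <- if (strand == "+") exon_seqs else rev(revcomp(exon_seqs))
      n_introns <- k - 1L
      introns <- if (n_introns > 0) {
        vapply(seq_len(n_introns), function(i)
          sample_nt(rint(intron_length_range)), character(1))
      } else character(0)
      block <- character(0)
      exon_start <- integer(k)
      pos <- cursor
      for (e in seq_len(k)) {
        exon_start[e] <- pos + 1L
        block <- c(block, block_exons[e])
        pos <- pos + nchar(block_exons[e])
        if (e <= n_introns) {
          block <- c(block, introns[e])
          pos <- pos + nchar(introns[e])
        }
      }
      exon_end <- exon_start + nchar(block_exons) - 1L
      pieces <- c(pieces, block)
      cursor <- pos
      # exon_index in transcript (5'->3') order
      idx <- if (strand == "+") seq_len(k) - 1L else rev(seq_len(k) - 1L)
      ann[[gi]] <- tibble::tibble(
        contig = contig, start = exon_start, end = exon_end,
        strand = strand, transcript_id = genes$id[gi], exon_index = idx)
      truth[[gi]] <- tibble::tibble(
        transcript_id = genes$id[gi], strand = strand,
        span_start = exon_start[1], span_end = exon_end[k],
        n_exons = k)
    }
    tail_sp <- sample_nt(rint(intergenic_length_range))
    genome <- seq_tbl(id = contig, seq = paste(c(pieces, tail_sp),
                                               collapse = ""))
    list(genome = genome, annotation = dplyr::bind_rows(ann),
         truth = dplyr::bind_rows(truth))
  })
}

#' Write an exon annotation as GFF3
#'
#' @param annotation Exon tibble from [generate_annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = "exon",
    Parent = annotation$transcript_id,
    transcript_id = annotation$transcript_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
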