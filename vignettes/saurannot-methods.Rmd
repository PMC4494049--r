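---
title: "Homology annotation with saurannot: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology annotation with saurannot: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saurannot)
```

## The problem

De novo transcriptome assemblies of non-model organisms (reptiles are the
motivating case: contigs and singletons from mixed 454/Illumina libraries)
carry no gene labels. The practical route to annotation is homology: compare
every assembled sequence against reference databases of increasing
evolutionary distance and decreasing reliability, keep the best-supported
assignment, and stop searching a sequence once it is annotated. saurannot
implements this as a reusable pipeline:

1. **Preprocess** — drop sequences of 90 nt or shorter; collapse
   redundancy by greedy clustering at ≥ 95% identity, keeping the longest
   sequence of each cluster.
2. **Iterative annotation** — ordered stages: a mitochondrial genome
   (nucleotide search), a pooled non-coding RNA set (nucleotide), then
   per-reference-species coding cDNA and UniGene-like sets (six-frame
   translated search with reciprocal-best-hit control, closest species
   first), then a broad taxon mRNA collection (translated). Sequences
   without any hit after all stages — and after an optional repeat-masking
   hook — are *orphans*, candidate taxonomically restricted genes.
3. **Partition** — the *phylogeny set* (reciprocal best hits only; high
   confidence, suitable for phylogenomics) and the *annotation set*
   (phylogeny set plus one-way cDNA/UniGene matches plus taxon mRNA
   matches).
4. **Consensus** — sequences sharing a best-match reference are assembled
   into a single consensus named after that reference (one-to-one when a
   single sequence matches, one-to-many otherwise).
5. **Genome projection** — for an unannotated genome, reference exons plus
   their 1,000-base flanks are projected onto the genome (accepted at
   ≥ 80% identity), matched segments are merged into *potential exons*,
   and these are reassembled into transcript consensuses by searching a
   coding cDNA database with no minimum alignment length.
6. **Completeness** — reference gene sets (conserved single-copy
   collections in the CEGMA/BUSCO spirit) are searched against the
   consensuses; the report gives the fraction found and the mean aligned
   coverage (interval union of all passing hits per reference).

## The search engine

The built-in engine substitutes for an external BLAST-like tool so the
pipeline is self-contained and deterministic; any external engine can be
plugged in through its 12-column tabular output (`read_hits_tabular()`).

*Model.* Seeded local alignment: exact-word seeding (11-nt words;
translated searches seed on peptide words of `word_size %/% 3`, i.e. 3
residues at the default), diagonal clustering, then banded gapped
extension with affine penalties around the seeded diagonals. Nucleotide
scoring is +2/−3 with gap open 5 / extend 2; translated scoring is
BLOSUM62 with gap open 11 / extend 1, over all 36 frame pairs, with `N`
codons translated to `X` and stop codons kept as `*` (never truncating).
E-values follow the Karlin–Altschul form `E = K·m·n·exp(−λS)` with raw
lengths and fixed (λ, K) per scoring system (0.625/0.41 nucleotide,
0.267/0.041 BLOSUM62); no edge-effect or compositional corrections are
applied.

*Heuristics.* Two standard devices keep translated search tractable: a
band is only extended when some single diagonal carries at least
`min_seed_count` seeds (a two-hit rule; default 2 in translated mode),
and when `ungapped_gate` is set (default 40 in translated mode) a band
must first reach that raw score under ungapped X-drop extension. Both are
parameters of `search_params()` and both are switched off in the
package's oracle tests, where the engine is configured exhaustively
(word 4, wide band, no gate) and its top-hit scores are checked to equal
full Smith–Waterman dynamic programming on both modes.

*Conventions.* One best-scoring hit is kept per query–subject pair (no
HSP tiling); reverse-strand hits are normalised so query coordinates
ascend, with strand carried in the frame fields. For a coding sequence
searched against itself the mirrored frame pair (−1,−1) can legitimately
outscore (+1,+1) — the reverse-strand conceptual translations are
identical too and have their own BLOSUM self-score — so the reported
frame pair of a perfect self-match is whichever scores higher, ties going
to the forward frames.

*Best match.* Hits of one query are ranked by the ordered criteria:
smallest e-value, then largest alignment length, then largest percent
identity; remaining ties break on subject identifier (ascending), making
every downstream decision deterministic.

## Reciprocal best hits and the iteration order

A query q and reference s form a reciprocal pair when s is q's best match
and q is s's best match under the same parameter profile. Within the
per-species cDNA/UniGene iteration a reciprocal hit finalises a query
immediately; a one-way hit does *not* — the query is still tried at the
remaining reference species (maximising reciprocal yield) and only at the
end of the group is it finalised with its best-ranked one-way hit. This
corner is not fully determined by the iterative design we follow; the
alternative (finalising one-way hits immediately) loses reciprocal pairs
whenever a more distant species would have returned one.

Note an arithmetic consequence of the definition: a reference sequence
has a single best match, so when several fragments of one gene are
searched, at most one of them can be reciprocal. Complete
reciprocal-best-hit recovery is therefore only a meaningful expectation
when queries and references pair one-to-one (the zero-divergence check in
the acceptance suite uses one fragment per gene for exactly this reason).

## Preprocessing choices

Clustering follows the greedy incremental scheme of CD-HIT-EST: sequences
sorted by length (ties by input order), each joining the first cluster
whose representative it matches at ≥ 95% identity, where identity is
matching columns divided by the *shorter* sequence's length under a
semi-global alignment (shorter sequence end-to-end, free ends on the
longer), both orientations tried. A q-gram prefilter skips pairs that
provably cannot reach the threshold: with word length w and shorter
length L, an alignment with `floor((1−t)·L)` mismatches destroys at most
`w` words each, so fewer than `(L−w+1) − floor((1−t)·L)·w` shared words
rules the pair out. The filter is lossless for the threshold; word length
10 is the default.

## Consensus model

The reference (anchor) sequence only defines the coordinate frame — it
never votes. Members are placed on anchor coordinates through their
pairwise local alignment to the anchor (an anchor-projection scheme
replacing a joint multiple alignment: deterministic and directly
checkable per column; an external MSA can be substituted upstream by
supplying its placements as hits). Per anchor column the consensus emits
the majority residue among covering members; ties go to the residue voted
by the member whose best match ranks higher under the ordered criteria.
Uncovered columns emit `-` (exported as `N` runs, or stripped). Member
insertions relative to the anchor are kept only when a strict majority of
members covering that junction carry an insertion there; the modal
insertion is emitted. A single member is a *one-to-one* consensus and is
passed through verbatim.

Coverage statistics split the anchor into the 5′ 30%, middle 40% and 3′
30% — `round(0.3·L)` positions at each end — and report the gap fraction
per region; anchors shorter than 4 positions fall back to one region with
a warning.

## Genome projection choices

"Minimum match percentage 80" is interpreted as alignment percent
identity of the projection hit, the closest observable semantics of the
original assembler parameter. Overlapping or abutting projections are
merged by interval union per (transcript, contig, strand); projections of
different transcripts stay separate. Flanks truncate at contig edges (no
wrap, no padding). GFF3 is the annotation dialect (1-based inclusive,
via rtracklayer); reassembly uses the profile with the minimum alignment
length disabled so even the shortest potential exons can align. The
genome phylogeny filter keeps consensuses strictly longer than 90 bp
(non-gap length) and, when requested, only those named after anchors with
a given prefix (the cross-species reference filter).

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested,
with full ground truth:

- `generate_reference_transcriptome()` — random coding genes (ATG start,
  no internal stop in frame +1, terminal stop), lengths 600–1,800 nt by
  default, codon-weighted to the requested GC.
- `mutate_and_fragment()` — fragments of 150–500 nt sampled uniformly,
  per-position substitution at the stated divergence with a 2:1
  transition:transversion bias (substitution-only by design, so identity
  arithmetic in tests is exact), random strand, optional planted
  adaptors, near-identical duplicates (2% extra divergence, adaptors kept
  intact) and true orphans drawn from fresh random sequence.
- `generate_annotated_genome()` — genes split into 2–5 exons
  (≥ 60 nt each) separated by 120–400 nt introns, embedded on random
  strands in intergenic spacers of 1,500–3,000 nt. The spacers
  deliberately exceed the 1,000-base projection flanks: in a toy genome
  with sub-kilobase spacers, flanks overlap neighbouring genes and merged
  projections get claimed by the neighbour's cDNA — an artifact of
  unrealistic gene density, not of the method; vertebrate intergenic
  tracts are typically multi-kilobase.

What the generators do *not* emulate: indels (available as an explicit
option, default off), sequencing error profiles and coverage waves,
alternative splicing, paralogy and gene families, compositional bias
beyond GC. Passing tests therefore demonstrate correctness of the
machinery and calibration under substitution-type divergence; they do not
certify recall on real data with assembly artifacts or deep paralogy.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_excluded_len` | 90 nt | short-sequence filter; 91-nt sequences are kept |
| `identity_threshold` | 0.95 | redundancy clustering threshold (identity over the shorter sequence) |
| `e_value_max` | 1e-3 | default reporting threshold (nucleotide and translated profiles) |
| `min_alignment_length` | 50 nt | nucleotide stages only; disabled for projection reassembly |
| genome-validation profile | 1e-5, 90% id | the stringent cross-check profile |
| completeness profile | 1e-5, no id floor | reference-set recovery |
| `min_match_pct` | 80 | projection acceptance identity |
| `flank_len` | 1,000 nt | UTR-capturing flanks around reference transcripts |
| `word_size` | 11 nt | seed length (3-residue peptide words in translated mode) |

## Numerical and degenerate-input choices

Gap cost is `gap_open + g·gap_extend` for a gap of length g. Score ties
inside the dynamic program resolve to the earlier cell (diagonal
preferred over gaps), making tracebacks deterministic. Empty databases
return empty hit tables, not errors; an empty query set is a validation
error in the pipeline driver. `N` seeds nothing and scores as a mismatch
everywhere, including against itself. Coordinates are 1-based inclusive
at every user-facing surface (the tabular dialect's convention);
0-based arithmetic is confined to the compiled core and the BED export.

## Problem sizes

The test suite and the acceptance script run the full pipeline at 50
genes × 5 fragments (divergence 0.05, 10% planted orphans), the genome
round trip at 20 genes × 2–5 exons, consensus property checks on 100
randomised cases, and engine-vs-oracle comparisons on 30 random instances
per mode — sizes chosen so every check derives from enumerable ground
truth while the whole suite completes in a few minutes on one CPU.

## Known limitations

No HSP tiling or sum statistics: a query matching one reference in two
widely separated blocks is scored by its best block only. Translated
e-values use nucleotide search-space lengths. The repeat stage is a hook
(masked-fraction ≥ 0.5 labels `repeat`), with a no-op default rather than
a bundled masker. Completeness scoring is presence/coverage only — no
duplication-aware classification. The engine's heuristics (two-hit rule,
ungapped gate) can miss genuinely weak homologies that exhaustive
dynamic programming would report; both can be relaxed per profile when
sensitivity matters more than speed.
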