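# Alphabets, scoring matrices, and the standard genetic code.
# Codes are 0-based for the compiled aligner; characters outside the
# alphabet map to the ambiguity code (N / X), which never seeds and
# scores as a mismatch.

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "*", "X")

# byte -> 0-based code lookup tables (code length(alphabet)-1 = ambiguity)
.lookup_table <- function(alphabet) {
  tab <- rep.int(length(alphabet) - 1L, 256L)
  tab[utf8ToInt(paste(alphabet, collapse = "")) + 1L] <-
    seq_along(alphabet) - 1L
  tab
}
NT_LOOKUP <- .lookup_table(NT_ALPHABET)
AA_LOOKUP <- .lookup_table(AA_ALPHABET)

# Nucleotide scoring: match/mismatch filled in per search profile; N is a
# mismatch against everything, including itself.
nt_score_matrix <- function(match, mismatch) {
  m <- matrix(as.integer(mismatch), 5L, 5L)
  diag(m)[1:4] <- as.integer(match)
  m
}

# BLOSUM62 in AA_ALPHABET order (standard public matrix; '*' column as in
# NCBI BLAST distributions).
BLOSUM62_MATRIX <- matrix(as.integer(c(
  4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-4,-1,
  -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-4,-1,
  -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,-4,-1,
  -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,-4,-1,
  0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-4,-1,
  -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,-4,-1,
  -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,-4,-1,
  0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-4,-1,
  -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,-4,-1,
  -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-4,-1,
  -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-4,-1,
  -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,-4,-1,
  -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-4,-1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-4,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-4,-1,
  1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,-4,-1,
  0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-4,-1,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-4,-1,
  -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-4,-1,
  0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-4,-1,
  -4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,1,-4,
  -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-4,-1)),
  nrow = 22L, byrow = TRUE,
  dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Standard genetic code, codon -> single-letter amino acid.
GENETIC_CODE_TABLE <- local({
  codons <- strsplit(
    paste0("TTT,TTC,TTA,TTG,TCT,TCC,TCA,TCG,TAT,TAC,TAA,TAG,TGT,TGC,TGA,",
           "TGG,CTT,CTC,CTA,CTG,CCT,CCC,CCA,CCG,CAT,CAC,CAA,CAG,CGT,CGC,",
           "CGA,CGG,ATT,ATC,ATA,ATG,ACT,ACC,ACA,ACG,AAT,AAC,AAA,AAG,AGT,",
           "AGC,AGA,AGG,GTT,GTC,GTA,GTG,GCT,GCC,GCA,GCG,GAT,GAC,GAA,GAG,",
           "GGT,GGC,GGA,GGG"), ",")[[1]]
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stats::setNames(aa, codons)
})

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
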