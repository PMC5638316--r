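# Independent oracles used to cross-check the package's sequence
# arithmetic: a hand-rolled base-complement map and seqinr's translator
# (a different code path from the one the package uses).

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

oracle_translate <- function(dna) {
  aa <- seqinr::translate(seqinr::s2c(tolower(dna)))
  paste(aa, collapse = "")
}

random_peptide <- function(len, seed) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Count occurrences of a fixed pattern (overlaps included) - oracle for
# uniqueness checks.
count_occurrences <- function(pattern, subject) {
  n <- 0L
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (p == -1L) return(n)
    n <- n + 1L
    from <- from + as.integer(p)
  }
}

# Build a protein that contains a given motif flanked by residues drawn
# so the motif occurs exactly once.
protein_with_motif <- function(motif, at, total_len, seed = 1L) {
  stopifnot(at + nchar(motif) - 1L <= total_len)
  repeat {
    seq <- random_peptide(total_len, seed)
    substr(seq, at, at + nchar(motif) - 1L) <- motif
    if (count_occurrences(motif, seq) == 1L) break
    seed <- seed + 1000L
  }
  protein_record("fixture", seq)
}
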