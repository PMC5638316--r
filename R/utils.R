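# Shared internal helpers: alphabets, seeding, small sequence ops.

AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

BAMHI_SITE <- "GGATCC"
SALI_SITE <- "GTCGAC"

# Average residue masses (Da) of the 20 standard amino acids; mass of a
# peptide is the sum of residue masses plus one water (18.0153 Da).
RESIDUE_MASS_DA <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_DA <- 18.0153

#' @noRd
validate_residues <- function(sequence, what = "sequence") {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET_20)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s contains non-standard residue '%s' at position %d",
      what, chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
validate_dna <- function(sequence, what = "sequence", allow_n = FALSE) {
  allowed <- if (allow_n) c(DNA_ALPHABET, "N") else DNA_ALPHABET
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s contains illegal base '%s' at position %d",
      what, chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x A DNA string (A/C/G/T/N).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a DNA string in frame 1 with the standard code; codons containing
# N translate to "X". Length must be a multiple of 3.
#' @noRd
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("coding sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
    unname(code[codons])
  )
  if (anyNA(aa)) {
    stop("untranslatable codon '", codons[which(is.na(aa))[1]], "'", call. = FALSE)
  }
  paste(aa, collapse = "")
}

# Find all start positions of a fixed pattern (overlapping matches included).
#' @noRd
find_all_fixed <- function(pattern, subject) {
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (p == -1L) break
    hit <- from + as.integer(p) - 1L
    hits <- c(hits, hit)
    from <- hit + 1L
  }
  hits
}
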