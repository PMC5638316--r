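# Verification of sequenced inserts against the designed oligos.
#
# A correct clone's read contains GGATCC + cds + TAA + GTCGAC in one
# orientation. Verification is residue-level first (the method's purpose is
# correct peptides, so synonymous changes still verify), with
# nucleotide-level identity reported secondarily.

#' Sanger read
#'
#' @param id Read identifier.
#' @param sequence DNA string over A/C/G/T/N.
#' @return An object of class `sanger_read`.
#' @export
sanger_read <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("read sequence must be non-empty", call. = FALSE)
  validate_dna(sequence, what = paste0("read '", id, "'"), allow_n = TRUE)
  structure(list(id = id, sequence = sequence), class = "sanger_read")
}

#' Recommended sequencing primer
#'
#' The 20-nt primer used to sequence inserts in the pXXGST vectors.
#'
#' @return The primer sequence, 5' to 3'.
#' @export
sequencing_primer <- function() {
  "GGCCATCATACGTTATATAG"
}

#' Locate the BamHI..SalI insert in a read
#'
#' Searches the read, then its reverse complement, for the first GGATCC
#' followed downstream by GTCGAC, and returns the 1-based span strictly
#' between the two recognition sequences. Only the first such pair per
#' orientation is considered; additional pairs trigger a warning.
#'
#' @param read A [sanger_read()].
#' @return A list with `orientation` (`"forward"`/`"reverse"`), `span`
#'   (c(start, end) on the searched strand), and `inner` (the spanned
#'   sequence), or `NULL` when neither orientation contains the site pair.
#' @export
locate_insert <- function(read) {
  stopifnot(inherits(read, "sanger_read"))
  for (orientation in c("forward", "reverse")) {
    seq <- if (orientation == "forward") read$sequence else revcomp(read$sequence)
    bam <- find_all_fixed(BAMHI_SITE, seq)
    if (length(bam) == 0L) next
    b <- bam[1]
    sal <- find_all_fixed(SALI_SITE, seq)
    sal <- sal[sal >= b + 6L]
    if (length(sal) == 0L) next
    if (length(sal) > 1L || length(bam) > 1L) {
      warning("read '", read$id, "' contains multiple candidate inserts; ",
              "using the first", call. = FALSE)
    }
    s <- sal[1]
    span <- c(b + 6L, s - 1L)
    inner <- if (span[2] >= span[1]) substr(seq, span[1], span[2]) else ""
    return(list(orientation = orientation, span = span, inner = inner))
  }
  NULL
}

#' Verify a sequenced insert against its designed oligo pair
#'
#' Locates the insert, checks the inner span equals `cds + TAA`, translates
#' the coding part and compares residues against the designed (padded)
#' peptide. `N` bases mismatch every base and surface as differences.
#'
#' @param read A [sanger_read()].
#' @param expected The designed `oligo_pair`.
#' @return A list of class `verification_report`: `status` (`"match"`,
#'   `"mismatch"`, `"frame_error"`, `"insert_not_found"`), `orientation`,
#'   `extracted_cds`, `translated`, `differences` (data.frame of position /
#'   expected / observed residues), `stop_ok` (TAA immediately before the
#'   SalI site), and `nt_identity` (fraction of matching bases over the
#'   designed inner span).
#' @export
verify_insert <- function(read, expected) {
  stopifnot(inherits(expected, "oligo_pair"))
  loc <- locate_insert(read)
  expected_peptide <- paste0(expected$n_terminal_pad, expected$peptide)
  expected_inner <- paste0(expected$cds, "TAA")
  if (is.null(loc)) {
    return(new_verification_report("insert_not_found", NA_character_, "", "",
                                   empty_diffs(), FALSE, NA_real_, read$id))
  }
  inner <- loc$inner
  nt_identity <- inner_identity(inner, expected_inner)
  if (nchar(inner) %% 3L != 0L || nchar(inner) < 3L) {
    return(new_verification_report("frame_error", loc$orientation, inner, "",
                                   empty_diffs(), FALSE, nt_identity, read$id))
  }
  stop_ok <- substr(inner, nchar(inner) - 2L, nchar(inner)) == "TAA"
  cds <- substr(inner, 1L, nchar(inner) - 3L)
  translated <- if (nchar(cds) > 0L) translate_cds(cds) else ""
  diffs <- residue_diffs(expected_peptide, translated)
  status <- if (translated == expected_peptide && stop_ok) "match" else "mismatch"
  new_verification_report(status, loc$orientation, cds, translated, diffs,
                          stop_ok, nt_identity, read$id)
}

#' @noRd
empty_diffs <- function() {
  data.frame(position = integer(0), expected = character(0),
             observed = character(0), stringsAsFactors = FALSE)
}

#' @noRd
residue_diffs <- function(expected, observed) {
  n <- max(nchar(expected), nchar(observed))
  if (n == 0L) return(empty_diffs())
  exp_ch <- substring(expected, 1:n, 1:n)
  obs_ch <- substring(observed, 1:n, 1:n)
  exp_ch[exp_ch == ""] <- "-"
  obs_ch[obs_ch == ""] <- "-"
  bad <- which(exp_ch != obs_ch)
  data.frame(position = bad, expected = exp_ch[bad], observed = obs_ch[bad],
             stringsAsFactors = FALSE)
}

# Positionwise base identity over the designed inner span (N never matches).
#' @noRd
inner_identity <- function(observed, expected) {
  n <- nchar(expected)
  if (n == 0L) return(NA_real_)
  obs <- substring(observed, 1:n, 1:n)
  exp <- substring(expected, 1:n, 1:n)
  sum(obs == exp & obs %in% DNA_ALPHABET) / n
}

#' @noRd
new_verification_report <- function(status, orientation, extracted_cds,
                                    translated, differences, stop_ok,
                                    nt_identity, read_id) {
  structure(
    list(read_id = read_id, status = status, orientation = orientation,
         extracted_cds = extracted_cds, translated = translated,
         differences = differences, stop_ok = stop_ok,
         nt_identity = nt_identity),
    class = "verification_report"
  )
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %s: %s (%s)\n", x$read_id, x$status,
              ifelse(is.na(x$orientation), "no orientation", x$orientation)))
  if (nrow(x$differences) > 0L) {
    cat("  residue differences:\n")
    print(x$differences, row.names = FALSE)
  }
  invisible(x)
}
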