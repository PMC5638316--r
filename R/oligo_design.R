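# Reverse translation and clonable duplex design.
#
# Each peptide tile is reverse-translated and wrapped into a plus/minus
# single-stranded oligo pair whose annealed duplex drops directly into the
# BamHI/SalI sites downstream of the GST188 gene:
#
#   plus  5'-GATCC <cds> TAA G-3'
#   minus 5'-TCGACTTA <revcomp(cds)> G-3'
#
# leaving the 4-nt cohesive overhangs GATC (BamHI) and TCGA (SalI) single
# stranded, with a TAA stop between the peptide and the SalI site so the
# vector's GSVD read-through is never appended to the expressed peptide.

#' Codon selection policy
#'
#' Controls how peptides are reverse-translated. `most_frequent` always
#' picks the single highest-frequency codon per amino acid from the usage
#' table (deterministic); `seeded_random` samples codons proportionally to
#' their usage fractions, reproducibly under `seed`. Codon optimisation is
#' not required for expression of these short fusions, so the deterministic
#' default simply maximises reproducibility.
#'
#' @param mode `"most_frequent"` or `"seeded_random"`.
#' @param seed Integer seed, used only by `seeded_random`.
#' @param table_id Label of the codon-usage table shipped with the package
#'   (currently `"ecoli_k12"`).
#' @return An object of class `codon_policy` carrying the usage table.
#' @examples
#' codon_policy()
#' codon_policy("seeded_random", seed = 7)
#' @export
codon_policy <- function(mode = c("most_frequent", "seeded_random"),
                         seed = 1L, table_id = "ecoli_k12") {
  mode <- match.arg(mode)
  table <- load_codon_table(table_id)
  structure(
    list(table_id = table_id, mode = mode, seed = as.integer(seed), table = table),
    class = "codon_policy"
  )
}

#' @export
print.codon_policy <- function(x, ...) {
  cat(sprintf("<codon_policy> %s, table %s\n", x$mode, x$table_id))
  invisible(x)
}

#' @noRd
load_codon_table <- function(table_id) {
  path <- system.file("extdata", paste0(table_id, "_codon_usage.tsv"),
                      package = "bspmap")
  if (!nzchar(path)) {
    stop("unknown codon usage table '", table_id, "'", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "aa", "fraction") %in% names(tab)))
  if (!all(AA_ALPHABET_20 %in% tab$aa)) {
    stop("codon table must cover all 20 amino acids", call. = FALSE)
  }
  tab
}

# Synonymous codons of one amino acid, most frequent first (ties broken
# alphabetically for determinism).
#' @noRd
codons_for <- function(aa, table) {
  rows <- table[table$aa == aa, , drop = FALSE]
  rows <- rows[order(-rows$fraction, rows$codon), , drop = FALSE]
  rows
}

#' Reverse-translate a peptide
#'
#' @param peptide Residue string (standard 20-letter alphabet).
#' @param policy A [codon_policy()].
#' @return A DNA string of length `3 * nchar(peptide)` whose frame-1
#'   translation reproduces `peptide`.
#' @examples
#' reverse_translate("MW", codon_policy())  # "ATGTGG" (unique codons)
#' @export
reverse_translate <- function(peptide, policy = codon_policy()) {
  stopifnot(inherits(policy, "codon_policy"))
  if (!nzchar(peptide)) stop("peptide must be non-empty", call. = FALSE)
  peptide <- toupper(peptide)
  validate_residues(peptide, what = "peptide")
  residues <- strsplit(peptide, "")[[1]]
  pick_one <- function(aa) {
    rows <- codons_for(aa, policy$table)
    if (policy$mode == "most_frequent") {
      rows$codon[1]
    } else {
      sample(rows$codon, 1L, prob = rows$fraction)
    }
  }
  codons <- if (policy$mode == "seeded_random") {
    with_seed(policy$seed, vapply(residues, pick_one, character(1)))
  } else {
    vapply(residues, pick_one, character(1))
  }
  paste(codons, collapse = "")
}

#' Pad short peptides with an N-terminal AAA tripeptide
#'
#' Very short peptides (3-5-mers used to pin down a minimal motif) receive
#' a literal `AAA` (tri-alanine) N-terminal pad purely for the convenience
#' of constructing recombinant clones; the pad is recorded in the returned
#' attribute so downstream motif logic can ignore it.
#'
#' @param peptide Residue string.
#' @param min_core Peptides shorter than this receive the pad (default 6).
#' @return The (possibly padded) peptide, with attribute `n_terminal_pad`
#'   holding `""` or `"AAA"`.
#' @examples
#' pad_short_peptide("ELRHY")  # "AAAELRHY"
#' pad_short_peptide("YYGVGDYP")  # unchanged
#' @export
pad_short_peptide <- function(peptide, min_core = 6L) {
  stopifnot(nchar(peptide) >= 1L)
  validate_residues(toupper(peptide), what = "peptide")
  if (nchar(peptide) < min_core) {
    structure(paste0("AAA", peptide), n_terminal_pad = "AAA")
  } else {
    structure(peptide, n_terminal_pad = "")
  }
}

#' Build the plus/minus oligo pair for one peptide tile
#'
#' Assembles the two single-stranded synthesis oligos whose annealed duplex
#' carries BamHI/SalI cohesive ends and the TAA stop. For an n-residue
#' peptide both strands are `3n + 9` nt long (33/57/63 nt for 8/16/18-mers).
#' Internal BamHI/SalI sites are scanned for and, by default, removed by
#' synonymous recoding.
#'
#' @param tile_id Label carried through to order sheets.
#' @param peptide The peptide to encode. May carry the `n_terminal_pad`
#'   attribute from [pad_short_peptide()]; the pad is part of the coding
#'   sequence but recorded separately.
#' @param policy A [codon_policy()].
#' @param cds Optional explicit coding sequence (must translate to the
#'   padded peptide); by default [reverse_translate()] is used.
#' @param auto_recode Remove internal restriction sites via
#'   [recode_to_remove_sites()] (default `TRUE`).
#' @return An object of class `oligo_pair` with fields `tile_id`, `peptide`,
#'   `n_terminal_pad`, `cds`, `plus_strand`, `minus_strand`, `flags`.
#' @examples
#' build_oligo_pair("P1", "M")  # plus strand "GATCCATGTAAG"
#' @export
build_oligo_pair <- function(tile_id, peptide, policy = codon_policy(),
                             cds = NULL, auto_recode = TRUE) {
  pad <- attr(peptide, "n_terminal_pad")
  if (is.null(pad)) pad <- ""
  peptide <- toupper(as.character(peptide))
  validate_residues(peptide, what = "peptide")
  core <- substring(peptide, nchar(pad) + 1L)
  if (is.null(cds)) {
    cds <- reverse_translate(peptide, policy)
  } else {
    cds <- toupper(cds)
    validate_dna(cds, what = "cds")
    if (translate_cds(cds) != peptide) {
      stop("supplied cds does not translate to the peptide", call. = FALSE)
    }
  }
  pair <- new_oligo_pair(tile_id, core, pad, cds, flags = character(0))
  if (auto_recode && any(!scan_internal_sites(pair)$expected)) {
    pair$flags <- union(pair$flags, "internal_site_found")
    pair <- recode_to_remove_sites(pair, policy)
  }
  pair
}

#' @noRd
new_oligo_pair <- function(tile_id, peptide, pad, cds, flags) {
  structure(
    list(
      tile_id = tile_id,
      peptide = peptide,
      n_terminal_pad = pad,
      cds = cds,
      plus_strand = paste0("GATCC", cds, "TAA", "G"),
      minus_strand = paste0("TCGACTTA", revcomp(cds), "G"),
      flags = flags
    ),
    class = "oligo_pair"
  )
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf(
    "<oligo_pair> %s: %s%s (%d nt/strand)%s\n  plus  5'-%s-3'\n  minus 5'-%s-3'\n",
    x$tile_id,
    if (nzchar(x$n_terminal_pad)) paste0("[", x$n_terminal_pad, "]") else "",
    x$peptide, nchar(x$plus_strand),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else "",
    x$plus_strand, x$minus_strand
  ))
  invisible(x)
}

# The insert as it sits in the ligated plasmid, i.e. with both restriction
# sites restored: GGATCC + cds + TAA + GTCGAC.
#' @noRd
assembled_insert <- function(pair) {
  paste0(BAMHI_SITE, pair$cds, "TAA", SALI_SITE)
}

#' Scan an oligo pair for internal restriction sites
#'
#' Scans the assembled plasmid-context insert (`GGATCC + cds + TAA +
#' GTCGAC`) for every BamHI (GGATCC) and SalI (GTCGAC) occurrence. The
#' leading BamHI and trailing SalI sites are expected; anything else would
#' disturb annealing/cloning and must be recoded away.
#'
#' @param pair An `oligo_pair`.
#' @return A `data.frame` with columns `site` (`"BamHI"`/`"SalI"`),
#'   `position` (1-based offset in the assembled insert) and `expected`.
#' @export
scan_internal_sites <- function(pair) {
  stopifnot(inherits(pair, "oligo_pair"))
  ctx <- assembled_insert(pair)
  bam <- find_all_fixed(BAMHI_SITE, ctx)
  sal <- find_all_fixed(SALI_SITE, ctx)
  hits <- data.frame(
    site = c(rep("BamHI", length(bam)), rep("SalI", length(sal))),
    position = c(bam, sal),
    stringsAsFactors = FALSE
  )
  hits$expected <- (hits$site == "BamHI" & hits$position == 1L) |
    (hits$site == "SalI" & hits$position == nchar(ctx) - 5L)
  hits[order(hits$position), , drop = FALSE]
}

#' Remove internal restriction sites by synonymous recoding
#'
#' Greedy left-to-right repair: for each unexpected BamHI/SalI hit, the
#' codons overlapping the site are tried in order, substituting the
#' next-most-frequent synonymous codon that removes the hit; the insert is
#' re-scanned after each change so newly created sites are caught. The
#' returned coding sequence translates to the same (padded) peptide and
#' differs in the minimum number of codons a single-codon-per-site repair
#' can achieve.
#'
#' @param pair An `oligo_pair` with unexpected hits (pairs with none are
#'   returned unchanged).
#' @param policy A [codon_policy()] supplying synonymous codons.
#' @return A clean `oligo_pair`; its `flags` gain `"recoded"` if any codon
#'   changed.
#' @export
recode_to_remove_sites <- function(pair, policy = codon_policy()) {
  stopifnot(inherits(pair, "oligo_pair"), inherits(policy, "codon_policy"))
  padded <- paste0(pair$n_terminal_pad, pair$peptide)
  cds <- pair$cds
  n_cod <- nchar(cds) / 3L
  changed <- FALSE
  for (iter in seq_len(n_cod * 4L + 8L)) {
    tmp <- new_oligo_pair(pair$tile_id, pair$peptide, pair$n_terminal_pad, cds, pair$flags)
    hits <- scan_internal_sites(tmp)
    bad <- hits[!hits$expected, , drop = FALSE]
    if (nrow(bad) == 0L) {
      flags <- pair$flags
      if (changed) flags <- union(flags, c("internal_site_found", "recoded"))
      return(new_oligo_pair(pair$tile_id, pair$peptide, pair$n_terminal_pad, cds, flags))
    }
    hit <- bad[1, ]
    # context position p maps to cds positions (p - 6)..(p - 1)
    cds_lo <- max(1L, hit$position - 6L)
    cds_hi <- min(nchar(cds), hit$position - 1L)
    if (cds_lo > cds_hi) {
      stop("internal site lies outside the coding sequence and cannot be recoded",
           call. = FALSE)
    }
    codon_idx <- unique(((cds_lo:cds_hi) - 1L) %/% 3L + 1L)
    fixed <- FALSE
    for (ci in codon_idx) {
      cur <- substr(cds, 3L * ci - 2L, 3L * ci)
      aa <- substr(padded, ci, ci)
      alts <- setdiff(codons_for(aa, policy$table)$codon, cur)
      for (alt in alts) {
        cand <- cds
        substr(cand, 3L * ci - 2L, 3L * ci) <- alt
        cand_hits <- scan_internal_sites(
          new_oligo_pair(pair$tile_id, pair$peptide, pair$n_terminal_pad, cand, pair$flags)
        )
        cand_bad <- cand_hits[!cand_hits$expected, , drop = FALSE]
        # accept if this specific hit is gone and we have not grown the problem
        still_here <- any(cand_bad$position == hit$position & cand_bad$site == hit$site)
        if (!still_here && nrow(cand_bad) <= nrow(bad) - 1L) {
          cds <- cand
          changed <- TRUE
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      stop("no synonymous recoding removes the internal ", hit$site, " site",
           call. = FALSE)
    }
  }
  stop("site recoding did not converge", call. = FALSE)
}
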