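# Synthetic fixtures: random proteins with planted epitopes, simulated
# blot reactivity under a containment rule, and simulated Sanger reads.
# Everything is seeded; no global RNG state leaks to the caller.

#' Generate a random protein
#'
#' Residues are drawn uniformly over the 20-letter alphabet; the same seed
#' always yields the same sequence.
#'
#' @param length Residue count (>= 8).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A [protein_record()].
#' @export
gen_protein <- function(length, seed = 1L, id = sprintf("sim_prot_%d", seed)) {
  length <- as.integer(length)
  if (length < 8L) stop("protein length must be >= 8", call. = FALSE)
  seq <- with_seed(seed, paste(
    sample(AA_ALPHABET_20, length, replace = TRUE), collapse = ""
  ))
  protein_record(id, seq)
}

#' Plant an epitope motif into a protein
#'
#' Overwrites the window at `position` with `motif` and, if the motif then
#' occurs elsewhere too, resamples the residues of the spurious
#' occurrences (never touching the planted window) until the motif occurs
#' exactly once in the whole sequence.
#'
#' @param protein A [protein_record()].
#' @param motif Residue string of length 3-8.
#' @param position 1-based start for the planted copy.
#' @param seed Seed for the resampling.
#' @param max_retries Bounded retries before giving up on uniqueness.
#' @return A list with `protein` (modified record) and `epitope`
#'   (`list(motif, position)`).
#' @export
plant_epitope <- function(protein, motif, position, seed = 1L,
                          max_retries = 100L) {
  stopifnot(inherits(protein, "protein_record"))
  motif <- toupper(motif)
  validate_residues(motif, what = "motif")
  m <- nchar(motif)
  if (m < 3L || m > 8L) stop("motif length must be 3-8", call. = FALSE)
  position <- as.integer(position)
  if (position < 1L || position + m - 1L > protein$length) {
    stop("motif does not fit at position ", position, call. = FALSE)
  }
  seq <- protein$sequence
  substr(seq, position, position + m - 1L) <- motif
  seq <- with_seed(seed, {
    retries <- 0L
    repeat {
      occ <- find_all_fixed(motif, seq)
      spurious <- setdiff(occ, position)
      if (length(spurious) == 0L) break
      retries <- retries + 1L
      if (retries > max_retries) {
        stop("could not make motif '", motif, "' unique after ",
             max_retries, " retries", call. = FALSE)
      }
      for (p in spurious) {
        idx <- setdiff(p:(p + m - 1L), position:(position + m - 1L))
        for (i in idx) {
          substr(seq, i, i) <- sample(AA_ALPHABET_20, 1L)
        }
      }
    }
    seq
  })
  list(
    protein = protein_record(protein$id, seq),
    epitope = list(motif = motif, position = position)
  )
}

#' Reactivity simulation rule
#'
#' Noiseless blots follow full containment: a tile reacts iff it fully
#' contains at least one planted motif. Optional false-positive /
#' false-negative rates flip calls per tile, reproducibly under `seed`.
#'
#' @param false_positive_rate,false_negative_rate Probabilities in
#'   `[0, 1]`.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `reactivity_rule` (mode
#'   `"full_containment"`).
#' @export
reactivity_rule <- function(false_positive_rate = 0,
                            false_negative_rate = 0, seed = 1L) {
  stopifnot(false_positive_rate >= 0, false_positive_rate <= 1,
            false_negative_rate >= 0, false_negative_rate <= 1)
  structure(
    list(mode = "full_containment",
         false_positive_rate = false_positive_rate,
         false_negative_rate = false_negative_rate,
         seed = as.integer(seed)),
    class = "reactivity_rule"
  )
}

#' Simulate per-tile blot reactivity
#'
#' @param tiles A design-sheet `data.frame` with absolute coordinates.
#' @param epitopes List of `list(motif, position)` planted epitopes.
#' @param rule A [reactivity_rule()].
#' @param antibody_id Label for the simulated antibody.
#' @return A [reactivity_table()].
#' @export
simulate_reactivity <- function(tiles, epitopes, rule = reactivity_rule(),
                                antibody_id = "sim_ab") {
  stopifnot(inherits(rule, "reactivity_rule"))
  contains <- rep(FALSE, nrow(tiles))
  for (ep in epitopes) {
    ep_start <- ep$position
    ep_end <- ep$position + nchar(ep$motif) - 1L
    contains <- contains | (tiles$start <= ep_start & tiles$end >= ep_end)
  }
  reactive <- contains
  if (rule$false_positive_rate > 0 || rule$false_negative_rate > 0) {
    reactive <- with_seed(rule$seed, {
      u <- stats::runif(nrow(tiles))
      ifelse(contains, u >= rule$false_negative_rate,
             u < rule$false_positive_rate)
    })
  }
  reactivity_table(tiles$tile_id, reactive = reactive,
                   antibody_id = antibody_id)
}

#' Simulate a Sanger read of a recombinant clone
#'
#' The read is `random flank + GGATCC + cds + TAA + GTCGAC + random
#' flank`, with optional point substitutions applied inside the insert and
#' optional reverse-complementation of the whole read.
#'
#' @param pair The designed `oligo_pair`.
#' @param mutations List of `list(offset, base)` substitutions; `offset` is
#'   1-based within the assembled insert (GGATCC...GTCGAC).
#' @param flank_lengths Lengths of the 5' and 3' random flanks.
#' @param seed Seed for the flank sequences.
#' @param reverse Emit the reverse complement of the read.
#' @param id Read identifier.
#' @return A [sanger_read()].
#' @export
simulate_read <- function(pair, mutations = list(), flank_lengths = c(20L, 20L),
                          seed = 1L, reverse = FALSE,
                          id = paste0(pair$tile_id, "_read")) {
  stopifnot(inherits(pair, "oligo_pair"))
  insert <- assembled_insert(pair)
  for (mut in mutations) {
    off <- as.integer(mut$offset)
    if (off < 1L || off > nchar(insert)) {
      stop("mutation offset ", off, " lies outside the insert (1-",
           nchar(insert), ")", call. = FALSE)
    }
    base <- toupper(mut$base)
    if (!base %in% c(DNA_ALPHABET, "N")) {
      stop("mutation base must be A/C/G/T/N", call. = FALSE)
    }
    substr(insert, off, off) <- base
  }
  flanks <- with_seed(seed, list(
    left = paste(sample(DNA_ALPHABET, flank_lengths[1], replace = TRUE),
                 collapse = ""),
    right = paste(sample(DNA_ALPHABET, flank_lengths[2], replace = TRUE),
                  collapse = "")
  ))
  seq <- paste0(flanks$left, insert, flanks$right)
  if (reverse) seq <- revcomp(seq)
  sanger_read(id, seq)
}

#' Generate a complete simulated fixture bundle
#'
#' One call exercises the whole pipeline's inputs: a random protein with a
#' planted epitope, the two-round tile design, oligo pairs, reactivity
#' tables for both rounds, and perfect reads for the reactive fine tiles.
#'
#' @param protein_length Host protein length.
#' @param motif Planted motif (length 3-8); default draws a random 5-mer.
#' @param position Planted start; default places it mid-protein.
#' @param seed Master seed (sub-seeds are derived from it).
#' @param scheme1,scheme2 Tile schemes for the two rounds.
#' @return A list with `protein`, `epitope`, `round1_tiles`,
#'   `round1_table`, `round2_scans`, `oligos`, `reads`, `truth`.
#' @export
simulate_bundle <- function(protein_length = 120L, motif = NULL,
                            position = NULL, seed = 1L,
                            scheme1 = tile_scheme("round1"),
                            scheme2 = tile_scheme("round2")) {
  base <- gen_protein(protein_length, seed = seed)
  if (is.null(motif)) {
    motif <- with_seed(seed + 1L,
      paste(sample(AA_ALPHABET_20, 5L, replace = TRUE), collapse = ""))
  }
  m <- nchar(motif)
  if (is.null(position)) position <- (protein_length - m) %/% 2L + 1L
  planted <- plant_epitope(base, motif, position, seed = seed + 2L)
  protein <- planted$protein
  epitopes <- list(planted$epitope)

  r1 <- assign_tile_ids(design_round1(protein, scheme1), 1L)
  t1 <- simulate_reactivity(r1, epitopes)
  reactive1 <- r1[r1$tile_id %in% t1$tile_id[t1$reactive], , drop = FALSE]
  intervals <- merge_reactive_parents(reactive1)
  next_id <- nrow(r1) + 1L
  round2_scans <- list()
  for (i in seq_len(nrow(intervals))) {
    parent <- list(
      parent_id = protein$id,
      start = intervals$start[i], end = intervals$end[i],
      peptide = substr(protein$sequence, intervals$start[i], intervals$end[i])
    )
    tiles <- assign_tile_ids(design_round2(parent, scheme2), next_id)
    next_id <- next_id + nrow(tiles)
    round2_scans <- c(round2_scans, list(list(
      tiles = tiles, table = simulate_reactivity(tiles, epitopes)
    )))
  }
  fine_tiles <- if (length(round2_scans)) {
    do.call(rbind, lapply(round2_scans, `[[`, "tiles"))
  } else {
    r1[0, ]
  }
  policy <- codon_policy()
  oligos <- lapply(seq_len(nrow(fine_tiles)), function(i) {
    build_oligo_pair(fine_tiles$tile_id[i], fine_tiles$peptide[i], policy)
  })
  reads <- lapply(seq_along(oligos), function(i) {
    simulate_read(oligos[[i]], seed = seed + 100L + i)
  })
  list(
    protein = protein, epitope = planted$epitope,
    round1_tiles = r1, round1_table = t1, round2_scans = round2_scans,
    oligos = oligos, reads = reads,
    truth = list(motif = motif, start = position, end = position + m - 1L)
  )
}
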