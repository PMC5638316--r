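# File formats, configuration and the full-pipeline orchestration.
#
# TSV is the canonical tabular dialect (tab-separated, header row, UTF-8,
# '.' decimal); every report is mirrored as JSON for machine use.

#' Read proteins from a FASTA file
#'
#' @param path FASTA file (single or multi record). Sequences are
#'   case-normalised and validated against the 20-letter alphabet.
#' @return A list of [protein_record()]s in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  recs <- lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    protein_record(id, as.character(set[[i]]))
  })
  recs
}

#' Read Sanger reads from a FASTA file
#'
#' @param path FASTA file of nucleotide reads (A/C/G/T/N).
#' @return A list of [sanger_read()]s in file order.
#' @export
read_reads_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    sanger_read(id, as.character(set[[i]]))
  })
}

#' Write / read a design sheet
#'
#' @param tiles Design-sheet `data.frame` (`tile_id`, `parent_id`,
#'   `round`, `start`, `end`, `peptide`).
#' @param path TSV path.
#' @return `write_design_sheet` returns `path` invisibly;
#'   `read_design_sheet` returns the sheet.
#' @export
write_design_sheet <- function(tiles, path) {
  utils::write.table(tiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_sheet
#' @export
read_design_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(start = "integer", end = "integer"))
}

#' Write an oligo order sheet
#'
#' @param pairs List of `oligo_pair`s.
#' @param path TSV path.
#' @param fasta_path Optional FASTA path for the single strands, named
#'   `<tile_id>_plus` / `<tile_id>_minus`.
#' @return The order sheet `data.frame`, invisibly.
#' @export
write_oligo_sheet <- function(pairs, path, fasta_path = NULL) {
  sheet <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      tile_id = p$tile_id,
      peptide = p$peptide,
      n_terminal_pad = p$n_terminal_pad,
      cds = p$cds,
      plus_strand = p$plus_strand,
      minus_strand = p$minus_strand,
      length_nt = nchar(p$plus_strand),
      flags = paste(p$flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(sheet)) {
    sheet <- data.frame(tile_id = character(0), peptide = character(0),
                        n_terminal_pad = character(0), cds = character(0),
                        plus_strand = character(0), minus_strand = character(0),
                        length_nt = integer(0), flags = character(0),
                        stringsAsFactors = FALSE)
  }
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(fasta_path) && nrow(sheet) > 0L) {
    strands <- Biostrings::DNAStringSet(c(
      stats::setNames(sheet$plus_strand, paste0(sheet$tile_id, "_plus")),
      stats::setNames(sheet$minus_strand, paste0(sheet$tile_id, "_minus"))
    ))
    Biostrings::writeXStringSet(strands, fasta_path)
  }
  invisible(sheet)
}

#' Read a reactivity table from CSV/TSV
#'
#' Expects columns `tile_id` and either logical/0-1 `reactive` or numeric
#' `intensity` (binarised at `cutoff`).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param antibody_id Antibody label.
#' @param cutoff Intensity cutoff.
#' @return A [reactivity_table()].
#' @export
read_reactivity <- function(path, antibody_id = "ab", cutoff = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"tile_id" %in% names(tab)) stop("missing column tile_id", call. = FALSE)
  if ("reactive" %in% names(tab)) {
    reactivity_table(tab$tile_id, reactive = as.logical(tab$reactive),
                     intensity = tab$intensity, antibody_id = antibody_id,
                     cutoff = cutoff)
  } else if ("intensity" %in% names(tab)) {
    reactivity_table(tab$tile_id, intensity = tab$intensity,
                     antibody_id = antibody_id, cutoff = cutoff)
  } else {
    stop("need a reactive or intensity column", call. = FALSE)
  }
}

#' Run configuration
#'
#' Bundles every tunable parameter with defaults that reproduce the
#' method's worked design: round-1 18-mers at step 8, round-2 8-mers at
#' step 1, most-frequent E. coli codons, the printed synthesis prices, a
#' 0.8 kDa gel-resolution threshold and the 21-30 kDa weak-antigenic
#' window.
#'
#' @param round1_window,round1_step,round2_window,round2_step Tiling
#'   parameters (residues).
#' @param codon_mode,codon_seed,codon_table Codon policy fields.
#' @param pad_min_core Peptides shorter than this get the AAA pad.
#' @param distinct_kda Gel distinguishability threshold (kDa).
#' @param weak_window kDa bounds of the weak antigenic window.
#' @param reactivity_cutoff Intensity cutoff when binarising.
#' @param cost [cost_model()] parameters as a list.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(round1_window = 18L, round1_step = 8L,
                       round2_window = 8L, round2_step = 1L,
                       codon_mode = "most_frequent", codon_seed = 1L,
                       codon_table = "ecoli_k12",
                       pad_min_core = 6L, distinct_kda = 0.8,
                       weak_window = c(21, 30), reactivity_cutoff = 0,
                       cost = list(), seed = 1L) {
  if (round1_window < round2_window + 1L) {
    stop("round-1 window must be at least round-2 window + 1", call. = FALSE)
  }
  cfg <- structure(
    list(
      round1 = tile_scheme("round1", window = round1_window, step = round1_step),
      round2 = tile_scheme("round2", window = round2_window, step = round2_step),
      policy = codon_policy(codon_mode, seed = codon_seed,
                            table_id = codon_table),
      pad_min_core = as.integer(pad_min_core),
      distinct_kda = distinct_kda,
      weak_window = weak_window,
      reactivity_cutoff = reactivity_cutoff,
      cost = do.call(cost_model, cost),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; missing keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key '", unknown[1], "'", call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Run the full design-and-mapping pipeline
#'
#' Orchestrates tiling, oligo design, optional construct screening tables,
#' and two-round motif inference, writing every sheet and report under
#' `out_dir`. Round-2 reactivity may be omitted (design outputs only) or
#' may fail to cover some reactive round-1 region (warning in the report).
#'
#' @param protein A [protein_record()] (or path to a one-record FASTA).
#' @param round1_table Optional [reactivity_table()] over the round-1
#'   design.
#' @param round2_tables Optional list of [reactivity_table()]s, one per
#'   merged reactive interval in coordinate order.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return A list with `round1_tiles`, `round2_scans`, `oligos`,
#'   `screening`, `motif_report` (NULL without reactivity), `cost`.
#' @export
run_pipeline <- function(protein, round1_table = NULL, round2_tables = NULL,
                         config = run_config(), out_dir = NULL) {
  if (is.character(protein)) protein <- read_protein_fasta(protein)[[1]]
  stopifnot(inherits(protein, "protein_record"), inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }

  r1 <- assign_tile_ids(design_round1(protein, config$round1), 1L)
  next_id <- nrow(r1) + 1L
  emit("round1_design.tsv", r1, write_design_sheet)

  round2_scans <- list()
  motif_report <- NULL
  if (!is.null(round1_table)) {
    reactive1 <- r1[r1$tile_id %in%
                      round1_table$tile_id[round1_table$reactive], , drop = FALSE]
    intervals <- merge_reactive_parents(reactive1)
    for (i in seq_len(nrow(intervals))) {
      parent <- list(
        parent_id = protein$id,
        start = intervals$start[i], end = intervals$end[i],
        peptide = substr(protein$sequence, intervals$start[i], intervals$end[i])
      )
      tiles <- assign_tile_ids(design_round2(parent, config$round2), next_id)
      next_id <- next_id + nrow(tiles)
      tab <- if (!is.null(round2_tables) && i <= length(round2_tables)) {
        round2_tables[[i]]
      } else {
        NULL
      }
      round2_scans <- c(round2_scans, list(list(tiles = tiles, table = tab)))
    }
    if (length(round2_scans) > 0L &&
        all(vapply(round2_scans, function(s) !is.null(s$table), logical(1)))) {
      motif_report <- two_round_report(round1_table, r1, round2_scans, protein)
    } else if (length(round2_scans) > 0L) {
      warning("round-2 reactivity missing for some reactive region; ",
              "motif report omitted", call. = FALSE)
    } else {
      motif_report <- two_round_report(round1_table, r1, list(), protein)
    }
  }
  all_tiles <- rbind(r1, do.call(rbind, c(
    lapply(round2_scans, `[[`, "tiles"), list(r1[0, ])
  )))
  for (i in seq_along(round2_scans)) {
    emit(sprintf("round2_design_%d.tsv", i), round2_scans[[i]]$tiles,
         write_design_sheet)
  }

  oligos <- lapply(seq_len(nrow(all_tiles)), function(i) {
    pep <- pad_short_peptide(all_tiles$peptide[i], config$pad_min_core)
    build_oligo_pair(all_tiles$tile_id[i], pep, config$policy)
  })
  if (!is.null(out_dir)) {
    write_oligo_sheet(oligos, file.path(out_dir, "oligo_order.tsv"),
                      fasta_path = file.path(out_dir, "oligo_strands.fasta"))
  }

  screening <- screening_table(config)
  emit("screening.tsv", screening, write_design_sheet)

  cost <- design_cost_report(all_tiles, config$cost)
  emit("cost_report.tsv", cost$per_tile, write_design_sheet)

  if (!is.null(motif_report)) {
    mdf <- as.data.frame(motif_report)
    emit("motif_report.tsv", mdf, write_design_sheet)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(antibody = attr(round1_table, "antibody_id"),
             calls = mdf, warnings = motif_report$warnings),
        file.path(out_dir, "motif_report.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }
  list(round1_tiles = r1, round2_scans = round2_scans, oligos = oligos,
       screening = screening, motif_report = motif_report, cost = cost)
}

# Reference screening table: the gel bands a user compares against when
# picking recombinant clones.
#' @noRd
screening_table <- function(config) {
  kinds <- list(
    list(kind = "carrier_only", len = 0L),
    list(kind = "self_ligation_gsvd", len = 0L),
    list(kind = "r_clone", len = config$round2$window),
    list(kind = "r_clone", len = config$round1$window),
    list(kind = "carrier_e7", len = 0L)
  )
  ref <- fusion_product("carrier_only")
  do.call(rbind, lapply(kinds, function(k) {
    fp <- fusion_product(k$kind, k$len)
    dec <- screen_decision(fp, ref, config$distinct_kda)
    data.frame(
      construct = if (k$kind == "r_clone") {
        sprintf("r_clone_%dmer", k$len)
      } else {
        k$kind
      },
      total_res = fp$total_res,
      est_kda = round(as.numeric(fp$est_mass), 2),
      expressed = fp$expressed,
      in_weak_window = fp$in_weak_window,
      vs_carrier = dec$call,
      stringsAsFactors = FALSE
    )
  }))
}
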