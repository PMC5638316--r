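# Fine epitope-motif inference from per-tile Western-blot reactivity.
#
# For a step-1 scan of window W, a run of k consecutive reactive tiles
# pins the epitope to their intersection, a stretch of W - k + 1 residues
# (the shared sequence of the run); a single reactive tile bounds the
# epitope only to the whole tile.

#' Reactivity table
#'
#' Per-tile antibody reactivity from one blot. Graded intensities, when
#' provided, are binarised at `cutoff`; blots are otherwise read
#' qualitatively and the boolean calls are trusted as given.
#'
#' @param tile_id Character vector of tile labels (unique).
#' @param reactive Logical vector, or `NULL` to derive from `intensity`.
#' @param intensity Optional non-negative numeric intensities.
#' @param antibody_id Label of the mAb/antiserum probed.
#' @param cutoff Intensity cutoff when binarising (default: any positive).
#' @return A `data.frame` of class `reactivity_table` with columns
#'   `tile_id`, `reactive` and (if given) `intensity`; the antibody id is
#'   kept as an attribute.
#' @export
reactivity_table <- function(tile_id, reactive = NULL, intensity = NULL,
                             antibody_id = "ab", cutoff = 0) {
  if (anyDuplicated(tile_id)) stop("tile_ids must be unique", call. = FALSE)
  if (is.null(reactive)) {
    if (is.null(intensity)) stop("supply reactive or intensity", call. = FALSE)
    reactive <- intensity > cutoff
  }
  stopifnot(length(reactive) == length(tile_id))
  tab <- data.frame(tile_id = as.character(tile_id),
                    reactive = as.logical(reactive),
                    stringsAsFactors = FALSE)
  if (!is.null(intensity)) {
    stopifnot(all(intensity >= 0))
    tab$intensity <- intensity
  }
  attr(tab, "antibody_id") <- antibody_id
  class(tab) <- c("reactivity_table", "data.frame")
  tab
}

#' Find maximal runs of consecutive reactive tiles
#'
#' Tiles are ordered by start position; a run is a maximal block of
#' reactive tiles at consecutive scan positions (start-to-start distance
#' equal to the scan step). Non-reactive tiles break runs. Row order of
#' the reactivity table is immaterial.
#'
#' @param table A [reactivity_table()] whose `tile_id`s all appear in
#'   `tiles`.
#' @param tiles Design sheet of the step-1 scan the table was read from.
#' @return A list of design-sheet `data.frame`s, one per run, in
#'   coordinate order; empty list when nothing is reactive.
#' @export
find_reactive_runs <- function(table, tiles) {
  unknown <- setdiff(table$tile_id, tiles$tile_id)
  if (length(unknown) > 0L) {
    stop("reactivity table refers to unknown tile_id '", unknown[1], "'",
         call. = FALSE)
  }
  tiles <- tiles[order(tiles$start), , drop = FALSE]
  reactive <- tiles$tile_id %in% table$tile_id[table$reactive]
  if (!any(reactive)) return(list())
  step <- if (nrow(tiles) > 1L) min(diff(tiles$start)) else 1L
  runs <- list()
  current <- integer(0)
  for (i in seq_len(nrow(tiles))) {
    if (reactive[i]) {
      if (length(current) > 0L &&
          tiles$start[i] - tiles$start[current[length(current)]] != step) {
        runs <- c(runs, list(tiles[current, , drop = FALSE]))
        current <- integer(0)
      }
      current <- c(current, i)
    } else if (length(current) > 0L) {
      runs <- c(runs, list(tiles[current, , drop = FALSE]))
      current <- integer(0)
    }
  }
  if (length(current) > 0L) runs <- c(runs, list(tiles[current, , drop = FALSE]))
  runs
}

#' Infer the motif shared by a run of reactive tiles
#'
#' For a run of `k` reactive window-`W` step-1 tiles: `k == 1` bounds the
#' epitope to the whole tile (`isolated_tile`); `2 <= k <= W` pins it to
#' the intersection `[start of last tile, end of first tile]`, of length
#' `W - k + 1` (`exact`); `k > W` has an empty intersection and most
#' likely reflects several adjacent epitopes
#' (`ambiguous_empty_intersection`, interval = union of the run).
#'
#' @param run One run from [find_reactive_runs()] (a design-sheet
#'   `data.frame` with absolute protein coordinates).
#' @param protein The [protein_record()] the scan coordinates refer to.
#' @return A list of class `motif_call`: `run_tiles`, `motif`, `start`,
#'   `end`, `status`.
#' @export
infer_motif <- function(run, protein) {
  stopifnot(is.data.frame(run), nrow(run) >= 1L,
            inherits(protein, "protein_record"))
  run <- run[order(run$start), , drop = FALSE]
  W <- unique(nchar(run$peptide))
  if (length(W) != 1L) stop("run tiles must share one window length", call. = FALSE)
  k <- nrow(run)
  if (k > 1L && any(diff(run$start) != 1L)) {
    stop("run tiles are not consecutive", call. = FALSE)
  }
  if (k == 1L) {
    call <- new_motif_call(run, run$peptide[1], run$start[1], run$end[1],
                           "isolated_tile")
  } else if (k <= W) {
    start <- run$start[k]
    end <- run$end[1]
    call <- new_motif_call(run, substr(protein$sequence, start, end),
                           start, end, "exact")
  } else {
    warning("run of ", k, " tiles exceeds the window (", W,
            "); empty intersection - multiple adjacent epitopes are likely",
            call. = FALSE)
    call <- new_motif_call(run, "", run$start[1], run$end[k],
                           "ambiguous_empty_intersection")
  }
  map_to_protein(call, protein)
}

#' @noRd
new_motif_call <- function(run, motif, start, end, status) {
  structure(
    list(run_tiles = run$tile_id, motif = motif,
         start = as.integer(start), end = as.integer(end), status = status),
    class = "motif_call"
  )
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("<motif_call> %s^%d-%d (%s; tiles %s)\n",
              if (nzchar(x$motif)) x$motif else "<ambiguous>",
              x$start, x$end, x$status, paste(x$run_tiles, collapse = ",")))
  invisible(x)
}

#' Check a motif call against full-protein coordinates
#'
#' Confirms the call's 1-based inclusive interval lies on the protein and
#' (for non-ambiguous calls) that the motif equals the protein subsequence
#' there.
#'
#' @param call A `motif_call` whose tiles carry absolute coordinates.
#' @param protein The [protein_record()].
#' @return The validated call.
#' @export
map_to_protein <- function(call, protein) {
  stopifnot(inherits(call, "motif_call"), inherits(protein, "protein_record"))
  if (call$start < 1L || call$end > protein$length) {
    stop("motif interval [", call$start, ",", call$end,
         "] falls outside protein '", protein$id, "'", call. = FALSE)
  }
  if (call$status != "ambiguous_empty_intersection") {
    ref <- substr(protein$sequence, call$start, call$end)
    if (ref != call$motif) {
      stop("motif '", call$motif, "' does not match protein '", protein$id,
           "' at [", call$start, ",", call$end, "] ('", ref, "')", call. = FALSE)
    }
  }
  call
}

#' Degenerate consensus of equal-length motif variants
#'
#' Positions where all variants agree keep the residue; variable positions
#' become a bracketed set of the observed residues in alphabetical order
#' (e.g. `{ELRHY, EYRHY}` gives `E[LY]RHY`).
#'
#' @param variants Character vector of equal-length residue strings.
#' @return A list of class `degenerate_motif` with `pattern` and
#'   `variants`.
#' @export
consensus_motif <- function(variants) {
  stopifnot(length(variants) >= 1L)
  variants <- toupper(variants)
  lens <- nchar(variants)
  if (length(unique(lens)) != 1L) {
    stop("all variants must have equal length", call. = FALSE)
  }
  n <- lens[1]
  cols <- lapply(seq_len(n), function(i) {
    sort(unique(substring(variants, i, i)))
  })
  pattern <- paste(vapply(cols, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(list(pattern = pattern, variants = variants),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s (from %s)\n", x$pattern,
              paste(x$variants, collapse = ", ")))
  invisible(x)
}

#' Aggregate motif calls across both mapping rounds
#'
#' Combines the round-1 antigenic-peptide scan with the round-2 fine scans:
#' finds reactive round-1 tiles, checks each merged reactive interval is
#' covered by a round-2 scan, infers motifs from every round-2 run, and
#' deduplicates calls by protein interval and motif string. Provenance
#' records which reactive round-1 tile(s) overlap each motif.
#'
#' @param round1_table [reactivity_table()] over `round1_tiles`.
#' @param round1_tiles Round-1 design sheet.
#' @param round2_scans List of `list(tiles = <design sheet>, table =
#'   <reactivity_table>)`, one per fine scan.
#' @param protein The [protein_record()].
#' @return A list of class `motif_report`: `calls` (list of `motif_call`s,
#'   each with a `parents` field), `warnings` (uncovered reactive round-1
#'   regions), `reactive_round1` (tile ids).
#' @export
two_round_report <- function(round1_table, round1_tiles, round2_scans, protein) {
  unknown <- setdiff(round1_table$tile_id, round1_tiles$tile_id)
  if (length(unknown) > 0L) {
    stop("reactivity table refers to unknown tile_id '", unknown[1], "'",
         call. = FALSE)
  }
  reactive_ids <- round1_table$tile_id[round1_table$reactive]
  reactive_tiles <- round1_tiles[round1_tiles$tile_id %in% reactive_ids, ,
                                 drop = FALSE]
  reactive_tiles <- reactive_tiles[order(reactive_tiles$start), , drop = FALSE]
  warnings <- character(0)
  if (nrow(reactive_tiles) > 0L) {
    intervals <- merge_reactive_parents(reactive_tiles)
    for (i in seq_len(nrow(intervals))) {
      covered <- any(vapply(round2_scans, function(sc) {
        min(sc$tiles$start) <= intervals$start[i] &&
          max(sc$tiles$end) >= intervals$end[i]
      }, logical(1)))
      if (!covered) {
        warnings <- c(warnings, sprintf(
          "reactive round-1 interval [%d,%d] has no covering round-2 scan",
          intervals$start[i], intervals$end[i]
        ))
      }
    }
  }
  calls <- list()
  for (sc in round2_scans) {
    for (run in find_reactive_runs(sc$table, sc$tiles)) {
      calls <- c(calls, list(infer_motif(run, protein)))
    }
  }
  # deduplicate on (start, end, motif) at protein coordinates
  keys <- vapply(calls, function(cl) {
    paste(cl$start, cl$end, cl$motif, sep = "|")
  }, character(1))
  calls <- calls[!duplicated(keys)]
  # provenance: reactive round-1 tiles overlapping each motif interval
  calls <- lapply(calls, function(cl) {
    if (nrow(reactive_tiles) > 0L) {
      ov <- reactive_tiles$start <= cl$end & reactive_tiles$end >= cl$start
      cl$parents <- reactive_tiles$tile_id[ov]
    } else {
      cl$parents <- character(0)
    }
    cl
  })
  structure(
    list(calls = calls, warnings = warnings,
         reactive_round1 = reactive_tiles$tile_id,
         antibody_id = attr(round1_table, "antibody_id")),
    class = "motif_report"
  )
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> %d motif call(s)\n", length(x$calls)))
  for (cl in x$calls) print(cl)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Motif report as a data.frame
#'
#' @param x A `motif_report`.
#' @param ... Unused.
#' @return One row per motif call: `motif`, `start`, `end`, `status`,
#'   `run_tiles`, `parents`.
#' @export
as.data.frame.motif_report <- function(x, ...) {
  if (length(x$calls) == 0L) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), status = character(0),
                      run_tiles = character(0), parents = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$calls, function(cl) {
    data.frame(motif = cl$motif, start = cl$start, end = cl$end,
               status = cl$status,
               run_tiles = paste(cl$run_tiles, collapse = ","),
               parents = paste(cl$parents, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
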