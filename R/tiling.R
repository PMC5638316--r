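#' Protein record
#'
#' A validated protein sequence with an identifier, the unit on which
#' overlapping peptide tiles are designed.
#'
#' @param id Character identifier.
#' @param sequence Residue string over the 20 standard one-letter amino-acid
#'   codes (uppercased on input).
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `length`.
#' @examples
#' protein_record("toy", "MKTAYIAKQR")
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein sequence must be non-empty", call. = FALSE)
  validate_residues(sequence, what = paste0("protein '", id, "'"))
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

#' Tile scheme
#'
#' Window/step parameters for one round of overlapping-peptide design.
#' Round 1 scans the whole protein with 16- or 18-mers at step 8 (so
#' consecutive tiles share 8 or 10 residues); round 2 scans each reactive
#' round-1 region with 8-mers at step 1 (7 shared residues).
#'
#' @param round `"round1"` or `"round2"`.
#' @param window Tile length in residues. Defaults: 18 (round 1), 8 (round 2).
#' @param step Start-to-start distance in residues. Defaults: 8 (round 1),
#'   1 (round 2).
#' @return An object of class `tile_scheme`.
#' @examples
#' tile_scheme("round1")               # 18-mers, step 8
#' tile_scheme("round1", window = 16)  # 16-mers, step 8
#' tile_scheme("round2")               # 8-mers, step 1
#' @export
tile_scheme <- function(round = c("round1", "round2"), window = NULL, step = NULL) {
  round <- match.arg(round)
  if (is.null(window)) window <- if (round == "round1") 18L else 8L
  if (is.null(step)) step <- if (round == "round1") 8L else 1L
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (step < 1L || step > window) {
    stop("step must satisfy 1 <= step <= window", call. = FALSE)
  }
  structure(
    list(window = window, step = step, round = round,
         overlap = window - step),
    class = "tile_scheme"
  )
}

#' @export
print.tile_scheme <- function(x, ...) {
  cat(sprintf(
    "<tile_scheme> %s: %d-mers at step %d (overlap %d)\n",
    x$round, x$window, x$step, x$overlap
  ))
  invisible(x)
}

# Tiles are kept as a data.frame design sheet: one row per peptide, columns
# tile_id, parent_id, round, start, end, peptide (1-based inclusive
# coordinates on the parent protein).
#' @noRd
new_tile_sheet <- function(tile_id, parent_id, round, start, end, peptide) {
  data.frame(
    tile_id = tile_id, parent_id = parent_id, round = round,
    start = as.integer(start), end = as.integer(end), peptide = peptide,
    stringsAsFactors = FALSE
  )
}

#' Design round-1 overlapping peptide tiles
#'
#' Slides a 16/18-residue window along the full protein at the scheme's step.
#' If the last regular tile stops short of the C-terminus, one extra tile is
#' anchored at position `L - window + 1` so the tiles cover `[1, L]` exactly;
#' its overlap with the previous tile may exceed the nominal overlap. All
#' emitted peptides have full window length.
#'
#' @param protein A [protein_record()].
#' @param scheme A round-1 [tile_scheme()].
#' @return A design-sheet `data.frame` with columns `tile_id`, `parent_id`,
#'   `round`, `start`, `end`, `peptide`, ordered by start position and
#'   labelled `P1, P2, ...` (relabel with [assign_tile_ids()]).
#' @examples
#' p <- gen_protein(40, seed = 1)
#' design_round1(p, tile_scheme("round1"))
#' @seealso [design_round2()], [merge_reactive_parents()]
#' @export
design_round1 <- function(protein, scheme = tile_scheme("round1")) {
  stopifnot(inherits(protein, "protein_record"), inherits(scheme, "tile_scheme"))
  if (scheme$round != "round1") stop("scheme must be a round-1 scheme", call. = FALSE)
  L <- protein$length
  w <- scheme$window
  if (L < w) {
    stop(sprintf(
      "protein '%s' (%d aa) is shorter than the tile window; minimum length is %d",
      protein$id, L, w
    ), call. = FALSE)
  }
  starts <- seq.int(1L, L - w + 1L, by = scheme$step)
  last_end <- starts[length(starts)] + w - 1L
  if (last_end < L) starts <- c(starts, L - w + 1L)
  ends <- starts + w - 1L
  tiles <- new_tile_sheet(
    tile_id = paste0("P", seq_along(starts)),
    parent_id = protein$id,
    round = "round1",
    start = starts, end = ends,
    peptide = substring(protein$sequence, starts, ends)
  )
  tiles
}

#' Design round-2 8-mer tiles over a reactive region
#'
#' Enumerates every window-length peptide at step 1 across a reactive
#' round-1 tile (or a merged reactive interval), recording absolute 1-based
#' coordinates on the original protein. A parent of `n` residues yields
#' `n - window + 1` tiles, e.g. 11 eight-mers for an 18-mer parent.
#'
#' @param parent Either one row of a round-1 design sheet (a `data.frame`
#'   with `start`, `end`, `peptide`, `parent_id`) or a list with those
#'   fields.
#' @param scheme A round-2 [tile_scheme()] (default 8-mers at step 1).
#' @return A design-sheet `data.frame` as in [design_round1()].
#' @examples
#' p <- gen_protein(40, seed = 1)
#' r1 <- design_round1(p)
#' design_round2(r1[1, ], tile_scheme("round2"))
#' @export
design_round2 <- function(parent, scheme = tile_scheme("round2")) {
  stopifnot(inherits(scheme, "tile_scheme"))
  if (scheme$round != "round2") stop("scheme must be a round-2 scheme", call. = FALSE)
  if (is.data.frame(parent)) {
    stopifnot(nrow(parent) == 1L)
    parent <- as.list(parent)
  }
  plen <- nchar(parent$peptide)
  w <- scheme$window
  if (plen < w) {
    stop(sprintf("parent region (%d aa) is shorter than the window (%d aa)", plen, w),
         call. = FALSE)
  }
  offsets <- seq.int(0L, plen - w, by = scheme$step)
  starts <- parent$start + offsets
  new_tile_sheet(
    tile_id = paste0("P", seq_along(offsets)),
    parent_id = parent$parent_id,
    round = "round2",
    start = starts, end = starts + w - 1L,
    peptide = substring(parent$peptide, offsets + 1L, offsets + w)
  )
}

#' Merge reactive round-1 tiles into maximal intervals
#'
#' Takes the reactive round-1 tiles of one protein and returns the maximal
#' merged 1-based intervals of their union, so that an 8-mer scan over each
#' merged interval designs every 8-mer exactly once even where adjacent
#' reactive tiles overlap.
#'
#' @param reactive_tiles Design-sheet rows of the reactive tiles (one parent
#'   protein).
#' @return A `data.frame` with columns `start`, `end`, `parent_id`, one row
#'   per merged interval; zero rows for empty input.
#' @export
merge_reactive_parents <- function(reactive_tiles) {
  if (is.null(reactive_tiles) || nrow(reactive_tiles) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      parent_id = character(0), stringsAsFactors = FALSE))
  }
  if (length(unique(reactive_tiles$parent_id)) != 1L) {
    stop("reactive tiles must share one parent protein", call. = FALSE)
  }
  ord <- order(reactive_tiles$start, reactive_tiles$end)
  starts <- reactive_tiles$start[ord]
  ends <- reactive_tiles$end[ord]
  m_start <- starts[1]
  m_end <- ends[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end + 1L) {
      m_end <- max(m_end, ends[i])
    } else {
      out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
      m_start <- starts[i]; m_end <- ends[i]
    }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
  data.frame(start = out_s, end = out_e,
             parent_id = reactive_tiles$parent_id[1], stringsAsFactors = FALSE)
}

#' Relabel tiles with a serial P-number counter
#'
#' Labels tiles `P<start_index>, P<start_index + 1>, ...` in sheet order,
#' mirroring the serial numbering used on design sheets and blot lanes
#' (e.g. an 8-mer scan labelled P110..P120).
#'
#' @param tiles A design-sheet `data.frame`.
#' @param start_index First serial number (>= 1).
#' @return The sheet with `tile_id` replaced.
#' @export
assign_tile_ids <- function(tiles, start_index = 1L) {
  start_index <- as.integer(start_index)
  if (start_index < 1L) stop("start_index must be >= 1", call. = FALSE)
  if (nrow(tiles) > 0L) {
    tiles$tile_id <- paste0("P", seq.int(start_index, length.out = nrow(tiles)))
  }
  tiles
}
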