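scan_with_pattern <- function(protein, pattern, scan_start = 1L) {
  # build an 8-mer step-1 scan over the protein and a reactivity table
  # following the given 0/1 pattern (one digit per tile)
  parent <- list(parent_id = protein$id, start = scan_start,
                 end = protein$length,
                 peptide = substr(protein$sequence, scan_start, protein$length))
  tiles <- assign_tile_ids(design_round2(parent), 1L)
  stopifnot(nchar(pattern) == nrow(tiles))
  flags <- strsplit(pattern, "")[[1]] == "1"
  list(tiles = tiles,
       table = reactivity_table(tiles$tile_id, reactive = flags))
}

test_that("maximal reactive runs are found regardless of table row order", {
  p <- protein_with_motif("PLTLELQW", 7, 18, seed = 21)
  sc <- scan_with_pattern(p, "00000110000")
  runs <- find_reactive_runs(sc$table, sc$tiles)
  expect_length(runs, 1L)
  expect_equal(runs[[1]]$tile_id, c("P6", "P7"))

  none <- scan_with_pattern(p, "00000000000")
  expect_length(find_reactive_runs(none$table, none$tiles), 0L)

  p2 <- protein_record("p2", random_peptide(14, 22))
  sc2 <- scan_with_pattern(p2, "0110100")
  runs2 <- find_reactive_runs(sc2$table, sc2$tiles)
  expect_length(runs2, 2L)
  expect_equal(vapply(runs2, nrow, integer(1)), c(2L, 1L))

  # permutation invariance of reactivity rows
  shuffled <- sc2$table[c(5, 2, 7, 1, 3, 6, 4), ]
  attr(shuffled, "antibody_id") <- "ab"
  runs2b <- find_reactive_runs(shuffled, sc2$tiles)
  expect_identical(lapply(runs2b, `[[`, "tile_id"),
                   lapply(runs2, `[[`, "tile_id"))

  bogus <- reactivity_table(c("P1", "P99"), reactive = c(TRUE, TRUE))
  expect_error(find_reactive_runs(bogus, sc2$tiles), "P99")
})

test_that("run intersection pins the motif; isolated tiles bound it", {
  # two consecutive reactive 8-mers sharing a 7-residue stretch
  p <- protein_with_motif("PLTLELQ", 2, 9, seed = 31)  # a + motif + b
  sc <- scan_with_pattern(p, "11")
  runs <- find_reactive_runs(sc$table, sc$tiles)
  call <- infer_motif(runs[[1]], p)
  expect_equal(call$status, "exact")
  expect_equal(call$motif, "PLTLELQ")
  expect_equal(c(call$start, call$end), c(2L, 8L))

  # single reactive 8-mer: the whole tile is the bound
  p2 <- protein_with_motif("YYGVGDYP", 5, 20, seed = 32)
  sc2 <- scan_with_pattern(p2, paste(as.integer(seq_len(13) == 5), collapse = ""))
  call2 <- infer_motif(find_reactive_runs(sc2$table, sc2$tiles)[[1]], p2)
  expect_equal(call2$status, "isolated_tile")
  expect_equal(call2$motif, "YYGVGDYP")
  expect_equal(nchar(call2$motif), 8L)

  # run longer than the window: empty intersection, ambiguous
  p3 <- protein_record("p3", random_peptide(16, 33))
  sc3 <- scan_with_pattern(p3, "111111111")
  expect_warning(
    call3 <- infer_motif(find_reactive_runs(sc3$table, sc3$tiles)[[1]], p3),
    "multiple adjacent epitopes"
  )
  expect_equal(call3$status, "ambiguous_empty_intersection")
  expect_equal(call3$motif, "")
  expect_equal(c(call3$start, call3$end), c(1L, 16L))

  # non-consecutive tiles are rejected
  bad_run <- rbind(sc3$tiles[1, ], sc3$tiles[5, ])
  expect_error(infer_motif(bad_run, p3), "not consecutive")
})

test_that("motif length follows W - k + 1 for every run length", {
  W <- 8L
  for (k in 2:8) {
    m <- W - k + 1L
    motif <- random_peptide(m, 40 + k)
    p <- protein_with_motif(motif, 10, 40, seed = 50 + k)
    parent <- list(parent_id = p$id, start = 1L, end = p$length,
                   peptide = p$sequence)
    tiles <- assign_tile_ids(design_round2(parent), 1L)
    tab <- simulate_reactivity(tiles, list(list(motif = motif, position = 10L)))
    runs <- find_reactive_runs(tab, tiles)
    expect_length(runs, 1L)
    expect_equal(nrow(runs[[1]]), k)  # 9 - m reactive tiles
    call <- infer_motif(runs[[1]], p)
    expect_equal(nchar(call$motif), m)
    expect_equal(call$motif, motif)
  }
})

test_that("motif coordinates use the 1-based protein frame", {
  p <- protein_with_motif("DKNYGSY", 324, 340, seed = 61)
  parent <- list(parent_id = p$id, start = 317L, end = 338L,
                 peptide = substr(p$sequence, 317, 338))
  tiles <- assign_tile_ids(design_round2(parent), 1L)
  tab <- simulate_reactivity(tiles, list(list(motif = "DKNYGSY", position = 324L)))
  call <- infer_motif(find_reactive_runs(tab, tiles)[[1]], p)
  expect_equal(c(call$start, call$end), c(324L, 330L))
  expect_equal(call$motif, "DKNYGSY")

  # motif at the very start of the protein
  p1 <- protein_with_motif("WHKWMF", 1, 20, seed = 62)
  parent1 <- list(parent_id = p1$id, start = 1L, end = 13L,
                  peptide = substr(p1$sequence, 1, 13))
  tiles1 <- assign_tile_ids(design_round2(parent1), 1L)
  tab1 <- simulate_reactivity(tiles1, list(list(motif = "WHKWMF", position = 1L)))
  call1 <- infer_motif(find_reactive_runs(tab1, tiles1)[[1]], p1)
  expect_equal(call1$start, 1L)

  # coordinate mismatch with the protein is an error
  fake <- call
  fake$motif <- "AAAAAAA"
  expect_error(map_to_protein(fake, p), "does not match")
})

test_that("degenerate consensus brackets variable positions", {
  cm <- consensus_motif(c("ELRHY", "EYRHY"))
  expect_equal(cm$pattern, "E[LY]RHY")

  expect_equal(consensus_motif("CHIRP")$pattern, "CHIRP")
  expect_equal(consensus_motif(c("AAA", "ACA", "AGA"))$pattern, "A[ACG]A")
  expect_error(consensus_motif(c("AA", "AAA")), "equal length")

  # every variant matches the emitted pattern; pattern length == variant length
  for (seed in 1:10) {
    set.seed(seed)
    base <- random_peptide(6, 70 + seed)
    variants <- vapply(1:3, function(i) {
      v <- base
      pos <- sample(6, 1)
      substr(v, pos, pos) <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1)
      v
    }, character(1))
    pat <- consensus_motif(variants)$pattern
    expect_true(all(grepl(paste0("^", pat, "$"), variants)))
    expect_equal(nchar(gsub("\\[[A-Z]+\\]", "x", pat)), 6L)
  }
})

test_that("two-round reports aggregate, deduplicate and track provenance", {
  # three epitopes inside one protein, one sitting in the 10-aa overlap of
  # two adjacent round-1 18-mers
  set.seed(81)
  p <- gen_protein(80, seed = 81)
  p <- plant_epitope(p, "PLTLELQ", 20, seed = 1)$protein
  p <- plant_epitope(p, "DKNYGSY", 43, seed = 2)$protein  # inside [41,50] overlap
  p <- plant_epitope(p, "YYGVGDYP", 60, seed = 3)$protein
  eps <- list(list(motif = "PLTLELQ", position = 20L),
              list(motif = "DKNYGSY", position = 43L),
              list(motif = "YYGVGDYP", position = 60L))
  r1 <- assign_tile_ids(design_round1(p), 1L)
  t1 <- simulate_reactivity(r1, eps)
  reactive1 <- r1[r1$tile_id %in% t1$tile_id[t1$reactive], ]
  expect_gt(nrow(reactive1), 0L)
  # the overlap epitope makes both flanking 18-mers reactive
  olap <- reactive1$start <= 43 & reactive1$end >= 49
  expect_gte(sum(olap), 2L)

  intervals <- merge_reactive_parents(reactive1)
  scans <- lapply(seq_len(nrow(intervals)), function(i) {
    parent <- list(parent_id = p$id, start = intervals$start[i],
                   end = intervals$end[i],
                   peptide = substr(p$sequence, intervals$start[i],
                                    intervals$end[i]))
    tiles <- assign_tile_ids(design_round2(parent), 100L * i)
    list(tiles = tiles, table = simulate_reactivity(tiles, eps))
  })
  rep <- two_round_report(t1, r1, scans, p)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 3L)
  expect_setequal(df$motif, c("PLTLELQ", "DKNYGSY", "YYGVGDYP"))
  expect_equal(df$start[df$motif == "DKNYGSY"], 43L)
  # the overlap motif is one deduplicated call with two round-1 parents
  parents <- strsplit(df$parents[df$motif == "DKNYGSY"], ",")[[1]]
  expect_gte(length(parents), 2L)
  expect_length(rep$warnings, 0L)

  # no reactive round-1 tiles: empty report
  t_none <- reactivity_table(r1$tile_id, reactive = rep(FALSE, nrow(r1)))
  empty <- two_round_report(t_none, r1, list(), p)
  expect_length(empty$calls, 0L)

  # reactive regions without a covering round-2 scan are flagged
  partial <- two_round_report(t1, r1, list(), p)
  expect_gt(length(partial$warnings), 0L)
  expect_length(partial$calls, 0L)
})
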