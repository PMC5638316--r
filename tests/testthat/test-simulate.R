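test_that("protein generation is seeded and alphabet-correct", {
  a <- gen_protein(50, seed = 9)
  b <- gen_protein(50, seed = 9)
  expect_identical(a$sequence, b$sequence)
  expect_equal(gen_protein(237, seed = 1)$length, 237L)
  expect_error(gen_protein(5), ">= 8")

  differs <- vapply(1:20, function(s) {
    gen_protein(50, seed = s)$sequence != gen_protein(50, seed = s + 1000)$sequence
  }, logical(1))
  expect_true(all(differs))
})

test_that("planted epitopes occur exactly once at the requested position", {
  for (seed in 1:20) {
    m <- 3L + (seed %% 6L)
    motif <- random_peptide(m, 500 + seed)
    pos <- 10L + seed
    host <- gen_protein(80, seed = seed)
    planted <- plant_epitope(host, motif, pos, seed = seed)
    expect_equal(count_occurrences(motif, planted$protein$sequence), 1L)
    expect_equal(substr(planted$protein$sequence, pos, pos + m - 1L), motif)
    expect_equal(planted$epitope$position, pos)
  }
  host <- gen_protein(20, seed = 3)
  expect_error(plant_epitope(host, "YY", 5), "3-8")
  expect_error(plant_epitope(host, "YYGVGDYP", 19), "does not fit")
})

test_that("containment reactivity marks exactly the motif-containing tiles", {
  # 7-mer planted mid-protein: exactly two consecutive reactive 8-mers
  p <- protein_with_motif("PLTLELQ", 12, 30, seed = 91)
  parent <- list(parent_id = p$id, start = 1L, end = 30L, peptide = p$sequence)
  tiles <- assign_tile_ids(design_round2(parent), 1L)
  tab <- simulate_reactivity(tiles, list(list(motif = "PLTLELQ", position = 12L)))
  expect_equal(sum(tab$reactive), 2L)
  hit <- tiles[tiles$tile_id %in% tab$tile_id[tab$reactive], ]
  expect_equal(hit$start, c(11L, 12L))

  # count law 9 - m for every motif length
  for (m in 3:8) {
    motif <- random_peptide(m, 600 + m)
    pm <- protein_with_motif(motif, 15, 40, seed = 92 + m)
    parentm <- list(parent_id = pm$id, start = 1L, end = 40L,
                    peptide = pm$sequence)
    tilesm <- assign_tile_ids(design_round2(parentm), 1L)
    tabm <- simulate_reactivity(tilesm, list(list(motif = motif, position = 15L)))
    expect_equal(sum(tabm$reactive), 9L - m)
  }

  # a motif inside the 10-residue overlap of adjacent 18-mers lights up both
  po <- protein_with_motif("DKNYGSY", 20, 40, seed = 93)  # inside [17,26]
  r1 <- assign_tile_ids(design_round1(po), 1L)
  t1 <- simulate_reactivity(r1, list(list(motif = "DKNYGSY", position = 20L)))
  reactive <- r1[r1$tile_id %in% t1$tile_id[t1$reactive], ]
  expect_gte(nrow(reactive), 2L)

  # zero epitopes, zero noise: silence
  t0 <- simulate_reactivity(r1, list())
  expect_false(any(t0$reactive))
})

test_that("reactivity noise is seeded and never corrupts exact calls", {
  p <- protein_with_motif("WHKWM", 20, 60, seed = 94)
  parent <- list(parent_id = p$id, start = 1L, end = 60L, peptide = p$sequence)
  tiles <- assign_tile_ids(design_round2(parent), 1L)
  ep <- list(list(motif = "WHKWM", position = 20L))

  noisy1 <- simulate_reactivity(tiles, ep, reactivity_rule(0.05, 0.2, seed = 5))
  noisy2 <- simulate_reactivity(tiles, ep, reactivity_rule(0.05, 0.2, seed = 5))
  expect_identical(noisy1$reactive, noisy2$reactive)

  # with false negatives only, any exact/isolated call still contains the
  # planted motif interval (broken runs give wider, not wrong, intervals)
  for (seed in 1:15) {
    tab <- simulate_reactivity(tiles, ep, reactivity_rule(0, 0.3, seed = seed))
    for (run in find_reactive_runs(tab, tiles)) {
      call <- suppressWarnings(infer_motif(run, p))
      if (call$status %in% c("exact", "isolated_tile")) {
        expect_lte(call$start, 20L)
        expect_gte(call$end, 24L)
      }
    }
  }
})

test_that("simulated reads round-trip and respect mutation bounds", {
  pair <- build_oligo_pair("P7", random_peptide(8, 7))
  rd <- simulate_read(pair, seed = 1)
  expect_equal(verify_insert(rd, pair)$status, "match")

  rr <- simulate_read(pair, seed = 1, reverse = TRUE)
  v <- verify_insert(rr, pair)
  expect_equal(v$status, "match")
  expect_equal(v$orientation, "reverse")

  expect_error(simulate_read(pair, mutations = list(list(offset = 0, base = "A"))),
               "outside the insert")
  expect_error(simulate_read(pair, mutations = list(list(offset = 999, base = "A"))),
               "outside the insert")

  # one nonsynonymous substitution gives mismatch with one difference
  mut <- simulate_read(pair, mutations = list(list(offset = 8, base = "C")),
                       seed = 2)
  vm <- verify_insert(mut, pair)
  obs_pep <- oracle_translate(vm$extracted_cds)
  if (obs_pep == paste0(pair$n_terminal_pad, pair$peptide)) {
    expect_equal(vm$status, "match")  # synonymous draw
  } else {
    expect_equal(vm$status, "mismatch")
    expect_equal(nrow(vm$differences), 1L)
  }
})

test_that("fixture bundles drive the whole pipeline to the planted truth", {
  b <- simulate_bundle(protein_length = 120, seed = 11)
  expect_equal(count_occurrences(b$truth$motif, b$protein$sequence), 1L)
  rep <- two_round_report(b$round1_table, b$round1_tiles, b$round2_scans,
                          b$protein)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1L)
  expect_equal(df$motif, b$truth$motif)
  expect_equal(df$start, b$truth$start)
  expect_equal(df$end, b$truth$end)
  # reads verify against their oligos (a random flank can contain a spare
  # recognition site, which only triggers the first-hit warning)
  for (i in seq_along(b$oligos)) {
    v <- suppressWarnings(verify_insert(b$reads[[i]], b$oligos[[i]]))
    expect_equal(v$status, "match")
  }
})
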