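test_that("reverse translation is faithful and policy-controlled", {
  pol <- codon_policy()
  expect_equal(reverse_translate("M", pol), "ATG")
  expect_equal(reverse_translate("W", pol), "TGG")
  gs <- reverse_translate("GS", pol)
  expect_equal(nchar(gs), 6L)
  expect_equal(oracle_translate(gs), "GS")
  expect_error(reverse_translate("GJS", pol), "'J' at position 2")

  # seeded_random is reproducible and differs across seeds somewhere
  pep <- random_peptide(30, 11)
  r1 <- reverse_translate(pep, codon_policy("seeded_random", seed = 7))
  r2 <- reverse_translate(pep, codon_policy("seeded_random", seed = 7))
  expect_identical(r1, r2)
  expect_equal(oracle_translate(r1), pep)

  # round trip identity for both modes over random peptides
  for (seed in 1:10) {
    pep <- random_peptide(5 + seed, 100 + seed)
    expect_equal(oracle_translate(reverse_translate(pep, pol)), pep)
    expect_equal(
      oracle_translate(reverse_translate(
        pep, codon_policy("seeded_random", seed = seed))),
      pep
    )
  }
})

test_that("oligo pairs carry the cohesive flanks, stop and length law", {
  m <- build_oligo_pair("P0", "M")
  expect_equal(m$plus_strand, "GATCCATGTAAG")
  expect_equal(m$minus_strand, "TCGACTTACATG")

  for (n in c(8L, 16L, 18L)) {
    pair <- build_oligo_pair("Px", random_peptide(n, n))
    expect_equal(nchar(pair$plus_strand), 3L * n + 9L)
    expect_equal(nchar(pair$minus_strand), 3L * n + 9L)
    expect_match(pair$plus_strand, "^GATCC")
    expect_match(pair$plus_strand, "TAAG$")
    expect_match(pair$minus_strand, "^TCGACTTA")
    expect_match(pair$minus_strand, "G$")
  }
})

test_that("annealed duplex and reading frame laws hold for random peptides", {
  pol <- codon_policy()
  for (seed in 1:25) {
    n <- 3L + (seed %% 16L)
    pep <- random_peptide(n, 200 + seed)
    pair <- build_oligo_pair("Pr", pep, pol)
    # 4-nt overhangs GATC / TCGA stay single-stranded; the rest anneals
    expect_equal(
      oracle_revcomp(substr(pair$minus_strand, 5, nchar(pair$minus_strand))),
      substr(pair$plus_strand, 5, nchar(pair$plus_strand))
    )
    # frame 1 of the cds, and of plus strand positions 6..(6 + 3n - 1)
    expect_equal(oracle_translate(pair$cds), pep)
    expect_equal(
      oracle_translate(substr(pair$plus_strand, 6, 5 + 3 * n)),
      pep
    )
  }
})

test_that("internal-site scan distinguishes the two expected flanking sites", {
  clean <- build_oligo_pair("Pm", "M")
  hits <- scan_internal_sites(clean)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$expected))
  expect_setequal(hits$site, c("BamHI", "SalI"))

  vd <- build_oligo_pair("Pvd", "VD", cds = "GTCGAC", auto_recode = FALSE)
  vd_hits <- scan_internal_sites(vd)
  expect_true(any(!vd_hits$expected & vd_hits$site == "SalI"))

  gs <- build_oligo_pair("Pgs", "GS", cds = "GGATCC", auto_recode = FALSE)
  gs_hits <- scan_internal_sites(gs)
  expect_true(any(!gs_hits$expected & gs_hits$site == "BamHI"))
})

test_that("synonymous recoding removes internal sites and nothing else", {
  pol <- codon_policy()
  vd <- build_oligo_pair("Pvd", "VD", cds = "GTCGAC", auto_recode = FALSE)
  fixed <- recode_to_remove_sites(vd, pol)
  expect_true("recoded" %in% fixed$flags)
  expect_equal(oracle_translate(fixed$cds), "VD")
  expect_true(all(scan_internal_sites(fixed)$expected))
  # minimal repair: exactly one codon changed
  codon_of <- function(cds) substring(cds, c(1, 4), c(3, 6))
  expect_equal(sum(codon_of(fixed$cds) != codon_of(vd$cds)), 1L)

  gs <- build_oligo_pair("Pgs", "GS", cds = "GGATCC", auto_recode = FALSE)
  gs_fixed <- recode_to_remove_sites(gs, pol)
  expect_equal(oracle_translate(gs_fixed$cds), "GS")
  expect_true(all(scan_internal_sites(gs_fixed)$expected))
  expect_equal(sum(codon_of(gs_fixed$cds) != codon_of(gs$cds)), 1L)

  # identity on already-clean pairs
  clean <- build_oligo_pair("Pc", "MW")
  expect_identical(recode_to_remove_sites(clean, pol)$cds, clean$cds)
})

test_that("every emitted insert has exactly one BamHI and one SalI site", {
  pol_rand <- codon_policy("seeded_random", seed = 3)
  for (seed in 1:40) {
    pep <- random_peptide(3L + (seed %% 16L), 300 + seed)
    pol <- if (seed %% 2L) codon_policy() else pol_rand
    pair <- build_oligo_pair("Ps", pep, pol)
    ctx <- paste0("G", pair$plus_strand, "TCGAC")
    expect_equal(count_occurrences("GGATCC", ctx), 1L)
    expect_equal(count_occurrences("GTCGAC", ctx), 1L)
    expect_equal(oracle_translate(pair$cds), pep)
  }
})

test_that("short peptides receive the AAA construction pad", {
  p5 <- pad_short_peptide("ELRHY")
  expect_equal(as.character(p5), "AAAELRHY")
  expect_equal(attr(p5, "n_terminal_pad"), "AAA")
  p3 <- pad_short_peptide("RHY")
  expect_equal(as.character(p3), "AAARHY")
  p8 <- pad_short_peptide("YYGVGDYP")
  expect_equal(as.character(p8), "YYGVGDYP")
  expect_equal(attr(p8, "n_terminal_pad"), "")
  # threshold is configurable
  expect_equal(as.character(pad_short_peptide("PLTLELQ", min_core = 8)),
               "AAAPLTLELQ")

  # the pad flows into the oligo but stays out of the reported peptide
  pair <- build_oligo_pair("P5", p5)
  expect_equal(pair$n_terminal_pad, "AAA")
  expect_equal(pair$peptide, "ELRHY")
  expect_equal(oracle_translate(pair$cds), "AAAELRHY")
  expect_equal(nchar(pair$plus_strand), 3L * 8L + 9L)
})
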