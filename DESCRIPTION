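Package: bspmap
Title: Biosynthetic-Peptide Design and Fine B-Cell Epitope Mapping with a
    Truncated GST Carrier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for linear B-cell epitope (BCE) mapping with
    biosynthetic peptides (BSP) expressed as fusions with a truncated
    188-residue glutathione S-transferase carrier. Designs overlapping
    16/18-mer and 8-mer peptide tiles over a target protein, reverse
    translates each tile into clonable plus/minus oligonucleotide duplexes
    with BamHI/SalI cohesive ends and a TAA stop, screens and recodes
    internal restriction sites, predicts plasmid digest fragments and
    fusion-protein sizes used to screen recombinant clones on SDS-PAGE,
    verifies sequenced inserts against the design, infers minimal epitope
    motifs from per-tile Western-blot reactivity by tile intersection, and
    reproduces the method's tiered synthesis cost model. A simulation
    module generates proteins with planted epitopes, reactivity tables and
    Sanger reads so the whole pipeline can be exercised without wet-lab
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
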