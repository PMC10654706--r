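Package: conjscreen
Title: Recipient-Cell Conjugation Screen Analysis and PilV Receptor Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome-wide recipient-cell conjugation screens of the
    Keio single-gene deletion collection and inference of the lipopolysaccharide
    (LPS) receptor motifs recognized by PilV adhesins of IncI2 conjugative
    plasmids. Turns replicate 384-position colony-array density grids into
    per-mutant conjugation scores with replicate Pearson quality control,
    calls hits by Z score with hypergeometric term enrichment under
    Benjamini-Hochberg control, models E. coli core-oligosaccharide
    biosynthesis as gene-annotated glycan trees across the five core
    prototypes, and deduces minimal disaccharide receptor-motif sets
    consistent with adhesin-by-strain transfer panels. Includes seeded
    synthetic-data generators for both screen plates and receptor panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
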