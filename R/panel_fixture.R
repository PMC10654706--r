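#' Load the packaged PilV adhesin receptor panel
#'
#' Returns the package's synthetic transcription of the adhesin-by-strain
#' transfer panel: eight PilV variants against 25 recipient strains (the
#' five core-OS prototypes, ClearColi, K-12 waa knockouts, and waa
#' knock-in strains), together with genotypes and glycan structures built
#' from the packaged biosynthesis tables. The matrix is a reconstruction
#' assembled from the study's narrated knockout/knock-in observations and
#' its receptor summary, not measured data; it exists so the inference
#' engine can be exercised end to end without the original heat-map source
#' files.
#'
#' @return List with `matrix` (a [transfer_matrix()]), `genotypes` (named
#'   list of [genotype()]s), and `structures` (named list of
#'   [glycan_tree()]s).
#' @export
tp114_panel <- function() {
  pdir <- system.file("extdata", "panel", package = "conjscreen")
  tm <- read_transfer_matrix(file.path(pdir, "transfer_rates_synthetic.tsv"))
  raw <- jsonlite::fromJSON(file.path(pdir, "strains_synthetic.json"),
                            simplifyVector = FALSE)
  genotypes <- lapply(raw, function(x) {
    genotype(x$background, unlist(x$deletions) %||% character(),
             unlist(x$additions) %||% character())
  })
  structures <- lapply(genotypes, apply_genotype)
  list(matrix = tm, genotypes = genotypes, structures = structures)
}
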