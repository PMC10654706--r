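test_that("plate grids round-trip byte-exactly through their canonical form", {
  set.seed(11)
  for (i in 1:5) {
    dens <- matrix(round(stats::runif(384, 0, 50), 6), 16, 24)
    pg <- plate_grid(dens, sprintf("p%02d", i), "broth", "recipient", i)
    f1 <- withr::local_tempfile()
    f2 <- withr::local_tempfile()
    write_plate_grid(pg, f1)
    back <- read_plate_grid(f1)
    expect_equal(back$densities, pg$densities)
    expect_identical(back$plate_id, pg$plate_id)
    expect_identical(back$replicate, pg$replicate)
    write_plate_grid(back, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("an all-zero plate file parses into an all-zero grid", {
  f <- write_lines_tmp(c("# plate_id: z", "# condition: broth",
                         "# selection: recipient", "# replicate: 1",
                         rep(paste(rep("0", 24), collapse = "\t"), 16)))
  pg <- read_plate_grid(f)
  expect_true(all(pg$densities == 0))
})

test_that("plate parsing rejects wrong shapes, negatives and malformed numerics", {
  hdr <- c("# plate_id: x", "# condition: broth",
           "# selection: recipient", "# replicate: 1")
  row24 <- paste(rep("1", 24), collapse = "\t")
  expect_error(read_plate_grid(write_lines_tmp(c(hdr, rep(row24, 15)))),
               class = "conjscreen_shape_error")
  short <- paste(rep("1", 23), collapse = "\t")
  expect_error(read_plate_grid(write_lines_tmp(c(hdr, short, rep(row24, 15)))),
               class = "conjscreen_shape_error")
  neg <- sub("^1", "-2", row24)
  expect_error(read_plate_grid(write_lines_tmp(c(hdr, neg, rep(row24, 15)))),
               class = "conjscreen_validation_error")
  bad <- sub("^1", "1,5", row24)
  expect_error(read_plate_grid(write_lines_tmp(c(hdr, bad, rep(row24, 15)))),
               class = "conjscreen_parse_error")
})

test_that("CRLF line endings and trailing whitespace are accepted", {
  f <- withr::local_tempfile()
  lines <- c("# plate_id: crlf", "# condition: solid",
             "# selection: transconjugant", "# replicate: 2",
             rep(paste(c(rep("1.5", 23), "2 "), collapse = "\t"), 16))
  writeLines(paste0(lines, "\r"), f, sep = "\n")
  pg <- read_plate_grid(f)
  expect_equal(pg$densities[1, 24], 2)
  expect_identical(pg$condition, "solid")
})

test_that("series layouts validate positions and round-trip via JSON", {
  pos <- list(a = cbind(0:15, 0L), b = cbind(0:15, 1L))
  lay <- series_layout(pos, plate_of = c(a = "p1", b = "p1"))
  f <- withr::local_tempfile()
  write_series_layout(lay, f)
  back <- read_series_layout(f)
  expect_identical(back$mutant_positions, lay$mutant_positions)
  expect_identical(back$plate_of, lay$plate_of)
  expect_error(series_layout(list(a = cbind(0:15, 0L), b = cbind(0:15, 0L))),
               class = "conjscreen_validation_error")
  expect_error(series_layout(list(a = cbind(16L, 0L))),
               class = "conjscreen_validation_error")
  # same coordinates on different plates are fine
  expect_s3_class(series_layout(list(a = cbind(0:15, 0L), b = cbind(0:15, 0L)),
                                plate_of = c(a = "p1", b = "p2")),
                  "series_layout")
})

test_that("transfer matrices round-trip with BD sentinels intact", {
  rates <- matrix(c(1e-3, NA, 5.9e-5, 1e-7), 2, 2)
  bd <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  tm <- transfer_matrix(rates, bd, adhesins = c("A", "B"),
                        strains = c("s1", "s2"))
  f <- withr::local_tempfile()
  write_transfer_matrix(tm, f)
  back <- read_transfer_matrix(f)
  expect_equal(back$rates, tm$rates)
  expect_identical(back$below_detection, tm$below_detection)
  expect_error(transfer_matrix(matrix(-1e-3), adhesins = "A", strains = "s"),
               class = "conjscreen_validation_error")
  f2 <- write_lines_tmp(c("adhesin\ts1", "A\tabc"))
  expect_error(read_transfer_matrix(f2), class = "conjscreen_parse_error")
})

test_that("glycan tables round-trip and reject dangling or malformed rows", {
  tree <- build_prototype("K-12")
  f <- withr::local_tempfile()
  write_glycan_table(tree, f)
  back <- read_glycan_table(f)
  expect_setequal(back$residues$id, tree$residues$id)
  expect_identical(names(enumerate_motifs(back)), names(enumerate_motifs(tree)))

  hdr <- paste(c("residue_id", "mono", "stereo", "anomeric", "child_pos",
                 "parent_pos", "parent_id", "substituents", "added_by"),
               collapse = "\t")
  one <- "root\tlipA\t\tn/a\t\t\tROOT\t\tconstitutive"
  expect_s3_class(read_glycan_table(write_lines_tmp(c(hdr, one))), "glycan_tree")
  dangling <- c(hdr, one, "x\tGlc\t\ta\t1\t3\tnope\t\twaaG")
  expect_error(read_glycan_table(write_lines_tmp(dangling)),
               class = "conjscreen_reference_error")
  badanom <- c(hdr, one, "x\tGlc\t\tq\t1\t3\troot\t\twaaG")
  expect_error(read_glycan_table(write_lines_tmp(badanom)),
               class = "conjscreen_parse_error")
})

test_that("the packaged K-12 table carries the waaP phosphate on heptose I", {
  f <- system.file("extdata", "lps", "glycan_k12.tsv", package = "conjscreen")
  tree <- read_glycan_table(f)
  expect_gte(nrow(tree$residues), 12)
  hep1 <- tree$residues[tree$residues$id == "HepI", ]
  expect_true("4P:waaP" %in% hep1$subs[[1]])
  expect_identical(tree$residues$added_by[tree$residues$id == "HepI"], "waaC")
})

test_that("motif rendering matches the field's naming and is injective", {
  expect_identical(
    render_motif(motif("GlcNAc", "b", 1, 7, "Hep")),
    "GlcNAc-b(1-7)-Hep"
  )
  expect_identical(
    render_motif(motif("Hep", "a", 1, 3, "Hep", proximal_sub = "4P")),
    "Hep-a(1-3)-Hep[4P]"
  )
  expect_match(
    render_motif(motif("Hep", "a", 1, 3, "Hep", proximal_sub = "4P",
                       distal_stereo = "L-D", proximal_stereo = "D-D"),
                 full_names = TRUE),
    "^L-glycero-D-manno-heptose-a-\\(1-3\\)-D-glycero-D-manno-heptose-4-phosphate$"
  )
  # injectivity over every motif of every packaged prototype
  all_motifs <- unlist(lapply(setdiff(lps_backgrounds(), "ClearColi"),
                              function(b) names(enumerate_motifs(build_prototype(b)))))
  objs <- lapply(unique(all_motifs), parse_motif)
  expect_identical(vapply(objs, render_motif, character(1)), unique(all_motifs))
})

test_that("parse_motif inverts render_motif and rejects junk", {
  m <- motif("Gal", "b", 1, 4, "Glc", proximal_sub = c("4P"))
  expect_identical(render_motif(parse_motif(render_motif(m))), render_motif(m))
  expect_error(parse_motif("not a motif"), class = "conjscreen_parse_error")
})
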