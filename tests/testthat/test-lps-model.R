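k12 <- function(del = character(), add = character()) {
  apply_genotype(genotype("K-12", deletions = del, additions = add))
}

test_that("every prototype tree is a valid rooted acyclic glycan tree", {
  for (bg in lps_backgrounds()) {
    tree <- build_prototype(bg)
    expect_s3_class(tree, "glycan_tree")
    expect_identical(sum(is.na(tree$residues$parent_id)), 1L)
    if (bg == "ClearColi") {
      expect_identical(nrow(tree$residues), 1L)
      expect_length(enumerate_motifs(tree), 0)
    } else {
      expect_gte(nrow(tree$residues), 11)
    }
  }
})

test_that("the K-12 prototype displays its narrated motifs", {
  wt <- build_prototype("K-12")
  expect_true(contains_motif(wt, "GlcNAc-b(1-7)-Hep"))
  expect_true(contains_motif(wt, "Hep-a(1-3)-Hep"))
  expect_true(contains_motif(wt, "Hep-a(1-3)-Hep[4P]"))
  expect_true(contains_motif(wt, "Glc-a(1-2)-Glc"))
  ms <- names(enumerate_motifs(wt))
  expect_true(all(c("Hep-a(1-3)-Hep", "Hep-a(1-3)-Hep[4P]") %in% ms))
})

test_that("motif count equals saccharide edges times substituent multiplicity", {
  wt <- build_prototype("K-12")
  r <- wt$residues
  anchor <- r$id[is.na(r$parent_id)]
  edges <- r[!is.na(r$parent_id) & r$parent_id != anchor, ]
  mult <- vapply(seq_len(nrow(edges)), function(i) {
    p <- match(edges$parent_id[i], r$id)
    (1 + (length(edges$subs[[i]]) > 0)) * (1 + (length(r$subs[[p]]) > 0))
  }, numeric(1))
  expect_identical(length(enumerate_motifs(wt)), as.integer(sum(mult)))
  no_var <- enumerate_motifs(wt, include_substituent_variants = FALSE)
  expect_identical(length(no_var), nrow(edges))
})

test_that("every enumerated motif is contained in its own tree", {
  for (bg in c("K-12", "R3", "R4")) {
    tree <- build_prototype(bg)
    for (m in enumerate_motifs(tree)) expect_true(contains_motif(tree, m))
  }
  expect_false(contains_motif(build_prototype("ClearColi"),
                              "GlcNAc-b(1-7)-Hep"))
})

test_that("waaL truncation removes the terminal GlcNAc motif", {
  tree <- k12("waaL")
  expect_false(contains_motif(tree, "GlcNAc-b(1-7)-Hep"))
  expect_true(contains_motif(tree, "Hep-a(1-6)-Glc"))
})

test_that("phosphate logic: waaP is required, waaY and waaQ are not", {
  expect_false(contains_motif(k12("waaP"), "Hep-a(1-3)-Hep[4P]"))
  expect_true(contains_motif(k12("waaP"), "Hep-a(1-3)-Hep"))
  expect_true(contains_motif(k12("waaY"), "Hep-a(1-3)-Hep[4P]"))
  expect_true(contains_motif(k12("waaQ"), "Hep-a(1-3)-Hep[4P]"))
  expect_false(contains_motif(k12("waaQ"), "Hep-a(1-7)-Hep"))
  # waaY's phosphate depends on waaP acting first
  expect_false(contains_motif(k12("waaP"), "Hep[6P]-a(1-3)-Hep"))
  expect_true(contains_motif(k12("waaY"), "Hep-a(1-3)-Hep[4P]"))
  expect_false(contains_motif(k12("waaY"), "Hep[6P]-a(1-3)-Hep[4P]"))
})

test_that("inner-core truncations cascade to everything distal", {
  for (g in c("waaF", "waaC", "waaE", "gmhD")) {
    tree <- k12(g)
    expect_false(contains_motif(tree, "Hep-a(1-3)-Hep[4P]"))
    expect_false(contains_motif(tree, "GlcNAc-b(1-7)-Hep"))
    expect_false(contains_motif(tree, "Glc-a(1-3)-Hep"))
  }
  # waaF keeps heptose I, waaC and the precursor pathway lose all heptoses
  expect_true(contains_motif(k12("waaF"), "Hep-a(1-5)-Kdo"))
  expect_false(contains_motif(k12("waaC"), "Hep-a(1-5)-Kdo"))
  expect_false(contains_motif(k12("gmhD"), "Hep-a(1-5)-Kdo"))
  expect_identical(names(enumerate_motifs(k12("waaC"))), "Kdo-a(2-4)-Kdo")
})

test_that("knock-ins graft onto matching parents (waaI+waaD gains the PilVD' motif)", {
  tree <- k12(add = c("R3:waaI", "R3:waaD"))
  expect_true(contains_motif(tree, "GlcNAc-a(1-3)-Gal"))
  expect_true(contains_motif(tree, "Gal-a(1-3)-Glc"))
  expect_true(contains_motif(tree, "GlcNAc-b(1-7)-Hep"))
  # listing order cannot matter: waaD precedes waaI alphabetically but needs
  # waaI's product
  tree2 <- k12(add = c("R3:waaD", "R3:waaI"))
  expect_identical(names(enumerate_motifs(tree2)),
                   names(enumerate_motifs(tree)))
  expect_true(contains_motif(k12(add = "R2:waaK"), "GlcNAc-a(1-2)-Glc"))
})

test_that("an addition with no matching parent warns and changes nothing", {
  expect_warning(tree <- k12("waaR", add = "R2:waaK"), "waaK")
  expect_identical(names(enumerate_motifs(tree)),
                   names(enumerate_motifs(k12("waaR"))))
})

test_that("unknown genes in deletions or additions are rejected", {
  expect_error(k12("notAGene"), class = "conjscreen_reference_error")
  expect_error(k12(add = "notAGene"), class = "conjscreen_reference_error")
  expect_error(k12(add = "waaT"), class = "conjscreen_reference_error")  # ambiguous source
  expect_error(genotype("K-12", deletions = "waaK", additions = "waaK"),
               class = "conjscreen_validation_error")
})

test_that("knockouts only remove motifs; knock-ins only add them", {
  genes <- c("waaL", "waaU", "waaR", "waaO", "waaB", "waaG", "waaQ",
             "waaY", "waaP", "waaF", "waaC")
  set.seed(14)
  for (i in 1:12) {
    del <- sample(genes, sample(0:3, 1))
    base <- names(enumerate_motifs(k12(del)))
    extra <- sample(setdiff(genes, del), 1)
    deeper <- names(enumerate_motifs(k12(c(del, extra))))
    expect_true(all(deeper %in% base),
                label = paste("deletions", paste(c(del, extra), collapse = "+")))
  }
  base <- names(enumerate_motifs(k12()))
  added <- names(enumerate_motifs(suppressWarnings(k12(add = "R4:waaX"))))
  expect_true(all(base %in% added))
})

test_that("deletion order never changes the resulting structure", {
  del <- c("waaY", "waaB", "waaR")
  t1 <- k12(del)
  t2 <- k12(rev(del))
  t3 <- k12(sample(del))
  expect_identical(t1$residues, t2$residues)
  expect_identical(t1$residues, t3$residues)
})

test_that("substituent constraints are positive-only in matching", {
  # a structure with extra substituents still matches the bare motif
  wt <- build_prototype("K-12")
  expect_true(contains_motif(wt, "Hep-a(1-3)-Hep"))
  # but a required substituent must be present
  expect_false(contains_motif(k12("waaP"), "Hep-a(1-3)-Hep[4P]"))
})
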