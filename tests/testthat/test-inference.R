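tiny_panel <- function(perm, strains, adhesins = rownames(perm)) {
  rates <- ifelse(perm, 1e-2, NA_real_)
  transfer_matrix(rates, !perm, adhesins = adhesins, strains = strains)
}

test_that("binarize applies the inclusive significance floor", {
  rates <- matrix(c(1e-3, NA, 5.9e-5, 5.8e-5), 1, 4)
  bd <- matrix(c(FALSE, TRUE, FALSE, FALSE), 1, 4)
  tm <- transfer_matrix(rates, bd, adhesins = "A",
                        strains = c("hot", "bd", "edge", "under"))
  p <- binarize(tm)
  expect_identical(unname(p$permissive["A", ]), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(p$floor, 5.9e-5)
})

test_that("inference matches the paper's PilVC knockout reasoning", {
  strains <- c("wt", "dwaaL", "dwaaU", "dwaaG", "clearcoli")
  structures <- list(
    wt = apply_genotype(genotype("K-12")),
    dwaaL = apply_genotype(genotype("K-12", "waaL")),
    dwaaU = apply_genotype(genotype("K-12", "waaU")),
    dwaaG = apply_genotype(genotype("K-12", "waaG")),
    clearcoli = apply_genotype(genotype("ClearColi"))
  )
  perm <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE), 1,
                 dimnames = list("PilVC", strains))
  calls <- infer_receptors(binarize(tiny_panel(perm, strains)), structures)
  expect_identical(calls$PilVC$status, "unique")
  expect_identical(calls$PilVC$minimal_sets[[1]], "GlcNAc-b(1-7)-Hep")
})

test_that("a permissive strain dominated by a non-permissive one is inconsistent", {
  strains <- c("small", "big")
  structures <- list(
    small = chain_tree(c("Kdo", "Glc"), c("a", "a"), c(6, 3)),
    big = chain_tree(c("Kdo", "Glc", "Gal"), c("a", "a", "b"), c(6, 3, 4))
  )
  perm <- matrix(c(TRUE, FALSE), 1, dimnames = list("A", strains))
  calls <- infer_receptors(binarize(tiny_panel(perm, strains)), structures)
  expect_identical(calls$A$status, "inconsistent")
  ev <- explain_call(calls$A, binarize(tiny_panel(perm, strains)), structures)
  expect_identical(unname(ev$conflict["permissive"]), "small")
  expect_identical(unname(ev$conflict["non_permissive"]), "big")
})

test_that("degenerate panels: no strains, no permissive strain, single strain", {
  strains <- c("s1")
  structures <- list(s1 = chain_tree(c("Kdo", "Glc", "Gal"),
                                     c("a", "a", "b"), c(6, 3, 4)))
  none <- matrix(FALSE, 1, 1, dimnames = list("A", strains))
  calls <- infer_receptors(binarize(tiny_panel(none, strains)), structures)
  expect_identical(calls$A$status, "no_permissive")

  one <- matrix(TRUE, 1, 1, dimnames = list("A", strains))
  calls1 <- infer_receptors(binarize(tiny_panel(one, strains)), structures)
  expect_identical(calls1$A$status, "ambiguous")
  # all singletons of the strain's motifs are minimal sound sets
  expect_setequal(unlist(calls1$A$minimal_sets),
                  names(enumerate_motifs(structures$s1)))
  expect_true(all(lengths(calls1$A$minimal_sets) == 1))
})

test_that("returned sets are sound and minimal on every call", {
  for (s in 1:10) {
    sim <- simulate_panel(panel_sim_config(n_strains = 8, n_adhesins = 3,
                                           universe_size = 6, seed = s))
    panel <- binarize(sim$matrix)
    M <- conjscreen:::containment_matrix(panel$strains, sim$structures)
    calls <- infer_receptors(panel, sim$structures, kmax = 3)
    for (a in panel$adhesins) {
      perm <- panel$strains[panel$permissive[a, ]]
      nonperm <- setdiff(panel$strains, perm)
      if (!calls[[a]]$status %in% c("unique", "ambiguous")) next
      for (S in calls[[a]]$minimal_sets) {
        expect_true(all(rowSums(M[perm, S, drop = FALSE]) > 0))
        if (length(nonperm)) {
          expect_identical(sum(M[nonperm, S, drop = FALSE]), 0L)
        }
        if (length(S) > 1) {
          for (drop in seq_along(S)) {
            sub <- S[-drop]
            expect_false(all(rowSums(M[perm, sub, drop = FALSE]) > 0))
          }
        }
      }
    }
  }
})

test_that("pruned inference equals the exhaustive oracle (200-seed sweep)", {
  for (s in 0:199) {
    sim <- simulate_panel(panel_sim_config(n_strains = 8, n_adhesins = 2,
                                           universe_size = 6,
                                           flip_prob = if (s %% 4 == 0) 0.05 else 0,
                                           seed = s))
    panel <- binarize(sim$matrix)
    calls <- infer_receptors(panel, sim$structures, kmax = 3)
    oracle <- brute_force_oracle(panel, sim$structures, kmax = 3)
    expect_identical(call_signature(calls), call_signature(oracle),
                     label = paste("seed", s))
  }
})

test_that("adding a strain can only constrain the sound sets", {
  for (s in 1:8) {
    sim <- simulate_panel(panel_sim_config(n_strains = 6, n_adhesins = 1,
                                           universe_size = 5, seed = s))
    full_panel <- binarize(sim$matrix)
    reduced <- full_panel
    keep <- full_panel$strains[-length(full_panel$strains)]
    reduced$permissive <- full_panel$permissive[, keep, drop = FALSE]
    reduced$strains <- keep
    sound_sets <- function(panel, structures) {
      calls <- brute_force_oracle(panel, structures, kmax = 2)
      calls[[1]]$minimal_sets
    }
    # every minimal sound set of the larger panel is sound in the smaller
    M <- conjscreen:::containment_matrix(full_panel$strains, sim$structures)
    big <- sound_sets(full_panel, sim$structures)
    small_perm <- keep[reduced$permissive[1, ]]
    small_nonperm <- setdiff(keep, small_perm)
    for (S in big) {
      expect_true(all(rowSums(M[small_perm, S, drop = FALSE]) > 0))
      if (length(small_nonperm)) {
        expect_identical(sum(M[small_nonperm, S, drop = FALSE]), 0L)
      }
    }
  }
})

test_that("planted receptor sets are recovered on discriminating panels", {
  hits <- 0; total <- 0; wrong_unique <- 0
  for (s in 0:99) {
    sim <- simulate_panel(panel_sim_config(n_strains = 12, n_adhesins = 1,
                                           universe_size = 8, seed = s))
    calls <- infer_receptors(binarize(sim$matrix), sim$structures, kmax = 3)
    total <- total + 1
    got <- calls[[1]]
    if (got$status == "unique" &&
        identical(got$minimal_sets[[1]], sim$truth$planted_sets[[1]])) {
      hits <- hits + 1
    } else if (got$status == "unique") {
      wrong_unique <- wrong_unique + 1
    }
  }
  expect_gte(hits / total, 0.95)
  expect_equal(wrong_unique, 0)
})

test_that("one flipped cell degrades the call rather than misleading it", {
  wrong <- 0; changed_or_same_correct <- 0
  for (s in 0:49) {
    sim <- simulate_panel(panel_sim_config(n_strains = 12, n_adhesins = 1,
                                           universe_size = 8, seed = s))
    perm <- sim$truth$permissive
    j <- (s %% ncol(perm)) + 1
    perm[1, j] <- !perm[1, j]
    tm <- tiny_panel(perm, colnames(perm))
    calls <- infer_receptors(binarize(tm), sim$structures, kmax = 3)
    st <- calls[[1]]$status
    if (st == "unique" &&
        !identical(calls[[1]]$minimal_sets[[1]], sim$truth$planted_sets[[1]])) {
      wrong <- wrong + 1
    }
  }
  expect_lte(wrong / 50, 0.10)
})

test_that("max_violations tolerates the configured number of cells", {
  strains <- c("s1", "s2", "s3")
  structures <- list(
    s1 = chain_tree(c("Kdo", "Glc"), c("a", "a"), c(6, 3)),
    s2 = chain_tree(c("Kdo", "Glc"), c("a", "a"), c(6, 3)),
    s3 = chain_tree(c("Kdo", "Gal"), c("a", "b"), c(6, 4))
  )
  # s2 is identical to s1 but observed non-permissive: unsatisfiable at 0
  perm <- matrix(c(TRUE, FALSE, FALSE), 1, dimnames = list("A", strains))
  p <- binarize(tiny_panel(perm, strains))
  expect_identical(infer_receptors(p, structures)$A$status, "inconsistent")
  relaxed <- infer_receptors(p, structures, max_violations = 1)
  expect_true(relaxed$A$status %in% c("unique", "ambiguous"))
  expect_true(all(relaxed$A$violations <= 1))
})

test_that("explain_call reports witnesses and discriminating suggestions", {
  sim <- simulate_panel(panel_sim_config(n_strains = 10, n_adhesins = 1,
                                         universe_size = 6, seed = 4))
  panel <- binarize(sim$matrix)
  calls <- infer_receptors(panel, sim$structures, kmax = 3)
  ev <- explain_call(calls[[1]], panel, sim$structures)
  perm_rows <- ev$per_strain[ev$per_strain$permissive, ]
  if (calls[[1]]$status == "unique") {
    expect_true(all(nzchar(perm_rows$motifs_present)))
  }
  # force an ambiguous call: single permissive strain with several motifs
  strains <- "s1"
  structures <- list(s1 = chain_tree(c("Kdo", "Glc", "Gal"),
                                     c("a", "a", "b"), c(6, 3, 4)))
  one <- matrix(TRUE, 1, 1, dimnames = list("A", strains))
  pan1 <- binarize(tiny_panel(one, strains))
  amb <- infer_receptors(pan1, structures)
  ev1 <- explain_call(amb$A, pan1, structures)
  expect_identical(ev1$status, "ambiguous")
  expect_match(ev1$suggestion, "separate")
})
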