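#' Binarize a transfer matrix at the significance floor
#'
#' A cell is permissive when its transfer frequency reaches the floor
#' (boundary inclusive: frequencies "underneath" the floor are discarded as
#' not significant); below-detection sentinels are never permissive.
#'
#' @param tm a [transfer_matrix()].
#' @param floor significance floor on the transfer frequency
#'   (default `5.9e-5`).
#' @return A `binary_panel`: logical permissive matrix plus the threshold
#'   used (provenance).
#' @export
binarize <- function(tm, floor = 5.9e-5) {
  stopifnot(inherits(tm, "transfer_matrix"))
  permissive <- !tm$below_detection & !is.na(tm$rates) & tm$rates >= floor
  dimnames(permissive) <- list(tm$adhesins, tm$strains)
  structure(list(permissive = permissive, adhesins = tm$adhesins,
                 strains = tm$strains, floor = floor),
            class = "binary_panel")
}

#' @export
print.binary_panel <- function(x, ...) {
  cat(sprintf("<binary_panel> %d adhesins x %d strains, floor %g\n",
              length(x$adhesins), length(x$strains), x$floor))
  invisible(x)
}

# containment matrix: strains x motifs (canonical strings), over the union
# of motifs displayed by the panel structures
containment_matrix <- function(strains, structures) {
  missing <- setdiff(strains, names(structures))
  if (length(missing) > 0) {
    stop_conjscreen(sprintf("no structure for panel strain '%s'", missing[1]),
                    "conjscreen_reference_error")
  }
  per_strain <- lapply(strains, function(s) {
    names(enumerate_motifs(structures[[s]], include_substituent_variants = TRUE))
  })
  universe <- sort(unique(unlist(per_strain)))
  M <- matrix(FALSE, length(strains), length(universe),
              dimnames = list(strains, universe))
  for (i in seq_along(strains)) M[i, per_strain[[i]]] <- TRUE
  M
}

all_subsets_upto <- function(items, kmax) {
  out <- list()
  for (k in seq_len(min(kmax, length(items)))) {
    cmb <- utils::combn(items, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# drop sets that have a proper subset also present
minimal_sets_only <- function(sets) {
  if (length(sets) <= 1) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] &&
          length(sets[[j]]) < length(sets[[i]]) &&
          all(sets[[j]] %in% sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

sort_sets <- function(sets) {
  sets <- lapply(sets, sort)
  ord <- order(vapply(sets, length, integer(1)),
               vapply(sets, paste, character(1), collapse = "|"))
  sets[ord]
}

receptor_call <- function(adhesin, status, minimal_sets, witness = NULL,
                          violations = NULL) {
  structure(list(adhesin = adhesin, status = status,
                 minimal_sets = minimal_sets, witness = witness,
                 violations = violations),
            class = "receptor_call")
}

#' @export
print.receptor_call <- function(x, ...) {
  cat(sprintf("<receptor_call> %s: %s\n", x$adhesin, x$status))
  for (s in x$minimal_sets) cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
print.receptor_calls <- function(x, ...) {
  for (cl in x) print(cl)
  invisible(x)
}

witness_table <- function(set, perm, M) {
  tibble(
    strain = rownames(M),
    permissive = rownames(M) %in% perm,
    motifs_present = vapply(rownames(M), function(s) {
      paste(set[M[s, set]], collapse = ", ")
    }, character(1))
  )
}

infer_one <- function(adhesin, perm, nonperm, M, kmax, max_violations) {
  universe <- colnames(M)
  if (length(perm) + length(nonperm) == 0) {
    return(receptor_call(adhesin, "ambiguous",
                         sort_sets(as.list(universe))))
  }
  if (length(perm) == 0) {
    return(receptor_call(adhesin, "no_permissive", list(character())))
  }
  if (max_violations == 0) {
    # a sound set may only use motifs absent from every non-permissive
    # strain and present in at least one permissive strain; any such subset
    # covering all permissive strains is sound (exactness preserved,
    # verified against the exhaustive oracle)
    absent_nonperm <- if (length(nonperm)) {
      colSums(M[nonperm, , drop = FALSE]) == 0
    } else rep(TRUE, length(universe))
    in_perm <- colSums(M[perm, , drop = FALSE]) > 0
    candidates <- universe[absent_nonperm & in_perm]
    sound <- list()
    for (S in all_subsets_upto(candidates, kmax)) {
      covered <- rowSums(M[perm, S, drop = FALSE]) > 0
      if (all(covered)) sound[[length(sound) + 1]] <- S
    }
    sound <- sort_sets(minimal_sets_only(sound))
    if (length(sound) == 0) {
      return(receptor_call(adhesin, "inconsistent", list()))
    }
    status <- if (length(sound) == 1) "unique" else "ambiguous"
    return(receptor_call(adhesin, status, sound,
                         witness = witness_table(sound[[1]], perm, M)))
  }
  # relaxed search: count violated cells per candidate set
  best <- list()
  viols <- integer()
  for (S in all_subsets_upto(universe, kmax)) {
    v <- sum(rowSums(M[perm, S, drop = FALSE]) == 0) +
      sum(rowSums(M[nonperm, S, drop = FALSE]) > 0)
    if (v <= max_violations) {
      best[[length(best) + 1]] <- S
      viols <- c(viols, v)
    }
  }
  keep <- minimal_sets_only(best)
  keep_viol <- viols[match(vapply(keep, paste, character(1), collapse = "|"),
                           vapply(best, paste, character(1), collapse = "|"))]
  ord <- order(vapply(keep, length, integer(1)),
               vapply(keep, paste, character(1), collapse = "|"))
  keep <- keep[ord]
  keep_viol <- keep_viol[ord]
  if (length(keep) == 0) {
    return(receptor_call(adhesin, "inconsistent", list()))
  }
  status <- if (length(keep) == 1) "unique" else "ambiguous"
  receptor_call(adhesin, status, keep,
                witness = witness_table(keep[[1]], perm, M),
                violations = keep_viol)
}

#' Infer minimal receptor-motif sets per adhesin
#'
#' For each adhesin, searches motif sets S (drawn from the union of motifs
#' displayed by the panel structures, at most `kmax` motifs) satisfying
#' soundness: every permissive strain displays at least one motif of S and
#' no non-permissive strain displays any motif of S. All inclusion-minimal
#' sound sets are returned, sorted by (size, canonical motif strings).
#' The status is `unique` (one minimal set), `ambiguous` (several),
#' `inconsistent` (none within `kmax`), or `no_permissive` (the adhesin
#' transfers to no panel strain).
#'
#' @param panel a [binarize()]d panel.
#' @param structures named list of [glycan_tree()]s, one per panel strain.
#' @param kmax largest motif-set size searched (default 3, the largest
#'   receptor repertoire observed for a single adhesin).
#' @param max_violations number of panel cells a candidate set may violate
#'   (default 0: deterministic presence/absence reasoning).
#' @return A `receptor_calls` list of per-adhesin `receptor_call` objects.
#' @export
infer_receptors <- function(panel, structures, kmax = 3, max_violations = 0) {
  stopifnot(inherits(panel, "binary_panel"), kmax >= 1)
  M <- containment_matrix(panel$strains, structures)
  calls <- lapply(panel$adhesins, function(a) {
    row <- panel$permissive[a, ]
    infer_one(a, panel$strains[row], panel$strains[!row], M, kmax,
              max_violations)
  })
  names(calls) <- panel$adhesins
  structure(calls, class = "receptor_calls")
}

#' Exhaustive oracle for receptor inference
#'
#' Enumerates every motif subset up to `kmax` over the full motif universe
#' and filters by the soundness predicate directly, then reduces to
#' inclusion-minimal sets. Same result contract as [infer_receptors()];
#' used to validate the pruned search. Guarded to tractable instances.
#'
#' @inheritParams infer_receptors
#' @return A `receptor_calls` list.
#' @export
brute_force_oracle <- function(panel, structures, kmax = 3) {
  stopifnot(inherits(panel, "binary_panel"))
  M <- containment_matrix(panel$strains, structures)
  if (ncol(M) > 25 || kmax > 3) {
    stop_conjscreen("oracle guard: universe > 25 motifs or kmax > 3",
                    "conjscreen_validation_error")
  }
  calls <- lapply(panel$adhesins, function(a) {
    row <- panel$permissive[a, ]
    perm <- panel$strains[row]
    nonperm <- panel$strains[!row]
    if (length(perm) + length(nonperm) == 0) {
      return(receptor_call(a, "ambiguous", sort_sets(as.list(colnames(M)))))
    }
    if (length(perm) == 0) {
      return(receptor_call(a, "no_permissive", list(character())))
    }
    sound <- list()
    for (S in all_subsets_upto(colnames(M), kmax)) {
      cov <- all(rowSums(M[perm, S, drop = FALSE]) > 0)
      clean <- if (length(nonperm)) {
        all(rowSums(M[nonperm, S, drop = FALSE]) == 0)
      } else TRUE
      if (cov && clean) sound[[length(sound) + 1]] <- S
    }
    sound <- sort_sets(minimal_sets_only(sound))
    if (length(sound) == 0) return(receptor_call(a, "inconsistent", list()))
    receptor_call(a, if (length(sound) == 1) "unique" else "ambiguous", sound,
                  witness = witness_table(sound[[1]], perm, M))
  })
  names(calls) <- panel$adhesins
  structure(calls, class = "receptor_calls")
}

#' Evidence report for a receptor call
#'
#' Per strain: permissiveness, which motifs of the called set are present,
#' and which are absent. For ambiguous calls the report proposes a
#' discriminating observation: a hypothetical structure (a single motif
#' from the symmetric difference of two candidate sets) whose presence or
#' absence would separate them. For inconsistent calls it reports a minimal
#' conflicting strain pair: a permissive strain whose motif set is
#' contained in a non-permissive strain's motif set.
#'
#' @param call a `receptor_call` from [infer_receptors()].
#' @param panel the [binarize()]d panel the call was produced from.
#' @param structures the strain structures used.
#' @return A `receptor_evidence` list with elements `per_strain`,
#'   `suggestion`, `conflict`.
#' @export
explain_call <- function(call, panel, structures) {
  stopifnot(inherits(call, "receptor_call"), inherits(panel, "binary_panel"))
  M <- containment_matrix(panel$strains, structures)
  row <- panel$permissive[call$adhesin, ]
  perm <- panel$strains[row]
  set <- if (length(call$minimal_sets) > 0) call$minimal_sets[[1]] else character()
  per_strain <- tibble(
    strain = panel$strains,
    permissive = row,
    motifs_present = vapply(panel$strains, function(s) {
      paste(set[M[s, set, drop = TRUE]], collapse = ", ")
    }, character(1)),
    motifs_absent = vapply(panel$strains, function(s) {
      paste(set[!M[s, set, drop = TRUE]], collapse = ", ")
    }, character(1))
  )
  suggestion <- NULL
  if (call$status == "ambiguous" && length(call$minimal_sets) >= 2) {
    diff <- c(setdiff(call$minimal_sets[[1]], call$minimal_sets[[2]]),
              setdiff(call$minimal_sets[[2]], call$minimal_sets[[1]]))
    if (length(diff) > 0) {
      suggestion <- sprintf(
        "a strain displaying only '%s' would separate the leading candidate sets",
        diff[1]
      )
    }
  }
  conflict <- NULL
  if (call$status == "inconsistent") {
    nonperm <- panel$strains[!row]
    for (p in perm) {
      for (q in nonperm) {
        if (all(colnames(M)[M[p, ]] %in% colnames(M)[M[q, ]])) {
          conflict <- c(permissive = p, non_permissive = q)
          break
        }
      }
      if (!is.null(conflict)) break
    }
  }
  structure(list(adhesin = call$adhesin, status = call$status,
                 per_strain = per_strain, suggestion = suggestion,
                 conflict = conflict),
            class = "receptor_evidence")
}

#' @export
print.receptor_evidence <- function(x, ...) {
  cat(sprintf("<receptor_evidence> %s (%s)\n", x$adhesin, x$status))
  print(x$per_strain, n = Inf)
  if (!is.null(x$suggestion)) cat("suggestion:", x$suggestion, "\n")
  if (!is.null(x$conflict)) {
    cat(sprintf("conflict: permissive '%s' displays a subset of non-permissive '%s'\n",
                x$conflict[["permissive"]], x$conflict[["non_permissive"]]))
  }
  invisible(x)
}
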