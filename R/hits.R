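#' Z-transform a screen's conjugation scores
#'
#' Standardizes per-mutant mean conjugation scores against the screen-wide
#' mean and standard deviation of that condition:
#' `z = (score - screen mean) / screen sd`. Mutants with a missing mean
#' score are carried with `NA` z. Over the non-missing mutants the z values
#' have mean 0 and sd 1 by construction.
#'
#' @param scores a `score_table` from [aggregate_replicates()], or a tibble
#'   with columns `mutant_id` and `mean_score`.
#' @return Tibble `mutant_id`, `mean_score`, `z`, classed `z_table`, with
#'   the screen mean/sd in attributes.
#' @export
z_transform <- function(scores) {
  x <- scores$mean_score
  valid <- !is.na(x)
  if (sum(valid) < 2) {
    stop_conjscreen("need at least 2 mutants with valid mean scores",
                    "conjscreen_validation_error")
  }
  mu <- mean(x[valid])
  sigma <- stats::sd(x[valid])
  if (sigma == 0) {
    stop_conjscreen("degenerate screen: all scores identical (sd = 0)",
                    "conjscreen_degenerate_error")
  }
  out <- tibble(mutant_id = scores$mutant_id, mean_score = x,
                z = (x - mu) / sigma)
  attr(out, "screen_mean") <- mu
  attr(out, "screen_sd") <- sigma
  attr(out, "condition") <- attr(scores, "condition", exact = TRUE)
  class(out) <- c("z_table", class(out))
  out
}

#' Call low and high hits from a Z table
#'
#' Low hits are mutants with `z < threshold` (default -1.96, the lower 2.5%
#' of a standard normal, p <= 0.05); high hits mirror them at
#' `z > -threshold`. Inequalities are strict, so a mutant exactly at the
#' threshold is not a hit. Members are sorted by z.
#'
#' @param ztab a [z_transform()] result.
#' @param threshold lower-tail z cutoff (negative; default `-1.96`).
#' @return List with `low` and `high` `hit_set` objects (tibbles of
#'   `mutant_id`, `z` with `direction`/`threshold` attributes).
#' @export
call_hits <- function(ztab, threshold = -1.96) {
  mk <- function(rows, direction, thr) {
    rows <- rows[order(rows$z), c("mutant_id", "z")]
    structure(rows, direction = direction, threshold = thr,
              class = c("hit_set", class(rows)))
  }
  ok <- !is.na(ztab$z)
  list(
    low = mk(ztab[ok & ztab$z < threshold, ], "low", threshold),
    high = mk(ztab[ok & ztab$z > -threshold, ], "high", -threshold)
  )
}

#' Overlap between two hit sets of the same direction
#'
#' Partitions two hit sets (e.g. broth and solid low hits) into exclusive
#' and shared members.
#'
#' @param a,b `hit_set` objects with the same direction.
#' @return List `only_a`, `only_b`, `shared` (id vectors) and `counts`.
#' @export
hit_overlap <- function(a, b) {
  if (!identical(attr(a, "direction", exact = TRUE),
                 attr(b, "direction", exact = TRUE))) {
    stop_conjscreen("hit sets have different directions",
                    "conjscreen_validation_error")
  }
  ia <- a$mutant_id
  ib <- b$mutant_id
  shared <- intersect(ia, ib)
  out <- list(only_a = setdiff(ia, ib), only_b = setdiff(ib, ia),
              shared = shared)
  out$counts <- c(only_a = length(out$only_a), only_b = length(out$only_b),
                  shared = length(shared))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Order-preserving BH step-up adjustment,
#' `adj_(i) = min_(j >= i) p_(j) * m / j` capped at 1, delegated to
#' [stats::p.adjust()].
#'
#' @param pvals numeric p values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_conjscreen("p values must lie in [0, 1]", "conjscreen_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric term enrichment among hits
#'
#' For each annotation term with at least one annotated gene in the
#' universe, tests over-representation among the hits with the upper-tail
#' hypergeometric probability `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)` (N universe size, K term-annotated in universe,
#' n hits, k term-annotated hits), then applies [bh_adjust()] across all
#' tested terms. The universe should be the set of mutants actually scored
#' in the condition, not the whole genome. Terms with `K < 3` are tested
#' but flagged low-power.
#'
#' @param hits character vector of hit gene ids (or a `hit_set`).
#' @param universe character vector of all scored gene ids.
#' @param annotation tibble/data frame with columns `gene_id`, `term_id`
#'   (multiple rows per gene); restricted to the universe internally.
#' @return Tibble `term_id`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `low_power`,
#'   sorted by `p_adj` then `term_id`.
#' @export
hypergeom_enrich <- function(hits, universe, annotation) {
  if (inherits(hits, "hit_set")) hits <- hits$mutant_id
  hits <- unique(hits)
  universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop_conjscreen("hits must be a subset of the universe",
                    "conjscreen_validation_error")
  }
  ann <- as_tibble(annotation)
  ann <- ann[ann$gene_id %in% universe, c("gene_id", "term_id")]
  ann <- dplyr::distinct(ann)
  N <- length(universe)
  n <- length(hits)
  per_term <- split(ann$gene_id, ann$term_id)
  res <- tibble(
    term_id = names(per_term),
    K = unname(vapply(per_term, length, integer(1))),
    k = unname(vapply(per_term, function(g) sum(g %in% hits), integer(1))),
    n = n, N = N
  )
  res$p <- stats::phyper(res$k - 1, res$K, res$N - res$K, res$n,
                         lower.tail = FALSE)
  res$p_adj <- bh_adjust(res$p)
  res$low_power <- res$K < 3
  res <- res[order(res$p_adj, res$term_id),
             c("term_id", "k", "K", "n", "N", "p", "p_adj", "low_power")]
  res
}
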