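# Independent brute-force oracles, written from textbook definitions and
# kept free of the package's own code paths.

# Pearson correlation from the definitional formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# upper-tail hypergeometric P(X >= k) by direct enumeration of the pmf
oracle_hyper_upper <- function(k, K, N, n) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / total
  }, numeric(1)))
}

# BH step-up from the definition: adj_(i) = min_{j>=i} p_(j) * m / j, cap 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# sample sd with the n - 1 denominator, from the formula
oracle_sample_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - sum(x) / n)^2) / (n - 1))
}

# hand-built tiny glycan trees -----------------------------------------------

# linear chain anchor -> A -> B -> ... with given labels/linkages
chain_tree <- function(labels, anomerics, parent_pos,
                       subs = vector("list", length(labels))) {
  rows <- list(tibble::tibble(
    id = "anchor", mono = "lipA", stereo = NA_character_, anomeric = "n/a",
    child_pos = NA_integer_, parent_pos = NA_integer_,
    parent_id = NA_character_, subs = list(character()),
    added_by = "constitutive"
  ))
  prev <- "anchor"
  for (i in seq_along(labels)) {
    id <- paste0("r", i)
    rows[[i + 1]] <- tibble::tibble(
      id = id, mono = labels[i], stereo = NA_character_,
      anomeric = anomerics[i], child_pos = 1L,
      parent_pos = as.integer(parent_pos[i]), parent_id = prev,
      subs = list(subs[[i]] %||% character()), added_by = "constitutive"
    )
    prev <- id
  }
  glycan_tree(dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical motif-set representation of a receptor_calls object, for
# comparing implementation and oracle results
call_signature <- function(calls) {
  lapply(unclass(calls), function(x) list(status = x$status,
                                          sets = x$minimal_sets))
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
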