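#' Glycan trees of the LPS core oligosaccharide
#'
#' A `glycan_tree` is a rooted labeled tree of monosaccharide residues: the
#' membrane-proximal lipid A anchor at the root, each further residue joined
#' to its parent by an anomeric linkage, with optional substituents (e.g.
#' phosphates) and the biosynthetic gene that installs each element. It is
#' stored as a residue tibble with columns `id`, `mono` (short label),
#' `stereo` (heptose backbone qualifier or `NA`), `anomeric` (`a`/`b`/`n/a`),
#' `child_pos`, `parent_pos`, `parent_id` (`NA` at the root), `added_by`,
#' and a list-column `subs` of substituent tokens `"<pos><token>:<gene>"`.
#'
#' @param residues residue tibble as described above.
#' @param background optional background name the tree was built for.
#' @return A `glycan_tree`.
#' @export
glycan_tree <- function(residues, background = NA_character_) {
  residues <- as_tibble(residues)
  if (anyDuplicated(residues$id)) {
    stop_conjscreen("residue ids must be unique", "conjscreen_validation_error")
  }
  root <- is.na(residues$parent_id)
  if (sum(root) != 1) {
    stop_conjscreen("glycan tree must have exactly one root residue",
                    "conjscreen_validation_error")
  }
  dangling <- !root & !(residues$parent_id %in% residues$id)
  if (any(dangling)) {
    stop_conjscreen(
      sprintf("residue '%s' references undefined parent '%s'",
              residues$id[dangling][1], residues$parent_id[dangling][1]),
      "conjscreen_reference_error"
    )
  }
  # acyclicity/connectivity: walking parents from every residue must reach
  # the root without revisiting
  idx <- match(residues$parent_id, residues$id)
  for (i in seq_len(nrow(residues))) {
    seen <- integer()
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) {
        stop_conjscreen("cyclic parent reference in glycan tree",
                        "conjscreen_reference_error")
      }
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  structure(list(residues = residues, background = background),
            class = "glycan_tree")
}

#' @export
print.glycan_tree <- function(x, ...) {
  r <- x$residues
  cat(sprintf("<glycan_tree>%s %d residues\n",
              if (is.na(x$background)) "" else paste0(" [", x$background, "]"),
              nrow(r)))
  ord <- order(!is.na(r$parent_id))
  for (i in seq_len(nrow(r))) {
    ri <- r[i, ]
    subs <- sub_tokens(ri$subs[[1]])
    cat(sprintf("  %-10s %-7s %s%s\n", ri$id,
                residue_label(ri$mono, subs),
                if (is.na(ri$parent_id)) "(anchor)"
                else sprintf("%s(%d-%d) -> %s", ri$anomeric, ri$child_pos,
                             ri$parent_pos, ri$parent_id),
                if (ri$added_by == "constitutive") "" else paste0("  [", ri$added_by, "]")))
  }
  invisible(x)
}

# strip the ":gene" provenance from substituent encodings
sub_tokens <- function(subs) sub(":.*$", "", subs %||% character())

`%||%` <- function(a, b) if (is.null(a)) b else a

anchor_id <- function(tree) tree$residues$id[is.na(tree$residues$parent_id)]

#' Read a glycan structure table (TSV)
#'
#' Columns: `residue_id`, `mono`, `stereo`, `anomeric` (`a`, `b`, or `n/a`),
#' `child_pos`, `parent_pos`, `parent_id` (`ROOT` for the anchor),
#' `substituents` (comma-separated `"<pos><token>:<gene>"`, may be empty),
#' `added_by`. Rows must be parent-before-child; a dangling or cyclic parent
#' reference is rejected.
#'
#' @param path TSV file path.
#' @return A [glycan_tree()].
#' @export
read_glycan_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  expected <- c("residue_id", "mono", "stereo", "anomeric", "child_pos",
                "parent_pos", "parent_id", "substituents", "added_by")
  if (!identical(header, expected)) {
    stop_conjscreen("unexpected glycan table header", "conjscreen_parse_error")
  }
  seen <- character()
  rows <- lapply(cells[-1], function(row) {
    length(row) <- 9L
    row[is.na(row)] <- ""
    if (!(row[4] %in% c("a", "b", "n/a"))) {
      stop_conjscreen(sprintf("unknown anomeric token '%s' for residue '%s'",
                              row[4], row[1]), "conjscreen_parse_error")
    }
    is_root <- row[7] == "ROOT"
    if (!is_root && !(row[7] %in% seen)) {
      stop_conjscreen(
        sprintf("residue '%s' references parent '%s' not defined earlier",
                row[1], row[7]),
        "conjscreen_reference_error"
      )
    }
    seen <<- c(seen, row[1])
    tibble(
      id = row[1], mono = row[2],
      stereo = if (nzchar(row[3])) row[3] else NA_character_,
      anomeric = row[4],
      child_pos = if (is_root) NA_integer_ else as.integer(parse_strict_numeric(row[5])),
      parent_pos = if (is_root) NA_integer_ else as.integer(parse_strict_numeric(row[6])),
      parent_id = if (is_root) NA_character_ else row[7],
      subs = list(if (nzchar(row[8])) strsplit(row[8], ",", fixed = TRUE)[[1]] else character()),
      added_by = row[9]
    )
  })
  glycan_tree(dplyr::bind_rows(rows))
}

#' @rdname read_glycan_table
#' @param tree a [glycan_tree()].
#' @export
write_glycan_table <- function(tree, path) {
  stopifnot(inherits(tree, "glycan_tree"))
  r <- tree$residues
  # parent-before-child order
  ord <- integer()
  remaining <- seq_len(nrow(r))
  placed <- character()
  while (length(remaining) > 0) {
    ready <- remaining[is.na(r$parent_id[remaining]) |
                         r$parent_id[remaining] %in% placed]
    ord <- c(ord, ready)
    placed <- c(placed, r$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  r <- r[ord, ]
  body <- vapply(seq_len(nrow(r)), function(i) {
    paste(c(r$id[i], r$mono[i],
            if (is.na(r$stereo[i])) "" else r$stereo[i],
            r$anomeric[i],
            if (is.na(r$child_pos[i])) "" else as.character(r$child_pos[i]),
            if (is.na(r$parent_pos[i])) "" else as.character(r$parent_pos[i]),
            if (is.na(r$parent_id[i])) "ROOT" else r$parent_id[i],
            paste(r$subs[[i]], collapse = ","),
            r$added_by[i]),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("residue_id", "mono", "stereo", "anomeric", "child_pos",
                       "parent_pos", "parent_id", "substituents", "added_by"),
                     collapse = "\t"), body), path)
  invisible(path)
}

#' Enumerate disaccharide motifs displayed by a glycan tree
#'
#' Emits one motif per parent-child edge between saccharide residues; edges
#' touching the lipid anchor are excluded. With
#' `include_substituent_variants`, each motif is additionally emitted with
#' and without each residue's substituent constraints, so a phosphorylated
#' proximal heptose yields both `Hep-a(1-3)-Hep` and `Hep-a(1-3)-Hep[4P]`.
#'
#' @param tree a [glycan_tree()].
#' @param include_substituent_variants emit substituent-constrained variants
#'   alongside the unconstrained motif (default `TRUE`).
#' @return A list of [motif()] objects, named by their canonical strings,
#'   sorted and deduplicated.
#' @export
enumerate_motifs <- function(tree, include_substituent_variants = TRUE) {
  stopifnot(inherits(tree, "glycan_tree"))
  r <- tree$residues
  anchor <- anchor_id(tree)
  out <- list()
  for (i in seq_len(nrow(r))) {
    if (is.na(r$parent_id[i]) || r$parent_id[i] == anchor || r$id[i] == anchor) next
    p <- which(r$id == r$parent_id[i])
    d_subs <- sub_tokens(r$subs[[i]])
    p_subs <- sub_tokens(r$subs[[p]])
    d_opts <- if (include_substituent_variants && length(d_subs) > 0) {
      list(character(), d_subs)
    } else list(character())
    p_opts <- if (include_substituent_variants && length(p_subs) > 0) {
      list(character(), p_subs)
    } else list(character())
    for (ds in d_opts) for (ps in p_opts) {
      m <- motif(distal = r$mono[i], anomeric = r$anomeric[i],
                 child_pos = r$child_pos[i], parent_pos = r$parent_pos[i],
                 proximal = r$mono[p], distal_sub = ds, proximal_sub = ps,
                 distal_stereo = r$stereo[i], proximal_stereo = r$stereo[p])
      out[[render_motif(m)]] <- m
    }
  }
  if (length(out) == 0) return(stats::setNames(list(), character()))
  out[order(names(out))]
}

#' Test whether a glycan tree displays a motif
#'
#' `TRUE` iff some saccharide parent-child edge matches the motif's residue
#' labels, linkage, and all required substituents. Constraints are
#' positive-only: extra substituents on the structure never block a match.
#'
#' @param tree a [glycan_tree()].
#' @param m a [motif()] or canonical motif string.
#' @return Logical scalar.
#' @export
contains_motif <- function(tree, m) {
  stopifnot(inherits(tree, "glycan_tree"))
  if (is.character(m)) m <- parse_motif(m)
  r <- tree$residues
  anchor <- anchor_id(tree)
  for (i in seq_len(nrow(r))) {
    if (is.na(r$parent_id[i]) || r$parent_id[i] == anchor || r$id[i] == anchor) next
    p <- which(r$id == r$parent_id[i])
    if (r$mono[i] != m$distal || r$mono[p] != m$proximal) next
    if (r$anomeric[i] != m$anomeric || r$child_pos[i] != m$child_pos ||
        r$parent_pos[i] != m$parent_pos) next
    if (!all(m$distal_sub %in% sub_tokens(r$subs[[i]]))) next
    if (!all(m$proximal_sub %in% sub_tokens(r$subs[[p]]))) next
    return(TRUE)
  }
  FALSE
}
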