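#' Core-oligosaccharide biosynthesis tables
#'
#' Each supported background (the five E. coli core-OS prototypes K-12, R1,
#' R2, R3, R4, plus ClearColi) ships with a TSV table describing the action
#' of every biosynthetic gene: attaching a residue to a parent matched by a
#' structural selector, attaching a substituent, or acting upstream on a
#' nucleotide-sugar precursor. The `requires` column lists genes that must
#' be functional for the action to occur (e.g. the Hep II phosphotransferase
#' requires the Hep I kinase; all heptosyltransferases require the
#' ADP-heptose precursor pathway).
#'
#' @param background one of [lps_backgrounds()].
#' @return A tibble of gene actions with class `biosynthesis_table`.
#' @export
biosynthesis_table <- function(background) {
  background <- match.arg(background, lps_backgrounds())
  cached <- .conjscreen_cache[[background]]
  if (!is.null(cached)) return(cached)
  fname <- paste0("biosynthesis_", background_slug(background), ".tsv")
  path <- system.file("extdata", "lps", fname, package = "conjscreen")
  if (!nzchar(path)) {
    stop_conjscreen(sprintf("packaged table for '%s' not found", background),
                    "conjscreen_reference_error")
  }
  tab <- read_biosynthesis_table(path, background = background)
  assign(background, tab, envir = .conjscreen_cache)
  tab
}

.conjscreen_cache <- new.env(parent = emptyenv())

#' Supported LPS backgrounds
#'
#' @return Character vector of background names.
#' @export
lps_backgrounds <- function() c("K-12", "R1", "R2", "R3", "R4", "ClearColi")

background_slug <- function(x) {
  c(`K-12` = "k12", R1 = "r1", R2 = "r2", R3 = "r3", R4 = "r4",
    ClearColi = "clearcoli")[[x]]
}

#' Read a biosynthesis table from TSV
#'
#' @param path TSV path; see [biosynthesis_table()] for the schema.
#' @param background background name to attach as metadata.
#' @return A `biosynthesis_table` tibble.
#' @export
read_biosynthesis_table <- function(path, background = NA_character_) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           colClasses = "character")
  expected <- c("gene", "action", "res_id", "mono", "stereo", "anomeric",
                "child_pos", "parent_pos", "token", "position", "sel_mono",
                "sel_anomeric", "sel_parent_pos", "sel_parent_mono", "requires")
  if (!identical(names(tab), expected)) {
    stop_conjscreen("unexpected biosynthesis table columns",
                    "conjscreen_parse_error")
  }
  bad <- !tab$action %in% c("residue", "substituent", "precursor")
  if (any(bad)) {
    stop_conjscreen(sprintf("unknown action '%s'", tab$action[bad][1]),
                    "conjscreen_parse_error")
  }
  tab <- as_tibble(tab)
  tab$requires <- lapply(tab$requires, function(s) {
    if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]] else character()
  })
  # "requires" must be acyclic
  req <- stats::setNames(tab$requires, tab$gene)
  visit <- function(g, path) {
    if (g %in% path) {
      stop_conjscreen("cyclic 'requires' relation in biosynthesis table",
                      "conjscreen_reference_error")
    }
    for (r in req[[g]] %||% character()) if (r %in% names(req)) visit(r, c(path, g))
  }
  for (g in unique(tab$gene)) visit(g, character())
  structure(tab, background = background,
            class = c("biosynthesis_table", class(tab)))
}

#' Describe a strain genotype
#'
#' @param background one of [lps_backgrounds()] (the strain's core-OS
#'   prototype; `"ClearColi"` for the saccharide-free background).
#' @param deletions character vector of deleted gene ids (must exist in the
#'   background table).
#' @param additions character vector of plasmid-expressed genes from other
#'   prototypes, either bare (`"waaK"`, unique across packaged tables) or
#'   source-qualified (`"R1:waaT"`).
#' @return A `genotype` object.
#' @export
genotype <- function(background, deletions = character(), additions = character()) {
  background <- match.arg(background, lps_backgrounds())
  deletions <- unique(as.character(deletions))
  additions <- unique(as.character(additions))
  if (length(intersect(deletions, sub("^.*:", "", additions))) > 0) {
    stop_conjscreen("a gene cannot be both deleted and added",
                    "conjscreen_validation_error")
  }
  structure(list(background = background, deletions = deletions,
                 additions = additions), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype> %s%s%s\n", x$background,
              if (length(x$deletions)) paste0(" d", paste(x$deletions, collapse = " d")) else "",
              if (length(x$additions)) paste0(" +", paste(x$additions, collapse = " +")) else ""))
  invisible(x)
}

#' Read or write a genotype (JSON)
#'
#' @param path JSON file with fields `background`, `deletions`, `additions`.
#' @return A [genotype()] for the reader; `path` invisibly for the writer.
#' @export
read_genotype <- function(path) {
  x <- jsonlite::fromJSON(path)
  genotype(x$background, x$deletions %||% character(), x$additions %||% character())
}

#' @rdname read_genotype
#' @param g a [genotype()].
#' @export
write_genotype <- function(g, path) {
  stopifnot(inherits(g, "genotype"))
  jsonlite::write_json(
    list(background = g$background, deletions = as.list(g$deletions),
         additions = as.list(g$additions)),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

# ---- construction engine ----------------------------------------------------

# availability of a gene's action given the deletion set and the combined
# requires relation; a deleted gene disables every action downstream of it
gene_available <- function(gene, deletions, requires_map) {
  if (gene %in% deletions) return(FALSE)
  for (r in requires_map[[gene]] %||% character()) {
    if (!gene_available(r, deletions, requires_map)) return(FALSE)
  }
  TRUE
}

# first residue (in insertion order) matching a structural parent selector
match_selector <- function(residues, row) {
  for (i in seq_len(nrow(residues))) {
    if (residues$mono[i] != row$sel_mono) next
    if (nzchar(row$sel_anomeric) && !identical(residues$anomeric[i], row$sel_anomeric)) next
    if (nzchar(row$sel_parent_pos) &&
        !identical(residues$parent_pos[i], as.integer(row$sel_parent_pos))) next
    if (nzchar(row$sel_parent_mono)) {
      pid <- residues$parent_id[i]
      pmono <- if (is.na(pid)) "ROOT" else residues$mono[match(pid, residues$id)]
      if (!identical(pmono, row$sel_parent_mono)) next
    }
    return(i)
  }
  NA_integer_
}

apply_action <- function(residues, row, gene_label) {
  target <- match_selector(residues, row)
  if (is.na(target)) return(list(residues = residues, applied = FALSE))
  if (row$action == "residue") {
    new_id <- row$res_id
    while (new_id %in% residues$id) new_id <- paste0(new_id, "+")
    residues <- dplyr::bind_rows(residues, tibble(
      id = new_id, mono = row$mono,
      stereo = if (nzchar(row$stereo)) row$stereo else NA_character_,
      anomeric = row$anomeric,
      child_pos = as.integer(row$child_pos),
      parent_pos = as.integer(row$parent_pos),
      parent_id = residues$id[target],
      subs = list(character()), added_by = gene_label
    ))
  } else {
    token <- paste0(row$position, row$token, ":", gene_label)
    if (!token %in% residues$subs[[target]]) {
      residues$subs[[target]] <- c(residues$subs[[target]], token)
    }
  }
  list(residues = residues, applied = TRUE)
}

resolve_additions <- function(additions, background) {
  if (length(additions) == 0) return(NULL)
  sources <- setdiff(lps_backgrounds(), "ClearColi")
  tables <- lapply(sources, biosynthesis_table)
  names(tables) <- sources
  rows <- list()
  for (ad in sort(additions)) {
    if (grepl(":", ad, fixed = TRUE)) {
      src <- sub(":.*$", "", ad)
      gene <- sub("^.*:", "", ad)
      if (!src %in% sources) {
        stop_conjscreen(sprintf("unknown source background '%s'", src),
                        "conjscreen_reference_error")
      }
      hit <- tables[[src]][tables[[src]]$gene == gene &
                             tables[[src]]$action != "precursor", ]
      if (nrow(hit) == 0) {
        stop_conjscreen(sprintf("gene '%s' not found in background '%s'", gene, src),
                        "conjscreen_reference_error")
      }
      rows[[ad]] <- list(gene = gene, src = src, rows = hit)
    } else {
      hits <- lapply(sources, function(s) {
        tables[[s]][tables[[s]]$gene == ad & tables[[s]]$action != "precursor", ]
      })
      n <- vapply(hits, nrow, integer(1))
      if (sum(n > 0) == 0) {
        stop_conjscreen(sprintf("unknown gene '%s' in additions", ad),
                        "conjscreen_reference_error")
      }
      # prefer the strain's own background if the gene occurs there, else the
      # gene must be unique across prototypes
      cands <- sources[n > 0]
      src <- if (background %in% cands) background else if (length(cands) == 1) {
        cands
      } else {
        stop_conjscreen(
          sprintf("gene '%s' occurs in several prototypes (%s); qualify as 'R1:%s'",
                  ad, paste(cands, collapse = ", "), ad),
          "conjscreen_reference_error"
        )
      }
      rows[[ad]] <- list(gene = ad, src = src, rows = hits[[match(src, sources)]])
    }
  }
  rows
}

#' Build the glycan tree encoded by a genotype
#'
#' Constructs the background's wild-type core-OS tree by applying each gene
#' action in table (topological) order, skipping deleted genes and every
#' action whose `requires` chain includes a deleted gene. A residue whose
#' parent never appears is silently skipped, so truncations cascade to all
#' distal residues. Plasmid-expressed additions are applied after the
#' background, repeatedly until no further action fires, so a knocked-in
#' gene may act on a truncated or chimeric structure whenever its parent
#' selector matches; an addition that matches nothing leaves the structure
#' unchanged with a warning.
#'
#' @param g a [genotype()].
#' @param table optionally, a pre-loaded [biosynthesis_table()] for the
#'   background (defaults to the packaged one).
#' @return A [glycan_tree()].
#' @export
apply_genotype <- function(g, table = NULL) {
  stopifnot(inherits(g, "genotype"))
  if (is.null(table)) table <- biosynthesis_table(g$background)
  known <- unique(table$gene)
  addition_rows <- resolve_additions(g$additions, g$background)
  known_added <- vapply(addition_rows %||% list(), function(a) a$gene, character(1))
  unknown <- setdiff(g$deletions, c(known, known_added))
  if (length(unknown) > 0) {
    stop_conjscreen(sprintf("unknown gene '%s' in deletions", unknown[1]),
                    "conjscreen_reference_error")
  }

  requires_map <- list()
  for (i in seq_len(nrow(table))) {
    requires_map[[table$gene[i]]] <-
      union(requires_map[[table$gene[i]]] %||% character(), table$requires[[i]])
  }
  for (a in addition_rows %||% list()) {
    for (i in seq_len(nrow(a$rows))) {
      requires_map[[a$gene]] <-
        union(requires_map[[a$gene]] %||% character(), a$rows$requires[[i]])
    }
  }

  residues <- tibble(
    id = "lipA", mono = "lipA", stereo = NA_character_, anomeric = "n/a",
    child_pos = NA_integer_, parent_pos = NA_integer_,
    parent_id = NA_character_, subs = list(character()),
    added_by = "constitutive"
  )

  action_rows <- table[table$action != "precursor", ]
  for (i in seq_len(nrow(action_rows))) {
    row <- action_rows[i, ]
    if (!gene_available(row$gene, g$deletions, requires_map)) next
    residues <- apply_action(residues, row, row$gene)$residues
  }

  # additions: fixpoint so an added gene can build on another addition's
  # product regardless of listing order
  if (length(addition_rows %||% list()) > 0) {
    pending <- list()
    for (a in addition_rows) {
      for (i in seq_len(nrow(a$rows))) {
        pending[[length(pending) + 1]] <- list(gene = a$gene, row = a$rows[i, ])
      }
    }
    fired <- rep(FALSE, length(pending))
    repeat {
      progress <- FALSE
      for (k in seq_along(pending)) {
        if (fired[k]) next
        gene <- pending[[k]]$gene
        if (!gene_available(gene, g$deletions, requires_map)) {
          fired[k] <- TRUE
          next
        }
        res <- apply_action(residues, pending[[k]]$row, gene)
        if (res$applied) {
          residues <- res$residues
          fired[k] <- TRUE
          progress <- TRUE
        }
      }
      if (!progress) break
    }
    if (any(!fired)) {
      unmatched <- unique(vapply(pending[!fired], function(p) p$gene, character(1)))
      rlang::warn(sprintf(
        "addition(s) %s matched no parent residue; structure unchanged by them",
        paste(unmatched, collapse = ", ")
      ))
    }
  }

  glycan_tree(residues, background = g$background)
}

#' Build a wild-type core-OS prototype tree
#'
#' `"ClearColi"` returns the anchor-only tree (lipid IVA, no saccharides,
#' hence zero motifs).
#'
#' @param name one of [lps_backgrounds()].
#' @param table optional pre-loaded [biosynthesis_table()].
#' @return A [glycan_tree()].
#' @export
build_prototype <- function(name, table = NULL) {
  apply_genotype(genotype(name), table = table)
}
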