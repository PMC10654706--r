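#' Construct a 384-position plate density grid
#'
#' A `plate_grid` holds the background-subtracted integrated growth densities
#' of one 16 x 24 colony-array selection plate from one replicate of the
#' high-throughput conjugation assay. Two selection plates exist per mating
#' plate: one selecting all recipients, one selecting transconjugants only.
#'
#' @param densities numeric 16 x 24 matrix of non-negative densities
#'   (arbitrary units).
#' @param plate_id plate identifier, unique within a screen together with
#'   `(condition, selection, replicate)`.
#' @param condition `"broth"` or `"solid"` mating condition.
#' @param selection `"recipient"` or `"transconjugant"` selective plate.
#' @param replicate positive integer biological replicate index.
#' @return A `plate_grid` object.
#' @export
plate_grid <- function(densities, plate_id, condition, selection, replicate) {
  densities <- as.matrix(densities)
  if (!identical(dim(densities), c(16L, 24L))) {
    stop_conjscreen(
      sprintf("plate grid must be 16 x 24, got %d x %d",
              nrow(densities), ncol(densities)),
      "conjscreen_shape_error"
    )
  }
  if (anyNA(densities) || !is.numeric(densities)) {
    stop_conjscreen("plate densities must be numeric and non-missing",
                    "conjscreen_validation_error")
  }
  neg <- which(densities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_conjscreen(
      sprintf("negative density at row %d, column %d (0-based: %d, %d)",
              neg[1, 1], neg[1, 2], neg[1, 1] - 1L, neg[1, 2] - 1L),
      "conjscreen_validation_error"
    )
  }
  condition <- match.arg(condition, c("broth", "solid"))
  selection <- match.arg(selection, c("recipient", "transconjugant"))
  replicate <- as.integer(replicate)
  if (length(replicate) != 1 || is.na(replicate) || replicate < 1) {
    stop_conjscreen("replicate must be a positive integer",
                    "conjscreen_validation_error")
  }
  dimnames(densities) <- NULL
  structure(
    list(densities = densities, plate_id = as.character(plate_id),
         condition = condition, selection = selection, replicate = replicate),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("<plate_grid> %s | %s | %s | replicate %d\n",
              x$plate_id, x$condition, x$selection, x$replicate))
  cat(sprintf("  densities: 16 x 24, total %.4g, %d empty cells\n",
              sum(x$densities), sum(x$densities == 0)))
  invisible(x)
}

#' Read a plate density grid from tab-delimited text
#'
#' The canonical format is a `#`-prefixed header block
#' (`plate_id`, `condition`, `selection`, `replicate`) followed by 16
#' tab-separated data rows of 24 cells. Grid coordinates are 0-based
#' (row, column), row-major. CRLF and trailing whitespace are accepted;
#' malformed numerics are rejected, never coerced.
#'
#' @param path path to a plate-grid file.
#' @return A [plate_grid()] object.
#' @export
read_plate_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  required <- c("plate_id", "condition", "selection", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop_conjscreen(
      paste0("plate header missing field(s): ", paste(missing, collapse = ", ")),
      "conjscreen_parse_error"
    )
  }
  if (length(body) != 16) {
    stop_conjscreen(
      sprintf("expected 16 data rows, found %d (file %s)", length(body), path),
      "conjscreen_shape_error"
    )
  }
  rows <- lapply(seq_along(body), function(i) {
    cells <- strsplit(sub("\\s+$", "", body[i]), "\t", fixed = TRUE)[[1]]
    if (length(cells) != 24) {
      stop_conjscreen(
        sprintf("row %d (0-based %d) has %d cells, expected 24",
                i, i - 1L, length(cells)),
        "conjscreen_shape_error"
      )
    }
    parse_strict_numeric(cells, context = sprintf("cell in row %d", i - 1L))
  })
  plate_grid(do.call(rbind, rows), plate_id = meta$plate_id,
             condition = meta$condition, selection = meta$selection,
             replicate = parse_strict_numeric(meta$replicate, "replicate"))
}

#' Write a plate grid to its canonical tab-delimited form
#'
#' @param grid a [plate_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "plate_grid"))
  header <- c(
    "# format: conjscreen plate grid v1 (16x24, tab-delimited, 0-based row/col)",
    sprintf("# plate_id: %s", grid$plate_id),
    sprintf("# condition: %s", grid$condition),
    sprintf("# selection: %s", grid$selection),
    sprintf("# replicate: %d", grid$replicate)
  )
  rows <- apply(grid$densities, 1, function(r) paste(format_num(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Define the dilution-series layout of a colony array
#'
#' Each library mutant occupies an ordered run of grid positions forming its
#' serial-dilution series (16 spots by default, one column of a 384-position
#' plate). Positions are 0-based `(row, column)` pairs and must be disjoint
#' across mutants.
#'
#' @param mutant_positions named list; for each mutant id, an integer matrix
#'   with two columns (row, column, 0-based) ordered from the least to the
#'   most dilute spot.
#' @param series_length expected number of spots per series.
#' @param plate_of optional named character vector assigning each mutant to
#'   a plate id; positions must be disjoint between mutants sharing a
#'   plate. Omitted = single-plate layout.
#' @return A `series_layout` object.
#' @export
series_layout <- function(mutant_positions, series_length = 16L,
                          plate_of = NULL) {
  if (is.null(names(mutant_positions)) || anyDuplicated(names(mutant_positions))) {
    stop_conjscreen("mutant_positions must be uniquely named",
                    "conjscreen_validation_error")
  }
  mutant_positions <- lapply(mutant_positions, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    if (any(m[, 1] < 0 | m[, 1] > 15 | m[, 2] < 0 | m[, 2] > 23)) {
      stop_conjscreen("series position outside the 16 x 24 grid",
                      "conjscreen_validation_error")
    }
    m
  })
  ids <- names(mutant_positions)
  if (!is.null(plate_of) &&
      !all(ids %in% names(plate_of))) {
    stop_conjscreen("plate_of must cover every mutant",
                    "conjscreen_validation_error")
  }
  plates <- if (is.null(plate_of)) rep("p", length(ids)) else
    unname(plate_of[ids])
  keys <- unlist(lapply(seq_along(ids), function(i) {
    m <- mutant_positions[[i]]
    paste(plates[i], m[, 1], m[, 2])
  }))
  if (anyDuplicated(keys)) {
    stop_conjscreen("series positions overlap between mutants",
                    "conjscreen_validation_error")
  }
  structure(list(mutant_positions = mutant_positions,
                 series_length = as.integer(series_length),
                 plate_of = if (is.null(plate_of)) NULL else
                   stats::setNames(unname(plate_of[ids]), ids)),
            class = "series_layout")
}

#' @export
print.series_layout <- function(x, ...) {
  cat(sprintf("<series_layout> %d mutants, series length %d\n",
              length(x$mutant_positions), x$series_length))
  invisible(x)
}

#' Read or write a series layout (JSON)
#'
#' @param path JSON file with fields `series_length` and `mutants`
#'   (mutant id to list of `[row, column]` 0-based pairs).
#' @return [series_layout()] for the reader; `path` invisibly for the writer.
#' @export
read_series_layout <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  pos <- lapply(x$mutants, function(m) matrix(as.integer(m), ncol = 2))
  plate_of <- if (!is.null(x$plate_of)) unlist(x$plate_of) else NULL
  series_layout(pos, series_length = x$series_length, plate_of = plate_of)
}

#' @rdname read_series_layout
#' @param layout a [series_layout()].
#' @export
write_series_layout <- function(layout, path) {
  stopifnot(inherits(layout, "series_layout"))
  obj <- list(
    series_length = layout$series_length,
    mutants = lapply(layout$mutant_positions, function(m) {
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    })
  )
  if (!is.null(layout$plate_of)) obj$plate_of <- as.list(layout$plate_of)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
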