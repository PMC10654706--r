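#' Adhesin-by-strain transfer-rate matrix
#'
#' Holds manual conjugation frequencies (transconjugants per recipient CFU)
#' for a panel of recipient strains mated with plasmid derivatives each
#' displaying a single PilV adhesin. Cells below the assay detection limit
#' carry the sentinel `"BD"` (below detection, the heat maps' cross marks),
#' encoded as `NA` in the numeric matrix plus a logical mask.
#'
#' @param rates numeric matrix (adhesins x strains) of transfer frequencies
#'   in `[0, 1]`; `NA` where below detection.
#' @param below_detection logical matrix, `TRUE` where the sentinel applies.
#' @param adhesins,strains ordered id vectors naming rows/columns.
#' @return A `transfer_matrix` object.
#' @export
transfer_matrix <- function(rates, below_detection = is.na(rates),
                            adhesins = rownames(rates),
                            strains = colnames(rates)) {
  rates <- as.matrix(rates)
  below_detection <- as.matrix(below_detection)
  if (!identical(dim(rates), dim(below_detection))) {
    stop_conjscreen("rates and below_detection shapes differ",
                    "conjscreen_shape_error")
  }
  if (is.null(adhesins) || is.null(strains)) {
    stop_conjscreen("adhesin and strain ids are required",
                    "conjscreen_validation_error")
  }
  if (any(rates[!below_detection] < 0, na.rm = TRUE)) {
    stop_conjscreen("transfer rates must be non-negative",
                    "conjscreen_validation_error")
  }
  rates[below_detection] <- NA_real_
  dimnames(rates) <- list(adhesins, strains)
  dimnames(below_detection) <- list(adhesins, strains)
  structure(list(rates = rates, below_detection = below_detection,
                 adhesins = adhesins, strains = strains),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %d adhesins x %d strains (%d below detection)\n",
              length(x$adhesins), length(x$strains), sum(x$below_detection)))
  invisible(x)
}

#' Read or write a transfer-rate matrix (TSV)
#'
#' First column `adhesin`, remaining columns one per strain; cells are plain
#' decimal frequencies or the literal token `BD` for below-detection results.
#'
#' @param path TSV file path.
#' @return A [transfer_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_transfer_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "adhesin") {
    stop_conjscreen("first column of a transfer matrix must be 'adhesin'",
                    "conjscreen_parse_error")
  }
  strains <- header[-1]
  body <- cells[-1]
  adhesins <- vapply(body, `[`, character(1), 1)
  rates <- matrix(NA_real_, length(adhesins), length(strains))
  bd <- matrix(FALSE, length(adhesins), length(strains))
  for (i in seq_along(body)) {
    row <- body[[i]][-1]
    if (length(row) != length(strains)) {
      stop_conjscreen(sprintf("row '%s' has %d cells, expected %d",
                              adhesins[i], length(row), length(strains)),
                      "conjscreen_shape_error")
    }
    isbd <- trimws(row) == "BD"
    bd[i, ] <- isbd
    if (any(!isbd)) {
      rates[i, !isbd] <- parse_strict_numeric(row[!isbd],
                                              context = paste("rate for", adhesins[i]))
    }
  }
  transfer_matrix(rates, bd, adhesins = adhesins, strains = strains)
}

#' @rdname read_transfer_matrix
#' @param tm a [transfer_matrix()].
#' @export
write_transfer_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "transfer_matrix"))
  rows <- vapply(seq_along(tm$adhesins), function(i) {
    cells <- ifelse(tm$below_detection[i, ], "BD", format_num(tm$rates[i, ]))
    paste(c(tm$adhesins[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("adhesin", tm$strains), collapse = "\t"), rows), path)
  invisible(path)
}
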