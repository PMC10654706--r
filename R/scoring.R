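#' Total dilution-series density of one mutant on one plate
#'
#' Sums the plate densities over the mutant's dilution-series positions; the
#' colony-array quantification treats this total as the growth readout of
#' the whole 16-spot serial dilution.
#'
#' @param grid a [plate_grid()].
#' @param layout a [series_layout()].
#' @param mutant_id mutant present in the layout.
#' @return Non-negative numeric scalar.
#' @export
series_density <- function(grid, layout, mutant_id) {
  stopifnot(inherits(grid, "plate_grid"), inherits(layout, "series_layout"))
  pos <- layout$mutant_positions[[mutant_id]]
  if (is.null(pos)) {
    stop_conjscreen(sprintf("unknown mutant '%s'", mutant_id),
                    "conjscreen_reference_error")
  }
  sum(grid$densities[pos[, 1] + 1L + 16L * pos[, 2]])
}

#' Per-mutant conjugation score
#'
#' The screen readout: transconjugant-plate density divided by
#' recipient-plate density for the same mutant, replicate and condition.
#' When the recipient density is zero (the mutant failed to grow) the score
#' is flagged missing (`NA`), never an infinity; it is excluded downstream.
#'
#' @param t_density,r_density non-negative densities from the
#'   transconjugant- and recipient-selection plates.
#' @return Numeric vector; `NA` where `r_density == 0`.
#' @export
conjugation_score <- function(t_density, r_density) {
  if (any(t_density < 0, na.rm = TRUE) || any(r_density < 0, na.rm = TRUE)) {
    stop_conjscreen("densities must be non-negative", "conjscreen_validation_error")
  }
  ifelse(r_density > 0, t_density / r_density, NA_real_)
}

#' Per-mutant series densities for a set of plates
#'
#' @param plates list of [plate_grid()] objects covering one condition
#'   (both selections, all replicates).
#' @param layout a [series_layout()]; each mutant's series must lie on
#'   exactly one plate per (selection, replicate).
#' @return Tibble with columns `mutant_id`, `replicate`, `selection`,
#'   `density`.
#' @export
series_density_table <- function(plates, layout) {
  stopifnot(inherits(layout, "series_layout"))
  out <- lapply(plates, function(g) {
    stopifnot(inherits(g, "plate_grid"))
    ids <- names(layout$mutant_positions)
    # a layout typically spans many plates; only mutants assigned to this
    # plate contribute
    if (!is.null(layout$plate_of)) ids <- ids[layout$plate_of[ids] == g$plate_id]
    tibble(
      mutant_id = ids,
      replicate = g$replicate,
      selection = g$selection,
      density = vapply(ids, function(m) series_density(g, layout, m), numeric(1))
    )
  })
  dplyr::bind_rows(out)
}

#' Replicate conjugation scores from a density table
#'
#' @param densities tibble from [series_density_table()].
#' @return Tibble `mutant_id`, `replicate`, `score` (`NA` = flagged missing).
#' @export
replicate_scores <- function(densities) {
  wide <- tidyr::pivot_wider(densities, names_from = "selection",
                             values_from = "density")
  tibble(
    mutant_id = wide$mutant_id,
    replicate = wide$replicate,
    score = conjugation_score(wide$transconjugant, wide$recipient)
  )
}

#' Aggregate replicate scores and compute replicate QC
#'
#' Per mutant, the mean and sample standard deviation (n - 1 denominator)
#' over non-missing replicate scores; mutants with fewer than two valid
#' replicates are kept but flagged low-confidence. The QC report gives the
#' pairwise Pearson correlation of per-mutant densities between replicates,
#' separately for the recipient and transconjugant selections, plus their
#' per-selection averages (the screen's replicate-agreement statistic).
#'
#' @param rep_scores tibble from [replicate_scores()].
#' @param densities tibble from [series_density_table()] (for the QC part);
#'   omit to skip QC.
#' @param condition optional condition label stored on the result.
#' @return List with elements `scores` (tibble `mutant_id`, `mean_score`,
#'   `sd_score`, `n_valid`, `low_confidence`) and `qc` (list with `pairs`
#'   tibble and `mean` per selection), classed `score_table` / `qc_report`.
#' @export
aggregate_replicates <- function(rep_scores, densities = NULL, condition = NA_character_) {
  if (nrow(rep_scores) == 0) {
    stop_conjscreen("no replicate scores supplied", "conjscreen_validation_error")
  }
  reps <- sort(unique(rep_scores$replicate))
  if (length(reps) > 1) {
    by_rep <- split(rep_scores$mutant_id, rep_scores$replicate)
    if (length(Reduce(intersect, by_rep)) == 0) {
      stop_conjscreen("no overlapping mutants across replicates",
                      "conjscreen_validation_error")
    }
  }
  scores <- rep_scores |>
    dplyr::group_by(.data$mutant_id) |>
    dplyr::summarise(
      mean_score = if (any(!is.na(.data$score))) mean(.data$score, na.rm = TRUE) else NA_real_,
      sd_score = stats::sd(.data$score[!is.na(.data$score)]),
      n_valid = sum(!is.na(.data$score)),
      .groups = "drop"
    ) |>
    dplyr::mutate(low_confidence = .data$n_valid < 2)
  attr(scores, "condition") <- condition
  class(scores) <- c("score_table", class(scores))

  qc <- NULL
  if (!is.null(densities)) {
    qc_one <- function(sel) {
      d <- densities[densities$selection == sel, ]
      wide <- tidyr::pivot_wider(d[, c("mutant_id", "replicate", "density")],
                                 names_from = "replicate", values_from = "density")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      combs <- utils::combn(ncol(mat), 2)
      tibble(
        selection = sel,
        rep_a = colnames(mat)[combs[1, ]],
        rep_b = colnames(mat)[combs[2, ]],
        pearson = vapply(seq_len(ncol(combs)), function(k) {
          # a constant replicate (e.g. a noise-free simulation) has no
          # defined correlation; report NA quietly
          suppressWarnings(stats::cor(mat[, combs[1, k]], mat[, combs[2, k]],
                                      use = "pairwise.complete.obs",
                                      method = "pearson"))
        }, numeric(1))
      )
    }
    sels <- unique(densities$selection)
    pairs <- if (length(reps) >= 2) dplyr::bind_rows(lapply(sels, qc_one)) else
      tibble(selection = character(), rep_a = character(),
             rep_b = character(), pearson = numeric())
    means <- vapply(sels, function(s) mean(pairs$pearson[pairs$selection == s]),
                    numeric(1))
    qc <- structure(list(pairs = pairs, mean = stats::setNames(means, sels)),
                    class = "qc_report")
  }
  list(scores = scores, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> average pairwise Pearson per selection:\n")
  for (s in names(x$mean)) cat(sprintf("  %-15s %.3f\n", s, x$mean[[s]]))
  invisible(x)
}

#' Manual conjugation frequency from colony counts
#'
#' Transconjugants per recipient CFU from a standard plate-count mating
#' assay: `(t_colonies * t_dilution) / (r_colonies * r_dilution)`, where the
#' dilutions are the multiplicative factors back to the mating mix. Zero
#' transconjugant colonies censor the result at the assay detection limit
#' and it is reported as `"< limit"`.
#'
#' @param t_colonies,r_colonies colony counts on the transconjugant and
#'   recipient plates.
#' @param t_dilution,r_dilution dilution factors back to the mating mix.
#' @param detection_limit assay detection limit (default `1e-8`).
#' @return A `frequency` object with fields `value`, `censored`,
#'   `detection_limit`.
#' @export
manual_frequency <- function(t_colonies, t_dilution, r_colonies, r_dilution,
                             detection_limit = 1e-8) {
  if (t_colonies < 0 || r_colonies < 0) {
    stop_conjscreen("colony counts must be non-negative",
                    "conjscreen_validation_error")
  }
  if (r_colonies == 0) {
    stop_conjscreen("recipient count is zero: frequency unquantifiable",
                    "conjscreen_validation_error")
  }
  if (t_colonies == 0) {
    return(structure(list(value = detection_limit, censored = TRUE,
                          detection_limit = detection_limit),
                     class = "frequency"))
  }
  structure(list(
    value = (t_colonies * t_dilution) / (r_colonies * r_dilution),
    censored = FALSE, detection_limit = detection_limit
  ), class = "frequency")
}

#' @export
format.frequency <- function(x, ...) {
  if (x$censored) paste0("< ", format(x$detection_limit)) else format(x$value)
}

#' @export
print.frequency <- function(x, ...) {
  cat("<frequency>", format(x), "\n")
  invisible(x)
}
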