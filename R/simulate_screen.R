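#' Configuration for the synthetic conjugation screen
#'
#' Defaults emulate the broth arm of the genome-wide screen: ~4,000 arrayed
#' deletion mutants, four biological replicates, null conjugation scores
#' around 0.81 with population sd 0.09, and a 16-spot serial-dilution
#' readout per mutant (one plate column). Planted hits are shifted by
#' `effect_sd` population sds. Growth variability (log-normal per-mutant and
#' per-replicate factors) scales both selection plates of a mating spot
#' equally, so it cancels from the score but drives the replicate Pearson
#' QC, as in the real screen.
#'
#' @param n_mutants number of mutants (default 4000).
#' @param n_replicates biological replicates (default 4).
#' @param score_mean,score_sd null-population mean/sd of the true
#'   conjugation score (defaults 0.81 / 0.09).
#' @param n_planted number of planted low-transfer mutants (default 0).
#' @param effect_sd planted effect in population-sd units (default -4).
#' @param noise_sd replicate measurement noise on the score (default 0.09).
#' @param noise_sd_slope optional heteroscedasticity: noise sd grows by this
#'   amount per unit of (true score - score_mean) above the mean
#'   (default 0).
#' @param dilution serial dilution factor between consecutive spots
#'   (default 5).
#' @param cap spot saturation cap, arbitrary density units (default 1.0).
#' @param n0 initial (undiluted) density in cap units (default 0.2, leaving
#'   linear-regime headroom for growth variability; values
#'   above `cap` saturate the first spots, making the readout
#'   semi-quantitative).
#' @param series_length spots per dilution series (default 16).
#' @param growth_sd_mutant,growth_sd_rep log-scale sd of the per-mutant and
#'   per-(mutant, replicate) growth factors (defaults 0.25 / 0.15).
#' @param condition condition label (default `"broth"`).
#' @param seed integer seed; every random substream derives from it.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_mutants = 4000, n_replicates = 4,
                              score_mean = 0.81, score_sd = 0.09,
                              n_planted = 0, effect_sd = -4,
                              noise_sd = 0.09, noise_sd_slope = 0,
                              dilution = 5, cap = 1.0, n0 = 0.2,
                              series_length = 16,
                              growth_sd_mutant = 0.25, growth_sd_rep = 0.15,
                              condition = "broth", seed = 1) {
  cfg <- list(n_mutants = as.integer(n_mutants),
              n_replicates = as.integer(n_replicates),
              score_mean = score_mean, score_sd = score_sd,
              n_planted = as.integer(n_planted), effect_sd = effect_sd,
              noise_sd = noise_sd, noise_sd_slope = noise_sd_slope,
              dilution = dilution, cap = cap, n0 = n0,
              series_length = as.integer(series_length),
              growth_sd_mutant = growth_sd_mutant,
              growth_sd_rep = growth_sd_rep,
              condition = match.arg(condition, c("broth", "solid")),
              seed = as.integer(seed))
  if (cfg$n_mutants < 1 || cfg$n_replicates < 1 || cfg$score_sd <= 0 ||
      cfg$dilution <= 1 || cfg$cap <= 0 || cfg$n0 <= 0 ||
      cfg$series_length < 1 || cfg$series_length > 16 ||
      cfg$n_planted > cfg$n_mutants ||
      cfg$n_planted < 0 || cfg$noise_sd < 0) {
    stop_conjscreen("invalid screen simulation configuration",
                    "conjscreen_validation_error")
  }
  structure(cfg, class = "screen_sim_config")
}

#' Simulate a full colony-array conjugation screen
#'
#' Draws a true conjugation score per mutant (planted hits shifted by the
#' configured effect), adds replicate noise truncated at zero, and renders
#' recipient- and transconjugant-selection plate grids spot by spot:
#' recipient spot k has density `cap * min(1, n0 * g * d^-(k-1))` for
#' growth factor `g`, and the transconjugant series uses `n0 * g * s'` in
#' place of `n0 * g`. Mutants are laid out one dilution series per plate
#' column (24 mutants per 384-position plate). The same seed reproduces the
#' output exactly.
#'
#' @param cfg a [screen_sim_config()].
#' @return List with `plates` (named list of [plate_grid()]s across
#'   replicates and selections), `layout` (a [series_layout()] whose
#'   `plate_of` field maps mutants to plates), and `truth` (tibble
#'   `mutant_id`, `true_score`, `planted`).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  n <- cfg$n_mutants
  ids <- sprintf("m%05d", seq_len(n))

  planted <- rep(FALSE, n)
  if (cfg$n_planted > 0) {
    planted[with_stream(cfg$seed, "planted",
                        sample.int(n, cfg$n_planted))] <- TRUE
  }
  true_score <- with_stream(cfg$seed, "scores",
                            stats::rnorm(n, cfg$score_mean, cfg$score_sd))
  # planted mutants sit at a defined true score (mean + effect in sd units),
  # so recall measures detection of a known effect size rather than the
  # overlap of two score populations
  true_score[planted] <- cfg$score_mean + cfg$effect_sd * cfg$score_sd
  true_score <- pmax(true_score, 0)

  g_mut <- with_stream(cfg$seed, "growth_mutant",
                       exp(stats::rnorm(n, 0, cfg$growth_sd_mutant)))
  g_rep <- with_stream(cfg$seed, "growth_rep",
                       matrix(exp(stats::rnorm(n * cfg$n_replicates, 0,
                                               cfg$growth_sd_rep)),
                              nrow = n))
  sd_eff <- pmax(cfg$noise_sd +
                   cfg$noise_sd_slope * pmax(true_score - cfg$score_mean, 0), 0)
  noise <- with_stream(cfg$seed, "noise",
                       matrix(stats::rnorm(n * cfg$n_replicates), nrow = n) * sd_eff)
  rep_score <- pmax(true_score + noise, 0)

  # layout: mutant j -> plate ceiling(j / 24), column (j - 1) %% 24,
  # rows 0..series_length-1 (0-based, row-major addressing)
  n_plates <- ceiling(n / 24)
  plate_of <- sprintf("p%03d", (seq_len(n) - 1) %/% 24 + 1)
  positions <- lapply(seq_len(n), function(j) {
    cbind(seq_len(cfg$series_length) - 1L, (j - 1L) %% 24L)
  })
  names(positions) <- ids
  layout <- series_layout(positions, series_length = cfg$series_length,
                          plate_of = stats::setNames(plate_of, ids))

  dil <- cfg$dilution^-(seq_len(cfg$series_length) - 1)
  plates <- list()
  for (r in seq_len(cfg$n_replicates)) {
    for (sel in c("recipient", "transconjugant")) {
      base <- cfg$n0 * g_mut * g_rep[, r]
      if (sel == "transconjugant") base <- base * rep_score[, r]
      for (p in seq_len(n_plates)) {
        on_plate <- which(plate_of == sprintf("p%03d", p))
        dens <- matrix(0, 16, 24)
        for (j in on_plate) {
          col <- (j - 1L) %% 24L + 1L
          dens[seq_len(cfg$series_length), col] <-
            cfg$cap * pmin(1, base[j] * dil)
        }
        pg <- plate_grid(dens, plate_id = sprintf("p%03d", p),
                         condition = cfg$condition, selection = sel,
                         replicate = r)
        plates[[sprintf("%s_%s_r%d_p%03d", cfg$condition, sel, r, p)]] <- pg
      }
    }
  }

  list(plates = plates, layout = layout,
       truth = tibble(mutant_id = ids, true_score = true_score,
                      planted = planted))
}

#' Score a simulated (or loaded) screen end to end
#'
#' Convenience pipeline: series densities, replicate scores, aggregation
#' and QC in one call.
#'
#' @param plates named list of [plate_grid()]s (one condition).
#' @param layout the matching [series_layout()].
#' @param condition condition label for the score table.
#' @return As [aggregate_replicates()], plus the `densities` and
#'   `rep_scores` tibbles.
#' @export
score_screen <- function(plates, layout, condition = NA_character_) {
  densities <- series_density_table(plates, layout)
  rep_scores <- replicate_scores(densities)
  agg <- aggregate_replicates(rep_scores, densities, condition = condition)
  c(agg, list(densities = densities, rep_scores = rep_scores))
}
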