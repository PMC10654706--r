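#' Configuration for synthetic receptor panels
#'
#' Generates adhesin-by-strain transfer panels with a known planted
#' receptor-motif set per adhesin. Strain structures are built over a motif
#' universe of distinct disaccharide units hanging off a common hub
#' residue; each unit's proximal residue can also occur bare (without its
#' distal partner), so incidental hub-proximal motifs are separable from
#' planted ones given enough strains. Permissive pairs draw a transfer rate
#' log-uniform on `[1e-4, 1e-1]`; non-permissive pairs are below-detection
#' sentinels or rates log-uniform between the detection limit (1e-8) and
#' just under the significance floor. Optional flip noise toggles cells
#' after rate assignment.
#'
#' @param n_strains number of randomly composed panel strains (default 14).
#' @param include_probes also include one single-unit "probe" strain per
#'   universe unit, displaying only that disaccharide (default `TRUE`).
#'   This mirrors the deliberate knockout series of a receptor-mapping
#'   study, in which each candidate structure is interrogated by a strain
#'   that isolates it; without probes the random panels are often not
#'   discriminating enough to identify the planted sets uniquely.
#' @param n_adhesins number of adhesins (default 4).
#' @param universe_size number of plantable disaccharide units (default 12).
#' @param planted_sizes integer vector of allowed planted-set sizes; one is
#'   drawn per adhesin (default `1:3`).
#' @param p_motif probability a strain displays a unit in full (default
#'   0.45).
#' @param p_bare probability a strain displays only the unit's proximal
#'   residue (default 0.25).
#' @param p_bd probability a non-permissive cell is a below-detection
#'   sentinel rather than a sub-floor rate (default 0.7).
#' @param flip_prob probability each cell's permissiveness is flipped
#'   (default 0).
#' @param floor significance floor used for rate regimes (default 5.9e-5).
#' @param seed integer seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_strains = 14, n_adhesins = 4,
                             universe_size = 12, planted_sizes = 1:3,
                             include_probes = TRUE,
                             p_motif = 0.45, p_bare = 0.25, p_bd = 0.7,
                             flip_prob = 0, floor = 5.9e-5, seed = 1) {
  cfg <- list(n_strains = as.integer(n_strains),
              n_adhesins = as.integer(n_adhesins),
              universe_size = as.integer(universe_size),
              planted_sizes = as.integer(planted_sizes),
              include_probes = isTRUE(include_probes),
              p_motif = p_motif, p_bare = p_bare, p_bd = p_bd,
              flip_prob = flip_prob, floor = floor, seed = as.integer(seed))
  if (cfg$n_strains < 1 || cfg$n_adhesins < 1 || cfg$universe_size < 1 ||
      any(cfg$planted_sizes < 1) ||
      max(cfg$planted_sizes) > cfg$universe_size ||
      any(c(p_motif, p_bare, p_bd, flip_prob) < 0) ||
      any(c(p_motif, p_bare, p_bd, flip_prob) > 1) ||
      p_motif + p_bare > 1) {
    stop_conjscreen("invalid panel simulation configuration",
                    "conjscreen_validation_error")
  }
  structure(cfg, class = "panel_sim_config")
}

# one plantable unit: distal residue Dk linked to proximal residue Sk,
# with a randomized linkage; proximal residues are unique per unit
panel_units <- function(cfg) {
  anomeric <- rep(c("a", "b"), length.out = cfg$universe_size)
  child <- rep(1L, cfg$universe_size)
  parent <- rep(c(2L, 3L, 4L, 6L, 7L), length.out = cfg$universe_size)
  lapply(seq_len(cfg$universe_size), function(k) {
    list(distal = sprintf("D%02d", k), proximal = sprintf("S%02d", k),
         anomeric = anomeric[k], child_pos = child[k], parent_pos = parent[k])
  })
}

panel_unit_motif <- function(u) {
  motif(distal = u$distal, anomeric = u$anomeric, child_pos = u$child_pos,
        parent_pos = u$parent_pos, proximal = u$proximal)
}

build_panel_tree <- function(present_full, present_bare, units, strain_id) {
  rows <- list(tibble(
    id = "lipA", mono = "lipA", stereo = NA_character_, anomeric = "n/a",
    child_pos = NA_integer_, parent_pos = NA_integer_,
    parent_id = NA_character_, subs = list(character()),
    added_by = "constitutive"
  ), tibble(
    id = "HUB", mono = "HUB", stereo = NA_character_, anomeric = "a",
    child_pos = 2L, parent_pos = 6L, parent_id = "lipA",
    subs = list(character()), added_by = "constitutive"
  ))
  for (k in which(present_full | present_bare)) {
    u <- units[[k]]
    rows[[length(rows) + 1]] <- tibble(
      id = u$proximal, mono = u$proximal, stereo = NA_character_,
      anomeric = "a", child_pos = 1L, parent_pos = 5L, parent_id = "HUB",
      subs = list(character()), added_by = "constitutive"
    )
    if (present_full[k]) {
      rows[[length(rows) + 1]] <- tibble(
        id = u$distal, mono = u$distal, stereo = NA_character_,
        anomeric = u$anomeric, child_pos = u$child_pos,
        parent_pos = u$parent_pos, parent_id = u$proximal,
        subs = list(character()), added_by = "constitutive"
      )
    }
  }
  glycan_tree(dplyr::bind_rows(rows), background = strain_id)
}

#' Simulate a receptor panel with planted ground truth
#'
#' @param cfg a [panel_sim_config()].
#' @return List with `structures` (named list of [glycan_tree()]s),
#'   `matrix` (a [transfer_matrix()]), and `truth` (list with
#'   `planted_sets`: canonical motif strings per adhesin, and
#'   `permissive`: the noise-free logical matrix).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  units <- panel_units(cfg)
  unit_motifs <- vapply(lapply(units, panel_unit_motif), render_motif,
                        character(1))
  strains <- sprintf("strain%02d", seq_len(cfg$n_strains))
  adhesins <- sprintf("adhesin%02d", seq_len(cfg$n_adhesins))

  pres <- with_stream(cfg$seed, "structures", {
    u <- matrix(stats::runif(cfg$n_strains * cfg$universe_size),
                nrow = cfg$n_strains)
    list(full = u < cfg$p_motif,
         bare = u >= cfg$p_motif & u < cfg$p_motif + cfg$p_bare)
  })
  if (cfg$include_probes) {
    # one strain displaying only unit k in full, and one displaying only its
    # bare proximal residue: together they separate each unit from the
    # incidental proximal-hub motif it drags along
    strains <- c(strains, sprintf("probe%02d", seq_len(cfg$universe_size)),
                 sprintf("bare%02d", seq_len(cfg$universe_size)))
    pres$full <- rbind(pres$full, diag(cfg$universe_size) == 1,
                       matrix(FALSE, cfg$universe_size, cfg$universe_size))
    pres$bare <- rbind(pres$bare,
                       matrix(FALSE, cfg$universe_size, cfg$universe_size),
                       diag(cfg$universe_size) == 1)
  }
  structures <- lapply(seq_along(strains), function(i) {
    build_panel_tree(pres$full[i, ], pres$bare[i, ], units, strains[i])
  })
  names(structures) <- strains

  planted <- with_stream(cfg$seed, "planted", {
    lapply(seq_len(cfg$n_adhesins), function(a) {
      k <- sample(cfg$planted_sizes, 1)
      sort(unit_motifs[sample.int(cfg$universe_size, k)])
    })
  })
  names(planted) <- adhesins

  permissive <- matrix(FALSE, cfg$n_adhesins, length(strains),
                       dimnames = list(adhesins, strains))
  for (a in seq_len(cfg$n_adhesins)) {
    member <- unit_motifs %in% planted[[a]]
    permissive[a, ] <- rowSums(pres$full[, member, drop = FALSE]) > 0
  }

  flips <- with_stream(cfg$seed, "flips",
                       matrix(stats::runif(length(permissive)) < cfg$flip_prob,
                              nrow = nrow(permissive)))
  observed <- xor(permissive, flips)

  rates <- with_stream(cfg$seed, "rates", {
    r <- matrix(NA_real_, nrow(observed), ncol(observed))
    bd <- matrix(FALSE, nrow(observed), ncol(observed))
    for (i in seq_len(nrow(observed))) {
      for (j in seq_len(ncol(observed))) {
        if (observed[i, j]) {
          r[i, j] <- 10^stats::runif(1, -4, -1)
        } else if (stats::runif(1) < cfg$p_bd) {
          bd[i, j] <- TRUE
        } else {
          r[i, j] <- 10^stats::runif(1, -8, log10(cfg$floor) - 0.05)
        }
      }
    }
    list(r = r, bd = bd)
  })

  tm <- transfer_matrix(rates$r, rates$bd, adhesins = adhesins,
                        strains = strains)
  list(structures = structures, matrix = tm,
       truth = list(planted_sets = planted, permissive = permissive,
                    unit_motifs = unit_motifs))
}
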