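#' Disaccharide recognition motif
#'
#' The unit of PilV adhesin recognition: a distal residue joined to a
#' proximal residue by an anomeric linkage, optionally constrained by
#' required substituents (e.g. a 4-phosphate on the proximal heptose).
#' Substituent constraints are positive-only: a motif may require a
#' substituent, never forbid one.
#'
#' @param distal,proximal short monosaccharide labels (e.g. `"GlcNAc"`,
#'   `"Hep"`, `"Glc"`).
#' @param anomeric `"a"` or `"b"` (ASCII for alpha/beta).
#' @param child_pos,parent_pos linkage positions: the distal residue's
#'   anomeric carbon and the proximal residue's attachment carbon.
#' @param distal_sub,proximal_sub character vectors of required substituent
#'   tokens, position-prefixed (e.g. `"4P"`).
#' @param distal_stereo,proximal_stereo optional stereochemistry qualifiers
#'   (`"L-D"`/`"D-D"` for the two heptose backbones), used only by full-name
#'   rendering.
#' @return A `motif` object.
#' @export
motif <- function(distal, anomeric, child_pos, parent_pos, proximal,
                  distal_sub = character(), proximal_sub = character(),
                  distal_stereo = NA_character_, proximal_stereo = NA_character_) {
  anomeric <- match.arg(anomeric, c("a", "b"))
  if (!nzchar(distal) || !nzchar(proximal)) {
    stop_conjscreen("motif residue labels must be non-empty",
                    "conjscreen_validation_error")
  }
  structure(
    list(distal = as.character(distal), anomeric = anomeric,
         child_pos = as.integer(child_pos), parent_pos = as.integer(parent_pos),
         proximal = as.character(proximal),
         distal_sub = sort(as.character(distal_sub)),
         proximal_sub = sort(as.character(proximal_sub)),
         distal_stereo = distal_stereo, proximal_stereo = proximal_stereo),
    class = "motif"
  )
}

residue_label <- function(label, subs) {
  if (length(subs) == 0) return(label)
  paste0(label, "[", paste(sort(subs), collapse = ","), "]")
}

full_name_map <- c(
  Glc = "glucose", Gal = "galactose", GlcNAc = "N-acetylglucosamine",
  GlcN = "glucosamine", Kdo = "3-deoxy-D-manno-octulosonic acid",
  Hep = "heptose", lipA = "lipid A"
)

full_residue_name <- function(label, stereo, subs) {
  base <- if (label == "Hep" && !is.na(stereo)) {
    if (stereo == "D-D") "D-glycero-D-manno-heptose" else "L-glycero-D-manno-heptose"
  } else if (label %in% names(full_name_map)) {
    full_name_map[[label]]
  } else {
    label
  }
  for (s in subs) {
    pos <- sub("^([0-9]+).*$", "\\1", s)
    tok <- sub("^[0-9]+", "", s)
    tokname <- switch(tok, P = "phosphate", PPEtN = "pyrophosphoethanolamine", tok)
    base <- paste0(base, "-", pos, "-", tokname)
  }
  base
}

#' Render a motif as its canonical one-line string
#'
#' The canonical short form is `Distal[-subst]-x(c-p)-Proximal[-subst]`, e.g.
#' `GlcNAc-b(1-7)-Hep` or `Hep-a(1-3)-Hep[4P]`, with ASCII `a`/`b` for
#' alpha/beta. Rendering is deterministic and injective over valid motifs;
#' it is the identity used for motif comparison throughout the package.
#'
#' @param m a [motif()].
#' @param full_names render field-style full chemical names (heptose
#'   stereochemistry spelled out, substituents as suffixes) instead of the
#'   short canonical form.
#' @return A single string.
#' @export
render_motif <- function(m, full_names = FALSE) {
  stopifnot(inherits(m, "motif"))
  if (full_names) {
    return(paste0(
      full_residue_name(m$distal, m$distal_stereo, m$distal_sub),
      "-", m$anomeric, "-(", m$child_pos, "-", m$parent_pos, ")-",
      full_residue_name(m$proximal, m$proximal_stereo, m$proximal_sub)
    ))
  }
  paste0(residue_label(m$distal, m$distal_sub), "-", m$anomeric,
         "(", m$child_pos, "-", m$parent_pos, ")-",
         residue_label(m$proximal, m$proximal_sub))
}

#' Parse the canonical short motif string
#'
#' Inverse of [render_motif()] on the short form.
#'
#' @param text canonical motif string such as `"GlcNAc-b(1-7)-Hep"` or
#'   `"Hep-a(1-3)-Hep[4P]"`.
#' @return A [motif()].
#' @export
parse_motif <- function(text) {
  pat <- "^([A-Za-z0-9]+)(\\[([^]]*)\\])?-([ab])\\(([0-9]+)-([0-9]+)\\)-([A-Za-z0-9]+)(\\[([^]]*)\\])?$"
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) == 0) {
    stop_conjscreen(sprintf("cannot parse motif string '%s'", text),
                    "conjscreen_parse_error")
  }
  split_subs <- function(s) if (is.na(s) || !nzchar(s)) character() else
    strsplit(s, ",", fixed = TRUE)[[1]]
  motif(distal = m[2], anomeric = m[5], child_pos = as.integer(m[6]),
        parent_pos = as.integer(m[7]), proximal = m[8],
        distal_sub = split_subs(m[4]), proximal_sub = split_subs(m[10]))
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif>", render_motif(x), "\n")
  invisible(x)
}

#' @export
format.motif <- function(x, ...) render_motif(x)
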