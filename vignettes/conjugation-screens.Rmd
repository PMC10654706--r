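---
title: "Conjugation screens and PilV receptor inference with conjscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjugation screens and PilV receptor inference with conjscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjscreen)
```

## The problem

Conjugative plasmids of the I-complex (IncI2 plasmids such as TP114 among
them) carry, besides their transfer machinery, an accessory type IVb pilus
whose minor pilin PilV acts as an adhesin. A shufflon — a site-specific DNA
inversion system at the 3' end of *pilV* — lets a plasmid population display
up to eight PilV variants, each recognizing specific carbohydrate structures
on the recipient's surface. In liquid culture this recognition provides
mating pair stabilization and is required for efficient transfer; on solid
media it is dispensable.

`conjscreen` implements the computational side of a two-part experimental
strategy for mapping these requirements:

1. **A genome-wide recipient screen.** Each of ~4,000 single-gene deletion
   mutants (a Keio-style ordered library) is mated with a donor in broth and
   on solid medium, arrayed at 384 positions per plate, and each mating is
   serially replicated 16 times to create a dilution series. Growth density
   on a transconjugant-selective plate relative to a recipient-selective
   plate gives a per-mutant *conjugation score*; Z scores call hits; term
   enrichment summarizes the pathways involved.
2. **Receptor elucidation.** Manual conjugation assays against strains with
   defined lipopolysaccharide (LPS) structures — the five *E. coli*
   core-oligosaccharide prototypes (K-12, R1–R4), core-truncating knockouts,
   glycosyltransferase knock-ins, and the saccharide-free ClearColi — are
   binarized at a significance floor. For each adhesin the package searches
   for the minimal sets of disaccharide motifs whose presence/absence
   pattern explains the panel.

## Screen scoring model

For mutant $i$, replicate $r$, the dilution-series densities on the two
selective plates are summed and the conjugation score is their ratio:

$$s_{ir} = \frac{D^{T}_{ir}}{D^{R}_{ir}},$$

with $D^R = 0$ flagged missing (the mutant failed to grow) rather than an
infinity. Replicates aggregate to a mean and a sample standard deviation
($n-1$ denominator; replicate counts are small, typically 4). Mutants with
fewer than two valid replicates are kept but flagged low-confidence, because
a near-complete library matters more than uniform precision. Replicate
agreement is summarized by the pairwise Pearson correlation of per-mutant
densities, averaged per selection — the screen-level QC statistic.

Z scores standardize each condition separately against its own screen mean
and sd, $z_i = (\bar s_i - \mu)/\sigma$, and hits are mutants with
$z < -1.96$ (strictly below: the lower 2.5% tail of a normal screen,
$p \le 0.05$). Because broth and solid screens have distinct score
distributions (historically ~0.81 ± 0.09 vs ~0.86 ± 0.08), each gets its own
standardization. Enrichment among hits uses the upper-tail hypergeometric
test over a flat gene→term annotation, with Benjamini–Hochberg adjustment
across the tested terms; the universe is the set of mutants actually scored
in that condition, not the genome. Ontology-graph propagation is out of
scope: annotations are treated as flat sets.

```{r screen}
cfg <- screen_sim_config(n_mutants = 480, n_planted = 12, seed = 1)
sim <- simulate_screen(cfg)
res <- score_screen(sim$plates, sim$layout, condition = "broth")
res$qc
hits <- call_hits(z_transform(res$scores))
mean(sim$truth$mutant_id[sim$truth$planted] %in% hits$low$mutant_id)
```

## The LPS model

The core oligosaccharide is modeled as a rooted tree of residues anchored at
lipid A: two Kdo units, a phosphorylated heptose backbone, and a
prototype-specific outer core of glucose/galactose/N-acetylglucosamine
residues. Every residue and substituent carries the gene whose product
installs it. A per-background biosynthesis table drives construction: each
gene's action attaches a residue (to a parent matched by a structural
selector: the parent's monosaccharide, its own linkage, and its parent's
monosaccharide) or a substituent, or marks a precursor-pathway step
(`gmhD`, `waaE` for ADP-heptose; `wecA`, `wzx` for the terminal GlcNAc
donor). Dependencies that are not visible in the tree are explicit
`requires` edges — the Hep II phosphotransferase (WaaY) requires the Hep I
kinase (WaaP), and every heptosyltransferase requires the precursor pathway
— so deleting an upstream gene removes downstream products even when the
attachment site would still exist.

Genotypes are `(background, deletions, additions)`. Construction applies
the background's actions in table order, skipping unavailable genes; a
residue whose parent never appears is skipped, so truncations cascade
distally. Plasmid-expressed additions are applied afterwards, iterating to
a fixpoint so one knock-in can build on another regardless of listing
order; an addition whose parent selector matches nothing warns and leaves
the structure unchanged. Two properties follow and are property-tested:
knockouts only remove motifs, knock-ins only add them, and deletion order
is irrelevant.

Recognition is modeled at the granularity of disaccharide motifs: a distal
residue, an anomeric linkage with positions, a proximal residue, and
positive-only substituent constraints (a motif may require a phosphate,
never forbid one — the experimental logic can demonstrate required
chemistry, not inhibitory chemistry). `enumerate_motifs()` emits one motif
per saccharide edge, optionally with and without each residue's substituent
constraints, so a phosphorylated heptose yields both `Hep-a(1-3)-Hep` and
`Hep-a(1-3)-Hep[4P]`. Containment is purely topological; steric masking by
distal sugars is not modeled.

```{r lps}
wt <- build_prototype("K-12")
contains_motif(wt, "GlcNAc-b(1-7)-Hep")
dl <- apply_genotype(genotype("K-12", deletions = "waaL"))
contains_motif(dl, "GlcNAc-b(1-7)-Hep")
```

The two heptose backbones (L-glycero-D-manno vs D-glycero-D-manno) are
distinct stereochemistry labels internally — the receptor summary
distinguishes them — but both render as `Hep` in the default short form;
`render_motif(full_names = TRUE)` spells them out.

### What the packaged tables are, and are not

The inner core, all receptor-bearing edges, the knockout dependency
structure, and the gene assignments narrated in the study (waaL, waaP,
waaY, waaQ, waaF, waaC, waaE, gmhD, waaI+waaD, waaK, waaX, waaT, waaW) are
fixed by that evidence. The remaining outer-core edges of the R1–R4
prototypes follow the published core-OS structure literature as closely as
a text-only reconstruction allows, with placeholder gene ids (`wabA`,
`wabB`, `wabC`) for transferases the panel never interrogates. Files are
suffixed `_synthetic` and should be treated as a documented transcription,
not ground truth. The WaaY phosphate position (6) and the Hep IV attachment
position (6) are reconstruction choices that no motif in the panel depends
on. The terminal GlcNAc of the K-12 background is modeled as a single
residue attached by the action labeled `waaL` (with `wecA`/`wzx` as
requirements), and O-antigen repeats are not modeled: the O-antigen-less
derivative of K-12 is represented by the wild-type tree itself, since the
adhesins do not read the O antigen.

## Receptor inference

A transfer matrix is binarized at the significance floor
$5.9\times10^{-5}$ (inclusive: a rate exactly at the floor counts;
"below detection" sentinels never do). For each adhesin the engine searches
motif sets $S$ with $|S| \le k_{max}$ (default 3, the largest observed
repertoire) satisfying *soundness*: every permissive strain displays at
least one motif of $S$, and no non-permissive strain displays any motif of
$S$. All inclusion-minimal sound sets are reported, sorted by size then
canonical string; the call is `unique`, `ambiguous`, `inconsistent` (no
sound set — some observation contradicts pure presence/absence logic), or
`no_permissive`. The search space is pruned to motifs present in at least
one permissive strain and absent from all non-permissive strains; this
preserves exactness, and an exhaustive subset-enumeration oracle
(`brute_force_oracle()`) verifies equality on hundreds of random panels in
the test suite. Binarization is deterministic; noise handling is out of
band (`max_violations` permits a configured number of violated cells and
reports them, default 0).

Where the motif universe underdetermines the answer the engine reports
ambiguity rather than reproducing expert chemical reasoning; on the
packaged panel this is exactly the status of the two adhesins whose
receptors the study left open.

```{r infer}
fixture <- tp114_panel()
calls <- infer_receptors(binarize(fixture$matrix), fixture$structures)
calls
```

## Synthetic data: what it emulates, and what it does not

`simulate_screen()` reproduces the screen's observable structure: true
scores drawn from the broth-like null (mean 0.81, sd 0.09), planted hits
*at* a configured effect (default $-4$ population sds — a point effect, so
recall measures detection of a known effect size rather than the overlap of
two spread-out populations), replicate noise (sd 0.09) truncated at zero,
and a 16-spot serial-dilution readout (factor 5) rendered into 384-position
plate grids, one series per column. Log-normal growth factors (per-mutant
sd 0.25, per-replicate sd 0.15 on the log scale) multiply both selective
plates of a mating spot equally — they cancel from the score, as replicating
the same mating spot onto two selective plates would, but give the replicate
Pearson QC realistic values near the reported 0.74/0.81 averages; the pair
(0.25, 0.15) was chosen once to land the recipient correlation near 0.74
and is not otherwise calibrated. The default inoculum `n0 = 0.2` keeps the
whole series in the linear regime so that, with all noise switched off, the
pipeline recovers every true score to machine precision; raising `n0` above
the cap saturates early spots and reproduces the semi-quantitative
compression of a real dilution series. An optional `noise_sd_slope` adds
score-dependent noise (the real screen is noisier at high scores); its
linear form is a modeling convenience, not an estimated curve. Not
emulated: spatial plate effects, colony morphology, donor-side variation,
and cross-contamination — passing tests say nothing about those.

`simulate_panel()` builds strains over a universe of independent
disaccharide units hanging off a common hub, plants a motif set per
adhesin, and emits permissive rates log-uniform on $[10^{-4}, 10^{-1}]$ and
non-permissive cells as below-detection sentinels or sub-floor rates, with
optional cell-flip noise. By default the panel includes, per unit, one
probe strain displaying only that unit and one displaying only its bare
proximal residue — the in-silico analogue of the deliberate knockout series
a receptor-mapping study assembles. Without such probes, randomly composed
panels often cannot separate a unit from the incidental proximal–hub motif
it drags along, and unique recovery drops well below the ~100% achieved
with them.

## Numerical and design choices

* Scores are exact ratios; missing scores are `NA`, excluded pairwise.
* Sample sd uses $n-1$; z-scoring uses the screen's empirical mean/sd, so
  planted contamination inflates $\sigma$ and *lowers* the null
  false-positive rate below the nominal 2.5% — visible in the planted-hit
  simulations (~1% null rate at 100 planted mutants of $-4$ sd).
* Strict inequality at the hit threshold; ties at the threshold are not
  hits.
* BH adjustment, Pearson correlation and the hypergeometric tail are
  delegated to R's stats primitives behind the package's module surface,
  and cross-checked against definitional oracles in the tests.
* Minimality of receptor sets is by set inclusion, not cardinality; all
  minimal sets are reported deterministically sorted.
* One global seed drives named pseudo-random substreams per artifact, so
  adding a new stream never perturbs existing draws.
* Problem sizes in the test-suite closed loops (4,000-mutant screens for
  calibration and recall; 8–12-strain, 6–8-unit panels for the
  200-instance oracle sweeps) were chosen to exercise the study-scale
  screen while keeping the panel oracle exhaustive search exact.

## Known limitations

* The packaged R1–R4 outer cores are a literature-shaped reconstruction;
  receptor-bearing edges are evidence-anchored but the remaining edges and
  placeholder gene ids should not be cited as structural fact.
* Motif constraints are positive-only; an adhesin blocked by a substituent
  would be mis-modeled as simply not recognizing the bare motif.
* Containment ignores steric accessibility of interior motifs.
* The density→rate calibration of the dilution-series readout is treated
  as relative (semi-quantitative), as the screen design itself does.
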