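---
title: "Classifying prokaryotic histone-fold proteins from predicted structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying prokaryotic histone-fold proteins from predicted structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofold)
```

## The problem

Archaea, many bacteria, and some phages encode proteins built on the histone
fold: roughly 65 residues forming three α-helices (a short α1, a long central
α2, and a C-terminal α3) joined by two short linkers L1 and L2. The fold
always dimerizes in the "handshake" arrangement — the two α2 helices cross
and both α1 helices form one DNA-binding face — but what the dimers do next
varies enormously: archaeal nucleosomal histones stack dimers into
superhelices; a large family with a truncated α3 closes two dimers into a
torus-shaped "face-to-face" (FtF) tetramer thought to wrap DNA into ~8 nm
beads; others tetramerize through C-terminal coiled coils or tetramerization
domains and bridge DNA instead of wrapping it; still others have fused
zinc-finger or Rab-GTPase domains, gained transmembrane segments, or
dimerize through structured C-terminal tails next to integration-host-factor
genes.

With structure predictors, these architectures can be read off predicted
monomer and homo-multimer models — provided the reading is disciplined:
quaternary calls must be gated on the predictor's own confidence in the
interface. `histofold` turns that reading into an automated, parameterized,
testable pipeline: per-chain fold detection from Cα geometry, fold-family
calling, quaternary-topology classification with predicted-aligned-error
(PAE) gating, sequence-feature annotation, and a final category decision
tree with an evidence trail. A deterministic synthetic-structure generator
replaces structure-prediction runs, so every stage is testable at desk
scale.

## Fold detection from Cα geometry

Predicted models always carry Cα atoms, so secondary structure is assigned
from Cα geometry alone (in the spirit of P-SEA) rather than from hydrogen
bonds. A four-residue window $i..i{+}3$ is helical when

* the Cα($i$)–Cα($i{+}3$) distance lies in 4.6–6.4 Å (ideal α-helix: 5.05 Å), and
* the virtual torsion over the four Cα lies in 35–75° (ideal: ≈ +50°, so
  left-handed geometry can never qualify);

all four residues of a qualifying window are marked H. Under this marking an
ideal $n$-residue helix yields an H-run of exactly $n$, which is what lets
detected run lengths be compared directly with the defining helix lengths.
Runs shorter than 4 are smoothed to coil.

The histone fold is then the best triple of H-runs with α1 ∈ 6–16, α2 ∈
18–34, α3 ∈ 2–14 residues and linkers of 1–8 residues; among qualifying
triples the longest α2 wins (α2 is the fold's defining helix), ties going to
the most N-terminal. Chains under 30 residues never carry a fold, and
absence of a fold is an ordinary result, not an error.

**Truncated α3.** The α3-truncated family has an α3 of only 3–4 residues —
below the minimum any window-based assigner can resolve reliably, since a
4-residue helix leaves exactly one qualifying window. When no regular H-run
follows α2 within linker range, a dedicated relaxed single-window test
(distance 3.9–7.0 Å, torsion 20–100°) within 8 residues after α2 recovers
the truncated helix.

**Noise tolerance.** The strict window bands leave only ≈ 1σ of margin
against 0.3 Å Gaussian coordinate noise, and window failures are strongly
correlated (adjacent windows share three atoms). Three refinements make run
extraction robust without loosening the published criteria themselves:

1. *Gap closure*: a single coil residue flanked by solid H-runs is closed if
   some bridging window superposes onto a 4-residue ideal-helix template
   with RMSD ≤ 0.65 Å — a true in-helix split passes this; a real linker
   residue drags the fit far off. Closure never grows a run beyond the α2
   band (34), so it cannot bridge a genuine linker.
2. *End recovery*: run ends hang on single windows, so up to 2 residues per
   side are recovered under relaxed bands, never crossing another run.
3. *Split recovery*: if no fold triple is found, overlong runs (≥ 20) are
   split at their worst-fitting window (template RMSD > 0.65 Å) and the
   search is retried — this undoes the rare chance event of a linker window
   passing the strict bands and fusing two helices.

**Fold family.** The nucleosomal α3 is 10 residues long, the truncated α3 is
3–4. The call is made from the detected α3 run with conservative bands that
absorb end-fraying: ≤ 5 → `alpha3`, ≥ 8 → `nucleosomal`, 6–7 → `ambiguous`.
A shortened α2 (≤ 26 vs ≥ 27 residues) is recorded as corroborating
evidence but is never decisive — the α2 shortening is only known relatively
(4–5 residues shorter than nucleosomal), so no absolute α2 band can be
decisive.

## Quaternary topology and confidence gating

Interfaces are summarized as Cα–Cα contacts at ≤ 8 Å (a standard coarse
contact definition; there is no single canonical cutoff, so the generator
builds assemblies that are unambiguous at this scale — see below).

* **Handshake dimer**: ≥ 10 α2↔α2 inter-chain contacts and an α2 axis
  crossing angle (least-squares line fits) of 15–60°.
* **Tetramers** are first paired into two handshake dimers by maximal α2↔α2
  contact count over the three possible pairings. Inter-dimer contacts are
  then classified by the fold elements that carry them:
  * `ftf_torus` — exactly two inter-dimer interfaces (chain pairs with ≥ 3
    contacts) and ≥ 60% of inter-dimer contacts on α3 or the last 8
    residues of α2: both dimer ends engage, closing a torus;
  * `cc_bundle` — ≥ 60% of inter-dimer contacts on post-fold C-terminal
    residues *and* the post-fold helices of all four chains mutually within
    12 Å (a coiled-coil-like bundle);
  * `ctail_tetramer` — C-terminal dominance without bundle geometry
    (Methanococcales-type tetramerization domains);
  * `open_stack` — a single FtF-style interface (nucleosomal-like
    stacking);
  * `none` — anything else, including separated dimers.

Sixty percent is a deliberate clear-majority threshold; fixtures are
constructed far from that boundary, so green tests certify the rules, not
the threshold's fine calibration.

**PAE gate.** A multimer interface is trusted only if the mean predicted
aligned error over both off-diagonal blocks of the chain pair is strictly
below 10 Å; a mean of exactly 10 is low quality. PAE is directional, so the
matrix is kept asymmetric and the mean over both blocks is the symmetric
aggregate. A topology call is high-confidence only when every decisive
interface passes the gate; any category rule whose decisive evidence is a
low-confidence interface is skipped, and when no decisive rule survives the
protein is `undefined`.

## Category assignment

A first-match decision tree combines fold family, topologies, fused-domain
flags and sequence features (in order): transmembrane (no basic residues on
the α1 face plus a hydrophobic segment), zz (α3 fold + compact N-terminal
domain with C4/C2H2 zinc sites), rab_gtpase (α3 fold + ≥ 120-residue compact
N-terminal domain with a Walker-A P-loop), phage_like (α3 fold
tetramerizing through its C-terminal domain), ftf (α3 fold + torus),
bacterial_dimer (α3 fold + confident handshake dimer only), coiled_coil
(nucleosomal fold + bundle; flagged RdgC-like when the C-helix is ≥ 30
residues — the two cannot be separated by structure alone), mc_like
(nucleosomal + C-terminal tetramerization), ihf_like (nucleosomal dimer
with a structured dimerizing C-tail), nucleosomal, undefined. Every rule
fired or skipped is appended to the row's evidence string.

Because all predictions are homomers, a multimer chain whose own fold
detection fails (noise) inherits the monomer annotation when the residue
counts agree.

The wrapped-bead model for torus tetramers is
$d = \mathrm{extent}_{\text{in-plane}}/10 + 2\,d_{\mathrm{DNA}}$ nm: the
maximal Cα–Cα extent after projecting out the smallest principal axis of
the Cα cloud (the torus axis), plus one 2 nm DNA duplex on either side. The exact geometric
definition behind the reported 8.3 nm bead size is not fixed by any
standard; this construction reproduces the arithmetic (a 43 Å in-plane extent
gives 4.3 + 4.0 = 8.3 nm) and is tested as such.

## Sequence features

* **L2 motif**: RxTxxxxD (R at $i$, T at $i{+}2$, D at $i{+}7$; the spacing
  consistent with R47…D54 in the FtF exemplar), upgraded to RKTxxxxD by a
  lysine at $i{+}1$; the 6-offset variant (RxTxxxD) is a configurable
  alternate. A hit is structurally anchored when its threonine falls within
  L2 ± 2 of a supplied fold annotation.
* **Zinc sites**: the interleaved ZZ arrangement C1-C2 … C3-C4 … C5-C6 …
  H1-H2 with gaps 1–4 / 2–6 / 1–6 / 1–7 inside a ≤ 60-residue window; the
  C4 site is {C1,C2,C5,C6}, the C2H2 site {C3,C4,H1,H2}. With a structure,
  sites whose side-chain proxies (Cβ, Cα for Gly) are pairwise within 8 Å
  are flagged spatially clustered (predicted models carry no zinc atoms).
* **Tails**: flanks ≥ 5 residues outside the fold span that are not compact
  domains; net charge counts K/R = +1, D/E = −1, H = 0 (the simplest
  defensible neutral-pH model), charge class at ± 0.2 per residue;
  disordered when mean pLDDT < 50 (the predictor's "very low" band).
* **Transmembrane**: Kyte–Doolittle hydropathy, window 19, threshold 1.6;
  maximal runs of passing windows are merged, so every reported segment
  spans ≥ 19 residues and every fully interior window passes.
* **Conservation profiles**: per-column amino-acid frequencies over non-gap
  symbols with a 0.5 pseudocount per residue type and uniform background;
  information content is $\log_2 20 - H$ bits. Columns with > 50% gaps map
  to no reference position. This deliberately does not replicate
  HMMER/Skylign weighting, so profile positions are approximate and are
  never used as decisive classification evidence.

## The synthetic-data generator

`build_fold_monomer()`, `assemble_oligomer()`, `synth_confidence()`,
`synth_sequence_set()` and `synth_msa()` build the world the classifiers
are tested in; `write_golden_suite()` bundles 15 fixtures covering every
topology with both fold presets (nucleosomal 11/29/10, α3-truncated
11/25/4, linkers 3/3, per the defining lengths), plus fused-domain,
transmembrane and PAE-gate variants.

What the generator emulates: ideal α-helices (1.5 Å rise, 100° twist,
2.3 Å radius) packed as a handshake with a 30° α2 crossing; torus tetramers
touching only through their protruding α3 ends; coiled-coil bundles and
separate C-tail patches; arc-routed linkers at extended (~3.3 Å) spacing so
no linker window ever reads as helix; block pLDDT tracks (core vs tail) and
block PAE matrices (intra vs inter); background sequences drawn from a
fold-friendly alphabet with no Arg/Cys/His/Pro, with requested features
implanted and *rejection sampling* guaranteeing the implanted features are
the only scanner matches.

What it does not emulate — and hence what a green test does not establish:
side-chain packing, realistic Ramachandran statistics, sequence-dependent
helix propensity, heteromeric assemblies, partial-occupancy interfaces, or
realistic PAE textures. A green golden suite certifies that the advertised
decision rules fire on unambiguous instances of each architecture; it does
not certify performance on borderline real predictions.

Determinism: one RNG seed per artifact; byte-identical outputs for equal
seeds, and the generator restores the caller's RNG state. Gaussian
coordinate jitter emulates predictor noise; the clash check (2.5 Å minimum
separation, residues ≤ 6 apart along a chain exempt) runs on the ideal
coordinates. The canonical suite (seed 42) classifies identically under
jitter σ up to 0.3 Å; across arbitrary seeds the per-chain fold-detection
failure rate at σ = 0.3 is about 0.5% (measured over 600 chains), so very
occasionally a fixture at some seed degrades to `undefined` — an honest
limit of window-based assignment at that noise level, not hidden by the
test seeds.

## Pipeline

`run_batch()` classifies a TSV manifest of prediction records (monomer
required; dimer/tetramer/hexamer structures, their PAE JSONs, and a FASTA
sequence optional; hexamers are reduced to their best 4-chain
sub-assembly, since no category is defined by a hexamer). Per-record
failures produce an `undefined` row with warnings and never abort the
batch; row order follows the manifest; reruns are byte-identical. Every
numeric threshold lives in one configuration list (`hf_config()`),
overridable from JSON, and the report logs an MD5 hash of the configuration
used. The CLI (`inst/cli/histofold.R`) exposes `classify`, `fixtures`, and
`inspect`.

```{r example, eval = FALSE}
dir <- tempfile()
suite <- write_golden_suite(dir, seed = 42)
report <- run_batch(suite$manifest)
table(report$category)
```

## Known limitations

* The bacterial-dimer category is, in its original definition, a sequence
  cluster; the structural rule here (α3 fold, confident dimer, nothing
  larger) approximates but cannot reproduce cluster membership.
* RdgC-like vs coiled-coil histones are not separable by structure alone;
  the output is `coiled_coil` with an `rdgc_flag`.
* The eukaryotic-contamination filter of the original workflow (≥ 60% MSA
  identity to eukaryotic sequences) requires the original alignments and is
  out of scope; reports do not check it.
* Conservation-profile column numbering is the package's own; it does not
  attempt to match published HMM-logo coordinates, which depend on the full
  source alignments.
* Window-based Cα secondary structure cannot resolve helices shorter than
  4 residues; 3-residue truncated α3 helices are only recovered through
  the relaxed single-window test, and only when geometry cooperates.
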