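# histofold

Classification of prokaryotic histone-fold proteins from predicted
structures, in R.

Archaea, a scattering of bacterial lineages, and some phages encode
histone-fold proteins — the ~65-residue α1–L1–α2–L2–α3 three-helix motif —
whose quaternary architectures diverge far beyond the eukaryotic
nucleosome: handshake dimers that stack into superhelices, α3-truncated
histones whose two dimers close into a torus-shaped face-to-face (FtF)
tetramer that can wrap DNA into ~8 nm beads, coiled-coil and
Methanococcales-type tetramers that bridge DNA through C-terminal domains,
zinc-finger and Rab-GTPase fusions, transmembrane variants, and
IHF-associated dimers with structured C-terminal tails.

`histofold` reads predicted monomer/multimer structures (PDB or mmCIF with
per-residue pLDDT in the B-factor column) together with AlphaFold-style
predicted-aligned-error (PAE) JSON matrices and sequences, and assigns each
protein to one of these architectural categories with a full evidence
trail:

* **fold detection** from Cα geometry (P-SEA-style window criteria:
  Cα(i)–Cα(i+3) distance 4.6–6.4 Å, virtual torsion 35–75°), locating the
  α1/L1/α2/L2/α3 elements and calling the fold family — `nucleosomal`
  (10-residue α3) vs `alpha3` (3–4-residue truncated α3);
* **quaternary topology** of dimers and tetramers from Cα contact maps
  (8 Å): handshake dimer, `ftf_torus`, `cc_bundle`, `ctail_tetramer`,
  `open_stack`;
* **confidence gating**: an interface counts only when its mean inter-chain
  PAE is below 10 Å; rules whose decisive interface fails the gate are
  skipped, and proteins with no surviving decisive rule are `undefined`;
* **sequence features**: the L2 RxTxxxxD / RKTxxxxD motif, ZZ-type C4 +
  C2H2 zinc sites, basic residues on the DNA-binding α1 face, charged
  disordered tails, Kyte–Doolittle transmembrane segments, Walker-A
  P-loops, and pseudocounted information-content conservation profiles
  from MSAs;
* a **synthetic fixture generator** that builds idealized monomers, dimers
  and tetramers in every topology, with matching sequences, pLDDT tracks
  and block PAE matrices — so the entire pipeline is testable with no
  structure-prediction runs and no downloads.

See `vignettes/histofold-methods.Rmd` for the model, the thresholds and
their rationale, and what the synthetic fixtures do and do not establish.

## Worked example

```r
library(histofold)

dir <- tempfile()
suite <- write_golden_suite(dir, seed = 42)   # 15 fixtures, all topologies
report <- run_batch(suite$manifest, log_fun = NULL)
report[report$protein_id %in% c("nuc_monomer", "a3_ftf", "a3_ftf_lowpae"),
       c("protein_id", "fold_family", "alpha3_len", "tetramer_topology",
         "interface_pae", "category")]
#>     protein_id fold_family alpha3_len tetramer_topology
#>    nuc_monomer nucleosomal         10              <NA>
#>         a3_ftf      alpha3          4         ftf_torus
#>  a3_ftf_lowpae      alpha3          4         ftf_torus
#>                          interface_pae        category
#>                                   <NA>     nucleosomal
#>  dimer 5.0 (high); tetramer 5.0 (high)             ftf
#>  dimer 5.0 (high); tetramer 25.0 (low) bacterial_dimer
```

`nuc_monomer` has only a monomer: a nucleosomal fold, no multimer evidence,
category `nucleosomal` (low confidence, noted in the evidence column).
`a3_ftf` is an α3-truncated fold whose tetramer closes a torus through two
α3-carried interfaces with confident PAE → `ftf`. `a3_ftf_lowpae` is the
same geometry with inter-chain tetramer PAE of 25 Å: the torus rule is
skipped and the protein falls back to the confident dimer-level call,
`bacterial_dimer` — the sub-10 Å PAE gate at work.

Single structures can be inspected directly:

```r
fx <- build_fold_monomer(arch_alpha3(), seed = 1)
detect_histone_fold(fx$model, "A")
#> <hf_fold> chain A: a1 1-12 (12) | L1 2 | a2 15-39 (25) | L2 3 | a3 43-46 (4)  family=alpha3
```

and the per-category tally over the whole suite:

```r
table(report$category)
#> bacterial_dimer     coiled_coil             ftf        ihf_like         mc_like
#>               3               2               1               1               1
#>     nucleosomal      phage_like      rab_gtpase   transmembrane              zz
#>               3               1               1               1               1
```

A command-line interface ships in `inst/cli/histofold.R`:

```sh
Rscript inst/cli/histofold.R fixtures --suite golden --seed 42 --out fixtures/
Rscript inst/cli/histofold.R classify --manifest fixtures/manifest.tsv --out report.tsv
Rscript inst/cli/histofold.R inspect  --structure fixtures/a3_ftf/tetramer.pdb
```

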