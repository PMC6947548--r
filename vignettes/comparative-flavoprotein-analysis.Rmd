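---
title: "Comparative structural analysis of FAD/NADH-dependent oxidoreductases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative structural analysis of FAD/NADH-dependent oxidoreductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavocompare)
```

## The scientific problem

Flavoprotein oxidoreductases — the family spanning the mammalian
apoptosis-inducing factor (AIF), bacterial and fungal type II NADH
dehydrogenases (NDH-2, NDI), and the dihydrolipoamide-dehydrogenase (DLD)
relatives — catalyse the same core chemistry: oxidation of NADH via an FAD
cofactor, with ubiquinone (UQ) as the downstream electron acceptor in the
NDH-2/NDI branch. Their sequences diverge heavily (often 15–30% identity),
but their folds and cofactor cavities are strikingly alike. `flavocompare`
implements the comparative workflow that makes that similarity quantitative
and exploitable:

1. **Homolog filtering** of tabular sequence-search hits by E-value, query
   coverage and percent identity, plus exact-duplicate removal.
2. **Sequence-alignment-guided rigid-body superposition** of structure
   pairs with iterative outlier rejection, and RMSD matrices over structure
   sets.
3. **Binding-region extraction**: all residues with a heavy atom within a
   cutoff (4 Å by default) of a bound cofactor.
4. **Ligand transfer**: mapping a cofactor from one structure into a
   homolog's frame via their superposition, to *predict* a binding region
   the homolog was never crystallized with (the route by which a putative
   UQ site in AIF is proposed).
5. **Interface detection and distance audits**, including the
   electron-tunneling criterion (inter-cofactor edge distances up to
   ~13 Å).
6. **Conservation profiling and motif detection** on an MSA, with
   taxon-stratified consensus and mapping of motif spans onto structure
   author numbering.
7. **Distance-tree clustering** of the family (AIF-like vs NDH-2/NDI-like)
   with bootstrap support.

## Models and procedures

### Superposition

Residues of the two chains are paired by Needleman–Wunsch global alignment
(BLOSUM62, gap open 10, gap extend 0.5 — the conventional protein
defaults). Fit atoms are the backbone N, CA, C, O present in both partners
(CA-only is available). The optimal rigid transform is the Kabsch
least-squares rotation, computed by SVD of the cross-covariance matrix with
the reflection corrected so the rotation determinant is +1. After each fit,
residue pairs whose backbone deviation exceeds `max(2.0, 2 × RMSD)` Å are
dropped and the fit repeated, for at most 5 cycles or until stable; this
mirrors the default refinement of the interactive superposition tools used
in practice, which the published analyses rarely parameterize. Both the
refined RMSD (retained pairs) and the all-pair RMSD are reported, because
published RMSD values for the same structure pair vary by several tenths of
an Ångström depending on unstated masks and cycles; comparisons against
published values should use a tolerance of about ±0.3 Å.

### Binding regions, transfers, interfaces, tunneling

"Within 4 Å of the cofactor" is interpreted as: any *heavy* atom of the
residue within the cutoff of any heavy atom of the ligand, whole-residue
inclusion, waters excluded, the ligand's own residue excluded. Hydrogens
are dropped on read — the crystal structures in scope do not resolve them —
so all distance work is heavy-atom by construction. Transfers reuse the
superposition transform verbatim: with the identity transform a transfer
reproduces the crystallized region exactly, which is tested. Interfaces use
the same whole-residue rule in both directions. The tunneling audit reports
the minimum heavy-atom distance between two atom sets (ligands, heme
groups, or whole chains, treated uniformly) and flags distances **up to and
including** 13 Å as within physiological electron-transfer range — the
bound is read inclusively, and the boundary case is tested.

### Conservation and motifs

Column conservation is the modal-residue fraction among non-gap entries —
deliberately simple, matching the qualitative "conserved in all sequences"
reading used in the field; an entropy score would change the ranking of
borderline columns but not the detected blocks at the default threshold. A
motif is a maximal run of at least 5 columns with conservation ≥ 0.8 and
gap fraction ≤ 0.2. These defaults were chosen once so that alignments with
the family's characteristic ten conserved blocks (two glycine-rich motifs
among them) yield exactly ten hits; no numeric criterion is published, so
the thresholds are this package's own calibration. Motif spans are mapped
to structures through each chain's author numbering, allowing a constant
offset between the MSA record and the crystallized construct; positions in
disordered (coordinate-free) segments are flagged unmapped rather than
guessed.

### Homolog filtering

Retention requires E-value **strictly below** 1e-25, query coverage
**strictly above** 70%, and identity **strictly above** 30% — the
comparative wording ("lower than", "higher than", "greater than") is
honoured literally, so records sitting exactly on a threshold are rejected,
and this boundary behaviour is tested. Deduplication removes only exact
full-length string duplicates, keeping the first-listed id.

### Trees

The family-clustering claim this package exercises is about *topology*:
AIF-homologs and NDH-2/NDI-homologs separate into two clusters. A
maximum-likelihood fit (JTT+Γ) adds branch-length realism but not
topological information at this separation, so the desk-scale pipeline uses
p-distances (optionally Poisson-corrected, `-ln(1-p)`, capped when `p = 1`)
with neighbor joining, and the same bootstrap protocol as the original
protocol: 100 column resamplings, support = fraction of replicates
containing each original bipartition. The ungapped MSA can be exported for
external ML software when exact replication is wanted. The bootstrap seed
is a required argument — there is no hidden default.

## The synthetic-data generators

Every stage is testable without downloads because the generators emit data
*with* their ground truth:

- **Toy structures** place CA atoms on an idealized helix (rise 1.5 Å,
  100° twist, radius 2.3 Å) with N/C/O at fixed local offsets and ligands
  planted at exact offsets from anchor residues, so pockets are knowable in
  closed form. They are geometrically sane (no two atoms closer than 1 Å)
  but make no physical claim — no side chains, no realistic φ/ψ.
- **Perturbed copies** carry their planted rotation/translation in an
  attribute; noise is isotropic Gaussian per coordinate; deletions are
  uniform over residues.
- **Synthetic MSAs** plant conserved blocks on a uniform background.
  Mutations are planted at an exact per-column count
  (`round(rate × n)` sequences mutated), so block conservation is exactly
  `1 - rate` up to rounding and recovery at the default thresholds is
  deterministic for rates ≤ 0.1; background gaps never fall inside blocks.
- **Hit tables** draw records on both sides of every filter threshold and
  include three exact-boundary records.

What passing these tests does *not* show: performance on real crystal
structures with alternate conformations, missing loops, or genuinely
ambiguous alignments. The reference-structure checks
(`reference_structure_checks()`) cover that ground but require the user to
download the nine reference PDB entries; they are large external database
files and are not shipped.

Two limitations surfaced by the closed loop are worth stating. First,
sequence-guided pairing degrades when too many residues are deleted at
random: at 50% scattered deletions the affine-gap alignment prefers a
compact misalignment over opening ~n/2 single-residue gaps, so transform
recovery is only guaranteed up to roughly one-third deletions (tested at
30%). This is a property of alignment-guided superposition generally, not
of this implementation. Second, between two *independently* noisy copies at
σ = 0.2 Å the expected backbone RMSD is σ√6 ≈ 0.49 Å (σ√3 ≈ 0.35 Å against
the clean original); tests assert the analytically correct band.

## Numerical and design choices

- **Alternate locations**: highest occupancy wins; ties keep the first
  conformer encountered.
- **Chain policy**: the first polymer chain is used unless overridden;
  multi-chain entries (e.g. dimers of homodimers) are flagged in reports
  via the chain id carried on every row.
- **Ligand dictionary**: FAD-like {FAD}; NAD-like {NAD, NAI, NAP, NDP};
  UQ-like {UQ1, UQ2, UQ5, UQ6, DCQ, SMA}; CoA {COA}; everything else —
  including O₂ and H₂S, which are genuine substrates here — is category
  "other". The dictionary is user-extensible through the run config, since
  trivial ligand names map inconsistently onto het codes across entries.
- **Config format**: run configs are YAML (the R ecosystem's standard
  config format with a maintained parser); a `ligands` section extends the
  dictionary.
- **Degenerate inputs**: Kabsch refuses fewer than 3 pairs or collinear
  sets; the RMSD matrix records failing pairs with reasons instead of
  aborting; the pipeline runs independent stages past a failed one and
  reports nonzero status.
- **Tie-breaks**: alignment traceback follows the pairwise aligner's
  deterministic preference; modal-residue ties resolve alphabetically and
  are flagged in taxon consensus.
- **Catalogue fixture**: the packaged 49-entry structure catalogue is
  checksummed; internal inconsistencies of the published table (alternative
  RMSD values for the three query pairs quoted elsewhere) are preserved as
  a `caption_rmsd` attribute, not corrected.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
toy structures of 30–60 residues (≤ 500 atoms, where the exhaustive
distance oracle is exact), 20-sequence × 320-column MSAs for the
ten-block recovery, 100-record hit tables, 6-taxon trees for the exhaustive
105-topology oracle, and 10-taxon alignments with 100 bootstrap replicates.
These sizes were chosen as the smallest at which every claim is
non-trivially exercised; all generators scale to larger inputs unchanged.

## A worked example

```{r example, eval = FALSE}
library(flavocompare)

# a toy structure with a planted FAD pocket, and a rigidly moved homolog
s   <- make_toy_structure(40, seed = 3, ligands = list(
         list(het_code = "FAD", anchor = 10, offset = c(4.5, 0, 0))))
hom <- perturb_structure(s, rotation_matrix(2.2, "y"), c(-8, 3, 11), seed = 1)

sup <- superpose_structures(s, hom)
sup
#> superposition toy03_pert -> toy03: rmsd_refined 0.000 A (40/40 pairs,
#> 1 cycle(s)); rmsd_all 0.000 A

# predict the pocket in `s` from the homolog's crystallized ligand
tr <- transfer_ligand(hom, s, get_ligand(hom, "FAD"))
tr$region
#> binding region of FAD in toy03 (cutoff 4.0 A, transferred): 4 residues
#>   TYR8 LEU9 SER11 ILE12
```

The transferred region reproduces the pocket planted in `s` exactly; on
real homolog pairs the same call proposes cofactor sites for structures
crystallized without the cofactor.
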