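---
title: "Binding-site profiling and profile alignment for GPCRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site profiling and profile alignment for GPCRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrprofile)
```

## The idea

G protein-coupled receptors share a conserved seven-transmembrane-helix
barrel, with the orthosteric ligand pocket sitting in the upper,
extracellular third of the bundle. Because the fold is conserved while
sequences are not, two receptors whose pockets present similar
physico-chemical surfaces to their ligands are candidates for swapping
those ligands — the basis of structure-driven drug repurposing.

`gpcrprofile` turns a ligand-bound receptor structure into seven short
integer strings, one per transmembrane helix:

1. **Binding-site detection.** Every receptor residue with at least one
   heavy atom within a cutoff (default 4.0 Å, inclusive) of any ligand
   heavy atom is a binding-site residue.
2. **Reduced-alphabet profiling.** Each residue is mapped to a small
   physico-chemical group. The 8-digit scheme (8DP) uses four groups —
   hydrophobic 0, hydrophilic 1, negatively charged 2, positively
   charged 3 — and raises the value by 4 for binding-site residues, so
   eight symbols encode both chemistry and pocket membership. The
   10-digit scheme (10DP) splits hydrophobic into aliphatic (0) and
   aromatic (1) — so π-stacking pockets are distinguishable — with
   hydrophilic 2, negative 3, positive 4 and a flag offset of 5.
3. **Topology mapping.** The profile is split by helix (TM1–TM7), from a
   user annotation file or from backbone φ/ψ dihedral detection. Loop
   residues are not profiled; the short intracellular helix 8 that some
   receptors carry is never included.
4. **Alignment and normalization.** Each helix string of the *target* is
   aligned to the corresponding helix of the *reference* (never
   cross-helix) with Smith–Waterman local dynamic programming under a
   group-level substitution matrix and a linear gap penalty. The total
   score $T$ is the sum over the seven helices; $R$ is the reference's
   self-alignment total computed the same way; the normalized score is

   $$N = T / R.$$

   $N$ is 1 for self-comparison and, because $R$ scales with the length
   and strength of the reference's own pocket strings, it corrects for
   pockets of different size. Pairs with $N$ at or above a threshold
   (default 0.5) are reported as repurposing candidates.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 4.0 Å | ligand–residue contact distance, inclusive at the boundary |
| `heavy_atoms_only` | `TRUE` | ignore hydrogens in the contact test |
| `miss` | −2 | mismatch / flag-mismatch penalty, must be ≤ 0 |
| `gap` | −2 | linear gap penalty, must be ≤ 0 |
| `flag_policy` | `"penalize"` | how flagged symbols score against unflagged ones |
| `aggregate` | `"mean"` | reduction statistic over residue pairs |
| `scope` | `"helix"` | align full helix strings or pocket positions only |
| `threshold` | 0.5 | normalized-score cut for screen hits |

The distance cutoff is **inclusive** (d ≤ cutoff): a residue at exactly
4.0 Å is part of the site. Heavy atoms only is the default because most
crystal structures have no modelled hydrogens; including them would make
results resolution-dependent. Both are configurable.

### Group membership

The scheme tables ship with defaults and are fully overridable
(`profile_scheme(groups = ...)` or a key-value config file via
`read_group_config()`):

* 8DP hydrophobic = {G, A, V, L, I, P, M, C, F, W, Y}; hydrophilic =
  {S, T, N, Q}; negative = {D, E}; positive = {K, R, H}.
* 10DP aliphatic = {G, A, V, L, I, P, M, C}; aromatic = {F, W, Y};
  the other three groups as in 8DP.

Histidine sits with the positives because it is protonatable at
physiological pH; tyrosine goes with the aromatics because the 10DP
scheme exists to emphasize π-interactions; cysteine and glycine sit with
the aliphatics for want of a better bin. These are assignments by table
at pH 7, not a protonation-state calculation. Because reasonable people
group residues differently, the tables are configuration, not code.

### Substitution models

Group-level scores are derived from a 20×20 residue matrix by averaging
the residue-level entries over all ordered pairs of the two groups
(`aggregate = "mean"`; median and min are available for sensitivity
analysis). BLOSUM62 is bundled (via Biostrings); the negative–negative
8DP entry, for example, is mean(D/D = 6, E/E = 5, D/E = 2, E/D = 2) =
3.75. Scores stay real-valued; nothing is rounded.

Mode `"gpcrtm"` applies the same reduction to a residue-level matrix
read from a file, intended for transmembrane-specific matrices derived
from class A GPCR sequences. **No such matrix is bundled**: the package
ships only a clearly-labelled synthetic stand-in
(`inst/extdata/matrices/gpcrtm_synthetic_standin.mat`, BLOSUM62 with a
+1 hydrophobic diagonal) so the code path can be exercised; supply the
real matrix file for production use. Mode `"identity"` scores `match` on
the diagonal and `miss` elsewhere; mode `"custom"` reads a group-level
matrix directly.

The interaction between the binding-site flag and the group score is not
fixed by the encoding itself, so it is a policy knob: `"penalize"` (the
default) adds `miss` to the group score when exactly one of the two
symbols is flagged, `"miss_only"` replaces the score by `miss`, and
`"ignore"` makes flags invisible to scoring.

### Alignment details

"Local" means the standard Smith–Waterman recurrence with a linear gap
penalty (a single GAP value, not affine):

$$H_{ij} = \max(0,\; H_{i-1,j-1} + s(a_i, b_j),\; H_{i-1,j} + g,\;
H_{i,j-1} + g).$$

Ties are resolved deterministically — traceback starts at the maximal
cell with the smallest row then column index and prefers diagonal over
up over left — so outputs are bit-identical across runs. A best score of
zero yields an empty alignment; local scores are never negative. A
reference whose self-alignment total is zero (possible only with
pathological all-non-positive matrices) raises an explicit error rather
than producing NaN.

Whether to align the full helix strings (`scope = "helix"`) or only the
flagged pocket positions (`scope = "pocket"`) is genuinely open: the
normalization argument about pocket volume suggests pocket-only strings,
but full-helix strings use more context. Both are implemented; the
package defaults to `"helix"` and `calibrate_config()` grid-searches the
knob (together with `flag_policy` and `aggregate`) against any set of
pairs with known published scores, should reference structures be
available.

## Helix detection

When no annotation file is given, helices are detected from backbone
dihedrals: a residue is α-helical when φ ∈ (−100°, −30°) and
ψ ∈ (−80°, −5°). Core marking requires the window to hold for residues
i−1, i, i+1 simultaneously (a three-residue consensus that suppresses
isolated torsion noise); each marked run is then extended outward over
adjacent residues whose *defined* dihedrals are in-window. The extension
step matters: dihedrals are undefined at chain termini and across
resSeq gaps, so without it every detected segment would lose residues at
both ends relative to the true helix. Runs shorter than `min_len`
(default 8) are dropped and the seven longest survivors, in sequence
order, become TM1–TM7. The dihedral windows are part of the contract and
the annotation source (`"user"`/`"detected"`) is recorded in results; a
user annotation always wins over detection. Ballesteros–Weinstein
generic numbering is out of scope.

This detector is deliberately simpler than hydrogen-bond-energy methods
(DSSP-style): for kinked real helices it may split a helix at a strong
proline kink, which is why user annotations override it.

## The synthetic fixture generator

`make_complex()` builds an idealized receptor-like bundle with recorded
ground truth, so every pipeline stage is testable without downloading
structures:

* helices are grown residue-by-residue in internal coordinates
  (N–CA–C–O backbone plus Cβ; bond lengths/angles from standard peptide
  geometry; φ = −57°, ψ = −47°, ω = 180°), so detection sees exact
  ideal dihedrals;
* the seven helices sit on a circle (default radius 13 Å) with
  alternating direction, rotated so that each planned pocket residue's
  side chain faces the bundle axis;
* consecutive helices are separated by resSeq gaps, emulating
  unmodelled loops in crystal structures;
* one ligand atom is placed exactly `contact_distance` (default 3.5 Å)
  from each planned pocket residue's Cβ, in the direction that maximizes
  clearance from all other residues; central filler atoms bring the
  ligand to ≥ 6 heavy atoms so auto-detection applies. The generator
  *verifies* by a brute-force distance scan that planned residues are in
  contact and every other residue is beyond `spacer_distance` (default
  6 Å) and refuses geometrically infeasible plans. Random sequences
  avoid glycine at planned contact positions (no Cβ anchor); everything
  is deterministic under the seed.

The defaults (7 helices × 24 residues, a five-residue pocket with two
contributions from TM3, contact 3.5 Å vs spacer 6 Å straddling the 4 Å
cutoff) emulate the geometry of a compact class A receptor pocket.

What the fixtures do **not** emulate: side-chain rotamers (Cβ proxies
only), helix kinks and irregularity, real loops, chemically sensible
ligands, crystallographic noise. Green tests on fixtures therefore
demonstrate the correctness of the bookkeeping and the algorithms —
binding-site geometry, topology mapping, encoding, alignment arithmetic
— not the biological accuracy of any particular score on real
structures.

## Numerical and degenerate-input choices

* altLoc conformers: highest occupancy wins, ties go to the
  alphabetically first identifier; insertion codes are preserved in
  residue keys.
* MSE and other common modified residues are remapped to their parent
  amino acids at parse time; unknown residue codes are an error unless
  configured.
* Waters, monatomic ions and common cryo-agents are excluded from
  ligand auto-detection via a built-in, user-extensible list; ligand
  auto-detection requires exactly one remaining heterogen with ≥ 6
  heavy atoms and errors with the candidate list otherwise.
* Receptors longer than 450 residues trigger a fusion-domain warning;
  excision is the user's job via `residue_range`.
* Custom matrices must be symmetric to 1e-9; asymmetry errors name the
  offending cell.
* The screen caches one self-alignment per complex (k, not k²) and is
  free of randomness: identical inputs and configuration give
  byte-identical outputs.

## A worked example

```{r example}
fx <- make_complex(fixture_spec(seed = 42))
pdb <- tempfile(fileext = ".pdb")
write_fixture(fx, pdb)

scheme <- profile_scheme("10DP")
prof <- profile_structure(pdb, scheme)
head(render_profile(prof), 10)

model <- substitution_model(scheme, scoring_params("blosum62"))
align_complexes(prof, prof, model)
```

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated
fixtures: bundles of 7 × 24 residues, pockets of 3–5 residues, 20–50
random complexes per property, 200 random string pairs (length ≤ 7)
against an exhaustive substring-pair alignment oracle, and a
five-complex screen with hand-computable hit structure. These sizes were
chosen so every expected value is derivable by brute force or in closed
form.

## Known limitations

* Spatial information beyond the contact list is discarded: two pockets
  can score well while their residues point in incompatible directions.
  Inspecting how the score responds to different gap penalties is a
  useful robustness check — the less it moves, the more similar the
  ligand volumes tend to be.
* The published transmembrane substitution matrix must be supplied by
  the user; scores under the synthetic stand-in are for mechanics
  testing only.
* Helix detection assumes reasonably ideal helices; use annotations for
  kinked or low-resolution structures.
* No docking, no binding free energies, no statistical significance for
  alignment scores: the normalized score ranks hypotheses, it does not
  validate them.
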