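---
title: "Methods: interaction fingerprints, pose triage and MM-PBSA bookkeeping"
author: "specsift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints, pose triage and MM-PBSA bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsift)
```

# Scope

`specsift` implements the *post-docking* stages of a protease
substrate-specificity study: given pose ensembles, docking score tables and
per-snapshot energy components produced by external engines (docking
programs, MD packages), it computes structural interaction fingerprints,
validates and triages poses, ranks substrates and performs MM-PBSA
end-state bookkeeping.  It deliberately does *not* build homology models,
run docking or MD, or solve the Poisson-Boltzmann equation; those are
upstream tools whose outputs this package consumes.

The reference system is cysteine protease 1 from *Zea mays* (zmCP1), a
papain-family (C1A) enzyme.  Its annotation ships with the package:
catalytic triad Cys149/His285/Asn306, oxyanion hole Gln143/Cys149, S1
subsite Gly147/Cys189/Asp190/Gly191, S2 subsite
Leu193/Met194/Ala259/Leu283/Ala286, nucleophile Cys149 SG.  Two S2
definitions circulate for this enzyme, with and without Ala259.  The
shipped default keeps Ala259 (the broader, five-residue set) with a comment
in the annotation file; users who prefer the narrow set edit one line.  We
do not silently resolve the discrepancy because subsite-occupancy calls can
change with membership.

# The nine-bit interaction fingerprint

For every protein residue of a complex we compute nine boolean interaction
bits, in fixed order: *any, backbone, side chain, polar, hydrophobic,
H-bond acceptor, H-bond donor, aromatic, charged*.  Averaging the bit
matrices over a population of complexes (poses x ligands x receptor
conformations) gives per-residue frequencies in [0, 1]; thresholding the
"any" frequency (default 50%) yields the consensus binding-site residues.

The geometric criteria live in `geometric_criteria()` and are deliberately
ordinary structural-biology values, since fingerprint methods are specified
by their bit semantics rather than by exact cutoffs:

| parameter | default | meaning |
|---|---|---|
| `contact_cutoff` | 4.5 A | heavy-atom contact (any/hydrophobic bits) |
| `polar_cutoff` | 4.0 A | N/O/S-N/O/S contact |
| `hbond_heavy_cutoff` | 3.5 A | donor-acceptor heavy-atom distance |
| `hbond_angle_min` | 120 deg | donor-H...acceptor angle, if H present |
| `aromatic_centroid_cutoff` | 5.0 A | ring centroid-centroid distance |
| `salt_bridge_cutoff` | 4.0 A | oppositely charged N/O pair |

Conventions that were genuinely open and that we fixed explicitly:

* **H-bond direction.**  The "H-bond donor" bit means *the protein residue
  donates*.  The opposite convention is obtained by swapping the two bit
  columns; nothing else changes.
* **Hydrogens optional.**  Docked poses usually lack hydrogens, so
  hydrogen bonds are detected distance-only in that case; when the donor
  hydrogen is present the angle test applies.  Donor/acceptor capability
  is assigned from residue templates (backbone N donates except proline,
  backbone O accepts, side chains per standard chemistry).  Thiol SG is
  typed polar but not as a hydrogen-bonding atom: thiol hydrogen bonds are
  marginal, and excluding them keeps the polar and H-bond bits separable.
* **`any` is recomputed** as the OR of plain contact and the eight
  specific bits, so the "any" frequency dominates every specific bit by
  construction.  Externally reported averaged-SIFt tables do not always
  satisfy this hierarchy (rounding, post-editing); `read_profile()`
  therefore accepts them with `n_complexes = NA` and skips the
  granularity/hierarchy checks that apply to profiles the package computes
  itself.
* **Ligand ring perception** infers bonds from covalent radii (+0.4 A
  tolerance) and accepts smallest cycles of 5-6 C/N atoms that are planar
  within 0.1 A RMS - no connectivity records required.
* **Ligand charged groups** without formal charges: nitrogens are
  positive candidates, carboxylate-like oxygens (two oxygens on one
  carbon) negative; explicit charges override.

# Pose validation and binding-mode triage

`heavy_atom_rmsd()` computes ligand heavy-atom RMSD with *no*
superposition (docked and reference poses share the receptor frame).  With
`symmetry = TRUE` it minimises over all element-preserving automorphisms
of the inferred ligand bond graph (VF2), so topologically equivalent atoms
may swap.  `classify_docking()` applies the standard redocking rule:
success iff RMSD <= 2.5 A, inclusive - the threshold is quoted as "about",
so the boundary is taken as a pass.

`select_binding_mode()` encodes three geometric rules for a catalytically
competent pose of a fluorogenic AMC substrate:

* **R1 - subsite occupancy**: at least one P1-group heavy atom within the
  occupancy cutoff (default 4.5 A) of an S1-residue heavy atom; likewise
  P2/S2 when a P2 group is declared.
* **R2 - catalytic distance**: scissile carbonyl carbon to nucleophile
  sulfur within 4.5 A.  The literature phrase "about 4 A" is
  operationalised as an inclusive <= 4.5 A gate; the accepted worked
  examples measure 4.33 A and 3.29 A, both inside.  One wording in the
  source describes this atom as "the carbon of hydroxyl group", which is
  chemically impossible for an anilide-linked AMC probe (there is no
  hydroxyl); we interpret it as the scissile amide carbonyl carbon and
  say so here rather than guessing silently.
* **R3 - oxyanion hydrogen bond**: at least one hydrogen bond (fingerprint
  criteria) between the P1 charged group and an oxyanion-hole residue.

P-group membership is declared by the user as ligand atom-name sets rather
than inferred from chemistry; the toy substrate fixtures ship with their
declarations.  Among poses passing all applicable rules the best-scoring
one is selected; score ties break to the lowest pose index (engine order),
making selection deterministic.

# MM-PBSA bookkeeping

The binding free energy of each snapshot is

$$\Delta G_\mathrm{bind} = G_\mathrm{complex} - (G_\mathrm{protein} + G_\mathrm{ligand}),
\qquad G = E_\mathrm{gas} + G_\mathrm{solv} - TS,$$

with $E_\mathrm{gas} = E_\mathrm{int} + E_\mathrm{vdW} + E_\mathrm{ele}$ and
$G_\mathrm{solv} = G_\mathrm{PB} + G_\mathrm{np}$.  The package follows the
single-trajectory protocol: complex, protein and ligand snapshots come from
the same complex trajectory, so the internal term cancels exactly
($\Delta E_\mathrm{int} \equiv 0$) - consistent with decomposition tables
that carry no internal-energy row.  The entropy term defaults to zero
(entropy neglect for chemically similar substrates); supplying a `TS`
column shifts $\Delta G_\mathrm{bind}$ by exactly $-\Delta TS$.

The two summary rows group components as *nonpolar* =
$\Delta E_\mathrm{vdW} + \Delta G_\mathrm{np}$ and *polar* =
$\Delta E_\mathrm{ele} + \Delta G_\mathrm{PB}$; we verified by independent
summation that this grouping reproduces the published zmCP1 decomposition
for both substrates exactly at two decimals:

```{r}
comp <- read.delim(system.file("extdata", "zmcp1_mmpbsa_components.tsv",
                               package = "specsift"))
decs <- lapply(seq_len(nrow(comp)), function(i)
  decompose(comp$dE_ele[i], comp$dE_vdW[i], comp$dG_PB[i], comp$dG_np[i]))
names(decs) <- comp$complex
writeLines(energy_report(decs))
```

The computed R-AMC vs D-AMC difference is 27.06 kcal/mol.  The source
narrative quotes 26.06, which is inconsistent with its own table
arithmetic; the package always prints the computed difference and leaves
the discrepancy on record rather than resolving it.  Similarly, the
snapshot count is a plain argument (`make_energy_series(n = ...)`,
`average_binding()` takes whatever series it is given) because the source
protocol is described with two different counts (1000 snapshots every 2 ps
over 2 ns, and 2000 over 4 ns) in different places.

`evaluate_components()` provides a *force-field-lite* evaluator so the full
path can run end-to-end without external engines: pairwise Coulomb
(332.0636 kcal mol^-1 A e^-2, vacuum dielectric by default, 12 A
nonbonded cutoff), Lennard-Jones with element-based parameters and
Lorentz-Berthelot mixing, Shrake-Rupley SASA (1.4 A probe, golden-spiral
sampling, gamma = 0.00542 kcal mol^-1 A^-2, beta = 0.92 kcal/mol), and a
**generalized-Born-style pairwise screening surrogate** for the polar
solvation term.  The surrogate is exactly that: it reproduces the sign and
rough magnitude of polar-solvation effects but makes no claim of agreement
with a finite-difference Poisson-Boltzmann solver.  Only the bookkeeping
identities are validated quantities; the evaluator's own numbers are
checked against closed forms (Coulomb constant, LJ zero/minimum, isolated
sphere SASA) rather than against published energies.

# Substrate ranking

Score tables follow the docking convention (kcal/mol, lower = better; a
flag flips the sign convention).  Ranking sorts ascending with
alphabetical tie-breaks, making the preference call a total order that is
invariant to row permutations and to adding a constant to all scores.  The
shipped tables reproduce the published calls: Arg preferred at P1 (best
R-AMC at -10.4, 2.1 kcal/mol ahead of F-AMC; worst D-AMC at -5.5) and
aromatic/hydrophobic residues at P2 (best F-R-AMC at -9.8).  The dipeptide
table carries 20 rows, one per amino acid at P2.

# What the synthetic data emulates - and what it does not

The generators exist so that every stage has inputs with *known ground
truth*:

* `make_planted_complex()` places residue geometric templates on an
  icosahedral shell (default radius 8 A) with one ligand partner atom (or
  ring/carboxylate unit) per planted interaction at exactly the requested
  distance/angle.  Ground truth bits are derived from the planted roles
  and geometry at construction time, never by running the detector.
  Default planted distances keep a 0.3 A guard band to every cutoff so
  recovery tests are immune to floating-point detail.  Where one planted
  geometry necessarily satisfies two criteria (a salt bridge inside the
  H-bond cutoff, stacked rings inside the contact cutoff), the truth
  records both bits.
* `make_pose_ensemble()` switches each planted interaction on with
  probability *p* per pose (off = the ligand unit translated far inside
  the pocket, out of range of everything) and appends rigidly displaced
  poses whose heavy-atom RMSD to the base pose equals the requested target
  by construction.
* `make_energy_series()` draws independent Gaussians around stated
  component means - the fluctuation model behind standard-error
  reasoning on MM-PBSA averages.
* `zmcp1_mini_pocket()` + `make_triage_pose()` build a toy active site
  carrying the real residue names and a rigid planar bicyclic AMC stand-in
  whose scissile carbon, P1 guanidinium and P2 carbons can be posed at
  controlled distances from the nucleophile, oxyanion hole and subsites.

These fixtures are geometric and statistical idealisations.  They contain
no conformational strain, no correlated noise, no solvent, no
protonation-state ambiguity, and their residue geometry is template-built
rather than force-field-refined.  Passing tests therefore demonstrate that
the *algorithms* are correct (detection, averaging, selection rules,
bookkeeping, statistics), not that the defaults are optimal for any
particular real protein-ligand system.

# Numerical choices and problem sizes

* Coordinates round-trip through PDB at 3 decimals (1e-3 A).
* Frequency-granularity checks use 1e-9; decomposition additivity 1e-9.
* Threshold comparisons are inclusive throughout ("about"/"within"
  language).
* Binomial recovery tests use a 4-sigma band, `4*sqrt(p(1-p)/n)`;
  snapshot-mean recovery uses `4*sd/sqrt(n)` with the per-snapshot sd of
  the summed components.
* Ties: score ties break alphabetically; pose-score ties break to the
  lowest index; consensus ordering is by descending frequency then
  residue number.
* Test and validation problem sizes were chosen as the smallest that
  exercise the statistics meaningfully: ensembles of 10-200 poses,
  snapshot series of 50-1000, ligands of 3-20 heavy atoms for the
  brute-force symmetry oracle (all permutations are enumerated only up to
  8 atoms).

# Known limitations

* The polar-solvation surrogate is not a PB solver; absolute
  $\Delta G_\mathrm{PB}$ values from `evaluate_components()` should not be
  compared with Amber/APBS outputs.
* Interaction detection is per-residue boolean; no pseudo-energies,
  water-mediated contacts or halogen bonds.
* Symmetry-corrected RMSD relies on distance-inferred bonds; exotic
  coordination geometries may perceive wrong graphs.
* mmCIF input, protonation assignment and structure repair are out of
  scope by design.
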