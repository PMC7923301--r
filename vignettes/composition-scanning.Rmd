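---
title: "Scanning WT/mutant compositions of a protein oligomer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning WT/mutant compositions of a protein oligomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligovar)
library(dplyr)
```

## The problem

A dominantly inherited missense variant in a homo-oligomeric protein does not
produce a single mutant species. If each protomer of a trimeric assembly
independently carries the wild-type or the variant allele's product, a
globular head samples $2^3 - 1 = 7$ non-wild-type compositions, and two
head-to-head interacting trimers sample $2^6 - 1 = 63$. The biology of a
dominant disorder lives in this mixed-state space: a single mutated protomer
per trimer is the most common species at allelic balance, so the question is
not "what does the homozygous mutant look like" but "how does damage scale
with the number of mutated protomers".

oligovar makes that state space a first-class object. It enumerates every
composition, builds the corresponding mutant structures by side-chain
replacement, scores each with a fixed-structure thermodynamic cycle, and
pools the results by mutation count into the familiar
mean ± SD per-group table. Around that core it provides the standard
supporting steps: biological-unit reconstruction from crystal symmetry
operators, head-to-head hexamer construction by rigid superposition,
structure preparation (water pruning, protonation at a target pH,
displacement-capped minimization), a finite-difference Poisson–Boltzmann
solver for surface-potential maps and isopotential meshes, and
hydrophobic/electrostatic surface-patch aggregation scoring.

## The thermodynamic cycle

For a composition $c$ of an assembly with an evaluation pairing
$(L, R)$ — a protomer against the complementary dimer for trimers, head
against head for hexamers — the apparent binding free-energy change is

$$
\Delta\Delta G_b^{app}(c) \;=\;
\big[E(\text{complex}_c) - E(L_c) - E(R_c)\big] -
\big[E(\text{complex}_{WT}) - E(L_{WT}) - E(R_{WT})\big]
$$

with every term evaluated on the complex geometry (single-structure
convention: the separated units are never re-relaxed, so no conformational
ensemble enters and the all-WT composition closes the cycle at exactly
zero). The folding analogue replaces the separated units by an
unfolded-state reference — an extended Gly-X-Gly tripeptide per mutated
residue — chosen because every energy term not local to the mutation cancels
in the mutant-minus-WT difference.

The energy function is additive,

$$
E = E_{bonded} + E_{vdW} + E_{Coulomb} + E_{GB} + E_{SASA},
$$

and each $\Delta\Delta G$ is reported with its Coulomb contribution (C), its
solvation contribution (S = generalized Born polar + surface-area nonpolar)
and the residual (bonded + van der Waals), so a pooled table mirrors the
C/S column layout used when such scans are reported for disease variants.
These are *apparent* values: comparative indices on fixed structures, not
ensemble free energies, and they should only ever be read as signs, ratios
and orderings.

## The energy model and its parameters

The package scores structures with its own coarse united-atom model,
embedded in `R/params.R`:

* **Representation.** Heavy atoms only; implicit hydrogens are folded into
  their parent heavy atom's charge and are tracked as counts during
  preparation. Backbone charges (N −0.25, CA +0.25, C +0.50, O −0.50) sum
  to zero per residue; side-chain charge sets reproduce each residue's
  formal charge at pH 7.5 and its dominant dipoles (e.g. the Gln amide
  +0.55/−0.55 pair, the Glu carboxylate −0.60/−0.60 with +0.30 on the
  carbon).
* **Bonded terms.** Harmonic bonds (k = 300 kcal mol⁻¹ Å⁻²) on template
  equilibrium lengths and harmonic angles (k = 50 kcal mol⁻¹ rad⁻²) at
  109.5°/120° by center-atom hybridization. Torsions are omitted: with
  displacement-capped refinement the structures never leave the
  neighborhood of their input geometry, and the comparative signal of a
  charge-swap scan is carried by the nonbonded terms.
* **Nonbonded terms.** Lennard-Jones by element with 1-2/1-3 exclusions;
  Coulomb with the electrostatic constant 332.0637 kcal Å mol⁻¹ e⁻²;
  solute dielectric 1.
* **Solvation.** Hawkins–Cramer–Truhlar pairwise-descreening generalized
  Born (solvent dielectric 80, intrinsic radii = vdW − 0.09 Å) with the
  Still interpolation, plus a linear SASA term
  (γ = 0.0072 kcal mol⁻¹ Å⁻², Shrake–Rupley areas with a 1.4 Å probe made
  rigid-motion invariant by evaluating in the molecule's principal-axis
  frame). For a single ion the GB term reduces analytically to the Born
  formula, which the tests exploit.
* **Minimization** runs on the vacuum MM terms (bonds, angles, LJ, Coulomb)
  with analytic gradients under L-BFGS; GB and SASA enter scoring only.
  This keeps the minimization surface smooth and cheap, and because scoring
  is always mutant-minus-WT on equally treated structures, the omission
  cancels to first order.

This model deliberately trades accuracy for openness and speed: no claim of
numerical agreement with commercial force fields is made anywhere, and all
downstream claims are sign/trend claims.

## Preparation conventions

* **Water pruning (3.5 Å rule).** A water is deleted iff every non-water
  heavy atom is farther than 3.5 Å from its oxygen — i.e. waters that touch
  only other waters (or nothing) go, waters in contact with protein stay.
  Decisions are taken on the original structure and applied simultaneously,
  which makes the rule order-independent and removes isolated water
  clusters whole.
* **Protonation at pH 7.5** is rule-based: Asp/Glu deprotonated, Lys/Arg
  protonated, Cys thiol unless its Sγ is within 2.5 Å of another Sγ
  (disulfide), His neutral with the tautomer that maximizes the count of
  geometric hydrogen-bond partners within 3.5 Å (a protonated ring nitrogen
  wants an acceptor, a bare one a donor; ties default to the Nε2-H
  tautomer). Empirical pKa-shift prediction is out of scope; a hook accepts
  externally supplied per-residue pKa values.
* **The 0.3 Å cap.** "Minimize until the heavy-atom RMSD reaches 0.3 Å" is
  read as a displacement *cap*: minimization proceeds only while the
  heavy-atom RMSD from the crystal coordinates stays within 0.3 Å, and the
  last in-cap iterate is kept (chunks that overshoot are re-run shorter, so
  the cap is never exceeded by more than one step). The alternative
  reading — minimize until at least that much displacement — rewards drift
  away from the experimental structure and was rejected.

## Mutagenesis conventions

Side chains are replaced on a fixed backbone. The mutant side chain is grown
by internal-coordinate construction (NeRF) from an embedded
backbone-independent rotamer library of canonical chi values with coarse
frequencies; the most probable rotamer that places no heavy atom closer than
0.7 × the summed vdW radii of any environment atom wins, with ties broken by
lower clash score and then lexicographic chi order. Rotamers for all flagged
protomers are decided against the shared context (all flagged side chains
removed) and applied simultaneously, so exactly symmetric environments
provably receive identical rotamers. Optional local relaxation
(`relax_environment()`) minimizes side chains within a configurable radius
(default 5 Å) of the mutated site under the displacement cap. The default
pipeline scores unrelaxed mutants: on the synthetic fixtures the clash-free
rotamer placement is already strain-free, relaxation adds minutes per scan,
and the pooled trends are unchanged — a run can opt in with
`scan = list(relax = TRUE)`.

## What the synthetic fixtures emulate

`make_c3_trimer()` builds three identical ideal poly-Ala helices (12
residues by default, with a leucine two positions downstream of the plant as
a zipper-like apolar neighbor) arranged with exact C3 symmetry, one
glutamine side chain per protomer pointing at the three-fold axis. The
default packing radius of 5.8 Å puts the planted glutamines in genuine
van-der-Waals contact across the interface (closest inter-protomer distance
≈ 3.4 Å), so a Q→E charge swap buries like charges against each other — the
geometry that forces a positive, mutation-count-monotone destabilization.
The `"surface"` orientation is the matched control: the identical protomer
with the planted side chain pointing into solvent. Seeded chi-angle jitter
(σ = 4°) on non-planted side chains makes each seed a distinct but
reproducible fixture; the same seed yields byte-identical PDB output.

What the fixtures do **not** emulate: a real β-sandwich fold, intramolecular
burial of the mutation site in the monomer, crystallographic waters, or the
size of a real gC1q domain. Passing trend tests on these fixtures therefore
demonstrates that the machinery orders geometrically forced cases correctly
— not that the force field reproduces any particular experimental or
published ΔΔG value. On an isolated fixture protomer the planted residue is
fully solvent-exposed, so its single-protomer folding ΔΔG is legitimately
near zero, unlike a real protein where the site is partly buried
intramolecularly.

## Electrostatics

The linearized Poisson–Boltzmann equation is solved at zero ionic strength
by finite differences: two-dielectric map (solute 1, solvent 80; cavity =
union of atom spheres, optionally probe-inflated), trilinear charge
spreading, Dirichlet boundary from the Coulomb far field in solvent,
red-black successive over-relaxation (ω = 1.9) until the largest node
update falls below the tolerance. Grid spacing defaults to 0.8 Å with a 5 Å
extension; potentials are reported in kT/e at 298 K (25.693 mV). Solvation
energies come from the two-solve difference (uniform solute-dielectric
reference on the same grid), which cancels the grid self-energy — the
Born-ion test holds to ~2% at 0.35 Å spacing. Molecular-surface maps use a
probe-rolled union-of-spheres surface (exact for isolated spheres, a smooth
approximation of the reentrant surface elsewhere) triangulated by marching
tetrahedra, with raw per-vertex potentials retained and a clamped copy on
the −0.3 … +0.3 kT/e rendering scale; isopotential meshes default to
±10 kT/e.

## Aggregation scoring

Exposed atoms (per-atom SASA > 0.1 Å²) are classified as hydrophobic
(apolar C/S, |q| < 0.25 e) or electrostatic (|q| ≥ 0.25 e) and clustered
into connected patches (5 Å cutoff, ≥ 3 atoms). A residue's score is its own
exposed area inside hydrophobic patches plus 0.3 × the rest of each such
patch, minus 0.5 × the same quantity over electrostatic patches; residues
below 5% relative SASA are flagged buried and excluded from the ranking.
The weights are transparent and configurable; the proprietary index this
stands in for is not reproduced numerically, so the meaningful output is the
*ranking* (planted apolar plateaus occupy the top ranks; burying a residue
in a complex can only lower its score).

## A worked run

```{r run, eval = FALSE}
run <- run_scan_pipeline(run_config(seed = 1))
run$pooled$trimer |>
  select(n_mut, n, ddg_b_app_mean, ddg_b_app_sd, ddg_f_app_mean, ddg_f_app_sd)
```

At seed 1 the pooled trimer table reads (kcal/mol, mean over the 9/9/3
protomer-vs-rest records per group):

| n_mut | n | ΔΔG_b | ΔΔG_f |
|------:|--:|------:|------:|
| 1 | 9 | 0.50 | 0.65 |
| 2 | 9 | 2.13 | 2.64 |
| 3 | 3 | 4.39 | 5.57 |

both columns positive and strictly increasing with mutation count, the
signature of a dominant interface-destabilizing charge swap. The identical
substitution at the surface-control site gives |ΔΔG_f| several-fold smaller.
These numbers are fixture-scale: a 12-residue helix mimic with a coarse
force field produces kcal-scale apparent values, roughly an order of
magnitude below what a full gC1q trimer yields in published scans — the
ordering, not the magnitude, is the tested claim.

## Numerical choices and degenerate inputs

* Pooled SD is the sample SD (n−1); an n = 1 group (e.g. the all-mutant
  hexamer) reports its SD as absent, not zero.
* Scan records re-use one mutated structure per composition across its
  three pairings (cheaper; pairings differ only in the partition, not the
  structure).
* Deterministic tie-breaks everywhere: rotamers by probability, then clash,
  then chi order; rankings by score, then chain, then residue number;
  composition order is lexicographic in the flags.
* `symmetry_reduce()` is an opt-in accelerator (energies are computed per
  composition by default, mirroring exhaustive residue scanning); its
  orbit multiplicities are checked against full enumeration.
* Degenerate cases: a zero displacement cap returns input coordinates
  unchanged; an all-WT composition scores exactly zero by construction; an
  isopotential level outside the grid range yields an empty mesh with a
  warning; coincident point charges raise a singularity error; a template
  placing two trimers on top of each other is rejected as a clash.
* Problem sizes used by the test-suite and acceptance runs: 12-residue
  protomers (201-atom trimers, 402-atom hexamers), PB grids of ≤ 60³ nodes
  at 0.25–0.5 Å spacing for analytic checks. A trimer scan takes seconds,
  a hexamer scan about a minute and a half on one core.

## Known limitations

No torsional terms or 1-4 scaling; no explicit hydrogens; no conformational
sampling or entropy; single-structure MM/GBSA only; rule-based protonation
(no pKa shifts); the molecular surface approximates reentrant geometry; PDB
input only (no mmCIF); glycans, ligands, alternate locations and NMR
multi-model files are out of scope. The hexamer's trimer–trimer interface in
the synthetic fixture is backbone-dominated, so its Coulomb/solvation split
does not mirror what a charge-dense real interface produces — sign-pattern
claims about real structures require the real structures.
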