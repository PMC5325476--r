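---
title: "Methods: peptide design filters, interface energetics and trajectory observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide design filters, interface energetics and trajectory observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepforge)
```

pepforge implements the computational core of a structure-guided peptide
antagonist design workflow: short peptides (the bundled examples are
11-mers derived from the second cysteine-rich domain of Dickkopf-3,
aimed at the Wnt-binding face of the LRP6 co-receptor) are iteratively
mutated, scored against a binding model, filtered on physicochemical
criteria, and finally characterized structurally and dynamically. This
vignette documents the models, their parameters, the numerical choices,
and what the synthetic test fixtures do and do not demonstrate.

## Sequence-level design filters

Every candidate peptide is screened with the standard desk calculators:

* **GRAVY** — the arithmetic mean of Kyte–Doolittle hydropathy values.
  Positive means hydrophobic. It is exactly linear in composition, so
  the GRAVY of a concatenation is the length-weighted mean of its
  parts; the tests exploit this as an invariant.
* **Instability index** — the dipeptide-weight statistic
  $II = (10/L)\sum_{i=1}^{L-1} \mathrm{DIWV}(x_i, x_{i+1})$, with the
  $<40$ rule for the "stable in vitro" call. The bundled 400-entry
  DIWV table follows the variant used by the ProtParam web service,
  which differs from the originally published table in the K→Q entry
  (24.68 rather than 24.64; 24.68 recurs ten times elsewhere in the
  table, 24.64 only once). Only the server variant reproduces the
  printed instability index of the bundled reference peptide
  WQKGKQGALDR (0.61); all other eight reference values are identical
  under either variant.
* **Net charge** — a Henderson–Hasselbalch sum: each basic group
  (Arg, Lys, His, N-terminus) contributes $1/(1+10^{pH-pK_a})$, each
  acidic group (Asp, Glu, Cys, Tyr, C-terminus) contributes
  $-1/(1+10^{pK_a-pH})$. The default pKa set (N-term 9.0, C-term 3.1,
  D 3.65, E 4.25, C 8.3, Y 10.1, H 6.0, K 10.5, R 12.0) was chosen
  because it reproduces all nine bundled reference net charges after
  one-decimal rounding; published pKa sets differ by a few tenths of a
  unit and the set is swappable (`defaultPKaSet()` documents the
  format). Note that with these terminal pKa values a peptide with no
  ionizable side chains (e.g. GGG) carries a *slightly negative* net
  charge at pH 7 (−0.0098): the two terminal terms nearly cancel.
* **Isoelectric point** — the unique zero of the charge curve (net
  charge is strictly decreasing in pH), found by bisection on (0, 14)
  to 10⁻³ pH units. If the charge does not change sign on the interval
  the pI is reported as undefined (`NA`), never extrapolated.
* **Aliphatic index** and **molecular weight** follow their usual
  closed forms (average residue masses plus one water).
* **Aggregation hot spots** — a sliding five-residue window over an
  a3v-style per-residue aggregation propensity scale; a hot spot is a
  maximal run of at least five positions above the threshold (default:
  the scale average) containing no proline. Hot-spot calls are
  scale-dependent, flagged as such in reports, and tested only against
  planted constructs built from the bundled scale itself.
* **Solubility** — closed-source solubility predictors cannot be
  reproduced, so the package ships an explicit, versioned heuristic
  (`charged-fraction-v1`): *Good* iff the charged-residue fraction
  (D/E/K/R/H) is ≥ 0.25, or |net charge at pH 7| ≥ 1 with negative
  GRAVY. It reproduces most but not all of the bundled reference
  calls (the reference peptide CQRGFWGAVRC is called Good here but
  Poor by the original closed-source tool); the rule is configurable
  and its version is recorded in every record.

## The design loop

`designRun()` implements affinity maturation as scan → recombine →
filter → rank:

1. **Substitution scan.** Every non-frozen position is substituted
   with every residue whose BLOSUM62 score against the original is
   above the exclusion threshold. The default threshold "omit scores
   of −4" is implemented as *scores ≤ −4*; since −4 is the BLOSUM62
   minimum the two readings coincide, and the threshold is
   configurable for other matrices. Frozen positions model
   receptor-contacting residues that must not change; the default is
   none, since the key positions are a property of the target, not of
   the algorithm.
2. **Classification.** With lower score meaning stronger binding, a
   substitution is *favorable* when Δscore ≤ −band, *unfavorable* when
   Δscore ≥ +band, *neutral* otherwise. The default band of 100 is in
   the units of the docking-style scorer the workflow was designed
   around; the band always applies in whatever units the active scorer
   declares. A scorer failure on one variant marks that outcome
   `failed` and the scan continues.
3. **Recombination.** All combinations of favorable substitutions
   (keep-or-substitute per position) are enumerated — exactly
   $\prod_i(1+k_i)-1$ candidates — and *re-scored individually*;
   additivity is never assumed at selection time. When the product
   exceeds `maxCandidates` the space is sampled uniformly with the
   run's seed and the shortfall is logged. On additive landscapes the
   loop provably returns the exhaustive optimum (tested against brute
   force); under sign epistasis it may be suboptimal because only
   single-point-favorable moves are recombined — the tests assert it
   never *beats* the exhaustive optimum, and the limitation is
   inherent to the published procedure, not an implementation choice.
4. **Filtering and ranking.** Default filters: instability < 40, net
   charge at pH 7 > 0, solubility Good, no aggregation hot spot (the
   positive-charge and hydrophilicity emphasis reflects the negatively
   charged receptor cavity the peptides target). Survivors are ranked
   by score; ties break by higher net charge, then lower instability,
   then lexicographic sequence, making the ranking total and
   reproducible. Per-filter attrition counts are always reported.

The scorer is a pluggable contract (sequence → finite scalar, lower =
better). Docking is out of scope: `additiveLandscapeScorer()` provides
a transparent test landscape, and `interfaceScorer()` adapts the
interface energy model to score externally supplied poses.

## Interface energetics

* **Interfacial contacts.** A residue pair across the interface is a
  contact iff *any* heavy-atom pair is within 5.5 Å; each residue pair
  counts once (the single-digit class-pair counts of published
  interface tables match residue-pair, not atom-pair, granularity).
  Residues partition into charged {D,E,K,R,H}, polar {N,Q,S,T,Y} and
  apolar (the rest), the convention of contact-based binding-affinity
  models. The implementation is vectorised but asserted identical to
  an O(n²) brute-force oracle on every fixture.
* **SASA.** Shrake–Rupley sphere sampling with a deterministic
  golden-spiral point set (default 960 points per atom, probe 1.4 Å).
  Determinism makes reports byte-reproducible; accuracy is checked
  against closed forms (isolated sphere < 1% error; two-sphere
  spherical-cap geometry < 2%) and a doubling of the point count
  changes fixture totals by < 0.5%.
* **Non-interacting surface (NIS).** Residues with relative SASA
  ≥ 5% (absolute SASA over a Tien-style per-residue maximum) that are
  in no contact pair; the composition is the percentage of NIS
  residues per polarity class. An all-interface complex yields an
  explicit empty-NIS state rather than NaN percentages.
* **Binding free energy.** The linear interfacial-contact model
  $$\Delta G = -0.09459\,IC_{cc} - 0.10007\,IC_{ca} + 0.19577\,IC_{pp}
  - 0.22671\,IC_{pa} + 0.18681\,\%NIS_{ap} + 0.3810\,\%NIS_{ch} - 15.9433$$
  in kcal/mol, with the charged/polar and apolar/apolar counts carried
  but unweighted. Two coefficient sets are provided: `"printed"` (the
  default, as above) and `"alternate"`, which uses 0.13810 for the
  %NIS-charged weight as in the original contacts-based model this
  equation derives from — the two published values disagree and
  neither can be arbitrated without the underlying structures, so both
  are implemented and the choice is recorded in the result. Evaluating
  the printed equation on the bundled reference contact/surface inputs
  of peptide CQRGVWARVRC gives −0.768 kcal/mol, far from that
  complex's published −8.0 kcal/mol; the published ΔG row was
  evidently produced by a server run on full (undeposited) structures,
  so the package asserts the linear form itself, never that row.
* **Kd.** $K_d = \exp(\Delta G / RT)$ with
  $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and default
  $T = 298.15$ K (the temperature is not stated with the published
  values; 25 °C is the convention of the model's server
  implementation). The conversion round-trips to 10⁻¹² relative.
* **Hydrogen bonds.** Donor–acceptor (N/O) distance ≤ 3.5 Å and, when
  explicit hydrogens are present, minimum H–donor–acceptor angle
  ≤ 30°. Without hydrogens the detector degrades to the distance
  criterion alone and says so — typical for heavy-atom-only models.
* **Simplified non-bonded energies.** Inter-molecular Coulomb
  ($k_e q_iq_j/\varepsilon_r r_{ij}$, $k_e = 332.06$ kcal Å mol⁻¹ e⁻²)
  and Lennard-Jones 12-6 with Lorentz–Berthelot combination, summed
  over *all* cross pairs with no distance cutoff, plus the additive
  identity $E_{MM} = E_{internal} + E_{elec} + E_{VdW}$ with
  $E_{internal} = 0$ for rigid species. The bundled per-element LJ
  parameters are generic placeholders sufficient for the additive
  bookkeeping — this is explicitly not a force field.

## Trajectory observables

Multi-model PDB is the native trajectory format (text, desk-scale,
dependency-free); times are reconstructed from a user-stated time step
because the format stores none. Coordinates are Å internally; reports
use nm and nm² as is conventional for MD observables. "Backbone" means
N, CA, C, O.

* **RMSD** — per-frame least-squares optimal superposition (Kabsch via
  SVD with the determinant sign correction, so the rotation is always
  proper) against a reference frame.
* **Rg** — mass-weighted by default, from element masses.
* **RMSF** — per-atom fluctuation about the *windowed mean structure*
  after superposing every window frame onto the first window frame
  (removing rigid-body motion), aggregated to per-residue means. The
  fitting group equals the profile selection by default and is
  configurable, since published per-residue fluctuation plots rarely
  state their fitting group.
* **Snapshot extraction** — `count` frames at a fixed interval ending
  at the final frame (the default 31 × 100 ps covers a 3 ns tail).
  Targets that fall between frames map to the nearest frame and the
  maximum time error is reported.

## Synthetic fixtures: what passing tests show

The generators plant known ground truth: two-chain complexes whose
contact counts, residue classes and non-interface composition are
exact by construction, and trajectories whose per-residue fluctuation
amplitudes $\sigma_i$ imply an expected RMSF of $\sigma_i\sqrt{3}$.
They use simplified residues — one heavy pseudo-atom per residue with
a correct residue *name* — because contact, class, SASA and H-bond
logic depends only on names, elements, radii and coordinates.

Passing these tests therefore shows the *algorithms* are correct
against their definitions; it does not validate the models against
real complexes. Real interfaces have packed, chemically detailed
residues, correlated motions, and anharmonic fluctuations that
independent isotropic Gaussians do not emulate; the planted complexes
also make "interface" and "surface" unambiguous, which real structures
do not. Problem sizes in the test suite (100 planted complexes for the
contact oracle, 2000 frames for RMSF recovery within 5%, exhaustive
design search over three free positions) were chosen as the smallest
sizes at which the stochastic checks are sharp.

## Degenerate inputs and numerical conventions

Empty chain selections, atoms without radii or charges, windows
outside a trajectory, divergent frame topologies and non-canonical
residues are rejected with messages naming the offender. The empty-NIS
state and the undefined-pI state are explicit values, not errors.
Internal computation keeps full precision; report formatting mirrors
the conventional table layouts (3 decimals GRAVY, 2 instability, 1 net
charge). Report headers embed the configuration hash and seed, and all
randomness flows from a single seed, so identical inputs give
byte-identical report bundles.

## Known limitations

* Docking, flexible-backbone tolerance sampling, Poisson–Boltzmann
  solvation and MD production are out of scope; the package consumes
  their outputs (seed sequences, poses, trajectories).
* The solubility heuristic and aggregation scale are transparent
  substitutes for closed-source tools and will not reproduce every
  published call.
* The recombination step explores only combinations of individually
  favorable substitutions, as in the workflow it implements; epistatic
  optima outside that space are not found.
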