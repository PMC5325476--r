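# pepforge

Structure-guided design of short peptide binders, in R. The package is
aimed at computational structural biologists who design receptor-blocking
peptides (the bundled examples are 11-mers targeting the Wnt-binding
face of the LRP6 co-receptor) and need the desk-scale computational
core of that workflow to be reproducible and testable:

* **Sequence filters** — GRAVY, instability index (ProtParam-compatible
  DIWV table), Henderson–Hasselbalch net charge and pI, aliphatic
  index, molecular weight, aggregation hot spots, and an explicit,
  versioned solubility heuristic.
* **Design loop** — BLOSUM62-constrained single-position substitution
  scanning against a pluggable binding scorer (lower = better), a
  neutral band for classifying substitutions, exhaustive recombination
  of favorable substitutions with re-scoring, and multi-criteria
  filtering/ranking.
* **Interface energetics** — interfacial contacts at a 5.5 Å
  heavy-atom cutoff classified by residue polarity, Shrake–Rupley SASA
  with a deterministic point set, non-interacting surface composition,
  the linear interfacial-contact binding free energy model, Kd
  conversion, geometric H-bond detection, and simplified Coulomb /
  Lennard-Jones cross-pair energies.
* **Trajectory observables** — RMSD (Kabsch), radius of gyration,
  per-residue RMSF, SASA and H-bond series over multi-model PDB
  trajectories, and equally spaced snapshot extraction.
* **Synthetic fixtures** — seeded generators of planted complexes and
  trajectories with known ground truth, so every stage is testable
  without downloads.

The central model is the interfacial-contact / non-interacting-surface
binding free energy (kcal/mol):

```
ΔG = −0.09459 IC_cc − 0.10007 IC_ca + 0.19577 IC_pp − 0.22671 IC_pa
     + 0.18681 %NIS_apolar + 0.3810 %NIS_charged − 15.9433
Kd  = exp(ΔG / RT),  R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹,  T = 298.15 K
```

where `IC_xy` counts residue pairs of polarity classes x/y (charged,
polar, apolar) with any heavy-atom pair within 5.5 Å, and `%NIS_*` is
the polarity composition of solvent-exposed residues outside the
interface (relative SASA ≥ 5%). See the methods vignette
(`vignettes/pepforge-methods.Rmd`) for every model, parameter and
numerical choice, including the alternate %NIS-charged coefficient set.

## Worked example

```r
library(pepforge)

## sequence filters on one of the bundled reference peptides
rec <- peptideProperties("WQKGKQGALDR", id = "PEP-II2")
rec$gravy              # -1.718182   (hydrophilic)
rec$instability_index  # 0.6090909   (< 40: stable)
rec$net_charge         # 1.990029    (prints as 2.0 at 1 decimal)
rec$solubility         # "Good"

## interface energetics from that complex's published contact counts
e <- deltaGInteraction(c(cc = 5, cp = 7, ca = 15, pp = 1, pa = 6, aa = 18),
                       c(charged = 30.32, apolar = 33.84))
e
#> dG_interaction = -1.2082 kcal/mol (printed coefficients); Kd = 0.13 M at 298.15 K
```

The negative GRAVY, sub-40 instability index and +2 net charge are the
design criteria the loop filters on (hydrophilic, stable, positively
charged binders for a negatively charged receptor cavity). The ΔG value
is the linear model evaluated on the stated counts alone — on published
reference complexes it does not reproduce server-computed ΔG values,
which used the full (undeposited) structures; the model here is asserted
against hand arithmetic, not against that row (methods vignette,
"Binding free energy").

A full pipeline run, from files to reports:

```r
writeFixtures("fx", seed = 1)
cfg <- runConfig(stages = c("props", "interface"),
                 complexPdb = "fx/planted_complex.pdb", outdir = "out")
runPipeline(cfg)   # writes out/properties.tsv, out/energetics.tsv
```

or from a shell, `Rscript inst/scripts/pepforge.R run --stages
props,interface --complex fx/planted_complex.pdb --outdir out`.

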