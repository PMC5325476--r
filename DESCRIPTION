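Package: pepforge
Title: Structure-Guided Peptide Antagonist Design and Interface Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rational design of short peptide binders against
    protein receptors: sequence-level physicochemical filters (GRAVY,
    instability index, net charge, isoelectric point, aliphatic index,
    aggregation hot spots), a BLOSUM62-constrained substitution-scanning
    and recombination loop against a pluggable binding scorer,
    contact-classified interface energetics (interfacial contacts at a
    heavy-atom cutoff, Shrake-Rupley solvent accessibility, non-interacting
    surface composition, a linear interfacial-contact binding free energy
    model with Kd conversion, hydrogen-bond detection, simplified
    Coulomb/Lennard-Jones terms), and trajectory observables (RMSD, radius
    of gyration, RMSF, SASA and H-bond series) over multi-model PDB files.
    Includes seeded synthetic-structure generators so every stage is
    testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, bio3d, jsonlite
Suggests: testthat (>= 3.0.0), Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
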