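# Seeded synthetic-structure generators: planted two-chain complexes
# with known interfacial-contact counts and non-interface surface
# composition, synthetic trajectories with planted per-residue
# fluctuation amplitudes, and minimal geometries for closed-form SASA
# and H-bond oracles. Every generator is deterministic under its seed
# and emits models that round-trip through the PDB writer/reader.

# Representative residue names per polarity class for simplified
# single-atom residues (element C so radii/SASA are uniform).
.CLASS_RESNAMES <- list(charged = c("ARG", "ASP", "LYS", "GLU", "HIS"),
                        polar = c("SER", "ASN", "GLN", "THR", "TYR"),
                        apolar = c("LEU", "ALA", "VAL", "ILE", "PHE"))

.local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification for a planted two-chain complex
#'
#' @param icCounts Named integer vector of target contact counts over
#'   class pairs cc, cp, ca, pp, pa, aa (missing keys = 0).
#' @param nisCounts Named integer vector (`charged`, `polar`,
#'   `apolar`) of non-interface surface residues to plant on the
#'   receptor chain.
#' @param contactDistance Heavy-atom distance given to each planted
#'   contact pair, Angstrom; must be below the 5.5 A contact rule.
#' @param spacing Grid spacing separating planted units, Angstrom;
#'   must be comfortably above the contact cutoff.
#' @param seed RNG seed for the (small) coordinate jitter.
#' @return Object of class `plantedComplexSpec`.
#' @export
plantedComplexSpec <- function(icCounts, nisCounts = c(charged = 0, polar = 0, apolar = 0),
                               contactDistance = 5.0, spacing = 30, seed = 1L) {
  counts <- stats::setNames(integer(length(.IC_KEYS)), .IC_KEYS)
  if (length(icCounts)) {
    bad <- setdiff(names(icCounts), .IC_KEYS)
    if (length(bad)) stop("unknown class-pair key(s): ", paste(bad, collapse = ", "))
    counts[names(icCounts)] <- as.integer(icCounts)
  }
  if (any(counts < 0) || any(nisCounts < 0)) stop("counts must be non-negative")
  if (contactDistance >= 5.5) stop("contactDistance must satisfy the 5.5 A contact rule")
  if (spacing < 2 * 5.5 + contactDistance) stop("spacing too small: planted units would cross-talk")
  structure(list(icCounts = counts, nisCounts = nisCounts,
                 contactDistance = contactDistance, spacing = spacing,
                 seed = as.integer(seed)),
            class = "plantedComplexSpec")
}

# Class pair key -> the two classes it joins.
.split_pair <- function(key) {
  abbr <- c(c = "charged", p = "polar", a = "apolar")
  c(abbr[[substr(key, 1, 1)]], abbr[[substr(key, 2, 2)]])
}

#' Build a planted two-chain complex
#'
#' Places simplified single-heavy-atom residues on a coarse grid:
#' each target contact is a chain A / chain B residue pair at the
#' spec's contact distance, isolated from every other unit by the grid
#' spacing, so the brute-force contact counts equal the spec exactly.
#' Extra receptor-chain residues of stated classes are planted far
#' from chain A as the non-interface surface set.
#'
#' @param spec A `plantedComplexSpec`.
#' @return A `StructureModel` with chains "A" (ligand) and "B"
#'   (receptor).
#' @export
makePlantedComplex <- function(spec) {
  stopifnot(inherits(spec, "plantedComplexSpec"))
  .local_seed(spec$seed, {
    rows <- list()
    unit <- 0L
    addAtom <- function(chain, resno, resname, pos) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resno = resno, resname = resname, atom = "CA",
        element = "C", x = pos[1], y = pos[2], z = pos[3],
        stringsAsFactors = FALSE)
    }
    gridPos <- function(k) {
      # 10 x 10 x inf grid, spacing apart
      c((k %% 10) * spec$spacing, ((k %/% 10) %% 10) * spec$spacing,
        (k %/% 100) * spec$spacing)
    }
    resA <- 0L; resB <- 0L
    pickName <- function(class, i) {
      pool <- .CLASS_RESNAMES[[class]]
      pool[(i - 1L) %% length(pool) + 1L]
    }
    for (key in .IC_KEYS) {
      cls <- .split_pair(key)
      k <- spec$icCounts[[key]]
      if (k == 0) next
      for (i in seq_len(k)) {
        base <- gridPos(unit); unit <- unit + 1L
        dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        resA <- resA + 1L; resB <- resB + 1L
        addAtom("A", resA, pickName(cls[1], resA), base)
        addAtom("B", resB, pickName(cls[2], resB), base + spec$contactDistance * dirv)
      }
    }
    # non-interface surface residues: far slab of the receptor chain
    for (class in names(spec$nisCounts)) {
      k <- spec$nisCounts[[class]]
      for (i in seq_len(k)) {
        base <- gridPos(unit) + c(0, 0, 1000)
        unit <- unit + 1L
        resB <- resB + 1L
        addAtom("B", resB, pickName(class, resB), base)
      }
    }
    if (!length(rows)) stop("unrealizable spec: no residues requested")
    if (resA == 0L) {
      # contact-free spec still needs two chains for interface operations
      addAtom("A", 1L, "GLY", c(-1000, -1000, -1000))
    }
    structureModel(do.call(rbind, rows), modelId = "planted-complex")
  })
}

#' Specification for a synthetic trajectory
#'
#' @param base A `StructureModel`; frame coordinates fluctuate about
#'   it.
#' @param sigma Per-residue isotropic Gaussian displacement amplitude
#'   in nm (recycled over residues of `base`); expected recovered RMSF
#'   is sigma * sqrt(3).
#' @param drift Optional rigid-body drift velocity, Angstrom per
#'   frame (length-3).
#' @param nFrames Number of frames.
#' @param dt Time step in ps.
#' @param seed RNG seed.
#' @return Object of class `syntheticTrajectorySpec`.
#' @export
syntheticTrajectorySpec <- function(base, sigma, drift = c(0, 0, 0),
                                    nFrames = 100L, dt = 1, seed = 1L) {
  nres <- nrow(residueTable(base))
  sigma <- rep_len(sigma, nres)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(base = base, sigma = sigma, drift = drift,
                 nFrames = as.integer(nFrames), dt = dt,
                 seed = as.integer(seed)),
            class = "syntheticTrajectorySpec")
}

#' Build a synthetic trajectory with planted fluctuations
#'
#' Frames are the base coordinates plus independent per-residue
#' isotropic Gaussian displacements of amplitude sigma_i (applied to
#' every atom of residue i), plus optional rigid drift. The expected
#' RMSF profile is sigma_i * sqrt(3).
#'
#' @param spec A `syntheticTrajectorySpec`.
#' @return A `Trajectory`.
#' @export
makeSyntheticTrajectory <- function(spec) {
  stopifnot(inherits(spec, "syntheticTrajectorySpec"))
  .local_seed(spec$seed, {
    base <- coords(spec$base)
    a <- atoms(spec$base)
    reskey <- paste(a$chain, a$resno)
    resIdx <- match(reskey, unique(reskey))
    sigmaA <- spec$sigma[resIdx] * 10  # nm -> Angstrom
    frames <- lapply(seq_len(spec$nFrames), function(k) {
      disp <- matrix(stats::rnorm(length(spec$sigma) * 3), ncol = 3) * spec$sigma * 10
      base + disp[resIdx, , drop = FALSE] +
        matrix(spec$drift * (k - 1), nrow = nrow(base), ncol = 3, byrow = TRUE)
    })
    trajectory(spec$base, frames, dt = spec$dt)
  })
}

#' Sphere-cluster model for closed-form SASA oracles
#'
#' @param radii Per-atom van der Waals radii (Angstrom).
#' @param centers n x 3 matrix of centres.
#' @param elements Element symbols (default "C"; radii are taken from
#'   `radii`, not the element table).
#' @return A single-chain `StructureModel`, one residue per atom.
#' @export
makeSphereCluster <- function(radii, centers, elements = "C") {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  elements <- rep_len(elements, n)
  radii <- rep_len(radii, n)
  structureModel(data.frame(
    chain = "A", resno = seq_len(n), resname = "ALA", atom = "CA",
    element = elements, x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radii, stringsAsFactors = FALSE), modelId = "sphere-cluster")
}

#' Minimal donor/hydrogen/acceptor geometry for H-bond oracles
#'
#' Chain A holds a donor nitrogen with one hydrogen; chain B an
#' acceptor oxygen at the stated donor-acceptor distance, with the
#' hydrogen placed so the H-donor-acceptor angle equals `angle`.
#'
#' @param distance Donor-acceptor distance, Angstrom.
#' @param angle H-donor-acceptor angle, degrees.
#' @param withHydrogen Include the explicit hydrogen (default TRUE).
#' @return A two-chain `StructureModel`.
#' @export
makeHBondGeometry <- function(distance, angle = 0, withHydrogen = TRUE) {
  th <- angle * pi / 180
  rows <- data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), resname = c("ASN", "SER"),
    atom = c("ND2", "OG"), element = c("N", "O"),
    x = c(0, distance), y = c(0, 0), z = c(0, 0),
    stringsAsFactors = FALSE)
  if (withHydrogen) {
    rows <- rbind(rows, data.frame(
      chain = "A", resno = 1L, resname = "ASN", atom = "HD2", element = "H",
      x = cos(th), y = sin(th), z = 0, stringsAsFactors = FALSE))
  }
  structureModel(rows, modelId = "hbond-geometry")
}

#' Reference peptide fixture table
#'
#' The nine bundled 11-mer peptides (two initial box sequences and
#' seven optimized candidates) with their published physicochemical
#' properties and docking scores, used as golden values in tests.
#'
#' @param name Optional peptide name to look up a single row.
#' @return data.frame of 9 rows (or 1 row when `name` is given).
#' @export
paperPeptides <- function(name = NULL) {
  tab <- .cached_table("table1", function() .read_tsv(.extdata("table1_peptides.tsv")))
  if (!is.null(name)) {
    i <- match(name, tab$name)
    if (is.na(i)) stop("unknown peptide: ", name)
    return(tab[i, , drop = FALSE])
  }
  tab
}

#' Reference interface-energetics fixture table
#'
#' Published interfacial-contact counts, non-interacting-surface
#' percentages, dG and Kd for the seven optimized peptides in complex
#' with their receptor.
#'
#' @return data.frame, one row per quantity, one column per peptide.
#' @export
paperEnergetics <- function() {
  .cached_table("table2", function() .read_tsv(.extdata("table2_energetics.tsv")))
}

#' Write a fixture set to a directory
#'
#' Emits the bundled peptide FASTA, a planted complex PDB, a synthetic
#' trajectory multi-model PDB, and the reference tables as TSV, so
#' every pipeline stage can be exercised from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the synthetic structures.
#' @return Invisible character vector of written paths.
#' @export
writeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tab <- paperPeptides()
  fasta <- file.path(dir, "peptides.fasta")
  writeLines(paste0(">", tab$name, "\n", tab$sequence), fasta)
  paths <- c(paths, fasta)
  spec <- plantedComplexSpec(
    icCounts = c(cc = 4, ca = 16, pp = 2, pa = 4),
    nisCounts = c(charged = 19, polar = 24, apolar = 27), seed = seed)
  cpx <- file.path(dir, "planted_complex.pdb")
  writePDB(makePlantedComplex(spec), cpx)
  paths <- c(paths, cpx)
  base <- makePlantedComplex(plantedComplexSpec(icCounts = c(aa = 5), seed = seed))
  tspec <- syntheticTrajectorySpec(base, sigma = 0.05, nFrames = 20L,
                                   dt = 100, seed = seed)
  trj <- file.path(dir, "synthetic_trajectory.pdb")
  writeMultiModelPDB(makeSyntheticTrajectory(tspec), trj)
  paths <- c(paths, trj)
  for (f in c("table1_peptides.tsv", "table2_energetics.tsv")) {
    p <- file.path(dir, f)
    file.copy(.extdata(f), p, overwrite = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
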