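# StructureModel: the atom-level container behind every structural
# operation (contacts, SASA, H-bonds, non-bonded energies). Heavy atoms
# by default; coordinates in Angstrom.

#' StructureModel class
#'
#' Atoms grouped by chain and residue, with coordinates in Angstrom,
#' element symbols and van der Waals radii. Built by [readPDB()] or the
#' synthetic generators, consumed by the interface and trajectory
#' analyses.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (integer),
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `radius`, `charge`
#'   (partial charge in e, may be NA).
#' @slot modelId Character scalar identifier.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", modelId = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "radius", "charge")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) == 0) return("model contains no atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    return("non-finite coordinates")
  }
  key <- paste(a$chain, a$resno)
  if (anyDuplicated(unique(cbind(key, a$resname))[, 1])) {
    return("conflicting residue names at the same (chain, resno)")
  }
  TRUE
})

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame as described in [StructureModel-class]; a
#'   missing `radius` column is filled from [vdwRadii()] by element, a
#'   missing `charge` column with NA.
#' @param modelId Identifier string.
#' @return A `StructureModel`.
#' @export
structureModel <- function(atoms, modelId = "model") {
  if (is.null(atoms$radius)) atoms$radius <- unname(vdwRadii()[atoms$element])
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  methods::new("StructureModel", atoms = atoms, modelId = modelId)
}

#' @describeIn structureModel Atom table accessor.
#' @param x A `StructureModel`.
#' @export
atoms <- function(x) x@atoms

#' @describeIn structureModel Number of atoms.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn structureModel Chain identifiers present.
#' @export
chains <- function(x) unique(x@atoms$chain)

#' @describeIn structureModel Coordinate matrix (n x 3, Angstrom).
#' @export
coords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel '", object@modelId, "': ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno))), " residues, chains ",
      paste(unique(a$chain), collapse = ","), "\n", sep = "")
})

#' Per-residue table of a model
#'
#' @param model A `StructureModel`.
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, in atom order.
#' @export
residueTable <- function(model) {
  a <- atoms(model)
  out <- unique(a[, c("chain", "resno", "resname")])
  rownames(out) <- NULL
  out
}

# Element inference from a PDB atom name: strip digits/primes, take the
# leading letter; protein heavy atoms are single-letter elements.
.infer_element <- function(atomName) {
  nm <- gsub("[^A-Za-z]", "", atomName)
  toupper(substr(nm, 1, 1))
}

#' Read a PDB file into a StructureModel
#'
#' Parses ATOM records of a single-model PDB file (via bio3d). HETATM
#' records (waters, ligands) are excluded by default; hydrogens are kept
#' if present. Elements missing from the file are inferred from the atom
#' name with a warning.
#'
#' @param path PDB file path.
#' @param keepHetatm Keep HETATM records (default FALSE).
#' @param keepHydrogens Keep hydrogens (default TRUE; heavy-atom
#'   operations ignore them explicitly).
#' @return A `StructureModel`.
#' @export
readPDB <- function(path, keepHetatm = FALSE, keepHydrogens = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("malformed PDB file '", path, "': ",
                                           conditionMessage(e)))
  .atoms_from_bio3d(pdb$atom, path, keepHetatm, keepHydrogens)
}

.atoms_from_bio3d <- function(at, path, keepHetatm, keepHydrogens) {
  if (!keepHetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  elem <- at$elesy
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_elem)) {
    warning("element column missing for ", sum(missing_elem),
            " atoms; inferred from atom names")
    elem[missing_elem] <- .infer_element(at$elety[missing_elem])
  }
  elem <- toupper(trimws(elem))
  if (!keepHydrogens) {
    keep <- elem != "H"
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  structureModel(data.frame(
    chain = chain, resno = as.integer(at$resno), resname = at$resid,
    atom = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  ), modelId = basename(path))
}

#' Write a StructureModel as a PDB file
#'
#' Plain fixed-column ATOM records plus element symbols; round-trips
#' through [readPDB()].
#'
#' @param model A `StructureModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_model_records(model, con)
  writeLines("END", con)
  invisible(path)
}

.write_model_records <- function(model, con, xyz = NULL) {
  a <- atoms(model)
  if (is.null(xyz)) xyz <- coords(model)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, substr(a$atom, 1, 4), substr(a$resname, 1, 3),
    substr(a$chain, 1, 1), a$resno, xyz[, 1], xyz[, 2], xyz[, 3],
    1, 0, a$element)
  writeLines(lines, con)
}

# Backbone atom names used by the default trajectory selection.
.BACKBONE <- c("N", "CA", "C", "O")

# Indices of atoms matching a selection spec: "all", "backbone",
# "heavy", a logical/integer vector, or a chain filter list.
.select_atoms <- function(model, selection = "all") {
  a <- atoms(model)
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.logical(selection)) return(which(selection))
  switch(selection,
         all = seq_len(nrow(a)),
         backbone = which(a$atom %in% .BACKBONE & a$element != "H"),
         heavy = which(a$element != "H"),
         stop("unknown selection: ", selection))
}
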