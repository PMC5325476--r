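#' @keywords internal
#' @import methods
"_PACKAGE"

# Cache for parsed parameter tables shipped under extdata/.
.pepforge_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepforge")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

.cached_table <- function(key, reader) {
  if (!exists(key, envir = .pepforge_cache)) {
    assign(key, reader(), envir = .pepforge_cache)
  }
  get(key, envir = .pepforge_cache)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, alphabetical.
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [gravy()]. Positive values are
#' hydrophobic, negative hydrophilic.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kyteDoolittle <- function() {
  .cached_table("kd", function() {
    tab <- .read_tsv(.extdata("kyte_doolittle.tsv"))
    stats::setNames(tab$value, tab$aa)
  })
}

#' Dipeptide instability weight values
#'
#' The complete 400-entry DIWV table behind the instability index
#' (Guruprasad-type statistic), in the variant used by the ProtParam
#' server. `DIWV[x, y]` is the weight of the ordered dipeptide `xy`.
#' @return 20 x 20 numeric matrix with residue dimnames.
#' @export
diwvTable <- function() {
  .cached_table("diwv", function() {
    tab <- .read_tsv(.extdata("diwv.tsv"))
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$first
    storage.mode(m) <- "double"
    m
  })
}

#' Default pKa set for the charge model
#'
#' Ionizable-group pKa values (pH units) used by [netCharge()] and
#' [isoelectricPoint()]. The set reproduces the bundled reference
#' peptides' printed net charges after one-decimal rounding, and can be
#' swapped for any data frame with columns `group`, `pka`, `kind`.
#' @return data.frame with columns `group` (Nterm, Cterm, or a residue
#'   letter), `pka`, `kind` ("acidic"/"basic"), plus a `"pka_set"`
#'   attribute naming the set.
#' @export
defaultPKaSet <- function() {
  .cached_table("pka", function() {
    tab <- .read_tsv(.extdata("pka_default.tsv"))
    attr(tab, "pka_set") <- "pepforge-default-v1"
    tab
  })
}

#' Aggregation propensity scale
#'
#' An a3v-style per-residue aggregation propensity table used by
#' [aggregationHotspots()]. Hot-spot calls are scale-dependent and
#' reported as such.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
aggrescanScale <- function() {
  .cached_table("a3v", function() {
    tab <- .read_tsv(.extdata("aggrescan_a3v.tsv"))
    stats::setNames(tab$a3v, tab$aa)
  })
}

# Average residue masses (Da); peptide MW = sum + one water.
.residueMasses <- function() {
  .cached_table("mass", function() {
    tab <- .read_tsv(.extdata("residue_masses.tsv"))
    stats::setNames(tab$residue_mass, tab$aa)
  })
}

#' Maximum accessible surface area reference
#'
#' Theoretical per-residue maximum ASA values (Tien-style, in
#' Angstrom^2) used to convert absolute SASA into relative SASA when
#' classifying surface residues.
#' @return data.frame with columns `resname`, `aa`, `max_asa`.
#' @export
maxASAReference <- function() {
  .cached_table("maxasa", function() .read_tsv(.extdata("max_asa_tien.tsv")))
}

#' Van der Waals radii by element
#' @return Named numeric vector (Angstrom) over H, C, N, O, S, P.
#' @export
vdwRadii <- function() {
  .cached_table("vdw", function() {
    tab <- .read_tsv(.extdata("vdw_radii.tsv"))
    stats::setNames(tab$radius, tab$element)
  })
}

#' Residue polarity classes
#'
#' Partition of the 20 canonical residues into charged / polar / apolar,
#' following the convention of interfacial-contact binding models:
#' charged = D, E, K, R, H; polar = N, Q, S, T, Y; apolar = the rest.
#' @return data.frame with columns `resname`, `aa`, `class`.
#' @export
polarityClasses <- function() {
  .cached_table("polarity", function() .read_tsv(.extdata("polarity_classes.tsv")))
}
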