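# Contact-classified interface analysis: interfacial contacts at a
# heavy-atom distance cutoff, non-interacting-surface composition, and
# the linear interfacial-contact binding free energy model with its Kd
# conversion.

# Unordered polarity class-pair keys, fixed order used everywhere.
.IC_KEYS <- c("cc", "cp", "ca", "pp", "pa", "aa")

.class_abbrev <- c(charged = "c", polar = "p", apolar = "a")

#' Polarity class of a residue
#'
#' charged = D, E, K, R, H; polar = N, Q, S, T, Y; apolar = the
#' remaining ten residues. Accepts three-letter or one-letter codes.
#'
#' @param resname Character vector of residue names.
#' @param unknown What to do with non-canonical residues: "error"
#'   (default) or a class name to assign.
#' @return Character vector in {"charged", "polar", "apolar"}.
#' @export
residueClass <- function(resname, unknown = "error") {
  tab <- polarityClasses()
  key <- toupper(resname)
  cls <- tab$class[match(key, tab$resname)]
  one <- tab$class[match(key, tab$aa)]
  cls[is.na(cls)] <- one[is.na(cls)]
  if (anyNA(cls)) {
    if (identical(unknown, "error")) {
      stop("non-canonical residue: ", paste(unique(key[is.na(cls)]), collapse = ", "))
    }
    cls[is.na(cls)] <- unknown
  }
  cls
}

# Unordered class-pair key for two residue classes, ordered
# charged < polar < apolar (the convention behind cc/cp/ca/pp/pa/aa).
.pair_key <- function(classA, classB) {
  rank <- c(charged = 1L, polar = 2L, apolar = 3L)
  ra <- rank[classA]; rb <- rank[classB]
  abbr <- c("c", "p", "a")
  paste0(abbr[pmin(ra, rb)], abbr[pmax(ra, rb)])
}

#' Interfacial contacts between two chain groups
#'
#' A residue pair (one residue from each side) is an interfacial
#' contact iff any of their heavy-atom pairs lies within `cutoff`
#' Angstrom. Each residue pair counts once; counts are binned by the
#' unordered polarity class pair.
#'
#' @param model A `StructureModel` with at least two chains.
#' @param chainsA,chainsB Disjoint chain id vectors.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.5).
#' @return Object of class `icCounts`: list with `counts` (named
#'   integer vector over cc, cp, ca, pp, pa, aa), `pairs` (data.frame of
#'   contacting residue pairs) and `cutoff`.
#' @export
interfaceContacts <- function(model, chainsA, chainsB, cutoff = 5.5) {
  a <- atoms(model)
  if (length(intersect(chainsA, chainsB))) stop("chain groups must be disjoint")
  selA <- which(a$chain %in% chainsA & a$element != "H")
  selB <- which(a$chain %in% chainsB & a$element != "H")
  if (!length(selA) || !length(selB)) stop("empty chain selection")
  xyzA <- as.matrix(a[selA, c("x", "y", "z")])
  xyzB <- as.matrix(a[selB, c("x", "y", "z")])
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  keyA <- paste(a$chain[selA], a$resno[selA])
  keyB <- paste(a$chain[selB], a$resno[selB])
  pairs <- unique(data.frame(
    chainA = a$chain[selA][hit[, 1]], resnoA = a$resno[selA][hit[, 1]],
    resnameA = a$resname[selA][hit[, 1]],
    chainB = a$chain[selB][hit[, 2]], resnoB = a$resno[selB][hit[, 2]],
    resnameB = a$resname[selB][hit[, 2]],
    stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  counts <- stats::setNames(integer(length(.IC_KEYS)), .IC_KEYS)
  if (nrow(pairs)) {
    k <- .pair_key(residueClass(pairs$resnameA), residueClass(pairs$resnameB))
    tab <- table(factor(k, levels = .IC_KEYS))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, pairs = pairs, cutoff = cutoff),
            class = "icCounts")
}

#' @export
print.icCounts <- function(x, ...) {
  cat("Interfacial contacts (cutoff", x$cutoff, "A):\n")
  print(x$counts)
  invisible(x)
}

#' Non-interacting surface composition
#'
#' NIS residues are residues whose relative SASA (absolute SASA over a
#' per-residue maximum-ASA reference) is at least `rsaThreshold`
#' percent and which take part in no interfacial contact pair. The
#' composition is the percentage of NIS residues in each polarity
#' class.
#'
#' @param model The complex `StructureModel`.
#' @param contacts `icCounts` from [interfaceContacts()] on the same
#'   model.
#' @param sasaProfile `sasaProfile` from [sasa()] on the same model.
#' @param rsaThreshold Relative-SASA threshold in percent (default 5).
#' @return Object of class `nisComposition`: list with `percent`
#'   (named vector charged/polar/apolar, NA when the NIS set is empty),
#'   `nResidues`, `empty` flag, `rsaThreshold`.
#' @export
nisComposition <- function(model, contacts, sasaProfile, rsaThreshold = 5) {
  res <- sasaProfile$residues
  ref <- maxASAReference()
  maxasa <- ref$max_asa[match(toupper(res$resname), ref$resname)]
  if (anyNA(maxasa)) {
    stop("no max-ASA reference for residue(s): ",
         paste(unique(res$resname[is.na(maxasa)]), collapse = ", "))
  }
  rsa <- 100 * res$sasa / maxasa
  ckey <- c(paste(contacts$pairs$chainA, contacts$pairs$resnoA),
            paste(contacts$pairs$chainB, contacts$pairs$resnoB))
  nis <- rsa >= rsaThreshold & !(paste(res$chain, res$resno) %in% ckey)
  pct <- c(charged = NA_real_, polar = NA_real_, apolar = NA_real_)
  n <- sum(nis)
  if (n > 0) {
    cls <- factor(residueClass(res$resname[nis]),
                  levels = c("charged", "polar", "apolar"))
    pct[] <- 100 * as.vector(table(cls)) / n
  }
  structure(list(percent = pct, nResidues = n, empty = n == 0,
                 rsaThreshold = rsaThreshold),
            class = "nisComposition")
}

#' @export
print.nisComposition <- function(x, ...) {
  if (x$empty) cat("NIS composition: empty NIS set\n")
  else {
    cat("NIS composition over", x$nResidues, "residues (%):\n")
    print(round(x$percent, 2))
  }
  invisible(x)
}

# Coefficient sets of the interfacial-contact binding model. "printed"
# is the equation as published alongside the peptide tables;
# "alternate" uses the 0.13810 %NIS-charged weight of the original
# contacts-based model the equation derives from.
.DG_COEFS <- list(
  printed = c(cc = -0.09459, ca = -0.10007, pp = 0.19577, pa = -0.22671,
              nis_ap = 0.18681, nis_ch = 0.3810, intercept = -15.9433),
  alternate = c(cc = -0.09459, ca = -0.10007, pp = 0.19577, pa = -0.22671,
                nis_ap = 0.18681, nis_ch = 0.13810, intercept = -15.9433)
)

#' Interfacial-contact binding free energy model
#'
#' Linear model over four contact class-pair counts and two
#' non-interacting-surface percentages:
#' dG = -0.09459 IC_cc - 0.10007 IC_ca + 0.19577 IC_pp - 0.22671 IC_pa
#'      + 0.18681 %NIS_apolar + 0.3810 %NIS_charged - 15.9433.
#' The charged/polar and apolar/apolar counts are carried in the input
#' but take no weight. The `"alternate"` coefficient set replaces the
#' %NIS_charged weight with 0.13810.
#'
#' @param ic `icCounts` object, or a named numeric vector with entries
#'   among cc, cp, ca, pp, pa, aa.
#' @param nis `nisComposition` object, or named vector with `charged`
#'   and `apolar` percentages.
#' @param coefficientSet `"printed"` (default) or `"alternate"`.
#' @param temperature Temperature in Kelvin for the Kd conversion.
#' @return Object of class `interactionEnergy`: list with `dG`
#'   (kcal/mol), `kd` (molar), `temperature`, `coefficientSet`.
#' @export
deltaGInteraction <- function(ic, nis, coefficientSet = c("printed", "alternate"),
                              temperature = 298.15) {
  coefficientSet <- match.arg(coefficientSet)
  cf <- .DG_COEFS[[coefficientSet]]
  counts <- if (inherits(ic, "icCounts")) ic$counts else ic
  pct <- if (inherits(nis, "nisComposition")) {
    if (nis$empty) stop("NIS set is empty; composition undefined")
    nis$percent
  } else nis
  get0n <- function(v, k) if (k %in% names(v)) as.numeric(v[[k]]) else 0
  dg <- cf[["cc"]] * get0n(counts, "cc") + cf[["ca"]] * get0n(counts, "ca") +
    cf[["pp"]] * get0n(counts, "pp") + cf[["pa"]] * get0n(counts, "pa") +
    cf[["nis_ap"]] * get0n(pct, "apolar") + cf[["nis_ch"]] * get0n(pct, "charged") +
    cf[["intercept"]]
  structure(list(dG = dg, kd = kdFromDg(dg, temperature),
                 temperature = temperature, coefficientSet = coefficientSet),
            class = "interactionEnergy")
}

#' @export
print.interactionEnergy <- function(x, ...) {
  cat(sprintf("dG_interaction = %.4f kcal/mol (%s coefficients); Kd = %.3g M at %.2f K\n",
              x$dG, x$coefficientSet, x$kd, x$temperature))
  invisible(x)
}

# Gas constant in kcal / (mol K).
.R_KCAL <- 1.987e-3

#' Dissociation constant from binding free energy
#'
#' Kd = exp(dG / (R T)) with R = 1.987e-3 kcal/(mol K).
#'
#' @param dg Binding free energy in kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return Kd in molar.
#' @export
kdFromDg <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  exp(dg / (.R_KCAL * temperature))
}

#' @rdname kdFromDg
#' @param kd Dissociation constant in molar.
#' @return `dgFromKd`: binding free energy in kcal/mol.
#' @export
dgFromKd <- function(kd, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  if (any(kd <= 0)) stop("Kd must be positive")
  .R_KCAL * temperature * log(kd)
}

#' Per-residue burial on complex formation
#'
#' Difference of per-residue SASA between the free and the bound form
#' of the same molecule, for a stated residue list.
#'
#' @param sasaFree,sasaComplex `sasaProfile` objects sharing residue
#'   numbering.
#' @param residueList data.frame with columns `chain`, `resno` (or a
#'   vector of "chain resno" keys); empty input gives an empty table.
#' @return data.frame with `chain`, `resno`, `sasa_free`,
#'   `sasa_complex`, `delta_sasa` (all Angstrom^2; positive = buried)
#'   and `missing` flag; attribute `mean_delta` over non-missing rows.
#' @export
burialReport <- function(sasaFree, sasaComplex, residueList) {
  if (is.character(residueList)) {
    parts <- strsplit(residueList, " ", fixed = TRUE)
    residueList <- data.frame(chain = vapply(parts, `[`, "", 1),
                              resno = as.integer(vapply(parts, `[`, "", 2)))
  }
  if (NROW(residueList) == 0) {
    out <- data.frame(chain = character(), resno = integer(),
                      sasa_free = numeric(), sasa_complex = numeric(),
                      delta_sasa = numeric(), missing = logical())
    attr(out, "mean_delta") <- NaN
    return(out)
  }
  lookup <- function(prof, chain, resno) {
    i <- match(paste(chain, resno), paste(prof$residues$chain, prof$residues$resno))
    prof$residues$sasa[i]
  }
  sf <- lookup(sasaFree, residueList$chain, residueList$resno)
  sc <- lookup(sasaComplex, residueList$chain, residueList$resno)
  out <- data.frame(chain = residueList$chain, resno = residueList$resno,
                    sasa_free = sf, sasa_complex = sc,
                    delta_sasa = sf - sc, missing = is.na(sf) | is.na(sc))
  attr(out, "mean_delta") <- mean(out$delta_sasa[!out$missing])
  out
}
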