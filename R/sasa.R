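# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set, plus per-residue aggregation.

# Deterministic, near-uniform unit-sphere point set (golden-spiral /
# Fibonacci lattice). Same points for a given n, so SASA is exactly
# reproducible.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the heavy atoms of a model: each atom's
#' accessible area is the fraction of `nPoints` deterministic
#' golden-spiral test points on its expanded sphere (vdW radius +
#' probe) lying outside every neighbouring expanded sphere, times the
#' sphere area. Hydrogens are excluded.
#'
#' @param model A `StructureModel` with radii for all heavy atoms.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param nPoints Test points per atom (default 960).
#' @return Object of class `sasaProfile`: list with `atom` (per-atom
#'   areas, Angstrom^2, NA for hydrogens), `residues` (data.frame
#'   chain/resno/resname/sasa), `total`, `probe`, `nPoints`.
#' @export
sasa <- function(model, probe = 1.4, nPoints = 960L) {
  a <- atoms(model)
  heavy <- which(a$element != "H")
  if (!length(heavy)) stop("no heavy atoms in model")
  r <- a$radius[heavy]
  if (anyNA(r)) {
    bad <- heavy[which(is.na(r))[1]]
    stop(sprintf("atom %d (%s %s %d %s) has no van der Waals radius",
                 bad, a$chain[bad], a$resname[bad], a$resno[bad], a$atom[bad]))
  }
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  re <- r + probe
  n <- length(heavy)
  pts <- .sphere_points(nPoints)
  # neighbour lists from squared distances
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    p <- pts * re[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > re[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * re[i]^2 * sum(acc) / nPoints
  }
  atomArea <- rep(NA_real_, nrow(a))
  atomArea[heavy] <- area
  key <- paste(a$chain[heavy], a$resno[heavy])
  res <- unique(data.frame(chain = a$chain[heavy], resno = a$resno[heavy],
                           resname = a$resname[heavy], stringsAsFactors = FALSE))
  res$sasa <- as.vector(tapply(area, factor(key, levels = unique(key)), sum))
  rownames(res) <- NULL
  structure(list(atom = atomArea, residues = res, total = sum(area),
                 probe = probe, nPoints = nPoints),
            class = "sasaProfile")
}

#' @export
print.sasaProfile <- function(x, ...) {
  cat(sprintf("SASA: total %.1f A^2 over %d residues (probe %.1f A, %d points)\n",
              x$total, nrow(x$residues), x$probe, x$nPoints))
  invisible(x)
}
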