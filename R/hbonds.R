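# Geometric hydrogen-bond detection between two atom groups. N/O-based
# donor/acceptor typing; when explicit hydrogens are present the
# H-donor-acceptor angle criterion is applied, otherwise detection
# degrades to the donor-acceptor distance alone (logged once).

# Polar heavy atoms (N, O) can both donate and accept under the
# simple typing used here; S is excluded.
.polar_idx <- function(a, sel) sel[a$element[sel] %in% c("N", "O")]

# Hydrogens covalently attached to a heavy atom: within 1.25 A.
.attached_h <- function(a, heavyIdx) {
  hIdx <- which(a$element == "H")
  if (!length(hIdx)) return(vector("list", length(heavyIdx)))
  hxyz <- as.matrix(a[hIdx, c("x", "y", "z")])
  lapply(heavyIdx, function(i) {
    d2 <- (hxyz[, 1] - a$x[i])^2 + (hxyz[, 2] - a$y[i])^2 + (hxyz[, 3] - a$z[i])^2
    hIdx[d2 <= 1.25^2]
  })
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds between two groups
#'
#' A donor-acceptor pair is a hydrogen bond iff the heavy-atom
#' distance is at most `dCut` and, when the donor carries an explicit
#' hydrogen, the hydrogen-donor-acceptor angle is at most `angleCut`
#' for at least one such hydrogen. Donors and acceptors are N and O
#' atoms; both directions across the two groups are scanned.
#'
#' @param model A `StructureModel`.
#' @param groupsA,groupsB Chain-id vectors defining the two sides.
#' @param dCut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angleCut H-donor-acceptor angle cutoff, degrees (default 30).
#' @return data.frame with one row per bond: donor/acceptor chain,
#'   resno, atom indices, `distance`, `angle` (NA without hydrogens).
#'   Zero rows (with a warning) when a selection has no polar atoms.
#' @export
detectHBonds <- function(model, groupsA, groupsB, dCut = 3.5, angleCut = 30) {
  a <- atoms(model)
  selA <- which(a$chain %in% groupsA)
  selB <- which(a$chain %in% groupsB)
  polA <- .polar_idx(a, selA)
  polB <- .polar_idx(a, selB)
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      donorChain = character(), donorResno = integer(),
                      acceptorChain = character(), acceptorResno = integer(),
                      distance = numeric(), angle = numeric())
  if (!length(polA) || !length(polB)) {
    warning("no polar (N/O) atoms in one of the selections")
    return(empty)
  }
  hmap <- stats::setNames(.attached_h(a, c(polA, polB)),
                          as.character(c(polA, polB)))
  anyH <- any(lengths(hmap) > 0)
  if (!anyH) message("no explicit hydrogens: H-bond detection uses donor-acceptor distance only")
  rows <- list()
  for (don in polA) for (acc in polB) {
    for (pair in list(c(don, acc), c(acc, don))) {
      d <- pair[1]; ac <- pair[2]
      dist <- sqrt((a$x[d] - a$x[ac])^2 + (a$y[d] - a$y[ac])^2 + (a$z[d] - a$z[ac])^2)
      if (dist > dCut) next
      hs <- hmap[[as.character(d)]]
      ang <- NA_real_
      if (length(hs)) {
        angs <- vapply(hs, function(h) {
          .angle_deg(c(a$x[h] - a$x[d], a$y[h] - a$y[d], a$z[h] - a$z[d]),
                     c(a$x[ac] - a$x[d], a$y[ac] - a$y[d], a$z[ac] - a$z[d]))
        }, numeric(1))
        ang <- min(angs)
        if (ang > angleCut) next
      } else if (anyH) {
        # donors without hydrogens in a structure that has them are
        # treated as non-donating
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, acceptor = ac,
        donorChain = a$chain[d], donorResno = a$resno[d],
        acceptorChain = a$chain[ac], acceptorResno = a$resno[ac],
        distance = dist, angle = ang)
      break  # count each unordered pair once
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
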