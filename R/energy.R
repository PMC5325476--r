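# Simplified inter-molecular non-bonded energies: Coulomb with a
# relative permittivity, Lennard-Jones 12-6 with Lorentz-Berthelot
# combination, and the additive molecular-mechanics identity
# E_MM = E_internal + E_electrostatic + E_VdW. No distance cutoff is
# applied: every cross pair enters the sums.

# Coulomb constant in kcal A / (mol e^2).
.K_COULOMB <- 332.06

.cross_pairs <- function(model, chainsA, chainsB) {
  a <- atoms(model)
  selA <- which(a$chain %in% chainsA)
  selB <- which(a$chain %in% chainsB)
  if (!length(selA) || !length(selB)) stop("empty chain selection")
  list(a = a, selA = selA, selB = selB,
       d = sqrt(outer(a$x[selA], a$x[selB], "-")^2 +
                  outer(a$y[selA], a$y[selB], "-")^2 +
                  outer(a$z[selA], a$z[selB], "-")^2))
}

#' Inter-molecular Coulomb energy
#'
#' Sum of k_e q_i q_j / (eps_r r_ij) over all atom pairs crossing the
#' two chain groups, k_e = 332.06 kcal A / (mol e^2), no cutoff.
#'
#' @param model A `StructureModel` whose atoms carry partial charges
#'   (the `charge` column, in elementary charges).
#' @param chainsA,chainsB Chain groups defining the two molecules.
#' @param relativePermittivity Dimensionless eps_r (default 1).
#' @return Energy in kcal/mol.
#' @export
coulombEnergy <- function(model, chainsA, chainsB, relativePermittivity = 1) {
  cp <- .cross_pairs(model, chainsA, chainsB)
  q <- cp$a$charge
  bad <- c(cp$selA, cp$selB)[is.na(q[c(cp$selA, cp$selB)])]
  if (length(bad)) {
    stop(sprintf("atom %d (%s %s %d %s) has no partial charge", bad[1],
                 cp$a$chain[bad[1]], cp$a$resname[bad[1]],
                 cp$a$resno[bad[1]], cp$a$atom[bad[1]]))
  }
  sum(.K_COULOMB * outer(q[cp$selA], q[cp$selB]) / (relativePermittivity * cp$d))
}

#' Inter-molecular Lennard-Jones 12-6 energy
#'
#' 4 eps ((sigma/r)^12 - (sigma/r)^6) over all cross pairs, with
#' Lorentz-Berthelot combination (arithmetic sigma, geometric eps), no
#' cutoff.
#'
#' @inheritParams coulombEnergy
#' @param ljParams data.frame with columns `element`, `sigma`
#'   (Angstrom), `epsilon` (kcal/mol); defaults to a minimal bundled
#'   table.
#' @return Energy in kcal/mol.
#' @export
ljEnergy <- function(model, chainsA, chainsB, ljParams = defaultLJParams()) {
  cp <- .cross_pairs(model, chainsA, chainsB)
  idx <- match(cp$a$element, ljParams$element)
  bad <- c(cp$selA, cp$selB)[is.na(idx[c(cp$selA, cp$selB)])]
  if (length(bad)) {
    stop(sprintf("atom %d (%s, element %s) has no Lennard-Jones parameters",
                 bad[1], cp$a$atom[bad[1]], cp$a$element[bad[1]]))
  }
  sig <- ljParams$sigma[idx]
  eps <- ljParams$epsilon[idx]
  sij <- outer(sig[cp$selA], sig[cp$selB], "+") / 2
  eij <- sqrt(outer(eps[cp$selA], eps[cp$selB]))
  sr6 <- (sij / cp$d)^6
  sum(4 * eij * (sr6^2 - sr6))
}

#' Minimal Lennard-Jones parameter table
#'
#' Generic per-element sigma/epsilon values sufficient for the
#' simplified rigid-species energy evaluation; not a force field.
#' @return data.frame with columns `element`, `sigma`, `epsilon`.
#' @export
defaultLJParams <- function() {
  data.frame(element = c("H", "C", "N", "O", "S", "P"),
             sigma = c(2.50, 3.40, 3.25, 3.00, 3.55, 3.74),
             epsilon = c(0.030, 0.086, 0.170, 0.210, 0.250, 0.200))
}

#' Additive molecular-mechanics energy
#'
#' E_MM = E_internal + E_electrostatic + E_VdW, with E_internal = 0 for
#' rigid species (identical bound and unbound conformations).
#'
#' @param internal,electrostatic,vdw Component energies in kcal/mol.
#' @return Object of class `nonbondedEnergy`: list with the three
#'   components and their exact sum `eMM`.
#' @export
eMM <- function(electrostatic, vdw, internal = 0) {
  stopifnot(is.finite(internal), is.finite(electrostatic), is.finite(vdw))
  structure(list(eInternal = internal, eElectrostatic = electrostatic,
                 eVdW = vdw, eMM = internal + electrostatic + vdw),
            class = "nonbondedEnergy")
}

#' @export
print.nonbondedEnergy <- function(x, ...) {
  cat(sprintf("E_MM = %.3f kcal/mol (internal %.3f + electrostatic %.3f + VdW %.3f)\n",
              x$eMM, x$eInternal, x$eElectrostatic, x$eVdW))
  invisible(x)
}
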