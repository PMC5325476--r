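# Trajectory container and MD observables: Kabsch superposition, RMSD,
# radius of gyration, RMSF, SASA and H-bond series, snapshot
# extraction. Coordinates are Angstrom internally; series are reported
# in nm / nm^2, matching the usual MD plotting convention.

#' Trajectory class
#'
#' Ordered coordinate frames over a fixed topology. Frames share atom
#' count and ordering; times (ps) are strictly increasing.
#'
#' @slot topology A `StructureModel` giving the shared topology (its
#'   coordinates are frame 1's unless stated otherwise).
#' @slot xyz Numeric array `c(nAtoms, 3, nFrames)`, Angstrom.
#' @slot times Numeric vector of frame times in ps.
#' @export
setClass("Trajectory",
         representation(topology = "StructureModel", xyz = "array",
                        times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@xyz)
  if (length(d) != 3 || d[2] != 3) return("xyz must be an nAtoms x 3 x nFrames array")
  if (d[1] != nAtoms(object@topology)) return("frame atom count differs from topology")
  if (d[3] != length(object@times)) return("times length differs from frame count")
  if (length(object@times) > 1 && any(diff(object@times) <= 0)) {
    return("times must be strictly increasing")
  }
  if (!all(is.finite(object@xyz))) return("non-finite coordinates")
  TRUE
})

#' Construct a Trajectory
#'
#' @param topology A `StructureModel`.
#' @param frames List of nAtoms x 3 coordinate matrices (Angstrom), or
#'   an nAtoms x 3 x nFrames array.
#' @param times Frame times in ps; defaults to `0, dt, 2 dt, ...`.
#' @param dt Time step in ps used when `times` is NULL (default 1).
#' @return A `Trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL, dt = 1) {
  if (is.list(frames)) {
    xyz <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
    for (i in seq_along(frames)) {
      if (!identical(dim(frames[[i]]), dim(frames[[1]]))) {
        stop("frame ", i, " has a divergent atom count")
      }
      xyz[, , i] <- frames[[i]]
    }
  } else xyz <- frames
  if (is.null(times)) times <- (seq_len(dim(xyz)[3]) - 1) * dt
  methods::new("Trajectory", topology = topology, xyz = xyz, times = times)
}

#' @describeIn trajectory Number of frames.
#' @param x A `Trajectory`.
#' @export
nFrames <- function(x) dim(x@xyz)[3]

#' @describeIn trajectory Frame times (ps).
#' @export
frameTimes <- function(x) x@times

#' @describeIn trajectory One frame's coordinates (nAtoms x 3 matrix).
#' @param i Frame index.
#' @export
frameCoords <- function(x, i) {
  m <- x@xyz[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @describeIn trajectory Topology accessor.
#' @export
topology <- function(x) x@topology

#' @describeIn trajectory Frame `i` as a `StructureModel`.
#' @export
frameModel <- function(x, i) {
  a <- atoms(x@topology)
  a[, c("x", "y", "z")] <- frameCoords(x, i)
  structureModel(a, modelId = sprintf("%s#%d", x@topology@modelId, i))
}

setMethod("show", "Trajectory", function(object) {
  t <- object@times
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              nFrames(object), nAtoms(object@topology), t[1], t[length(t)]))
})

#' Read a multi-model PDB file as a Trajectory
#'
#' MODEL/ENDMDL-delimited frames over a constant topology; a model
#' whose atom count diverges is rejected with its model number.
#'
#' @param path PDB file path.
#' @param dt Time spacing between models in ps (multi-model PDB stores
#'   no times).
#' @param keepHetatm,keepHydrogens Passed to the record filter, as in
#'   [readPDB()].
#' @return A `Trajectory`.
#' @export
readMultiModelPDB <- function(path, dt = 1, keepHetatm = FALSE,
                              keepHydrogens = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    model <- readPDB(path, keepHetatm, keepHydrogens)
    return(trajectory(model, list(coords(model)), dt = dt))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
                  error = function(e) stop("malformed PDB file '", path, "': ",
                                           conditionMessage(e)))
  # bio3d requires consistent models; double-check raw atom counts so a
  # divergent model is named explicitly
  counts <- vapply(seq_along(starts), function(i) {
    sum(grepl("^ATOM  ", lines[starts[i]:ends[i]]))
  }, integer(1))
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop("model ", bad, " has ", counts[bad], " atoms; expected ", counts[1])
  }
  model <- .atoms_from_bio3d(pdb$atom, path, keepHetatm, keepHydrogens)
  sel <- .frame_filter(pdb$atom, keepHetatm, keepHydrogens)
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    m[sel, , drop = FALSE]
  })
  trajectory(model, frames, dt = dt)
}

# Row filter matching .atoms_from_bio3d's record selection.
.frame_filter <- function(at, keepHetatm, keepHydrogens) {
  keep <- if (keepHetatm) rep(TRUE, nrow(at)) else at$type == "ATOM"
  if (!keepHydrogens) {
    elem <- at$elesy
    miss <- is.na(elem) | !nzchar(trimws(elem))
    elem[miss] <- .infer_element(at$elety[miss])
    keep <- keep & toupper(trimws(elem)) != "H"
  }
  which(keep)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' @param traj A `Trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    .write_model_records(traj@topology, con, xyz = frameCoords(traj, i))
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of a mobile coordinate set onto
#' a reference, via SVD of the covariance matrix with the usual
#' determinant sign correction, guaranteeing a proper rotation.
#'
#' @param mobile,reference n x 3 coordinate matrices (equal n >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom), and `transform(x)` applying the fit
#'   to any n x 3 matrix.
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("need at least 3 atoms for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(crossprod(A, B))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2) {
    stop("degenerate (collinear) coordinates: superposition undefined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  transform <- function(x) sweep(sweep(as.matrix(x), 2, cm) %*% t(R), 2, cr, "+")
  list(rotation = R, translation = as.vector(cr - cm %*% t(R)),
       rmsd = rmsd, transform = transform)
}

.series <- function(name, values, times, unit, profile = NULL, window = NULL) {
  structure(list(name = name, values = values, times = times, unit = unit,
                 profile = profile, window = window),
            class = "seriesResult")
}

#' @export
print.seriesResult <- function(x, ...) {
  cat(sprintf("%s series: %d frames [%s], mean %.4g\n",
              x$name, length(x$values), x$unit, mean(x$values)))
  invisible(x)
}

#' RMSD series over a trajectory
#'
#' Per-frame RMSD (nm) against a reference frame after optimal
#' superposition on the stated selection.
#'
#' @param traj A `Trajectory`.
#' @param referenceFrame Reference frame index (default 1).
#' @param selection Atom selection ("backbone", "heavy", "all", or
#'   indices); must be non-empty.
#' @return A `seriesResult` with per-frame values in nm.
#' @export
rmsdSeries <- function(traj, referenceFrame = 1L, selection = "backbone") {
  sel <- .select_atoms(traj@topology, selection)
  if (!length(sel)) stop("empty atom selection")
  ref <- frameCoords(traj, referenceFrame)[sel, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(i) {
    kabschSuperpose(frameCoords(traj, i)[sel, , drop = FALSE], ref)$rmsd
  }, numeric(1)) / 10
  .series("RMSD", vals, frameTimes(traj), "nm")
}

#' Radius of gyration series
#'
#' Per-frame Rg (nm): sqrt(sum m_i |r_i - r_com|^2 / sum m_i), with
#' per-atom masses taken from the residue-independent element masses,
#' or unweighted when `massWeighted = FALSE`.
#'
#' @param traj A `Trajectory`.
#' @param massWeighted Use atomic masses (default TRUE).
#' @param selection Atom selection (default all).
#' @return A `seriesResult` in nm.
#' @export
radiusOfGyration <- function(traj, massWeighted = TRUE, selection = "all") {
  sel <- .select_atoms(traj@topology, selection)
  if (!length(sel)) stop("empty atom selection")
  elemMass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                S = 32.06, P = 30.974)
  m <- if (massWeighted) {
    mm <- elemMass[atoms(traj@topology)$element[sel]]
    if (anyNA(mm)) stop("unknown element mass in selection")
    mm
  } else rep(1, length(sel))
  if (sum(m) <= 0) stop("zero total mass")
  vals <- vapply(seq_len(nFrames(traj)), function(i) {
    x <- frameCoords(traj, i)[sel, , drop = FALSE]
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, numeric(1)) / 10
  .series("Rg", vals, frameTimes(traj), "nm")
}

#' Per-residue root-mean-square fluctuation
#'
#' Per-atom sqrt(mean |r_i - <r_i>|^2) about the windowed mean
#' structure, after optional superposition of every window frame onto
#' the first window frame (removing rigid-body motion), aggregated to
#' per-residue means. Values in nm.
#'
#' @param traj A `Trajectory` with at least 2 frames in the window.
#' @param selection Atom selection used both for fitting and the
#'   profile (default "all").
#' @param fitFirst Superpose frames before measuring (default TRUE).
#' @param window Optional `c(tStart, tEnd)` in ps restricting the
#'   frames used.
#' @return data.frame with `chain`, `resno`, `resname`, `rmsf` (nm);
#'   per-atom values in attribute `atom_rmsf`.
#' @export
rmsfProfile <- function(traj, selection = "all", fitFirst = TRUE, window = NULL) {
  sel <- .select_atoms(traj@topology, selection)
  if (!length(sel)) stop("empty atom selection")
  t <- frameTimes(traj)
  frames <- seq_len(nFrames(traj))
  if (!is.null(window)) {
    if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
      stop("window [", window[1], ", ", window[2], "] outside trajectory span")
    }
    frames <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  }
  if (length(frames) < 2) stop("need >= 2 frames in window")
  ref <- frameCoords(traj, frames[1])[sel, , drop = FALSE]
  X <- array(0, dim = c(length(sel), 3, length(frames)))
  for (k in seq_along(frames)) {
    x <- frameCoords(traj, frames[k])[sel, , drop = FALSE]
    if (fitFirst) x <- kabschSuperpose(x, ref)$transform(x)
    X[, , k] <- x
  }
  meanX <- apply(X, c(1, 2), mean)
  dev2 <- vapply(seq_along(frames), function(k) rowSums((X[, , k] - meanX)^2),
                 numeric(length(sel)))
  atomRmsf <- sqrt(rowMeans(matrix(dev2, nrow = length(sel)))) / 10
  a <- atoms(traj@topology)[sel, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  res <- unique(data.frame(chain = a$chain, resno = a$resno,
                           resname = a$resname, stringsAsFactors = FALSE))
  res$rmsf <- as.vector(tapply(atomRmsf, factor(key, levels = unique(key)), mean))
  rownames(res) <- NULL
  attr(res, "atom_rmsf") <- atomRmsf
  res
}

#' Per-residue SASA series over a trajectory
#'
#' Per-frame SASA of listed residues (nm^2 in the report), with window
#' averages per residue and over the list.
#'
#' @param traj A `Trajectory`.
#' @param residueList data.frame with `chain`, `resno` columns.
#' @param window Optional `c(tStart, tEnd)` ps window for averaging
#'   (default whole trajectory).
#' @param probe,nPoints Passed to [sasa()].
#' @return List with `series` (frames x residues matrix, nm^2),
#'   `times`, `residueMeans`, `listMean` over the window.
#' @export
sasaSeries <- function(traj, residueList, window = NULL, probe = 1.4,
                       nPoints = 960L) {
  if (NROW(residueList) == 0) {
    return(list(series = matrix(numeric(), nrow = nFrames(traj), ncol = 0),
                times = frameTimes(traj), residueMeans = numeric(),
                listMean = NaN))
  }
  res <- residueTable(traj@topology)
  want <- paste(residueList$chain, residueList$resno)
  miss <- setdiff(want, paste(res$chain, res$resno))
  if (length(miss)) stop("residue(s) not in topology: ", paste(miss, collapse = ", "))
  t <- frameTimes(traj)
  frames <- seq_len(nFrames(traj))
  if (!is.null(window)) frames <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  series <- matrix(NA_real_, nrow = length(frames), ncol = length(want),
                   dimnames = list(NULL, want))
  for (k in seq_along(frames)) {
    prof <- sasa(frameModel(traj, frames[k]), probe = probe, nPoints = nPoints)
    idx <- match(want, paste(prof$residues$chain, prof$residues$resno))
    series[k, ] <- prof$residues$sasa[idx] / 100  # A^2 -> nm^2
  }
  means <- colMeans(series)
  list(series = series, times = t[frames], residueMeans = means,
       listMean = mean(means))
}

#' Hydrogen-bond count series
#'
#' Per-frame count of hydrogen bonds between two chain groups, using
#' the [detectHBonds()] criteria.
#'
#' @inheritParams detectHBonds
#' @param traj A `Trajectory`.
#' @return A `seriesResult` with integer per-frame counts.
#' @export
hbondSeries <- function(traj, groupsA, groupsB, dCut = 3.5, angleCut = 30) {
  vals <- vapply(seq_len(nFrames(traj)), function(i) {
    nrow(suppressMessages(suppressWarnings(
      detectHBonds(frameModel(traj, i), groupsA, groupsB, dCut, angleCut))))
  }, integer(1))
  .series("H-bonds", vals, frameTimes(traj), "count")
}

#' Extract equally spaced snapshots
#'
#' Takes `count` frames at `interval` ps spacing ending at the last
#' frame time (inclusive endpoints): the snapshot protocol applied to
#' the tail of a production run. Targets not matching a frame time
#' exactly are mapped to the nearest frame, with the maximum time error
#' reported in an attribute (and a message when nonzero).
#'
#' @param traj A `Trajectory`.
#' @param interval Snapshot spacing in ps (default 100).
#' @param count Number of snapshots (default 31; 31 snapshots at 100 ps
#'   span the final 3 ns).
#' @return A `Trajectory` of exactly `count` frames; attribute
#'   `max_time_error` in ps.
#' @export
extractSnapshots <- function(traj, interval = 100, count = 31L) {
  t <- frameTimes(traj)
  tEnd <- t[length(t)]
  targets <- tEnd - (count - seq_len(count)) * interval
  if (targets[1] < t[1] - 1e-9) {
    stop("requested window (", (count - 1) * interval,
         " ps) longer than trajectory span (", tEnd - t[1], " ps)")
  }
  idx <- vapply(targets, function(tt) which.min(abs(t - tt)), integer(1))
  err <- max(abs(t[idx] - targets))
  if (err > 1e-9) message(sprintf("snapshot targets mapped to nearest frames; max time error %.3g ps", err))
  out <- trajectory(traj@topology, traj@xyz[, , idx, drop = FALSE],
                    times = t[idx])
  attr(out, "max_time_error") <- err
  out
}
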