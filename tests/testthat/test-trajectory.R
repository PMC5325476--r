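# Base structures for trajectory tests are small planted complexes
# (single-heavy-atom residues), which keeps every observable cheap.
simple_base <- function(nres = 12, seed = 1) {
  makePlantedComplex(plantedComplexSpec(icCounts = c(aa = nres / 2), seed = seed))
}

rigid_move <- function(x, theta = 0.6, shift = c(4, -2, 9)) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  sweep(x %*% t(R), 2, shift, "+")
}

test_that("multi-model PDB reading enforces consistent topology", {
  base <- simple_base(8, seed = 21)
  tr <- makeSyntheticTrajectory(syntheticTrajectorySpec(base, sigma = 0.02,
                                                        nFrames = 3, dt = 10, seed = 2))
  f <- tempfile(fileext = ".pdb")
  writeMultiModelPDB(tr, f)
  tr2 <- readMultiModelPDB(f, dt = 10)
  expect_identical(nFrames(tr2), 3L)
  expect_identical(frameTimes(tr2), c(0, 10, 20))
  expect_lt(max(abs(tr2@xyz - tr@xyz)), 1e-3)
  # single-model file is a valid 1-frame trajectory
  f1 <- tempfile(fileext = ".pdb")
  writePDB(base, f1)
  expect_identical(nFrames(readMultiModelPDB(f1)), 1L)
  # a model with a divergent atom count is rejected with its number
  lines <- readLines(f)
  atomLines <- grep("^ATOM", lines)
  bad <- lines[-atomLines[length(atomLines)]]  # drop one atom of model 3
  f3 <- tempfile(fileext = ".pdb")
  writeLines(bad, f3)
  expect_error(readMultiModelPDB(f3), "model 3")
})

test_that("Kabsch superposition recovers rigid transformations exactly", {
  set.seed(31)
  x <- matrix(rnorm(30, sd = 5), ncol = 3)
  idfit <- kabschSuperpose(x, x)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-10)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-10)
  moved <- rigid_move(x)
  fit <- kabschSuperpose(moved, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$transform(moved), x, tolerance = 1e-8)
  # hand-checkable 4-point planar case: pure 90-degree rotation
  sq <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  rot90 <- cbind(-sq[, 2], sq[, 1], sq[, 3])
  fit90 <- kabschSuperpose(rot90, sq)
  expect_equal(fit90$rmsd, 0, tolerance = 1e-10)
  expect_error(kabschSuperpose(rbind(c(0, 0, 0), c(1, 1, 1)), sq[1:2, ]),
               "at least 3")
  # noisy optimum agrees with the independent bio3d fit
  y <- x + matrix(rnorm(30, sd = 0.3), ncol = 3)
  ours <- kabschSuperpose(y, x)$rmsd
  ref <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("RMSD series is zero for identical or rigidly moved frames", {
  base <- simple_base(10, seed = 22)
  x <- coords(base)
  frames <- list(x, x, rigid_move(x, 0.4), rigid_move(x, 1.2, c(-8, 3, 2)))
  tr <- trajectory(base, frames, dt = 5)
  out <- rmsdSeries(tr, selection = "all")
  expect_equal(out$values, rep(0, 4), tolerance = 1e-10)
  expect_identical(out$unit, "nm")
  expect_error(rmsdSeries(tr, selection = integer(0)), "selection")
})

test_that("RMSD of isotropically noised frames concentrates at sigma*sqrt(3)", {
  set.seed(5)
  n <- 600
  x <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
  a <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA", atom = "CA",
                  element = "C", x = x[, 1], y = x[, 2], z = x[, 3])
  base <- structureModel(a)
  sigma <- 0.4  # Angstrom, per coordinate
  frames <- c(list(x), lapply(1:20, function(i) x + matrix(rnorm(3 * n, sd = sigma), ncol = 3)))
  tr <- trajectory(base, frames)
  vals <- rmsdSeries(tr, selection = "all")$values[-1] * 10  # nm -> A
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.05)
})

test_that("radius of gyration matches closed forms and scales linearly", {
  # two equal masses at distance d: Rg = d/2
  m2 <- makeSphereCluster(c(1.7, 1.7), rbind(c(0, 0, 0), c(6, 0, 0)))
  tr2 <- trajectory(m2, list(coords(m2)))
  expect_equal(radiusOfGyration(tr2)$values, 0.3, tolerance = 1e-12)
  # single atom: Rg = 0
  m1 <- makeSphereCluster(1.7, c(3, 1, 2))
  expect_equal(radiusOfGyration(trajectory(m1, list(coords(m1))))$values, 0)
  # uniform ring of radius a has Rg = a
  k <- 360
  ring <- cbind(10 * cos(2 * pi * seq_len(k) / k), 10 * sin(2 * pi * seq_len(k) / k), 0)
  mr <- makeSphereCluster(rep(1.7, k), ring)
  expect_equal(radiusOfGyration(trajectory(mr, list(ring)))$values, 1.0,
               tolerance = 1e-9)
  # linear scaling of coordinates
  expect_equal(radiusOfGyration(trajectory(mr, list(2.5 * ring)))$values, 2.5,
               tolerance = 1e-9)
  # mass weighting: unequal elements shift Rg toward the heavy atom
  a <- atoms(m2); a$element <- c("C", "H"); m3 <- structureModel(a)
  tr3 <- trajectory(m3, list(coords(m3)))
  expect_lt(radiusOfGyration(tr3, massWeighted = TRUE)$values,
            radiusOfGyration(tr3, massWeighted = FALSE)$values)
})

test_that("RMSF recovers a planted step amplitude profile within 5%", {
  base <- simple_base(40, seed = 23)
  nres <- nrow(residueTable(base))
  sigma <- rep(c(0.01, 0.05), length.out = nres)  # nm, step profile
  spec <- syntheticTrajectorySpec(base, sigma = sigma, nFrames = 2000,
                                  dt = 1, seed = 77)
  tr <- makeSyntheticTrajectory(spec)
  prof <- rmsfProfile(tr, fitFirst = FALSE)
  expected <- sigma * sqrt(3)
  expect_identical(nrow(prof), nres)
  expect_lt(max(abs(prof$rmsf - expected) / expected), 0.05)
})

test_that("RMSF is zero for static frames and for fitted rigid-body motion", {
  base <- simple_base(10, seed = 24)
  x <- coords(base)
  trStatic <- trajectory(base, list(x, x, x))
  expect_true(all(rmsfProfile(trStatic)$rmsf == 0))
  drift <- lapply(0:5, function(k) rigid_move(x, 0.1 * k, c(2 * k, 0, 0)))
  trDrift <- trajectory(base, drift)
  expect_lt(max(rmsfProfile(trDrift, fitFirst = TRUE)$rmsf), 1e-8)
  expect_gt(max(rmsfProfile(trDrift, fitFirst = FALSE)$rmsf), 0.05)
  expect_error(rmsfProfile(trStatic, window = c(0, 100)), "window")
})

test_that("SASA series tracks an approaching occluder monotonically", {
  target <- c(0, 0, 0)
  frames <- lapply(c(100, 12, 6, 4.5), function(d) rbind(target, c(d, 0, 0)))
  base <- makeSphereCluster(c(1.7, 1.7), frames[[1]])
  tr <- trajectory(base, frames)
  out <- sasaSeries(tr, data.frame(chain = "A", resno = 1L))
  expect_identical(dim(out$series), c(4L, 1L))
  expect_true(all(diff(out$series[, 1]) <= 0))
  expect_lt(out$series[4, 1], out$series[1, 1])
  # static single atom: constant closed-form series
  one <- makeSphereCluster(1.7, c(0, 0, 0))
  trOne <- trajectory(one, list(coords(one), coords(one)))
  sOne <- sasaSeries(trOne, data.frame(chain = "A", resno = 1L))
  expect_equal(sOne$series[, 1], rep(4 * pi * 3.1^2 / 100, 2), tolerance = 0.01)
  # empty residue list and unknown residues
  expect_identical(ncol(sasaSeries(trOne, data.frame(chain = character(),
                                                     resno = integer()))$series), 0L)
  expect_error(sasaSeries(trOne, data.frame(chain = "Z", resno = 1L)), "not in topology")
})

test_that("H-bond series counts planted geometries frame by frame", {
  g0 <- makeHBondGeometry(4.5, 10)   # too far: 0 bonds
  g1 <- makeHBondGeometry(2.9, 10)   # 1 bond
  x0 <- coords(g0); x1 <- coords(g1)
  # frame with 2 bonds: tighten and also move H onto the axis
  x2 <- x1; x2[2, 1] <- 2.8
  base <- g0
  tr <- trajectory(base, list(x0, x1, x2))
  out <- hbondSeries(tr, "A", "B")
  expect_identical(out$values[1:2], c(0L, 1L))
  expect_gte(out$values[3], 1L)
  expect_identical(length(out$values), nFrames(tr))
  # no polar atoms at all: all zeros
  apol <- makeSphereCluster(c(1.7, 1.7), rbind(c(0, 0, 0), c(3, 0, 0)))
  a <- atoms(apol); a$chain <- c("A", "B")
  trA <- trajectory(structureModel(a), list(as.matrix(a[, c("x", "y", "z")])))
  expect_identical(hbondSeries(trA, "A", "B")$values, 0L)
})

test_that("snapshot extraction takes equally spaced frames from the tail", {
  base <- simple_base(6, seed = 25)
  nf <- 201  # 20 ns at 100-ps steps
  x <- coords(base)
  tr <- trajectory(base, replicate(nf, x, simplify = FALSE), dt = 100)
  snap <- extractSnapshots(tr, interval = 100, count = 31)
  expect_identical(nFrames(snap), 31L)
  expect_equal(frameTimes(snap), seq(17000, 20000, by = 100))
  expect_equal(attr(snap, "max_time_error"), 0)
  # count = 1 takes the last frame only
  last <- extractSnapshots(tr, interval = 100, count = 1)
  expect_identical(frameTimes(last), 20000)
  # non-commensurate stride maps to nearest frames with a reported error
  tr2 <- trajectory(base, replicate(41, x, simplify = FALSE), dt = 7)
  expect_message(s2 <- extractSnapshots(tr2, interval = 10, count = 5),
                 "nearest")
  expect_identical(nFrames(s2), 5L)
  expect_lte(attr(s2, "max_time_error"), 3.5)
  expect_error(extractSnapshots(tr2, interval = 100, count = 31), "longer than")
})

test_that("observables are invariant under a global rigid move of every frame", {
  base <- simple_base(10, seed = 26)
  tr <- makeSyntheticTrajectory(syntheticTrajectorySpec(base, sigma = 0.03,
                                                        nFrames = 40, seed = 9))
  moved <- trajectory(base, lapply(seq_len(nFrames(tr)), function(i) {
    rigid_move(frameCoords(tr, i), 0.8, c(12, -7, 3))
  }))
  expect_equal(rmsdSeries(moved, selection = "all")$values,
               rmsdSeries(tr, selection = "all")$values, tolerance = 1e-8)
  expect_equal(radiusOfGyration(moved)$values, radiusOfGyration(tr)$values,
               tolerance = 1e-9)
  expect_equal(rmsfProfile(moved)$rmsf, rmsfProfile(tr)$rmsf, tolerance = 1e-8)
})
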