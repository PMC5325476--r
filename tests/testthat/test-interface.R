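test_that("PDB round-trip preserves atoms, residues and coordinates", {
  m <- makePlantedComplex(plantedComplexSpec(
    icCounts = c(cc = 2, aa = 3), nisCounts = c(charged = 1, polar = 2, apolar = 1),
    seed = 4))
  f <- tempfile(fileext = ".pdb")
  writePDB(m, f)
  m2 <- readPDB(f)
  expect_identical(nAtoms(m2), nAtoms(m))
  expect_identical(residueTable(m2), residueTable(m))
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
  # waters in HETATM records are excluded by default
  lines <- readLines(f)
  lines <- append(lines, "HETATM 9999  O   HOH W 500      99.000  99.000  99.000  1.00  0.00           O",
                  after = length(lines) - 1)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  expect_identical(nAtoms(readPDB(f2)), nAtoms(m))
  expect_identical(nAtoms(readPDB(f2, keepHetatm = TRUE)), nAtoms(m) + 1L)
  # empty file rejected
  f3 <- tempfile(fileext = ".pdb")
  writeLines(character(), f3)
  expect_error(readPDB(f3))
})

test_that("residue polarity classes partition the 20 residues", {
  expect_identical(residueClass("ARG"), "charged")
  expect_identical(residueClass("SER"), "polar")
  expect_identical(residueClass("TRP"), "apolar")
  cls <- residueClass(aminoAcids())
  expect_identical(as.vector(table(factor(cls, c("charged", "polar", "apolar")))),
                   c(5L, 5L, 10L))
  expect_error(residueClass("XYZ"), "non-canonical")
  expect_identical(residueClass("MSE", unknown = "apolar"), "apolar")
})

test_that("interface contacts equal the brute-force oracle on planted complexes", {
  spec <- plantedComplexSpec(icCounts = c(cc = 4, ca = 16, pp = 2, pa = 4), seed = 1)
  m <- makePlantedComplex(spec)
  ic <- interfaceContacts(m, "A", "B")
  expect_identical(ic$counts,
                   c(cc = 4L, cp = 0L, ca = 16L, pp = 2L, pa = 4L, aa = 0L))
  expect_identical(ic$counts, oracle_contacts(m, "A", "B"))
  expect_identical(sum(ic$counts), nrow(ic$pairs))
  # symmetry under swapping the chain groups
  ic2 <- interfaceContacts(m, "B", "A")
  expect_identical(ic2$counts, ic$counts)
  # chains far apart give all-zero counts
  far <- makePlantedComplex(plantedComplexSpec(
    icCounts = integer(), nisCounts = c(charged = 1, polar = 0, apolar = 2), seed = 2))
  expect_identical(sum(interfaceContacts(far, "A", "B")$counts), 0L)
  expect_error(interfaceContacts(m, "A", "Z"), "empty chain selection")
  expect_error(interfaceContacts(m, "A", "A"), "disjoint")
})

test_that("contacts match the oracle over many random planted specs", {
  set.seed(99)
  for (rep in 1:25) {
    counts <- sample(0:4, 6, replace = TRUE)
    names(counts) <- c("cc", "cp", "ca", "pp", "pa", "aa")
    spec <- plantedComplexSpec(icCounts = counts,
                               nisCounts = c(charged = sample(0:3, 1),
                                             polar = sample(0:3, 1),
                                             apolar = sample(0:3, 1)),
                               seed = rep)
    m <- makePlantedComplex(spec)
    got <- interfaceContacts(m, "A", "B")$counts
    expect_identical(got, oracle_contacts(m, "A", "B"), info = paste("rep", rep))
    expect_identical(as.integer(got), as.integer(counts), info = paste("rep", rep))
  }
})

test_that("NIS composition counts surface residues outside the interface", {
  spec <- plantedComplexSpec(icCounts = c(cc = 2, aa = 2),
                             nisCounts = c(charged = 3, polar = 1, apolar = 4),
                             seed = 5)
  m <- makePlantedComplex(spec)
  ic <- interfaceContacts(m, "A", "B")
  nis <- nisComposition(m, ic, sasa(m))
  expect_identical(nis$nResidues, 8L)
  expect_equal(unname(nis$percent),
               100 * c(3, 1, 4) / 8, tolerance = 1e-9)
  expect_equal(sum(nis$percent), 100, tolerance = 0.01)
  # every-residue-interfacial complex gives the explicit empty-NIS state
  only <- makePlantedComplex(plantedComplexSpec(icCounts = c(aa = 3), seed = 6))
  ic2 <- interfaceContacts(only, "A", "B")
  nis2 <- nisComposition(only, ic2, sasa(only))
  expect_true(nis2$empty)
  expect_true(all(is.na(nis2$percent)))
  expect_error(deltaGInteraction(ic2, nis2), "empty")
})

test_that("buried residues are excluded from the NIS set by the rSASA threshold", {
  # a central atom fully caged by 26 neighbours is buried
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2.2
  m <- makeSphereCluster(rep(1.7, 27), offs)
  prof <- sasa(m)
  centre <- which(rowSums(abs(offs)) == 0)
  rsa <- 100 * prof$residues$sasa / 129  # ALA reference
  expect_lt(rsa[centre], 5)
  ic <- list(pairs = data.frame(chainA = character(), resnoA = integer(),
                                chainB = character(), resnoB = integer()))
  nis <- nisComposition(m, ic, prof)
  # the caged centre never counts; corners and edges (at least) do
  expect_lte(nis$nResidues, 26L)
  expect_gte(nis$nResidues, 8L)
  expect_false(nis$empty)
})

test_that("the interaction free energy linear model matches hand arithmetic", {
  z <- c(charged = 0, apolar = 0)
  expect_equal(deltaGInteraction(c(cc = 0), z)$dG, -15.9433, tolerance = 1e-12)
  expect_equal(deltaGInteraction(c(cc = 1), z)$dG, -15.9433 - 0.09459,
               tolerance = 1e-12)
  # the published contact/surface inputs of the first optimized peptide
  dg <- deltaGInteraction(c(cc = 4, ca = 16, pp = 2, pa = 4),
                          c(charged = 27.54, apolar = 38.42))$dG
  hand <- -0.09459 * 4 - 0.10007 * 16 + 0.19577 * 2 - 0.22671 * 4 +
    0.18681 * 38.42 + 0.3810 * 27.54 - 15.9433
  expect_equal(dg, hand, tolerance = 1e-12)
  expect_equal(dg, -0.768, tolerance = 1e-3)
  # alternate coefficient set only changes the %NIS-charged weight
  dgAlt <- deltaGInteraction(c(cc = 4, ca = 16, pp = 2, pa = 4),
                             c(charged = 27.54, apolar = 38.42),
                             coefficientSet = "alternate")$dG
  expect_equal(dgAlt - dg, (0.13810 - 0.3810) * 27.54, tolerance = 1e-9)
  # cp and aa counts are carried but unweighted
  expect_equal(deltaGInteraction(c(cc = 1, cp = 9, aa = 9), z)$dG,
               deltaGInteraction(c(cc = 1), z)$dG, tolerance = 1e-12)
})

test_that("dG model is exactly additive over contact increments", {
  z <- c(charged = 0, apolar = 0)
  base <- deltaGInteraction(c(cc = 0), z)$dG
  for (k in c("cc", "ca", "pp", "pa")) {
    ic1 <- stats::setNames(1, k)
    ic3 <- stats::setNames(3, k)
    step <- deltaGInteraction(ic1, z)$dG - base
    expect_equal(deltaGInteraction(ic3, z)$dG, base + 3 * step, tolerance = 1e-12)
  }
})

test_that("Kd conversion matches the thermodynamically consistent printed values", {
  expect_equal(kdFromDg(0), 1)
  expect_equal(signif(kdFromDg(-8.3), 2), 8.2e-7)
  expect_equal(round(dgFromKd(1.1e-6), 1), -8.1)
  expect_lt(abs(kdFromDg(-8.1) - 1.1e-6) / 1.1e-6, 0.05)
  # round trip to 1e-12 relative, both ways
  for (dg in c(-15, -8.3, -0.5, 0, 2)) {
    expect_equal(dgFromKd(kdFromDg(dg)), dg, tolerance = 1e-12)
  }
  for (kd in 10^seq(-9, 0, by = 3)) {
    expect_equal(kdFromDg(dgFromKd(kd)) / kd, 1, tolerance = 1e-12)
  }
  # strictly increasing in dG
  dgs <- seq(-12, 0, by = 0.5)
  expect_true(all(diff(kdFromDg(dgs)) > 0))
  expect_error(kdFromDg(-8, temperature = 0), "positive")
})

test_that("hydrogen bonds follow the distance and angle criteria", {
  expect_identical(nrow(detectHBonds(makeHBondGeometry(2.9, 10), "A", "B")), 1L)
  expect_identical(nrow(detectHBonds(makeHBondGeometry(4.5, 10), "A", "B")), 0L)
  expect_identical(nrow(detectHBonds(makeHBondGeometry(2.9, 50), "A", "B")), 0L)
  # without hydrogens, detection degrades to distance only
  expect_identical(nrow(suppressMessages(
    detectHBonds(makeHBondGeometry(2.9, 50, withHydrogen = FALSE), "A", "B"))), 1L)
  # grid of k compliant pairs counts exactly k
  k <- 4L
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(chain = c("A", "B"), resno = i, resname = c("ASN", "SER"),
               atom = c("ND2", "OG"), element = c("N", "O"),
               x = c(0, 2.9), y = i * 20, z = 0)
  }))
  m <- structureModel(rows)
  expect_identical(nrow(suppressMessages(detectHBonds(m, "A", "B"))), k)
  # apolar-only selection warns and returns no bonds
  apol <- makeSphereCluster(c(1.7, 1.7), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_warning(out <- detectHBonds(apol, "A", "A"), "polar")
  expect_identical(nrow(out), 0L)
})

test_that("burial report localizes an occluder to the affected residue", {
  free <- makeSphereCluster(rep(1.7, 3), rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)))
  profFree <- sasa(free)
  # identical profiles give zero everywhere
  rl <- residueTable(free)[, c("chain", "resno")]
  rep0 <- burialReport(profFree, profFree, rl)
  expect_true(all(rep0$delta_sasa == 0))
  # occluder over residue 2 only
  occl <- makeSphereCluster(rep(1.7, 4),
                            rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0), c(50, 3, 0)))
  profOccl <- sasa(occl)
  rep1 <- burialReport(profFree, profOccl, rl)
  expect_gt(rep1$delta_sasa[rep1$resno == 2], 0)
  expect_equal(rep1$delta_sasa[rep1$resno == 1], 0, tolerance = 1e-9)
  expect_equal(rep1$delta_sasa[rep1$resno == 3], 0, tolerance = 1e-9)
  # empty list and missing residues are explicit
  expect_identical(nrow(burialReport(profFree, profOccl, rl[0, ])), 0L)
  repm <- burialReport(profFree, profOccl, data.frame(chain = "Z", resno = 9L))
  expect_true(repm$missing)
})
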