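# Independent brute-force oracles used against the package
# implementations. These deliberately share no code with R/: plain
# double loops and closed forms.

# O(n^2) residue-pair contact oracle: min heavy-atom distance per
# residue pair, counted by unordered polarity class pair.
oracle_contacts <- function(model, chainsA, chainsB, cutoff = 5.5) {
  a <- atoms(model)
  a <- a[a$element != "H", ]
  A <- a[a$chain %in% chainsA, ]
  B <- a[a$chain %in% chainsB, ]
  resA <- unique(paste(A$chain, A$resno))
  resB <- unique(paste(B$chain, B$resno))
  counts <- c(cc = 0L, cp = 0L, ca = 0L, pp = 0L, pa = 0L, aa = 0L)
  classify <- function(resname) {
    aa1 <- c(D = "charged", E = "charged", K = "charged", R = "charged", H = "charged",
             N = "polar", Q = "polar", S = "polar", T = "polar", Y = "polar")
    three <- c(ASP = "D", GLU = "E", LYS = "K", ARG = "R", HIS = "H",
               ASN = "N", GLN = "Q", SER = "S", THR = "T", TYR = "Y",
               ALA = "A", CYS = "C", PHE = "F", GLY = "G", ILE = "I",
               LEU = "L", MET = "M", PRO = "P", VAL = "V", TRP = "W")
    code <- three[[toupper(resname)]]
    if (code %in% names(aa1)) aa1[[code]] else "apolar"
  }
  rankOf <- c(charged = 1, polar = 2, apolar = 3)
  for (ra in resA) for (rb in resB) {
    ia <- which(paste(A$chain, A$resno) == ra)
    ib <- which(paste(B$chain, B$resno) == rb)
    touching <- FALSE
    for (i in ia) {
      for (j in ib) {
        d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
        if (d <= cutoff) { touching <- TRUE; break }
      }
      if (touching) break
    }
    if (touching) {
      cls <- sort(rankOf[c(classify(A$resname[ia[1]]), classify(B$resname[ib[1]]))])
      key <- paste0(c("c", "p", "a")[cls[1]], c("c", "p", "a")[cls[2]])
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# Accessible area of two intersecting spheres of expanded radii R1, R2
# at centre distance d (each loses one spherical cap).
oracle_two_sphere_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  # cap heights from the radical plane
  x <- (d^2 - R2^2 + R1^2) / (2 * d)
  h1 <- R1 - x
  h2 <- R2 - (d - x)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Exhaustive search over the allowed substitution space of a seed
# (keep-or-substitute per position), returning the best scoring
# sequence under a scorer.
oracle_best_sequence <- function(seed, scorer, config, matrix = blosum62()) {
  allowed <- allowedSubstitutions(seed, config, matrix)
  opts <- lapply(seq_len(nchar(seed)), function(i) {
    c(substr(seed, i, i), allowed[[i]])
  })
  grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  seqs <- do.call(paste0, grid)
  scores <- vapply(seqs, scorer, numeric(1))
  list(sequence = seqs[which.min(scores)], score = min(scores),
       all = data.frame(sequence = seqs, score = scores))
}

# Small helper: peptide built from a random draw of residues.
random_peptide <- function(n, seed) {
  set.seed(seed)
  paste(sample(aminoAcids(), n, replace = TRUE), collapse = "")
}
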