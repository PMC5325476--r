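# Sequence-level physicochemical property calculators: the design
# filters applied to every candidate peptide (GRAVY, instability index,
# charge model, pI, aliphatic index, molecular weight, aggregation
# hot spots, and a configurable solubility heuristic).

#' Validate a peptide sequence
#'
#' Checks that a sequence is a single string of length >= 2 over the
#' 20-letter amino-acid alphabet and returns it as an upper-case
#' character scalar. All property calculators call this first.
#'
#' @param seq Character scalar (one-letter codes).
#' @param minLength Minimum accepted length.
#' @return The validated upper-case sequence, invisibly usable.
#' @export
validatePeptide <- function(seq, minLength = 2L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string")
  }
  seq <- toupper(seq)
  if (nchar(seq) < minLength) {
    stop("sequence must have length >= ", minLength, " (got ", nchar(seq), ")")
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% aminoAcids()))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  seq
}

.seq_chars <- function(seq, minLength = 2L) {
  strsplit(validatePeptide(seq, minLength), "")[[1]]
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values. Positive GRAVY
#' indicates a hydrophobic peptide, negative a hydrophilic one.
#'
#' @param seq Peptide sequence (one-letter codes).
#' @param scale Named numeric hydropathy scale; Kyte-Doolittle default.
#' @return Dimensionless numeric scalar.
#' @examples
#' gravy("FQRGLLFPVCT")  # 0.836
#' @export
gravy <- function(seq, scale = kyteDoolittle()) {
  chars <- .seq_chars(seq, minLength = 1L)
  if (!all(chars %in% names(scale))) stop("hydropathy scale incomplete for sequence")
  mean(scale[chars])
}

#' Instability index
#'
#' Dipeptide-weight statistic of in vitro stability:
#' (10 / L) * sum over consecutive ordered pairs of DIWV(x_i, x_{i+1}).
#' Values below 40 classify the peptide as stable.
#'
#' @param seq Peptide sequence, length >= 2.
#' @param diwv 20 x 20 dipeptide weight matrix, see [diwvTable()].
#' @return Numeric scalar with attribute `stable` (logical, `< 40` rule).
#' @examples
#' instabilityIndex("FQRGLLFPVCT")  # 66.03, unstable
#' @export
instabilityIndex <- function(seq, diwv = diwvTable()) {
  chars <- .seq_chars(seq)
  n <- length(chars)
  idx <- cbind(chars[-n], chars[-1])
  val <- 10 / n * sum(diwv[idx])
  attr(val, "stable") <- val < 40
  val
}

#' Is a peptide stable by the instability-index rule?
#' @inheritParams instabilityIndex
#' @return Logical: instability index < 40.
#' @export
isStable <- function(seq, diwv = diwvTable()) {
  as.vector(instabilityIndex(seq, diwv)) < 40
}

# Counts of each ionizable group in a sequence (including termini).
.ionizable_counts <- function(chars, pka) {
  counts <- integer(nrow(pka))
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    counts[i] <- if (g %in% c("Nterm", "Cterm")) 1L else sum(chars == g)
  }
  counts
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch charge model: each basic group contributes
#' +1 / (1 + 10^(pH - pKa)), each acidic group contributes
#' -1 / (1 + 10^(pKa - pH)); termini count once each.
#'
#' @param seq Peptide sequence.
#' @param pH pH in (0, 14).
#' @param pka pKa set data frame, see [defaultPKaSet()].
#' @return Net charge in elementary charges (full precision).
#' @examples
#' round(netCharge("WQKGKQGALDR"), 1)  # 2.0
#' @export
netCharge <- function(seq, pH = 7, pka = defaultPKaSet()) {
  if (!is.numeric(pH) || pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  chars <- .seq_chars(seq)
  n <- .ionizable_counts(chars, pka)
  basic <- pka$kind == "basic"
  pos <- sum(n[basic] / (1 + 10^(pH - pka$pka[basic])))
  neg <- sum(n[!basic] / (1 + 10^(pka$pka[!basic] - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which the net charge crosses zero, found by bisection on
#' (0, 14) to 1e-3 pH units. The charge is strictly decreasing in pH,
#' so the root is unique when it exists.
#'
#' @inheritParams netCharge
#' @param tol Bisection tolerance in pH units.
#' @return pH units, or `NA_real_` when the charge does not change sign
#'   on the interval (reported as undefined).
#' @export
isoelectricPoint <- function(seq, pka = defaultPKaSet(), tol = 1e-3) {
  f <- function(p) netCharge(seq, p, pka)
  lo <- 1e-6; hi <- 14 - 1e-6
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Aliphatic index
#'
#' 100 * (f_A + 2.9 f_V + 3.9 (f_I + f_L)) with f the mole fractions of
#' alanine, valine, isoleucine and leucine.
#' @inheritParams gravy
#' @return Dimensionless numeric scalar.
#' @export
aliphaticIndex <- function(seq) {
  chars <- .seq_chars(seq, minLength = 1L)
  f <- function(a) mean(chars == a)
  100 * (f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L")))
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#' @inheritParams gravy
#' @return Mass in Daltons.
#' @export
molecularWeight <- function(seq) {
  chars <- .seq_chars(seq, minLength = 1L)
  sum(.residueMasses()[chars]) + 18.0153
}

#' Aggregation hot spots
#'
#' Sliding-window scan of per-residue aggregation propensities. A hot
#' spot is a maximal run of at least `minRun` consecutive positions
#' whose window-averaged propensity exceeds `threshold`, containing no
#' proline. Window values are assigned to window centres; positions
#' within half a window of either end take the nearest full window.
#'
#' @param seq Peptide sequence with length >= `window`.
#' @param scale Named propensity scale, see [aggrescanScale()].
#' @param window Odd window width (residues).
#' @param threshold Hot-spot threshold; defaults to the scale average.
#' @param minRun Minimum run length to call a hot spot.
#' @return data.frame with columns `start`, `end` (possibly 0 rows) and
#'   attributes `threshold` and `scale_dependent = TRUE`.
#' @export
aggregationHotspots <- function(seq, scale = aggrescanScale(), window = 5L,
                                threshold = NULL, minRun = 5L) {
  chars <- .seq_chars(seq, minLength = 1L)
  n <- length(chars)
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  if (is.null(threshold)) threshold <- mean(scale)
  vals <- scale[chars]
  half <- (window - 1L) %/% 2L
  centre <- vapply(seq_len(n), function(i) {
    lo <- min(max(1L, i - half), n - window + 1L)
    mean(vals[lo:(lo + window - 1L)])
  }, numeric(1))
  hot <- centre > threshold & chars != "P"
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= minRun
  out <- data.frame(start = starts[keep], end = ends[keep])
  attr(out, "threshold") <- threshold
  attr(out, "scale_dependent") <- TRUE
  out
}

#' Water-solubility heuristic
#'
#' Explicit, versioned replacement for closed-source solubility
#' predictors. Default rule (`"charged-fraction-v1"`): Good iff the
#' fraction of charged residues (D, E, K, R, H) is at least 0.25, OR
#' the absolute net charge at pH 7 is at least 1 while GRAVY is
#' negative; otherwise Poor.
#'
#' @inheritParams netCharge
#' @param chargedFraction Minimum charged-residue fraction.
#' @param minAbsCharge,maxGravy Thresholds of the second clause.
#' @return "Good" or "Poor", with attribute `rule` naming the rule
#'   version.
#' @export
solubilityEstimate <- function(seq, pka = defaultPKaSet(),
                               chargedFraction = 0.25,
                               minAbsCharge = 1, maxGravy = 0) {
  chars <- .seq_chars(seq)
  frac <- mean(chars %in% c("D", "E", "K", "R", "H"))
  good <- frac >= chargedFraction ||
    (abs(netCharge(seq, 7, pka)) >= minAbsCharge && gravy(seq) < maxGravy)
  out <- if (good) "Good" else "Poor"
  attr(out, "rule") <- "charged-fraction-v1"
  out
}

#' Full property record for one peptide
#'
#' Computes every design-filter property for a peptide: GRAVY,
#' instability index and stability call, net charge at a stated pH, pI,
#' aliphatic index, molecular weight, solubility call and aggregation
#' hot spots.
#'
#' @inheritParams netCharge
#' @param id Free-text identifier carried into the record.
#' @return One-row data.frame (a property record); hot-spot runs are
#'   stored in the `hotspots` attribute.
#' @export
peptideProperties <- function(seq, id = seq, pH = 7, pka = defaultPKaSet()) {
  seq <- validatePeptide(seq)
  ii <- instabilityIndex(seq)
  hs <- aggregationHotspots(seq)
  rec <- data.frame(
    id = id,
    sequence = seq,
    length = nchar(seq),
    gravy = gravy(seq),
    instability_index = as.vector(ii),
    stable = attr(ii, "stable"),
    net_charge = netCharge(seq, pH, pka),
    pH = pH,
    pI = isoelectricPoint(seq, pka),
    aliphatic_index = aliphaticIndex(seq),
    molecular_weight = molecularWeight(seq),
    solubility = as.vector(solubilityEstimate(seq, pka)),
    n_hotspots = nrow(hs),
    stringsAsFactors = FALSE
  )
  attr(rec, "hotspots") <- hs
  attr(rec, "pka_set") <- attr(pka, "pka_set")
  rec
}

#' Property table for a set of peptides
#'
#' @param seqs Named character vector of sequences (names become ids).
#' @inheritParams peptideProperties
#' @return data.frame with one row per peptide, in input order.
#' @export
propertyTable <- function(seqs, pH = 7, pka = defaultPKaSet()) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- seqs
  out <- do.call(rbind, Map(function(s, i) peptideProperties(s, i, pH, pka),
                            unname(seqs), ids))
  rownames(out) <- NULL
  out
}
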