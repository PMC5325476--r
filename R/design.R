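# The affinity-maturation loop: BLOSUM62-constrained single-position
# substitution scanning against a pluggable binding scorer (lower =
# stronger binding), favorability classification with a neutral band,
# exhaustive recombination of favorable substitutions, and
# multi-criteria filtering/ranking of candidates.

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by NCBI tools (comment
#' lines starting with '#', a header row of residue letters, one row
#' per residue). Restricted to the 20 canonical residues.
#'
#' @param path Matrix file; defaults to the bundled BLOSUM62.
#' @return Symmetric integer matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("blosum62.txt")
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(NA_integer_, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, "", 1), cols))
  for (i in seq_along(rows)) m[i, ] <- as.integer(rows[[i]][-1])
  keep <- intersect(rownames(m), aminoAcids())
  m <- m[keep, keep]
  if (!all(aminoAcids() %in% rownames(m))) stop("matrix incomplete over the 20 residues")
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  m
}

#' Bundled BLOSUM62 matrix
#' @return 20 x 20 symmetric integer matrix.
#' @export
blosum62 <- function() {
  .cached_table("blosum62", function() readSubstitutionMatrix())
}

#' Design-loop configuration
#'
#' @param frozenPositions Integer vector of 1-based positions never
#'   mutated (key receptor-contacting residues).
#' @param excludedScore Substitutions with matrix score <= this value
#'   are omitted as deleterious (default -4, the BLOSUM62 minimum).
#' @param neutralBand Score change below which a substitution is
#'   neutral, in the active scorer's units (default 100).
#' @param maxCandidates Cap on enumerated combinations; beyond it,
#'   seeded uniform sampling with the shortfall logged.
#' @param seed RNG seed for any sampling.
#' @return Object of class `designConfig`.
#' @export
designConfig <- function(frozenPositions = integer(), excludedScore = -4,
                         neutralBand = 100, maxCandidates = 10000L,
                         seed = 1L) {
  stopifnot(neutralBand >= 0)
  structure(list(frozenPositions = as.integer(frozenPositions),
                 excludedScore = excludedScore, neutralBand = neutralBand,
                 maxCandidates = as.integer(maxCandidates),
                 seed = as.integer(seed)),
            class = "designConfig")
}

#' Allowed substitutions per position
#'
#' For each non-frozen position with residue X, the residues Y != X
#' with matrix(X, Y) > `excludedScore`; frozen positions map to empty
#' sets.
#'
#' @param seq Seed peptide sequence.
#' @param config A `designConfig`.
#' @param matrix Substitution matrix (default bundled BLOSUM62).
#' @return Named list (position -> character vector of residues).
#' @export
allowedSubstitutions <- function(seq, config = designConfig(),
                                 matrix = blosum62()) {
  chars <- .seq_chars(seq)
  n <- length(chars)
  if (length(config$frozenPositions) &&
      any(config$frozenPositions < 1 | config$frozenPositions > n)) {
    stop("frozen position outside sequence (length ", n, ")")
  }
  out <- vector("list", n)
  names(out) <- as.character(seq_len(n))
  for (i in seq_len(n)) {
    if (i %in% config$frozenPositions) {
      out[[i]] <- character()
    } else {
      x <- chars[i]
      alt <- setdiff(aminoAcids(), x)
      out[[i]] <- alt[matrix[x, alt] > config$excludedScore]
    }
  }
  out
}

#' Classify a substitution by score change
#'
#' Lower score = stronger binding: |delta| < band is neutral,
#' delta <= -band favorable, delta >= +band unfavorable.
#'
#' @param delta Score change (variant minus seed), scorer units.
#' @param neutralBand Dead-zone half-width, same units.
#' @return "favorable", "neutral" or "unfavorable" (vectorised).
#' @export
classifySubstitution <- function(delta, neutralBand = 100) {
  stopifnot(all(is.finite(delta)), neutralBand >= 0)
  ifelse(delta <= -neutralBand, "favorable",
         ifelse(delta >= neutralBand, "unfavorable", "neutral"))
}

.apply_subst <- function(seq, pos, res) {
  substr(seq, pos, pos) <- res
  seq
}

#' Single-position substitution scan
#'
#' Scores the seed once and each allowed single-point variant once,
#' labelling every outcome. A scorer failure on a variant marks that
#' outcome `failed` and the scan continues. Deterministic ordering:
#' position, then alphabetical residue.
#'
#' @param seq Seed peptide sequence.
#' @param scorer Function mapping a sequence to a finite scalar score
#'   (lower = better binding); deterministic for fixed inputs.
#' @param config A `designConfig`.
#' @param matrix Substitution matrix.
#' @return data.frame with `position`, `from`, `to`, `score`, `delta`,
#'   `label`; seed score in attribute `seed_score`.
#' @export
scanPositions <- function(seq, scorer, config = designConfig(),
                          matrix = blosum62()) {
  seq <- validatePeptide(seq)
  allowed <- allowedSubstitutions(seq, config, matrix)
  base <- scorer(seq)
  if (!is.finite(base)) stop("scorer returned a non-finite seed score")
  rows <- list()
  for (i in seq_along(allowed)) {
    for (res in sort(allowed[[i]])) {
      variant <- .apply_subst(seq, i, res)
      sc <- tryCatch(scorer(variant), error = function(e) {
        warning("scorer failed on ", variant, ": ", conditionMessage(e))
        NA_real_
      })
      d <- sc - base
      rows[[length(rows) + 1L]] <- data.frame(
        position = i, from = substr(seq, i, i), to = res,
        score = sc, delta = d,
        label = if (is.na(sc)) "failed" else classifySubstitution(d, config$neutralBand),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), from = character(), to = character(),
               score = numeric(), delta = numeric(), label = character())
  rownames(out) <- NULL
  attr(out, "seed_score") <- base
  out
}

#' Recombine favorable substitutions
#'
#' Cartesian product over positions of {keep} plus the favorable
#' residues found there, minus the unmodified seed. The candidate count
#' is prod(1 + k_i) - 1 with k_i favorable options at position i.
#' Exhaustive when that count is within `config$maxCandidates`,
#' otherwise a seeded uniform sample of distinct candidates (shortfall
#' logged).
#'
#' @param seed Seed sequence.
#' @param outcomes Scan table from [scanPositions()].
#' @param config A `designConfig`.
#' @return Character vector of candidate sequences; attribute
#'   `exhaustive` (logical).
#' @export
combineFavorables <- function(seed, outcomes, config = designConfig()) {
  seed <- validatePeptide(seed)
  fav <- outcomes[outcomes$label == "favorable", , drop = FALSE]
  n <- nchar(seed)
  opts <- lapply(seq_len(n), function(i) {
    c(substr(seed, i, i), sort(unique(fav$to[fav$position == i])))
  })
  total <- prod(lengths(opts)) - 1
  if (total <= 0) {
    return(structure(character(), exhaustive = TRUE, total = 0))
  }
  if (total <= config$maxCandidates) {
    grid <- do.call(expand.grid, c(rev(opts), stringsAsFactors = FALSE))
    cand <- do.call(paste0, rev(grid))
    cand <- setdiff(cand, seed)
    return(structure(sort(cand), exhaustive = TRUE, total = total))
  }
  # seeded uniform sampling of distinct non-seed candidates
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  got <- character()
  rounds <- 0L
  while (length(got) < config$maxCandidates && rounds < 50L) {
    batch <- vapply(opts, function(o) {
      o[sample.int(length(o), config$maxCandidates, replace = TRUE)]
    }, character(config$maxCandidates))
    drawn <- apply(batch, 1, paste0, collapse = "")
    got <- unique(c(got, setdiff(drawn, seed)))
    rounds <- rounds + 1L
  }
  got <- got[seq_len(min(length(got), config$maxCandidates))]
  message(sprintf("combination space (%g) exceeds maxCandidates (%d); sampled %d",
                  total, config$maxCandidates, length(got)))
  structure(sort(got), exhaustive = FALSE, total = total)
}

#' Filter and rank design candidates
#'
#' Default filters: instability index < 40; net charge at pH 7 > 0;
#' solubility "Good"; no aggregation hot spot. Survivors are ranked by
#' scorer value ascending, ties broken by higher net charge, then
#' lower instability, then lexicographic sequence.
#'
#' @param candidates data.frame with `sequence` and `score` columns.
#' @param records Property table from [propertyTable()] aligned with
#'   `candidates` (computed when NULL).
#' @param criteria Named logical vector enabling filters: `stability`,
#'   `charge`, `solubility`, `aggregation`.
#' @return Ranked data.frame of survivors joined with their property
#'   records; attrition counts per filter in attribute `attrition`.
#' @export
filterCandidates <- function(candidates, records = NULL,
                             criteria = c(stability = TRUE, charge = TRUE,
                                          solubility = TRUE, aggregation = TRUE)) {
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "attrition") <- c(stability = 0L, charge = 0L,
                                solubility = 0L, aggregation = 0L)
    return(out)
  }
  if (is.null(records)) records <- propertyTable(candidates$sequence)
  stopifnot(nrow(records) == nrow(candidates))
  keep <- rep(TRUE, nrow(candidates))
  attrition <- c(stability = 0L, charge = 0L, solubility = 0L, aggregation = 0L)
  apply_filter <- function(name, pass) {
    if (!isTRUE(criteria[[name]])) return()
    fail <- keep & !pass
    attrition[[name]] <<- sum(fail)
    keep <<- keep & pass
  }
  apply_filter("stability", records$instability_index < 40)
  apply_filter("charge", records$net_charge > 0)
  apply_filter("solubility", records$solubility == "Good")
  apply_filter("aggregation", records$n_hotspots == 0)
  out <- cbind(candidates[keep, , drop = FALSE],
               records[keep, setdiff(names(records), "sequence"), drop = FALSE])
  ord <- order(out$score, -out$net_charge, out$instability_index, out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}

#' Run the full design loop
#'
#' Orchestrates scan -> recombination -> property computation ->
#' filtering -> ranking. Fully reproducible from (inputs, seed).
#'
#' @inheritParams scanPositions
#' @param criteria Passed to [filterCandidates()].
#' @return Object of class `designReport`: list with `seed`,
#'   `seedScore`, `config`, `outcomes`, `candidates` (scored),
#'   `ranked` (filtered + ranked with properties), `attrition`.
#' @export
designRun <- function(seq, scorer, config = designConfig(),
                      matrix = blosum62(),
                      criteria = c(stability = TRUE, charge = TRUE,
                                   solubility = TRUE, aggregation = TRUE)) {
  seq <- validatePeptide(seq)
  outcomes <- scanPositions(seq, scorer, config, matrix)
  cands <- combineFavorables(seq, outcomes, config)
  scored <- data.frame(sequence = cands,
                       score = vapply(cands, scorer, numeric(1), USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  ranked <- filterCandidates(scored, criteria = criteria)
  structure(list(seed = seq, seedScore = attr(outcomes, "seed_score"),
                 config = config, outcomes = outcomes, candidates = scored,
                 ranked = ranked, attrition = attr(ranked, "attrition"),
                 exhaustive = attr(cands, "exhaustive")),
            class = "designReport")
}

#' @export
print.designReport <- function(x, ...) {
  cat("Design run on seed", x$seed, sprintf("(score %.4g)\n", x$seedScore))
  cat(" substitutions scanned:", nrow(x$outcomes),
      "| favorable:", sum(x$outcomes$label == "favorable"), "\n")
  cat(" candidates:", nrow(x$candidates),
      if (isTRUE(x$exhaustive)) "(exhaustive)" else "(sampled)",
      "| pass filters:", nrow(x$ranked), "\n")
  if (nrow(x$ranked)) {
    cat(" top:", x$ranked$sequence[1], sprintf("score %.4g\n", x$ranked$score[1]))
  }
  invisible(x)
}

#' Transparent additive scoring landscape
#'
#' Builds a deterministic scorer assigning each (position, residue)
#' pair an additive contribution; used as the default test landscape
#' and for exhaustive-search cross-checks. Lower = better.
#'
#' @param weights Matrix positions x 20 residues (column names the
#'   amino acids) of additive contributions.
#' @param baseline Constant added to every score.
#' @return Scorer function with attributes `label`, `units`.
#' @export
additiveLandscapeScorer <- function(weights, baseline = 0) {
  stopifnot(!is.null(colnames(weights)), all(colnames(weights) %in% aminoAcids()))
  f <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    stopifnot(length(chars) == nrow(weights))
    baseline + sum(weights[cbind(seq_along(chars), match(chars, colnames(weights)))])
  }
  attr(f, "label") <- "additive-landscape"
  attr(f, "units") <- "arbitrary"
  f
}

#' Interface-energetics scorer adapter
#'
#' Adapts the interfacial-contact binding model to the scorer
#' contract: given a function producing a posed complex
#' `StructureModel` for a candidate sequence, scores the candidate by
#' the model's dG (kcal/mol; lower = stronger). Pose generation
#' (docking) is external to the package.
#'
#' @param poseFun Function: sequence -> `StructureModel` of the posed
#'   complex.
#' @param chainsA,chainsB Chain split of the complex.
#' @param ... Passed to [deltaGInteraction()].
#' @return Scorer function with `label`/`units` attributes.
#' @export
interfaceScorer <- function(poseFun, chainsA, chainsB, ...) {
  f <- function(seq) {
    model <- poseFun(seq)
    ic <- interfaceContacts(model, chainsA, chainsB)
    prof <- sasa(model)
    nis <- nisComposition(model, ic, prof)
    deltaGInteraction(ic, nis, ...)$dG
  }
  attr(f, "label") <- "interface-dG"
  attr(f, "units") <- "kcal/mol"
  f
}
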