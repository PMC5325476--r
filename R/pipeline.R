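# Orchestration: a validated run configuration, stage execution in the
# workflow order (properties -> design -> interface scoring ->
# trajectory observables), and diffable TSV/JSON reports whose headers
# embed the configuration hash and seed. Identical inputs give
# byte-identical outputs.

#' Validated pipeline configuration
#'
#' All thresholds default to the workflow's standard values: 5.5 A
#' contact cutoff, neutral band 100 scorer units, instability cutoff
#' 40, 5% relative-SASA surface threshold, 298.15 K.
#'
#' @param stages Character subset of c("props", "design", "interface",
#'   "traj") to execute, in that order.
#' @param fasta Peptide FASTA path (props/design input); NULL uses the
#'   bundled reference peptides.
#' @param complexPdb Complex PDB path (interface input).
#' @param chainsA,chainsB Chain split of the complex.
#' @param trajectoryPdb Multi-model PDB path (traj input).
#' @param outdir Output directory for reports.
#' @param cutoff,neutralBand,instabilityCutoff,rsaThreshold,temperature
#'   Stage thresholds.
#' @param coefficientSet dG coefficient set ("printed"/"alternate").
#' @param dt Trajectory time step, ps.
#' @param seed RNG seed recorded in every report.
#' @return Object of class `runConfig`.
#' @export
runConfig <- function(stages = "props", fasta = NULL, complexPdb = NULL,
                      chainsA = "A", chainsB = "B", trajectoryPdb = NULL,
                      outdir = tempfile("pepforge-run-"),
                      cutoff = 5.5, neutralBand = 100,
                      instabilityCutoff = 40, rsaThreshold = 5,
                      temperature = 298.15,
                      coefficientSet = "printed", dt = 1, seed = 1L) {
  known <- c("props", "design", "interface", "traj")
  if (!length(stages) || !all(stages %in% known)) {
    stop("stages must be a non-empty subset of: ", paste(known, collapse = ", "))
  }
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (neutralBand < 0) stop("neutralBand must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  if (!coefficientSet %in% c("printed", "alternate")) {
    stop("coefficientSet must be 'printed' or 'alternate'")
  }
  for (p in c(fasta, complexPdb, trajectoryPdb)) {
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  }
  if ("interface" %in% stages && is.null(complexPdb)) {
    stop("stage 'interface' requires complexPdb")
  }
  if ("traj" %in% stages && is.null(trajectoryPdb)) {
    stop("stage 'traj' requires trajectoryPdb")
  }
  structure(list(stages = known[known %in% stages], fasta = fasta,
                 complexPdb = complexPdb, chainsA = chainsA, chainsB = chainsB,
                 trajectoryPdb = trajectoryPdb, outdir = outdir,
                 cutoff = cutoff, neutralBand = neutralBand,
                 instabilityCutoff = instabilityCutoff,
                 rsaThreshold = rsaThreshold, temperature = temperature,
                 coefficientSet = coefficientSet, dt = dt,
                 seed = as.integer(seed)),
            class = "runConfig")
}

# Stable hash of a configuration: md5 of its deparsed value. The
# output directory is excluded so reruns into fresh directories hash
# identically.
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.report_header <- function(config) {
  c(sprintf("# pepforge report"),
    sprintf("# config_hash=%s", .config_hash(config)),
    sprintf("# seed=%d", config$seed),
    sprintf("# cutoff=%g neutral_band=%g instability_cutoff=%g rsa_threshold=%g temperature=%g coefficient_set=%s",
            config$cutoff, config$neutralBand, config$instabilityCutoff,
            config$rsaThreshold, config$temperature, config$coefficientSet))
}

.write_report <- function(df, path, config, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.report_header(config), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Property report in the reference-table layout
#'
#' Columns mirror the published peptide-property table (name,
#' sequence, instability index, GRAVY, net charge at pH 7, water
#' solubility, aggregation hot spot) plus pI, molecular weight and
#' aliphatic index. Missing fields are written as explicit blanks with
#' a warning.
#'
#' @param records Property table from [propertyTable()].
#' @param path Output TSV path.
#' @param config `runConfig` providing the report header.
#' @return `path`, invisibly.
#' @export
reportTable1 <- function(records, path, config = runConfig()) {
  cols <- c(id = "Peptide Name", sequence = "Sequence",
            instability_index = "Instability Index", gravy = "GRAVY",
            net_charge = "Net Charge at pH 7", solubility = "Water Solubility",
            n_hotspots = "Aggregation Hot Spot", pI = "pI",
            molecular_weight = "MW", aliphatic_index = "Aliphatic Index")
  if (nrow(records) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         unname(cols)), check.names = FALSE)
    return(.write_report(out, path, config))
  }
  missing <- setdiff(names(cols), names(records))
  if (length(missing)) {
    warning("missing field(s) written blank: ", paste(missing, collapse = ", "))
    for (m in missing) records[[m]] <- NA
  }
  out <- data.frame(
    records$id, records$sequence,
    sprintf("%.2f", records$instability_index),
    sprintf("%.3f", records$gravy),
    sprintf("%.1f", records$net_charge),
    records$solubility,
    ifelse(records$n_hotspots > 0, "Yes", "No"),
    sprintf("%.2f", records$pI),
    sprintf("%.2f", records$molecular_weight),
    sprintf("%.2f", records$aliphatic_index),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- unname(cols)
  .write_report(out, path, config)
}

#' Interface-energetics report in the reference-table layout
#'
#' One block per complex: dG, Kd, the six interfacial-contact rows and
#' the two non-interacting-surface percentage rows.
#'
#' @param energetics Named list of per-complex results, each a list
#'   with elements `ic` (`icCounts`), `nis` (`nisComposition`) and
#'   `energy` (`interactionEnergy`).
#' @inheritParams reportTable1
#' @return `path`, invisibly.
#' @export
reportTable2 <- function(energetics, path, config = runConfig()) {
  rows <- c("dG_interaction", "Kd_M", "ICs ch-ch", "ICs ch-po", "ICs ch-ap",
            "ICs po-po", "ICs po-ap", "ICs ap-ap", "%NIS ch", "%NIS ap")
  out <- data.frame(Quantity = rows, check.names = FALSE)
  for (nm in names(energetics)) {
    e <- energetics[[nm]]
    cnt <- e$ic$counts
    pct <- e$nis$percent
    out[[nm]] <- c(sprintf("%.4f", e$energy$dG), sprintf("%.3g", e$energy$kd),
                   sprintf("%d", cnt[c("cc", "cp", "ca", "pp", "pa", "aa")]),
                   sprintf("%.2f", pct[c("charged", "apolar")]))
  }
  .write_report(out, path, config)
}

# Minimal FASTA reader (header lines + sequence lines).
.read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(stats::setNames(lines, lines))
  id <- sub("^>\\s*", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  stats::setNames(unname(seqs), id)
}

#' Run the pipeline
#'
#' Executes the configured stages in workflow order, writing TSV
#' reports into `config$outdir`. A stage failure preserves the
#' already-written partial results and re-raises with the stage named.
#'
#' @param config A `runConfig`.
#' @param scorer Scorer for the design stage (see [scanPositions()]);
#'   required when `"design"` is among the stages.
#' @return Invisible list of per-stage results plus `files`.
#' @export
runPipeline <- function(config, scorer = NULL) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list(files = character())
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seqs <- NULL
  getSeqs <- function() {
    if (is.null(seqs)) {
      seqs <<- if (is.null(config$fasta)) {
        stats::setNames(paperPeptides()$sequence, paperPeptides()$name)
      } else .read_fasta(config$fasta)
    }
    seqs
  }
  for (stage in config$stages) {
    if (stage == "props") {
      run_stage("props", function() {
        records <- propertyTable(getSeqs())
        path <- file.path(config$outdir, "properties.tsv")
        reportTable1(records, path, config)
        results$props <<- records
        results$files <<- c(results$files, path)
      })
    } else if (stage == "design") {
      run_stage("design", function() {
        if (is.null(scorer)) stop("design stage requires a scorer")
        cfg <- designConfig(neutralBand = config$neutralBand, seed = config$seed)
        reports <- lapply(getSeqs(), function(s) designRun(s, scorer, cfg))
        path <- file.path(config$outdir, "design.json")
        jsonlite::write_json(
          lapply(reports, function(r) list(
            seed = r$seed, seedScore = r$seedScore,
            favorable = sum(r$outcomes$label == "favorable"),
            candidates = nrow(r$candidates), ranked = r$ranked$sequence)),
          path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        results$design <<- reports
        results$files <<- c(results$files, path)
      })
    } else if (stage == "interface") {
      run_stage("interface", function() {
        model <- readPDB(config$complexPdb)
        ic <- interfaceContacts(model, config$chainsA, config$chainsB,
                                cutoff = config$cutoff)
        prof <- sasa(model)
        nis <- nisComposition(model, ic, prof, rsaThreshold = config$rsaThreshold)
        energy <- deltaGInteraction(ic, nis, config$coefficientSet,
                                    temperature = config$temperature)
        path <- file.path(config$outdir, "energetics.tsv")
        reportTable2(stats::setNames(
          list(list(ic = ic, nis = nis, energy = energy)),
          basename(config$complexPdb)), path, config)
        results$interface <<- list(ic = ic, nis = nis, energy = energy)
        results$files <<- c(results$files, path)
      })
    } else if (stage == "traj") {
      run_stage("traj", function() {
        traj <- readMultiModelPDB(config$trajectoryPdb, dt = config$dt)
        rmsd <- rmsdSeries(traj)
        rg <- radiusOfGyration(traj)
        rmsf <- rmsfProfile(traj)
        path <- file.path(config$outdir, "observables.tsv")
        .write_report(data.frame(time_ps = frameTimes(traj),
                                 rmsd_nm = rmsd$values, rg_nm = rg$values),
                      path, config)
        pathP <- file.path(config$outdir, "rmsf.tsv")
        .write_report(rmsf, pathP, config)
        results$traj <<- list(rmsd = rmsd, rg = rg, rmsf = rmsf)
        results$files <<- c(results$files, path, pathP)
      })
    }
  }
  invisible(results)
}
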