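#' Read / write a simulation configuration as YAML
#'
#' The YAML keys mirror the arguments of \code{\link{simulationConfig}};
#' unknown keys are an error so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return a validated \code{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(simulationConfig, raw)
}

#' @rdname readSimulationConfig
#' @param config a \code{SimulationConfig}.
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(inherits(config, "SimulationConfig"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x), path, precision = 15L)
  invisible(path)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline: simulate, classify, profile, quantify
#'
#' Orchestrates every stage on a simulated mock/auxin experiment and
#' writes deterministic text outputs: the class tally, coverage and
#' start-site profiles (raw + CPM), the termination-class distributions,
#' the headline ratio/fold report, a summary of derived statistics
#' (initiation fractions, distinct start sites, molecules-per-cell
#' calibration), the sample sheet, and a JSON run manifest. Re-running
#' with the same config and seed reproduces every output byte for byte.
#'
#' @param config a \code{\link{simulationConfig}} or path to its YAML.
#' @param outdir output directory.
#' @param seed overrides \code{config$seed} when given.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param writeFragments also write per-sample classified fragment BEDs
#'   (off by default; they dominate the output size).
#' @param profileAggregate \code{"sum"} or \code{"mean"} across replicate
#'   samples for the CPM profiles.
#' @return invisibly, a list with the manifest and the in-memory tables.
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        seed = NULL, overwrite = FALSE,
                        writeFragments = FALSE,
                        profileAggregate = c("sum", "mean")) {
  profileAggregate <- match.arg(profileAggregate)
  .assertFlag(overwrite, "overwrite")
  .assertFlag(writeFragments, "writeFragments")
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file '", config, "' not found", call. = FALSE)
    config <- readSimulationConfig(config)
  }
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("output directory '", outdir, "' exists and is not empty; use ",
         "overwrite = TRUE", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  wrap <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  ## simulate
  sim <- wrap(simulateExperiment(config))
  model <- sim$model
  sheet <- sim$sheet
  fragments <- unname(sim$fragments)
  all <- suppressWarnings(do.call(c, fragments))

  ## classify + tally
  classified <- wrap(classifyFragments(all, model,
                       lengthThreshold = config$lengthThreshold))
  tally <- wrap(tallyFragments(classified, sheet))
  counts <- list(fragments = length(classified), tallyRows = nrow(tally))

  ## profiles (centromeric + noncoding pericentromeric classes)
  cov <- wrap(coverageProfile(classified, model, sheet))
  ss <- wrap(startSiteProfile(classified, model, sheet))

  ## quantify
  ab <- abundanceTable(tally)
  report <- wrap(classRatioReport(ab))
  termDists <- do.call(rbind, lapply(c("mock", "auxin"), function(cond) {
    d <- termClassDistribution(tally, cond)
    d$condition <- cond
    d
  }))

  summary <- .pipelineSummary(classified, model, sheet, ab, sim$refGenes)

  paths <- c(
    sample_sheet = file.path(outdir, "samples.tsv"),
    tally = file.path(outdir, "tally.tsv"),
    abundance = file.path(outdir, "abundance.tsv"),
    report = file.path(outdir, "report.tsv"),
    term_class = file.path(outdir, "term_class_distribution.tsv"),
    coverage_profile = file.path(outdir, "coverage_profile.tsv"),
    start_site_profile = file.path(outdir, "start_site_profile.tsv"),
    summary = file.path(outdir, "summary.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  writeSampleSheet(sheet, paths[["sample_sheet"]])
  data.table::fwrite(tally, paths[["tally"]], sep = "\t")
  data.table::fwrite(ab, paths[["abundance"]], sep = "\t")
  data.table::fwrite(report, paths[["report"]], sep = "\t")
  data.table::fwrite(termDists, paths[["term_class"]], sep = "\t")
  exportProfile(cov, sheet, paths[["coverage_profile"]],
                aggregate = profileAggregate)
  exportProfile(ss, sheet, paths[["start_site_profile"]],
                aggregate = profileAggregate)
  data.table::fwrite(summary, paths[["summary"]], sep = "\t")
  if (writeFragments) {
    fragDir <- file.path(outdir, "classified")
    dir.create(fragDir, showWarnings = FALSE)
    for (nm in unique(classified$sample)) {
      p <- file.path(fragDir, paste0(nm, ".classified.bed"))
      writeClassifiedFragments(classified[classified$sample == nm], p)
      paths <- c(paths, stats::setNames(p, nm))
    }
  }
  manifest <- list(
    tool = "cenRNAtools",
    version = as.character(utils::packageVersion("cenRNAtools")),
    seed = config$seed,
    configHash = .configHash(config),
    config = lapply(unclass(config), function(x)
      if (!is.null(names(x))) as.list(x) else x),
    stageCounts = counts,
    outputs = as.list(vapply(paths[names(paths) != "manifest"],
                             basename, character(1))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, paths = paths, tally = tally,
                 abundance = ab, report = report, summary = summary,
                 termClassDistributions = termDists, model = model,
                 sheet = sheet))
}

## derived per-condition statistics for the human-readable summary
.pipelineSummary <- function(classified, model, sheet, ab, refGenes) {
  rows <- list()
  add <- function(statistic, condition, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, condition = condition, value = value,
      display = signif2(value))
  }
  condOf <- stats::setNames(sheet$condition, sheet$sample)
  cond <- condOf[classified$sample]
  cenRegion <- GenomicRanges::resize(cenCores(model),
    BiocGenerics::width(cenCores(model)) + 2L * periWindowBp(model),
    fix = "center")
  upWin <- periWindows(model)
  upWin <- upWin[upWin$side == "UP"]
  for (cc in c("mock", "auxin")) {
    isCen <- classified$tclass == "CEN" & cond == cc
    if (any(isCen)) {
      add("cen_initiated_in_pericen_fraction", cc,
          mean(classified$initiatedInPericen[isCen]))
      p5 <- .fivePrime(classified[isCen])
      pts <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(classified[isCen]),
        IRanges::IRanges(p5, p5))
      add("cen_initiated_upstream_fraction", cc,
          mean(IRanges::overlapsAny(pts, upWin, ignore.strand = TRUE)))
      ssc <- startSiteCount(classified[isCen], cenRegion)
      add("cen_distinct_start_sites", cc, ssc$distinct)
    }
    cenCount <- .lookupCount(ab, cc, "CEN")
    if (!is.na(cenCount) && any(refGenes$count > 0)) {
      mpc <- moleculesPerCell(cenCount,
               round(mean(BiocGenerics::width(cenCores(model)))), refGenes)
      add("cen_molecules_per_cell", cc, mpc$estimate)
      if (!is.na(mpc$sem)) add("cen_molecules_per_cell_sem", cc, mpc$sem)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
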