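#' @include AllClasses.R sim-droplets.R quant-core.R duplex-linkage.R
#' @include titer-estimators.R io.R
NULL

## Deterministic per-well seed derived from the replicate seed and the
## condition index; kept inside 32-bit integer range.
wellSeed <- function(replicateSeed, conditionIndex) {
  as.integer((as.numeric(replicateSeed) * 1009 + conditionIndex) %%
               2147483647)
}

#' Scenario builders
#'
#' Each builder assembles a \code{\link{ScenarioSpec}} for one of the three
#' simulated experiments, with defaults matching the study conditions the
#' assays were characterised under:
#' \describe{
#'   \item{\code{singleVirusGradientSpec}}{a single-virus concentration
#'     gradient quantified per well; estimands are the dilution-adjusted
#'     genome titer and the genome:infectious ratio.}
#'   \item{\code{duplexMixtureSpec}}{a two-virus mixture quantified in
#'     duplex; estimands are both marginal genome titers.}
#'   \item{\code{singleCellTiterSpec}}{infected cells across a set of MOIs;
#'     estimands are the two infectious-titer estimates and linkage. The
#'     inoculum volume is derived per MOI from the configured true titer so
#'     that MOI, titer, dilution and cell number stay mutually consistent.}
#' }
#'
#' @param prep,prepA,prepB \code{\link{VirusPrep}} objects (template prep
#'   for the gradient; FAM and HEX preps for the duplex mixture).
#' @param infectiousTiters numeric vector of gradient input titers (iu/mL).
#' @param cfg an \code{\link{AssayConfig}}.
#' @param cellCfg a \code{\link{CellAssayConfig}} template; \code{moi} and
#'   \code{inoculumVolumeMl} are overridden per condition.
#' @param trueTiterIuPerMl true infectious titer driving the infections.
#' @param mois numeric vector of multiplicities of infection.
#' @param replicates number of replicate runs.
#' @param seeds one integer seed per replicate.
#' @return a \code{\link{ScenarioSpec}}.
#' @name scenario-builders
NULL

#' @rdname scenario-builders
#' @export
singleVirusGradientSpec <- function(
    prep = VirusPrep("FAM", infectiousTiterIuPerMl = 2.2e5,
                     genomePerInfectiousRatio = 20.16),
    infectiousTiters = prep@infectiousTiterIuPerMl * c(0.25, 0.5, 1, 2, 4),
    cfg = AssayConfig(),
    replicates = 3L, seeds = seq_len(replicates)) {
  new("ScenarioSpec", scenario = "single_virus_gradient",
      replicates = as.integer(replicates), seeds = as.integer(seeds),
      config = list(prep = prep, infectiousTiters = infectiousTiters,
                    assay = cfg))
}

#' @rdname scenario-builders
#' @export
duplexMixtureSpec <- function(
    prepA = VirusPrep("FAM", infectiousTiterIuPerMl = 3.4e8 / 20.16,
                      genomePerInfectiousRatio = 20.16),
    prepB = VirusPrep("HEX", infectiousTiterIuPerMl = 1.68e9 / 3.53,
                      genomePerInfectiousRatio = 3.53),
    cfg = AssayConfig(dilutionFactor = 100),
    replicates = 3L, seeds = seq_len(replicates)) {
  new("ScenarioSpec", scenario = "duplex_mixture",
      replicates = as.integer(replicates), seeds = as.integer(seeds),
      config = list(prepA = prepA, prepB = prepB, assay = cfg))
}

#' @rdname scenario-builders
#' @export
singleCellTiterSpec <- function(
    trueTiterIuPerMl = 1.73e7,
    mois = c(0.074, 0.4, 2),
    cellCfg = CellAssayConfig(),
    cfg = AssayConfig(),
    replicates = 3L, seeds = seq_len(replicates)) {
  new("ScenarioSpec", scenario = "single_cell_titer",
      replicates = as.integer(replicates), seeds = as.integer(seeds),
      config = list(trueTiter = trueTiterIuPerMl, mois = mois,
                    cell = cellCfg, assay = cfg))
}

runGradientWell <- function(prep, titer, cfg, seed) {
  p <- prep; p@infectiousTiterIuPerMl <- titer
  batch <- simulateVirusAssay(p, cfg, seed = seed)
  cc <- countBatch(batch)
  est <- estimateConcentration(cc@nTotal, nPositiveA(cc),
                               dropletVolumeNl = cfg@dropletVolumeNl)
  genome <- copiesPerMl(sampleTiter(est, cfg))
  list(counts = cc, genomeTiter = genome,
       ratio = genomeToInfectiousRatio(genome, titer))
}

runDuplexWell <- function(prepA, prepB, cfg, seed) {
  batch <- simulateVirusAssay(list(prepA, prepB), cfg, seed = seed)
  cc <- countBatch(batch)
  dup <- duplexAnalysis(cc, dropletVolumeNl = cfg@dropletVolumeNl)
  list(counts = cc, duplex = dup,
       genomeA = copiesPerMl(sampleTiter(dup@concA, cfg)),
       genomeB = copiesPerMl(sampleTiter(dup@concB, cfg)))
}

runCellWell <- function(cellCfg, cfg, seed) {
  batch <- simulateCellAssay(cellCfg, cfg, seed = seed)
  cc <- countBatch(batch)
  dup <- duplexAnalysis(cc, dropletVolumeNl = cfg@dropletVolumeNl)
  eq1 <- titerFromDoublePositives(cc, cellCfg@nCellsTotal,
                                  cellCfg@dilutionFactor,
                                  cellCfg@inoculumVolumeMl)
  eq2 <- titerFromLinkage(dup, nCellsTotal = cellCfg@nCellsTotal,
                          dilution = cellCfg@dilutionFactor,
                          inoculumVolumeMl = cellCfg@inoculumVolumeMl)
  list(counts = cc, duplex = dup, eq1 = eq1, eq2 = eq2)
}

#' Run a simulated experiment scenario end to end
#'
#' Simulates every well (condition x replicate) of the scenario, quantifies
#' it, and collects per-well estimates, a mean/SEM summary and a manifest
#' from which the run can be reproduced exactly. Per-well seeds derive
#' deterministically from the replicate seeds, so identical specs give
#' byte-identical outputs.
#'
#' @param spec a \code{\link{ScenarioSpec}}.
#' @param outDir optional directory; when given, writes
#'   \code{counts.csv} (per-well cluster counts), \code{results.csv}
#'   (per-well estimates), \code{summary.csv} and \code{manifest.yaml}.
#' @return a \code{\link{ScenarioReport}}.
#' @examples
#' spec <- singleCellTiterSpec(mois = 0.4, replicates = 2L,
#'                             cfg = AssayConfig(nDroplets = 4000L))
#' report <- runScenario(spec)
#' report
#' @export
runScenario <- function(spec, outDir = NULL) {
  cfg <- spec@config$assay
  rows <- list()
  allCounts <- list()
  for (r in seq_len(spec@replicates)) {
    seedR <- spec@seeds[r]
    if (spec@scenario == "single_virus_gradient") {
      titers <- spec@config$infectiousTiters
      for (i in seq_along(titers)) {
        res <- runGradientWell(spec@config$prep, titers[i], cfg,
                               wellSeed(seedR, i))
        wid <- sprintf("r%02d_c%02d", r, i)
        allCounts[[wid]] <- res$counts
        rows[[wid]] <- data.frame(
          well_id = wid, condition = sprintf("titer_%0.3g", titers[i]),
          replicate = r, seed = wellSeed(seedR, i),
          truth_genome_titer = titers[i] *
            spec@config$prep@genomePerInfectiousRatio,
          est_genome_titer = res$genomeTiter,
          est_genome_ratio = res$ratio)
      }
    } else if (spec@scenario == "duplex_mixture") {
      res <- runDuplexWell(spec@config$prepA, spec@config$prepB, cfg,
                           wellSeed(seedR, 1L))
      wid <- sprintf("r%02d", r)
      allCounts[[wid]] <- res$counts
      rows[[wid]] <- data.frame(
        well_id = wid, condition = "mixture", replicate = r,
        seed = wellSeed(seedR, 1L),
        truth_genome_A = spec@config$prepA@infectiousTiterIuPerMl *
          spec@config$prepA@genomePerInfectiousRatio,
        truth_genome_B = spec@config$prepB@infectiousTiterIuPerMl *
          spec@config$prepB@genomePerInfectiousRatio,
        est_genome_A = res$genomeA, est_genome_B = res$genomeB,
        est_observed_dp = res$duplex@observedDoublePos,
        est_expected_dp = res$duplex@expectedDoublePos)
    } else {  # single_cell_titer
      mois <- spec@config$mois
      for (i in seq_along(mois)) {
        cc <- spec@config$cell
        cc@moi <- mois[i]
        cc@inoculumVolumeMl <- inoculumVolumeForMoi(
          mois[i], spec@config$trueTiter, cc@dilutionFactor, cc@nCellsTotal)
        res <- runCellWell(cc, cfg, wellSeed(seedR, i))
        wid <- sprintf("r%02d_m%02d", r, i)
        allCounts[[wid]] <- res$counts
        rows[[wid]] <- data.frame(
          well_id = wid, condition = sprintf("moi_%0.3g", mois[i]),
          replicate = r, seed = wellSeed(seedR, i),
          truth_titer = spec@config$trueTiter,
          est_titer_double_positive = titerValue(res$eq1),
          est_titer_linkage = titerValue(res$eq2),
          est_linkage_copies_per_ul = linkageValue(res$duplex))
      }
    }
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  summaryTab <- summarizeReport(estimates)
  manifest <- scenarioSpecToList(spec)
  manifest$package_version <- as.character(utils::packageVersion("dropletTiter"))
  if (spec@scenario == "single_virus_gradient") {
    fit <- stats::lm(est_genome_titer ~ truth_genome_titer, data = estimates)
    manifest$regression <- list(
      slope = unname(stats::coef(fit)[2]),
      r_squared = summary(fit)$r.squared)
  }
  report <- new("ScenarioReport", scenario = spec@scenario,
                estimates = estimates, summary = summaryTab,
                manifest = manifest)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeClusterCounts(allCounts, file.path(outDir, "counts.csv"))
    utils::write.csv(estimates, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summaryTab, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  report
}

#' @rdname summarizeReport
setMethod("summarizeReport", "ScenarioReport", function(x, ...) {
  summarizeReport(x@estimates)
})

#' @rdname summarizeReport
setMethod("summarizeReport", "data.frame", function(x, ...) {
  estCols <- grep("^est_", names(x), value = TRUE)
  truthCols <- grep("^truth_", names(x), value = TRUE)
  out <- list()
  for (cond in unique(x$condition)) {
    sub <- x[x$condition == cond, , drop = FALSE]
    for (ec in estCols) {
      v <- sub[[ec]]
      if (all(is.na(v))) {
        warning("estimand '", ec, "' has no values in condition '", cond,
                "'; omitted", call. = FALSE)
        next
      }
      v <- v[!is.na(v)]
      # matching truth column: est_genome_A -> truth_genome_A, etc.
      tc <- sub("^est_", "truth_", ec)
      truth <- if (tc %in% truthCols) sub[[tc]][1] else NA_real_
      if (is.na(truth) && length(truthCols) == 1L &&
          grepl("titer", ec)) truth <- sub[[truthCols]][1]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, estimand = sub("^est_", "", ec),
        mean = mean(v),
        sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
              else NA_real_,
        n = length(v),
        truth = truth,
        rel_bias = if (is.na(truth) || truth == 0) NA_real_
                   else (mean(v) - truth) / truth)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
})

## ---- manifest round trip --------------------------------------------------

scenarioSpecToList <- function(spec) {
  cfgList <- list(assay = assayConfigToList(spec@config$assay))
  if (spec@scenario == "single_virus_gradient") {
    cfgList$prep <- virusPrepToList(spec@config$prep)
    cfgList$infectious_titers <- spec@config$infectiousTiters
  } else if (spec@scenario == "duplex_mixture") {
    cfgList$prep_a <- virusPrepToList(spec@config$prepA)
    cfgList$prep_b <- virusPrepToList(spec@config$prepB)
  } else {
    cfgList$cell <- cellConfigToList(spec@config$cell)
    cfgList$true_titer = spec@config$trueTiter
    cfgList$mois = spec@config$mois
  }
  list(scenario = spec@scenario, replicates = spec@replicates,
       seeds = spec@seeds, config = cfgList)
}

listToScenarioSpec <- function(x) {
  cfg <- list(assay = listToAssayConfig(x$config$assay))
  if (x$scenario == "single_virus_gradient") {
    cfg$prep <- listToVirusPrep(x$config$prep)
    cfg$infectiousTiters <- unlist(x$config$infectious_titers)
  } else if (x$scenario == "duplex_mixture") {
    cfg$prepA <- listToVirusPrep(x$config$prep_a)
    cfg$prepB <- listToVirusPrep(x$config$prep_b)
  } else {
    cfg$cell <- listToCellConfig(x$config$cell)
    cfg$trueTiter <- x$config$true_titer
    cfg$mois <- unlist(x$config$mois)
  }
  new("ScenarioSpec", scenario = x$scenario,
      replicates = as.integer(x$replicates),
      seeds = as.integer(unlist(x$seeds)), config = cfg)
}

#' Rebuild a scenario spec from a run manifest
#'
#' A manifest written by \code{\link{runScenario}} contains the full
#' scenario configuration and seeds; re-running the rebuilt spec reproduces
#' the original run byte for byte.
#'
#' @param path path to a \code{manifest.yaml}.
#' @return a \code{\link{ScenarioSpec}}.
#' @export
readScenarioManifest <- function(path) {
  listToScenarioSpec(yaml::read_yaml(path))
}
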