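#' @include AllClasses.R quant-core.R
NULL

eventTableCols <- c("well_id", "droplet_index", "ch1_amplitude",
                    "ch2_amplitude")
clusterCountCols <- c("well_id", "n_total", "n_pos_ch1", "n_pos_ch2",
                      "n_double_pos")

#' Read and write droplet event tables
#'
#' The event-table CSV has one row per droplet with columns
#' \code{well_id, droplet_index, ch1_amplitude, ch2_amplitude} -- the
#' simulator's export and the quantifier's input.
#'
#' @param events data.frame as produced by \code{\link{renderAmplitudes}}.
#' @param path file path.
#' @return \code{readEventTable} returns the validated data.frame;
#'   \code{writeEventTable} returns \code{path} invisibly.
#' @export
writeEventTable <- function(events, path) {
  if (!all(eventTableCols %in% names(events)))
    stopInput(paste("event table needs columns:",
                    paste(eventTableCols, collapse = ", ")))
  utils::write.csv(events[eventTableCols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  events <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(eventTableCols %in% names(events)))
    stopInput(paste("not an event table; expected columns:",
                    paste(eventTableCols, collapse = ", ")))
  events
}

#' Read and write cluster-count tables
#'
#' The cluster-count CSV carries one row per well with columns
#' \code{well_id, n_total, n_pos_ch1, n_pos_ch2, n_double_pos}, where the
#' per-channel counts include the double positives.
#'
#' @param counts a \code{\link{TwoChannelCounts}} or a named list of them
#'   (names become well ids).
#' @param path file path.
#' @param wellId well identifier used when \code{counts} is a single object.
#' @return \code{readClusterCounts} returns a named list of
#'   \code{TwoChannelCounts}; \code{writeClusterCounts} returns \code{path}
#'   invisibly.
#' @export
writeClusterCounts <- function(counts, path, wellId = "A01") {
  if (is(counts, "TwoChannelCounts")) {
    counts <- stats::setNames(list(counts), wellId)
  }
  if (is.null(names(counts)))
    names(counts) <- sprintf("well%02d", seq_along(counts))
  df <- do.call(rbind, lapply(names(counts), function(w) {
    cc <- counts[[w]]
    data.frame(well_id = w, n_total = cc@nTotal,
               n_pos_ch1 = nPositiveA(cc), n_pos_ch2 = nPositiveB(cc),
               n_double_pos = cc@nDoublePos)
  }))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeClusterCounts
#' @export
readClusterCounts <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(clusterCountCols %in% names(df)))
    stopInput(paste("not a cluster-count table; expected columns:",
                    paste(clusterCountCols, collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i) {
    dp <- df$n_double_pos[i]
    aOnly <- df$n_pos_ch1[i] - dp
    bOnly <- df$n_pos_ch2[i] - dp
    TwoChannelCounts(nPosAOnly = aOnly, nPosBOnly = bOnly, nDoublePos = dp,
                     nDoubleNeg = df$n_total[i] - aOnly - bOnly - dp)
  })
  stats::setNames(out, df$well_id)
}

#' Per-channel quantification table for one well
#'
#' Runs the single-channel estimator on both marginals and back-calculates
#' sample titers; one row per channel, matching the results-CSV layout
#' (\code{well_id, channel, n_total, n_positive, lambda, copies_per_ul,
#' ci_low, ci_high, titer_copies_per_ml}).
#'
#' @param counts a \code{\link{TwoChannelCounts}}.
#' @param cfg an \code{\link{AssayConfig}}.
#' @param wellId well identifier.
#' @param confLevel nominal confidence level.
#' @return a data.frame with one row per channel.
#' @export
quantifyWell <- function(counts, cfg, wellId = "A01", confLevel = 0.95) {
  build <- function(channel, nPos) {
    est <- estimateConcentration(counts@nTotal, nPos,
                                 dropletVolumeNl = cfg@dropletVolumeNl,
                                 confLevel = confLevel)
    data.frame(
      well_id = wellId, channel = channel, n_total = counts@nTotal,
      n_positive = nPos, lambda = est@lambdaMean,
      copies_per_ul = est@copiesPerUl, ci_low = est@ciLow,
      ci_high = est@ciHigh,
      titer_copies_per_ml = copiesPerMl(sampleTiter(est, cfg)))
  }
  rbind(build("ch1", nPositiveA(counts)), build("ch2", nPositiveB(counts)))
}

#' Duplex results table for one well
#'
#' @param duplex a \code{\link{DuplexResult}}.
#' @param wellId well identifier.
#' @return a one-row data.frame with columns \code{well_id, conc_A, conc_B,
#'   observed_dp, expected_dp, linkage_copies_per_ul}.
#' @export
duplexTable <- function(duplex, wellId = "A01") {
  data.frame(
    well_id = wellId,
    conc_A = copiesPerUl(duplex@concA),
    conc_B = copiesPerUl(duplex@concB),
    observed_dp = duplex@observedDoublePos,
    expected_dp = duplex@expectedDoublePos,
    linkage_copies_per_ul = duplex@linkageCopiesPerUl)
}

## ---- config serialization -------------------------------------------------
## YAML config documents mirror the configuration field names exactly
## (snake_case keys <-> camelCase slots).

assayConfigToList <- function(cfg) {
  list(n_droplets = cfg@nDroplets,
       droplet_volume_nl = cfg@dropletVolumeNl,
       reaction_volume_ul = cfg@reactionVolumeUl,
       sample_volume_ul = cfg@sampleVolumeUl,
       dilution_factor = cfg@dilutionFactor,
       rng_seed = cfg@rngSeed)
}

listToAssayConfig <- function(x) {
  AssayConfig(
    nDroplets = x$n_droplets %||% 20000L,
    dropletVolumeNl = x$droplet_volume_nl %||% 0.85,
    reactionVolumeUl = x$reaction_volume_ul %||% 20,
    sampleVolumeUl = x$sample_volume_ul %||% 2,
    dilutionFactor = x$dilution_factor %||% 1,
    rngSeed = x$rng_seed %||% 1L)
}

virusPrepToList <- function(prep) {
  list(label = prep@label,
       infectious_titer_iu_per_ml = prep@infectiousTiterIuPerMl,
       genome_per_infectious_ratio = prep@genomePerInfectiousRatio,
       free_rna_fraction = prep@freeRnaFraction)
}

listToVirusPrep <- function(x) {
  VirusPrep(label = x$label %||% "FAM",
            infectiousTiterIuPerMl = x$infectious_titer_iu_per_ml,
            genomePerInfectiousRatio = x$genome_per_infectious_ratio %||% 1,
            freeRnaFraction = x$free_rna_fraction %||% 0)
}

cellConfigToList <- function(cc) {
  list(n_cells_total = cc@nCellsTotal,
       n_cells_loaded = cc@nCellsLoaded,
       moi = cc@moi,
       occupancy_model = cc@occupancyModel,
       occupancy_probs = cc@occupancyProbs,
       free_actin_rna_rate = cc@freeActinRnaRate,
       free_viral_rna_rate = cc@freeViralRnaRate,
       inoculum_volume_ml = cc@inoculumVolumeMl,
       dilution_factor = cc@dilutionFactor)
}

listToCellConfig <- function(x) {
  CellAssayConfig(
    nCellsTotal = x$n_cells_total %||% 2e6,
    nCellsLoaded = x$n_cells_loaded %||% 2000,
    moi = x$moi %||% 0.074,
    occupancyModel = x$occupancy_model %||% "empirical",
    occupancyProbs = unlist(x$occupancy_probs) %||% empiricalOccupancyProbs,
    freeActinRnaRate = x$free_actin_rna_rate %||% 1,
    freeViralRnaRate = x$free_viral_rna_rate %||% 15,
    inoculumVolumeMl = x$inoculum_volume_ml %||% 0.1,
    dilutionFactor = x$dilution_factor %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write assay configuration files
#'
#' Configurations are stored as YAML whose keys mirror the configuration
#' field names exactly (\code{n_droplets}, \code{droplet_volume_nl},
#' \code{infectious_titer_iu_per_ml}, ...). A document may contain any of
#' the sections \code{assay}, \code{cell} and \code{preps} (a list).
#'
#' @param config list with any of \code{assay} (\code{AssayConfig}),
#'   \code{cell} (\code{CellAssayConfig}), \code{preps} (list of
#'   \code{VirusPrep}).
#' @param path file path.
#' @return \code{readConfigFile} returns the same structure with S4 objects
#'   rebuilt; \code{writeConfigFile} returns \code{path} invisibly.
#' @export
writeConfigFile <- function(config, path) {
  doc <- list()
  if (!is.null(config$assay)) doc$assay <- assayConfigToList(config$assay)
  if (!is.null(config$cell)) doc$cell <- cellConfigToList(config$cell)
  if (!is.null(config$preps))
    doc$preps <- lapply(config$preps, virusPrepToList)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeConfigFile
#' @export
readConfigFile <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(doc$assay)) out$assay <- listToAssayConfig(doc$assay)
  if (!is.null(doc$cell)) out$cell <- listToCellConfig(doc$cell)
  if (!is.null(doc$preps)) out$preps <- lapply(doc$preps, listToVirusPrep)
  out
}
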