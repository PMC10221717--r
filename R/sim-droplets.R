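#' @include AllClasses.R conditions.R
NULL

#' Mean copies per droplet for a reaction concentration
#'
#' @param concentrationCopiesPerUl target concentration in the reaction mix
#'   (copies/uL).
#' @param cfg an \code{\link{AssayConfig}}; only \code{dropletVolumeNl} is
#'   used.
#' @return lambda, the expected copies per droplet.
#' @export
lambdaFromConcentration <- function(concentrationCopiesPerUl, cfg) {
  concentrationCopiesPerUl * cfg@dropletVolumeNl / 1000
}

#' Genome concentration a virus prep contributes to the reaction
#'
#' Total genome copies delivered are
#' \code{infectiousTiter x genomePerInfectiousRatio x (1 + freeRnaFraction)}
#' per mL of sample, scaled by the sample volume and dilution and divided by
#' the reaction volume.
#'
#' @param prep a \code{\link{VirusPrep}}.
#' @param cfg an \code{\link{AssayConfig}}.
#' @return copies per uL of reaction mix.
#' @export
prepReactionConcentration <- function(prep, cfg) {
  copiesPerMlSample <- prep@infectiousTiterIuPerMl *
    prep@genomePerInfectiousRatio * (1 + prep@freeRnaFraction)
  copiesInReaction <- copiesPerMlSample * (cfg@sampleVolumeUl / 1000) /
    cfg@dilutionFactor
  copiesInReaction / cfg@reactionVolumeUl
}

#' Partition target copies into droplets
#'
#' Each droplet receives an independent Poisson(lambda) copy count with
#' \code{lambda = concentration x dropletVolumeNl / 1000} -- the standard
#' digital PCR partitioning assumption. Uses the current RNG state; seed at
#' the batch level (see \code{\link{simulateVirusAssay}}).
#'
#' @inheritParams lambdaFromConcentration
#' @return integer vector of length \code{cfg@nDroplets}.
#' @examples
#' cfg <- AssayConfig(nDroplets = 1000L)
#' copies <- withr::with_seed(1, sampleCopiesPerDroplet(500, cfg))
#' mean(copies == 0)   # ~ exp(-lambda)
#' @export
sampleCopiesPerDroplet <- function(concentrationCopiesPerUl, cfg) {
  if (!is.finite(concentrationCopiesPerUl) || concentrationCopiesPerUl < 0)
    stopDomain("concentration must be a finite number >= 0")
  lambda <- lambdaFromConcentration(concentrationCopiesPerUl, cfg)
  stats::rpois(cfg@nDroplets, lambda)
}

#' Simulate a single- or two-virus droplet assay
#'
#' Each prep's genome copies are partitioned into droplets independently of
#' the other prep's; a channel reads positive iff the droplet holds at least
#' one copy of the matching target. Double positives therefore arise purely
#' from random co-encapsulation.
#'
#' @param preps a \code{\link{VirusPrep}} or list of one or two preps with
#'   distinct channel labels; the FAM prep drives channel A, the HEX prep
#'   channel B.
#' @param cfg an \code{\link{AssayConfig}}.
#' @param seed integer seed for this simulation call; defaults to
#'   \code{cfg@rngSeed}. Recorded in the batch provenance.
#' @return a \code{\link{DropletBatch}} with latent columns
#'   \code{copiesA}/\code{copiesB} and observed \code{chAPositive}/
#'   \code{chBPositive}.
#' @examples
#' prep <- VirusPrep("FAM", infectiousTiterIuPerMl = 2e5,
#'                   genomePerInfectiousRatio = 20.16)
#' batch <- simulateVirusAssay(prep, AssayConfig(nDroplets = 5000L), seed = 7)
#' countBatch(batch)
#' @export
simulateVirusAssay <- function(preps, cfg, seed = cfg@rngSeed) {
  if (is(preps, "VirusPrep")) preps <- list(preps)
  if (length(preps) < 1L || length(preps) > 2L)
    stopConfig("supply one or two VirusPrep objects")
  labels <- vapply(preps, function(p) p@label, character(1))
  if (anyDuplicated(labels))
    stopConfig("virus preps must target distinct channels (FAM / HEX)")

  n <- cfg@nDroplets
  withr::with_seed(seed, {
    copies <- list(FAM = integer(n), HEX = integer(n))
    for (p in preps) {
      conc <- prepReactionConcentration(p, cfg)
      copies[[p@label]] <- sampleCopiesPerDroplet(conc, cfg)
    }
    df <- DataFrame(
      copiesA = copies$FAM,
      copiesB = copies$HEX,
      chAPositive = copies$FAM >= 1L,
      chBPositive = copies$HEX >= 1L
    )
  })
  new("DropletBatch", droplets = df, config = cfg,
      provenance = list(type = "virus", seed = seed, preps = preps))
}

#' Draw cells-per-droplet occupancy
#'
#' Under the empirical model, occupancy categories are drawn from
#' \code{occupancyProbs} (microscopy-measured by default). Under the Poisson
#' model, counts are Poisson with mean \code{nCellsLoaded / nDroplets}.
#' Uses the current RNG state.
#'
#' @param cellCfg a \code{\link{CellAssayConfig}}.
#' @param cfg an \code{\link{AssayConfig}}.
#' @return integer vector of cells per droplet, length \code{cfg@nDroplets}.
#' @export
sampleCellOccupancy <- function(cellCfg, cfg) {
  n <- cfg@nDroplets
  if (cellCfg@occupancyModel == "poisson") {
    if (cellCfg@nCellsLoaded == 0) return(integer(n))
    return(stats::rpois(n, cellCfg@nCellsLoaded / n))
  }
  p <- cellCfg@occupancyProbs
  if (length(p) < 1L)
    stopConfig("empirical occupancy model requires occupancyProbs")
  if (cellCfg@nCellsLoaded == 0) return(integer(n))
  sample.int(length(p), n, replace = TRUE, prob = p) - 1L
}

#' Flag cells as infected under a Poisson infection model
#'
#' Each cell is independently infected with probability
#' \code{1 - exp(-moi)}: the zero-truncation complement of Poisson virion
#' delivery at the given multiplicity of infection. Uses the current RNG
#' state.
#'
#' @param nCells number of cells.
#' @param moi multiplicity of infection, >= 0.
#' @return logical vector of length \code{nCells}.
#' @export
infectCells <- function(nCells, moi) {
  if (!is.finite(moi) || moi < 0) stopDomain("moi must be >= 0")
  nCells <- as.integer(nCells)
  stats::runif(nCells) < (1 - exp(-moi))
}

#' Simulate a single-cell infection ddPCR assay
#'
#' Droplets receive cells under the configured occupancy model; each
#' encapsulated cell is independently infected with probability
#' \code{1 - exp(-moi)}. Free-floating RNA from cell damage is partitioned
#' independently of the cells: beta-actin debris with reaction-wide mean
#' \code{(realised encapsulated cells) x freeActinRnaRate} and viral debris
#' with mean \code{(realised infected cells) x freeViralRnaRate}. Channel A
#' (beta-actin) is positive iff the droplet holds a cell or a free actin
#' copy; channel B (viral) iff it holds an infected cell or a free viral
#' copy.
#'
#' @param cellCfg a \code{\link{CellAssayConfig}}.
#' @param cfg an \code{\link{AssayConfig}}.
#' @param seed integer seed; defaults to \code{cfg@rngSeed}.
#' @return a \code{\link{DropletBatch}} with latent columns \code{cells},
#'   \code{infectedCells}, \code{freeActinCopies}, \code{freeViralCopies}
#'   and observed channel states.
#' @examples
#' cellCfg <- CellAssayConfig(moi = 0.4, freeActinRnaRate = 0,
#'                            freeViralRnaRate = 0)
#' batch <- simulateCellAssay(cellCfg, AssayConfig(nDroplets = 5000L),
#'                            seed = 11)
#' countBatch(batch)
#' @export
simulateCellAssay <- function(cellCfg, cfg, seed = cfg@rngSeed) {
  n <- cfg@nDroplets
  withr::with_seed(seed, {
    cells <- sampleCellOccupancy(cellCfg, cfg)
    pInfect <- 1 - exp(-cellCfg@moi)
    infected <- stats::rbinom(n, size = cells, prob = pInfect)
    nLoaded <- sum(cells)
    nInfectedLoaded <- sum(infected)
    freeActin <- stats::rpois(n, nLoaded * cellCfg@freeActinRnaRate / n)
    freeViral <- stats::rpois(n, nInfectedLoaded * cellCfg@freeViralRnaRate / n)
    df <- DataFrame(
      cells = cells,
      infectedCells = infected,
      freeActinCopies = freeActin,
      freeViralCopies = freeViral,
      chAPositive = cells >= 1L | freeActin >= 1L,
      chBPositive = infected >= 1L | freeViral >= 1L
    )
  })
  new("DropletBatch", droplets = df, config = cfg,
      provenance = list(type = "cell", seed = seed, cellConfig = cellCfg,
                        nCellsEncapsulated = sum(df$cells),
                        nInfectedEncapsulated = sum(df$infectedCells)))
}

#' Render per-droplet fluorescence amplitudes
#'
#' Positive droplets draw from the positive Gaussian cluster and negatives
#' from the negative cluster; a \code{rainFraction} of positives instead
#' falls uniformly between the cluster means ("rain"). With well-separated
#' clusters, midpoint thresholding of the rendered amplitudes recovers the
#' latent channel states for at least \code{1 - rainFraction} of droplets.
#'
#' @param batch a \code{\link{DropletBatch}}.
#' @param model an \code{\link{AmplitudeModel}}.
#' @param seed integer seed; defaults to the batch seed + 1 so rendering is
#'   reproducible but decoupled from the partitioning draw.
#' @param wellId character well identifier written into the table.
#' @return a data.frame event table with columns \code{well_id},
#'   \code{droplet_index}, \code{ch1_amplitude}, \code{ch2_amplitude}.
#' @export
renderAmplitudes <- function(batch, model,
                             seed = batch@provenance$seed + 1L,
                             wellId = "A01") {
  states <- cbind(batch@droplets$chAPositive, batch@droplets$chBPositive)
  n <- nrow(states)
  amp <- matrix(0, n, 2)
  withr::with_seed(seed, {
    for (ch in 1:2) {
      pos <- states[, ch]
      a <- stats::rnorm(n,
                        mean = ifelse(pos, model@positiveMean[ch],
                                      model@negativeMean[ch]),
                        sd = model@clusterSd[ch])
      if (model@rainFraction > 0 && any(pos)) {
        rain <- pos & stats::runif(n) < model@rainFraction
        a[rain] <- stats::runif(sum(rain), model@negativeMean[ch],
                                model@positiveMean[ch])
      }
      amp[, ch] <- a
    }
  })
  data.frame(
    well_id = wellId,
    droplet_index = seq_len(n),
    ch1_amplitude = amp[, 1],
    ch2_amplitude = amp[, 2]
  )
}

#' Midpoint classification thresholds for an amplitude model
#'
#' @param model an \code{\link{AmplitudeModel}}.
#' @return named numeric, thresholds for ch1 and ch2 halfway between the
#'   cluster means.
#' @export
midpointThresholds <- function(model) {
  c(ch1 = mean(c(model@negativeMean[1], model@positiveMean[1])),
    ch2 = mean(c(model@negativeMean[2], model@positiveMean[2])))
}
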