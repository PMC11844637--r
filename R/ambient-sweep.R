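#' Ambient-contamination sweep with truth-assignment consistency
#'
#' Runs the package's canonical validation experiment: a series of
#' simulated multiplexed multiome datasets across ambient contamination
#' levels, followed by allele pileup and variant-consistency
#' classification under truth assignments, pooled across levels. The
#' headline outputs are the squared Pearson correlations between
#' per-droplet I1 counts and the true ambient molecule counts in each
#' modality — the quantification of how well I1 tracks ambient load.
#'
#' Defaults give a scaled-down sweep: 4 donors, 10% doublets, six
#' ambient levels from 0 to 50%, 250 droplets per level (1,500 total),
#' mean depths of 2,000 RNA reads and 3,200 ATAC reads per droplet on a
#' 2 Mb toy genome carrying 5,000 SNPs (the common-variant density of
#' one per 400 bp).
#'
#' @param reference a toy reference as returned by [makeToyReference()],
#'   or `NULL` to generate the default one (2 Mb, 5,000 SNPs, 4 donors).
#' @param ambientLevels experiment-level ambient fractions to sweep.
#' @param dropletsPerLevel droplets per sweep point.
#' @param doubletRate heterotypic doublet rate.
#' @param rnaDepthMean,atacDepthMean mean reads per droplet.
#' @param params a [SimParams-class].
#' @param seed integer seed; per-level sub-seeds are derived from it.
#' @return list with `perDroplet` (data.frame: ambient level, barcode,
#'   true ambient molecules and I1 counts per modality, over
#'   correctly-assigned singlets), `r2` (named vector, `rna`/`atac`),
#'   `meanI1Rate` and `meanC1Rate` (named vectors) and `n` (droplets
#'   simulated).
#' @export
runAmbientSweep <- function(reference = NULL,
                            ambientLevels = seq(0, 0.5, by = 0.1),
                            dropletsPerLevel = 250L,
                            doubletRate = 0.1,
                            rnaDepthMean = 2000, atacDepthMean = 3200,
                            params = simParams(), seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(reference))
    reference <- makeToyReference(tempfile("ambimux_ref"), seed = seed)
  panel <- loadGenotypes(reference$vcf)
  wl <- reference$whitelist_barcodes
  si <- .genomeSeqinfo(reference$genome)
  pieces <- list()
  i1rates <- c(rna = 0, atac = 0)
  c1rates <- c(rna = 0, atac = 0)
  weights <- c(rna = 0, atac = 0)
  for (li in seq_along(ambientLevels)) {
    cfg <- experimentConfig(
      nDroplets = dropletsPerLevel, nDonors = nDonors(panel),
      doubletRate = doubletRate, ambientLevel = ambientLevels[li],
      rnaDepthMean = rnaDepthMean, atacDepthMean = atacDepthMean,
      seed = seed * 1000L + li)
    ds <- sampleDroplets(cfg, barcodes = wl)
    sim <- simulateReads(ds, panel, reference$regions$rna,
                         reference$regions$atac, si, params = params,
                         seed = seed * 1000L + 500L + li)
    calls <- truthCalls(sim)
    truth <- simTruth(sim)
    lvl <- list(level = ambientLevels[li])
    for (m in c("rna", "atac")) {
      ap <- pileupFromReads(sim, m)
      res <- consistencyCounts(ap, panel, calls)
      f <- consistencyCountMatrix(res)
      rates <- consistencyRates(res)
      ok <- rowSums(f) > 0
      i1rates[m] <- i1rates[m] + sum(rates[ok, "I1"])
      c1rates[m] <- c1rates[m] + sum(rates[ok, "C1"])
      weights[m] <- weights[m] + sum(ok)
      tm <- match(rownames(f), truth$barcode)
      lvl[[paste0(m, "I1")]] <- f[, "I1"]
      lvl[[paste0(m, "Ambient")]] <-
        truth[[if (m == "rna") "rnaAmbient" else "atacAmbient"]][tm]
      if (m == "rna") lvl$barcode <- rownames(f)
    }
    pieces[[li]] <- data.frame(level = lvl$level, barcode = lvl$barcode,
                               rnaI1 = lvl$rnaI1,
                               rnaAmbient = lvl$rnaAmbient,
                               atacI1 = lvl$atacI1,
                               atacAmbient = lvl$atacAmbient)
  }
  perDroplet <- do.call(rbind, pieces)
  r2 <- c(rna = stats::cor(perDroplet$rnaI1, perDroplet$rnaAmbient)^2,
          atac = stats::cor(perDroplet$atacI1, perDroplet$atacAmbient)^2)
  list(perDroplet = perDroplet,
       r2 = r2,
       meanI1Rate = i1rates / weights,
       meanC1Rate = c1rates / weights,
       n = length(ambientLevels) * dropletsPerLevel)
}
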