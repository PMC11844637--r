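#' Construct read-level simulation parameters
#'
#' @param rnaReadLength cDNA read length (bp); default 91, the standard
#'   10x multiome R2 length.
#' @param atacReadLength ATAC per-mate genomic read length (bp).
#' @param umiLength,barcodeLength UMI / cell-barcode lengths (bp).
#' @param seqErrorRate per-base substitution error rate, in `[0, 0.1]`.
#' @param ambientInformativeWeight probability that an ambient read is
#'   drawn from informative regions instead of uniformly from the whole
#'   genome. Ambient material tends to originate outside genes and
#'   peaks, so this weight is kept low (default 0.25).
#' @param insertMean,insertSd,insertMin,insertMax truncated-Normal ATAC
#'   insert-size law.
#' @param ambientDonorWeights donor composition of the ambient pool;
#'   empty (default) means proportional to the pool's donor proportions.
#' @return a [SimParams-class].
#' @export
simParams <- function(rnaReadLength = 91L, atacReadLength = 50L,
                      umiLength = 12L, barcodeLength = 16L,
                      seqErrorRate = 0.001,
                      ambientInformativeWeight = 0.25,
                      insertMean = 180, insertSd = 40,
                      insertMin = 60L, insertMax = 600L,
                      ambientDonorWeights = numeric(0)) {
  seqErrorRate <- .assertFraction(seqErrorRate, "seqErrorRate", 0, 0.1)
  ambientInformativeWeight <-
    .assertFraction(ambientInformativeWeight, "ambientInformativeWeight")
  if (length(ambientDonorWeights) &&
      abs(sum(ambientDonorWeights) - 1) > 1e-9)
    stop("ambientDonorWeights must sum to 1")
  if (insertMin < atacReadLength)
    stop("insertMin must be at least the ATAC read length")
  methods::new("SimParams",
    rnaReadLength = as.integer(rnaReadLength),
    atacReadLength = as.integer(atacReadLength),
    umiLength = as.integer(umiLength),
    barcodeLength = as.integer(barcodeLength),
    seqErrorRate = seqErrorRate,
    ambientInformativeWeight = ambientInformativeWeight,
    insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
    insertMin = as.integer(insertMin), insertMax = as.integer(insertMax),
    ambientDonorWeights = as.numeric(ambientDonorWeights))
}

# truncated-Normal insert sizes via inverse-CDF (no rejection loop)
.sampleInsert <- function(n, params) {
  lo <- stats::pnorm(params@insertMin, params@insertMean, params@insertSd)
  hi <- stats::pnorm(params@insertMax, params@insertMean, params@insertSd)
  u <- stats::runif(n, lo, hi)
  pmax(params@insertMin,
       pmin(params@insertMax,
            as.integer(round(stats::qnorm(u, params@insertMean,
                                          params@insertSd)))))
}

#' Sample read loci conditional on ambient status
#'
#' Native reads start uniformly over the bases of the modality's
#' informative regions (gene bodies for RNA, peaks for ATAC). Ambient
#' reads start, with probability `informativeWeight`, in informative
#' regions, and otherwise uniformly over the whole genome. Starts whose
#' read (span `span` bp) would run off the chromosome are redrawn.
#'
#' @param n number of loci.
#' @param isAmbient logical vector (length `n` or 1) of ambient flags.
#' @param regions `GRanges` of informative regions.
#' @param seqinfo `Seqinfo` of the genome.
#' @param span read/fragment span in bp (scalar or length `n`).
#' @param informativeWeight ambient informative-region weight.
#' @return data.table with columns `chrom`, `pos` (1-based start).
#' @export
sampleReadLoci <- function(n, isAmbient, regions, seqinfo, span,
                           informativeWeight = 0.25) {
  if (!length(regions)) stop("informative region set is empty")
  isAmbient <- rep_len(isAmbient, n)
  span <- rep_len(as.integer(span), n)
  fromInf <- !isAmbient | (stats::runif(n) < informativeWeight)
  genomeGr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(seqinfo),
    IRanges::IRanges(1L, GenomeInfoDb::seqlengths(seqinfo)),
    seqinfo = seqinfo)
  out <- data.table(chrom = character(n), pos = integer(n))
  for (grp in list(which(fromInf), which(!fromInf))) {
    if (!length(grp)) next
    src <- if (identical(grp, which(fromInf))) regions else genomeGr
    todo <- grp
    tries <- 0L
    while (length(todo)) {
      tries <- tries + 1L
      if (tries > 100L)
        stop("could not place reads within chromosome bounds; ",
             "regions may sit too close to a contig end")
      p <- .samplePositionsInRanges(length(todo), src)
      lim <- GenomeInfoDb::seqlengths(seqinfo)[p$chrom]
      ok <- p$pos >= 1L & (p$pos + span[todo] - 1L) <= lim
      set(out, i = todo[ok], j = "chrom", value = p$chrom[ok])
      set(out, i = todo[ok], j = "pos", value = p$pos[ok])
      todo <- todo[!ok]
    }
  }
  out
}

#' Apply uniform substitution errors to base strings
#'
#' Each base is independently substituted, with probability `errorRate`,
#' by one of the three other bases (uniformly). `errorRate = 0` is the
#' identity.
#'
#' @param seqs character vector of base strings.
#' @param errorRate per-base substitution probability, in `[0, 0.1]`.
#' @return character vector with errors applied.
#' @export
applySequencingErrors <- function(seqs, errorRate) {
  errorRate <- .assertFraction(errorRate, "errorRate", 0, 0.1)
  if (errorRate == 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nErr <- stats::rbinom(length(seqs), lens, errorRate)
  hit <- which(nErr > 0L)
  for (i in hit) {
    posn <- sample.int(lens[i], nErr[i])
    ch <- substring(seqs[i], posn, posn)
    ch <- .substituteBases(ch)
    for (k in seq_along(posn))
      substr(seqs[i], posn[k], posn[k]) <- ch[k]
  }
  seqs
}

#' Simulate reads for a multiplexed multiome experiment
#'
#' Turns a [DropletSet-class] into read-level data for one or both
#' modalities. Per droplet, the number of ambient molecules is
#' `Binomial(depth, ambientFraction)`; native molecules come from the
#' droplet's donor(s) (doublet reads split by the sampled mixing share),
#' ambient molecules from a donor drawn from the ambient pool weights.
#' Read loci follow [sampleReadLoci()]. At every SNP a read overlaps,
#' an allele is drawn from the source donor's genotype
#' (`Bernoulli(dosage / 2)` for the alternate allele) — one source donor
#' per molecule governs all SNPs the molecule covers — and the observed
#' base then passes through the sequencing-error channel. ATAC molecules
#' are fragments (`round(depth / 2)` of them, sequenced as mate pairs);
#' both mates share the fragment's emitted alleles but acquire errors
#' independently.
#'
#' The result holds per-molecule ground truth in memory;
#' [writeSimOutputs()] emits FASTQ/BAM/truth files from it.
#'
#' @param droplets a [DropletSet-class].
#' @param panel a [VariantPanel-class]; donor indices in `droplets` index
#'   its rows.
#' @param rnaRegions,atacRegions informative-region `GRanges` (gene
#'   bodies / peaks).
#' @param genome FASTA path, `DNAStringSet` or `Seqinfo` (only contig
#'   names/lengths are needed at this stage).
#' @param params a [SimParams-class].
#' @param seed integer RNG seed.
#' @param modality `"both"` (default), `"rna"` or `"atac"`.
#' @return a [SimExperiment-class].
#' @export
simulateReads <- function(droplets, panel, rnaRegions, atacRegions,
                          genome, params = simParams(), seed = 1L,
                          modality = c("both", "rna", "atac")) {
  modality <- match.arg(modality)
  stopifnot(methods::is(droplets, "DropletSet"),
            methods::is(panel, "VariantPanel"))
  si <- if (methods::is(genome, "Seqinfo")) genome else .genomeSeqinfo(genome)
  .checkContigs(si, panel, rnaRegions, atacRegions, modality)
  d <- droplets@droplets
  cfg <- droplets@config
  K <- cfg@nDonors
  ambW <- params@ambientDonorWeights
  if (!length(ambW)) ambW <- cfg@donorProportions
  if (length(ambW) != K) stop("ambientDonorWeights must have length ", K)
  reads <- list()
  hits <- list()
  truth <- data.table(
    barcode = d$barcode, type = d$type, donor1 = d$donor1,
    donor2 = d$donor2, ambientFraction = d$ambientFraction,
    rnaNative = 0L, rnaAmbient = 0L, atacNative = 0L, atacAmbient = 0L)
  .withSeed(seed, {
    if (modality %in% c("both", "rna")) {
      r <- .simulateModality(d, panel, rnaRegions, si, params, ambW, "rna")
      reads$rna <- r$reads
      hits$rna <- r$hits
      truth[, `:=`(rnaNative = r$native, rnaAmbient = r$ambient)]
    }
    if (modality %in% c("both", "atac")) {
      r <- .simulateModality(d, panel, atacRegions, si, params, ambW, "atac")
      reads$atac <- r$reads
      hits$atac <- r$hits
      truth[, `:=`(atacNative = r$native, atacAmbient = r$ambient)]
    }
  })
  methods::new("SimExperiment",
    droplets = droplets, panel = panel, params = params,
    reads = reads, hits = hits,
    truth = as.data.frame(truth),
    seqinfo = si,
    regions = list(rna = if (modality != "atac") rnaRegions else NULL,
                   atac = if (modality != "rna") atacRegions else NULL),
    seed = as.integer(seed))
}

.checkContigs <- function(si, panel, rnaRegions, atacRegions, modality) {
  have <- GenomeInfoDb::seqnames(si)
  vc <- unique(as.character(GenomicRanges::seqnames(variants(panel))))
  bad <- setdiff(vc, have)
  if (length(bad))
    stop("VCF contig(s) absent from genome: ", paste(bad, collapse = ", "),
         "; genome has: ", paste(have, collapse = ", "))
  regs <- list()
  if (modality %in% c("both", "rna")) regs$rna <- rnaRegions
  if (modality %in% c("both", "atac")) regs$atac <- atacRegions
  for (nm in names(regs)) {
    if (is.null(regs[[nm]]) || !length(regs[[nm]]))
      stop(nm, " region set is empty")
    rc <- unique(as.character(GenomicRanges::seqnames(regs[[nm]])))
    bad <- setdiff(rc, have)
    if (length(bad))
      stop(nm, " region contig(s) absent from genome: ",
           paste(bad, collapse = ", "))
  }
}

# one modality: sample molecules, loci, variant overlaps and alleles
.simulateModality <- function(d, panel, regions, si, params, ambW, mod) {
  nd <- nrow(d)
  gmat <- genotypes(panel)
  K <- nrow(gmat)
  v <- variants(panel)
  if (mod == "rna") {
    nMol <- d$rnaDepth
    span0 <- params@rnaReadLength
  } else {
    # ATAC depth counts fragments (sequenced read pairs), the unit 10x
    # depth recommendations are quoted in; each emits two mate records
    nMol <- d$atacDepth
    span0 <- NULL # per-fragment insert
  }
  nAmb <- stats::rbinom(nd, nMol, d$ambientFraction)
  nNat <- nMol - nAmb
  total <- sum(nMol)
  dropIdx <- rep(seq_len(nd), nMol)
  isAmb <- rep(rep(c(FALSE, TRUE), nd),
               as.vector(rbind(nNat, nAmb)))
  # source donor: one per molecule
  srcDonor <- integer(total)
  nat <- which(!isAmb)
  if (length(nat)) {
    dn <- d$donor1[dropIdx[nat]]
    dbl <- which(d$type[dropIdx[nat]] == "doublet")
    if (length(dbl)) {
      toD2 <- stats::runif(length(dbl)) >= d$doubletMix[dropIdx[nat[dbl]]]
      dn[dbl[toD2]] <- d$donor2[dropIdx[nat[dbl[toD2]]]]
    }
    srcDonor[nat] <- dn
  }
  amb <- which(isAmb)
  if (length(amb))
    srcDonor[amb] <- sample.int(K, length(amb), replace = TRUE, prob = ambW)
  # loci
  if (mod == "rna") {
    span <- rep.int(span0, total)
  } else {
    span <- .sampleInsert(total, params)
  }
  loci <- sampleReadLoci(total, isAmb, regions, si, span,
                         params@ambientInformativeWeight)
  if (mod == "rna") {
    reads <- data.table(
      readId = seq_len(total), droplet = dropIdx,
      chrom = loci$chrom, start = loci$pos,
      strand = sample(c("+", "-"), total, replace = TRUE),
      isAmbient = isAmb, srcDonor = srcDonor)
    cover <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(reads$start, width = span0))
    coverMol <- reads$readId
    coverMate <- rep.int(0L, total)
  } else {
    reads <- data.table(
      fragId = seq_len(total), droplet = dropIdx,
      chrom = loci$chrom, fragStart = loci$pos,
      insertLen = span,
      fragEnd = loci$pos + span - 1L,
      isAmbient = isAmb, srcDonor = srcDonor)
    L <- params@atacReadLength
    cover <- GenomicRanges::GRanges(
      rep(reads$chrom, 2L),
      IRanges::IRanges(c(reads$fragStart, reads$fragEnd - L + 1L),
                       width = L))
    coverMol <- rep.int(reads$fragId, 2L)
    coverMate <- rep(c(1L, 2L), each = total)
  }
  fo <- GenomicRanges::findOverlaps(GenomicRanges::granges(v), cover,
                                    ignore.strand = TRUE)
  hv <- S4Vectors::queryHits(fo)
  hc <- S4Vectors::subjectHits(fo)
  hitDT <- data.table(molecule = coverMol[hc], mate = coverMate[hc],
                      variant = hv)
  if (nrow(hitDT)) {
    # one emitted allele per (molecule, variant), shared across mates
    alleleDT <- unique(hitDT[, list(molecule, variant)])
    dos <- gmat[cbind(srcDonor[alleleDT$molecule], alleleDT$variant)]
    nMissing <- sum(is.na(dos))
    if (nMissing) {
      message("simulateReads: ", nMissing, " molecule-variant pair(s) hit ",
              "a missing genotype; emitting the reference allele")
      dos[is.na(dos)] <- 0L
    }
    alleleDT[, isAlt := stats::runif(.N) < dos / 2]
    hitDT <- merge(hitDT, alleleDT, by = c("molecule", "variant"),
                   sort = FALSE)
    # observed base per covering mate, after the error channel
    mc <- S4Vectors::mcols(v)
    base0 <- ifelse(hitDT$isAlt, mc$alt[hitDT$variant],
                    mc$ref[hitDT$variant])
    eps <- params@seqErrorRate
    if (eps > 0) {
      err <- stats::runif(nrow(hitDT)) < eps
      base0[err] <- .substituteBases(base0[err])
    }
    hitDT[, obsBase := base0]
    setkey(hitDT, molecule, variant, mate)
  } else {
    hitDT <- data.table(molecule = integer(0), mate = integer(0),
                        variant = integer(0), isAlt = logical(0),
                        obsBase = character(0))
  }
  list(reads = reads, hits = hitDT, native = nNat, ambient = nAmb)
}

#' @describeIn SimExperiment-class droplet barcodes.
#' @param x,object a `SimExperiment`.
#' @export
setMethod("barcodes", "SimExperiment", function(x) barcodes(x@droplets))

#' @export
setMethod("show", "SimExperiment", function(object) {
  cat("SimExperiment:", length(object@droplets), "droplets; modalities:",
      paste(names(object@reads), collapse = ", "), "\n")
  for (m in names(object@reads))
    cat(sprintf("  %s: %d molecules, %d variant hits\n", m,
                nrow(object@reads[[m]]), nrow(object@hits[[m]])))
  cat("  seed:", object@seed, "\n")
})

#' Per-droplet simulation ground truth
#'
#' One row per droplet: type, donor indices, ambient fraction, and the
#' realized native/ambient molecule counts per modality (RNA molecules
#' are reads; ATAC molecules are fragments).
#'
#' @param sim a [SimExperiment-class].
#' @return data.frame.
#' @export
simTruth <- function(sim) sim@truth

#' Read/fragment tables of a simulated experiment
#'
#' @param sim a [SimExperiment-class].
#' @param modality `"rna"` or `"atac"`.
#' @return data.table of read (RNA) or fragment (ATAC) records.
#' @export
simReads <- function(sim, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  sim@reads[[modality]]
}

#' Per-molecule variant hits of a simulated experiment
#'
#' The simulator's internal record of emitted alleles: one row per
#' (molecule, covering mate, variant) with the pre-error allele
#' (`isAlt`) and the observed base after sequencing error.
#'
#' @inheritParams simReads
#' @return data.table with columns `molecule`, `mate`, `variant`,
#'   `isAlt`, `obsBase`.
#' @export
simHits <- function(sim, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  sim@hits[[modality]]
}

#' Ground-truth allele count matrices
#'
#' Collapses the simulator's per-molecule hit records into droplet x
#' variant reference/alternate count matrices based on the *emitted*
#' (pre-error) alleles, one count per molecule per variant. At zero
#' sequencing error these equal the pileup of the emitted BAM exactly,
#' and they serve as the pileup module's oracle.
#'
#' @inheritParams simReads
#' @return list with sparse matrices `ref` and `alt` (variants x
#'   droplets, dimnames set) .
#' @export
truthAlleleCounts <- function(sim, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  h <- simHits(sim, modality)
  rd <- simReads(sim, modality)
  molDrop <- rd$droplet
  V <- nVariants(sim@panel)
  D <- length(sim@droplets)
  dn <- list(names(variants(sim@panel)), barcodes(sim))
  if (!nrow(h)) {
    z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(V, D), dimnames = dn)
    return(list(ref = z, alt = z))
  }
  u <- unique(h[, list(molecule, variant, isAlt)])
  u[, droplet := molDrop[molecule]]
  agg <- u[, list(n = .N), by = list(variant, droplet, isAlt)]
  mk <- function(sub) {
    Matrix::sparseMatrix(i = sub$variant, j = sub$droplet, x = sub$n,
                         dims = c(V, D), dimnames = dn)
  }
  list(ref = mk(agg[isAlt == FALSE]), alt = mk(agg[isAlt == TRUE]))
}
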