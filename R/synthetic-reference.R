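#' Generate a toy reference genome
#'
#' Writes a small random genome (i.i.d. bases at a target GC content) as
#' an indexed FASTA. Chromosomes are named `chr1..chrN`. Deterministic
#' given `seed` (byte-identical files).
#'
#' @param path output FASTA path.
#' @param nChroms number of chromosomes (>= 1).
#' @param chromLength length of each chromosome in bp (>= 10,000).
#' @param gcContent target GC fraction.
#' @param seed integer RNG seed.
#' @return the FASTA path, invisibly. A `.fai` index is written next to it.
#' @examples
#' fa <- makeToyGenome(tempfile(fileext = ".fa"), 1, 50000, seed = 7)
#' @export
makeToyGenome <- function(path, nChroms = 1L, chromLength = 2e6,
                          gcContent = 0.41, seed = 1L) {
  nChroms <- .assertCount(nChroms, "nChroms")
  chromLength <- .assertCount(chromLength, "chromLength", min = 10000L)
  gcContent <- .assertFraction(gcContent, "gcContent")
  probs <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
             (1 - gcContent) / 2)
  .withSeed(seed, {
    seqs <- vapply(seq_len(nChroms), function(i) {
      paste(sample(BASES, chromLength, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste0("chr", seq_len(nChroms))
  Biostrings::writeXStringSet(dss, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Generate a toy donor VCF with Hardy-Weinberg genotypes
#'
#' Places biallelic SNPs at distinct positions of a toy genome, draws an
#' alternate-allele frequency uniformly in `[mafLow, mafHigh]` per
#' variant, and samples each donor's diploid dosage as Binomial(2, AF)
#' (Hardy-Weinberg). When `nDonors >= 2`, variants where all donors end
#' up with identical genotypes are resampled (bounded retries) so every
#' variant discriminates at least one donor pair. INFO fields `R2`
#' (synthetic imputation quality, uniform in `[r2Low, r2High]`) and `AF`
#' are written so downstream filters are exercisable. GT is written
#' unphased (`0/1`), VCFv4.2.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param path output VCF path (plain text).
#' @param nVariants number of SNPs.
#' @param nDonors number of donor sample columns (>= 1).
#' @param mafLow,mafHigh bounds of the uniform alt-allele frequency draw.
#' @param r2Low,r2High bounds of the synthetic imputation-R2 draw.
#' @param seed integer RNG seed.
#' @return invisibly, a list with `path`, `variants` (data.frame: chrom,
#'   pos, ref, alt, r2, af), `genotypes` (donors x variants dosage
#'   matrix) and `donorIds` — the generator's in-memory truth, which
#'   [loadGenotypes()] must reproduce exactly.
#' @export
makeToyVcf <- function(genome, path, nVariants = 5000L, nDonors = 4L,
                       mafLow = 0.1, mafHigh = 0.5,
                       r2Low = 0.5, r2High = 1.0, seed = 1L) {
  nVariants <- .assertCount(nVariants, "nVariants")
  nDonors <- .assertCount(nDonors, "nDonors")
  stopifnot(mafLow <= mafHigh, mafLow > 0, mafHigh <= 0.5)
  g <- .loadGenome(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  lens <- Biostrings::width(g)
  total <- sum(as.numeric(lens))
  if (nVariants > total)
    stop("cannot place ", nVariants, " distinct variant positions in a ",
         total, " bp genome")
  .withSeed(seed, {
    off <- sort(sample(total, nVariants, replace = FALSE))
    cum <- cumsum(as.numeric(lens))
    ci <- findInterval(off - 1, cum) + 1L
    pos <- as.integer(off - c(0, cum)[ci])
    chrom <- names(g)[ci]
    ref <- character(nVariants)
    for (u in unique(ci)) {
      ii <- which(ci == u)
      s <- as.character(g[[u]])
      ref[ii] <- substring(s, pos[ii], pos[ii])
    }
    alt <- .substituteBases(ref)
    af <- round(stats::runif(nVariants, mafLow, mafHigh), 4)
    r2 <- round(stats::runif(nVariants, r2Low, r2High), 4)
    gt <- matrix(stats::rbinom(nDonors * nVariants, 2L, rep(af, each = nDonors)),
                 nrow = nDonors)
    if (nDonors >= 2L) {
      tries <- 0L
      repeat {
        mono <- which(matrixStats_colAllEqual(gt))
        if (!length(mono)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not sample discriminating genotypes for ",
               length(mono), " variants after 1000 retries")
        gt[, mono] <- stats::rbinom(nDonors * length(mono), 2L,
                                    rep(af[mono], each = nDonors))
      }
    }
  })
  donorIds <- sprintf("donor%d", seq_len(nDonors))
  rownames(gt) <- donorIds
  colnames(gt) <- sprintf("snp%d", seq_len(nVariants))
  gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nDonors)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(g), lens),
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donorIds), collapse = "\t")
  )
  body <- paste(chrom, pos, colnames(gt), ref, alt, ".", "PASS",
                sprintf("R2=%.4f;AF=%.4f", r2, af), "GT",
                sep = "\t")
  gtCols <- apply(gtStr, 2L, paste, collapse = "\t")
  writeLines(c(header, paste(body, gtCols, sep = "\t")), path)
  invisible(list(
    path = path,
    variants = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          r2 = r2, af = af, stringsAsFactors = FALSE),
    genotypes = gt,
    donorIds = donorIds
  ))
}

# all rows of each column equal (ignoring nothing; no NAs in generator)
matrixStats_colAllEqual <- function(m) {
  if (nrow(m) == 1L) return(rep(FALSE, ncol(m)))
  colSums(m == m[rep(1L, nrow(m)), , drop = FALSE]) == nrow(m)
}

#' Generate toy informative-region BED files
#'
#' Places non-overlapping intervals ("gene bodies" for RNA, "peaks" for
#' ATAC) uniformly on a toy genome and writes 0-based half-open BED3
#' files. Intervals within a file never overlap; RNA and ATAC regions may
#' overlap each other (as genes and peaks do). Lengths are drawn from a
#' Normal around the modality's mean, truncated below at 200 bp.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param rnaPath,atacPath output BED paths.
#' @param nRnaRegions,nAtacRegions number of intervals per file.
#' @param rnaMeanLength,atacMeanLength mean interval lengths in bp
#'   (gene bodies are kilobase-scale, peaks sub-kilobase).
#' @param seed integer RNG seed.
#' @return invisibly, a list with `rna`/`atac` (`GRanges`) and the paths.
#' @export
makeToyRegions <- function(genome, rnaPath, atacPath,
                           nRnaRegions = 30L, nAtacRegions = 80L,
                           rnaMeanLength = 10000L, atacMeanLength = 1000L,
                           seed = 1L) {
  si <- .genomeSeqinfo(genome)
  glen <- sum(as.numeric(GenomeInfoDb::seqlengths(si)))
  # fail fast on the expected total before attempting placement
  expected <- nRnaRegions * rnaMeanLength + nAtacRegions * atacMeanLength
  if (expected >= 0.8 * glen)
    stop("total region length (~", expected, " bp) must stay below 80% ",
         "of the ", glen, " bp genome")
  .withSeed(seed, {
    grRna <- .placeRegions(si, nRnaRegions, rnaMeanLength)
    grAtac <- .placeRegions(si, nAtacRegions, atacMeanLength)
  })
  tot <- sum(GenomicRanges::width(grRna)) + sum(GenomicRanges::width(grAtac))
  if (tot >= 0.8 * glen)
    stop("total region length (", tot, " bp) must stay below 80% of the ",
         glen, " bp genome")
  rtracklayer::export(grRna, rnaPath, format = "BED")
  rtracklayer::export(grAtac, atacPath, format = "BED")
  invisible(list(rna = grRna, atac = grAtac,
                 rnaPath = rnaPath, atacPath = atacPath))
}

.placeRegions <- function(si, n, meanLength, maxTries = 10000L) {
  n <- .assertCount(n, "number of regions")
  lens <- pmax(200L, as.integer(round(stats::rnorm(n, meanLength, meanLength / 4))))
  chromNames <- GenomeInfoDb::seqnames(si)
  chromLens <- GenomeInfoDb::seqlengths(si)
  pChrom <- integer(n)
  pStart <- integer(n)
  got <- 0L
  tries <- 0L
  for (len in lens) {
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place ", n, " non-overlapping regions after ",
             maxTries, " tries; reduce region count or length")
      ci <- sample.int(length(chromNames), 1L,
                       prob = as.numeric(chromLens))
      if (chromLens[ci] <= len) next
      st <- sample.int(chromLens[ci] - len, 1L)
      if (got > 0L) {
        same <- pChrom[seq_len(got)] == ci
        if (any(same &
                st <= pStart[seq_len(got)] + lens[seq_len(got)] - 1L &
                st + len - 1L >= pStart[seq_len(got)]))
          next
      }
      got <- got + 1L
      pChrom[got] <- ci
      pStart[got] <- st
      break
    }
  }
  GenomicRanges::sort(GenomicRanges::GRanges(
    chromNames[pChrom],
    IRanges::IRanges(pStart, width = lens),
    seqinfo = si))
}

#' Generate a cell-barcode whitelist
#'
#' Random fixed-length barcodes with pairwise Hamming distance at least
#' `minHamming`, mirroring the separability of droplet-kit whitelists and
#' preventing trivial collisions in pileup tests.
#'
#' @param path output text file (one barcode per line); `NULL` to skip
#'   writing.
#' @param n number of barcodes.
#' @param bpLength barcode length in bp.
#' @param minHamming minimum pairwise Hamming distance.
#' @param seed integer RNG seed.
#' @return character vector of barcodes (invisibly if written to a file).
#' @export
makeBarcodeWhitelist <- function(path = NULL, n = 2000L, bpLength = 16L,
                                 minHamming = 3L, seed = 1L) {
  n <- .assertCount(n, "n")
  bcs <- .withSeed(seed, .randomBarcodes(n, bpLength, minHamming))
  if (!is.null(path)) {
    writeLines(bcs, path)
    return(invisible(bcs))
  }
  bcs
}

#' Generate a complete self-contained toy reference
#'
#' Bundles [makeToyGenome()], [makeToyVcf()], [makeToyRegions()] and
#' [makeBarcodeWhitelist()] into one directory, so that every other step
#' (genotype loading, simulation, pileup, consistency) is runnable
#' without external downloads. The default scale (one 2 Mb chromosome,
#' 5,000 SNPs, 30 gene bodies, 80 peaks) keeps SNP density at one per
#' 400 bp — proportional to common-variant density on the human genome —
#' while staying seconds-scale.
#'
#' @param dir output directory (created if needed).
#' @param nChroms,chromLength genome shape.
#' @param nVariants,nDonors,mafLow,mafHigh,r2Low,r2High VCF parameters,
#'   see [makeToyVcf()].
#' @param nRnaRegions,nAtacRegions,rnaMeanLength,atacMeanLength region
#'   parameters, see [makeToyRegions()].
#' @param nBarcodes whitelist size.
#' @param seed integer RNG seed (sub-seeds are derived per artifact).
#' @return a list of paths (`genome`, `vcf`, `rnaRegions`, `atacRegions`,
#'   `whitelist`), the in-memory `vcfTruth` returned by [makeToyVcf()],
#'   region `GRanges`, the barcode vector and the seed.
#' @examples
#' \donttest{
#' ref <- makeToyReference(tempfile(), chromLength = 1e5, nVariants = 200,
#'                         nBarcodes = 50, seed = 1)
#' }
#' @export
makeToyReference <- function(dir, nChroms = 1L, chromLength = 2e6,
                             nVariants = 5000L, nDonors = 4L,
                             mafLow = 0.1, mafHigh = 0.5,
                             r2Low = 0.5, r2High = 1.0,
                             nRnaRegions = 30L, nAtacRegions = 80L,
                             rnaMeanLength = 10000L, atacMeanLength = 1000L,
                             nBarcodes = 2000L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "donors.vcf"),
    rnaRegions = file.path(dir, "rna_regions.bed"),
    atacRegions = file.path(dir, "atac_regions.bed"),
    whitelist = file.path(dir, "whitelist.txt")
  )
  makeToyGenome(paths$genome, nChroms, chromLength, seed = seed)
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  vcfTruth <- makeToyVcf(genome, paths$vcf, nVariants, nDonors,
                         mafLow, mafHigh, r2Low, r2High, seed = seed + 1L)
  regions <- makeToyRegions(genome, paths$rnaRegions, paths$atacRegions,
                            nRnaRegions, nAtacRegions,
                            rnaMeanLength, atacMeanLength, seed = seed + 2L)
  wl <- makeBarcodeWhitelist(paths$whitelist, nBarcodes, seed = seed + 3L)
  c(paths,
    list(vcfTruth = vcfTruth, regions = regions, whitelist_barcodes = wl,
         seed = seed))
}
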