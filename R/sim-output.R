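#' Write FASTQ, BAM and truth files for a simulated experiment
#'
#' Materializes a [SimExperiment-class] as sequencing data. RNA: an R1
#' FASTQ (16 bp cell barcode + 12 bp UMI) and an R2 FASTQ (cDNA), plus a
#' coordinate-sorted, indexed BAM with `CB`/`UB` tags. ATAC: R1/R3
#' genomic mate FASTQs and an R2 barcode FASTQ, plus a paired,
#' coordinate-sorted BAM with `CB` tags. Alignments are emitted directly
#' at the true loci with MAPQ 60 and full-match CIGARs — no aligner is
#' involved, so a pileup of a zero-error BAM reproduces the simulator's
#' internal allele counts exactly. Base qualities are constant Q37.
#'
#' Read sequences are the reference bases at the sampled locus with the
#' simulator's emitted variant alleles (and their recorded post-error
#' bases) injected, and substitution errors applied to the remaining
#' positions at the configured rate.
#'
#' @param sim a [SimExperiment-class].
#' @param dir output directory (created if needed).
#' @param genome FASTA path or `DNAStringSet` with the reference
#'   sequences reads were sampled from.
#' @param modality `"both"`, `"rna"` or `"atac"` (intersected with what
#'   the experiment contains).
#' @param fastq,bam which file kinds to emit.
#' @param perReadTruth also write per-molecule truth TSVs (ambient flag,
#'   source donor).
#' @param seed RNG seed for the background (non-variant) error bases.
#' @return named list of written file paths, invisibly.
#' @export
writeSimOutputs <- function(sim, dir, genome,
                            modality = c("both", "rna", "atac"),
                            fastq = TRUE, bam = TRUE,
                            perReadTruth = FALSE, seed = 1L) {
  modality <- match.arg(modality)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- .loadGenome(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  chromStr <- lapply(seq_along(g), function(i) as.character(g[[i]]))
  names(chromStr) <- names(g)
  mods <- intersect(
    switch(modality, both = c("rna", "atac"), modality),
    names(sim@reads))
  if (!length(mods)) stop("experiment contains no requested modality")
  out <- list()
  .withSeed(seed, {
    for (m in mods) {
      paths <- if (m == "rna")
        .writeRna(sim, dir, chromStr, fastq, bam)
      else
        .writeAtac(sim, dir, chromStr, fastq, bam)
      out <- c(out, paths)
    }
  })
  tpath <- file.path(dir, "truth_droplets.tsv")
  utils::write.table(simTruth(sim), tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out$truthDroplets <- tpath
  if (perReadTruth) {
    for (m in mods) {
      rd <- simReads(sim, m)
      df <- data.frame(id = rd[[1L]],
                       barcode = barcodes(sim)[rd$droplet],
                       isAmbient = rd$isAmbient, srcDonor = rd$srcDonor)
      p <- file.path(dir, sprintf("truth_reads_%s.tsv.gz", m))
      con <- gzfile(p, "wb")
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      out[[paste0("truthReads_", m)]] <- p
    }
  }
  invisible(out)
}

# reference-forward sequences for intervals, with observed variant bases
# injected and background errors applied off-variant
.buildSeqs <- function(chromStr, chrom, start, len, hitOff, hitRow, hitBase,
                       eps) {
  n <- length(start)
  seqs <- character(n)
  for (cn in unique(chrom)) {
    ii <- which(chrom == cn)
    seqs[ii] <- substring(chromStr[[cn]], start[ii], start[ii] + len[ii] - 1L)
  }
  # inject observed variant bases (loop over within-read hit rank so that
  # repeated row indices are not lost by vectorized assignment)
  if (length(hitRow)) {
    dt <- data.table(row = hitRow, off = hitOff, base = hitBase)
    dt[, rk := seq_len(.N), by = row]
    # substr<- takes scalar start/stop, so assign per (rank, offset) group
    for (k in seq_len(max(dt$rk))) {
      s <- dt[dt$rk == k]
      for (o in unique(s$off)) {
        sel <- which(s$off == o)
        y <- seqs[s$row[sel]]
        substr(y, o, o) <- s$base[sel]
        seqs[s$row[sel]] <- y
      }
    }
  }
  if (eps > 0) {
    varOff <- split(hitOff, hitRow)
    nErr <- stats::rbinom(n, len, eps)
    for (i in which(nErr > 0L)) {
      posn <- sample.int(len[i], nErr[i])
      vo <- varOff[[as.character(i)]]
      if (!is.null(vo)) posn <- setdiff(posn, vo)
      if (!length(posn)) next
      ch <- .substituteBases(substring(seqs[i], posn, posn))
      for (k in seq_along(posn))
        substr(seqs[i], posn[k], posn[k]) <- ch[k]
    }
  }
  seqs
}

.revComp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

.writeFastq <- function(ids, seqs, path) {
  qual <- strrep("F", nchar(seqs))
  .writeLinesGz(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
}

.samToSortedBam <- function(samLines, chromStr, dir, prefix) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chromStr),
                      vapply(chromStr, nchar, integer(1))))
  samPath <- file.path(dir, paste0(prefix, ".sam"))
  writeLines(c(header, samLines), samPath)
  bamPath <- Rsamtools::asBam(samPath, file.path(dir, prefix),
                              overwrite = TRUE, indexDestination = TRUE)
  unlink(samPath)
  bamPath
}

.writeRna <- function(sim, dir, chromStr, fastq, bam) {
  rd <- simReads(sim, "rna")
  h <- simHits(sim, "rna")
  p <- sim@params
  L <- p@rnaReadLength
  vpos <- GenomicRanges::start(variants(sim@panel))
  hitRow <- h$molecule
  hitOff <- vpos[h$variant] - rd$start[h$molecule] + 1L
  seqs <- .buildSeqs(chromStr, rd$chrom, rd$start, rep.int(L, nrow(rd)),
                     hitOff, hitRow, h$obsBase, p@seqErrorRate)
  bcs <- barcodes(sim)[rd$droplet]
  umis <- .encodeIdsAsBases(rd$readId, p@umiLength)
  ids <- sprintf("rna.read%d", rd$readId)
  out <- list()
  if (fastq) {
    out$rnaR1 <- .writeFastq(ids, paste0(bcs, umis),
                             file.path(dir, "rna_R1.fastq.gz"))
    r2 <- seqs
    neg <- rd$strand == "-"
    if (any(neg)) r2[neg] <- .revComp(r2[neg])
    out$rnaR2 <- .writeFastq(ids, r2, file.path(dir, "rna_R2.fastq.gz"))
  }
  if (bam) {
    flag <- ifelse(rd$strand == "-", 16L, 0L)
    lines <- paste(ids, flag, rd$chrom, rd$start, 60L,
                   sprintf("%dM", L), "*", 0L, 0L, seqs,
                   strrep("F", L),
                   paste0("CB:Z:", bcs), paste0("UB:Z:", umis),
                   sep = "\t")
    out$rnaBam <- .samToSortedBam(lines, chromStr, dir, "rna")
  }
  out
}

.writeAtac <- function(sim, dir, chromStr, fastq, bam) {
  rd <- simReads(sim, "atac")
  h <- simHits(sim, "atac")
  p <- sim@params
  L <- p@atacReadLength
  vpos <- GenomicRanges::start(variants(sim@panel))
  m2start <- rd$fragEnd - L + 1L
  h1 <- h[mate == 1L]
  h2 <- h[mate == 2L]
  seq1 <- .buildSeqs(chromStr, rd$chrom, rd$fragStart, rep.int(L, nrow(rd)),
                     vpos[h1$variant] - rd$fragStart[h1$molecule] + 1L,
                     h1$molecule, h1$obsBase, p@seqErrorRate)
  seq2 <- .buildSeqs(chromStr, rd$chrom, m2start, rep.int(L, nrow(rd)),
                     vpos[h2$variant] - m2start[h2$molecule] + 1L,
                     h2$molecule, h2$obsBase, p@seqErrorRate)
  bcs <- barcodes(sim)[rd$droplet]
  ids <- sprintf("atac.frag%d", rd$fragId)
  out <- list()
  if (fastq) {
    out$atacR1 <- .writeFastq(ids, seq1, file.path(dir, "atac_R1.fastq.gz"))
    out$atacR2 <- .writeFastq(ids, bcs, file.path(dir, "atac_R2.fastq.gz"))
    out$atacR3 <- .writeFastq(ids, .revComp(seq2),
                              file.path(dir, "atac_R3.fastq.gz"))
  }
  if (bam) {
    qual <- strrep("F", L)
    cbTag <- paste0("CB:Z:", bcs)
    l1 <- paste(ids, 99L, rd$chrom, rd$fragStart, 60L, sprintf("%dM", L),
                "=", m2start, rd$insertLen, seq1, qual, cbTag, sep = "\t")
    l2 <- paste(ids, 147L, rd$chrom, m2start, 60L, sprintf("%dM", L),
                "=", rd$fragStart, -rd$insertLen, seq2, qual, cbTag,
                sep = "\t")
    out$atacBam <- .samToSortedBam(c(l1, l2), chromStr, dir, "atac")
  }
  out
}
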