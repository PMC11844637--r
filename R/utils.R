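#' @import data.table
NULL

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

# run expr with a local RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be in [%g, %g]", name, lo, hi), call. = FALSE)
  as.numeric(x)
}

# substitute each base by a uniformly chosen different base; vectorized
.substituteBases <- function(bases) {
  idx <- match(bases, BASES)
  shift <- sample.int(3L, length(bases), replace = TRUE)
  BASES[((idx - 1L + shift) %% 4L) + 1L]
}

# all barcodes at Hamming distance <= 1 from b (b itself plus every
# single-position substitution)
.hammingBall1 <- function(b, bpLength) {
  out <- character(1L + 3L * bpLength)
  out[1L] <- b
  k <- 1L
  for (i in seq_len(bpLength)) {
    cur <- substr(b, i, i)
    for (repl in BASES[BASES != cur]) {
      k <- k + 1L
      out[k] <- paste0(substr(b, 1L, i - 1L), repl,
                       substr(b, i + 1L, bpLength))
    }
  }
  out
}

# random fixed-length barcodes with pairwise Hamming distance >= minHamming.
# For the default minHamming = 3 this is exact and linear in n: two codes
# lie within distance 2 iff their distance-<=1 neighborhoods intersect, so
# a hash of accepted neighborhoods suffices. Smaller minHamming values
# fall back to the same (conservative) scheme.
.randomBarcodes <- function(n, bpLength = 16L, minHamming = 3L) {
  if (minHamming > 3L)
    stop("minHamming > 3 is not supported")
  seen <- new.env(parent = emptyenv(), hash = TRUE, size = 4L * n * bpLength)
  accepted <- character(n)
  got <- 0L
  while (got < n) {
    need <- n - got
    batch <- matrix(sample.int(4L, 2L * need * bpLength, replace = TRUE),
                    ncol = bpLength)
    cands <- do.call(paste0, as.data.frame(matrix(BASES[batch],
                                                  ncol = bpLength)))
    for (b in cands) {
      if (got >= n) break
      ball <- .hammingBall1(b, bpLength)
      if (any(vapply(ball, exists, logical(1), envir = seen,
                     inherits = FALSE)))
        next
      for (z in ball) assign(z, TRUE, envir = seen)
      got <- got + 1L
      accepted[got] <- b
    }
  }
  accepted
}

# encode integer ids as fixed-length ACGT strings (base-4); unique by
# construction, used for UMIs so that distinct molecules never collide
.encodeIdsAsBases <- function(ids, len) {
  out <- matrix("A", nrow = length(ids), ncol = len)
  x <- as.integer(ids)
  for (j in seq_len(len)) {
    out[, len - j + 1L] <- BASES[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

# genome as a named DNAStringSet, from a path or passed through
.loadGenome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::readDNAStringSet(genome)
}

.genomeSeqinfo <- function(genome) {
  g <- .loadGenome(genome)
  nm <- sub("\\s.*$", "", names(g))
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = Biostrings::width(g))
}

# uniform draw of n genomic positions (1-based) over a set of ranges,
# weighted by width; returns data.table(chrom, pos)
.samplePositionsInRanges <- function(n, gr) {
  if (n == 0L)
    return(data.table(chrom = character(0), pos = integer(0)))
  w <- GenomicRanges::width(gr)
  cum <- cumsum(as.numeric(w))
  total <- cum[length(cum)]
  off <- ceiling(stats::runif(n) * total) # uniform in 1..total
  ri <- findInterval(off - 1, cum) + 1L   # which range
  within <- off - c(0, cum)[ri]           # 1-based offset inside range
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr))[ri],
    pos = GenomicRanges::start(gr)[ri] + as.integer(within) - 1L
  )
}

.writeLinesGz <- function(lines, path) {
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

utils::globalVariables(c(
  ".", ".N", ".SD", "droplet", "variant", "molecule", "mate", "isAlt",
  "obsBase", "chrom", "pos", "start", "strand", "isAmbient", "srcDonor",
  "readId", "fragId", "base", "cb", "ub", "qname", "nBase", "N", "V1",
  "barcode", "call", "type", "donor1", "donor2", "count", "coverage",
  "i1", "total", "fragStart", "fragEnd", "insertLen", "umi", "keepBase",
  "rk", "row", "n", "nBases", "ok", "category", "isSinglet",
  "bcIdx", "molKey"
))
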