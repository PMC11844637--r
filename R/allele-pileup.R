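.newAllelePileup <- function(ref, alt, panel, barcodes, other = 0,
                             ties = 0) {
  v <- variants(panel)
  dimnames(ref) <- dimnames(alt) <- list(names(v), barcodes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ref = ref, alt = alt), rowRanges = v)
  methods::new("AllelePileup", se, otherCount = as.numeric(other),
               tieCount = as.numeric(ties))
}

#' @describeIn AllelePileup-class sparse reference-allele count matrix
#'   (variants x droplets).
#' @param x,object an `AllelePileup`.
#' @export
setMethod("refCounts", "AllelePileup", function(x)
  SummarizedExperiment::assay(x, "ref"))

#' @describeIn AllelePileup-class sparse alternate-allele count matrix.
#' @export
setMethod("altCounts", "AllelePileup", function(x)
  SummarizedExperiment::assay(x, "alt"))

#' @describeIn AllelePileup-class droplet barcodes (column names).
#' @export
setMethod("barcodes", "AllelePileup", function(x) colnames(x))

#' @export
setMethod("show", "AllelePileup", function(object) {
  cat("AllelePileup:", nrow(object), "variants x", ncol(object),
      "droplets\n")
  cat(sprintf("  counts: ref %g, alt %g; other-base molecules %g, ties %g\n",
              sum(refCounts(object)), sum(altCounts(object)),
              object@otherCount, object@tieCount))
})

# shared collapse + classify step: takes a data.table with one row per
# (barcode index, molecule key, variant, base) observation and returns
# sparse matrices. A molecule contributes one count per variant if all
# its observations agree on the base; disagreeing molecules are dropped
# (tie), bases matching neither allele are tallied as "other".
.collapseAndCount <- function(obs, panel, nBarcodes) {
  V <- nVariants(panel)
  mc <- S4Vectors::mcols(variants(panel))
  if (!nrow(obs)) {
    z <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(V, nBarcodes))
    return(list(ref = z, alt = z, other = 0, ties = 0))
  }
  grp <- obs[, list(nBases = data.table::uniqueN(base), base = base[1L]),
             by = list(bcIdx, molKey, variant)]
  ties <- sum(grp$nBases > 1L)
  grp <- grp[nBases == 1L]
  isRef <- grp$base == mc$ref[grp$variant]
  isAlt <- grp$base == mc$alt[grp$variant]
  other <- sum(!isRef & !isAlt)
  mk <- function(mask) {
    sub <- grp[mask, list(n = .N), by = list(variant, bcIdx)]
    Matrix::sparseMatrix(i = sub$variant, j = sub$bcIdx, x = sub$n,
                         dims = c(V, nBarcodes))
  }
  list(ref = mk(isRef), alt = mk(isAlt), other = other, ties = ties)
}

#' Pile up allele counts from a barcode-tagged BAM
#'
#' Builds the droplet x variant reference/alternate count matrices from
#' a coordinate-sorted, indexed BAM with `CB` (and, for RNA, `UB`) tags.
#' One count is recorded per molecule per overlapped variant: RNA reads
#' sharing (CB, UB) collapse to a single molecule; ATAC mate pairs
#' (shared query name) count a variant once even when both mates cover
#' it. Molecules whose reads disagree at a variant are excluded (tie);
#' bases matching neither the reference nor the alternate allele are
#' excluded from both matrices and tallied separately.
#'
#' Only primary, mapped alignments with simple match CIGARs contribute;
#' reads below `minMapq` and bases below `minBaseq` are skipped.
#'
#' @param bam path to an indexed BAM.
#' @param panel a [VariantPanel-class].
#' @param whitelist character vector of droplet barcodes to keep (the
#'   matrix columns, in this order).
#' @param minMapq,minBaseq quality thresholds (defaults 20/20; the
#'   simulator emits MAPQ 60 / Q37, so the defaults are non-filtering on
#'   simulated data while remaining meaningful on real BAMs).
#' @param modality `"auto"` (UMI-collapse when UB tags are present,
#'   pair-collapse otherwise), `"rna"` or `"atac"`.
#' @return an [AllelePileup-class].
#' @export
pileupCounts <- function(bam, panel, whitelist, minMapq = 20L,
                         minBaseq = 20L, modality = c("auto", "rna", "atac")) {
  modality <- match.arg(modality)
  if (!length(whitelist))
    return(.newAllelePileup(
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(nVariants(panel), 0L)),
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(nVariants(panel), 0L)),
      panel, character(0)))
  v <- GenomicRanges::granges(variants(panel))
  param <- Rsamtools::ScanBamParam(
    which = v,
    what = c("qname", "pos", "cigar", "seq", "qual", "mapq"),
    tag = c("CB", "UB"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)
  vpos <- GenomicRanges::start(v)
  pieces <- vector("list", length(res))
  nTotal <- 0L
  nNoCB <- 0L
  for (i in seq_along(res)) {
    r <- res[[i]]
    nr <- length(r$pos)
    if (!nr) next
    nTotal <- nTotal + nr
    cb <- r$tag$CB
    if (is.null(cb)) cb <- rep(NA_character_, nr)
    nNoCB <- nNoCB + sum(is.na(cb))
    ub <- r$tag$UB
    if (is.null(ub)) ub <- rep(NA_character_, nr)
    simple <- grepl("^[0-9]+M$", r$cigar)
    off <- vpos[i] - r$pos + 1L
    sq <- as.character(r$seq)
    ok <- simple & !is.na(cb) & r$mapq >= minMapq &
      off >= 1L & off <= nchar(sq)
    if (!any(ok)) next
    off <- off[ok]
    sq <- sq[ok]
    base <- substring(sq, off, off)
    qualChar <- substring(as.character(r$qual)[ok], off, off)
    phred <- utf8ToInt(paste(qualChar, collapse = "")) - 33L
    keep <- phred >= minBaseq
    if (!any(keep)) next
    pieces[[i]] <- data.table(
      variant = i, cb = cb[ok][keep], ub = ub[ok][keep],
      qname = r$qname[ok][keep], base = base[keep])
  }
  if (nTotal > 0L && nNoCB > nTotal / 2)
    stop("more than half of the overlapping reads lack a CB tag (",
         nNoCB, "/", nTotal, "); is this the right BAM?")
  obs <- data.table::rbindlist(pieces)
  if (nrow(obs)) {
    obs[, bcIdx := match(cb, whitelist)]
    obs <- obs[!is.na(bcIdx)]
    useUmi <- switch(modality,
                     rna = TRUE, atac = FALSE,
                     auto = any(!is.na(obs$ub)))
    obs[, molKey := if (useUmi) ub else qname]
    obs <- obs[!is.na(molKey)]
  } else {
    obs <- data.table(bcIdx = integer(0), molKey = character(0),
                      variant = integer(0), base = character(0))
  }
  cc <- .collapseAndCount(obs, panel, length(whitelist))
  .newAllelePileup(cc$ref, cc$alt, panel, whitelist, cc$other, cc$ties)
}

#' Pile up allele counts directly from simulated reads
#'
#' File-free counterpart of [pileupCounts()]: aggregates the
#' [SimExperiment-class]'s per-molecule variant hits with the same
#' molecule-collapse and base-classification rules (RNA UMIs are unique
#' per read; ATAC mate pairs count once per fragment, disagreeing mates
#' are dropped). On a zero-error experiment both routes and the
#' simulator's internal truth agree exactly; this route scales to large
#' sweeps without touching disk.
#'
#' @param sim a [SimExperiment-class].
#' @param modality `"rna"` or `"atac"`.
#' @param whitelist barcodes to keep as columns (default: all droplets).
#' @return an [AllelePileup-class].
#' @export
pileupFromReads <- function(sim, modality = c("rna", "atac"),
                            whitelist = barcodes(sim)) {
  modality <- match.arg(modality)
  h <- simHits(sim, modality)
  rd <- simReads(sim, modality)
  obs <- data.table(
    bcIdx = match(barcodes(sim)[rd$droplet[h$molecule]], whitelist),
    molKey = as.character(h$molecule),
    variant = h$variant, base = h$obsBase)
  obs <- obs[!is.na(bcIdx)]
  cc <- .collapseAndCount(obs, sim@panel, length(whitelist))
  .newAllelePileup(cc$ref, cc$alt, sim@panel, whitelist, cc$other, cc$ties)
}

#' Merge allele pileups from multiple runs
#'
#' Barcode-wise union with count-wise summation on shared barcodes.
#' All pileups must be built against the identical variant table.
#'
#' @param ... [AllelePileup-class] objects (or a single list of them).
#' @return an [AllelePileup-class].
#' @export
mergePileups <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !methods::is(ps[[1]], "AllelePileup"))
    ps <- ps[[1]]
  if (length(ps) < 1L) stop("nothing to merge")
  ref0 <- SummarizedExperiment::rowRanges(ps[[1]])
  for (p in ps[-1]) {
    if (!identical(as.data.frame(SummarizedExperiment::rowRanges(p)),
                   as.data.frame(ref0)))
      stop("pileups were built against different variant tables")
  }
  allBc <- unique(unlist(lapply(ps, barcodes)))
  V <- nrow(ps[[1]])
  acc <- function(name) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(V, length(allBc)))
    for (p in ps) {
      j <- match(barcodes(p), allBc)
      expand <- Matrix::sparseMatrix(
        i = seq_along(j), j = j, x = 1,
        dims = c(length(j), length(allBc)))
      m <- m + SummarizedExperiment::assay(p, name) %*% expand
    }
    m
  }
  panelLike <- methods::new("VariantPanel",
    variants = ref0,
    genotypes = matrix(integer(0), nrow = 0, ncol = length(ref0),
                       dimnames = list(NULL, names(ref0))),
    dropped = 0L)
  .newAllelePileup(acc("ref"), acc("alt"), panelLike, allBc,
                   sum(vapply(ps, function(p) p@otherCount, 1)),
                   sum(vapply(ps, function(p) p@tieCount, 1)))
}

#' Write / read a pileup as MatrixMarket with TSV sidecars
#'
#' `writePileup()` stores `ref.mtx`, `alt.mtx`, `barcodes.tsv` and
#' `variants.tsv` in a directory, the interchange layout of the
#' single-cell matrix ecosystem; `readPileup()` reconstructs the
#' [AllelePileup-class].
#'
#' @param pileup an [AllelePileup-class].
#' @param dir directory to write to / read from.
#' @return `writePileup()`: `dir`, invisibly. `readPileup()`: an
#'   `AllelePileup` (genotype-free variant panel: coordinates and
#'   alleles only).
#' @export
writePileup <- function(pileup, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(refCounts(pileup), file.path(dir, "ref.mtx"))
  Matrix::writeMM(altCounts(pileup), file.path(dir, "alt.mtx"))
  writeLines(barcodes(pileup), file.path(dir, "barcodes.tsv"))
  v <- SummarizedExperiment::rowRanges(pileup)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(v)),
                   pos = GenomicRanges::start(v),
                   id = names(v),
                   ref = S4Vectors::mcols(v)$ref,
                   alt = S4Vectors::mcols(v)$alt)
  utils::write.table(df, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(other = pileup@otherCount, ties = pileup@tieCount)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writePileup
#' @export
readPileup <- function(dir) {
  ref <- methods::as(Matrix::readMM(file.path(dir, "ref.mtx")), "CsparseMatrix")
  alt <- methods::as(Matrix::readMM(file.path(dir, "alt.mtx")), "CsparseMatrix")
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  df <- utils::read.delim(file.path(dir, "variants.tsv"),
                          stringsAsFactors = FALSE)
  v <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
  names(v) <- df$id
  S4Vectors::mcols(v) <- S4Vectors::DataFrame(
    ref = df$ref, alt = df$alt, r2 = NA_real_, maf = NA_real_)
  panelLike <- methods::new("VariantPanel",
    variants = v,
    genotypes = matrix(integer(0), nrow = 0, ncol = length(v),
                       dimnames = list(NULL, names(v))),
    dropped = 0L)
  meta <- tryCatch(utils::read.delim(file.path(dir, "meta.tsv")),
                   error = function(e) data.frame(other = 0, ties = 0),
                   warning = function(w) data.frame(other = 0, ties = 0))
  .newAllelePileup(ref, alt, panelLike, bcs, meta$other, meta$ties)
}
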