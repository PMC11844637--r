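#' Load donor genotypes from a VCF
#'
#' Parses a VCF (plain or bgzipped) into a [VariantPanel-class]: a table
#' of biallelic SNPs plus the K x V donor dosage matrix. Non-SNP and
#' multiallelic records are dropped, counted and reported. Variant order
#' is the VCF order. GT values are converted to alt-allele dosage
#' (phasing is ignored); missing calls become `NA`. INFO fields `R2` and
#' `AF` are attached when present; the stored `maf` is `min(AF, 1 - AF)`.
#'
#' @param vcfPath path to the VCF.
#' @param donorSubset optional character vector of donor (sample) ids to
#'   keep, in the requested order. Unknown ids raise an error listing the
#'   donors available in the header.
#' @return a [VariantPanel-class].
#' @examples
#' \donttest{
#' ref <- makeToyReference(tempfile(), chromLength = 1e5, nVariants = 100,
#'                         nBarcodes = 10)
#' panel <- loadGenotypes(ref$vcf)
#' nVariants(panel); donorIds(panel)
#' }
#' @export
loadGenotypes <- function(vcfPath, donorSubset = NULL) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  avail <- colnames(vcf)
  if (!is.null(donorSubset)) {
    missing <- setdiff(donorSubset, avail)
    if (length(missing))
      stop("donor(s) not in VCF header: ", paste(missing, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
    vcf <- vcf[, donorSubset]
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  altFirst <- rep(NA_character_, length(nAlt))
  altFirst[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
  keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(altFirst) &
    nchar(altFirst) == 1L & ref %in% BASES & altFirst %in% BASES &
    ref != altFirst
  dropped <- sum(!keep)
  if (dropped)
    message("loadGenotypes: dropped ", dropped,
            " non-biallelic/non-SNP record(s)")
  vcf <- vcf[keep, ]
  ref <- ref[keep]
  alt <- altFirst[keep]

  gtChar <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtChar))
    stop("VCF has no GT field")
  lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage <- lut[gtChar]
  dim(dosage) <- dim(gtChar)
  dosage <- t(dosage) # K x V
  rownames(dosage) <- colnames(vcf)
  colnames(dosage) <- rownames(vcf)

  info <- VariantAnnotation::info(vcf)
  r2 <- rep(NA_real_, length(ref))
  af <- rep(NA_real_, length(ref))
  if ("R2" %in% names(info)) r2 <- as.numeric(info$R2)
  if ("AF" %in% names(info)) {
    afL <- info$AF
    if (is.list(afL) || methods::is(afL, "List")) {
      af <- vapply(as.list(afL),
                   function(x) if (length(x)) as.numeric(x[[1]]) else NA_real_,
                   numeric(1))
    } else af <- as.numeric(afL)
  }
  gr <- SummarizedExperiment::rowRanges(vcf)
  v <- GenomicRanges::granges(gr)
  names(v) <- rownames(vcf)
  S4Vectors::mcols(v) <- S4Vectors::DataFrame(
    ref = ref, alt = alt, r2 = r2, maf = pmin(af, 1 - af))
  methods::new("VariantPanel", variants = v, genotypes = dosage,
               dropped = as.integer(dropped))
}

#' @describeIn VariantPanel-class variant positions and alleles.
#' @param x,object a `VariantPanel`.
#' @export
setMethod("variants", "VariantPanel", function(x) x@variants)

#' @describeIn VariantPanel-class K x V alt-allele dosage matrix.
#' @export
setMethod("genotypes", "VariantPanel", function(x) x@genotypes)

#' @describeIn VariantPanel-class donor identifiers.
#' @export
setMethod("donorIds", "VariantPanel", function(x) rownames(x@genotypes))

#' @describeIn VariantPanel-class number of variants V.
#' @export
setMethod("nVariants", "VariantPanel", function(x) length(x@variants))

#' @describeIn VariantPanel-class number of donors K.
#' @export
setMethod("nDonors", "VariantPanel", function(x) nrow(x@genotypes))

#' @describeIn VariantPanel-class subset variants (genotype columns move
#'   in lockstep).
#' @param i variant index (logical, integer or character).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantPanel", function(x, i, j, ..., drop = FALSE) {
  methods::new("VariantPanel",
               variants = x@variants[i],
               genotypes = x@genotypes[, i, drop = FALSE],
               dropped = x@dropped)
})

#' @export
setMethod("show", "VariantPanel", function(object) {
  cat("VariantPanel:", nVariants(object), "biallelic SNPs x",
      nDonors(object), "donors\n")
  cat("  donors:", paste(donorIds(object), collapse = ", "), "\n")
  nr2 <- sum(!is.na(S4Vectors::mcols(object@variants)$r2))
  cat("  variants with R2 annotation:", nr2, "\n")
  if (object@dropped)
    cat("  records dropped at load:", object@dropped, "\n")
})

#' @rdname filterVariants
#' @export
setMethod("filterVariants", "VariantPanel", function(x, minR2 = 0, minMaf = 0) {
  mc <- S4Vectors::mcols(x@variants)
  passR2 <- is.na(mc$r2) | mc$r2 > minR2
  passMaf <- is.na(mc$maf) | mc$maf > minMaf
  nNa <- sum((is.na(mc$r2) & minR2 > 0) | (is.na(mc$maf) & minMaf > 0))
  if (nNa)
    message("filterVariants: ", nNa,
            " variant(s) passed for lack of an R2/MAF annotation")
  x[passR2 & passMaf]
})

#' Allele set carried by a donor at a variant
#'
#' Maps the diploid dosage of one donor at one variant to the set of
#' alleles that donor carries: dosage 0 -> `{ref}`, 1 -> `{ref, alt}`,
#' 2 -> `{alt}`. A missing genotype returns `character(0)`: the variant
#' is excluded from consistency classification for that donor rather
#' than a consistency being fabricated.
#'
#' @param panel a [VariantPanel-class].
#' @param donor donor id or index.
#' @param variant variant id or index.
#' @return character vector of allele bases (length 0, 1 or 2).
#' @export
donorAlleleSet <- function(panel, donor, variant) {
  if (is.character(variant)) variant <- match(variant, names(variants(panel)))
  g <- genotypes(panel)[donor, variant]
  mc <- S4Vectors::mcols(variants(panel))
  ref <- mc$ref[variant]
  alt <- mc$alt[variant]
  if (is.na(g)) return(character(0))
  switch(as.character(g),
         "0" = ref,
         "1" = c(ref, alt),
         "2" = alt)
}

#' Dump a variant table as TSV (debugging aid)
#'
#' @param panel a [VariantPanel-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
dumpVariants <- function(panel, path) {
  v <- variants(panel)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(v)),
    pos = GenomicRanges::start(v),
    id = if (is.null(names(v))) seq_along(v) else names(v),
    ref = S4Vectors::mcols(v)$ref,
    alt = S4Vectors::mcols(v)$alt,
    r2 = S4Vectors::mcols(v)$r2,
    maf = S4Vectors::mcols(v)$maf
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
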