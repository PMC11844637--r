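#' @include AllClasses.R
NULL

#' Accessors for ambimux classes
#'
#' Small accessor generics: `variants()` and `genotypes()` return the SNP
#' table and dosage matrix of a [VariantPanel-class]; `donorIds()`,
#' `nVariants()` and `nDonors()` its dimensions; `barcodes()` the droplet
#' identifiers of a [DropletSet-class], [SimExperiment-class] or
#' [AllelePileup-class]; `refCounts()`/`altCounts()` the sparse allele
#' count matrices of an [AllelePileup-class]; `consistencyCountMatrix()`
#' and `consistencyRates()` the F matrix and its row-normalized rates.
#'
#' @param x an ambimux object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("nDonors", function(x) standardGeneric("nDonors"))

#' @rdname accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname accessors
#' @export
setGeneric("consistencyCountMatrix", function(x) standardGeneric("consistencyCountMatrix"))

#' @rdname accessors
#' @export
setGeneric("consistencyRates", function(x) standardGeneric("consistencyRates"))

#' Filter variants on imputation quality and minor allele frequency
#'
#' Keeps variants with imputation R2 strictly greater than `minR2` and
#' minor allele frequency strictly greater than `minMaf`. Variants with
#' no R2 or MAF annotation pass the corresponding filter (the filter
#' applies only where the field exists); the number of such pass-through
#' variants is reported via `message()`.
#'
#' @param x a [VariantPanel-class].
#' @param minR2 imputation quality threshold (strict `>`), default 0
#'   (no filtering). The conventional stringent choice for imputed donor
#'   genotypes is 0.90.
#' @param minMaf minor allele frequency threshold (strict `>`), default 0.
#'   The conventional choice for common variants is 0.01.
#' @return a `VariantPanel` with the surviving variants, genotype columns
#'   subset in lockstep.
#' @export
setGeneric("filterVariants", function(x, minR2 = 0, minMaf = 0)
  standardGeneric("filterVariants"))
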