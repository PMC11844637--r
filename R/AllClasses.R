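#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' VariantPanel: biallelic SNPs with per-donor diploid genotypes
#'
#' Holds a set of biallelic SNVs together with the donor genotype matrix
#' `G` (K donors x V variants), encoded as alt-allele dosage 0/1/2 with
#' `NA` for missing calls. Variant coordinates are kept as a
#' [GenomicRanges::GRanges] of width-1 positions with metadata columns
#' `ref`, `alt` and, when present in the source VCF, `r2` (imputation
#' quality) and `maf` (minor allele frequency).
#'
#' @slot variants `GRanges` of V width-1 SNP positions.
#' @slot genotypes integer matrix, K x V, alt-allele dosage in {0,1,2,NA};
#'   rownames are donor identifiers.
#' @slot dropped integer; count of non-biallelic/non-SNP records discarded
#'   while loading.
#'
#' @seealso [loadGenotypes()], [filterVariants()], [donorAlleleSet()]
#' @export
setClass("VariantPanel",
  representation(
    variants = "GRanges",
    genotypes = "matrix",
    dropped = "integer"
  )
)

setValidity("VariantPanel", function(object) {
  msg <- character(0)
  v <- object@variants
  g <- object@genotypes
  if (length(v) != ncol(g))
    msg <- c(msg, "number of variants must equal ncol(genotypes)")
  if (nrow(g) > 0L && is.null(rownames(g)))
    msg <- c(msg, "genotypes must have donor ids as rownames")
  if (!all(c("ref", "alt") %in% names(S4Vectors::mcols(v))))
    msg <- c(msg, "variants must carry 'ref' and 'alt' metadata columns")
  if (length(v) && any(GenomicRanges::width(v) != 1L))
    msg <- c(msg, "variants must be width-1 SNP positions")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "genotype dosages must be 0, 1, 2 or NA")
  if (length(v) && any(S4Vectors::mcols(v)$ref == S4Vectors::mcols(v)$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if (length(msg)) msg else TRUE
})

#' ExperimentConfig: experiment-level simulation parameters
#'
#' Latent-attribute sampling parameters of a multiplexed droplet
#' experiment: pool composition, droplet-type rates, ambient
#' contamination level and per-modality sequencing depth.
#'
#' @slot nDroplets number of droplets to simulate.
#' @slot nDonors number of multiplexed donors K.
#' @slot doubletRate expected fraction of (heterotypic) doublets.
#' @slot emptyRate expected fraction of empty (ambient-only) droplets.
#' @slot donorProportions K-vector of pool proportions (sums to 1).
#' @slot ambientLevel experiment-level mean ambient read fraction in \[0,1).
#' @slot ambientConcentration Beta concentration of per-droplet ambient
#'   fractions around `ambientLevel`.
#' @slot rnaDepthMean,atacDepthMean mean reads per droplet, per modality.
#' @slot depthDispersion negative-binomial size parameter of depths
#'   (variance = mean + mean^2 / dispersion).
#' @slot emptyDepthFactor empty-droplet depth mean as a fraction of the
#'   cell depth mean.
#' @slot doubletMixShape1,doubletMixShape2 Beta shape parameters of the
#'   donor-1 share of native reads within a doublet.
#' @slot seed integer RNG seed.
#'
#' @seealso [experimentConfig()], [sampleDroplets()]
#' @export
setClass("ExperimentConfig",
  representation(
    nDroplets = "integer",
    nDonors = "integer",
    doubletRate = "numeric",
    emptyRate = "numeric",
    donorProportions = "numeric",
    ambientLevel = "numeric",
    ambientConcentration = "numeric",
    rnaDepthMean = "numeric",
    atacDepthMean = "numeric",
    depthDispersion = "numeric",
    emptyDepthFactor = "numeric",
    doubletMixShape1 = "numeric",
    doubletMixShape2 = "numeric",
    seed = "integer"
  )
)

#' SimParams: read-level simulation parameters
#'
#' @slot rnaReadLength cDNA read length in bp.
#' @slot atacReadLength per-mate genomic read length in bp.
#' @slot umiLength,barcodeLength UMI and cell-barcode lengths in bp.
#' @slot seqErrorRate per-base substitution error rate.
#' @slot ambientInformativeWeight probability that an ambient read is
#'   drawn from informative regions rather than uniformly from the genome.
#' @slot insertMean,insertSd,insertMin,insertMax ATAC fragment insert-size
#'   law: Normal(mean, sd) truncated to \[min, max\].
#' @slot ambientDonorWeights K-vector of donor weights of the ambient
#'   pool; empty means "use the pool proportions".
#'
#' @seealso [simParams()], [simulateReads()]
#' @export
setClass("SimParams",
  representation(
    rnaReadLength = "integer",
    atacReadLength = "integer",
    umiLength = "integer",
    barcodeLength = "integer",
    seqErrorRate = "numeric",
    ambientInformativeWeight = "numeric",
    insertMean = "numeric",
    insertSd = "numeric",
    insertMin = "integer",
    insertMax = "integer",
    ambientDonorWeights = "numeric"
  )
)

#' DropletSet: sampled per-droplet latent attributes
#'
#' One row per droplet: barcode, droplet type (singlet/doublet/empty),
#' donor indices, doublet mixing share, ambient fraction and per-modality
#' depths.
#'
#' @slot droplets data.frame with columns `barcode`, `type`, `donor1`,
#'   `donor2`, `doubletMix`, `ambientFraction`, `rnaDepth`, `atacDepth`.
#' @slot config the [ExperimentConfig-class] the set was drawn from.
#' @export
setClass("DropletSet",
  representation(droplets = "data.frame", config = "ExperimentConfig")
)

setValidity("DropletSet", function(object) {
  d <- object@droplets
  need <- c("barcode", "type", "donor1", "donor2", "doubletMix",
            "ambientFraction", "rnaDepth", "atacDepth")
  msg <- character(0)
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("missing droplet columns:",
                        paste(setdiff(need, names(d)), collapse = ", ")))
  else {
    if (anyDuplicated(d$barcode)) msg <- c(msg, "droplet barcodes must be unique")
    if (!all(d$type %in% c("singlet", "doublet", "empty")))
      msg <- c(msg, "droplet type must be singlet, doublet or empty")
    bad <- d$type == "singlet" & (is.na(d$donor1) | !is.na(d$donor2))
    if (any(bad)) msg <- c(msg, "singlets must have exactly one donor")
    bad <- d$type == "doublet" &
      (is.na(d$donor1) | is.na(d$donor2) | d$donor1 == d$donor2)
    if (any(bad)) msg <- c(msg, "doublets must have two distinct donors")
    bad <- d$type == "empty" &
      (!is.na(d$donor1) | !is.na(d$donor2) | d$ambientFraction != 1)
    if (any(bad)) msg <- c(msg, "empty droplets must have no donors and ambient fraction 1")
    if (any(d$rnaDepth < 0) || any(d$atacDepth < 0))
      msg <- c(msg, "depths must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SimExperiment: a simulated multiplexed multiome experiment
#'
#' In-memory result of [simulateReads()]: droplet attributes, per-read
#' tables for both modalities, per-molecule variant hits (the simulator's
#' internal ground truth of emitted alleles), and per-droplet truth
#' counts. Files (FASTQ/BAM/truth TSVs) are emitted separately by
#' [writeSimOutputs()].
#'
#' @slot droplets the [DropletSet-class] the reads were generated from.
#' @slot panel the [VariantPanel-class] used for allele injection.
#' @slot params the [SimParams-class] used.
#' @slot reads list with elements `rna` and `atac`; data.tables of read
#'   (RNA) or fragment (ATAC) records.
#' @slot hits list with elements `rna` and `atac`; data.tables of
#'   per-molecule variant overlaps: molecule id, mate, variant index,
#'   emitted allele (`isAlt`) and observed base after sequencing error.
#' @slot truth data.frame, one row per droplet: realized native/ambient
#'   molecule counts per modality.
#' @slot seqinfo `Seqinfo` of the reference genome.
#' @slot regions list of `GRanges`: `rna` (gene bodies) and `atac` (peaks).
#' @slot seed integer seed the experiment was generated under.
#' @export
setClass("SimExperiment",
  representation(
    droplets = "DropletSet",
    panel = "VariantPanel",
    params = "SimParams",
    reads = "list",
    hits = "list",
    truth = "data.frame",
    seqinfo = "ANY",
    regions = "list",
    seed = "integer"
  )
)

#' AllelePileup: droplet x variant allele count matrices
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with rows =
#' variants (rowRanges carry `ref`/`alt`) and columns = droplet barcodes,
#' and two sparse assays: `ref` (reference-allele read counts, the
#' Methods' R matrix) and `alt` (alternate-allele counts, A). Bases
#' matching neither allele are excluded from both and tallied in
#' `otherCount`; molecules whose reads disagree at a variant are excluded
#' and tallied in `tieCount`.
#'
#' @slot otherCount numeric; molecules carrying a non-ref, non-alt base.
#' @slot tieCount numeric; molecules excluded for within-molecule
#'   base disagreement (UMI or mate ties).
#' @export
setClass("AllelePileup",
  contains = "RangedSummarizedExperiment",
  representation(otherCount = "numeric", tieCount = "numeric")
)

setValidity("AllelePileup", function(object) {
  msg <- character(0)
  if (!all(c("ref", "alt") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'ref' and 'alt' are required")
  else {
    r <- SummarizedExperiment::assay(object, "ref")
    a <- SummarizedExperiment::assay(object, "alt")
    if (any(r@x < 0) || any(a@x < 0))
      msg <- c(msg, "allele counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' ConsistencyResult: per-droplet C1/C2/I1/I2 allele classification
#'
#' Output of [consistencyCounts()]: the D x 4 matrix F of classified
#' allele counts for assigned singlets, per-variant aggregates used by
#' [snpCoverageI1Profile()], and bookkeeping of excluded droplets.
#'
#' @slot counts numeric matrix, assigned droplets x c(C1, C2, I1, I2);
#'   rownames are barcodes.
#' @slot assignments data.frame (`barcode`, `call`) restricted to the
#'   donor-assigned droplets the rows of `counts` correspond to.
#' @slot variantStats data.frame per variant: experiment-wide coverage,
#'   classified allele count total and I1 total.
#' @slot perVariant logical; TRUE if counts were binarized per
#'   (droplet, variant, allele) before classification.
#' @slot skipped named integer vector of droplets left out (doublet or
#'   unassigned calls, barcodes absent from the pileup).
#' @export
setClass("ConsistencyResult",
  representation(
    counts = "matrix",
    assignments = "data.frame",
    variantStats = "data.frame",
    perVariant = "logical",
    skipped = "integer"
  )
)

setValidity("ConsistencyResult", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@counts), c("C1", "C2", "I1", "I2")))
    msg <- c(msg, "counts columns must be C1, C2, I1, I2")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})
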