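#' Classify one observed allele against donor genotypes
#'
#' The four variant-consistency categories of an observed allele, given
#' the assigned donor's allele set and the allele sets of the other
#' multiplexed donors:
#'
#' * `C1` — consistent with the assigned donor and with no other donor;
#' * `C2` — consistent with the assigned donor and with at least one
#'   other donor;
#' * `I1` — inconsistent with the assigned donor but carried by at least
#'   one other donor (such alleles must have come from another donor's
#'   material, so I1 is a lower bound on ambient contamination);
#' * `I2` — inconsistent with every donor (sequencing or genotyping
#'   error).
#'
#' A total function: every (allele, sets) combination maps to exactly
#' one category. Donors with a missing genotype contribute an empty
#' allele set and are thereby skipped in the "other donors" comparison.
#'
#' @param allele observed allele base (the variant's ref or alt).
#' @param assignedAlleles allele set of the assigned donor (see
#'   [donorAlleleSet()]).
#' @param otherAlleleSets list of allele sets of the remaining donors
#'   (may be empty, e.g. in a single-donor pool).
#' @return one of `"C1"`, `"C2"`, `"I1"`, `"I2"`.
#' @examples
#' classifyAllele("A", c("A", "G"), list("G"))        # C1
#' classifyAllele("A", c("A", "G"), list(c("A","G"))) # C2
#' classifyAllele("G", "A", list(c("A", "G")))        # I1
#' classifyAllele("G", "A", list("A"))                # I2
#' @export
classifyAllele <- function(allele, assignedAlleles, otherAlleleSets = list()) {
  consistent <- allele %in% assignedAlleles
  matchedOther <- any(vapply(otherAlleleSets,
                             function(s) allele %in% s, logical(1)))
  if (consistent) {
    if (matchedOther) "C2" else "C1"
  } else {
    if (matchedOther) "I1" else "I2"
  }
}

#' Classify pileup allele counts into C1/C2/I1/I2 per droplet
#'
#' Applies the variant-consistency classification to every observed
#' allele of every donor-assigned droplet, accumulating read counts into
#' the droplet x 4 matrix F. For a droplet assigned to donor k, each
#' variant with observed counts contributes its reference-count to the
#' category of the reference allele under k's genotype and its
#' alternate-count to the category of the alternate allele (the two
#' allele streams of a heterozygous droplet are classified
#' independently). Droplets called `doublet` or `unassigned` are
#' excluded (rows absent), as are assignment barcodes missing from the
#' pileup (logged). Variants where the assigned donor's genotype is
#' missing are skipped for that droplet; donors with missing genotypes
#' are skipped in the "other donors" comparison at that variant.
#'
#' @param pileup an [AllelePileup-class].
#' @param panel the [VariantPanel-class] with donor genotypes (same
#'   variant table the pileup was built on).
#' @param assignments data.frame with columns `barcode` and `call`
#'   (donor id, `"doublet"` or `"unassigned"`); each barcode at most
#'   once.
#' @param perVariant if TRUE, counts are binarized per (droplet,
#'   variant, allele) before classification, so F counts distinct
#'   variants rather than reads. Default FALSE (read-count weighting,
#'   which is what makes the per-droplet I1 count comparable to the true
#'   number of ambient molecules).
#' @return a [ConsistencyResult-class].
#' @export
consistencyCounts <- function(pileup, panel, assignments,
                              perVariant = FALSE) {
  stopifnot(all(c("barcode", "call") %in% names(assignments)))
  if (anyDuplicated(assignments$barcode))
    stop("assignment barcodes must be unique")
  if (!identical(names(variants(panel)), rownames(pileup)))
    stop("pileup and panel variant tables disagree")
  donors <- donorIds(panel)
  bad <- setdiff(unique(assignments$call),
                 c(donors, "doublet", "unassigned"))
  if (length(bad))
    stop("unknown assignment call(s): ", paste(bad, collapse = ", "))
  asg <- assignments[assignments$call %in% donors, , drop = FALSE]
  inPileup <- asg$barcode %in% barcodes(pileup)
  nMissing <- sum(!inPileup)
  if (nMissing)
    message("consistencyCounts: ", nMissing,
            " assigned barcode(s) absent from the pileup; skipped")
  asg <- asg[inPileup, , drop = FALSE]
  skipped <- c(doublet = sum(assignments$call == "doublet"),
               unassigned = sum(assignments$call == "unassigned"),
               notInPileup = nMissing)

  g <- genotypes(panel)
  V <- nVariants(panel)
  refM <- refCounts(pileup)
  altM <- altCounts(pileup)
  if (perVariant) {
    refM <- methods::as(refM > 0, "CsparseMatrix") * 1
    altM <- methods::as(altM > 0, "CsparseMatrix") * 1
  }
  # donors carrying each allele at each variant (missing genotypes do
  # not carry either allele)
  carriesRef <- !is.na(g) & g <= 1L
  carriesAlt <- !is.na(g) & g >= 1L
  nCarryRef <- colSums(carriesRef)
  nCarryAlt <- colSums(carriesAlt)

  F <- matrix(0, nrow = nrow(asg), ncol = 4L,
              dimnames = list(asg$barcode, c("C1", "C2", "I1", "I2")))
  i1Variant <- numeric(V)
  totalVariant <- numeric(V)
  colIdx <- match(asg$barcode, barcodes(pileup))
  for (k in donors) {
    rows <- which(asg$call == k)
    if (!length(rows)) next
    kMiss <- is.na(g[k, ])
    kRef <- carriesRef[k, ]
    kAlt <- carriesAlt[k, ]
    othRef <- (nCarryRef - kRef) > 0L
    othAlt <- (nCarryAlt - kAlt) > 0L
    catRef <- ifelse(kRef, ifelse(othRef, 2L, 1L), ifelse(othRef, 3L, 4L))
    catAlt <- ifelse(kAlt, ifelse(othAlt, 2L, 1L), ifelse(othAlt, 3L, 4L))
    subRef <- refM[, colIdx[rows], drop = FALSE]
    subAlt <- altM[, colIdx[rows], drop = FALSE]
    for (cat in 1:4) {
      vr <- which(!kMiss & catRef == cat)
      va <- which(!kMiss & catAlt == cat)
      contrib <- numeric(length(rows))
      if (length(vr))
        contrib <- contrib + Matrix::colSums(subRef[vr, , drop = FALSE])
      if (length(va))
        contrib <- contrib + Matrix::colSums(subAlt[va, , drop = FALSE])
      F[rows, cat] <- F[rows, cat] + contrib
      if (cat == 3L) {
        if (length(vr))
          i1Variant[vr] <- i1Variant[vr] +
            Matrix::rowSums(subRef[vr, , drop = FALSE])
        if (length(va))
          i1Variant[va] <- i1Variant[va] +
            Matrix::rowSums(subAlt[va, , drop = FALSE])
      }
    }
    keep <- !kMiss
    totalVariant[keep] <- totalVariant[keep] +
      Matrix::rowSums(subRef[keep, , drop = FALSE]) +
      Matrix::rowSums(subAlt[keep, , drop = FALSE])
  }
  coverage <- Matrix::rowSums(refCounts(pileup)) +
    Matrix::rowSums(altCounts(pileup))
  vs <- data.frame(
    variant = names(variants(panel)),
    coverage = as.numeric(coverage),
    classifiedTotal = totalVariant,
    i1 = i1Variant,
    stringsAsFactors = FALSE)
  methods::new("ConsistencyResult",
    counts = F,
    assignments = asg,
    variantStats = vs,
    perVariant = perVariant,
    skipped = skipped)
}

#' @describeIn ConsistencyResult-class the D x 4 matrix F of classified
#'   allele counts.
#' @param x,object a `ConsistencyResult`.
#' @export
setMethod("consistencyCountMatrix", "ConsistencyResult",
          function(x) x@counts)

#' @describeIn ConsistencyResult-class row-normalized category rates
#'   (rows with zero classified counts become `NA`).
#' @export
setMethod("consistencyRates", "ConsistencyResult", function(x) {
  rs <- rowSums(x@counts)
  out <- x@counts / rs
  out[rs == 0, ] <- NA_real_
  out
})

#' @describeIn ConsistencyResult-class barcodes of the classified
#'   droplets.
#' @export
setMethod("barcodes", "ConsistencyResult", function(x) rownames(x@counts))

#' @export
setMethod("show", "ConsistencyResult", function(object) {
  cat("ConsistencyResult:", nrow(object@counts), "assigned droplets",
      if (object@perVariant) "(per-variant counts)" else "(read counts)",
      "\n")
  cat("  column totals:\n")
  print(colSums(object@counts))
  if (any(object@skipped > 0)) {
    cat("  excluded droplets:\n")
    print(object@skipped[object@skipped > 0])
  }
})

#' Per-droplet I1 rate
#'
#' I1 / (C1 + C2 + I1 + I2) per droplet. Droplets with no classified
#' counts are returned as `NA` (and counted in a message).
#'
#' @param result a [ConsistencyResult-class].
#' @return named numeric vector (barcodes).
#' @export
i1Rate <- function(result) {
  f <- consistencyCountMatrix(result)
  rs <- rowSums(f)
  zero <- rs == 0
  if (any(zero))
    message("i1Rate: ", sum(zero), " droplet(s) with no classified counts")
  out <- f[, "I1"] / rs
  out[zero] <- NA_real_
  out
}

#' Mean I1 rate by experiment-wide SNP coverage
#'
#' Bins variants by how many times they are covered experiment-wide
#' (sum of ref+alt counts over all droplets in the pileup) and reports
#' the pooled I1 rate (sum of I1 counts / sum of classified counts) per
#' bin. Variants never covered are absent from the table.
#'
#' @param result a [ConsistencyResult-class].
#' @param breaks coverage bin edges (right-closed).
#' @return data.frame with `bin`, `nVariants`, `classified`, `i1`,
#'   `i1Rate`.
#' @export
snpCoverageI1Profile <- function(result,
                                 breaks = c(0, 1, 2, 5, 10, 20, 50, 100,
                                            Inf)) {
  vs <- result@variantStats
  vs <- vs[vs$coverage > 0, , drop = FALSE]
  bin <- cut(vs$coverage, breaks = breaks)
  agg <- stats::aggregate(
    cbind(classified = vs$classifiedTotal, i1 = vs$i1),
    by = list(bin = bin), FUN = sum, drop = TRUE)
  nv <- as.vector(table(bin)[as.character(agg$bin)])
  data.frame(bin = agg$bin, nVariants = nv, classified = agg$classified,
             i1 = agg$i1,
             i1Rate = ifelse(agg$classified > 0,
                             agg$i1 / agg$classified, NA_real_))
}

#' Correlation of per-droplet I1 counts with true ambient load
#'
#' Squared Pearson correlation between per-droplet I1 counts and the
#' true number of ambient molecules, over correctly-assigned singlets of
#' a simulated experiment. This is the metric's validation: I1 counts
#' track the amount of foreign material a droplet captured.
#'
#' @param result a [ConsistencyResult-class] computed with truth (or
#'   method) assignments.
#' @param sim the [SimExperiment-class] the pileup came from (its truth
#'   provides ambient molecule counts).
#' @param modality `"rna"` or `"atac"` — which truth column to use.
#' @return squared Pearson correlation (scalar).
#' @export
ambientCorrelation <- function(result, sim, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  truth <- simTruth(sim)
  ambCol <- if (modality == "rna") "rnaAmbient" else "atacAmbient"
  m <- match(barcodes(result), truth$barcode)
  if (anyNA(m)) stop("result contains barcodes unknown to the experiment")
  isSing <- truth$type[m] == "singlet"
  correct <- isSing &
    result@assignments$call == donorIds(sim@panel)[truth$donor1[m]]
  correct[is.na(correct)] <- FALSE
  if (sum(correct) < 3L)
    stop("need at least 3 correctly-assigned singlets")
  i1 <- consistencyCountMatrix(result)[correct, "I1"]
  amb <- truth[[ambCol]][m][correct]
  if (stats::sd(i1) == 0 || stats::sd(amb) == 0)
    stop("constant I1 or ambient counts; correlation undefined")
  stats::cor(i1, amb)^2
}

#' Full variant-consistency tensor
#'
#' For every droplet, variant and candidate donor, the classification
#' each observed allele stream would receive if the droplet were
#' assigned to that donor — the dense form of the metric, emitted on
#' demand for small inputs (its size is droplets x variants x donors x
#' 4).
#'
#' @param pileup an [AllelePileup-class].
#' @param panel a [VariantPanel-class].
#' @return data.table with columns `barcode`, `variant`, `donor`,
#'   `category`, `count` (non-zero entries only).
#' @export
consistencyTensor <- function(pileup, panel) {
  if (!identical(names(variants(panel)), rownames(pileup)))
    stop("pileup and panel variant tables disagree")
  g <- genotypes(panel)
  donors <- donorIds(panel)
  carriesRef <- !is.na(g) & g <= 1L
  carriesAlt <- !is.na(g) & g >= 1L
  nCarryRef <- colSums(carriesRef)
  nCarryAlt <- colSums(carriesAlt)
  cats <- c("C1", "C2", "I1", "I2")
  refS <- Matrix::summary(refCounts(pileup))
  altS <- Matrix::summary(altCounts(pileup))
  bcs <- barcodes(pileup)
  vn <- rownames(pileup)
  pieces <- list()
  for (k in donors) {
    kMiss <- is.na(g[k, ])
    catRef <- ifelse(carriesRef[k, ],
                     ifelse((nCarryRef - carriesRef[k, ]) > 0L, 2L, 1L),
                     ifelse((nCarryRef - carriesRef[k, ]) > 0L, 3L, 4L))
    catAlt <- ifelse(carriesAlt[k, ],
                     ifelse((nCarryAlt - carriesAlt[k, ]) > 0L, 2L, 1L),
                     ifelse((nCarryAlt - carriesAlt[k, ]) > 0L, 3L, 4L))
    for (stream in list(list(s = refS, cat = catRef),
                        list(s = altS, cat = catAlt))) {
      s <- stream$s
      if (!nrow(s)) next
      keep <- !kMiss[s$i]
      s <- s[keep, , drop = FALSE]
      if (!nrow(s)) next
      pieces[[length(pieces) + 1L]] <- data.table(
        barcode = bcs[s$j], variant = vn[s$i], donor = k,
        category = cats[stream$cat[s$i]], count = s$x)
    }
  }
  if (!length(pieces))
    return(data.table(barcode = character(0), variant = character(0),
                      donor = character(0), category = character(0),
                      count = numeric(0)))
  out <- data.table::rbindlist(pieces)
  out[, list(count = sum(count)),
      by = list(barcode, variant, donor, category)]
}
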