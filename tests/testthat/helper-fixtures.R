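# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated programmatically; nothing is read from disk
# except what the generators themselves wrote.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, build(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small toy reference: 200 kb, 600 SNPs, 4 donors
toyRef <- function() {
  .cached("toyRef", function() {
    suppressMessages(makeToyReference(
      file.path(tempdir(), "ambimux-toyref"),
      chromLength = 2e5, nVariants = 600, nDonors = 4,
      nRnaRegions = 10, nAtacRegions = 20,
      rnaMeanLength = 5000, atacMeanLength = 800,
      nBarcodes = 150, seed = 42))
  })
}

toyPanel <- function() {
  .cached("toyPanel", function() suppressMessages(loadGenotypes(toyRef()$vcf)))
}

# small zero-error experiment with ambient contamination and all three
# droplet types; workhorse for pileup/consistency oracles
toySim <- function() {
  .cached("toySim", function() {
    ref <- toyRef()
    cfg <- experimentConfig(
      nDroplets = 60, nDonors = 4, doubletRate = 0.1, emptyRate = 0.05,
      ambientLevel = 0.2, rnaDepthMean = 400, atacDepthMean = 300,
      seed = 11)
    ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
    suppressMessages(simulateReads(
      ds, toyPanel(), ref$regions$rna, ref$regions$atac, ref$genome,
      params = simParams(seqErrorRate = 0), seed = 12))
  })
}

# files written for the zero-error experiment (BAMs, FASTQs, truth)
toySimFiles <- function() {
  .cached("toySimFiles", function() {
    dir <- file.path(tempdir(), "ambimux-toysim-out")
    writeSimOutputs(toySim(), dir, toyRef()$genome, seed = 13)
  })
}

# independent per-read reclassification of a zero-error experiment:
# loops over molecules with the scalar classifyAllele(), the slow oracle
# against which consistencyCounts() is checked exactly
bruteForceConsistency <- function(sim, modality, assignments) {
  panel <- sim@panel
  donors <- donorIds(panel)
  g <- genotypes(panel)
  mc <- S4Vectors::mcols(variants(panel))
  refA <- mc$ref
  altA <- mc$alt
  # dosage -> allele set, on plain vectors (independent of the matrix
  # classification path; the category logic is classifyAllele itself)
  alleleSet <- function(k, v) {
    d <- g[k, v]
    if (is.na(d)) character(0)
    else if (d == 0L) refA[v]
    else if (d == 1L) c(refA[v], altA[v])
    else altA[v]
  }
  h <- unique(as.data.frame(simHits(sim, modality))[
    , c("molecule", "variant", "obsBase")])
  rd <- simReads(sim, modality)
  dropOf <- rd$droplet
  asg <- assignments[assignments$call %in% donors, ]
  F <- matrix(0, nrow = nrow(asg), ncol = 4,
              dimnames = list(asg$barcode, c("C1", "C2", "I1", "I2")))
  bcAll <- barcodes(sim)
  rowOf <- match(bcAll[dropOf[h$molecule]], asg$barcode)
  for (r in seq_len(nrow(h))) {
    row <- rowOf[r]
    if (is.na(row)) next
    k <- asg$call[row]
    v <- h$variant[r]
    mine <- alleleSet(k, v)
    if (!length(mine)) next # missing genotype: variant excluded
    others <- lapply(setdiff(donors, k), alleleSet, v = v)
    cat4 <- classifyAllele(h$obsBase[r], mine, others)
    F[row, cat4] <- F[row, cat4] + 1
  }
  F
}

expect_matrix_equal <- function(a, b) {
  expect_equal(as.matrix(a), as.matrix(b), ignore_attr = FALSE)
}
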