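test_that("allele classification covers all four categories", {
  # alt allele, assigned het, others hom-ref -> consistent & unique
  expect_identical(classifyAllele("G", c("A", "G"), list("A", "A")), "C1")
  # consistent with assigned and another donor
  expect_identical(classifyAllele("G", c("A", "G"), list(c("A", "G"))), "C2")
  # ref allele, assigned hom-alt, another donor het -> foreign material
  expect_identical(classifyAllele("A", "G", list(c("A", "G"))), "I1")
  # alt allele nobody carries -> sequencing/genotyping error
  expect_identical(classifyAllele("G", "A", list("A", "A")), "I2")
  # single-donor pool: no "other" set can ever match
  expect_identical(classifyAllele("A", "A", list()), "C1")
  expect_identical(classifyAllele("G", "A", list()), "I2")
})

test_that("consistency counts equal the per-read brute-force oracle", {
  sim <- toySim()
  panel <- toyPanel()
  calls <- truthCalls(sim)
  for (m in c("rna", "atac")) {
    ap <- pileupFromReads(sim, m)
    res <- consistencyCounts(ap, panel, calls)
    oracle <- bruteForceConsistency(sim, m, calls)
    expect_identical(consistencyCountMatrix(res)[rownames(oracle), ],
                     oracle)
  }
})

test_that("F rows conserve the classified allele totals", {
  sim <- toySim()
  ap <- pileupFromReads(sim, "rna")
  res <- consistencyCounts(ap, toyPanel(), truthCalls(sim))
  f <- consistencyCountMatrix(res)
  # no missing genotypes in the toy panel, so every counted allele of an
  # assigned droplet is classified
  perDroplet <- Matrix::colSums(refCounts(ap)) + Matrix::colSums(altCounts(ap))
  expect_equal(unname(rowSums(f)), unname(perDroplet[rownames(f)]))
})

test_that("single-donor pools cannot produce C2 or I1", {
  fa <- tempfile(fileext = ".fa")
  makeToyGenome(fa, chromLength = 1e5, seed = 91)
  vcf <- makeToyVcf(fa, tempfile(fileext = ".vcf"), nVariants = 300,
                    nDonors = 1, seed = 91)
  panel <- loadGenotypes(vcf$path)
  regions <- makeToyRegions(fa, tempfile(), tempfile(), nRnaRegions = 5,
                            nAtacRegions = 5, rnaMeanLength = 4000,
                            atacMeanLength = 800, seed = 91)
  cfg <- experimentConfig(nDroplets = 20, nDonors = 1, doubletRate = 0,
                          ambientLevel = 0.3, rnaDepthMean = 500,
                          atacDepthMean = 100, seed = 92)
  ds <- sampleDroplets(cfg, barcodes = makeBarcodeWhitelist(NULL, 20, seed = 92))
  sim <- simulateReads(ds, panel, regions$rna, regions$atac, fa, seed = 93)
  ap <- pileupFromReads(sim, "rna")
  res <- consistencyCounts(ap, panel, truthCalls(sim))
  f <- consistencyCountMatrix(res)
  expect_true(all(f[, "C2"] == 0))
  expect_true(all(f[, "I1"] == 0))
  # coverage profile is all zero I1 as well
  prof <- snpCoverageI1Profile(res)
  expect_true(all(prof$i1 == 0))
})

test_that("doublet/unassigned calls and unknown barcodes are excluded", {
  sim <- toySim()
  ap <- pileupFromReads(sim, "rna")
  panel <- toyPanel()
  calls <- truthCalls(sim)
  res <- consistencyCounts(ap, panel, calls)
  truth <- simTruth(sim)
  expect_identical(sort(rownames(consistencyCountMatrix(res))),
                   sort(truth$barcode[truth$type == "singlet"]))
  # a barcode outside the pileup is skipped with a message
  calls2 <- rbind(calls, data.frame(barcode = "AAAACCCCGGGGTTTT",
                                    call = donorIds(panel)[1]))
  expect_message(res2 <- consistencyCounts(ap, panel, calls2),
                 "absent from the pileup")
  expect_identical(dim(consistencyCountMatrix(res2)),
                   dim(consistencyCountMatrix(res)))
  # unknown call labels are an error
  calls3 <- calls
  calls3$call[1] <- "donorX"
  expect_error(consistencyCounts(ap, panel, calls3), "donorX")
})

test_that("droplets with no counts get all-zero rows", {
  sim <- toySim()
  panel <- toyPanel()
  # a whitelist column with no reads at all gives an all-zero F row
  zeroBc <- strrep("A", 16)
  ap <- pileupFromReads(sim, "rna",
                        whitelist = c(barcodes(sim), zeroBc))
  asg <- data.frame(barcode = c(barcodes(sim)[1], zeroBc),
                    call = donorIds(panel)[1])
  res <- consistencyCounts(ap, panel, asg)
  f <- consistencyCountMatrix(res)
  expect_identical(unname(f[zeroBc, ]), rep(0, 4))
  expect_message(r <- i1Rate(res), "no classified counts")
  expect_true(is.na(r[zeroBc]))
})

test_that("i1Rate is the I1 share of classified counts", {
  res <- methods::new("ConsistencyResult",
    counts = matrix(c(10, 5, 5, 0), 1, 4,
                    dimnames = list("BC", c("C1", "C2", "I1", "I2"))),
    assignments = data.frame(barcode = "BC", call = "d1"),
    variantStats = data.frame(),
    perVariant = FALSE,
    skipped = c(doublet = 0L, unassigned = 0L, notInPileup = 0L))
  expect_identical(unname(i1Rate(res)), 0.25)
})

test_that("missing genotypes exclude the variant for that donor only", {
  # two donors, two SNPs; donor dA has a missing call at SNP 2
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdA\tdB",
    "chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\ts2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1")
  p <- tempfile(fileext = ".vcf")
  writeLines(lines, p)
  panel <- loadGenotypes(p)
  ref <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(3, 4),
                              dims = c(2, 1))
  alt <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(2, 1))
  ap <- ambimux:::.newAllelePileup(ref, alt, panel, "BC1")
  res <- consistencyCounts(ap, panel, data.frame(barcode = "BC1", call = "dA"))
  f <- consistencyCountMatrix(res)
  # SNP2's 4 ref counts are excluded (dA missing there); SNP1: 3 ref
  # counts are C1 (dB is hom-alt), 2 alt counts are I1 (dB carries alt)
  expect_identical(unname(f["BC1", ]), c(3, 0, 2, 0))
  # assigned to dB instead: SNP2 counts; its ref read is C2? no -- dA
  # missing does not carry ref, so ref at SNP2 is consistent & unique
  resB <- consistencyCounts(ap, panel, data.frame(barcode = "BC1", call = "dB"))
  fB <- consistencyCountMatrix(resB)
  # SNP1: 3 ref I1 (dB hom-alt, dA carries ref), 2 alt C1;
  # SNP2: 4 ref C1 (dB het carries ref; dA missing, skipped as "other")
  expect_identical(unname(fB["BC1", ]), c(6, 0, 3, 0))
})

test_that("variants shared by all donors can never yield C1 or I1", {
  panel <- toyPanel()
  g <- genotypes(panel)
  sharedIdx <- which(apply(g, 2, function(x) max(x) == min(x)))
  # the generator forbids fully-shared variants, so construct one
  sim <- toySim()
  ap <- pileupFromReads(sim, "rna")
  tensor <- consistencyTensor(ap, panel)
  shared <- names(variants(panel))[sharedIdx]
  bad <- tensor[tensor$variant %in% shared &
                  tensor$category %in% c("C1", "I1"), ]
  expect_identical(nrow(bad), 0L)
  # and verify the law on a constructed two-donor identical-genotype panel
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdA\tdB",
    "chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1")
  p <- tempfile(fileext = ".vcf")
  writeLines(lines, p)
  panel2 <- loadGenotypes(p)
  ref <- Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(1, 1))
  alt <- Matrix::sparseMatrix(i = 1, j = 1, x = 7, dims = c(1, 1))
  ap2 <- ambimux:::.newAllelePileup(ref, alt, panel2, "BC1")
  f2 <- consistencyCountMatrix(consistencyCounts(
    ap2, panel2, data.frame(barcode = "BC1", call = "dA")))
  expect_identical(unname(f2["BC1", ]), c(0, 12, 0, 0))
})

test_that("coverage profile matches a brute-force group-by", {
  sim <- toySim()
  ap <- pileupFromReads(sim, "rna")
  res <- consistencyCounts(ap, toyPanel(), truthCalls(sim))
  breaks <- c(0, 2, 10, Inf)
  prof <- snpCoverageI1Profile(res, breaks = breaks)
  vs <- res@variantStats
  vs <- vs[vs$coverage > 0, ]
  manual <- tapply(vs$i1, cut(vs$coverage, breaks), sum) /
    tapply(vs$classifiedTotal, cut(vs$coverage, breaks), sum)
  manual <- as.numeric(manual[!is.na(manual)])
  expect_equal(unname(prof$i1Rate), manual)
})

test_that("per-variant mode counts distinct variants, not reads", {
  sim <- toySim()
  ap <- pileupFromReads(sim, "rna")
  panel <- toyPanel()
  calls <- truthCalls(sim)
  resPV <- consistencyCounts(ap, panel, calls, perVariant = TRUE)
  fPV <- consistencyCountMatrix(resPV)
  # per-variant totals equal the number of (variant, allele) streams
  # observed per droplet
  nStreams <- Matrix::colSums(refCounts(ap) > 0) +
    Matrix::colSums(altCounts(ap) > 0)
  expect_equal(unname(rowSums(fPV)), unname(nStreams[rownames(fPV)]))
  # binarized counts can never exceed the read-weighted ones
  fFull <- consistencyCountMatrix(consistencyCounts(ap, panel, calls))
  expect_true(all(fPV <= fFull[rownames(fPV), ]))
})

test_that("I1 counts track true ambient load; permutation kills it", {
  ref <- toyRef()
  cfg <- experimentConfig(nDroplets = 1000, doubletRate = 0,
                          ambientLevel = 0.25, rnaDepthMean = 300,
                          atacDepthMean = 50, seed = 95)
  ds <- sampleDroplets(cfg, barcodes = makeBarcodeWhitelist(NULL, 1000, seed = 95))
  sim <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                       ref$genome, params = simParams(seqErrorRate = 0),
                       seed = 96, modality = "rna")
  ap <- pileupFromReads(sim, "rna")
  res <- consistencyCounts(ap, toyPanel(), truthCalls(sim))
  r2 <- ambientCorrelation(res, sim, "rna")
  expect_gt(r2, 0.3)
  # oracle recomputation
  truth <- simTruth(sim)
  f <- consistencyCountMatrix(res)
  m <- match(rownames(f), truth$barcode)
  expect_equal(r2, stats::cor(f[, "I1"], truth$rnaAmbient[m])^2)
  # permuted I1 column -> correlation collapses toward zero
  set.seed(97)
  resPerm <- res
  resPerm@counts[, "I1"] <- sample(resPerm@counts[, "I1"])
  expect_lt(ambientCorrelation(resPerm, sim, "rna"), 0.01)
  # constant vectors are an error
  cfg0 <- experimentConfig(nDroplets = 10, doubletRate = 0,
                           ambientLevel = 0, rnaDepthMean = 50,
                           atacDepthMean = 50, seed = 98)
  ds0 <- sampleDroplets(cfg0, barcodes = ref$whitelist_barcodes)
  sim0 <- simulateReads(ds0, toyPanel(), ref$regions$rna,
                        ref$regions$atac, ref$genome,
                        params = simParams(seqErrorRate = 0), seed = 99)
  ap0 <- pileupFromReads(sim0, "rna")
  res0 <- consistencyCounts(ap0, toyPanel(), truthCalls(sim0))
  expect_error(ambientCorrelation(res0, sim0, "rna"), "constant")
})
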