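test_that("read counts are conserved per droplet and modality", {
  sim <- toySim()
  d <- as.data.frame(sim@droplets)
  truth <- simTruth(sim)
  rna <- simReads(sim, "rna")
  expect_identical(as.integer(tabulate(rna$droplet, nrow(d))), d$rnaDepth)
  atac <- simReads(sim, "atac")
  expect_identical(as.integer(tabulate(atac$droplet, nrow(d))), d$atacDepth)
  # native + ambient = total
  expect_identical(truth$rnaNative + truth$rnaAmbient, d$rnaDepth)
  expect_identical(truth$atacNative + truth$atacAmbient, d$atacDepth)
})

test_that("zero ambient level means zero ambient molecules", {
  ref <- toyRef()
  cfg <- experimentConfig(nDroplets = 30, doubletRate = 0,
                          ambientLevel = 0, rnaDepthMean = 100,
                          atacDepthMean = 100, seed = 21)
  ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
  sim <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                       ref$genome, seed = 22)
  truth <- simTruth(sim)
  expect_true(all(truth$rnaAmbient == 0))
  expect_true(all(truth$atacAmbient == 0))
})

test_that("empty droplets are purely ambient", {
  truth <- simTruth(toySim())
  emp <- truth[truth$type == "empty", ]
  expect_gt(nrow(emp), 0)
  expect_true(all(emp$rnaNative == 0))
  expect_true(all(emp$atacNative == 0))
})

test_that("realized ambient fractions match the configured level", {
  ref <- toyRef()
  cfg <- experimentConfig(nDroplets = 500, doubletRate = 0,
                          ambientLevel = 0.2, rnaDepthMean = 1000,
                          atacDepthMean = 50, seed = 23)
  ds <- sampleDroplets(cfg, barcodes = makeBarcodeWhitelist(NULL, 500, seed = 23))
  sim <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                       ref$genome, seed = 24, modality = "rna")
  truth <- simTruth(sim)
  frac <- truth$rnaAmbient / (truth$rnaNative + truth$rnaAmbient)
  # per-droplet variance = Beta spread + binomial sampling at depth 1000
  perVar <- 0.2 * 0.8 / 31 + 0.16 / 1000
  expect_lt(abs(mean(frac) - 0.2), 3 * sqrt(perVar / 500))
})

test_that("locus sampling respects ambient status and region structure", {
  ref <- toyRef()
  si <- GenomeInfoDb::Seqinfo("chr1", 2e5)
  inside <- function(loci, gr) {
    q <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos, width = 1))
    GenomicRanges::countOverlaps(q, gr) > 0
  }
  set.seed(31)
  nat <- sampleReadLoci(10000, FALSE, ref$regions$rna, si, 91,
                        informativeWeight = 0.25)
  expect_true(all(inside(nat, ref$regions$rna)))
  ambAll <- sampleReadLoci(5000, TRUE, ref$regions$rna, si, 91,
                           informativeWeight = 1)
  expect_true(all(inside(ambAll, ref$regions$rna)))
  ambNone <- sampleReadLoci(10000, TRUE, ref$regions$rna, si, 91,
                            informativeWeight = 0)
  pInf <- sum(GenomicRanges::width(ref$regions$rna)) / 2e5
  frac <- mean(inside(ambNone, ref$regions$rna))
  expect_lt(abs(frac - pInf), 3 * sqrt(pInf * (1 - pInf) / 10000) + 0.005)
  # reads always fit on the chromosome
  expect_true(all(ambNone$pos + 91 - 1 <= 2e5))
})

test_that("alleles follow the source donor's genotype", {
  ref <- toyRef()
  panel <- toyPanel()
  # all droplets are singlets of donor 2, no ambient: every molecule's
  # allele comes from donor 2's dosage
  cfg <- experimentConfig(nDroplets = 40, nDonors = 4, doubletRate = 0,
                          ambientLevel = 0, rnaDepthMean = 2000,
                          atacDepthMean = 50,
                          donorProportions = c(0, 1, 0, 0), seed = 41)
  ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
  sim <- simulateReads(ds, panel, ref$regions$rna, ref$regions$atac,
                       ref$genome, params = simParams(seqErrorRate = 0),
                       seed = 42, modality = "rna")
  h <- as.data.frame(simHits(sim, "rna"))
  dos <- genotypes(panel)[2, h$variant]
  expect_true(all(!h$isAlt[dos == 0])) # hom-ref: always ref
  expect_true(all(h$isAlt[dos == 2]))  # hom-alt: always alt
  het <- h$isAlt[dos == 1]
  expect_gt(length(het), 3000)
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / length(het)))
})

test_that("ambient alleles reflect the pooled donor genotypes", {
  ref <- toyRef()
  panel <- toyPanel()
  cfg <- experimentConfig(nDroplets = 20, doubletRate = 0, emptyRate = 1,
                          ambientLevel = 0.3, rnaDepthMean = 10000,
                          atacDepthMean = 50, emptyDepthFactor = 1,
                          seed = 43)
  ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
  sim <- simulateReads(ds, panel, ref$regions$rna, ref$regions$atac,
                       ref$genome, params = simParams(seqErrorRate = 0),
                       seed = 44, modality = "rna")
  h <- as.data.frame(simHits(sim, "rna"))
  expect_gt(nrow(h), 10000)
  # expected alt probability per hit: mean dosage / 2 across the equal-
  # weight ambient pool
  pAlt <- colMeans(genotypes(panel)) / 2
  expected <- pAlt[h$variant]
  diff <- mean(h$isAlt) - mean(expected)
  se <- sqrt(sum(expected * (1 - expected))) / nrow(h)
  expect_lt(abs(diff), 3 * se + 0.01)
})

test_that("sequencing errors are uniform substitutions at the set rate", {
  expect_identical(applySequencingErrors(c("ACGT", "GGGG"), 0),
                   c("ACGT", "GGGG"))
  set.seed(51)
  seqs <- strrep("A", 1000)[rep(1, 1000)] # 10^6 bases
  out <- applySequencingErrors(seqs, 0.01)
  mism <- sum(vapply(strsplit(out, ""), function(x) sum(x != "A"), 0L))
  expect_lt(abs(mism - 10000), 3 * sqrt(1e6 * 0.01 * 0.99))
  # substitutions stay within the DNA alphabet (and, the original being
  # all-A, every changed base is necessarily a different base)
  expect_true(all(unlist(strsplit(out, "")) %in% c("A", "C", "G", "T")))
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- toyRef()
  cfg <- experimentConfig(nDroplets = 20, rnaDepthMean = 100,
                          atacDepthMean = 100, seed = 61)
  ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
  s1 <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                      ref$genome, seed = 62)
  s2 <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                      ref$genome, seed = 62)
  expect_identical(as.data.frame(simReads(s1, "rna")),
                   as.data.frame(simReads(s2, "rna")))
  expect_identical(as.data.frame(simHits(s1, "atac")),
                   as.data.frame(simHits(s2, "atac")))
  s3 <- simulateReads(ds, toyPanel(), ref$regions$rna, ref$regions$atac,
                      ref$genome, seed = 63)
  expect_false(identical(as.data.frame(simReads(s1, "rna")),
                         as.data.frame(simReads(s3, "rna"))))
})

test_that("contig mismatches and empty regions are rejected", {
  ref <- toyRef()
  cfg <- experimentConfig(nDroplets = 5, rnaDepthMean = 10,
                          atacDepthMean = 10, seed = 71)
  ds <- sampleDroplets(cfg, barcodes = ref$whitelist_barcodes)
  badRegions <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100))
  expect_error(
    simulateReads(ds, toyPanel(), badRegions, ref$regions$atac,
                  ref$genome, seed = 72),
    "chrX")
  empty <- GenomicRanges::GRanges()
  expect_error(
    simulateReads(ds, toyPanel(), empty, ref$regions$atac,
                  ref$genome, seed = 72),
    "region set is empty")
})
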