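# ten-droplet hand fixture: 6 singlets, 2 doublets, 2 empties
.handTruth <- function() {
  data.frame(
    barcode = paste0("BC", 1:10),
    type = c(rep("singlet", 6), "doublet", "doublet", "empty", "empty"),
    donor1 = c("d1", "d1", "d2", "d2", "d3", "d3", "d1", "d2", NA, NA),
    donor2 = c(rep(NA, 6), "d2", "d3", NA, NA),
    stringsAsFactors = FALSE)
}

test_that("droplet-type accuracy matches hand-computed values", {
  truth <- .handTruth()
  # all categories right
  calls <- callSet(truth$barcode,
                   c("d1", "d1", "d2", "d2", "d3", "d3", "doublet",
                     "doublet", "unassigned", "doublet"))
  expect_identical(dropletTypeAccuracy(calls, truth), 1)
  # two singlets miscalled as doublet: 8/10
  calls2 <- callSet(truth$barcode,
                    c("d1", "doublet", "d2", "doublet", "d3", "d3",
                      "doublet", "doublet", "unassigned", "unassigned"))
  expect_identical(dropletTypeAccuracy(calls2, truth), 0.8)
  # a true empty called as a donor is wrong
  calls3 <- callSet(truth$barcode,
                    c("d1", "d1", "d2", "d2", "d3", "d3", "doublet",
                      "doublet", "d1", "doublet"))
  expect_identical(dropletTypeAccuracy(calls3, truth), 0.9)
  expect_error(dropletTypeAccuracy(callSet("ZZZ", "d1"), truth),
               "share no barcodes")
})

test_that("singleton-donor accuracy uses the donor-called denominator", {
  truth <- .handTruth()
  calls <- callSet(truth$barcode,
                   c("d1", "doublet", "d2", "d3", "d3", "d3", "doublet",
                     "doublet", "unassigned", "unassigned"))
  # donor-called true singlets: BC1 (d1 ok), BC3 (d2 ok), BC4 (d3 wrong),
  # BC5 (d3 ok), BC6 (d3 ok) -> 4/5; BC2 excluded from the denominator
  expect_identical(singletonDonorAccuracy(calls, truth), 0.8)
  # strict variant divides by all six true singlets
  expect_equal(singletonDonorAccuracy(calls, truth, strict = TRUE), 4 / 6)
  # no singlet called a donor -> NA
  allDbl <- callSet(truth$barcode, rep("doublet", 10))
  expect_true(is.na(singletonDonorAccuracy(allDbl, truth)))
})

test_that("random calls sit at the null accuracy bands", {
  set.seed(201)
  n <- 3000
  truth <- data.frame(
    barcode = paste0("B", seq_len(n)),
    type = sample(c("singlet", "doublet", "empty"), n, replace = TRUE),
    donor1 = sample(paste0("d", 1:4), n, replace = TRUE),
    donor2 = NA, stringsAsFactors = FALSE)
  truth$donor1[truth$type != "singlet"] <- NA
  # 3-category random calls: each truth category has exactly one correct
  # call category except empty, which has two (doublet or unassigned)
  calls <- callSet(truth$barcode,
                   sample(c("d1", "doublet", "unassigned"), n, replace = TRUE))
  pEmpty <- mean(truth$type == "empty")
  expAcc <- (1 - pEmpty) / 3 + pEmpty * 2 / 3
  acc <- dropletTypeAccuracy(calls, truth)
  expect_lt(abs(acc - expAcc), 3 * sqrt(expAcc * (1 - expAcc) / n))
  # uniform donor calls on singlets: ~ 1/4 correct
  donorCalls <- callSet(truth$barcode,
                        sample(paste0("d", 1:4), n, replace = TRUE))
  sda <- singletonDonorAccuracy(donorCalls, truth)
  nS <- sum(truth$type == "singlet")
  expect_lt(abs(sda - 0.25), 3 * sqrt(0.25 * 0.75 / nS))
})

test_that("label harmonization recovers planted permutations", {
  set.seed(202)
  n <- 1000
  donors <- paste0("d", 1:4)
  truth <- data.frame(barcode = paste0("B", seq_len(n)), type = "singlet",
                      donor1 = sample(donors, n, replace = TRUE),
                      donor2 = NA, stringsAsFactors = FALSE)
  perm <- c(d1 = "c3", d2 = "c1", d3 = "c4", d4 = "c2")
  clean <- callSet(truth$barcode, unname(perm[truth$donor1]))
  fixed <- harmonizeLabels(clean, truth)
  expect_identical(fixed$call, truth$donor1)
  expect_identical(singletonDonorAccuracy(fixed, truth), 1)
  # 10% label noise: map still recovered
  noisy <- clean
  flip <- sample(n, n / 10)
  noisy$call[flip] <- sample(paste0("c", 1:4), length(flip), replace = TRUE)
  fixedNoisy <- harmonizeLabels(noisy, truth)
  expect_identical(attr(fixedNoisy, "clusterMap"),
                   c(c1 = "d2", c2 = "d4", c3 = "d1", c4 = "d3"))
  # dominant-diagonal contingency: identity map
  t2 <- data.frame(barcode = paste0("X", 1:200), type = "singlet",
                   donor1 = rep(c("d1", "d2"), each = 100), donor2 = NA)
  c2 <- callSet(t2$barcode,
                c(rep("c1", 90), rep("c2", 10), rep("c1", 10), rep("c2", 90)))
  expect_identical(unname(attr(harmonizeLabels(c2, t2), "clusterMap")),
                   c("d1", "d2"))
  expect_error(
    harmonizeLabels(callSet(t2$barcode,
                            sample(paste0("c", 1:5), 200, replace = TRUE)),
                    t2),
    "more clusters")
})

test_that("accuracy is permutation-safe after harmonization", {
  set.seed(203)
  truth <- .handTruth()
  calls <- callSet(truth$barcode,
                   c("d1", "d1", "d2", "d2", "d3", "d3", "doublet",
                     "doublet", "unassigned", "unassigned"))
  base <- singletonDonorAccuracy(calls, truth)
  perm <- c(d1 = "k2", d2 = "k3", d3 = "k1")
  permuted <- callSet(truth$barcode,
                      ifelse(calls$call %in% names(perm),
                             perm[calls$call], calls$call))
  expect_identical(
    singletonDonorAccuracy(harmonizeLabels(permuted, truth), truth),
    base)
})

test_that("droplet-type correlation behaves at the poles and the null", {
  bcs <- paste0("B", 1:10000)
  set.seed(204)
  a <- callSet(bcs, sample(c("d1", "doublet"), 10000, replace = TRUE))
  expect_identical(dropletTypeCorrelation(a, a), 1)
  flipped <- callSet(bcs, ifelse(a$call == "d1", "doublet", "d1"))
  expect_identical(dropletTypeCorrelation(a, flipped), -1)
  b <- callSet(bcs, sample(c("d1", "doublet"), 10000, replace = TRUE))
  expect_lt(abs(dropletTypeCorrelation(a, b)), 0.05)
  # symmetry
  expect_equal(dropletTypeCorrelation(a, b),
               dropletTypeCorrelation(b, a))
  # constant indicator -> NA with warning
  const <- callSet(bcs, rep("d1", 10000))
  expect_warning(r <- dropletTypeCorrelation(a, const), "constant")
  expect_true(is.na(r))
  # Cramer's V runs on 3-level calls and is 1 on self-agreement
  c3 <- callSet(bcs, sample(c("d1", "doublet", "unassigned"), 10000,
                            replace = TRUE))
  expect_equal(dropletTypeCorrelation(c3, c3, method = "cramer"), 1)
})

test_that("multiway intersection statistics on constructed sets", {
  bcs <- paste0("B", 1:100)
  s1 <- callSet(bcs, rep(c("d1", "doublet"), each = 50), method = "m1")
  mw <- multiwayIntersection(list(s1, s1))
  expect_true(all(mw$pairwise == 1))
  expect_identical(mw$typeAgreement, 1)
  # exactly half the barcodes agree across all three sets
  s2 <- callSet(bcs, c(rep("d1", 50), rep("unassigned", 50)), method = "m2")
  s3 <- callSet(bcs, c(rep("d1", 50), rep("doublet", 25),
                       rep("unassigned", 25)), method = "m3")
  mw3 <- multiwayIntersection(list(s1, s2, s3))
  expect_identical(mw3$typeAgreement, 0.5)
  # membership counts partition the common barcode universe
  expect_identical(sum(mw3$membership$count), mw3$nCommon)
  # pairwise overlap never falls below the all-method agreement
  expect_true(all(mw3$pairwise >= mw3$typeAgreement))
  # donor agreement: among all-singlet barcodes, same donor everywhere
  s4 <- callSet(bcs, c(rep("d1", 25), rep("d2", 25), rep("doublet", 50)),
                method = "m4")
  s5 <- callSet(bcs, c(rep("d1", 50), rep("doublet", 50)), method = "m5")
  mw45 <- multiwayIntersection(list(s4, s5))
  expect_identical(mw45$donorAgreement, 0.5)
  expect_error(multiwayIntersection(list(s1)), "at least 2")
})

test_that("assignment tables round-trip through TSV", {
  cs <- callSet(paste0("B", 1:5), c("d1", "d2", "doublet", "unassigned", "d1"))
  p <- tempfile(fileext = ".tsv")
  writeAssignments(cs, p)
  back <- readAssignments(p)
  expect_identical(back$barcode, cs$barcode)
  expect_identical(back$call, cs$call)
})
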