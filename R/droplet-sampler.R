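#' Construct an ExperimentConfig
#'
#' Validates and assembles the experiment-level parameters of a
#' multiplexed droplet simulation. All violations are reported at once.
#'
#' Defaults mirror a standard 10x-scale multiome pool: 9,000 droplets,
#' 4 donors in equal proportions, 10% heterotypic doublets, mean depths
#' of 25,000 RNA and 40,000 ATAC reads per droplet. Per-droplet ambient
#' fractions are Beta-distributed around `ambientLevel` with
#' concentration `ambientConcentration`; depths are negative-binomial
#' with size `depthDispersion`.
#'
#' @param nDroplets number of droplets.
#' @param nDonors number of multiplexed donors K.
#' @param doubletRate,emptyRate expected doublet / empty fractions
#'   (`doubletRate + emptyRate <= 1`).
#' @param donorProportions pool proportions (default equal; must sum
#'   to 1).
#' @param ambientLevel experiment-level mean ambient fraction, in
#'   `[0, 1)`; 0 disables contamination exactly.
#' @param ambientConcentration Beta concentration (larger = tighter
#'   around `ambientLevel`).
#' @param rnaDepthMean,atacDepthMean mean reads per cell-containing
#'   droplet.
#' @param depthDispersion negative-binomial size.
#' @param emptyDepthFactor empty-droplet mean depth as a fraction of the
#'   cell mean.
#' @param doubletMixShape1,doubletMixShape2 Beta shapes of the donor-1
#'   read share within doublets.
#' @param seed integer RNG seed.
#' @return an [ExperimentConfig-class].
#' @examples
#' cfg <- experimentConfig(nDroplets = 100, nDonors = 4, seed = 7)
#' @export
experimentConfig <- function(nDroplets = 9000L, nDonors = 4L,
                             doubletRate = 0.1, emptyRate = 0,
                             donorProportions = NULL,
                             ambientLevel = 0.1, ambientConcentration = 30,
                             rnaDepthMean = 25000, atacDepthMean = 40000,
                             depthDispersion = 10, emptyDepthFactor = 0.05,
                             doubletMixShape1 = 5, doubletMixShape2 = 5,
                             seed = 1L) {
  errs <- character(0)
  if (is.null(donorProportions))
    donorProportions <- rep(1 / nDonors, nDonors)
  if (length(nDroplets) != 1L || is.na(nDroplets) || nDroplets < 1)
    errs <- c(errs, "nDroplets must be a positive integer")
  if (length(nDonors) != 1L || is.na(nDonors) || nDonors < 1)
    errs <- c(errs, "nDonors must be a positive integer")
  if (doubletRate < 0 || doubletRate > 1)
    errs <- c(errs, "doubletRate must be in [0, 1]")
  if (emptyRate < 0 || emptyRate > 1)
    errs <- c(errs, "emptyRate must be in [0, 1]")
  if (doubletRate + emptyRate > 1)
    errs <- c(errs, "doubletRate + emptyRate must not exceed 1")
  if (length(donorProportions) != nDonors)
    errs <- c(errs, "donorProportions must have length nDonors")
  else if (abs(sum(donorProportions) - 1) > 1e-9)
    errs <- c(errs, "donorProportions must sum to 1")
  if (ambientLevel < 0 || ambientLevel >= 1)
    errs <- c(errs, "ambientLevel must be in [0, 1)")
  if (ambientConcentration <= 0)
    errs <- c(errs, "ambientConcentration must be positive")
  if (rnaDepthMean <= 0 || atacDepthMean <= 0)
    errs <- c(errs, "depth means must be positive")
  if (depthDispersion <= 0)
    errs <- c(errs, "depthDispersion must be positive")
  if (nDonors < 2 && doubletRate > 0)
    errs <- c(errs, "doubletRate > 0 requires at least 2 donors")
  if (length(errs))
    stop("invalid ExperimentConfig:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  methods::new("ExperimentConfig",
    nDroplets = as.integer(nDroplets), nDonors = as.integer(nDonors),
    doubletRate = as.numeric(doubletRate), emptyRate = as.numeric(emptyRate),
    donorProportions = as.numeric(donorProportions),
    ambientLevel = as.numeric(ambientLevel),
    ambientConcentration = as.numeric(ambientConcentration),
    rnaDepthMean = as.numeric(rnaDepthMean),
    atacDepthMean = as.numeric(atacDepthMean),
    depthDispersion = as.numeric(depthDispersion),
    emptyDepthFactor = as.numeric(emptyDepthFactor),
    doubletMixShape1 = as.numeric(doubletMixShape1),
    doubletMixShape2 = as.numeric(doubletMixShape2),
    seed = as.integer(seed))
}

#' @export
setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig:", object@nDroplets, "droplets,",
      object@nDonors, "donors\n")
  cat(sprintf("  doublet rate %.3f, empty rate %.3f, ambient level %.3f (c = %g)\n",
              object@doubletRate, object@emptyRate, object@ambientLevel,
              object@ambientConcentration))
  cat(sprintf("  depth means: RNA %g, ATAC %g (NB dispersion %g); seed %d\n",
              object@rnaDepthMean, object@atacDepthMean,
              object@depthDispersion, object@seed))
})

#' Sample per-droplet ambient fractions
#'
#' Draws per-droplet ambient read fractions from
#' `Beta(mu * c, (1 - mu) * c)`, so the experiment-level mean is `mu`
#' and `c` controls droplet-to-droplet spread. `mu = 0` returns exact
#' zeros (contamination off).
#'
#' @param n number of draws.
#' @param mu mean ambient fraction, in `[0, 1)`.
#' @param concentration Beta concentration `c > 0`.
#' @return numeric vector of fractions in `[0, 1)`.
#' @export
sampleAmbientFraction <- function(n, mu, concentration = 30) {
  stopifnot(mu >= 0, mu < 1, concentration > 0)
  if (mu == 0) return(rep(0, n))
  stats::rbeta(n, mu * concentration, (1 - mu) * concentration)
}

#' Sample per-droplet sequencing depths
#'
#' Negative-binomial depths with the given mean and dispersion
#' (variance = mean + mean^2 / dispersion), capturing the droplet-level
#' overdispersion of real library sizes. `dispersion = Inf` gives the
#' Poisson limit.
#'
#' @param n number of draws.
#' @param mean mean reads per droplet.
#' @param dispersion negative-binomial size parameter.
#' @return integer-valued numeric vector of depths (>= 0).
#' @export
sampleDepth <- function(n, mean, dispersion = 10) {
  stopifnot(mean > 0, dispersion > 0)
  if (is.infinite(dispersion)) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = dispersion, mu = mean)
}

#' Sample the latent attributes of every droplet
#'
#' Draws, for each droplet: a type (singlet / doublet / empty) from the
#' configured rates, donor identities (doublets get two distinct donors
#' — heterotypic by construction), a doublet mixing share, an ambient
#' read fraction (exactly 1 for empties) and per-modality depths.
#' Deterministic given `config@seed`.
#'
#' @param config an [ExperimentConfig-class].
#' @param barcodes optional barcode whitelist (character, at least
#'   `nDroplets` entries); generated internally when `NULL`.
#' @return a [DropletSet-class].
#' @examples
#' ds <- sampleDroplets(experimentConfig(nDroplets = 50, seed = 3))
#' table(as.data.frame(ds)$type)
#' @export
sampleDroplets <- function(config, barcodes = NULL) {
  stopifnot(methods::is(config, "ExperimentConfig"))
  n <- config@nDroplets
  K <- config@nDonors
  .withSeed(config@seed, {
    if (is.null(barcodes))
      barcodes <- .randomBarcodes(n, 16L, 3L)
    else if (length(barcodes) < n)
      stop("need at least ", n, " barcodes, got ", length(barcodes))
    barcodes <- barcodes[seq_len(n)]
    type <- sample(c("singlet", "doublet", "empty"), n, replace = TRUE,
                   prob = c(1 - config@doubletRate - config@emptyRate,
                            config@doubletRate, config@emptyRate))
    donor1 <- rep(NA_integer_, n)
    donor2 <- rep(NA_integer_, n)
    isS <- type == "singlet"
    isD <- type == "doublet"
    donor1[isS] <- sample.int(K, sum(isS), replace = TRUE,
                              prob = config@donorProportions)
    if (any(isD)) {
      d1 <- sample.int(K, sum(isD), replace = TRUE,
                       prob = config@donorProportions)
      d2 <- vapply(d1, function(a) {
        p <- config@donorProportions
        p[a] <- 0
        sample.int(K, 1L, prob = p)
      }, integer(1))
      donor1[isD] <- d1
      donor2[isD] <- d2
    }
    doubletMix <- rep(NA_real_, n)
    doubletMix[isD] <- stats::rbeta(sum(isD), config@doubletMixShape1,
                                    config@doubletMixShape2)
    af <- sampleAmbientFraction(n, config@ambientLevel,
                                config@ambientConcentration)
    af[type == "empty"] <- 1
    isCell <- type != "empty"
    rnaDepth <- integer(n)
    atacDepth <- integer(n)
    rnaDepth[isCell] <- sampleDepth(sum(isCell), config@rnaDepthMean,
                                    config@depthDispersion)
    atacDepth[isCell] <- sampleDepth(sum(isCell), config@atacDepthMean,
                                     config@depthDispersion)
    if (any(!isCell)) {
      rnaDepth[!isCell] <- sampleDepth(sum(!isCell),
                                       config@rnaDepthMean * config@emptyDepthFactor,
                                       config@depthDispersion)
      atacDepth[!isCell] <- sampleDepth(sum(!isCell),
                                        config@atacDepthMean * config@emptyDepthFactor,
                                        config@depthDispersion)
    }
  })
  methods::new("DropletSet",
    droplets = data.frame(
      barcode = barcodes, type = type, donor1 = donor1, donor2 = donor2,
      doubletMix = doubletMix, ambientFraction = af,
      rnaDepth = as.integer(rnaDepth), atacDepth = as.integer(atacDepth),
      stringsAsFactors = FALSE),
    config = config)
}

#' @describeIn DropletSet-class droplet attribute table.
#' @param x,object a `DropletSet`.
#' @export
setMethod("as.data.frame", "DropletSet", function(x) x@droplets)

#' @describeIn DropletSet-class number of droplets.
#' @export
setMethod("length", "DropletSet", function(x) nrow(x@droplets))

#' @describeIn DropletSet-class droplet barcodes.
#' @export
setMethod("barcodes", "DropletSet", function(x) x@droplets$barcode)

#' @export
setMethod("show", "DropletSet", function(object) {
  d <- object@droplets
  cat("DropletSet:", nrow(d), "droplets\n")
  print(table(d$type))
  cat(sprintf("  mean ambient fraction %.3f; mean depths RNA %.0f / ATAC %.0f\n",
              mean(d$ambientFraction), mean(d$rnaDepth), mean(d$atacDepth)))
})

#' Write droplet truth attributes as TSV
#'
#' @param droplets a [DropletSet-class] (or the truth table of a
#'   [SimExperiment-class] via [simTruth()]).
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeDropletTruth <- function(droplets, path) {
  df <- if (methods::is(droplets, "DropletSet")) droplets@droplets else droplets
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
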