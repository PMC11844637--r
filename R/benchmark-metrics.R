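#' Construct a demultiplexing call set
#'
#' A validated per-barcode call table: each barcode appears once; a call
#' is a donor id, `"doublet"` or `"unassigned"` (anonymous cluster
#' labels from genotype-free methods are also calls — see
#' [harmonizeLabels()]).
#'
#' @param barcode character vector of droplet barcodes.
#' @param call character vector of calls, same length.
#' @param method,modality labels attached as attributes.
#' @return data.frame with columns `barcode`, `call` and attributes
#'   `method`/`modality`.
#' @export
callSet <- function(barcode, call, method = "method", modality = "rna") {
  stopifnot(length(barcode) == length(call))
  if (anyDuplicated(barcode)) stop("barcodes must be unique in a call set")
  out <- data.frame(barcode = as.character(barcode),
                    call = as.character(call), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "modality") <- modality
  out
}

#' Truth set from a simulated experiment
#'
#' @param sim a [SimExperiment-class] (or a [DropletSet-class]).
#' @return data.frame with `barcode`, `type` (`singlet`/`doublet`/
#'   `empty`) and donor id columns `donor1`/`donor2`.
#' @export
truthSet <- function(sim) {
  d <- if (methods::is(sim, "SimExperiment")) {
    donors <- donorIds(sim@panel)
    df <- as.data.frame(sim@droplets)
    df$donor1 <- ifelse(is.na(df$donor1), NA, donors[df$donor1])
    df$donor2 <- ifelse(is.na(df$donor2), NA, donors[df$donor2])
    df
  } else if (methods::is(sim, "DropletSet")) {
    as.data.frame(sim)
  } else sim
  if (anyDuplicated(d$barcode)) stop("truth barcodes must be unique")
  d[, c("barcode", "type", "donor1", "donor2")]
}

#' Truth-derived perfect call set (truth assignments)
#'
#' The call set an oracle demultiplexer would produce: every true
#' singlet assigned to its donor, doublets called `doublet`, empties
#' `unassigned`. Used to drive the consistency metric with truth
#' assignments.
#'
#' @param sim a [SimExperiment-class] or [DropletSet-class].
#' @return a [callSet()] data.frame.
#' @export
truthCalls <- function(sim) {
  t <- truthSet(sim)
  call <- ifelse(t$type == "singlet", t$donor1,
                 ifelse(t$type == "doublet", "doublet", "unassigned"))
  callSet(t$barcode, call, method = "truth")
}

.sharedJoin <- function(calls, truth) {
  m <- match(calls$barcode, truth$barcode)
  keep <- !is.na(m)
  if (!any(keep)) stop("call set and truth share no barcodes")
  data.frame(call = calls$call[keep],
             type = truth$type[m[keep]],
             donor1 = truth$donor1[m[keep]],
             stringsAsFactors = FALSE)
}

.isDonorCall <- function(call) !(call %in% c("doublet", "unassigned"))

#' Droplet-type accuracy
#'
#' Fraction of shared droplets whose called category matches the true
#' droplet type: a true singlet is correct when called as some donor, a
#' true doublet when called `doublet`, and a true empty when the method
#' refuses a singlet call (`doublet` or `unassigned`).
#'
#' @param calls a [callSet()] data.frame.
#' @param truth a [truthSet()] data.frame.
#' @return fraction in `[0, 1]`.
#' @export
dropletTypeAccuracy <- function(calls, truth) {
  j <- .sharedJoin(calls, truth)
  donorCall <- .isDonorCall(j$call)
  correct <- ifelse(j$type == "singlet", donorCall,
                    ifelse(j$type == "doublet", j$call == "doublet",
                           !donorCall))
  mean(correct)
}

#' Singleton-donor accuracy
#'
#' Among true singlets, the fraction assigned to the correct donor. By
#' default the denominator is the true singlets the method called as
#' *some* donor, isolating donor-assignment quality from detection
#' quality (which [dropletTypeAccuracy()] measures); `strict = TRUE`
#' divides by all true singlets instead.
#'
#' @inheritParams dropletTypeAccuracy
#' @param strict use all true singlets as the denominator.
#' @return fraction, or `NA` if the denominator is empty.
#' @export
singletonDonorAccuracy <- function(calls, truth, strict = FALSE) {
  j <- .sharedJoin(calls, truth)
  sing <- j$type == "singlet"
  donorCall <- .isDonorCall(j$call)
  denom <- if (strict) sing else sing & donorCall
  if (!any(denom)) return(NA_real_)
  sum(sing & donorCall & j$call == j$donor1) / sum(denom)
}

#' Map anonymous cluster labels to donors
#'
#' Genotype-free demultiplexers emit anonymous cluster labels. This
#' finds the bijective cluster-to-donor map maximizing agreement with a
#' reference truth set (optimal assignment on the cluster x donor
#' contingency table, solved as a linear sum assignment problem) and
#' relabels the calls. `doublet`/`unassigned` pass through.
#'
#' @param calls a [callSet()] whose donor-like calls are cluster labels.
#' @param truth a [truthSet()] data.frame.
#' @return the relabeled [callSet()], with the map in attribute
#'   `clusterMap`.
#' @export
harmonizeLabels <- function(calls, truth) {
  clusters <- sort(setdiff(unique(calls$call), c("doublet", "unassigned")))
  donors <- sort(unique(truth$donor1[truth$type == "singlet"]))
  if (length(clusters) > length(donors))
    stop("more clusters (", length(clusters), ") than donors (",
         length(donors), ")")
  j <- .sharedJoin(calls, truth)
  sing <- j$type == "singlet" & .isDonorCall(j$call)
  tab <- table(factor(j$call[sing], levels = clusters),
               factor(j$donor1[sing], levels = donors))
  # pad to square for the LSAP solver; dummy rows carry zero weight
  m <- matrix(0, nrow = length(donors), ncol = length(donors))
  m[seq_len(length(clusters)), ] <- tab
  sol <- clue::solve_LSAP(m, maximum = TRUE)
  map <- donors[as.integer(sol)[seq_len(length(clusters))]]
  names(map) <- clusters
  newCall <- calls$call
  hit <- newCall %in% clusters
  newCall[hit] <- map[newCall[hit]]
  out <- callSet(calls$barcode, newCall,
                 method = attr(calls, "method"),
                 modality = attr(calls, "modality"))
  attr(out, "clusterMap") <- map
  out
}

#' Between-method droplet-type correlation
#'
#' Pearson correlation of the binary "called singlet" indicators of two
#' methods over their shared barcodes (default), or Cramer's V over the
#' three-level calls (`method = "cramer"`).
#'
#' @param callsA,callsB [callSet()] data.frames.
#' @param method `"pearson"` (binary singlet indicator) or `"cramer"`
#'   (3-level association).
#' @return correlation in `[-1, 1]` (Cramer's V in `[0, 1]`); `NA` with
#'   a warning when an indicator is constant.
#' @export
dropletTypeCorrelation <- function(callsA, callsB,
                                   method = c("pearson", "cramer")) {
  method <- match.arg(method)
  m <- match(callsA$barcode, callsB$barcode)
  keep <- !is.na(m)
  if (sum(keep) < 3L) stop("need at least 3 shared barcodes")
  a <- callsA$call[keep]
  b <- callsB$call[m[keep]]
  if (method == "pearson") {
    ia <- as.numeric(.isDonorCall(a))
    ib <- as.numeric(.isDonorCall(b))
    if (stats::sd(ia) == 0 || stats::sd(ib) == 0) {
      warning("constant singlet indicator; correlation undefined")
      return(NA_real_)
    }
    stats::cor(ia, ib)
  } else {
    lvl <- function(x) ifelse(.isDonorCall(x), "singlet", x)
    tab <- table(lvl(a), lvl(b))
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      warning("constant call category; Cramer's V undefined")
      return(NA_real_)
    }
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    sqrt(as.numeric(chi$statistic) /
           (sum(tab) * (min(dim(tab)) - 1L)))
  }
}

#' Multi-method intersection statistics
#'
#' Agreement structure of two or more call sets over the barcodes common
#' to all of them: the pairwise droplet-type overlap matrix (fraction of
#' a pair's shared barcodes with equal category), the all-method
#' droplet-type agreement, the all-method donor agreement (among
#' barcodes called a donor by every method, the fraction where the
#' donor is identical), and UpSet-style membership counts of the
#' "called singlet" patterns.
#'
#' @param callSets list of two or more [callSet()] data.frames (named,
#'   or names are taken from the `method` attributes).
#' @return list with `pairwise` (matrix), `typeAgreement`,
#'   `donorAgreement`, `membership` (data.frame pattern/count) and
#'   `nCommon`.
#' @export
multiwayIntersection <- function(callSets) {
  if (length(callSets) < 2L) stop("need at least 2 call sets")
  nms <- names(callSets)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(seq_along(callSets), function(i) {
      m <- attr(callSets[[i]], "method")
      if (is.null(m)) paste0("method", i) else m
    }, character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  names(callSets) <- nms
  cat3 <- function(x) ifelse(.isDonorCall(x), "singlet", x)
  n <- length(callSets)
  pairwise <- matrix(NA_real_, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m <- match(callSets[[i]]$barcode, callSets[[j]]$barcode)
    keep <- !is.na(m)
    pairwise[i, j] <- mean(cat3(callSets[[i]]$call[keep]) ==
                             cat3(callSets[[j]]$call[m[keep]]))
  }
  common <- Reduce(intersect, lapply(callSets, `[[`, "barcode"))
  if (!length(common)) stop("no barcode common to all call sets")
  callsAt <- vapply(callSets, function(cs)
    cs$call[match(common, cs$barcode)], character(length(common)))
  if (length(common) == 1L) callsAt <- matrix(callsAt, nrow = 1L)
  cats <- matrix(cat3(callsAt), nrow = length(common))
  typeAgreement <- mean(apply(cats, 1L, function(r) all(r == r[1L])))
  allDonor <- apply(callsAt, 1L, function(r) all(.isDonorCall(r)))
  donorAgreement <- if (!any(allDonor)) NA_real_ else
    mean(apply(callsAt[allDonor, , drop = FALSE], 1L,
               function(r) all(r == r[1L])))
  isSing <- matrix(.isDonorCall(callsAt), nrow = length(common))
  pattern <- apply(isSing, 1L, function(r)
    paste(nms[r], collapse = "&"))
  pattern[pattern == ""] <- "(none)"
  memb <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(memb) <- c("pattern", "count")
  list(pairwise = pairwise, typeAgreement = typeAgreement,
       donorAgreement = donorAgreement, membership = memb,
       nCommon = length(common))
}

#' Read / write assignment TSVs
#'
#' Two-column (`barcode`, `call`) TSVs, the interchange format between
#' demultiplexers and the consistency/evaluation steps.
#'
#' @param path TSV path.
#' @param calls a [callSet()] data.frame.
#' @name assignmentIO
NULL

#' @rdname assignmentIO
#' @export
readAssignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "call") %in% names(df)))
    stop("assignment table needs 'barcode' and 'call' columns: ", path)
  callSet(df$barcode, df$call,
          method = sub("\\.tsv(\\.gz)?$", "", basename(path)))
}

#' @rdname assignmentIO
#' @export
writeAssignments <- function(calls, path) {
  utils::write.table(calls[, c("barcode", "call")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
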