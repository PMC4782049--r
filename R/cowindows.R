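## Receptor-centric cobinding windows: for each NXF1-like binding site, which
## SR libraries place >3 significant cross-link positions within +/-30 nt of
## the site center, stratified by the exon class of the center.

# stratum of each site center: first_exon / last_exon / other
.siteStrata <- function(sites, exonFeatures) {
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                    IRanges::IRanges(sites$center, width = 1L),
                                    strand = GenomicRanges::strand(sites))
  hit <- GenomicRanges::findOverlaps(centers, exonFeatures, select = "first")
  ord <- ifelse(is.na(hit), "other", exonFeatures$ordinal_class[hit])
  ifelse(ord %in% c("first", "last"), paste0(ord, "_exon"), "other")
}

# logical matrix sites x libraries: does library cobind the site's window?
.cobindMatrix <- function(sites, srPositions, halfWindow, minSites) {
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                    IRanges::IRanges(sites$center - halfWindow,
                                                     sites$center + halfWindow),
                                    strand = GenomicRanges::strand(sites))
  vapply(srPositions, function(pos)
    GenomicRanges::countOverlaps(centers, pos) >= minSites,
    logical(length(sites)))
}

#' Cobinding ratios around receptor binding sites
#'
#' An SR library cobinds a receptor site when it has at least
#' \code{minSites} significant cross-link positions (the "more than three"
#' rule at the default) within \code{halfWindow} nt of the site center on
#' the same strand. Ratios are reported per stratum (first exon, last exon,
#' all regions) relative to the total receptor sites in that stratum.
#'
#' @param nxf1Sites Receptor binding sites (\code{\link{mergeBindingSites}}).
#' @param srPositions Named list of significant-position \code{GRanges}, one
#'   per SR library.
#' @param exonFeatures Classified exons (\code{\link{classifyExons}}).
#' @param halfWindow Half-window in nt (default 30; both endpoints
#'   inclusive, 61 positions).
#' @param minSites Minimum significant positions to count as cobinding
#'   (default 4).
#' @return data.frame: stratum, library, n_cobound, n_total, ratio (NA for
#'   strata without receptor sites).
#' @export
cobindingRatio <- function(nxf1Sites, srPositions, exonFeatures,
                           halfWindow = 30L, minSites = 4L) {
  strata <- .siteStrata(nxf1Sites, exonFeatures)
  cb <- .cobindMatrix(nxf1Sites, srPositions, halfWindow, minSites)
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = length(nxf1Sites))
  colnames(cb) <- names(srPositions)
  out <- list()
  for (st in c("first_exon", "last_exon", "all")) {
    sel <- if (st == "all") rep(TRUE, length(strata)) else strata == st
    nT <- sum(sel)
    for (lib in names(srPositions)) {
      nC <- if (nT) sum(cb[sel, lib]) else 0L
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, library = lib, n_cobound = nC, n_total = nT,
        ratio = if (nT > 0) nC / nT else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Receptor sites with exactly one SR cobinder
#'
#' @inheritParams cobindingRatio
#' @return data.frame: stratum, library, n_exclusive (sites where only that
#'   library cobinds).
#' @export
exclusiveCobinding <- function(nxf1Sites, srPositions, exonFeatures,
                               halfWindow = 30L, minSites = 4L) {
  strata <- .siteStrata(nxf1Sites, exonFeatures)
  cb <- .cobindMatrix(nxf1Sites, srPositions, halfWindow, minSites)
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = length(nxf1Sites))
  colnames(cb) <- names(srPositions)
  nEach <- rowSums(cb)
  out <- list()
  for (st in c("first_exon", "last_exon", "all")) {
    sel <- if (st == "all") rep(TRUE, length(strata)) else strata == st
    for (lib in names(srPositions))
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, library = lib,
        n_exclusive = sum(sel & nEach == 1L & cb[, lib]))
  }
  do.call(rbind, out)
}

#' Pairwise SR co-occurrence at receptor sites
#'
#' Symmetric matrix over SR libraries: off-diagonal cells count receptor
#' sites where both libraries cobind; the diagonal counts sites where
#' exactly that single library cobinds.
#'
#' @inheritParams cobindingRatio
#' @param stratum \code{"all"} (default), \code{"first_exon"} or
#'   \code{"last_exon"}.
#' @return Integer matrix.
#' @export
pairwiseCobinding <- function(nxf1Sites, srPositions, exonFeatures,
                              halfWindow = 30L, minSites = 4L,
                              stratum = "all") {
  strata <- .siteStrata(nxf1Sites, exonFeatures)
  cb <- .cobindMatrix(nxf1Sites, srPositions, halfWindow, minSites)
  if (is.null(dim(cb))) cb <- matrix(cb, nrow = length(nxf1Sites))
  colnames(cb) <- names(srPositions)
  sel <- if (stratum == "all") rep(TRUE, length(strata)) else strata == stratum
  cb <- cb[sel, , drop = FALSE]
  k <- ncol(cb)
  m <- matrix(0L, k, k, dimnames = list(colnames(cb), colnames(cb)))
  if (nrow(cb)) {
    m <- crossprod(cb)
    storage.mode(m) <- "integer"
    nEach <- rowSums(cb)
    diag(m) <- vapply(seq_len(k), function(i)
      sum(cb[, i] & nEach == 1L), 0L)
  }
  m
}
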