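## Cross-link module: unique cDNAs, per-nucleotide cross-link events,
## within-gene permutation-FDR significant positions, merged binding sites.

#' Collapse reads to unique cDNAs
#'
#' One record is kept per (library, chrom, strand, 5' start, barcode);
#' further copies are PCR duplicates. Reads without a barcode are dropped
#' and counted.
#'
#' @param reads Read table with columns \code{library}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{cigar}, \code{barcode}.
#' @return List: \code{reads} (unique records), \code{nInput},
#'   \code{nDuplicates}, \code{nMissingBarcode}.
#' @export
deduplicateReads <- function(reads) {
  dt <- data.table::as.data.table(reads)
  nInput <- nrow(dt)
  bad <- is.na(dt$barcode) | dt$barcode == ""
  nMissing <- sum(bad)
  dt <- dt[!bad]
  start5 <- .start5(dt$start, dt$end, dt$strand)
  key <- paste(dt$library, dt$chrom, dt$strand, start5, dt$barcode)
  dup <- duplicated(key)
  list(reads = as.data.frame(dt[!dup]),
       nInput = nInput,
       nDuplicates = sum(dup),
       nMissingBarcode = nMissing)
}

#' Infer cross-link events from unique cDNAs
#'
#' The cross-linked nucleotide is the base immediately 5' of the read start
#' on the read's strand (plus strand: start - 1; minus strand: end + 1,
#' 1-based). Events falling off the chromosome are dropped and counted.
#'
#' @param uniqueReads Unique cDNA records (see \code{\link{deduplicateReads}}).
#' @param seqLengths Optional named chromosome lengths for bounds checking.
#' @return Width-1 \code{GRanges} with metadata \code{count} (unique cDNAs)
#'   and \code{library}; attribute \code{"nDropped"}.
#' @export
extractCrosslinks <- function(uniqueReads, seqLengths = NULL) {
  dt <- data.table::as.data.table(uniqueReads)
  pos <- ifelse(dt$strand == "+", dt$start - 1L, dt$end + 1L)
  bad <- pos < 1L
  if (!is.null(seqLengths))
    bad <- bad | pos > seqLengths[dt$chrom]
  nDropped <- sum(bad)
  dt <- dt[!bad]; pos <- pos[!bad]
  agg <- data.table::as.data.table(
    list(library = dt$library, chrom = dt$chrom, strand = dt$strand, pos = pos))
  agg <- agg[, list(count = .N), by = c("library", "chrom", "strand", "pos")]
  gr <- GenomicRanges::GRanges(agg$chrom, IRanges::IRanges(agg$pos, width = 1L),
                               strand = agg$strand, count = agg$count,
                               library = agg$library)
  gr <- sort(gr, ignore.strand = TRUE)
  attr(gr, "nDropped") <- nDropped
  gr
}

# assign events to genes (strand-matched pre-mRNA spans; same-strand
# overlaps resolved toward the longer gene span)
.assignToGenes <- function(events, annotation) {
  spans <- geneSpans(annotation)
  hits <- GenomicRanges::findOverlaps(events, spans)
  if (length(hits)) {
    w <- GenomicRanges::width(spans)[S4Vectors::subjectHits(hits)]
    dt <- data.table::data.table(q = S4Vectors::queryHits(hits),
                                 s = S4Vectors::subjectHits(hits), w = w)
    data.table::setorder(dt, q, -w)
    dt <- dt[!duplicated(dt$q)]
    gene <- rep(NA_character_, length(events))
    gene[dt$q] <- names(spans)[dt$s]
  } else gene <- rep(NA_character_, length(events))
  gene
}

#' Call significant cross-link positions by within-gene permutation FDR
#'
#' Per gene and library, the gene's total unique-cDNA count is redistributed
#' uniformly over the gene's pre-mRNA positions in each permutation. For
#' each count height h, FDR(h) is the permutation mean of the number of
#' positions with count >= h divided by the observed number, made monotone
#' non-increasing in h; a position is significant iff FDR(height) is below
#' the threshold.
#'
#' @param events Cross-link events (\code{\link{extractCrosslinks}}).
#' @param annotation A \code{GenomeAnnotation}.
#' @param fdrThreshold Significance threshold (default 0.05).
#' @param nPerm Number of permutations (>= 10; default 100).
#' @param seed Integer seed for the permutation stream.
#' @param minEvents Genes with fewer total unique cDNAs are skipped.
#' @return \code{GRanges} of significant positions with \code{count},
#'   \code{fdr}, \code{gene_id}, \code{library}; attributes
#'   \code{"nIntergenic"} and \code{"skippedGenes"}.
#' @export
callSignificantPositions <- function(events, annotation, fdrThreshold = 0.05,
                                     nPerm = 100L, seed = 1L, minEvents = 10L) {
  stopifnot(nPerm >= 10L)
  set.seed(seed)
  gene <- .assignToGenes(events, annotation)
  nIntergenic <- sum(is.na(gene))
  spans <- geneSpans(annotation)
  keepIdx <- which(!is.na(gene))
  dt <- data.table::data.table(
    idx = keepIdx,
    gene = gene[keepIdx],
    lib = events$library[keepIdx],
    count = events$count[keepIdx])
  skipped <- character(0)
  sigIdx <- integer(0); sigFdr <- numeric(0)
  if (nrow(dt)) {
    grp <- split(seq_len(nrow(dt)), paste(dt$gene, dt$lib, sep = "\r"))
    for (gname in names(grp)) {
      rows <- grp[[gname]]
      cnts <- dt$count[rows]
      N <- sum(cnts)
      gid <- dt$gene[rows[1]]
      if (N < minEvents) { skipped <- c(skipped, gname); next }
      L <- GenomicRanges::width(spans[gid])
      maxH <- max(cnts)
      permGe <- numeric(maxH)
      for (b in seq_len(nPerm)) {
        tb <- tabulate(tabulate(sample.int(L, N, replace = TRUE)), nbins = maxH)
        permGe <- permGe + .revCumsum(tb)
      }
      permGe <- permGe / nPerm
      obsGe <- .revCumsum(tabulate(cnts, nbins = maxH))
      fdrH <- pmin(1, permGe / obsGe)
      fdrH[obsGe == 0] <- 1
      fdrH <- cummin(fdrH)     # monotone non-increasing in h
      f <- fdrH[cnts]
      sel <- f < fdrThreshold
      sigIdx <- c(sigIdx, dt$idx[rows[sel]])
      sigFdr <- c(sigFdr, f[sel])
    }
  }
  out <- events[sigIdx]
  out$fdr <- sigFdr
  out$gene_id <- gene[sigIdx]
  out <- sort(out, ignore.strand = TRUE)
  attr(out, "nIntergenic") <- nIntergenic
  attr(out, "skippedGenes") <- skipped
  out
}

#' Merge significant positions into binding sites
#'
#' Positions no more than \code{maxGap} nt apart (same library, chrom,
#' strand) are merged. The site center is the maximal-count position, ties
#' resolved toward the 5'-most position on the site's strand.
#'
#' @param sig Significant positions (\code{\link{callSignificantPositions}}).
#' @param maxGap Maximum merge distance in nt (default 15).
#' @return \code{GRanges} of sites with \code{center}, \code{totalCount},
#'   \code{nSigPositions}, \code{library}.
#' @export
mergeBindingSites <- function(sig, maxGap = 15L) {
  if (length(sig) == 0L)
    return(GenomicRanges::GRanges(center = integer(0), totalCount = integer(0),
                                  nSigPositions = integer(0), library = character(0)))
  out <- list()
  for (lib in unique(sig$library)) {
    s <- sig[sig$library == lib]
    red <- GenomicRanges::reduce(s, min.gapwidth = maxGap)
    hits <- GenomicRanges::findOverlaps(s, red)
    stopifnot(length(hits) == length(s))
    grpI <- S4Vectors::subjectHits(hits)
    pos <- GenomicRanges::start(s)
    plus <- as.character(GenomicRanges::strand(s)) == "+"
    # order so that within each site the max-count, 5'-most position wins
    key5 <- ifelse(plus, pos, -pos)
    o <- order(grpI, -s$count, key5)
    first <- !duplicated(grpI[o])
    centers <- pos[o][first]
    grpSorted <- grpI[o][first]
    tot <- tapply(s$count, grpI, sum)
    nsig <- tapply(s$count, grpI, length)
    red$center <- NA_integer_
    red$center[grpSorted] <- centers
    red$totalCount <- as.integer(tot[as.character(seq_along(red))])
    red$nSigPositions <- as.integer(nsig[as.character(seq_along(red))])
    red$library <- lib
    out[[lib]] <- red
  }
  res <- do.call(c, unname(out))
  sort(res, ignore.strand = TRUE)
}
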