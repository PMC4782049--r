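## k-mer module: region-stratified 8-mer enrichment around significant
## cross-link positions against a randomized-placement background (the same
## number of windows re-placed uniformly within the same region intervals).

#' Extract sequence windows around significant positions
#'
#' Strand-oriented windows of length 2*flank+1 centered on each significant
#' position within the requested region (reverse-complemented on the minus
#' strand). Windows that would extend past the edge of their containing
#' region interval are discarded and counted.
#'
#' @param sig Significant positions (width-1 \code{GRanges}), one library.
#' @param annotation A \code{GenomeAnnotation} with genome sequence.
#' @param region \code{"all"} (whole representative-transcript spans),
#'   \code{"5utr"} or \code{"3utr"}.
#' @param flank Flank size in nt (default 20).
#' @param regions Optional precomputed regions.
#' @return List: \code{seqs} (\code{DNAStringSet}), \code{intervals}
#'   (\code{GRanges} the windows and the background are confined to),
#'   \code{positions} (the retained positions), \code{nDiscarded}.
#' @export
extractWindows <- function(sig, annotation, region = c("all", "5utr", "3utr"),
                           flank = 20L, regions = deriveRegions(annotation)) {
  region <- match.arg(region)
  genome <- genomeSeq(annotation)
  if (length(genome) == 0L) .stopf("annotation has no genome sequence")
  ivals <- switch(region,
    all = {
      rep <- representativeTranscripts(annotation)
      geneSpans(annotation)[names(rep)]
    },
    `5utr` = regions[regions$label == "five_prime_utr"],
    `3utr` = regions[regions$label == "three_prime_utr"])
  hit <- GenomicRanges::findOverlaps(sig, ivals, select = "first")
  keep <- !is.na(hit)
  sig <- sig[keep]; hit <- hit[keep]
  # window must fit inside its containing interval
  p <- GenomicRanges::start(sig)
  lo <- GenomicRanges::start(ivals)[hit]; hi <- GenomicRanges::end(ivals)[hit]
  fits <- p - flank >= lo & p + flank <= hi
  nDiscarded <- sum(!fits)
  sig <- sig[fits]; p <- p[fits]
  seqs <- .extractGenomeSeqs(genome,
    GenomicRanges::GRanges(GenomicRanges::seqnames(sig),
                           IRanges::IRanges(p - flank, p + flank),
                           strand = GenomicRanges::strand(sig)))
  list(seqs = seqs, intervals = ivals, positions = sig,
       nDiscarded = nDiscarded, region = region, flank = flank)
}

# strand-aware sequence extraction from an in-memory DNAStringSet genome
.extractGenomeSeqs <- function(genome, gr) {
  if (length(gr) == 0L) return(Biostrings::DNAStringSet())
  chrom <- as.character(GenomicRanges::seqnames(gr))
  parts <- list(); idx <- list()
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    parts[[ch]] <- Biostrings::extractAt(genome[[ch]],
                                         IRanges::IRanges(GenomicRanges::start(gr)[ix],
                                                          GenomicRanges::end(gr)[ix]))
    idx[[ch]] <- ix
  }
  res <- do.call(c, unname(parts))[order(unlist(idx, use.names = FALSE))]
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(neg)) res[neg] <- Biostrings::reverseComplement(res[neg])
  res
}

# total k-mer counts over a window set (N-separated concatenation)
.kmerCounts <- function(seqs, k) {
  if (length(seqs) == 0L)
    return(Biostrings::oligonucleotideFrequency(Biostrings::DNAString(""), k))
  combined <- Biostrings::DNAString(
    paste(as.character(seqs), collapse = strrep("N", k - 1L)))
  Biostrings::oligonucleotideFrequency(combined, k)
}

#' k-mer enrichment against randomized window placement
#'
#' Observed counts of every k-mer over the extracted windows are compared
#' with \code{nRand} background replicates in which the same number of
#' windows is placed uniformly at random within the same region intervals
#' (so background windows never leave the intervals the observed windows
#' came from). z = (observed - background mean) / background sd; k-mers
#' with zero background sd are flagged (z = NA).
#'
#' @param windows Result of \code{\link{extractWindows}} (needs >= 100
#'   windows).
#' @param annotation The same \code{GenomeAnnotation}.
#' @param k Word size (default 8).
#' @param nRand Background replicates (>= 10; default 100).
#' @param seed Seed for background placement.
#' @param minBackground Minimum background mean count for a z-score: below
#'   this support the count distribution is too discrete for the normal
#'   scale and z is flagged NA (the counts are still reported). Default 5.
#' @return data.frame sorted by decreasing z: kmer, observed, bg_mean,
#'   bg_sd, z; attributes record parameters.
#' @export
kmerEnrichment <- function(windows, annotation, k = 8L, nRand = 100L,
                           seed = 1L, minBackground = 5) {
  if (nRand < 10L) .stopf("nRand must be >= 10 (unstable background sd)")
  if (length(windows$seqs) < 100L)
    .stopf("need >= 100 windows (got %d)", length(windows$seqs))
  set.seed(seed)
  genome <- genomeSeq(annotation)
  flank <- windows$flank
  n <- length(windows$seqs)
  obs <- .kmerCounts(windows$seqs, k)

  # eligible center positions: intervals shrunk by flank on both sides
  iv <- windows$intervals
  w <- GenomicRanges::width(iv) - 2L * flank
  ok <- w > 0L
  iv <- iv[ok]; w <- w[ok]
  if (length(iv) == 0L) .stopf("no interval can host a window")
  bg <- matrix(0L, length(obs), nRand, dimnames = list(names(obs), NULL))
  chroms <- as.character(GenomicRanges::seqnames(iv))
  starts <- GenomicRanges::start(iv)
  strands <- as.character(GenomicRanges::strand(iv))
  for (b in seq_len(nRand)) {
    pick <- sample.int(length(iv), n, replace = TRUE, prob = w)
    offs <- floor(runif(n) * w[pick])
    centers <- starts[pick] + flank + offs
    gr <- GenomicRanges::GRanges(chroms[pick],
                                 IRanges::IRanges(centers - flank, centers + flank),
                                 strand = strands[pick])
    bg[, b] <- .kmerCounts(.extractGenomeSeqs(genome, gr), k)
  }
  mu <- rowMeans(bg)
  sdv <- matrixStats::rowSds(bg)
  z <- ifelse(sdv > 0 & mu >= minBackground, (obs - mu) / sdv, NA_real_)
  out <- data.frame(kmer = names(obs), observed = as.integer(obs),
                    bg_mean = mu, bg_sd = sdv, z = z,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$kmer, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "params") <- list(k = k, flank = flank, nRand = nRand, seed = seed,
                              nWindows = n, region = windows$region)
  out
}

# IUPAC degenerate code for a set of DNA bases
.iupac <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(map)[match(key, vapply(names(map), function(n)
    paste(sort(strsplit(map[[n]], "")[[1]]), collapse = ""), ""))]
  if (is.na(hit)) "N" else hit
}

#' Top enriched k-mers and a degenerate consensus
#'
#' Top-n k-mers by z (ties broken lexicographically); the consensus is a
#' per-column majority over the ungapped top-n alignment, using the
#' majority base when it reaches 50% and an IUPAC degenerate letter (bases
#' at >= 25%) otherwise.
#'
#' @param table k-mer table (\code{\link{kmerEnrichment}}).
#' @param n Number of top k-mers (default 10).
#' @param rna Report motifs in the RNA alphabet (U for T).
#' @return List: \code{top} (data.frame), \code{consensus} (string).
#' @export
topMotifs <- function(table, n = 10L, rna = FALSE) {
  tab <- table[!is.na(table$z), ]
  tab <- tab[order(-tab$z, tab$kmer), ]
  top <- head(tab, n)
  mat <- do.call(rbind, strsplit(top$kmer, ""))
  consensus <- vapply(seq_len(ncol(mat)), function(j) {
    f <- table(mat[, j]) / nrow(mat)
    if (max(f) >= 0.5) names(f)[which.max(f)]
    else .iupac(names(f)[f >= 0.25])
  }, "")
  consensus <- paste(consensus, collapse = "")
  if (rna) {
    top$kmer <- gsub("T", "U", top$kmer)
    consensus <- gsub("T", "U", consensus)
  }
  list(top = top, consensus = consensus)
}
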