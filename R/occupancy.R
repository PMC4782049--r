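## Occupancy module: region-level binding densities, exon binding matrices,
## cobound-exon fractions, correlation clustering of libraries, site-count
## distributions and 3' UTR length statistics.

#' Region-level binding density
#'
#' Density per region label = significant events in the label / total label
#' length, scaled to events-per-million unique cDNAs per library. Each event
#' is assigned to exactly one label of the representative transcript.
#'
#' @param sig Significant positions (\code{GRanges} with \code{count},
#'   \code{library}).
#' @param regions Labeled regions (\code{\link{deriveRegions}}).
#' @param librarySizes Named vector of unique-cDNA totals per library
#'   (default: per-library sums of \code{sig$count}).
#' @return data.frame: library, label, n_events, label_length, density
#'   (events/nt), density_per_million; attribute \code{"nUnassigned"}.
#' @export
regionDensity <- function(sig, regions,
                          librarySizes = tapply(sig$count, sig$library, sum)) {
  hit <- GenomicRanges::findOverlaps(sig, regions, select = "first")
  lab <- ifelse(is.na(hit), NA_character_, regions$label[hit])
  nUnassigned <- sum(is.na(lab))
  lens <- tapply(GenomicRanges::width(regions), regions$label, sum)
  keep <- !is.na(lab)
  dt <- data.table::data.table(library = sig$library[keep], label = lab[keep],
                               count = sig$count[keep])
  agg <- dt[, list(n_events = sum(count)), by = c("library", "label")]
  full <- data.table::CJ(library = sort(unique(sig$library)),
                         label = names(lens))
  agg <- agg[full, on = c("library", "label")]
  agg$n_events[is.na(agg$n_events)] <- 0L
  agg$label_length <- as.numeric(lens[agg$label])
  agg$density <- agg$n_events / agg$label_length
  agg$density_per_million <- agg$density * 1e6 /
    pmax(as.numeric(librarySizes[agg$library]), 1)
  out <- as.data.frame(agg)
  attr(out, "nUnassigned") <- nUnassigned
  out
}

#' Exon binding matrix
#'
#' Per-exon summed significant cross-link counts per library, stored as a
#' \link[SummarizedExperiment]{SummarizedExperiment} with assays
#' \code{counts} (summed cDNAs of significant positions), \code{cpm}
#' (per-million-normalized) and \code{nsig} (number of significant
#' positions). Row metadata carries exon ordinal class and length.
#'
#' @param sig Significant positions (all libraries).
#' @param exons Classified exons (\code{\link{classifyExons}}).
#' @param librarySizes Named unique-cDNA totals (default per-library sums).
#' @return A \code{SummarizedExperiment}, rows = exons, columns = libraries.
#' @export
exonBindingMatrix <- function(sig, exons,
                              librarySizes = tapply(sig$count, sig$library, sum)) {
  libs <- sort(unique(sig$library))
  nr <- length(exons); nc <- length(libs)
  counts <- matrix(0, nr, nc, dimnames = list(exons$exon_id, libs))
  nsig <- matrix(0L, nr, nc, dimnames = list(exons$exon_id, libs))
  hits <- GenomicRanges::findOverlaps(sig, exons)
  if (length(hits)) {
    dt <- data.table::data.table(
      ex = S4Vectors::subjectHits(hits),
      lib = match(sig$library[S4Vectors::queryHits(hits)], libs),
      count = sig$count[S4Vectors::queryHits(hits)])
    agg <- dt[, list(total = sum(count), n = .N), by = c("ex", "lib")]
    counts[cbind(agg$ex, agg$lib)] <- agg$total
    nsig[cbind(agg$ex, agg$lib)] <- agg$n
  }
  sizes <- pmax(as.numeric(librarySizes[libs]), 1)
  cpm <- sweep(counts, 2L, sizes, "/") * 1e6
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, cpm = cpm, nsig = nsig),
    rowRanges = exons)
}

#' Fraction of bound exons cobound by another SR library
#'
#' An exon is bound by a library when it carries at least
#' \code{boundThreshold} significant positions. For each library the
#' fraction of its bound exons also bound by at least one \emph{other} SR
#' library is reported; receptor/control libraries can be excluded from the
#' "other" set.
#'
#' @param ebm Exon binding matrix (\code{\link{exonBindingMatrix}}).
#' @param boundThreshold Minimum significant positions (default 1).
#' @param excludeLibraries Libraries that do not count as SR partners
#'   (default: names matching "NXF1" or "CTRL").
#' @return data.frame: library, n_bound, n_cobound, fraction (NA when a
#'   library binds no exons).
#' @export
coboundExonFraction <- function(ebm, boundThreshold = 1L,
                                excludeLibraries = grep("NXF1|CTRL",
                                  colnames(ebm), value = TRUE)) {
  nsig <- SummarizedExperiment::assay(ebm, "nsig")
  bound <- nsig >= boundThreshold
  sr <- setdiff(colnames(bound), excludeLibraries)
  res <- lapply(colnames(bound), function(lib) {
    b <- bound[, lib]
    others <- setdiff(sr, lib)
    nb <- sum(b)
    nc <- if (length(others)) sum(b & rowSums(bound[, others, drop = FALSE]) > 0)
          else 0L
    data.frame(library = lib, n_bound = nb, n_cobound = nc,
               fraction = if (nb > 0) nc / nb else NA_real_)
  })
  do.call(rbind, res)
}

# distance correlation between two numeric vectors (O(n^2))
.dcor <- function(x, y) {
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  B <- b - rowMeans(b)[row(b)] - colMeans(b)[col(b)] + mean(b)
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(NA_real_)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

#' Correlation clustering of libraries by exon binding
#'
#' Pairwise correlation of per-exon normalized counts (Spearman rank
#' correlation or distance correlation), followed by average-linkage
#' hierarchical clustering on dissimilarity 1 - correlation. Constant
#' columns are reported as NA and excluded from the tree. Distance
#' correlation is computed on a seeded subsample of exons (quadratic cost).
#'
#' @param ebm Exon binding matrix.
#' @param method \code{"spearman"} (default) or \code{"dcor"}.
#' @param assay Assay to correlate (default \code{"cpm"}).
#' @param log Log-transform (log2(x+1)) before correlating.
#' @param maxExons Subsample cap for \code{"dcor"} (default 5000).
#' @param seed Seed for the subsample.
#' @return List: \code{correlation} (matrix), \code{tree} (\code{hclust} or
#'   NULL), \code{leafOrder}, \code{method}.
#' @export
correlationClustering <- function(ebm, method = c("spearman", "dcor"),
                                  assay = "cpm", log = FALSE,
                                  maxExons = 5000L, seed = 1L) {
  method <- match.arg(method)
  m <- SummarizedExperiment::assay(ebm, assay)
  if (log) m <- log2(m + 1)
  if (ncol(m) < 2L) .stopf("need at least two libraries")
  if (method == "spearman") {
    cc <- suppressWarnings(cor(m, method = "spearman"))
    const <- apply(m, 2L, function(v) length(unique(v)) == 1L)
    cc[const, ] <- NA; cc[, const] <- NA
    diag(cc) <- 1
  } else {
    set.seed(seed)
    if (nrow(m) > maxExons) m <- m[.sampleInt(nrow(m), maxExons), , drop = FALSE]
    k <- ncol(m)
    cc <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
    diag(cc) <- 1
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      v <- .dcor(m[, i], m[, j])
      cc[i, j] <- v; cc[j, i] <- v
    }
  }
  ok <- colnames(cc)[colSums(is.na(cc)) < nrow(cc) - 1L]
  tree <- NULL; leafOrder <- character(0)
  if (length(ok) >= 2L) {
    sub <- cc[ok, ok, drop = FALSE]
    sub[is.na(sub)] <- 0
    tree <- hclust(as.dist(1 - sub), method = "average")
    leafOrder <- tree$labels[tree$order]
  }
  list(correlation = cc, tree = tree, leafOrder = leafOrder, method = method)
}

#' Binding-site counts per transcript and per-region placement
#'
#' @param sites Binding sites (\code{\link{mergeBindingSites}}), one library.
#' @param annotation A \code{GenomeAnnotation}.
#' @param regions Optional precomputed regions.
#' @return List: \code{histogram} (data.frame sites-per-transcript,
#'   including the zero bucket over representative transcripts),
#'   \code{regionTable} (site counts per region label).
#' @export
sitesPerTranscript <- function(sites, annotation,
                               regions = deriveRegions(annotation)) {
  rep <- representativeTranscripts(annotation)
  spans <- geneSpans(annotation)[names(rep)]
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                    IRanges::IRanges(sites$center, width = 1L),
                                    strand = GenomicRanges::strand(sites))
  hit <- GenomicRanges::findOverlaps(centers, spans, select = "first")
  counts <- table(factor(names(spans)[hit[!is.na(hit)]], levels = names(spans)))
  histo <- as.data.frame(table(n_sites = factor(as.integer(counts))),
                         stringsAsFactors = FALSE)
  rhit <- GenomicRanges::findOverlaps(centers, regions, select = "first")
  lab <- regions$label[rhit[!is.na(rhit)]]
  regionTable <- as.data.frame(table(label = lab), stringsAsFactors = FALSE)
  list(histogram = histo, regionTable = regionTable)
}

#' 3' UTR length distributions and rank-sum comparisons
#'
#' @param sets Named list of transcript-id (or gene-id) vectors.
#' @param annotation A \code{GenomeAnnotation}.
#' @param regions Optional precomputed regions.
#' @return List: \code{lengths} (per set), \code{medians}, \code{tests}
#'   (pairwise Wilcoxon rank-sum p-values), \code{nMissing} (ids without a
#'   3' UTR per set).
#' @export
utr3LengthStats <- function(sets, annotation,
                            regions = deriveRegions(annotation)) {
  u3 <- regions[regions$label == "three_prime_utr"]
  lenByTx <- tapply(GenomicRanges::width(u3), u3$transcript_id, sum)
  lenByGene <- tapply(GenomicRanges::width(u3), u3$gene_id, sum)
  getLens <- function(ids) {
    v <- lenByTx[ids]
    v[is.na(v)] <- lenByGene[ids[is.na(v)]]
    v
  }
  lens <- lapply(sets, getLens)
  nMissing <- vapply(lens, function(v) sum(is.na(v)), 0L)
  lens <- lapply(lens, function(v) as.numeric(v[!is.na(v)]))
  medians <- vapply(lens, median, 0)
  nm <- names(sets)
  tests <- list()
  if (length(nm) >= 2L)
    for (i in seq_len(length(nm) - 1L)) for (j in seq(i + 1L, length(nm))) {
      p <- if (length(lens[[i]]) && length(lens[[j]]))
        suppressWarnings(wilcox.test(lens[[i]], lens[[j]])$p.value) else NA_real_
      tests[[paste(nm[i], nm[j], sep = " vs ")]] <- p
    }
  list(lengths = lens, medians = medians, tests = unlist(tests),
       nMissing = nMissing)
}
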