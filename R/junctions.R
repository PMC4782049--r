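## Junction module: splice-site-anchored metagene profiles, spliced versus
## unspliced junction-read classification, and scaled last-exon profiles.

#' Splice-site metagene profile
#'
#' Accumulates cross-link event counts at signed offsets around anchor
#' sites. Offsets follow transcript direction: negative offsets are 5' of
#' the anchor (the exonic side for 5' splice sites, the intronic side for 3'
#' splice sites).
#'
#' @param events Cross-link events (width-1 \code{GRanges} with
#'   \code{count}), one library.
#' @param sites Anchor sites (width-1 \code{GRanges}), strand-matched.
#' @param window Half-window in nt (default 300).
#' @param librarySize Unique cDNAs in the library (default: sum of event
#'   counts) for per-million scaling.
#' @return data.frame with \code{offset}, \code{count}, \code{perMillion}.
#' @export
spliceSiteMetaprofile <- function(events, sites, window = 300L,
                                  librarySize = sum(events$count)) {
  if (length(sites) == 0L) .stopf("empty site list")
  win <- suppressWarnings(GenomicRanges::resize(sites, 2L * window + 1L, fix = "center"))
  hits <- GenomicRanges::findOverlaps(events, win)
  offs <- integer(0); cnts <- integer(0)
  if (length(hits)) {
    e <- events[S4Vectors::queryHits(hits)]
    s <- sites[S4Vectors::subjectHits(hits)]
    d <- .txdir(as.character(GenomicRanges::strand(s)))
    offs <- (GenomicRanges::start(e) - GenomicRanges::start(s)) * d
    cnts <- e$count
  }
  grid <- seq(-window, window)
  count <- vapply(split(cnts, factor(offs, levels = grid)), sum, 0)
  data.frame(offset = grid, count = as.numeric(count),
             perMillion = as.numeric(count) * 1e6 / max(librarySize, 1))
}

# read alignment blocks from the cDNA table (M/N CIGARs)
.readBlocks <- function(reads) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(reads$cigar, pos = reads$start,
                                                    ops = "M")
}

#' Classify junction-overlapping reads as spliced or unspliced
#'
#' Per annotated 5' splice site: a read is unspliced when one contiguous
#' alignment block covers at least \code{minOverhang} nt on both sides of
#' the exon/intron boundary, and spliced when its gap matches an annotated
#' intron exactly with at least \code{minOverhang} nt in both flanking
#' exons. Gapped reads matching no annotated intron are tallied separately
#' as novel junctions.
#'
#' @param reads Read table (library, chrom, start, end, strand, cigar).
#' @param annotation A \code{GenomeAnnotation}.
#' @param minOverhang Minimum nt required on each side (default 3).
#' @return List: \code{perLibrary} (data.frame with n_spliced, n_unspliced,
#'   n_novel, proportion_spliced), \code{perJunction} (data.frame of counts
#'   per 5' splice site and library).
#' @export
classifyJunctionReads <- function(reads, annotation, minOverhang = 3L) {
  introns <- .annotatedIntrons(annotation)
  if (length(introns) == 0L) .stopf("annotation contains no introns")
  ikey <- paste(GenomicRanges::seqnames(introns), GenomicRanges::start(introns),
                GenomicRanges::end(introns), GenomicRanges::strand(introns))
  dt <- data.table::as.data.table(reads)
  blocks <- .readBlocks(dt)
  nb <- S4Vectors::elementNROWS(blocks)

  plus <- dt$strand == "+"
  # 5' splice site position = first intronic base
  i5 <- ifelse(as.character(GenomicRanges::strand(introns)) == "+",
               GenomicRanges::start(introns), GenomicRanges::end(introns))

  ## unspliced: contiguous reads covering the boundary with overhang
  contig <- which(nb == 1L)
  unspl <- data.table::data.table(lib = character(0), j = integer(0))
  if (length(contig)) {
    rr <- GenomicRanges::GRanges(dt$chrom[contig],
                                 IRanges::IRanges(dt$start[contig], dt$end[contig]),
                                 strand = dt$strand[contig])
    # required coverage straddling the exon/intron boundary:
    # plus:  [i5-mo, i5+mo-1]; minus: [i5-mo+1, i5+mo] (i5 = first intron base)
    iplus <- as.character(GenomicRanges::strand(introns)) == "+"
    need <- GenomicRanges::GRanges(GenomicRanges::seqnames(introns),
                                   IRanges::IRanges(
                                     ifelse(iplus, i5 - minOverhang, i5 - minOverhang + 1L),
                                     width = 2L * minOverhang),
                                   strand = GenomicRanges::strand(introns))
    h <- GenomicRanges::findOverlaps(need, rr, type = "within")
    if (length(h))
      unspl <- data.table::data.table(
        lib = dt$library[contig[S4Vectors::subjectHits(h)]],
        j = S4Vectors::queryHits(h))
  }

  ## spliced / novel: gapped reads
  gapped <- which(nb == 2L)
  spl <- data.table::data.table(lib = character(0), j = integer(0))
  novel <- data.table::data.table(lib = character(0))
  if (length(gapped)) {
    b <- blocks[gapped]
    st <- IRanges::start(b); en <- IRanges::end(b)
    b1e <- vapply(en, `[`, 0L, 1L); b2s <- vapply(st, `[`, 0L, 2L)
    w1 <- b1e - vapply(st, `[`, 0L, 1L) + 1L
    w2 <- vapply(en, `[`, 0L, 2L) - b2s + 1L
    gkey <- paste(dt$chrom[gapped], b1e + 1L, b2s - 1L, dt$strand[gapped])
    m <- match(gkey, ikey)
    okOver <- w1 >= minOverhang & w2 >= minOverhang
    isSpl <- !is.na(m) & okOver
    if (any(isSpl))
      spl <- data.table::data.table(lib = dt$library[gapped[isSpl]], j = m[isSpl])
    isNovel <- is.na(m)
    if (any(isNovel))
      novel <- data.table::data.table(lib = dt$library[gapped[isNovel]])
  }

  libs <- sort(unique(dt$library))
  perLib <- data.frame(library = libs,
                       n_spliced = as.integer(table(factor(spl$lib, libs))),
                       n_unspliced = as.integer(table(factor(unspl$lib, libs))),
                       n_novel = as.integer(table(factor(novel$lib, libs))))
  perLib$proportion_spliced <- ifelse(perLib$n_spliced + perLib$n_unspliced > 0,
                                      perLib$n_spliced /
                                        (perLib$n_spliced + perLib$n_unspliced), NA)
  both <- rbind(cbind(spl, class = "spliced"), cbind(unspl, class = "unspliced"))
  perJ <- if (nrow(both)) as.data.frame(
    data.table::dcast(both[, list(n = .N), by = c("lib", "j", "class")],
                      lib + j ~ class, value.var = "n", fill = 0L))
  else data.frame(lib = character(0), j = integer(0))
  list(perLibrary = perLib, perJunction = perJ)
}

#' Scaled metagene profile over last exons
#'
#' Each last exon is scaled to \code{nBins} bins from its 3' splice site to
#' the poly(A) end; event counts are assigned fractionally (an event's 1-nt
#' footprint is spread over the bins it covers in scaled coordinates), so
#' total mass is preserved even for exons shorter than \code{nBins}.
#'
#' @param sig Significant positions (width-1 \code{GRanges} with
#'   \code{count}), one library.
#' @param lastExons \code{GRanges} of last exons (see
#'   \code{\link{classifyExons}}).
#' @param nBins Number of bins (default 100).
#' @param librarySize Per-million scaling denominator.
#' @return data.frame with \code{bin} (0-based), \code{mass},
#'   \code{meanDensity}, \code{perMillion}.
#' @export
lastExonProfile <- function(sig, lastExons, nBins = 100L,
                            librarySize = sum(sig$count)) {
  if (length(lastExons) == 0L) .stopf("empty last-exon set")
  hits <- GenomicRanges::findOverlaps(sig, lastExons)
  mass <- numeric(nBins)
  if (length(hits)) {
    e <- sig[S4Vectors::queryHits(hits)]
    x <- lastExons[S4Vectors::subjectHits(hits)]
    len <- GenomicRanges::width(x)
    plus <- as.character(GenomicRanges::strand(x)) == "+"
    r <- ifelse(plus, GenomicRanges::start(e) - GenomicRanges::start(x),
                GenomicRanges::end(x) - GenomicRanges::start(e))
    a <- r * nBins / len
    bnd <- (r + 1) * nBins / len
    cnt <- as.numeric(e$count)
    for (i in seq_along(a)) {
      k1 <- floor(a[i]); k2 <- min(floor(bnd[i] - 1e-9), nBins - 1)
      ks <- k1:k2
      # overlap of [a, bnd) with each covered bin
      ov <- pmin(bnd[i], ks + 1) - pmax(a[i], ks)
      mass[ks + 1L] <- mass[ks + 1L] + cnt[i] * ov / (bnd[i] - a[i])
    }
  }
  data.frame(bin = seq_len(nBins) - 1L,
             mass = mass,
             meanDensity = mass / length(lastExons),
             perMillion = mass * 1e6 / max(librarySize, 1))
}
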