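## Synthetic-data generator, part 2: iCLIP libraries.
##
## Cross-links are placed per gene at a uniform background rate over the
## pre-mRNA span, boosted lambda-fold at planted motif bases. Receptor
## (NXF1-like) cross-links come in clusters anchored near partner placements
## in 3' UTRs (at cobindRate) or placed independently. Each cross-linked
## cDNA emits a read starting one nucleotide 3' of the cross-linked base;
## junction-crossing reads are spliced with probability pSpliced; PCR
## duplicates share position and barcode.

#' Simulate iCLIP reads for all configured libraries
#'
#' @param config A \code{SimulationConfig}.
#' @param sim Result of \code{\link{simulateGenome}} (same config).
#' @return List with \code{reads} (data.frame: library, chrom, start, end,
#'   strand, cigar, barcode) and \code{truth} (per-library unique-cDNA
#'   counts, planted placements, receptor clusters, spliced fractions).
#' @export
simulateIclip <- function(config, sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  ann <- sim$annotation
  rep <- representativeTranscripts(ann)
  exl <- txExons(ann)[rep]
  geneIds <- names(rep)
  regions <- deriveRegions(ann)
  placements <- sim$truth$placements

  # per-gene genomic-sorted exon arrays
  geneInfo <- lapply(seq_along(exl), function(i) {
    ex <- exl[[i]]
    o <- order(GenomicRanges::start(ex))
    list(chrom = as.character(GenomicRanges::seqnames(ex))[1],
         strand = as.character(GenomicRanges::strand(ex))[1],
         gstarts = GenomicRanges::start(ex)[o],
         gends = GenomicRanges::end(ex)[o],
         span = c(min(GenomicRanges::start(ex)), max(GenomicRanges::end(ex))))
  })
  names(geneInfo) <- geneIds

  specs <- config$proteins
  nx <- config$nxf1
  allReads <- list()
  truth <- list(uniqueCounts = numeric(0), pSpliced = numeric(0))

  genome <- genomeSeq(ann)
  for (p in seq_len(nrow(specs))) {
    nm <- specs$name[p]
    xl <- .backgroundCrosslinks(geneInfo, specs$backgroundRate[p])
    if (!is.na(specs$motif[p]) && specs$lambda[p] > 1) {
      extra <- .motifCrosslinks(specs$motif[p], genome, geneInfo,
                                (specs$lambda[p] - 1) * specs$backgroundRate[p])
      if (nrow(extra) == 0L)
        .warnf("motif of library '%s' absent from the genome; background only", nm)
      xl <- rbind(xl, extra)
    }
    rd <- .emitReads(xl, geneInfo, config, specs$pSpliced[p])
    rd$library <- nm
    allReads[[nm]] <- rd
    truth$uniqueCounts[nm] <- nrow(rd)
    truth$pSpliced[nm] <- specs$pSpliced[p]
  }

  # receptor library
  nxres <- .nxf1Crosslinks(geneInfo, geneIds, regions, placements, nx)
  rd <- .emitReads(nxres$xl, geneInfo, config, specs$pSpliced[1])
  rd$library <- nx$name
  allReads[[nx$name]] <- rd
  truth$uniqueCounts[nx$name] <- nrow(rd)
  truth$pSpliced[nx$name] <- specs$pSpliced[1]
  truth$nxf1Clusters <- nxres$clusters

  reads <- data.table::rbindlist(allReads)
  # PCR duplication + barcodes (per unique cDNA)
  n <- nrow(reads)
  reads[, "barcode" := .randomBarcodes(n, config$barcodeLength)]
  copies <- 1L + rgeom(n, prob = 1 - config$pcrDuplicationRate)
  reads <- reads[rep(seq_len(n), copies)]
  data.table::setcolorder(reads, c("library", "chrom", "start", "end",
                                   "strand", "cigar", "barcode"))
  list(reads = as.data.frame(reads), truth = truth)
}

# uniform background cross-links over each gene's pre-mRNA span
.backgroundCrosslinks <- function(geneInfo, rate) {
  out <- vector("list", length(geneInfo))
  for (i in seq_along(geneInfo)) {
    gi <- geneInfo[[i]]
    L <- gi$span[2] - gi$span[1] + 1L
    nb <- rpois(1L, rate * L)
    if (nb == 0L) next
    out[[i]] <- data.frame(gene = i, pos = gi$span[1] + .sampleInt(L, nb, TRUE) - 1L)
  }
  data.table::rbindlist(out)
}

# extra cross-links at each base of every genomic occurrence of the motif
# within gene spans (strand-aware; planted copies are occurrences by
# construction, and chance occurrences bind identically)
.motifCrosslinks <- function(motif, genome, geneInfo, extraRate) {
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  occStart <- integer(0); occGene <- integer(0)
  for (i in seq_along(geneInfo)) {
    gi <- geneInfo[[i]]
    seq <- Biostrings::subseq(genome[[gi$chrom]], gi$span[1], gi$span[2])
    pat <- if (gi$strand == "+") fwd else rev
    m <- Biostrings::matchPattern(pat, seq)
    if (length(m)) {
      occStart <- c(occStart, gi$span[1] + Biostrings::start(m) - 1L)
      occGene <- c(occGene, rep(i, length(m)))
    }
  }
  if (length(occStart) == 0L)
    return(data.table::data.table(gene = integer(0), pos = integer(0)))
  n8 <- 8L
  posAll <- rep(occStart, each = n8) + rep(0:(n8 - 1L), length(occStart))
  gAll <- rep(occGene, each = n8)
  cnt <- rpois(length(posAll), extraRate)
  keep <- cnt > 0L
  data.table::data.table(gene = rep(gAll[keep], cnt[keep]),
                         pos = rep(posAll[keep], cnt[keep]))
}

# receptor cross-links: background + 3'UTR clusters (anchored at partner
# placements at cobindRate, else placed clear of them) + 5'UTR clusters
.nxf1Crosslinks <- function(geneInfo, geneIds, regions, placements, nx) {
  xl <- .backgroundCrosslinks(geneInfo, nx$backgroundRate)
  parts <- list(xl)
  clusters <- list()
  utr3 <- regions[regions$label == "three_prime_utr"]
  utr5 <- regions[regions$label == "five_prime_utr"]
  partnerPl <- if (length(placements))
    placements[placements$protein == nx$partner & placements$label %in% "three_prime_utr"]
  else GenomicRanges::GRanges()

  emitCluster <- function(geneIdx, center, anchored, stratum) {
    nc <- rpois(1L, nx$clusterMeanCdna)
    if (nc == 0L) return()
    offs <- .runifInt(nc, -nx$clusterSpread, nx$clusterSpread)
    parts[[length(parts) + 1L]] <<- data.table::data.table(
      gene = geneIdx, pos = center + offs)
    clusters[[length(clusters) + 1L]] <<- data.frame(
      gene_id = geneIds[geneIdx], center = center, anchored = anchored,
      stratum = stratum, stringsAsFactors = FALSE)
  }

  for (i in seq_along(geneIds)) {
    gene <- geneIds[i]
    pp <- partnerPl[partnerPl$gene_id == gene]
    u3 <- utr3[utr3$gene_id == gene]
    if (length(pp) && length(u3)) {
      for (k in seq_len(nx$clustersPerUtr3)) {
        if (runif(1) < nx$cobindRate) {
          a <- pp[sample.int(length(pp), 1L)]
          center <- round((GenomicRanges::start(a) + GenomicRanges::end(a)) / 2) +
            round(rnorm(1, 0, nx$offsetSd))
          emitCluster(i, as.integer(center), TRUE, "last_exon")
        } else {
          # uniform in the 3'UTR but clear of partner placements
          mid <- (GenomicRanges::start(pp) + GenomicRanges::end(pp)) / 2
          w <- GenomicRanges::width(u3)
          for (try in 1:20) {
            k2 <- sample.int(length(u3), 1L, prob = w)
            c0 <- GenomicRanges::start(u3)[k2] + .sampleInt(w[k2], 1L) - 1L
            if (all(abs(c0 - mid) > 45)) { emitCluster(i, c0, FALSE, "last_exon"); break }
          }
        }
      }
    }
    u5 <- utr5[utr5$gene_id == gene]
    if (length(u5) && runif(1) < nx$fivePrimeRate) {
      w <- GenomicRanges::width(u5)
      k2 <- sample.int(length(u5), 1L, prob = w)
      c0 <- GenomicRanges::start(u5)[k2] + .sampleInt(w[k2], 1L) - 1L
      emitCluster(i, c0, FALSE, "first_exon")
    }
  }
  list(xl = data.table::rbindlist(parts),
       clusters = if (length(clusters)) do.call(rbind, clusters)
                  else data.frame(gene_id = character(0), center = integer(0),
                                  anchored = logical(0), stratum = character(0)))
}

# Emit one read per cross-linked cDNA. Reads start one nucleotide 3' of the
# cross-link in transcript direction; reads crossing an exon/intron boundary
# of the gene's representative isoform are spliced with probability pSpliced
# (gapped exactly over the annotated intron), otherwise continue into the
# intron. Reads are clipped at the transcript 3' end and chromosome start.
.emitReads <- function(xl, geneInfo, config, pSpliced) {
  if (is.null(xl) || nrow(xl) == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  cigar = character(0)))
  xl <- data.table::as.data.table(xl)
  out <- vector("list", length(unique(xl$gene)))
  oi <- 0L
  lens <- .runifInt(nrow(xl), config$readLengthRange[1], config$readLengthRange[2])
  xl[, "len" := lens]
  for (g in unique(xl$gene)) {
    gi <- geneInfo[[g]]
    sub <- xl[xl$gene == g]
    pos <- sub$pos; len <- sub$len
    gs <- gi$gstarts; ge <- gi$gends; nex <- length(gs)
    if (gi$strand == "+") {
      rs <- pos + 1L
      k <- findInterval(rs, gs)
      exonic <- k >= 1L & rs <= ge[pmax(k, 1L)]
      reUn <- rs + len - 1L
      cross <- exonic & reUn > ge[pmax(k, 1L)] & k < nex
      lastClip <- exonic & reUn > ge[pmax(k, 1L)] & k == nex
      spl <- cross & runif(length(rs)) < pSpliced
      start <- rs; end <- reUn; cigar <- paste0(len, "M")
      # clip at transcript 3' end
      end[lastClip] <- ge[nex]
      cigar[lastClip] <- paste0(ge[nex] - rs[lastClip] + 1L, "M")
      # spliced reads: gap over the intron, clipped at next exon end
      if (any(spl)) {
        kk <- k[spl]
        w1 <- ge[kk] - rs[spl] + 1L
        rem <- len[spl] - w1
        b2e <- pmin(gs[kk + 1L] + rem - 1L, ge[kk + 1L])
        w2 <- b2e - gs[kk + 1L] + 1L
        gap <- gs[kk + 1L] - ge[kk] - 1L
        end[spl] <- b2e
        cigar[spl] <- paste0(w1, "M", gap, "N", w2, "M")
      }
    } else {
      rs <- pos - 1L                       # 5' end (genomic right)
      k <- findInterval(rs, gs)
      exonic <- k >= 1L & rs <= ge[pmax(k, 1L)]
      reUn <- rs - len + 1L
      cross <- exonic & reUn < gs[pmax(k, 1L)] & k > 1L
      lastClip <- exonic & reUn < gs[pmax(k, 1L)] & k == 1L
      spl <- cross & runif(length(rs)) < pSpliced
      start <- reUn; end <- rs; cigar <- paste0(len, "M")
      start[lastClip] <- gs[1L]
      cigar[lastClip] <- paste0(rs[lastClip] - gs[1L] + 1L, "M")
      if (any(spl)) {
        kk <- k[spl]
        w1 <- rs[spl] - gs[kk] + 1L
        rem <- len[spl] - w1
        b2s <- pmax(ge[kk - 1L] - rem + 1L, gs[kk - 1L])
        w2 <- ge[kk - 1L] - b2s + 1L
        gap <- gs[kk] - ge[kk - 1L] - 1L
        start[spl] <- b2s
        # reference-order CIGAR: left block first
        cigar[spl] <- paste0(w2, "M", gap, "N", w1, "M")
      }
    }
    ok <- start >= 1L & end >= start
    oi <- oi + 1L
    out[[oi]] <- data.table::data.table(
      chrom = gi$chrom, start = start[ok], end = end[ok],
      strand = gi$strand, cigar = cigar[ok])
  }
  data.table::rbindlist(out[seq_len(oi)])
}
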