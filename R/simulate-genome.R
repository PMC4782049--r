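## Synthetic-data generator, part 1: configuration and genome/annotation.
##
## The generator plants machine-readable ground truth (motif placements,
## receptor cobinding, export targets, isoform-usage shifts) that downstream
## modules are validated against.

#' Default iCLIP library specifications for the simulator
#'
#' Seven SR-protein-like sequence-specific binders with distinct preferred
#' 8-mers (the SRSF3-like binder carries a C-N-U-C core, written in DNA as
#' CNTC), plus a nonspecific control library. The NXF1-like receptor library
#' is configured separately (it has no sequence preference of its own).
#'
#' \code{lambda} is the per-nucleotide cross-link rate multiplier at planted
#' motif positions (>= 1); \code{backgroundRate} the expected unique cDNAs
#' per pre-mRNA nucleotide elsewhere; \code{pSpliced} the probability that a
#' junction-crossing read is spliced; \code{plantPerTx} the number of motif
#' copies planted per transcript (uniform over exons); \code{utr3PlantProb} /
#' \code{utr3PlantCount} govern additional 3' UTR plantings.
#'
#' @return A data.frame of library specifications.
#' @export
defaultProteinSpecs <- function() {
  data.frame(
    name = c("SRSF1", "SRSF2", "SRSF3", "SRSF4", "SRSF5", "SRSF6", "SRSF7", "CTRL"),
    motif = c("GAAGGACG", "GGCCAGCA", "TCAACATC", "TAGGACTT", "ACGCAGTA",
              "GTTAGCGT", "AGACGACG", NA),
    lambda = c(32, 32, 32, 32, 32, 32, 32, 1),
    backgroundRate = c(rep(0.2, 7), 0.1),
    pSpliced = c(rep(0.7, 7), 0.7),
    plantPerTx = c(rep(4L, 7), 0L),
    plantRegion = "exon",
    utr3PlantProb = c(0, 0, 0.7, 0, 0, 0, 0.5, 0),
    utr3PlantCount = c(0L, 0L, 2L, 0L, 0L, 0L, 2L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator with desk-scale defaults
#' (200 genes; roughly 2e5 unique cross-link events per specific library).
#' Every stage derives its random stream deterministically from \code{seed}.
#'
#' @param seed Integer seed.
#' @param nGenes Number of genes.
#' @param proteins Library specification data.frame (see
#'   \code{\link{defaultProteinSpecs}}).
#' @param nxf1 Receptor spec: \code{partner} (SR library whose 3' UTR
#'   placements anchor receptor clusters), \code{cobindRate} (fraction of
#'   receptor 3' UTR clusters anchored at partner sites), \code{offsetSd}
#'   (nt, Normal cluster-center offset), \code{fivePrimeRate} (probability of
#'   an independent 5' UTR cluster per gene), cluster shape and background.
#' @param rnaseq Fractionated RNA-seq spec: NB mean/dispersion, number of
#'   planted export targets and their cytoplasm-only log2 fold change, the
#'   fraction of targets coupled to partner 3' UTR binding, exon-usage
#'   plantings, and APA \eqn{\Delta\Psi}.
#' @param nTandemUTR,nALE Number of genes carrying tandem-3'UTR / alternative
#'   last exon isoform pairs.
#' @param pcrDuplicationRate Probability that a cDNA gains further PCR
#'   copies (geometric).
#' @param barcodeLength Random-barcode length (nt).
#' @param readLengthRange iCLIP read length range (nt).
#' @param genesPerChrom,exonCountRange,firstExonLengthRange,
#'   internalExonLengthRange,lastExonLengthRange,intronLengthRange,
#'   utr5LengthRange,utr3LengthRange,intergenicRange,tandemExtensionRange,
#'   aleGapRange,aleExonLengthRange Structural ranges (nt).
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(
    seed = 1L,
    nGenes = 200L,
    genesPerChrom = 50L,
    exonCountRange = c(2L, 10L),
    firstExonLengthRange = c(250L, 450L),
    internalExonLengthRange = c(120L, 250L),
    lastExonLengthRange = c(600L, 900L),
    intronLengthRange = c(200L, 800L),
    utr5LengthRange = c(80L, 150L),
    utr3LengthRange = c(450L, 700L),
    intergenicRange = c(500L, 1500L),
    nTandemUTR = 20L,
    nALE = 10L,
    tandemExtensionRange = c(300L, 500L),
    aleGapRange = c(300L, 500L),
    aleExonLengthRange = c(400L, 700L),
    proteins = defaultProteinSpecs(),
    nxf1 = list(name = "NXF1", partner = "SRSF3", cobindRate = 0.5,
                offsetSd = 10, fivePrimeRate = 0.5, clustersPerUtr3 = 1L,
                clusterMeanCdna = 12, clusterSpread = 4L,
                backgroundRate = 0.05),
    pcrDuplicationRate = 0.5,
    barcodeLength = 9L,
    readLengthRange = c(20L, 40L),
    rnaseq = list(meanCounts = 300, logSdCounts = 0.6, minMeanCounts = 0,
                  dispersion = 0.05,
                  nExportTargets = 50L, exportLog2fc = -1, bindTargetRate = 0.6,
                  nUsageChanges = 20L, usageLastFractionLess = 0.75,
                  usageLastFractionMore = 0.25, usageFoldLess = 0.35,
                  controlPsiRange = c(0.5, 0.7),
                  deltaPsi = 0.3, apaDepth = 500)) {
  cfg <- as.list(environment())
  stopifnot(all(proteins$lambda >= 1),
            all(proteins$backgroundRate > 0),
            all(proteins$pSpliced >= 0 & proteins$pSpliced <= 1),
            nxf1$cobindRate >= 0, nxf1$cobindRate <= 1,
            nxf1$fivePrimeRate >= 0, nxf1$fivePrimeRate <= 1,
            pcrDuplicationRate >= 0, pcrDuplicationRate < 1,
            rnaseq$dispersion > 0,
            intronLengthRange[1] >= 50L)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a genome and annotation with planted motifs
#'
#' Builds \code{nGenes} multi-exon genes on both strands across one or more
#' chromosomes, a configured subset carrying TandemUTR or ALE isoform pairs,
#' then generates uniform-composition random sequence and plants each
#' library's preferred 8-mer into exonic regions (recorded as ground truth).
#' Deterministic given \code{config$seed}.
#'
#' @param config A \code{SimulationConfig}.
#' @return List with elements \code{annotation} (a
#'   \linkS4class{GenomeAnnotation} including the genome sequence),
#'   \code{truth} (motifs, placements, APA genes) and \code{config}.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$nGenes
  nchrom <- ceiling(ng / config$genesPerChrom)
  geneChrom <- sprintf("chr%d", rep(seq_len(nchrom), each = config$genesPerChrom)[seq_len(ng)])
  geneStrand <- sample(c("+", "-"), ng, TRUE)

  apaKind <- rep("none", ng)
  nApa <- config$nTandemUTR + config$nALE
  if (nApa > ng) .stopf("nTandemUTR + nALE exceeds nGenes")
  apaGenes <- .sampleInt(ng, nApa)
  apaKind[apaGenes[seq_len(config$nTandemUTR)]] <- "TandemUTR"
  if (config$nALE > 0L)
    apaKind[apaGenes[config$nTandemUTR + seq_len(config$nALE)]] <- "ALE"

  exlist <- list(); cdlist <- list(); txid <- character(0); gid <- character(0)
  cursor <- setNames(rep(1L, nchrom), sprintf("chr%d", seq_len(nchrom)))
  rng <- function(r, n = 1L) .runifInt(n, r[1], r[2])

  for (g in seq_len(ng)) {
    chrom <- geneChrom[g]; strand <- geneStrand[g]
    gene <- sprintf("g%04d", g)
    nex <- rng(config$exonCountRange)
    exlens <- c(rng(config$firstExonLengthRange),
                if (nex > 2L) rng(config$internalExonLengthRange, nex - 2L) else integer(0),
                rng(config$lastExonLengthRange))
    intlens <- rng(config$intronLengthRange, nex - 1L)
    utr5 <- min(rng(config$utr5LengthRange), exlens[1] - 50L)
    utr3 <- min(rng(config$utr3LengthRange), exlens[nex] - 50L)

    kind <- apaKind[g]
    ext <- if (kind == "TandemUTR") rng(config$tandemExtensionRange) else 0L
    aleGap <- if (kind == "ALE") rng(config$aleGapRange) else 0L
    aleLen <- if (kind == "ALE") rng(config$aleExonLengthRange) else 0L

    # genomic footprint left->right; transcript order depends on strand
    gl <- cursor[chrom] + rng(config$intergenicRange)
    # isoform A block layout in transcript order
    blocksA <- exlens
    gaps <- intlens
    span <- sum(blocksA) + sum(gaps) + ext + aleGap + aleLen
    # left->right genomic layout of transcript-ordered pieces
    if (strand == "+") {
      starts <- gl + cumsum(c(0L, head(blocksA, -1L) + gaps))
      exA <- IRanges::IRanges(starts, width = blocksA)
    } else {
      # transcript order runs right->left; reserve APA space at genomic left
      gl2 <- gl + ext + aleGap + aleLen
      rev_b <- rev(exlens); rev_g <- rev(intlens)
      starts <- gl2 + cumsum(c(0L, head(rev_b, -1L) + rev_g))
      exA <- rev(IRanges::IRanges(starts, width = rev_b))  # transcript order
    }
    grA <- GenomicRanges::GRanges(chrom, exA, strand = strand)

    txlen <- sum(exlens)
    # CDS in transcript coords; for ALE genes end the CDS in the penultimate
    # exon so both isoforms share it
    cdsStartT <- utr5 + 1L
    cdsEndT <- if (kind == "ALE") sum(exlens[seq_len(nex - 1L)]) - 30L
               else txlen - utr3
    cdsGr <- .t2g(grA, cdsStartT, cdsEndT)

    txA <- paste0(gene, ".A")
    exlist[[txA]] <- grA; cdlist[[txA]] <- cdsGr
    txid <- c(txid, txA); gid <- c(gid, gene)

    if (kind == "TandemUTR") {
      grB <- grA
      if (strand == "+") {
        GenomicRanges::end(grB)[nex] <- GenomicRanges::end(grB)[nex] + ext
      } else {
        GenomicRanges::start(grB)[nex] <- GenomicRanges::start(grB)[nex] - ext
      }
      txB <- paste0(gene, ".B")
      exlist[[txB]] <- grB; cdlist[[txB]] <- cdsGr
      txid <- c(txid, txB); gid <- c(gid, gene)
    } else if (kind == "ALE") {
      grB <- grA[seq_len(nex - 1L)]
      lastA <- grA[nex]
      if (strand == "+") {
        as <- GenomicRanges::end(lastA) + aleGap + 1L
        alt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as, width = aleLen),
                                      strand = strand)
      } else {
        ae <- GenomicRanges::start(lastA) - aleGap - 1L
        alt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ae - aleLen + 1L, ae),
                                      strand = strand)
      }
      grB <- c(grB, alt)
      txB <- paste0(gene, ".B")
      exlist[[txB]] <- grB; cdlist[[txB]] <- cdsGr
      txid <- c(txid, txB); gid <- c(gid, gene)
    }
    cursor[chrom] <- gl + span
  }

  exl <- GenomicRanges::GRangesList(exlist)
  cdl <- GenomicRanges::GRangesList(cdlist)
  td <- S4Vectors::DataFrame(transcript_id = txid, gene_id = gid,
                             biotype = "protein_coding")

  # chromosome sequences (uniform base composition)
  chromLens <- cursor + 1000L
  genome <- Biostrings::DNAStringSet(vapply(chromLens, function(L)
    paste(c("A", "C", "G", "T")[.sampleInt(4L, L, TRUE)], collapse = ""), ""))
  names(genome) <- names(chromLens)

  ann <- .GenomeAnnotation(exl, cdl, td, genome)

  # plant motifs into exonic sequence; record truth
  truth <- .plantMotifs(ann, config)
  ann@genome <- truth$genome
  truth$genome <- NULL

  apa <- data.frame(gene_id = sprintf("g%04d", seq_len(ng)), kind = apaKind,
                    stringsAsFactors = FALSE)
  list(annotation = ann,
       truth = c(truth, list(apaGenes = apa[apa$kind != "none", ])),
       config = config)
}

# Plant each library's 8-mer into exons of the representative transcript.
# Placements avoid exon junctions and each other (greedy, per gene).
.plantMotifs <- function(ann, config) {
  genome <- genomeSeq(ann)
  rep <- representativeTranscripts(ann)
  exl <- txExons(ann)[rep]
  regions <- deriveRegions(ann)
  utr3 <- regions[regions$label == "three_prime_utr"]
  specs <- config$proteins

  # plain-vector views of per-gene exon and 3'UTR intervals
  exAll <- unlist(exl, use.names = FALSE)
  gidx <- rep(seq_along(exl), S4Vectors::elementNROWS(exl))
  exStart <- split(GenomicRanges::start(exAll), gidx)
  exEnd <- split(GenomicRanges::end(exAll), gidx)
  geneChrom <- vapply(split(as.character(GenomicRanges::seqnames(exAll)), gidx),
                      `[`, "", 1L)
  geneStrand <- vapply(split(as.character(GenomicRanges::strand(exAll)), gidx),
                       `[`, "", 1L)
  u3g <- match(utr3$gene_id, names(rep))
  u3Start <- split(GenomicRanges::start(utr3), factor(u3g, seq_along(rep)))
  u3End <- split(GenomicRanges::end(utr3), factor(u3g, seq_along(rep)))
  cdsReg <- regions[regions$label == "cds"]
  cdg <- match(cdsReg$gene_id, names(rep))
  cdStart <- split(GenomicRanges::start(cdsReg), factor(cdg, seq_along(rep)))
  cdEnd <- split(GenomicRanges::end(cdsReg), factor(cdg, seq_along(rep)))
  if (!"plantRegion" %in% names(specs)) specs$plantRegion <- "exon"

  occupied <- lapply(setNames(nm = names(genome)), function(x) integer(0))

  plant1 <- function(st, en, chrom) {
    w <- en - st + 1L - 7L
    ok <- w > 0L
    if (!any(ok)) return(NA_integer_)
    st <- st[ok]; w <- w[ok]
    occ <- occupied[[chrom]]
    for (try in 1:10) {
      k <- if (length(st) == 1L) 1L else sample.int(length(st), 1L, prob = w)
      s <- st[k] + .sampleInt(w[k], 1L) - 1L
      if (length(occ) == 0L || min(abs(s - occ)) > 7L) return(s)
    }
    NA_integer_
  }

  cap <- as.integer(sum(specs$plantPerTx + specs$utr3PlantCount, na.rm = TRUE)) *
    length(rep)
  P <- list(protein = character(cap), gene = character(cap),
            chrom = character(cap), start = integer(cap),
            strand = character(cap), in_utr3 = logical(cap))
  np <- 0L
  for (p in seq_len(nrow(specs))) {
    if (is.na(specs$motif[p])) next
    for (gi in seq_along(rep)) {
      chrom <- geneChrom[gi]
      n1 <- specs$plantPerTx[p]
      nU <- if (specs$utr3PlantProb[p] > 0 &&
                runif(1) < specs$utr3PlantProb[p]) specs$utr3PlantCount[p] else 0L
      inCds <- specs$plantRegion[p] == "cds"
      for (j in seq_len(n1 + nU)) {
        inU <- j > n1
        s <- if (inU) plant1(u3Start[[gi]], u3End[[gi]], chrom)
             else if (inCds) plant1(cdStart[[gi]], cdEnd[[gi]], chrom)
             else plant1(exStart[[gi]], exEnd[[gi]], chrom)
        if (is.na(s)) next
        occupied[[chrom]] <- c(occupied[[chrom]], s)
        np <- np + 1L
        P$protein[np] <- specs$name[p]; P$gene[np] <- names(rep)[gi]
        P$chrom[np] <- chrom; P$start[np] <- s
        P$strand[np] <- geneStrand[gi]; P$in_utr3[np] <- inU
      }
    }
  }
  P <- lapply(P, `[`, seq_len(np))

  # write motifs into the sequence (strand-aware), one replaceAt per chrom
  motifByName <- setNames(specs$motif, specs$name)
  for (chrom in unique(P$chrom)) {
    ix <- which(P$chrom == chrom)
    ins <- motifByName[P$protein[ix]]
    rc <- P$strand[ix] == "-"
    if (any(rc))
      ins[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(ins[rc])))
    genome[[chrom]] <- Biostrings::replaceAt(
      genome[[chrom]], IRanges::IRanges(P$start[ix], P$start[ix] + 7L),
      unname(ins))
  }

  plGr <- if (np == 0L) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(P$chrom, IRanges::IRanges(P$start, P$start + 7L),
                           strand = P$strand, protein = P$protein,
                           gene_id = P$gene, in_utr3 = P$in_utr3)
  # label placements with their transcript region
  if (length(plGr)) {
    hit <- GenomicRanges::findOverlaps(plGr, regions, select = "first")
    plGr$label <- ifelse(is.na(hit), NA_character_, regions$label[hit])
  }
  motifs <- setNames(specs$motif, specs$name)
  list(genome = genome, motifs = motifs[!is.na(motifs)], placements = plGr)
}

#' Write simulated genome and annotation to disk
#'
#' @param sim Result of \code{\link{simulateGenome}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
writeSimulatedGenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  Biostrings::writeXStringSet(genomeSeq(sim$annotation), fa)
  writeAnnotationGtf(sim$annotation, gtf)
  c(fasta = fa, gtf = gtf)
}
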