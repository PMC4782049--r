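# In-code fixtures shared across tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
  library(SummarizedExperiment)
})

# Small annotation: a plus-strand 3-exon coding gene, a minus-strand 2-exon
# coding gene, a TandemUTR isoform pair and an ALE isoform pair.
makeToyAnnotation <- function(withGenome = FALSE) {
  gr <- function(s, e, strand) GRanges("chr1", IRanges(s, e), strand = strand)
  exA <- gr(c(101, 301, 501), c(200, 400, 700), "+")
  cdA <- gr(c(151, 301, 501), c(200, 400, 560), "+")
  exB <- gr(c(1201, 1001), c(1300, 1100), "-")      # 5'->3' on minus
  cdB <- gr(c(1201, 1051), c(1270, 1100), "-")      # 5'UTR [1271,1300]
  # TandemUTR pair: same exons, last exon extended in isoform T2
  exT1 <- gr(c(2001, 2301), c(2100, 2800), "+")
  exT2 <- gr(c(2001, 2301), c(2100, 3100), "+")
  cdT <- gr(c(2051, 2301), c(2100, 2400), "+")
  # ALE pair: shared first exon, alternative non-overlapping last exons
  exL1 <- gr(c(4001, 4301), c(4100, 4700), "+")
  exL2 <- gr(c(4001, 5001), c(4100, 5400), "+")
  cdL <- gr(4041, 4090, "+")
  exl <- GRangesList(A1 = exA, B1 = exB, T1 = exT1, T2 = exT2,
                     L1 = exL1, L2 = exL2)
  cdl <- GRangesList(A1 = cdA, B1 = cdB, T1 = cdT, T2 = cdT,
                     L1 = cdL, L2 = cdL)
  td <- DataFrame(transcript_id = names(exl),
                  gene_id = c("gA", "gB", "gT", "gT", "gL", "gL"),
                  biotype = "protein_coding")
  genome <- if (withGenome) {
    set.seed(99)
    DNAStringSet(setNames(paste(sample(c("A", "C", "G", "T"), 6000, TRUE),
                                collapse = ""), "chr1"))
  } else DNAStringSet()
  srexport:::.GenomeAnnotation(exl, cdl, td, genome)
}

# Minimal read table builder
readRow <- function(chrom = "chr1", start, end, strand = "+",
                    cigar = paste0(end - start + 1, "M"),
                    barcode = "AAAA", library = "LIB") {
  data.frame(library = library, chrom = chrom, start = start, end = end,
             strand = strand, cigar = cigar, barcode = barcode,
             stringsAsFactors = FALSE)
}

# significant-position GRanges builder
sigPos <- function(pos, count = 5L, strand = "+", library = "LIB",
                   chrom = "chr1", fdr = 0.01) {
  GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
          count = as.integer(count), library = library, fdr = fdr)
}

# robust numeric-integration oracle for the Beta-Binomial Bayes factor
# (log-space Simpson; independent of the closed form under test)
bfNumericOracle <- function(k1, n1, k2, n2, n = 20001L) {
  logSimpson <- function(lf) {
    x <- seq(0, 1, length.out = n)
    v <- lf(x)
    w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) * (x[2] - x[1]) / 3
    m <- max(v)
    log(sum(w * exp(v - m))) + m
  }
  l1 <- logSimpson(function(t) dbinom(k1, n1, t, log = TRUE))
  l2 <- logSimpson(function(t) dbinom(k2, n2, t, log = TRUE))
  ls <- logSimpson(function(t) dbinom(k1, n1, t, log = TRUE) +
                     dbinom(k2, n2, t, log = TRUE))
  exp(l1 + l2 - ls)
}

# small fast simulation config used by several tests
tinyConfig <- function(seed = 1L, nGenes = 20L, ...) {
  simulationConfig(seed = seed, nGenes = nGenes, nTandemUTR = 3L, nALE = 2L,
                   ...)
}
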