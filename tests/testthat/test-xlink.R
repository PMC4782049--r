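# Cross-link module: dedup, truncation convention, permutation FDR, sites.

test_that("deduplication keys on (library, chrom, strand, 5' start, barcode)", {
  reads <- rbind(
    readRow(start = 100, end = 130, barcode = "AAAA"),
    readRow(start = 100, end = 135, barcode = "AAAA"),  # same 5' start + barcode
    readRow(start = 100, end = 130, barcode = "CCCC"),
    readRow(start = 100, end = 130, barcode = NA),
    readRow(start = 200, end = 230, strand = "-", barcode = "AAAA"),
    readRow(start = 190, end = 230, strand = "-", barcode = "AAAA"))  # minus: same end
  dd <- deduplicateReads(reads)
  expect_equal(nrow(dd$reads), 3L)
  expect_equal(dd$nDuplicates, 2L)
  expect_equal(dd$nMissingBarcode, 1L)
})

test_that("cross-link position is one nucleotide 5' of the read start", {
  reads <- rbind(readRow(start = 1001, end = 1030),
                 readRow(start = 901, end = 940, strand = "-"),
                 readRow(start = 1001, end = 1025, barcode = "GGGG"),
                 readRow(start = 1001, end = 1033, barcode = "TTTT"))
  ev <- extractCrosslinks(deduplicateReads(reads)$reads)
  plus <- ev[strand(ev) == "+"]
  expect_equal(start(plus), 1000L)     # plus: start - 1
  expect_equal(plus$count, 3L)         # 3 unique cDNAs at one position
  expect_equal(start(ev[strand(ev) == "-"]), 941L)  # minus: end + 1
  # off-chromosome events are dropped and counted
  ev2 <- extractCrosslinks(readRow(start = 1, end = 30))
  expect_length(ev2, 0L)
  expect_equal(attr(ev2, "nDropped"), 1L)
})

test_that("permutation FDR: uniform counts give nothing, a spike is called", {
  ann <- local({
    exl <- GRangesList(G1 = GRanges("chr1", IRanges(1, 10000), strand = "+"))
    srexport:::.GenomeAnnotation(exl, GRangesList(G1 = GRanges()),
      DataFrame(transcript_id = "G1", gene_id = "gG", biotype = "pc"))
  })
  # all singletons across a 1 kb stretch: no significant positions
  flat <- GRanges("chr1", IRanges(seq(1, 1000), width = 1), strand = "+",
                  count = 1L, library = "L")
  sig <- callSignificantPositions(flat, ann, nPerm = 1000L, seed = 4L)
  expect_length(sig, 0L)
  # one 50-count spike over 200 singletons in a 10 kb gene: called
  spiked <- c(GRanges("chr1", IRanges(5000, width = 1), strand = "+",
                      count = 50L, library = "L"),
              GRanges("chr1", IRanges(sample(seq(1, 10000, 7), 200), width = 1),
                      strand = "+", count = 1L, library = "L"))
  sig2 <- callSignificantPositions(spiked, ann, nPerm = 1000L, seed = 4L)
  expect_true(5000 %in% start(sig2))
  expect_true(all(sig2$count == 50L))
  # threshold 1 calls every tested position
  sig3 <- callSignificantPositions(flat, ann, fdrThreshold = 1.0, seed = 1L)
  expect_length(sig3, 1000L)
})

test_that("FDR monotonicity: higher counts are significant whenever lower are", {
  ann <- local({
    exl <- GRangesList(G1 = GRanges("chr1", IRanges(1, 5000), strand = "+"))
    srexport:::.GenomeAnnotation(exl, GRangesList(G1 = GRanges()),
      DataFrame(transcript_id = "G1", gene_id = "gG", biotype = "pc"))
  })
  set.seed(11)
  for (rep in 1:5) {
    pos <- sample(5000, 300)
    cnt <- rpois(300, 1.5) + 1L
    ev <- GRanges("chr1", IRanges(pos, width = 1), strand = "+",
                  count = cnt, library = "L")
    sig <- callSignificantPositions(ev, ann, nPerm = 200L, seed = rep)
    if (length(sig)) {
      minSig <- min(sig$count)
      expect_true(all(start(ev[ev$count > minSig]) %in% start(sig)))
    }
  }
})

test_that("genes with too few events are skipped; intergenic counted", {
  ann <- local({
    exl <- GRangesList(G1 = GRanges("chr1", IRanges(1, 1000), strand = "+"))
    srexport:::.GenomeAnnotation(exl, GRangesList(G1 = GRanges()),
      DataFrame(transcript_id = "G1", gene_id = "gG", biotype = "pc"))
  })
  ev <- c(GRanges("chr1", IRanges(c(10, 20, 30), width = 1), strand = "+",
                  count = 2L, library = "L"),
          GRanges("chr1", IRanges(5000, width = 1), strand = "+",
                  count = 100L, library = "L"))
  sig <- callSignificantPositions(ev, ann, seed = 1L)
  expect_length(sig, 0L)
  expect_equal(attr(sig, "nIntergenic"), 1L)
  expect_length(attr(sig, "skippedGenes"), 1L)
})

test_that("site merging: gap rule, max-count center, 5'-most ties, conservation", {
  s <- sigPos(c(100, 105, 130), count = c(3, 7, 2))
  sites <- mergeBindingSites(s, maxGap = 15L)
  expect_length(sites, 2L)
  expect_equal(sites$center[1], 105L)          # count 7 wins
  expect_equal(sites$nSigPositions, c(2L, 1L))
  expect_equal(sum(sites$totalCount), sum(s$count))   # conservation
  # equal counts: 5'-most wins on plus strand...
  tie <- sigPos(c(100, 105), count = c(5, 5))
  expect_equal(mergeBindingSites(tie)$center, 100L)
  # ...and 3'-most genomic (5'-most transcript) on minus strand
  tieM <- sigPos(c(100, 105), count = c(5, 5), strand = "-")
  expect_equal(mergeBindingSites(tieM)$center, 105L)
  # distance 15 merges, 16 does not
  expect_length(mergeBindingSites(sigPos(c(100, 115), count = 5)), 1L)
  expect_length(mergeBindingSites(sigPos(c(100, 116), count = 5)), 2L)
})

test_that("simulator round trip: dedup recovers the simulated unique count", {
  cfg <- tinyConfig(seed = 3L, nGenes = 10L,
                    proteins = defaultProteinSpecs()[3, ])
  sim <- simulateGenome(cfg)
  ic <- simulateIclip(cfg, sim)
  dd <- deduplicateReads(ic$reads[ic$reads$library == "SRSF3", ])
  # barcode collisions are the only loss channel (4^9 space): within 5%
  expect_gt(nrow(dd$reads) / ic$truth$uniqueCounts[["SRSF3"]], 0.95)
  expect_lte(nrow(dd$reads), ic$truth$uniqueCounts[["SRSF3"]])
})
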