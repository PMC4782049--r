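# Annotation: GTF round trip, regions, exon ordinals, splice sites, APA.

test_that("GTF round trip preserves models and coordinate conventions", {
  ann <- makeToyAnnotation()
  gtf <- tempfile(fileext = ".gtf")
  writeAnnotationGtf(ann, gtf)
  back <- loadAnnotation(gtf)
  expect_setequal(txInfo(back)$transcript_id, txInfo(ann)$transcript_id)
  for (tx in names(txExons(ann))) {
    a <- txExons(ann)[[tx]]; b <- txExons(back)[[tx]]
    expect_equal(start(a), start(b))
    expect_equal(end(a), end(b))
    expect_equal(as.character(strand(a)), as.character(strand(b)))
    expect_equal(width(txCds(ann)[[tx]]), width(txCds(back)[[tx]]))
  }
  # a GTF exon line written as 1-based [101, 200] reads back as width 100
  lines <- readLines(gtf)
  exon1 <- grep("\texon\t101\t200\t", lines, value = TRUE)
  expect_length(exon1, 1L)
  expect_equal(width(txExons(back)[["A1"]])[1], 100L)
  # minus-strand transcript: exons stored 5'->3' (decreasing coordinates)
  expect_equal(start(txExons(back)[["B1"]]), c(1201L, 1001L))
})

test_that("exonless declared transcripts and missing files are rejected", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste(c("chr1", "test", "transcript", "1", "500", ".", "+", ".",
                     'gene_id "gX"; transcript_id "tX";'), collapse = "\t"),
             gtf)
  expect_error(loadAnnotation(gtf), "no exon records")
  ann <- makeToyAnnotation()
  gtf2 <- tempfile(fileext = ".gtf")
  writeAnnotationGtf(ann, gtf2)
  extra <- paste(c("chr1", "test", "transcript", "9000", "9500", ".", "+", ".",
                   'gene_id "gX"; transcript_id "tX";'), collapse = "\t")
  writeLines(c(readLines(gtf2), extra), gtf2)
  expect_error(loadAnnotation(gtf2), "tX")
})

test_that("deriveRegions partitions the representative span with correct labels", {
  # two exons [1,100],[201,300] with CDS [51,250]:
  # 5'UTR [1,50]; CDS [51,100]+[201,250]; 3'UTR [251,300]; intron [101,200]
  exl <- GRangesList(X1 = GRanges("chr1", IRanges(c(1, 201), c(100, 300)), strand = "+"))
  cdl <- GRangesList(X1 = GRanges("chr1", IRanges(c(51, 201), c(100, 250)), strand = "+"))
  td <- DataFrame(transcript_id = "X1", gene_id = "gX", biotype = "protein_coding")
  ann <- srexport:::.GenomeAnnotation(exl, cdl, td)
  r <- deriveRegions(ann)
  get <- function(lab) {
    rr <- r[r$label == lab]
    unname(cbind(start(rr), end(rr)))
  }
  expect_equal(get("five_prime_utr"), cbind(1L, 50L))
  expect_equal(get("cds"), cbind(c(51L, 201L), c(100L, 250L)))
  expect_equal(get("three_prime_utr"), cbind(251L, 300L))
  expect_equal(get("intron"), cbind(101L, 200L))
  expect_equal(sum(width(r)), 300L)   # gap/overlap-free partition

  ann2 <- makeToyAnnotation()
  r2 <- deriveRegions(ann2)
  rep <- representativeTranscripts(ann2)
  spans <- unlist(range(txExons(ann2)[rep]))
  byGene <- tapply(width(r2), r2$gene_id, sum)
  expect_equal(as.vector(byGene[names(rep)]), unname(width(spans)))
  # minus-strand gene: UTR labels follow transcript direction
  rB <- r2[r2$gene_id == "gB"]
  expect_equal(start(rB[rB$label == "five_prime_utr"]), 1271L)
  expect_equal(end(rB[rB$label == "five_prime_utr"]), 1300L)
  expect_true(all(start(rB[rB$label == "three_prime_utr"]) == 1001L))
})

test_that("noncoding transcripts get noncoding_exon labels, no UTRs", {
  exl <- GRangesList(N1 = GRanges("chr1", IRanges(c(1, 201), c(100, 300)), strand = "+"))
  cdl <- GRangesList(N1 = GRanges())
  td <- DataFrame(transcript_id = "N1", gene_id = "gN", biotype = "lincRNA")
  ann <- srexport:::.GenomeAnnotation(exl, cdl, td)
  r <- deriveRegions(ann)
  expect_setequal(unique(r$label), c("noncoding_exon", "intron"))
})

test_that("representative transcript policy: longest CDS, then longest tx, then id", {
  ann <- makeToyAnnotation()
  rep <- representativeTranscripts(ann)
  # gT: equal CDS, T2 longer transcript
  expect_equal(unname(rep["gT"]), "T2")
  # gL: equal CDS, L2 longer (100 + 400 vs 100 + 400: compute)
  wL1 <- sum(width(txExons(ann)[["L1"]]))
  wL2 <- sum(width(txExons(ann)[["L2"]]))
  expect_equal(unname(rep["gL"]), if (wL2 > wL1) "L2" else "L1")
})

test_that("classifyExons is strand-aware and an exact partition", {
  ann <- makeToyAnnotation()
  exf <- classifyExons(ann)
  a <- exf[exf$transcript_id == "A1"]
  expect_equal(a$ordinal_class, c("first", "internal", "last"))
  # minus strand: the genomically rightmost exon is "first"
  b <- exf[exf$transcript_id == "B1"]
  expect_equal(b$ordinal_class[start(b) == 1201], "first")
  expect_equal(b$ordinal_class[start(b) == 1001], "last")
  # exact partition over ordinal classes
  expect_equal(length(exf), sum(table(exf$ordinal_class)))
  # single-exon transcript
  exl <- GRangesList(S1 = GRanges("chr1", IRanges(1, 500), strand = "+"))
  annS <- srexport:::.GenomeAnnotation(exl, GRangesList(S1 = GRanges()),
    DataFrame(transcript_id = "S1", gene_id = "gS", biotype = "pc"))
  expect_equal(classifyExons(annS)$ordinal_class, "single")
})

test_that("splice sites follow the first-intronic / first-exonic convention", {
  ann <- makeToyAnnotation()
  ss <- spliceSites(ann)
  # plus-strand exon ending at 200 -> 5ss at 201 (first intron base)
  s5 <- ss[ss$kind == "5ss" & strand(ss) == "+"]
  expect_true(201 %in% start(s5))
  # matching 3ss = first base of the downstream exon (301)
  s3 <- ss[ss$kind == "3ss" & strand(ss) == "+"]
  expect_true(301 %in% start(s3))
  # minus strand: exon with genomic start 1201 -> 5ss at 1200
  expect_true(1200 %in% start(ss[ss$kind == "5ss" & strand(ss) == "-"]))
  expect_true(1100 %in% start(ss[ss$kind == "3ss" & strand(ss) == "-"]))
  # deduplicated across isoforms (gT shares its intron between T1/T2)
  expect_equal(anyDuplicated(paste(start(ss), strand(ss), ss$kind)), 0L)
  # intronless transcript contributes nothing
  exl <- GRangesList(S1 = GRanges("chr1", IRanges(1, 500), strand = "+"))
  annS <- srexport:::.GenomeAnnotation(exl, GRangesList(S1 = GRanges()),
    DataFrame(transcript_id = "S1", gene_id = "gS", biotype = "pc"))
  expect_length(spliceSites(annS), 0L)
})

test_that("APA events: TandemUTR extension and non-overlapping ALE", {
  ann <- makeToyAnnotation()
  ev <- enumerateApaEvents(ann)
  tu <- ev[ev$kind == "TandemUTR", ]
  expect_equal(nrow(tu), 1L)
  expect_equal(start(tu$distal_region), 2801L)   # extension beyond shared end
  expect_equal(end(tu$distal_region), 3100L)
  expect_equal(width(tu$proximal_region), 500L)
  ale <- ev[ev$kind == "ALE", ]
  expect_equal(nrow(ale), 1L)
  expect_equal(start(ale$proximal_region), 4301L)
  expect_equal(start(ale$distal_region), 5001L)
  # identical 3' ends -> no event
  exl <- GRangesList(
    P1 = GRanges("chr1", IRanges(c(1, 201), c(100, 400)), strand = "+"),
    P2 = GRanges("chr1", IRanges(c(1, 151, 201), c(100, 160, 400)), strand = "+"))
  annP <- srexport:::.GenomeAnnotation(exl,
    GRangesList(P1 = GRanges(), P2 = GRanges()),
    DataFrame(transcript_id = c("P1", "P2"), gene_id = "gP", biotype = "pc"))
  expect_equal(nrow(enumerateApaEvents(annP)), 0L)
})
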