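# Synthetic-data generator: determinism, construction guarantees,
# distributional oracles.

test_that("simulateGenome is byte-identical under a fixed seed", {
  cfg <- tinyConfig(seed = 7L)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulatedGenome(simulateGenome(cfg), d1)
  writeSimulatedGenome(simulateGenome(cfg), d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
})

test_that("configured APA genes are recoverable from the annotation", {
  cfg <- simulationConfig(seed = 2L, nGenes = 50L, nTandemUTR = 10L, nALE = 4L)
  sim <- simulateGenome(cfg)
  ev <- enumerateApaEvents(sim$annotation)
  expect_gte(sum(ev$kind == "TandemUTR"), 10L)
  expect_gte(sum(ev$kind == "ALE"), 4L)
  # truth refers only to existing genes (referential integrity)
  expect_true(all(sim$truth$apaGenes$gene_id %in% txInfo(sim$annotation)$gene_id))
  expect_true(all(sim$truth$placements$gene_id %in% txInfo(sim$annotation)$gene_id))
})

test_that("genome composition is uniform (binomial GC oracle)", {
  cfg <- simulationConfig(seed = 4L, nGenes = 120L, nTandemUTR = 0L, nALE = 0L)
  sim <- simulateGenome(cfg)
  seq <- unlist(genomeSeq(sim$annotation))
  n <- length(seq)
  expect_gte(n, 5e5)
  gc <- sum(Biostrings::alphabetFrequency(seq)[c("C", "G")]) / n
  # binomial sd at this length is ~7e-4; planted motifs shift composition
  # by < 0.004; the spec's 0.5 +/- 0.02 band holds with wide margin
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("lambda = 1 cross-links are uniform over gene positions", {
  prot <- defaultProteinSpecs()[3, ]
  prot$lambda <- 1          # motif confers no enrichment
  cfg <- simulationConfig(seed = 6L, nGenes = 40L, nTandemUTR = 0L, nALE = 0L,
                          proteins = prot)
  sim <- simulateGenome(cfg)
  ic <- simulateIclip(cfg, sim)
  dd <- deduplicateReads(ic$reads[ic$reads$library == "SRSF3", ])
  ev <- extractCrosslinks(dd$reads)
  # chi-square on 1 kb bins across the covered genome
  spans <- geneSpans(sim$annotation)
  hits <- findOverlaps(ev, spans)
  e <- ev[queryHits(hits)]
  off <- start(e) - start(spans)[subjectHits(hits)]
  bin <- floor(off / 1000)
  key <- paste(subjectHits(hits), bin)
  binSpan <- floor((width(spans) - 1) / 1000)
  full <- unlist(lapply(seq_along(spans), function(i)
    paste(i, 0:(binSpan[i] - 1L))))   # complete 1 kb bins only
  cnt <- as.vector(table(factor(key[key %in% full], levels = full)))
  p <- chisq.test(cnt)$p.value
  expect_gt(p, 0.001)
})

test_that("PCR duplication preserves the unique-cDNA count through dedup", {
  # duplication rate 0.5 doubles reads on average; dedup recovers uniques
  cfg <- tinyConfig(seed = 9L, nGenes = 10L,
                    proteins = defaultProteinSpecs()[3, ],
                    pcrDuplicationRate = 0.5)
  sim <- simulateGenome(cfg)
  ic <- simulateIclip(cfg, sim)
  rr <- ic$reads[ic$reads$library == "SRSF3", ]
  uniq <- ic$truth$uniqueCounts[["SRSF3"]]
  expect_gt(nrow(rr) / uniq, 1.8)    # ~2x with geometric copies
  dd <- deduplicateReads(rr)
  expect_lt(abs(nrow(dd$reads) - uniq) / uniq, 0.05)
})

test_that("export effect is cytoplasm-only; dispersion->0 approaches Poisson", {
  cfg <- simulationConfig(seed = 12L, nGenes = 60L, nTandemUTR = 5L, nALE = 3L,
    rnaseq = modifyList(simulationConfig()$rnaseq,
                        list(nExportTargets = 20L, dispersion = 1e-4,
                             logSdCounts = 0)))
  sim <- simulateGenome(cfg)
  cnt <- simulateFractionCounts(cfg, sim)
  counts <- assay(cnt$txSE, "counts")
  cd <- as.data.frame(colData(cnt$txSE))
  tgt <- cnt$truth$exportTargets
  cytoKd <- counts[, cd$fraction == "cytoplasmic" & cd$condition == "KD"]
  cytoCt <- counts[, cd$fraction == "cytoplasmic" & cd$condition == "control"]
  wcKd <- counts[, cd$fraction == "whole_cell" & cd$condition == "KD"]
  wcCt <- counts[, cd$fraction == "whole_cell" & cd$condition == "control"]
  # true cytoplasmic mean halves for targets, whole-cell unchanged
  expect_lt(mean(rowMeans(cytoKd[tgt, ])) / mean(rowMeans(cytoCt[tgt, ])), 0.6)
  expect_gt(mean(rowMeans(wcKd[tgt, ])) / mean(rowMeans(wcCt[tgt, ])), 0.9)
  # near-zero dispersion: variance/mean ratio near 1 across control samples
  ctl <- counts[, cd$condition == "control"]
  vm <- apply(ctl, 1, var) / rowMeans(ctl)
  expect_lt(abs(mean(vm) - 1), 0.25)
})

test_that("planted delta-Psi shifts the distal/proximal ratio as configured", {
  cfg <- simulationConfig(seed = 14L, nGenes = 80L, nTandemUTR = 20L, nALE = 10L,
    rnaseq = modifyList(simulationConfig()$rnaseq, list(deltaPsi = 0.3)))
  sim <- simulateGenome(cfg)
  cnt <- simulateFractionCounts(cfg, sim)
  ac <- apaCountsByCondition(cnt$apaSE)
  psiC <- psiEstimate(ac$control[, 1], ac$control[, 2],
                      ac$events$proximal_length, ac$events$distal_length,
                      ac$events$kind)
  psiK <- psiEstimate(ac$kd[, 1], ac$kd[, 2],
                      ac$events$proximal_length, ac$events$distal_length,
                      ac$events$kind)
  expect_lt(abs(mean(psiC - psiK, na.rm = TRUE) - 0.3), 0.05)
})

test_that("iCLIP truth is referentially intact and seeded streams reproduce", {
  cfg <- tinyConfig(seed = 31L, nGenes = 12L,
                    proteins = defaultProteinSpecs()[c(3, 8), ])
  sim <- simulateGenome(cfg)
  ic1 <- simulateIclip(cfg, sim)
  ic2 <- simulateIclip(cfg, sim)
  expect_identical(ic1$reads, ic2$reads)
  cl <- ic1$truth$nxf1Clusters
  expect_true(all(cl$gene_id %in% txInfo(sim$annotation)$gene_id))
})
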