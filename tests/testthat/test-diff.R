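# Differential module: size factors, NB test, export calls, exon usage,
# Psi, Bayes factors, integration.

makeSe <- function(counts, fraction = "cytoplasmic",
                   condition = c("control", "control", "KD", "KD")) {
  dimnames(counts) <- list(if (is.null(rownames(counts)))
    paste0("t", seq_len(nrow(counts))) else rownames(counts),
    paste0("s", seq_len(ncol(counts))))
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(fraction = fraction, condition = condition,
                        replicate = rep(c("r1", "r2"), 2),
                        row.names = paste0("s", seq_len(ncol(counts)))))
}

test_that("median-of-ratios size factors: doubling and identity", {
  set.seed(1)
  base <- rpois(200, 100)
  counts <- cbind(base, base * 2L, base, base)
  rownames(counts) <- paste0("t", 1:200)
  se <- normalizeCounts(makeSe(counts))
  sf <- colData(se)$sizeFactor
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-9)
  expect_equal(sf[3], sf[1])
  # normalized counts equalized across the doubled sample
  nm <- assays(se)$normcounts
  expect_equal(nm[, 1], nm[, 2], tolerance = 1e-9)
  # identical samples -> all factors 1
  se2 <- normalizeCounts(makeSe(cbind(base, base, base, base)))
  expect_equal(unname(colData(se2)$sizeFactor), rep(1, 4))
})

test_that("size factors agree with DESeq2's median-of-ratios on shared data", {
  set.seed(2)
  mu <- rnbinom(200, mu = 200, size = 10) + 1
  counts <- sapply(c(1, 1.5, 0.7, 1.2), function(s) rpois(200, mu * s))
  rownames(counts) <- paste0("t", 1:200)
  se <- normalizeCounts(makeSe(counts))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(colData(se)$sizeFactor), unname(ref), tolerance = 1e-6)
})

test_that("simulated library-size gradient is recovered within 2%", {
  set.seed(3)
  mu <- exp(rnorm(400, log(300), 0.5))
  sf <- c(0.6, 1.0, 1.4, 2.0)
  counts <- sapply(sf, function(s) rpois(400, mu * s))
  rownames(counts) <- paste0("t", 1:400)
  se <- normalizeCounts(makeSe(counts))
  est <- colData(se)$sizeFactor
  est <- est / exp(mean(log(est)))
  ref <- sf / exp(mean(log(sf)))
  expect_lt(max(abs(est - ref) / ref), 0.02)
})

test_that("differential test: identical groups give log2fc 0 and honest nulls", {
  set.seed(4)
  counts <- matrix(rpois(400 * 4, 300), 400, 4,
                   dimnames = list(paste0("t", 1:400), NULL))
  se <- normalizeCounts(makeSe(counts))
  r <- differentialAbundance(se, "cytoplasmic")
  expect_lt(max(abs(r$log2fc)), 0.5)
  expect_true(all(r$q >= 0 & r$q <= 1, na.rm = TRUE))
  # q monotone in p
  o <- order(r$p)
  expect_true(all(diff(r$q[o]) >= -1e-12, na.rm = TRUE))
  # all-zero features untested
  counts2 <- counts; counts2[1, ] <- 0L
  r2 <- differentialAbundance(normalizeCounts(makeSe(counts2)), "cytoplasmic")
  expect_true(is.na(r2$p[1]))
})

test_that("export-target rule: net cytoplasmic decrease beyond whole-cell", {
  resC <- data.frame(feature = c("a", "b", "c", "d"),
                     log2fc = c(-1, -1, -1, 0.5),
                     p = 0.001, q = c(0.01, 0.01, 0.5, 0.01),
                     stringsAsFactors = FALSE)
  resW <- data.frame(feature = c("a", "b", "c", "d"),
                     log2fc = c(0, -1, 0, 0),
                     p = 0.5, q = 0.5, stringsAsFactors = FALSE)
  calls <- callExportTargets(resC, resW)
  expect_true(calls$is_target[calls$feature == "a"])    # net decrease
  expect_false(calls$is_target[calls$feature == "b"])   # delta = 0
  expect_false(calls$is_target[calls$feature == "c"])   # not significant
  expect_false(calls$is_target[calls$feature == "d"])   # increases
})

test_that("exon usage: planted drop detected with direction, nulls quiet", {
  set.seed(6)
  nGene <- 60; nEx <- 4
  gene <- rep(paste0("g", seq_len(nGene)), each = nEx)
  w <- matrix(1, nGene * nEx, 8)
  # gene 1 exon 1: usage drop 0.6 -> 0.3 under KD (cols 5:8 KD of one fraction)
  usage0 <- c(0.6, 0.4 / 3, 0.4 / 3, 0.4 / 3)
  usageK <- c(0.3, 0.7 / 3, 0.7 / 3, 0.7 / 3)
  counts <- matrix(0L, nGene * nEx, 8)
  for (j in 1:8) for (g in seq_len(nGene)) {
    tot <- rpois(1, 500)
    pr <- if (g == 1 && j >= 5) usageK else usage0
    counts[(g - 1) * nEx + 1:4, j] <- rmultinom(1, tot, pr)
  }
  rownames(counts) <- paste0(gene, ":E", rep(1:4, nGene))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(fraction = "cytoplasmic",
                        condition = rep(c("control", "KD"), each = 4),
                        replicate = rep(c("r1", "r2"), 4),
                        row.names = paste0("s", 1:8)),
    rowData = DataFrame(gene_id = gene,
                        ordinal_class = rep(c("first", "internal", "internal",
                                              "last"), nGene)))
  r <- exonUsageTest(se, "cytoplasmic", fdr = 0.1)
  expect_equal(r$direction[1], "less_inclusion")
  # null exons (genes 2+): realized false-direction rate stays near nominal
  nullCalls <- sum(!is.na(r$direction[-(1:4)]))
  expect_lte(nullCalls, ceiling(1.5 * 0.1 * sum(!is.na(r$p[-(1:4)]))))
  # gene with zero counts in one condition is untested
  se2 <- se
  assay(se2, "counts")[5:8, 1:4] <- 0L
  r2 <- exonUsageTest(se2, "cytoplasmic")
  expect_true(all(is.na(r2$p[5:8])))
})

test_that("classifyChangedExons tabulates proportions and survives empties", {
  res <- data.frame(exon_id = c("a", "b", "c"), gene_id = "g",
                    usage_control = 0.5, usage_kd = 0.3, p = 0.001, q = 0.001,
                    direction = c("less_inclusion", "less_inclusion",
                                  "more_inclusion"),
                    ordinal_class = c("last", "last", "internal"),
                    stringsAsFactors = FALSE)
  tab <- classifyChangedExons(res)
  expect_equal(tab$proportion[tab$direction == "less_inclusion" &
                                tab$ordinal_class == "last"], 1)
  empty <- classifyChangedExons(res[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("Psi estimator: edge cases and shared-region logic", {
  # distal density 0 -> Psi 0
  expect_equal(psiEstimate(100, 0, 100, 100, "TandemUTR"), 0)
  # equal densities in a TandemUTR -> all transcripts use the long isoform
  expect_equal(psiEstimate(100, 50, 100, 50, "TandemUTR"), 1)
  # ALE: distal share of densities
  expect_equal(psiEstimate(100, 100, 100, 100, "ALE"), 0.5)
  # both zero -> undefined
  expect_true(is.na(psiEstimate(0, 0, 100, 100, "ALE")))
  # capped at 1
  expect_equal(psiEstimate(10, 100, 100, 100, "TandemUTR"), 1)
})

test_that("Psi estimator is nearly unbiased at 500 informative reads", {
  set.seed(8)
  n <- 1000
  psi <- runif(n, 0.2, 0.8)
  tot <- rpois(n, 500)
  kd <- rbinom(n, tot, psi / (1 + psi))   # TandemUTR: theta = psi/(1+psi)
  est <- psiEstimate(tot - kd, kd, 100, 100, rep("TandemUTR", n))
  expect_lt(abs(mean(est - psi)), 0.02)
  estA <- psiEstimate(tot - kd, kd, 100, 100, rep("ALE", n))
  expect_lt(abs(mean(estA - psi / (1 + psi))), 0.02)
})

test_that("Bayes factor matches a numeric-integration oracle within 5%", {
  set.seed(9)
  ev <- data.frame(event_id = "e", kind = "ALE",
                   proximal_length = 100, distal_length = 100)
  for (i in 1:100) {
    n1 <- sample(20:600, 1); n2 <- sample(20:600, 1)
    k1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
    k2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
    r <- apaCall(ev, cbind(n1 - k1, k1), cbind(n2 - k2, k2), minInformative = 1)
    o <- bfNumericOracle(k1, n1, k2, n2)
    expect_lt(abs(r$bayes_factor - o) / o, 0.05)
  }
})

test_that("APA calling: identical counts not called, extremes called, gates hold", {
  ev <- data.frame(event_id = "e", kind = "ALE",
                   proximal_length = 100, distal_length = 100)
  same <- apaCall(ev, cbind(60, 40), cbind(60, 40))
  expect_lt(same$bayes_factor, 1)
  expect_false(same$called)
  extreme <- apaCall(ev, cbind(100, 0), cbind(0, 100))
  expect_true(extreme$called)
  expect_equal(abs(extreme$dpsi), 1)
  expect_equal(extreme$direction, "lengthening")
  # low coverage flag blocks calls
  low <- apaCall(ev, cbind(5, 0), cbind(0, 5))
  expect_true(low$low_coverage)
  expect_false(low$called)
  # dpsi below threshold blocks calls even at large BF
  nd <- apaCall(ev, cbind(1000, 1000), cbind(900, 1100), dpsiThreshold = 0.2)
  expect_false(nd$called)
})

test_that("null APA call rate stays below 5%", {
  set.seed(10)
  n <- 400
  psi <- runif(n, 0.3, 0.7)
  t1 <- rpois(n, 500); t2 <- rpois(n, 500)
  k1 <- rbinom(n, t1, psi); k2 <- rbinom(n, t2, psi)
  ev <- data.frame(event_id = paste0("e", 1:n), kind = "ALE",
                   proximal_length = 100, distal_length = 100)
  r <- apaCall(ev, cbind(t1 - k1, k1), cbind(t2 - k2, k2))
  expect_lte(mean(r$called), 0.05)
})

test_that("integration report counts bound targets and APA-removed sites", {
  ann <- makeToyAnnotation()
  calls <- data.frame(feature = c("gA", "gT", "gB"),
                      is_target = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  srSites <- GRanges("chr1", IRanges(600, 610), strand = "+", center = 605L,
                     totalCount = 5L, nSigPositions = 2L, library = "SRSF3")
  nxSites <- GRanges("chr1", IRanges(2900, 2910), strand = "+", center = 2905L,
                     totalCount = 5L, nSigPositions = 2L, library = "NXF1")
  ev <- enumerateApaEvents(ann)
  apa <- data.frame(event_id = ev$event_id, kind = ev$kind,
                    called = TRUE, direction = "shortening",
                    stringsAsFactors = FALSE)
  rep <- integrateTargetsBinding(calls, srSites, nxSites, ann,
                                 apaResults = apa, apaEvents = ev)
  expect_equal(rep$n_targets, 2L)
  expect_equal(rep$n_bound, 1L)                 # gA bound by SR in 3'UTR
  expect_equal(rep$n_bound_last_or_3utr, 1L)
  expect_equal(rep$n_nxf1, 1L)                  # gT distal-region NXF1 site
  expect_equal(rep$n_apa_removes_nxf1, 1L)      # shortening removes it
  # target with no sites is simply unbound
  rep2 <- integrateTargetsBinding(calls, srSites[0], nxSites[0], ann)
  expect_equal(rep2$n_bound, 0L)
})
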