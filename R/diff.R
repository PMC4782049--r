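## Fractionated differential module: size factors, NB two-group tests,
## export-target calling, exon-usage tests, APA Psi estimation and
## Beta-Binomial Bayes factors, and integration with binding sites.

#' Median-of-ratios size factors, computed within each fraction
#'
#' DESeq-style median-of-ratios against the per-fraction geometric-mean
#' pseudo-reference; falls back to total-count scaling (with a warning)
#' when no feature is nonzero in every sample of a fraction.
#'
#' @param se A \code{SummarizedExperiment} with assay \code{counts} and
#'   colData columns \code{fraction}, \code{condition}, \code{replicate}.
#' @return The same object with \code{sizeFactor} added to colData and a
#'   \code{normcounts} assay.
#' @export
normalizeCounts <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  fr <- SummarizedExperiment::colData(se)$fraction
  sf <- rep(NA_real_, ncol(counts))
  for (f in unique(fr)) {
    ix <- which(fr == f)
    m <- counts[, ix, drop = FALSE]
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos)) {
      .warnf("fraction '%s': no feature nonzero in all samples; total-count scaling", f)
      s <- colSums(m); sf[ix] <- s / exp(mean(log(pmax(s, 1))))
    } else {
      logGeo <- rowMeans(log(m[pos, , drop = FALSE]))
      sf[ix] <- apply(m[pos, , drop = FALSE], 2L, function(v)
        exp(median(log(v) - logGeo)))
    }
  }
  SummarizedExperiment::colData(se)$sizeFactor <- sf
  SummarizedExperiment::assays(se)$normcounts <- sweep(counts, 2L, sf, "/")
  se
}

# method-of-moments NB dispersion per feature, shrunk toward a mean trend
.shrunkDispersions <- function(norm, groups, priorDf = 4) {
  mu <- rowMeans(norm)
  grandVar <- rowMeans(vapply(unique(groups), function(g) {
    m <- norm[, groups == g, drop = FALSE]
    matrixStats::rowVars(m)
  }, numeric(nrow(norm))))
  raw <- pmax((grandVar - mu) / mu^2, 0)
  ok <- mu > 0 & is.finite(raw)
  trend <- rep(NA_real_, length(mu))
  if (sum(ok) >= 10) {
    lo <- lowess(log(mu[ok]), raw[ok], f = 0.5)
    trend[ok] <- pmax(approx(lo$x, lo$y, xout = log(mu[ok]), rule = 2)$y, 1e-4)
  } else trend[ok] <- pmax(mean(raw[ok]), 1e-4)
  df <- length(unique(groups)) * (sum(groups == groups[1]) - 1)
  w <- df / (df + priorDf)
  disp <- w * raw + (1 - w) * trend
  disp[!ok] <- NA_real_
  pmax(disp, 1e-6)
}

# NB log-likelihood with fixed dispersion, mean mu_j = s_j * q
.nbNegll <- function(k, s, q, size) {
  -sum(stats::dnbinom(k, size = size, mu = s * q, log = TRUE))
}

#' Two-group negative-binomial differential test within one fraction
#'
#' Per feature: log2 fold change of normalized group means (pseudocount 1);
#' p-value from a likelihood-ratio test of shared versus group-specific NB
#' means (size-factor offsets, fixed per-feature dispersion estimated by
#' method of moments and shrunk toward the mean trend); BH adjustment.
#'
#' @param se Normalized \code{SummarizedExperiment}
#'   (\code{\link{normalizeCounts}}).
#' @param fraction Which fraction to test (\code{"cytoplasmic"} or
#'   \code{"whole_cell"}).
#' @param contrast Conditions compared, default \code{c("KD", "control")}
#'   (log2FC is KD over control).
#' @return data.frame: feature, baseMean, log2fc, dispersion, p, q (NA for
#'   all-zero features).
#' @export
differentialAbundance <- function(se, fraction,
                                  contrast = c("KD", "control")) {
  cd <- SummarizedExperiment::colData(se)
  ix <- which(cd$fraction == fraction & cd$condition %in% contrast)
  if (length(ix) < 4L) .stopf("need >= 2 replicates per condition in '%s'", fraction)
  counts <- SummarizedExperiment::assay(se, "counts")[, ix, drop = FALSE]
  norm <- SummarizedExperiment::assays(se)$normcounts[, ix, drop = FALSE]
  sf <- cd$sizeFactor[ix]
  grp <- as.character(cd$condition[ix])
  g1 <- grp == contrast[1]; g2 <- grp == contrast[2]
  disp <- .shrunkDispersions(norm, grp)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  log2fc <- log2(m1 + 1) - log2(m2 + 1)
  n <- nrow(counts)
  p <- rep(NA_real_, n)
  tested <- which(m1 + m2 > 0 & !is.na(disp))
  for (i in tested) {
    k <- counts[i, ]
    size <- 1 / disp[i]
    qAll <- sum(k) / sum(sf)
    q1 <- sum(k[g1]) / sum(sf[g1]); q2 <- sum(k[g2]) / sum(sf[g2])
    ll0 <- .nbNegll(k, sf, qAll, size)
    ll1 <- .nbNegll(k[g1], sf[g1], q1, size) + .nbNegll(k[g2], sf[g2], q2, size)
    lrt <- max(2 * (ll0 - ll1), 0)
    p[i] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  q <- rep(NA_real_, n)
  q[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(feature = rownames(counts), baseMean = (m1 + m2) / 2,
             log2fc = log2fc, dispersion = disp, p = p, q = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call mRNA export targets from cytoplasmic and whole-cell contrasts
#'
#' A transcript is an export target when its cytoplasmic knockdown change
#' is significant (q < alpha), negative, and exceeds the whole-cell change
#' by at least \code{delta} log2 units (net cytoplasmic decrease).
#'
#' @param resCyto,resWhole Results of \code{\link{differentialAbundance}}
#'   for the cytoplasmic and whole-cell fractions.
#' @param alpha Significance threshold on cytoplasmic q (default 0.05).
#' @param delta Net-decrease threshold in log2 units (default 0.585,
#'   i.e. 1.5-fold).
#' @return data.frame: feature, log2fc_cyto, log2fc_whole, delta, p_cyto,
#'   q_cyto, is_target.
#' @export
callExportTargets <- function(resCyto, resWhole, alpha = 0.05, delta = 0.585) {
  m <- match(resCyto$feature, resWhole$feature)
  out <- data.frame(feature = resCyto$feature,
                    log2fc_cyto = resCyto$log2fc,
                    log2fc_whole = resWhole$log2fc[m],
                    p_cyto = resCyto$p, q_cyto = resCyto$q,
                    stringsAsFactors = FALSE)
  out$delta <- out$log2fc_cyto - out$log2fc_whole
  out$is_target <- !is.na(out$q_cyto) & !is.na(out$delta) &
    out$q_cyto < alpha & out$log2fc_cyto < 0 & out$delta <= -delta
  out
}

#' Differential exon usage (pooled 2x2 test)
#'
#' Per exon: usage = exon count / gene count. Conditions are compared on
#' replicate-pooled counts in a 2x2 table (exon vs rest-of-gene, KD vs
#' control) with a chi-squared test (Fisher's exact test when any expected
#' cell is < 5); BH adjustment at the stated FDR. Direction is the sign of
#' the usage change, defined for significant exons.
#'
#' @param seExon Exon-level \code{SummarizedExperiment} (assay
#'   \code{counts}; rowData \code{gene_id}, optionally
#'   \code{ordinal_class}).
#' @param fraction Compartment to test.
#' @param fdr FDR threshold for direction calls (default 0.1).
#' @param contrast Conditions, default \code{c("KD", "control")}.
#' @return data.frame: exon_id, gene_id, usage_control, usage_kd, p, q,
#'   direction (more_inclusion/less_inclusion/NA), ordinal_class.
#' @export
exonUsageTest <- function(seExon, fraction, fdr = 0.1,
                          contrast = c("KD", "control")) {
  cd <- SummarizedExperiment::colData(seExon)
  rd <- SummarizedExperiment::rowData(seExon)
  counts <- SummarizedExperiment::assay(seExon, "counts")
  i1 <- which(cd$fraction == fraction & cd$condition == contrast[1])
  i2 <- which(cd$fraction == fraction & cd$condition == contrast[2])
  kd <- rowSums(counts[, i1, drop = FALSE])
  ctl <- rowSums(counts[, i2, drop = FALSE])
  gene <- rd$gene_id
  gKd <- tapply(kd, gene, sum)[gene]
  gCtl <- tapply(ctl, gene, sum)[gene]
  n <- nrow(counts)
  p <- rep(NA_real_, n)
  usageK <- ifelse(gKd > 0, kd / gKd, NA)
  usageC <- ifelse(gCtl > 0, ctl / gCtl, NA)
  for (i in seq_len(n)) {
    if (is.na(usageK[i]) || is.na(usageC[i])) next
    tab <- matrix(c(kd[i], gKd[i] - kd[i], ctl[i], gCtl[i] - ctl[i]), 2L)
    if (any(tab < 0)) next
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p[i] <- if (any(expd < 5)) fisher.test(tab)$p.value
            else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  q <- rep(NA_real_, n)
  tested <- !is.na(p)
  q[tested] <- p.adjust(p[tested], method = "BH")
  direction <- ifelse(!is.na(q) & q < fdr,
                      ifelse(usageK > usageC, "more_inclusion", "less_inclusion"),
                      NA_character_)
  data.frame(exon_id = rownames(counts), gene_id = gene,
             usage_control = usageC, usage_kd = usageK,
             p = p, q = q, direction = direction,
             ordinal_class = if ("ordinal_class" %in% names(rd))
               rd$ordinal_class else NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ordinal-class proportions among changed exons
#'
#' @param results \code{\link{exonUsageTest}} output.
#' @return data.frame: direction, ordinal_class, n, proportion (within
#'   direction). Empty results give an empty table.
#' @export
classifyChangedExons <- function(results) {
  chg <- results[!is.na(results$direction), ]
  if (nrow(chg) == 0L)
    return(data.frame(direction = character(0), ordinal_class = character(0),
                      n = integer(0), proportion = numeric(0)))
  tab <- as.data.frame(table(direction = chg$direction,
                             ordinal_class = chg$ordinal_class),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$direction, sum)
  tab$proportion <- tab$n / tot[tab$direction]
  tab
}

#' Estimate Psi (distal/long-isoform fraction) for an APA event
#'
#' TandemUTR events share their proximal region between isoforms, so Psi is
#' the ratio of length-normalized distal to proximal densities, capped to
#' [0, 1]. ALE events have mutually exclusive last exons, so Psi is the
#' distal share of the summed densities. Undefined (NA) when both regions
#' have zero counts.
#'
#' @param proximalCount,distalCount Read counts in the two regions.
#' @param proximalLength,distalLength Region lengths (nt).
#' @param kind \code{"TandemUTR"} or \code{"ALE"} (vectorized).
#' @return Numeric vector of Psi values in [0, 1].
#' @export
psiEstimate <- function(proximalCount, distalCount, proximalLength,
                        distalLength, kind) {
  dp <- proximalCount / proximalLength
  dd <- distalCount / distalLength
  psi <- ifelse(kind == "TandemUTR",
                ifelse(dp > 0, pmin(dd / dp, 1), ifelse(dd > 0, 1, NA_real_)),
                ifelse(dp + dd > 0, dd / (dp + dd), NA_real_))
  psi[proximalCount + distalCount == 0] <- NA_real_
  psi
}

# log marginal likelihood of k successes in n under Beta(1,1) prior
# (equals -log(n+1)); shared-theta marginal for two binomials
.logBfDistinct <- function(k1, n1, k2, n2) {
  sep <- -log1p(n1) - log1p(n2)
  shared <- lchoose(n1, k1) + lchoose(n2, k2) +
    lbeta(k1 + k2 + 1, n1 + n2 - k1 - k2 + 1)
  sep - shared
}

#' Call APA shifts with a Beta-Binomial Bayes factor
#'
#' Informative counts per condition are the distal count k and the
#' length-rescaled proximal count m (proximal count scaled to the distal
#' region length), giving a binomial theta = k/(k+m) per condition. The
#' Bayes factor compares condition-specific theta (uniform priors) against
#' a shared theta. An event is called when BF > \code{bfThreshold} and
#' |dPsi| >= \code{dpsiThreshold}; events with fewer than
#' \code{minInformative} informative reads in total are flagged
#' low-coverage and never called.
#'
#' @param events APA events (\code{\link{enumerateApaEvents}}) or a
#'   data.frame with \code{event_id}, \code{kind}, \code{proximal_length},
#'   \code{distal_length}.
#' @param countsControl,countsKd Two-column matrices (proximal, distal) of
#'   replicate-pooled counts per event.
#' @param bfThreshold Bayes-factor threshold (default 5).
#' @param dpsiThreshold Minimum |dPsi| (default 0.20).
#' @param minInformative Minimum total informative reads (default 20).
#' @return data.frame: event_id, kind, psi_control, psi_kd, dpsi,
#'   bayes_factor, direction (lengthening/shortening), called,
#'   low_coverage.
#' @export
apaCall <- function(events, countsControl, countsKd, bfThreshold = 5,
                    dpsiThreshold = 0.20, minInformative = 20L) {
  if (is(events, "DataFrame")) {
    kind <- events$kind
    lp <- GenomicRanges::width(events$proximal_region)
    ld <- GenomicRanges::width(events$distal_region)
    eid <- events$event_id
  } else {
    kind <- events$kind; lp <- events$proximal_length
    ld <- events$distal_length; eid <- events$event_id
  }
  psiC <- psiEstimate(countsControl[, 1], countsControl[, 2], lp, ld, kind)
  psiK <- psiEstimate(countsKd[, 1], countsKd[, 2], lp, ld, kind)
  # informative counts on a common length basis
  mC <- round(countsControl[, 1] * ld / lp); kC <- countsControl[, 2]
  mK <- round(countsKd[, 1] * ld / lp); kK <- countsKd[, 2]
  logBf <- .logBfDistinct(kC, kC + mC, kK, kK + mK)
  bf <- exp(logBf)
  dpsi <- psiK - psiC
  lowCov <- (kC + mC) + (kK + mK) < minInformative
  called <- !is.na(dpsi) & !lowCov & bf > bfThreshold & abs(dpsi) >= dpsiThreshold
  direction <- ifelse(called, ifelse(dpsi > 0, "lengthening", "shortening"),
                      NA_character_)
  data.frame(event_id = eid, kind = kind, psi_control = psiC, psi_kd = psiK,
             dpsi = dpsi, bayes_factor = bf, direction = direction,
             called = called, low_coverage = lowCov,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integrate export targets with binding sites and APA
#'
#' Per-target overlap report: how many export targets carry cognate SR
#' binding sites, sites in last exons / 3' UTRs, receptor (NXF1) sites, and
#' called APA shortening events whose distal region contains a receptor
#' site (polyadenylation cleavage removing the site).
#'
#' @param exportCalls \code{\link{callExportTargets}} output (features are
#'   transcript or gene ids of the representative isoform).
#' @param srSites Cognate SR binding sites.
#' @param nxf1Sites Receptor binding sites.
#' @param annotation A \code{GenomeAnnotation}.
#' @param apaResults Optional \code{\link{apaCall}} output.
#' @param apaEvents Optional events (needed with \code{apaResults}).
#' @param regions Optional precomputed regions.
#' @return One-row data.frame of counts (n_targets, n_bound,
#'   n_bound_last_or_3utr, n_nxf1, n_nxf1_last_or_3utr, n_apa_removes_nxf1).
#' @export
integrateTargetsBinding <- function(exportCalls, srSites, nxf1Sites, annotation,
                                    apaResults = NULL, apaEvents = NULL,
                                    regions = deriveRegions(annotation)) {
  targets <- exportCalls$feature[exportCalls$is_target]
  rep <- representativeTranscripts(annotation)
  # accept either gene ids or representative transcript ids
  genes <- ifelse(targets %in% names(rep), targets,
                  names(rep)[match(targets, rep)])
  genes <- genes[!is.na(genes)]
  spans <- geneSpans(annotation)[genes]
  exf <- classifyExons(annotation)
  lastEx <- exf[exf$ordinal_class == "last" & exf$transcript_id %in% rep[genes]]
  u3 <- regions[regions$label == "three_prime_utr" & regions$gene_id %in% genes]
  endRegion <- c(GenomicRanges::granges(lastEx), GenomicRanges::granges(u3))

  centerGr <- function(sites) GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites), IRanges::IRanges(sites$center, width = 1L),
    strand = GenomicRanges::strand(sites))
  srC <- centerGr(srSites); nxC <- centerGr(nxf1Sites)

  boundGenes <- function(centers) {
    hit <- GenomicRanges::findOverlaps(centers, spans)
    unique(names(spans)[S4Vectors::subjectHits(hit)])
  }
  inEnd <- function(centers) {
    keep <- IRanges::overlapsAny(centers, endRegion)
    boundGenes(centers[keep])
  }
  bSr <- boundGenes(srC); bSrEnd <- inEnd(srC)
  bNx <- boundGenes(nxC); bNxEnd <- inEnd(nxC)

  nApaRemoves <- 0L
  if (!is.null(apaResults) && !is.null(apaEvents)) {
    sh <- apaResults$event_id[apaResults$called &
                                apaResults$direction == "shortening"]
    sh <- sh[!is.na(sh)]
    ev <- apaEvents[match(sh, apaEvents$event_id), , drop = FALSE]
    if (length(sh)) {
      evGenes <- ev$gene_id
      keep <- evGenes %in% genes
      if (any(keep)) {
        distal <- ev$distal_region[keep]
        hit <- IRanges::overlapsAny(distal, nxC, ignore.strand = FALSE)
        nApaRemoves <- length(unique(evGenes[keep][hit]))
      }
    }
  }
  data.frame(n_targets = length(genes),
             n_bound = length(bSr),
             n_bound_last_or_3utr = length(intersect(bSr, bSrEnd)),
             n_nxf1 = length(bNx),
             n_nxf1_last_or_3utr = length(intersect(bNx, bNxEnd)),
             n_apa_removes_nxf1 = nApaRemoves)
}
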