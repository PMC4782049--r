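## Synthetic-data generator, part 3: fractionated RNA-seq count tables.
##
## Transcript totals are negative binomial per sample (2 replicates x
## {control, KD} x {whole_cell, cytoplasmic}); "dispersion" is the
## extra-Poisson variance coefficient, var = (1 + dispersion) * mu, so the
## dispersion -> 0 limit is Poisson. Planted export targets lose abundance
## in the cytoplasm only. Exon counts are multinomial within each gene
## conditional on its total (usage proportions are exactly binomial given
## the totals); planted usage changes come in within-gene pairs (one exon
## loses inclusion, a designated sibling absorbs the mass), leaving every
## other exon's proportion untouched. APA events draw an NB total per
## sample, split binomially between proximal and distal regions according
## to the planted Psi.

# NB draw with var = (1 + phi) * mu
.rnbExtra <- function(n, mu, phi) {
  mu <- pmax(mu, 1e-8)
  rnbinom(n, size = mu / phi, mu = mu)
}

#' Simulate fractionated RNA-seq counts with planted truth
#'
#' @param config A \code{SimulationConfig}.
#' @param sim Result of \code{\link{simulateGenome}}.
#' @return List: \code{txSE}, \code{exonSE}, \code{apaSE} (all
#'   \code{SummarizedExperiment}s over the same 8 samples) and \code{truth}
#'   (export targets with true effect, paired usage changes, Psi per
#'   condition).
#' @export
simulateFractionCounts <- function(config, sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  rs <- config$rnaseq
  ann <- sim$annotation
  rep <- representativeTranscripts(ann)
  genes <- names(rep)
  ng <- length(genes)

  samples <- expand.grid(replicate = c("r1", "r2"),
                         condition = c("control", "KD"),
                         fraction = c("whole_cell", "cytoplasmic"),
                         stringsAsFactors = FALSE)
  samples$sample <- with(samples, paste(fraction, condition, replicate, sep = "."))
  nS <- nrow(samples)

  baseline <- pmax(exp(rnorm(ng, log(rs$meanCounts), rs$logSdCounts)),
                   rs$minMeanCounts)
  names(baseline) <- genes

  # export targets, optionally coupled to partner 3'UTR binding
  pl <- sim$truth$placements
  partner <- config$nxf1$partner
  utr3Genes <- if (length(pl)) unique(pl$gene_id[pl$protein == partner &
                                                   pl$label %in% "three_prime_utr"])
               else character(0)
  nT <- min(rs$nExportTargets, ng)
  nBound <- min(round(rs$bindTargetRate * nT), length(utr3Genes))
  tUnboundPool <- setdiff(genes, utr3Genes)
  targets <- c(sample(utr3Genes, nBound),
               sample(tUnboundPool, min(nT - nBound, length(tUnboundPool))))
  isTarget <- genes %in% targets
  effect <- ifelse(isTarget, rs$exportLog2fc, 0)

  counts <- matrix(0L, ng, nS, dimnames = list(rep[genes], samples$sample))
  for (j in seq_len(nS)) {
    mu <- baseline
    if (samples$condition[j] == "KD" && samples$fraction[j] == "cytoplasmic")
      mu <- mu * 2^effect
    counts[, j] <- .rnbExtra(ng, mu, rs$dispersion)
  }
  txSE <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
    rowData = S4Vectors::DataFrame(gene_id = genes))

  # exon-level: multinomial within gene; paired usage plantings under KD
  exf <- classifyExons(ann)
  exf <- exf[exf$transcript_id %in% rep]
  wts <- as.numeric(GenomicRanges::width(exf))
  exGene <- exf$gene_id
  gsplit <- split(seq_along(exf), exGene)
  nExPerGene <- lengths(gsplit)
  eligible <- names(gsplit)[nExPerGene >= 3L]
  nU <- min(rs$nUsageChanges, length(eligible))
  usageGenes <- sample(eligible, nU)
  pickLess <- integer(nU); pickMore <- integer(nU)
  for (u in seq_len(nU)) {
    ix <- gsplit[[usageGenes[u]]]
    cls <- exf$ordinal_class[ix]
    chooseByClass <- function(prefLast, excl = integer(0)) {
      pool <- setdiff(ix, excl)
      lastP <- pool[cls[match(pool, ix)] == "last"]
      intP <- pool[cls[match(pool, ix)] == "internal"]
      if (runif(1) < prefLast && length(lastP)) .pick1(lastP)
      else if (length(intP)) .pick1(intP)
      else .pick1(pool)
    }
    pickLess[u] <- chooseByClass(rs$usageLastFractionLess)
    pickMore[u] <- chooseByClass(rs$usageLastFractionMore, excl = pickLess[u])
  }
  # KD weights: less exon scaled by fold, paired exon absorbs the mass
  wKd <- wts
  moved <- wts[pickLess] * (1 - rs$usageFoldLess)
  wKd[pickLess] <- wts[pickLess] * rs$usageFoldLess
  wKd[pickMore] <- wts[pickMore] + moved

  exCounts <- matrix(0L, length(exf), nS,
                     dimnames = list(exf$exon_id, samples$sample))
  for (j in seq_len(nS)) {
    w <- if (samples$condition[j] == "KD") wKd else wts
    for (g in genes) {
      ix <- gsplit[[g]]
      tot <- counts[rep[[g]], j]
      if (tot == 0L) next
      exCounts[ix, j] <- rmultinom(1L, tot, prob = w[ix])
    }
  }
  exonSE <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = exCounts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
    rowData = S4Vectors::DataFrame(gene_id = exGene,
                                   ordinal_class = exf$ordinal_class))

  # APA region counts realizing planted Psi shifts (NB total, binomial split)
  events <- enumerateApaEvents(ann)
  truthPsi <- NULL
  apaSE <- NULL
  if (nrow(events)) {
    ne <- nrow(events)
    lp <- GenomicRanges::width(events$proximal_region)
    ld <- GenomicRanges::width(events$distal_region)
    psi0 <- runif(ne, rs$controlPsiRange[1], rs$controlPsiRange[2])
    psiK <- pmin(pmax(psi0 - rs$deltaPsi, 0.02), 0.98)
    apaCounts <- matrix(0L, 2L * ne, nS)
    rn <- c(rbind(paste0(events$event_id, ":proximal"),
                  paste0(events$event_id, ":distal")))
    dimnames(apaCounts) <- list(rn, samples$sample)
    tandem <- events$kind == "TandemUTR"
    D <- rs$apaDepth / lp            # per-nt depth; proximal averages apaDepth
    for (j in seq_len(nS)) {
      psi <- if (samples$condition[j] == "KD") psiK else psi0
      muP <- ifelse(tandem, D * lp, D * lp * (1 - psi))
      muD <- D * ld * psi
      tot <- .rnbExtra(ne, muP + muD, rs$dispersion)
      xd <- rbinom(ne, tot, muD / (muP + muD))
      apaCounts[seq(1L, 2L * ne, 2L), j] <- tot - xd
      apaCounts[seq(2L, 2L * ne, 2L), j] <- xd
    }
    apaSE <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = apaCounts),
      colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
      rowData = S4Vectors::DataFrame(
        event_id = rep(events$event_id, each = 2L),
        role = rep(c("proximal", "distal"), ne),
        kind = rep(events$kind, each = 2L),
        length = as.integer(c(rbind(lp, ld)))))
    truthPsi <- data.frame(event_id = events$event_id, kind = events$kind,
                           psi_control = psi0, psi_kd = psiK,
                           stringsAsFactors = FALSE)
  }

  truth <- list(
    exportTargets = rep[targets],
    exportTargetGenes = targets,
    trueLog2fc = setNames(effect, rep[genes]),
    usageChanges = data.frame(
      exon_id = exf$exon_id[c(pickLess, pickMore)],
      ordinal_class = exf$ordinal_class[c(pickLess, pickMore)],
      direction = c(rep("less_inclusion", nU), rep("more_inclusion", nU)),
      stringsAsFactors = FALSE),
    psi = truthPsi)
  list(txSE = txSE, exonSE = exonSE, apaSE = apaSE, truth = truth)
}

.pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Pool APA replicate counts per condition into proximal/distal matrices
#'
#' Convenience extractor turning the APA \code{SummarizedExperiment} into
#' the inputs of \code{\link{apaCall}} for one fraction.
#'
#' @param apaSE APA region counts (\code{\link{simulateFractionCounts}}).
#' @param fraction Fraction to use (default \code{"cytoplasmic"}).
#' @return List: \code{events} (data.frame with event_id, kind, lengths),
#'   \code{control}, \code{kd} (two-column proximal/distal matrices).
#' @export
apaCountsByCondition <- function(apaSE, fraction = "cytoplasmic") {
  cd <- SummarizedExperiment::colData(apaSE)
  rd <- SummarizedExperiment::rowData(apaSE)
  counts <- SummarizedExperiment::assay(apaSE, "counts")
  prox <- which(rd$role == "proximal"); dist <- which(rd$role == "distal")
  pool <- function(cond) {
    ix <- which(cd$fraction == fraction & cd$condition == cond)
    cbind(proximal = rowSums(counts[prox, ix, drop = FALSE]),
          distal = rowSums(counts[dist, ix, drop = FALSE]))
  }
  list(events = data.frame(event_id = rd$event_id[prox], kind = rd$kind[prox],
                           proximal_length = rd$length[prox],
                           distal_length = rd$length[dist],
                           stringsAsFactors = FALSE),
       control = pool("control"), kd = pool("KD"))
}
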