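## Pipeline orchestration: run the stages end-to-end on simulated data with
## a manifest (parameters, seed, output checksums) for reproducibility.

.stageOrder <- c("simulate", "callsites", "junctions", "occupancy", "cobind",
                 "motifs", "diffexport", "exonusage", "apa", "report")

.stageDeps <- list(
  simulate = character(0),
  callsites = "simulate", junctions = "simulate",
  occupancy = "callsites", cobind = "callsites", motifs = "callsites",
  diffexport = "simulate", exonusage = "simulate", apa = "simulate",
  report = c("callsites", "diffexport"))

#' Run the analysis pipeline on simulated data
#'
#' Executes the requested stages in order on a packaged simulation,
#' writing TSV/BED artifacts per stage plus a JSON manifest with the
#' configuration, seed and md5 checksum of every output. \code{"all"} runs
#' everything; stage dependencies are checked and a missing upstream
#' artifact raises an error naming the stage that produces it.
#'
#' @param config A \code{SimulationConfig} (its \code{seed} drives every
#'   stage).
#' @param outdir Output directory.
#' @param stages Character vector of stages (subset of
#'   \code{c("simulate","callsites","junctions","occupancy","cobind",
#'   "motifs","diffexport","exonusage","apa","report")}) or \code{"all"}.
#' @param fdrThreshold,nPerm Cross-link caller parameters.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        stages = "all", fdrThreshold = 0.05, nPerm = 100L) {
  if (identical(stages, "all")) stages <- .stageOrder
  bad <- setdiff(stages, .stageOrder)
  if (length(bad)) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- .stageOrder[.stageOrder %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- file.path(outdir, "state.rds")
  env <- if (file.exists(state)) readRDS(state) else list(done = character(0))

  need <- function(stage) {
    for (dep in .stageDeps[[stage]])
      if (!dep %in% env$done)
        .stopf("stage '%s' requires output of stage '%s'; run it first",
               stage, dep)
  }
  files <- character(0)
  addFile <- function(p) files <<- c(files, p)

  for (stage in stages) {
    need(stage)
    message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", stage)
    if (stage == "simulate") {
      env$sim <- simulateGenome(config)
      fp <- writeSimulatedGenome(env$sim, outdir)
      addFile(fp["fasta"]); addFile(fp["gtf"])
      env$iclip <- simulateIclip(config, env$sim)
      f <- file.path(outdir, "reads.tsv")
      writeCdnaTable(env$iclip$reads, f); addFile(f)
      env$counts <- simulateFractionCounts(config, env$sim)
      for (nm in c("txSE", "exonSE", "apaSE")) {
        if (is.null(env$counts[[nm]])) next
        f <- file.path(outdir, paste0(sub("SE$", "", nm), "_counts.tsv"))
        tab <- as.data.frame(SummarizedExperiment::assay(env$counts[[nm]], "counts"))
        tab <- cbind(feature = rownames(tab), tab)
        data.table::fwrite(tab, f, sep = "\t"); addFile(f)
      }
      tr <- env$sim$truth
      truthOut <- list(
        motifs = as.list(tr$motifs),
        apaGenes = tr$apaGenes,
        exportTargets = env$counts$truth$exportTargetGenes,
        psi = env$counts$truth$psi,
        usageChanges = env$counts$truth$usageChanges)
      f <- file.path(outdir, "truth.json")
      jsonlite::write_json(truthOut, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      addFile(f)
      env$regions <- deriveRegions(env$sim$annotation)
      env$exf <- classifyExons(env$sim$annotation)
    }
    if (stage == "callsites") {
      dd <- deduplicateReads(env$iclip$reads)
      env$events <- extractCrosslinks(dd$reads)
      env$sig <- callSignificantPositions(env$events, env$sim$annotation,
                                          fdrThreshold = fdrThreshold,
                                          nPerm = nPerm, seed = config$seed + 3L)
      env$sites <- mergeBindingSites(env$sig)
      f <- file.path(outdir, "significant_positions.bed")
      writeBed6(env$sig, f, score = pmin(-log10(pmax(env$sig$fdr, 1e-10)), 10),
                name = env$sig$library)
      addFile(f)
      f <- file.path(outdir, "binding_sites.bed")
      writeBed6(env$sites, f, score = env$sites$totalCount,
                name = paste0(env$sites$library, ":", env$sites$center))
      addFile(f)
    }
    if (stage == "junctions") {
      ss <- spliceSites(env$sim$annotation)
      dd <- deduplicateReads(env$iclip$reads)
      ev <- extractCrosslinks(dd$reads)
      prof <- list()
      for (lib in unique(ev$library)) {
        e <- ev[ev$library == lib]
        for (kind in c("5ss", "3ss")) {
          pr <- spliceSiteMetaprofile(e, ss[ss$kind == kind])
          pr$library <- lib; pr$anchor <- kind
          prof[[paste(lib, kind)]] <- pr
        }
      }
      f <- file.path(outdir, "splice_site_profiles.tsv")
      data.table::fwrite(data.table::rbindlist(prof), f, sep = "\t"); addFile(f)
      jc <- classifyJunctionReads(env$iclip$reads, env$sim$annotation)
      f <- file.path(outdir, "junction_counts.tsv")
      data.table::fwrite(jc$perLibrary, f, sep = "\t"); addFile(f)
    }
    if (stage == "occupancy") {
      dens <- regionDensity(env$sig, env$regions)
      f <- file.path(outdir, "region_density.tsv")
      data.table::fwrite(dens, f, sep = "\t"); addFile(f)
      ebm <- exonBindingMatrix(env$sig, env$exf)
      env$ebm <- ebm
      cb <- coboundExonFraction(ebm)
      f <- file.path(outdir, "cobound_exons.tsv")
      data.table::fwrite(cb, f, sep = "\t"); addFile(f)
      cl <- correlationClustering(ebm)
      if (!is.null(cl$tree)) {
        f <- file.path(outdir, "clustering.nwk")
        writeLines(ape::write.tree(ape::as.phylo(cl$tree)), f); addFile(f)
      }
      nx <- env$sites[env$sites$library == config$nxf1$name]
      spt <- sitesPerTranscript(nx, env$sim$annotation, env$regions)
      f <- file.path(outdir, "nxf1_sites_per_transcript.tsv")
      data.table::fwrite(spt$histogram, f, sep = "\t"); addFile(f)
    }
    if (stage == "cobind") {
      nx <- env$sites[env$sites$library == config$nxf1$name]
      srLibs <- setdiff(unique(env$sig$library), c(config$nxf1$name, "CTRL"))
      srPos <- setNames(lapply(srLibs, function(l) env$sig[env$sig$library == l]),
                        srLibs)
      cr <- cobindingRatio(nx, srPos, env$exf)
      f <- file.path(outdir, "cobinding_ratios.tsv")
      data.table::fwrite(cr, f, sep = "\t"); addFile(f)
      exc <- exclusiveCobinding(nx, srPos, env$exf)
      f <- file.path(outdir, "exclusive_cobinding.tsv")
      data.table::fwrite(exc, f, sep = "\t"); addFile(f)
      pw <- pairwiseCobinding(nx, srPos, env$exf)
      f <- file.path(outdir, "pairwise_cobinding.tsv")
      data.table::fwrite(as.data.frame(pw), f, sep = "\t", row.names = TRUE)
      addFile(f)
    }
    if (stage == "motifs") {
      libs <- c(config$nxf1$partner, config$nxf1$name)
      rows <- list()
      for (lib in libs) for (rg in c("all", "3utr")) {
        s <- env$sig[env$sig$library == lib]
        wins <- extractWindows(s, env$sim$annotation, rg, regions = env$regions)
        if (length(wins$seqs) < 100L) next
        tab <- kmerEnrichment(wins, env$sim$annotation, seed = config$seed + 4L)
        tab$library <- lib; tab$region <- rg
        rows[[paste(lib, rg)]] <- head(tab, 50)
      }
      f <- file.path(outdir, "kmer_enrichment.tsv")
      data.table::fwrite(data.table::rbindlist(rows), f, sep = "\t"); addFile(f)
    }
    if (stage == "diffexport") {
      se <- normalizeCounts(env$counts$txSE)
      env$resCyto <- differentialAbundance(se, "cytoplasmic")
      env$resWhole <- differentialAbundance(se, "whole_cell")
      env$exportCalls <- callExportTargets(env$resCyto, env$resWhole)
      f <- file.path(outdir, "export_calls.tsv")
      data.table::fwrite(env$exportCalls, f, sep = "\t"); addFile(f)
    }
    if (stage == "exonusage") {
      eu <- exonUsageTest(env$counts$exonSE, "cytoplasmic")
      env$exonUsage <- eu
      f <- file.path(outdir, "exon_usage.tsv")
      data.table::fwrite(eu, f, sep = "\t"); addFile(f)
      cc <- classifyChangedExons(eu)
      f <- file.path(outdir, "changed_exon_classes.tsv")
      data.table::fwrite(cc, f, sep = "\t"); addFile(f)
    }
    if (stage == "apa") {
      if (!is.null(env$counts$apaSE)) {
        ac <- apaCountsByCondition(env$counts$apaSE)
        env$apaResults <- apaCall(ac$events, ac$control, ac$kd)
        f <- file.path(outdir, "apa_calls.tsv")
        data.table::fwrite(env$apaResults, f, sep = "\t"); addFile(f)
      }
    }
    if (stage == "report") {
      partner <- config$nxf1$partner
      sr <- env$sites[env$sites$library == partner]
      nx <- env$sites[env$sites$library == config$nxf1$name]
      events <- enumerateApaEvents(env$sim$annotation)
      integ <- integrateTargetsBinding(env$exportCalls, sr, nx,
                                       env$sim$annotation,
                                       apaResults = env$apaResults,
                                       apaEvents = events,
                                       regions = env$regions)
      summary <- data.frame(
        metric = c("n_unique_cdnas", "n_significant_positions",
                   "n_binding_sites", "n_export_targets",
                   "n_targets_bound_by_partner", "stages_run"),
        value = c(sum(env$events$count), length(env$sig), length(env$sites),
                  sum(env$exportCalls$is_target), integ$n_bound,
                  paste(union(env$done, stages), collapse = ";")),
        stringsAsFactors = FALSE)
      f <- file.path(outdir, "report.tsv")
      data.table::fwrite(summary, f, sep = "\t"); addFile(f)
      f <- file.path(outdir, "integration.tsv")
      data.table::fwrite(integ, f, sep = "\t"); addFile(f)
    }
    env$done <- union(env$done, stage)
  }
  saveRDS(env, state)

  manifest <- list(
    seed = config$seed,
    nGenes = config$nGenes,
    parameters = list(fdrThreshold = fdrThreshold, nPerm = nPerm),
    stages = env$done,
    files = lapply(setNames(nm = basename(files)), function(b)
      unname(tools::md5sum(file.path(outdir, b)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
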