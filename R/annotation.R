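## Annotation module: GTF I/O, transcript regions, exon ordinals, splice
## sites and alternative-polyadenylation event structures.

#' Load a GTF annotation into a GenomeAnnotation
#'
#' Reads an Ensembl-dialect GTF (gene/transcript/exon and optional CDS
#' records) via \pkg{rtracklayer} and assembles per-transcript models with
#' exons in 5'->3' transcript order. A genome FASTA may be attached for
#' sequence-dependent operations.
#'
#' @param gtfPath Path to a GTF file.
#' @param fastaPath Optional path to the matching genome FASTA.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
loadAnnotation <- function(gtfPath, fastaPath = NULL) {
  gr <- tryCatch(rtracklayer::import(gtfPath, format = "gtf"),
                 error = function(e) .stopf("failed to parse GTF '%s': %s",
                                            gtfPath, conditionMessage(e)))
  if (!all(c("type", "transcript_id", "gene_id") %in% names(S4Vectors::mcols(gr))))
    .stopf("GTF '%s' lacks required attributes (type/transcript_id/gene_id)", gtfPath)
  exn <- gr[gr$type == "exon"]
  if (length(exn) == 0L) .stopf("GTF '%s' contains no exon records", gtfPath)
  # transcripts declared but exonless are rejected with their ids
  declared <- unique(gr$transcript_id[gr$type %in% c("transcript", "mRNA")])
  declared <- declared[!is.na(declared)]
  missing <- setdiff(declared, unique(exn$transcript_id))
  if (length(missing))
    .stopf("transcript(s) with zero exons: %s", paste(missing, collapse = ", "))

  exl <- GenomicRanges::split(GenomicRanges::granges(exn), exn$transcript_id)
  exl <- .orderExons5to3(exl)

  cdsr <- gr[gr$type == "CDS"]
  cdl <- GenomicRanges::split(GenomicRanges::granges(cdsr), cdsr$transcript_id)
  cdl <- .orderExons5to3(cdl)
  # parallel CDS list (empty elements where absent)
  full <- setNames(vector("list", length(exl)), names(exl))
  empty <- GenomicRanges::GRanges()
  for (nm in names(exl))
    full[[nm]] <- if (nm %in% names(cdl)) cdl[[nm]] else empty
  cdl <- GenomicRanges::GRangesList(full)

  meta <- S4Vectors::mcols(exn)
  first <- !duplicated(exn$transcript_id)
  td <- S4Vectors::DataFrame(
    transcript_id = exn$transcript_id[first],
    gene_id = exn$gene_id[first],
    biotype = if ("gene_biotype" %in% names(meta)) meta$gene_biotype[first]
              else rep("protein_coding", sum(first))
  )
  td <- td[match(names(exl), td$transcript_id), ]
  rownames(td) <- NULL

  genome <- if (!is.null(fastaPath)) Biostrings::readDNAStringSet(fastaPath)
            else Biostrings::DNAStringSet()
  if (length(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  .GenomeAnnotation(exl, cdl, td, genome)
}

# order each element of a GRangesList 5'->3' on its own strand
.orderExons5to3 <- function(grl) {
  if (length(grl) == 0L) return(grl)
  gr <- unlist(grl, use.names = FALSE)
  grp <- rep(seq_along(grl), S4Vectors::elementNROWS(grl))
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  key <- ifelse(neg, -GenomicRanges::start(gr), GenomicRanges::start(gr))
  o <- order(grp, key)
  out <- S4Vectors::split(gr[o], grp[o])
  names(out) <- names(grl)
  out
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits gene, transcript, exon and CDS records; reloading the file with
#' \code{loadAnnotation} reproduces the same models.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @param path Output GTF path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGtf <- function(annotation, path) {
  exl <- txExons(annotation)
  cdl <- txCds(annotation)
  td <- txInfo(annotation)
  ex <- unlist(exl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(exl)
  ex$type <- "exon"
  ex$transcript_id <- rep(td$transcript_id, n)
  ex$gene_id <- rep(td$gene_id, n)
  ex$gene_biotype <- rep(td$biotype, n)
  cd <- unlist(cdl, use.names = FALSE)
  ncd <- S4Vectors::elementNROWS(cdl)
  if (length(cd)) {
    cd$type <- "CDS"
    cd$transcript_id <- rep(td$transcript_id, ncd)
    cd$gene_id <- rep(td$gene_id, ncd)
    cd$gene_biotype <- rep(td$biotype, ncd)
    # reading frame per piece (5'->3' cumulative length)
    cw <- GenomicRanges::width(cd)
    grp <- rep(seq_along(cdl), ncd)
    before <- unlist(lapply(split(cw, grp), function(v)
      cumsum(c(0L, v[-length(v)]))), use.names = FALSE)
    cd$phase <- (3L - before %% 3L) %% 3L
  }
  txr <- unlist(range(exl), use.names = FALSE)
  txr$type <- "transcript"
  txr$transcript_id <- td$transcript_id
  txr$gene_id <- td$gene_id
  txr$gene_biotype <- td$biotype
  all <- c(txr, ex, if (length(cd)) cd else GenomicRanges::GRanges())
  all <- sort(all, ignore.strand = TRUE)
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Representative transcript per gene
#'
#' One transcript per gene: longest summed CDS, ties broken by longest
#' transcript (summed exon length), then lexicographically smallest id.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return Named character vector: gene_id -> transcript_id.
#' @export
representativeTranscripts <- function(annotation) {
  td <- txInfo(annotation)
  cdsw <- sum(GenomicRanges::width(txCds(annotation)))
  txw <- sum(GenomicRanges::width(txExons(annotation)))
  dt <- data.table::data.table(
    gene = td$gene_id, tx = td$transcript_id,
    cdsw = as.numeric(cdsw), txw = as.numeric(txw))
  data.table::setorder(dt, gene, -cdsw, -txw, tx)
  sel <- dt[!duplicated(dt$gene)]
  setNames(sel$tx, sel$gene)
}

# genomic position -> transcript coordinate (1-based along mRNA); NA if not exonic
.g2t <- function(ex, gpos) {
  w <- GenomicRanges::width(ex)
  cum0 <- cumsum(c(0L, w[-length(w)]))
  plus <- as.character(GenomicRanges::strand(ex))[1] == "+"
  st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(ex)) {
    inside <- gpos >= st[i] & gpos <= en[i]
    out[inside] <- if (plus) cum0[i] + gpos[inside] - st[i] + 1L
                   else cum0[i] + en[i] - gpos[inside] + 1L
  }
  out
}

# transcript interval [a,b] -> genomic GRanges (in 5'->3' piece order)
.t2g <- function(ex, a, b) {
  w <- GenomicRanges::width(ex)
  cum <- cumsum(w)
  cum0 <- c(0L, cum[-length(cum)])
  plus <- as.character(GenomicRanges::strand(ex))[1] == "+"
  st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
  pieces <- list()
  for (i in seq_along(ex)) {
    lo <- max(a, cum0[i] + 1L); hi <- min(b, cum[i])
    if (lo > hi) next
    if (plus) {
      gs <- st[i] + (lo - cum0[i]) - 1L
      ge <- st[i] + (hi - cum0[i]) - 1L
    } else {
      ge <- en[i] - (lo - cum0[i]) + 1L
      gs <- en[i] - (hi - cum0[i]) + 1L
    }
    pieces[[length(pieces) + 1L]] <-
      GenomicRanges::GRanges(GenomicRanges::seqnames(ex)[i],
                             IRanges::IRanges(gs, ge),
                             strand = GenomicRanges::strand(ex)[i])
  }
  if (length(pieces)) do.call(c, pieces) else GenomicRanges::GRanges()
}

#' Derive labeled transcript regions for one representative isoform per gene
#'
#' Partitions the representative transcript's genomic span into 5' UTR, CDS,
#' 3' UTR and intron intervals (noncoding transcripts yield
#' \code{noncoding_exon} plus introns). Genes whose CDS does not map onto the
#' exon chain are flagged and excluded.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @param policy Representative-transcript policy; only \code{"longest_cds"}
#'   is implemented.
#' @return A \code{GRanges} of labeled intervals with metadata columns
#'   \code{gene_id}, \code{transcript_id}, \code{label}. Attribute
#'   \code{"flagged"} lists excluded genes; attribute \code{"lengths"} gives
#'   total length per label.
#' @export
deriveRegions <- function(annotation, policy = "longest_cds") {
  stopifnot(identical(policy, "longest_cds"))
  rep <- representativeTranscripts(annotation)
  exl <- txExons(annotation)[rep]
  cdl <- txCds(annotation)[rep]
  ntx <- length(exl)
  ex <- unlist(exl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(exl)
  txi <- rep(seq_len(ntx), n)
  st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
  w <- en - st + 1L
  cum <- unlist(lapply(split(w, txi), cumsum), use.names = FALSE)
  cum0 <- cum - w
  first <- cumsum(n) - n + 1L
  chromTx <- as.character(GenomicRanges::seqnames(ex))[first]
  plusTx <- (as.character(GenomicRanges::strand(ex)) == "+")[first]
  strandTx <- ifelse(plusTx, "+", "-")
  txlen <- cum[cumsum(n)]

  # CDS boundaries in transcript coordinates (NA when unmappable)
  cdsAll <- unlist(cdl, use.names = FALSE)
  ncds <- S4Vectors::elementNROWS(cdl)
  coding <- ncds > 0L
  t1 <- rep(NA_integer_, ntx); t2 <- rep(NA_integer_, ntx)
  if (any(coding)) {
    cdsTx <- rep(seq_len(ntx), ncds)
    cmin <- tapply(GenomicRanges::start(cdsAll), cdsTx, min)
    cmax <- tapply(GenomicRanges::end(cdsAll), cdsTx, max)
    cidx <- as.integer(names(cmin))
    c5 <- ifelse(plusTx[cidx], cmin, cmax)
    c3 <- ifelse(plusTx[cidx], cmax, cmin)
    g2t <- function(gpos) {
      # exon containing gpos within its own transcript
      out <- rep(NA_integer_, length(gpos))
      for (q in seq_along(gpos)) {
        k <- which(txi == cidx[q] & st <= gpos[q] & en >= gpos[q])
        if (length(k) == 1L)
          out[q] <- if (plusTx[cidx[q]]) cum0[k] + gpos[q] - st[k] + 1L
                    else cum0[k] + en[k] - gpos[q] + 1L
      }
      out
    }
    t1[cidx] <- g2t(c5); t2[cidx] <- g2t(c3)
  }
  flagged <- names(rep)[coding & (is.na(t1) | is.na(t2))]
  okTx <- !(coding & (is.na(t1) | is.na(t2)))

  # label intervals in transcript coordinates, one row per (tx, label)
  labTx <- integer(0); labA <- integer(0); labB <- integer(0); labL <- character(0)
  addLab <- function(ix, a, b, lab) {
    keep <- which(a <= b)
    labTx <<- c(labTx, ix[keep]); labA <<- c(labA, a[keep])
    labB <<- c(labB, b[keep]); labL <<- c(labL, rep(lab, length(keep)))
  }
  cix <- which(coding & okTx); nix <- which(!coding & okTx)
  if (length(cix)) {
    addLab(cix, rep(1L, length(cix)), t1[cix] - 1L, "five_prime_utr")
    addLab(cix, t1[cix], t2[cix], "cds")
    addLab(cix, t2[cix] + 1L, txlen[cix], "three_prime_utr")
  }
  if (length(nix))
    addLab(nix, rep(1L, length(nix)), txlen[nix], "noncoding_exon")

  # intersect label tx-intervals with exon tx-intervals, map to genomic
  reps <- n[labTx]
  rTx <- rep(labTx, reps); rA <- rep(labA, reps); rB <- rep(labB, reps)
  rLab <- rep(labL, reps)
  eIdx <- unlist(lapply(labTx, function(i) which(txi == i)), use.names = FALSE)
  lo <- pmax(rA, cum0[eIdx] + 1L); hi <- pmin(rB, cum[eIdx])
  keep <- lo <= hi
  eK <- eIdx[keep]; loK <- lo[keep]; hiK <- hi[keep]
  plusK <- plusTx[rTx[keep]]
  gs <- ifelse(plusK, st[eK] + (loK - cum0[eK]) - 1L,
               en[eK] - (hiK - cum0[eK]) + 1L)
  ge <- ifelse(plusK, st[eK] + (hiK - cum0[eK]) - 1L,
               en[eK] - (loK - cum0[eK]) + 1L)
  regTx <- rTx[keep]; regLab <- rLab[keep]

  # introns between genomically adjacent exons of each kept transcript
  gOrd <- order(txi, st)
  sSt <- st[gOrd]; sEn <- en[gOrd]; sTx <- txi[gOrd]
  pair <- which(sTx[-length(sTx)] == sTx[-1L])
  pair <- pair[okTx[sTx[pair]]]
  iSt <- sEn[pair] + 1L; iEn <- sSt[pair + 1L] - 1L
  iTx <- sTx[pair]

  allTx <- c(regTx, iTx)
  res <- GenomicRanges::GRanges(
    chromTx[allTx],
    IRanges::IRanges(c(gs, iSt), c(ge, iEn)),
    strand = strandTx[allTx],
    gene_id = names(rep)[allTx],
    transcript_id = rep[allTx],
    label = c(regLab, rep("intron", length(iTx))))
  res <- sort(res, ignore.strand = TRUE)
  lens <- tapply(GenomicRanges::width(res), res$label, sum)
  attr(res, "flagged") <- flagged
  attr(res, "lengths") <- lens
  res
}

#' Classify exons as first/internal/last/single per transcript
#'
#' Ordinals follow transcript direction: on the minus strand the "first" exon
#' is the genomically rightmost one. Single-exon transcripts get ordinal
#' \code{single}.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return \code{GRanges} of exons with \code{exon_id}, \code{transcript_id},
#'   \code{gene_id} and \code{ordinal_class}.
#' @export
classifyExons <- function(annotation) {
  exl <- txExons(annotation)
  td <- txInfo(annotation)
  n <- unname(S4Vectors::elementNROWS(exl))
  gr <- unlist(exl, use.names = FALSE)
  txid <- rep(td$transcript_id, n)
  idx <- unlist(lapply(n, seq_len), use.names = FALSE)
  ntot <- rep(n, n)
  ord <- ifelse(ntot == 1L, "single",
         ifelse(idx == 1L, "first",
         ifelse(idx == ntot, "last", "internal")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    exon_id = paste0(txid, ":E", idx),
    transcript_id = txid,
    gene_id = rep(td$gene_id, n),
    ordinal_class = ord)
  gr
}

#' Annotated splice sites
#'
#' 5' splice sites are the first intronic nucleotide downstream of an exon;
#' 3' splice sites are the first exonic nucleotide of the downstream exon.
#' Sites are deduplicated across isoforms.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return Width-1 \code{GRanges} with metadata column \code{kind}
#'   (\code{"5ss"}/\code{"3ss"}).
#' @export
spliceSites <- function(annotation) {
  intr <- .annotatedIntrons(annotation)
  if (length(intr) == 0L)
    return(GenomicRanges::GRanges(kind = character(0)))
  plus <- as.character(GenomicRanges::strand(intr)) == "+"
  p5 <- ifelse(plus, GenomicRanges::start(intr), GenomicRanges::end(intr))
  p3 <- ifelse(plus, GenomicRanges::end(intr) + 1L, GenomicRanges::start(intr) - 1L)
  g5 <- GenomicRanges::GRanges(GenomicRanges::seqnames(intr),
                               IRanges::IRanges(p5, width = 1L),
                               strand = GenomicRanges::strand(intr), kind = "5ss")
  g3 <- GenomicRanges::GRanges(GenomicRanges::seqnames(intr),
                               IRanges::IRanges(p3, width = 1L),
                               strand = GenomicRanges::strand(intr), kind = "3ss")
  out <- c(g5, g3)
  out[!duplicated(paste(GenomicRanges::seqnames(out), GenomicRanges::start(out),
                        GenomicRanges::strand(out), out$kind))]
}

# unique introns across isoforms, with flanking-exon coordinates
.annotatedIntrons <- function(annotation) {
  exl <- txExons(annotation)
  keep <- S4Vectors::elementNROWS(exl) >= 2L
  if (!any(keep)) return(GenomicRanges::GRanges())
  exl <- exl[keep]
  gr <- unlist(exl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(exl)
  grp <- rep(seq_along(exl), n)
  idx <- unlist(lapply(n, seq_len), use.names = FALSE)
  up <- gr[idx < rep(n, n)]          # exon i (upstream of intron i)
  dn <- gr[idx > 1L]                 # exon i+1
  plus <- as.character(GenomicRanges::strand(up)) == "+"
  is <- ifelse(plus, GenomicRanges::end(up) + 1L, GenomicRanges::end(dn) + 1L)
  ie <- ifelse(plus, GenomicRanges::start(dn) - 1L, GenomicRanges::start(up) - 1L)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(up),
                                IRanges::IRanges(is, ie),
                                strand = GenomicRanges::strand(up))
  unique(out)
}

#' Enumerate alternative-polyadenylation (APA) events
#'
#' For genes with at least two isoforms differing in 3' end structure:
#' TandemUTR events when two last exons share their 5' boundary but differ in
#' 3' extent (distal region = the extension); ALE events when two isoforms
#' end in non-overlapping last exons. Other 3' differences are ignored.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return A \code{DataFrame} with columns \code{event_id}, \code{gene_id},
#'   \code{kind}, \code{proximal_tx}, \code{distal_tx} and \code{GRanges}
#'   columns \code{proximal_region}, \code{distal_region}.
#' @export
enumerateApaEvents <- function(annotation) {
  exl <- txExons(annotation)
  td <- txInfo(annotation)
  last <- unlist(exl[S4Vectors::elementNROWS(exl) >= 1L], use.names = FALSE)
  n <- S4Vectors::elementNROWS(exl)
  lastIdx <- cumsum(n)                     # last exon (5'->3' order) per tx
  le <- unlist(exl, use.names = FALSE)[lastIdx]
  names(le) <- td$transcript_id
  rows <- list()
  for (gene in unique(td$gene_id)) {
    ix <- which(td$gene_id == gene)
    if (length(ix) < 2L) next
    for (a in seq_along(ix)[-length(ix)]) for (b in seq(a + 1L, length(ix))) {
      ea <- le[ix[a]]; eb <- le[ix[b]]
      plus <- as.character(GenomicRanges::strand(ea)) == "+"
      s5a <- if (plus) GenomicRanges::start(ea) else GenomicRanges::end(ea)
      s5b <- if (plus) GenomicRanges::start(eb) else GenomicRanges::end(eb)
      wa <- GenomicRanges::width(ea); wb <- GenomicRanges::width(eb)
      if (s5a == s5b && wa != wb) {
        # TandemUTR: proximal = shared short exon, distal = extension
        shortIsA <- wa < wb
        short <- if (shortIsA) ea else eb
        long <- if (shortIsA) eb else ea
        distal <- GenomicRanges::setdiff(long, short)
        rows[[length(rows) + 1L]] <- list(
          gene_id = gene, kind = "TandemUTR",
          proximal_tx = td$transcript_id[ix[if (shortIsA) a else b]],
          distal_tx = td$transcript_id[ix[if (shortIsA) b else a]],
          proximal = GenomicRanges::granges(short), distal = distal)
      } else if (!IRanges::overlapsAny(ea, eb, ignore.strand = TRUE)) {
        # ALE: proximal = last exon starting 5'-most in transcript direction
        aFirst <- if (plus) s5a < s5b else s5a > s5b
        prox <- if (aFirst) ea else eb
        dist <- if (aFirst) eb else ea
        rows[[length(rows) + 1L]] <- list(
          gene_id = gene, kind = "ALE",
          proximal_tx = td$transcript_id[ix[if (aFirst) a else b]],
          distal_tx = td$transcript_id[ix[if (aFirst) b else a]],
          proximal = GenomicRanges::granges(prox), distal = GenomicRanges::granges(dist))
      }
    }
  }
  if (length(rows) == 0L)
    return(S4Vectors::DataFrame(event_id = character(0), gene_id = character(0),
                                kind = character(0)))
  df <- S4Vectors::DataFrame(
    event_id = sprintf("%s:%s", vapply(rows, `[[`, "", "gene_id"),
                       vapply(rows, `[[`, "", "kind")),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    kind = vapply(rows, `[[`, "", "kind"),
    proximal_tx = vapply(rows, `[[`, "", "proximal_tx"),
    distal_tx = vapply(rows, `[[`, "", "distal_tx"))
  df$proximal_region <- do.call(c, lapply(rows, `[[`, "proximal"))
  df$distal_region <- do.call(c, lapply(rows, `[[`, "distal"))
  dup <- duplicated(df$event_id)
  df[!dup, ]
}
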