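#' GenomeAnnotation: transcript models over a (possibly in-memory) genome
#'
#' Container for transcript models used throughout the package. Exons are
#' stored per transcript in 5'->3' transcript order (on the minus strand the
#' first exon is the genomically rightmost one); CDS spans are stored as
#' genomic ranges per transcript and may be empty for noncoding transcripts.
#' The genome sequence is optional and only required by the motif module and
#' the simulator.
#'
#' @slot exons A \link[GenomicRanges]{GRangesList}, one element per
#'   transcript, exons ordered 5'->3'.
#' @slot cds A \code{GRangesList} parallel to \code{exons} (zero-length
#'   elements for noncoding transcripts).
#' @slot txdata A \link[S4Vectors]{DataFrame} with one row per transcript:
#'   \code{transcript_id}, \code{gene_id}, \code{biotype}.
#' @slot genome A \link[Biostrings]{DNAStringSet} named by chromosome
#'   (may be empty).
#'
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(
    exons  = "GRangesList",
    cds    = "GRangesList",
    txdata = "DataFrame",
    genome = "DNAStringSet"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  ex <- object@exons
  if (length(ex) != nrow(object@txdata))
    msg <- c(msg, "exons and txdata must describe the same transcripts")
  if (!identical(names(ex), object@txdata$transcript_id))
    msg <- c(msg, "names(exons) must equal txdata$transcript_id")
  if (length(object@cds) != length(ex))
    msg <- c(msg, "cds must be parallel to exons")
  if (length(ex)) {
    str1 <- unlist(lapply(GenomicRanges::strand(ex), function(s)
      as.character(S4Vectors::runValue(s))[1]), use.names = FALSE)
    # exons sorted 5'->3' and non-overlapping within transcript
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    ok <- mapply(function(s, e, strd) {
      if (length(s) <= 1L) return(TRUE)
      if (strd == "+") all(s[-1] > e[-length(e)]) else all(e[-1] < s[-length(s)] )
    }, st, en, str1)
    if (!all(ok))
      msg <- c(msg, "exons must be non-overlapping and in 5'->3' order within each transcript")
    # cds contained in exon union
    ncds <- S4Vectors::elementNROWS(object@cds)
    has <- which(ncds > 0L)
    if (length(has)) {
      inside <- vapply(has, function(i) {
        all(IRanges::overlapsAny(object@cds[[i]],
                                 GenomicRanges::reduce(ex[[i]]), type = "within"))
      }, logical(1))
      if (!all(inside)) msg <- c(msg, "CDS ranges must lie within the exon union")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenomeAnnotation Compact summary.
#' @param object A \code{GenomeAnnotation}.
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@exons), "transcripts,",
      length(unique(object@txdata$gene_id)), "genes\n")
  ncod <- sum(S4Vectors::elementNROWS(object@cds) > 0L)
  cat("  coding transcripts:", ncod, "\n")
  if (length(object@genome))
    cat("  genome:", length(object@genome), "sequences,",
        sum(Biostrings::width(object@genome)), "bp\n")
  else cat("  genome: <absent>\n")
})

#' Accessors for GenomeAnnotation
#'
#' \code{txExons} returns the per-transcript exon \code{GRangesList} (5'->3'
#' order); \code{txCds} the parallel CDS list; \code{txInfo} the transcript
#' table; \code{genomeSeq} the genome sequence; \code{geneSpans} one range per
#' gene covering the pre-mRNA span (exons plus introns of all isoforms).
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return See description.
#' @export
txExons <- function(annotation) annotation@exons

#' @rdname txExons
#' @export
txCds <- function(annotation) annotation@cds

#' @rdname txExons
#' @export
txInfo <- function(annotation) annotation@txdata

#' @rdname txExons
#' @export
genomeSeq <- function(annotation) annotation@genome

#' @rdname txExons
#' @export
geneSpans <- function(annotation) {
  rng <- unlist(range(annotation@exons), use.names = FALSE)
  names(rng) <- names(annotation@exons)
  spl <- split(rng, annotation@txdata$gene_id)
  out <- unlist(range(spl), use.names = TRUE)
  out
}

# internal constructor
.GenomeAnnotation <- function(exons, cds, txdata, genome = Biostrings::DNAStringSet()) {
  new("GenomeAnnotation", exons = exons, cds = cds, txdata = txdata,
      genome = genome)
}
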