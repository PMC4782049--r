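## Plain-text interchange: cDNA/read tables, BED6, bedGraph.

#' Write / read the cDNA read table
#'
#' Tab-separated with columns library, chrom, start, end, strand, cigar,
#' barcode (1-based closed coordinates).
#'
#' @param reads Read table.
#' @param path Output path.
#' @return \code{path} (writer) or the read table (reader), invisibly for
#'   the writer.
#' @export
writeCdnaTable <- function(reads, path) {
  data.table::fwrite(data.table::as.data.table(reads), path, sep = "\t")
  invisible(path)
}

#' @rdname writeCdnaTable
#' @export
readCdnaTable <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = c("library",
                                    "chrom", "strand", "cigar", "barcode"))))
}

#' Write width-anything GRanges as BED6
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @param score Numeric score column.
#' @param name Name column.
#' @export
writeBed6 <- function(gr, path, score = 0, name = ".") {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score,
                   strand = as.character(GenomicRanges::strand(gr)))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write per-position event counts as bedGraph (one file per strand label)
#'
#' @param events Width-1 \code{GRanges} with \code{count}.
#' @param path Output path.
#' @export
writeBedGraph <- function(events, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(events)),
                   start = GenomicRanges::start(events) - 1L,
                   end = GenomicRanges::end(events),
                   count = events$count)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
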