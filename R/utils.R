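## Internal helpers shared across modules.

#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom stats p.adjust chisq.test fisher.test wilcox.test rpois rnbinom
#'   rnorm runif rgeom rmultinom rbinom hclust as.dist lowess approx setNames
#'   integrate dbinom pchisq dnbinom qnorm
#' @importFrom utils modifyList
#' @importFrom matrixStats rowSds rowVars
#' @importFrom data.table data.table as.data.table rbindlist setorder fwrite
#'   fread dcast CJ setcolorder
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom ape write.tree as.phylo
#' @importFrom tools md5sum
NULL

.datatable.aware <- TRUE

# strand-aware 5' position of a range: leftmost base on +, rightmost on -
.start5 <- function(start, end, strand) ifelse(strand == "+", start, end)

# transcript-direction sign: +1 on plus strand, -1 on minus
.txdir <- function(strand) ifelse(strand == "+", 1L, -1L)

.sampleInt <- function(n, k, replace = FALSE) {
  # sample.int with sane behaviour for n = 0
  if (n == 0L) integer(0) else sample.int(n, k, replace = replace)
}

# uniform integer draws in [lo, hi]
.runifInt <- function(n, lo, hi) {
  if (n == 0L) return(integer(0))
  lo + .sampleInt(hi - lo + 1L, n, replace = TRUE) - 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# random fixed-length DNA barcodes
.randomBarcodes <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(c("A", "C", "G", "T")[.sampleInt(4L, n * len, TRUE)], nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

# reverse cumulative sum: out[h] = sum(x[h:H])
.revCumsum <- function(x) rev(cumsum(rev(x)))
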