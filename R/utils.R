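## Internal helpers shared across the package.

#' @importFrom stats rnorm runif rlnorm quantile sd cor pt setNames
#' @importFrom utils read.delim write.table head
NULL

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so package functions never perturb user RNG.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Merge 0-based half-open intervals (single chromosome). Returns a matrix
## with columns start, end, sorted, non-overlapping (touching runs fused).
mergeIntervals0 <- function(start, end) {
    if (length(start) == 0L)
        return(cbind(start = numeric(0), end = numeric(0)))
    o <- order(start, end)
    start <- start[o]; end <- end[o]
    ms <- start[1L]; me <- end[1L]
    outs <- numeric(0); oute <- numeric(0)
    for (i in seq_along(start)[-1L]) {
        if (start[i] <= me) me <- max(me, end[i])
        else { outs <- c(outs, ms); oute <- c(oute, me)
               ms <- start[i]; me <- end[i] }
    }
    cbind(start = c(outs, ms), end = c(oute, me))
}

## GRanges <-> 0-based half-open data.frame conversions. GRanges is the
## in-memory currency (1-based closed, the Bioconductor convention); text
## formats are 0-based half-open.
grFromBed0 <- function(chrom, start0, end0, id = NULL, score = NULL) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0))
    if (!is.null(id)) names(gr) <- id
    if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
    gr
}

bed0FromGr <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

#' Empirical one-sided p-value from exceedance counts
#'
#' Given the number of null draws attaining at least (or strictly more
#' than) the observed statistic, returns the empirical p-value
#' \code{nExceed / nShuffles}, optionally with the plus-one correction
#' \code{(nExceed + 1) / (nShuffles + 1)} that avoids reporting zero.
#'
#' @param nExceed number of null draws at or beyond the observed value.
#' @param nShuffles total number of null draws.
#' @param plusOne apply the plus-one correction.
#' @return A single numeric p-value.
#' @examples
#' empiricalPvalue(74, 10000)   # 0.0074
#' @export
empiricalPvalue <- function(nExceed, nShuffles, plusOne = FALSE) {
    stopifnot(length(nExceed) == 1L, length(nShuffles) == 1L,
              nShuffles >= 1, nExceed >= 0, nExceed <= nShuffles)
    if (plusOne) (nExceed + 1) / (nShuffles + 1) else nExceed / nShuffles
}

## paste-free unique pair keys
pairKey <- function(tf, tg) paste(tf, tg, sep = "\r")
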