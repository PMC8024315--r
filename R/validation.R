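## Scoring predicted networks against gold standards.

#' Directed-edge precision, recall and F1
#'
#' Both edge sets are first restricted to pairs whose two endpoints lie
#' in \code{universe}; matching is directed. Precision is TP/|predicted|,
#' recall TP/|gold|, F1 their harmonic mean (0 when both are 0).
#'
#' @param predicted,gold data.frames with columns \code{regulator},
#'   \code{target}.
#' @param universe character vector of gene identifiers defining the
#'   evaluation frame.
#' @return List with \code{predicted}, \code{gold}, \code{tp},
#'   \code{precision}, \code{recall}, \code{f1}.
#' @examples
#' pred <- data.frame(regulator = c("A", "B"), target = c("B", "C"))
#' gold <- data.frame(regulator = "A", target = "B")
#' edgeMetrics(pred, gold, c("A", "B", "C"))
#' @export
edgeMetrics <- function(predicted, gold, universe) {
    stopifnot(length(universe) > 0L)
    restrict <- function(df) {
        df <- df[df$regulator %in% universe & df$target %in% universe, ,
                 drop = FALSE]
        unique(pairKey(df$regulator, df$target))
    }
    p <- restrict(predicted)
    g <- restrict(gold)
    if (!length(g))
        stop("no gold edges inside the universe: recall undefined")
    tp <- sum(p %in% g)
    precision <- if (length(p)) tp / length(p) else 0
    recall <- tp / length(g)
    f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
    list(predicted = length(p), gold = length(g), tp = tp,
         precision = precision, recall = recall, f1 = f1)
}

#' TF binding precision against peak intervals
#'
#' Fraction of the distinct regulatory elements bound by a TF (the
#' elements of its CRMs across all its triplets) that overlap at least
#' one peak by >= 1 bp.
#'
#' @param net a [RegNetwork-class] (or subclass).
#' @param tf TF identifier (must have at least one triplet).
#' @param peaks \code{GRanges} of gold-standard binding peaks.
#' @return List with \code{fraction}, \code{overlapping}, \code{bound}.
#' @export
bindingPrecision <- function(net, tf, peaks) {
    tr <- triplets(net)
    sel <- which(tr$tf == tf)
    if (!length(sel)) stop("TF '", tf, "' has no triplet in the network")
    res <- unique(unlist(crms(net)[sel]))
    hits <- GenomicRanges::countOverlaps(res, peaks) > 0L
    list(fraction = if (length(res)) mean(hits) else 0,
         overlapping = sum(hits), bound = length(res))
}

#' Fold-change enrichment of predicted target genes
#'
#' \code{F = (Npb / Np) / (Nb / N)}: the share of predicted genes that
#' are biased, relative to the genome-wide share of biased genes.
#'
#' @param nPb predicted genes that are biased.
#' @param nP predicted genes.
#' @param nB biased genes.
#' @param n all genes.
#' @return The fold change (0 when \code{nPb} is 0).
#' @examples
#' targetEnrichmentFc(5, 10, 100, 1000)  # 5
#' @export
targetEnrichmentFc <- function(nPb, nP, nB, n) {
    if (nP <= 0 || nB <= 0) stop("nP and nB must be positive")
    stopifnot(nPb <= min(nP, nB), n >= max(nP, nB))
    if (nPb == 0) return(0)
    (nPb / nP) / (nB / n)
}

#' Biased expressed genes between two conditions
#'
#' A gene is called biased toward condition A when a two-sample Welch
#' t-test between its A and B samples gives p <= \code{alpha} and its
#' mean expression is higher in A.
#'
#' @param exprA,exprB genes x samples matrices for the two conditions
#'   (same row order).
#' @param alpha significance cutoff (default 0.05).
#' @param varEqual assume equal variances (default \code{FALSE}, the
#'   Welch variant).
#' @return Character vector of biased gene identifiers.
#' @importFrom stats t.test
#' @export
biasedGenes <- function(exprA, exprB, alpha = 0.05, varEqual = FALSE) {
    stopifnot(identical(rownames(exprA), rownames(exprB)))
    keep <- vapply(seq_len(nrow(exprA)), function(i) {
        a <- exprA[i, ]; b <- exprB[i, ]
        if (sd(a) == 0 && sd(b) == 0) return(FALSE)
        p <- tryCatch(t.test(a, b, var.equal = varEqual)$p.value,
                      error = function(e) 1)
        p <= alpha && mean(a) > mean(b)
    }, logical(1))
    rownames(exprA)[keep]
}

#' Nearest-TSS target assignment baseline
#'
#' Assigns each enhancer to the gene whose TSS is closest to the
#' enhancer's midpoint; ties break to the lexicographically smaller gene
#' id. Enhancers on chromosomes without any TSS are left unassigned
#' (\code{NA}) with a message.
#'
#' @param enhancers \code{GRanges} of enhancer intervals.
#' @param tss data.frame with columns \code{gene}, \code{chrom},
#'   \code{pos} (0-based TSS position).
#' @return Character vector of assigned genes, parallel to
#'   \code{enhancers} (names kept when present).
#' @export
nearestTssBaseline <- function(enhancers, tss) {
    chrom <- as.character(GenomicRanges::seqnames(enhancers))
    ## midpoint in 0-based coordinates of the half-open interval
    mid <- (GenomicRanges::start(enhancers) - 1 +
            GenomicRanges::end(enhancers)) / 2
    o <- order(tss$gene)
    tss <- tss[o, , drop = FALSE]
    out <- rep(NA_character_, length(enhancers))
    for (i in seq_along(enhancers)) {
        sel <- tss$chrom == chrom[i]
        if (!any(sel)) next
        d <- abs(tss$pos[sel] - mid[i])
        out[i] <- tss$gene[sel][which.min(d)]  # tss sorted by gene id
    }
    if (anyNA(out))
        message(sum(is.na(out)),
                " enhancer(s) on chromosomes without a TSS left unassigned")
    names(out) <- names(enhancers)
    out
}

#' Fraction of predicted regulations that are distal
#'
#' A predicted element-to-gene assignment is distal when the predicted
#' gene differs from the element's nearest-TSS gene, i.e. it could not be
#' recovered by the proximity baseline.
#'
#' @param predicted data.frame with columns \code{element}, \code{gene}.
#' @param nearest named character vector, element -> nearest-TSS gene
#'   (e.g. from [nearestTssBaseline()]).
#' @return List with \code{nDistal}, \code{nTotal}, \code{fraction}.
#' @export
distalRegulationFraction <- function(predicted, nearest) {
    stopifnot(all(predicted$element %in% names(nearest)))
    distal <- predicted$gene != nearest[predicted$element]
    list(nDistal = sum(distal), nTotal = nrow(predicted),
         fraction = mean(distal))
}
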