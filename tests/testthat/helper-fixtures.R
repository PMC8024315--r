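## Shared fixture builders. Everything is constructed in code; nothing is
## read from disk except through the package's own writers.

library(GenomicRanges)

## GRanges from 0-based half-open coordinates (test-side mirror of the
## package's file convention)
gr0 <- function(chrom, start0, end0, id = NULL) {
    gr <- GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
    if (!is.null(id)) names(gr) <- id
    gr
}

## a replicate network from a triplet table and a list of CRM GRanges
repNet <- function(tf, tg, score, crmList = NULL, weight = 1,
                   id = "rep") {
    tr <- data.frame(tf = tf, tg = tg, score = score,
                     stringsAsFactors = FALSE)
    if (is.null(crmList))
        crmList <- rep(list(GRanges()), nrow(tr))
    RegNetwork(tr, GRangesList(crmList), id = id, weight = weight)
}

## consensus-ready toy: R replicates sharing one (tf, tg) pair with
## scalar scores and a fixed single-interval CRM
scalarReplicates <- function(scores, crm = gr0("chr1", 0, 10),
                             weights = rep(1, length(scores))) {
    lapply(seq_along(scores), function(r)
        repNet("TF1", "TG1", scores[r], list(crm), weight = weights[r],
               id = paste0("rep", r)))
}

## edge data.frame in the regulator/target layout the validators expect
edgeDf <- function(net) setNames(edges(net), c("regulator", "target"))

## order-insensitive pair keys for comparing triplet tables
pairKey2 <- function(df) sort(paste(df$tf, df$tg))

## per-base membership of a position set in a GRanges (oracle helper)
basesOf <- function(gr) {
    if (length(gr) == 0L) return(character(0))
    ch <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    unlist(lapply(seq_along(gr), function(i)
        paste(ch[i], seq(s[i], e[i]), sep = ":")))
}

## independent fixed-point residual of a consensus solution: rebuilds the
## per-base replicate vectors from the replicate CRMs by enumeration and
## applies the clamped update maps once
fixedPointResidual <- function(cn, replicates, alpha, beta, gamma, mu) {
    wts <- vapply(replicates, replicateWeight, numeric(1))
    w <- sum(wts)
    tr <- triplets(cn)
    rel <- relaxedCrm(cn)
    resid <- 0
    for (p in seq_len(nrow(tr))) {
        f <- rel[[p]]
        ## genomic base labels of the union frame, in frame order
        bases <- unlist(lapply(seq_along(f$chrom), function(s)
            if (f$ends[s] > f$starts[s])
                paste(f$chrom[s], seq(f$starts[s] + 1, f$ends[s]),
                      sep = ":")
            else character(0)))
        Crep <- vapply(replicates, function(net) {
            tri <- triplets(net)
            i <- which(tri$tf == tr$tf[p] & tri$tg == tr$tg[p])
            if (!length(i)) return(rep(0, length(bases)))
            as.numeric(bases %in% basesOf(crms(net)[[i]]))
        }, numeric(length(bases)))
        Srep <- vapply(replicates, function(net) {
            tri <- triplets(net)
            i <- which(tri$tf == tr$tf[p] & tri$tg == tr$tg[p])
            if (!length(i)) 0 else tri$score[i]
        }, numeric(1))
        Cv <- f$values
        Sv <- tr$score[p]
        sNew <- max((2 * sum(wts * Srep) + beta * sum(Cv) - mu) / (2 * w),
                    0)
        if (length(Cv)) {
            nb <- c(0, Cv[-length(Cv)]) + c(Cv[-1], 0)
            cNew <- drop(Crep %*% wts) / w +
                beta / (2 * w * alpha) * Sv +
                gamma / (2 * w * alpha) * nb
            cNew <- pmin(pmax(cNew, 0), 1)
            resid <- max(resid, max(abs(cNew - Cv)))
        }
        resid <- max(resid, abs(sNew - Sv))
    }
    resid
}

## sharply peaked motif whose consensus is the given string
mkMotif <- function(cons, thresholdFrac = 0.9) {
    idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
    counts <- matrix(0, 4, length(idx))
    counts[cbind(idx, seq_along(idx))] <- 10
    motifFromCounts(counts, cons, thresholdFrac = thresholdFrac)
}

## brute-force both-strand PWM scan oracle (independent of the package's
## vectorized scanner)
bruteBinding <- function(pwm, sequence) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mat <- pwm@mat
    w <- ncol(mat)
    score1 <- function(s) {
        v <- strsplit(s, "")[[1]]
        if (any(!v %in% rownames(mat))) return(-Inf)
        sum(vapply(seq_len(w), function(p) mat[v[p], p], numeric(1)))
    }
    v <- strsplit(toupper(sequence), "")[[1]]
    n <- length(v)
    if (n < w) return(0)
    total <- 0
    for (o in 1:(n - w + 1)) {
        win <- paste(v[o:(o + w - 1)], collapse = "")
        rcw <- paste(rev(comp[v[o:(o + w - 1)]]), collapse = "")
        for (s in c(score1(win), score1(rcw)))
            if (s >= pwm@threshold) total <- total + s
    }
    total
}
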