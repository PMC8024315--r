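## Mapping SNPs, genes and genomic elements onto a network: subnetwork
## extraction, z-score filtering, SNP enrichment curves, allele-specific
## motif rescoring, and shuffle-based empirical overlap p-values.

#' Extract the subnetwork selected by genes, SNPs or regions
#'
#' Gene mode keeps triplets whose TG is in the gene set; SNP mode keeps
#' triplets whose (binarized) CRM contains a SNP position; region mode
#' keeps triplets whose CRM overlaps a region by >= 1 bp. Exactly one
#' selector must be supplied; matches are the union over selector
#' members and are recorded per retained triplet.
#'
#' @param net a [RegNetwork-class] (or subclass).
#' @param genes character vector of target genes.
#' @param snps data.frame with columns \code{chrom}, \code{pos} (0-based)
#'   and \code{rsid} (see [readSnpTable()]).
#' @param regions \code{GRanges} of genomic elements.
#' @return An [AnnotatedSubnetwork-class].
#' @export
extractSubnetwork <- function(net, genes = NULL, snps = NULL,
                              regions = NULL) {
    given <- c(genes = !is.null(genes), snps = !is.null(snps),
               regions = !is.null(regions))
    if (sum(given) != 1L)
        stop("supply exactly one of 'genes', 'snps', 'regions'")
    tr <- triplets(net)
    crm <- crms(net)
    if (given[["genes"]]) {
        keep <- which(tr$tg %in% genes)
        matches <- lapply(keep, function(i) tr$tg[i])
        selector <- "genes"
    } else if (given[["snps"]]) {
        pts <- grFromBed0(snps$chrom, snps$pos, snps$pos + 1)
        ov <- GenomicRanges::findOverlaps(crm, pts)
        byTriplet <- split(S4Vectors::subjectHits(ov),
                           S4Vectors::queryHits(ov))
        keep <- as.integer(names(byTriplet))
        matches <- lapply(byTriplet, function(j) unique(snps$rsid[j]))
        selector <- "snps"
    } else {
        ov <- GenomicRanges::findOverlaps(crm, regions)
        byTriplet <- split(S4Vectors::subjectHits(ov),
                           S4Vectors::queryHits(ov))
        keep <- as.integer(names(byTriplet))
        nm <- if (!is.null(names(regions))) names(regions)
              else as.character(regions)
        matches <- lapply(byTriplet, function(j) unique(nm[j]))
        selector <- "regions"
    }
    new("AnnotatedSubnetwork",
        triplets = tr[keep, , drop = FALSE], crm = crm[keep],
        id = paste0(net@id, ":", selector),
        selector = selector, matches = unname(matches),
        lambda = NA_real_)
}

#' Filter a subnetwork's CRMs by per-target z-score
#'
#' For each target gene, the strengths of its triplets (one per CRM) are
#' standardized with the population standard deviation; triplets with
#' z < \code{lambda} are removed. Targets with fewer than two triplets or
#' zero spread are kept untouched (their z is taken as 0 and they are
#' exempt from the cut).
#'
#' @param sub an [AnnotatedSubnetwork-class].
#' @param lambda z-score threshold (1.5 selects clearly dominant CRMs; 0
#'   keeps above-average ones).
#' @return The filtered [AnnotatedSubnetwork-class], \code{lambda}
#'   recorded.
#' @export
filterByZscore <- function(sub, lambda) {
    stopifnot(is.finite(lambda))
    tr <- triplets(sub)
    keep <- rep(TRUE, nrow(tr))
    for (g in unique(tr$tg)) {
        i <- which(tr$tg == g)
        s <- tr$score[i]
        sdp <- sqrt(mean((s - mean(s))^2))  # population sd
        if (length(i) < 2L || sdp == 0) next
        z <- (s - mean(s)) / sdp
        keep[i] <- z >= lambda
    }
    new("AnnotatedSubnetwork",
        triplets = tr[keep, , drop = FALSE], crm = crms(sub)[keep],
        id = sub@id, selector = sub@selector,
        matches = sub@matches[keep], lambda = lambda)
}

#' SNP fold-change enrichment curve over a p-value ladder
#'
#' Each SNP's p-value is the minimum over its traits. For each threshold
#' t of the ladder, with P SNPs at p <= t of which Pr fall inside the
#' (merged) regions, the fold change is \code{FC = (Pr / Lr) / (P / L)}
#' where Lr is the total region length and L the genome length. FC is
#' \code{NA} at thresholds with no SNP.
#'
#' @param snps data.frame from [readSnpTable()] (trait columns in the
#'   \code{"traits"} attribute, else all columns beyond chrom, pos,
#'   rsid, ref, alt).
#' @param regions \code{GRanges}; merged before length computation.
#' @param genome named vector of chromosome lengths.
#' @param ladder strictly decreasing p-value thresholds (default 1 down
#'   to 1e-9 by decades).
#' @return data.frame with columns \code{threshold}, \code{P},
#'   \code{Pr}, \code{fc}, plus attributes \code{Lr} and \code{L}.
#' @export
snpRegionFc <- function(snps, regions, genome, ladder = 10^-(0:9)) {
    if (any(diff(ladder) >= 0)) stop("ladder must be strictly decreasing")
    regions <- GenomicRanges::reduce(sort(regions))
    Lr <- sum(GenomicRanges::width(regions))
    if (Lr == 0) stop("regions have zero total length")
    L <- sum(genome)
    traits <- attr(snps, "traits")
    if (is.null(traits))
        traits <- setdiff(colnames(snps),
                          c("chrom", "pos", "rsid", "ref", "alt"))
    pmin_ <- do.call(pmin, c(unname(snps[traits]), list(na.rm = TRUE)))
    pts <- grFromBed0(snps$chrom, snps$pos, snps$pos + 1)
    inside <- GenomicRanges::countOverlaps(pts, regions) > 0L
    out <- data.frame(threshold = ladder, P = NA_integer_,
                      Pr = NA_integer_, fc = NA_real_)
    for (i in seq_along(ladder)) {
        sel <- pmin_ <= ladder[i]
        out$P[i] <- sum(sel)
        out$Pr[i] <- sum(sel & inside)
        if (out$P[i] > 0)
            out$fc[i] <- (out$Pr[i] / Lr) / (out$P[i] / L)
    }
    attr(out, "Lr") <- Lr
    attr(out, "L") <- L
    out
}

#' Most associated trait of a SNP
#'
#' @param snp one row of a SNP table (or any list with trait p-values).
#' @param traits trait column names; defaults to the \code{"traits"}
#'   attribute, else every numeric entry beyond chrom/pos/ref/alt/rsid.
#' @return List with \code{trait} and \code{p} (minimum p; ties break
#'   lexicographically by trait name).
#' @export
snpTopTrait <- function(snp, traits = NULL) {
    if (is.null(traits)) traits <- attr(snp, "traits")
    if (is.null(traits))
        traits <- setdiff(names(snp),
                          c("chrom", "pos", "rsid", "ref", "alt"))
    p <- unlist(snp[traits])
    p <- p[!is.na(p)]
    if (!length(p)) stop("SNP has no trait p-values")
    o <- order(p, names(p))
    list(trait = names(p)[o[1L]], p = unname(p[o[1L]]))
}

#' Allele-dependent motif gain and loss
#'
#' Rescans the windows covering a variant with every motif, on the
#' reference and the alternate allele, both strands. A motif is gained
#' when only the alternate allele reaches the hit threshold, lost when
#' only the reference does.
#'
#' @param sequence character DNA string containing the variant.
#' @param offset 1-based position of the variant within
#'   \code{sequence}.
#' @param ref,alt reference and alternate base; \code{sequence} must
#'   carry \code{ref} at \code{offset}.
#' @param pwms list of [MotifMatrix-class] objects.
#' @return data.frame with one row per motif: \code{motif},
#'   \code{bestRef}, \code{bestAlt} (best covering-window score per
#'   allele, \code{-Inf} when no window fits), \code{delta}
#'   (bestAlt - bestRef, 0 when neither allele has a window) and
#'   \code{status} (\code{"gained"}, \code{"lost"}, \code{"none"}).
#' @export
alleleMotifDiff <- function(sequence, offset, ref, alt, pwms) {
    v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    stopifnot(offset >= 1L, offset <= length(v))
    if (v[offset] != toupper(ref))
        stop("reference mismatch: sequence has '", v[offset],
             "' at offset ", offset, ", not '", ref, "'")
    valt <- v
    valt[offset] <- toupper(alt)
    n <- length(v)
    bestCovering <- function(codes, w) {
        lo <- max(1L, offset - w + 1L)
        hi <- min(offset, n - w + 1L)
        if (hi < lo) return(-Inf)
        lo:hi
    }
    scoreAllele <- function(pwm, chars) {
        codes <- .encodeDna(paste(chars, collapse = ""))
        w <- motifWidth(pwm)
        win <- bestCovering(codes, w)
        if (!is.numeric(win) || identical(win, -Inf)) return(-Inf)
        fwd <- .scoreOffsets(pwm@mat, codes)
        rc <- .scoreOffsets(pwm@mat, .REVCOMP[rev(codes)])
        ## reverse-strand window starting at forward offset o is window
        ## n - w + 2 - o of the reverse-complemented sequence
        rcwin <- n - motifWidth(pwm) + 2L - win
        max(fwd[win], rc[rcwin])
    }
    res <- lapply(pwms, function(pwm) {
        br <- scoreAllele(pwm, v)
        ba <- scoreAllele(pwm, valt)
        thr <- pwm@threshold
        status <- if (ba >= thr && br < thr) "gained"
                  else if (br >= thr && ba < thr) "lost" else "none"
        delta <- if (is.infinite(br) && is.infinite(ba)) 0 else ba - br
        data.frame(motif = motifId(pwm), bestRef = br, bestAlt = ba,
                   delta = delta, status = status)
    })
    do.call(rbind, res)
}

## fast per-chromosome overlap test against merged, sorted regions:
## a 0-based half-open query [s, e) overlaps some region iff the last
## region starting at or before s is still open past s, or another
## region starts before e.
.overlapIndex <- function(regions) {
    df <- bed0FromGr(GenomicRanges::reduce(sort(regions)))
    split(df[c("start", "end")], df$chrom)
}

.anyOverlap <- function(idx, chrom, s, e) {
    out <- logical(length(s))
    for (ch in unique(chrom)) {
        reg <- idx[[ch]]
        sel <- chrom == ch
        if (is.null(reg)) next
        i <- findInterval(s[sel], reg$start)
        hit <- (i >= 1L & reg$end[pmax(i, 1L)] > s[sel])
        j <- i + 1L
        hit <- hit | (j <= nrow(reg) & reg$start[pmin(j, nrow(reg))] < e[sel])
        out[sel] <- hit
    }
    out
}

#' Empirical overlap p-value by length-preserving shuffling
#'
#' Counts how many elements overlap at least one regulatory element by
#' >= 1 bp, then relocates every element uniformly at random
#' (preserving its length, and by default its chromosome) \code{nShuffles}
#' times. The empirical p-value is the fraction of shuffles whose
#' overlap count reaches the observed count; the strictly-greater
#' variant and the plus-one-corrected value are also reported.
#'
#' @param elements \code{GRanges} of query elements (e.g. conserved
#'   elements).
#' @param res \code{GRanges} of regulatory elements.
#' @param genome named vector of chromosome lengths.
#' @param nShuffles number of random relocations (>= 100).
#' @param seed RNG seed.
#' @param genomeWide relocate across chromosomes (sampled proportionally
#'   to length) instead of within each element's own chromosome.
#' @return List with \code{observed}, \code{exceedGe}, \code{exceedGt},
#'   \code{p} (>= observed), \code{pStrict} (> observed),
#'   \code{pPlusOne}, \code{nullCounts}.
#' @export
empiricalOverlapPvalue <- function(elements, res, genome, nShuffles = 1000,
                                   seed = 1, genomeWide = FALSE) {
    stopifnot(nShuffles >= 100)
    widths <- GenomicRanges::width(elements)
    chrom <- as.character(GenomicRanges::seqnames(elements))
    if (any(widths > max(genome)))
        stop("element longer than every chromosome")
    if (!genomeWide && any(widths > genome[chrom]))
        stop("element longer than its chromosome")
    idx <- .overlapIndex(res)
    s0 <- GenomicRanges::start(elements) - 1
    e0 <- GenomicRanges::end(elements)
    observed <- sum(.anyOverlap(idx, chrom, s0, e0))
    nE <- length(elements)
    nullCounts <- withSeed(seed, vapply(seq_len(nShuffles), function(b) {
        if (genomeWide) {
            ok <- outer(widths, genome, function(wd, gl) wd <= gl)
            ch <- vapply(seq_len(nE), function(i) {
                pool <- which(ok[i, ])
                names(genome)[sample(pool, 1L,
                                     prob = genome[pool])]
            }, "")
        } else ch <- chrom
        ns <- floor(runif(nE) * (genome[ch] - widths + 1))
        sum(.anyOverlap(idx, ch, ns, ns + widths))
    }, numeric(1)))
    ge <- sum(nullCounts >= observed)
    gt <- sum(nullCounts > observed)
    list(observed = observed, exceedGe = ge, exceedGt = gt,
         p = empiricalPvalue(ge, nShuffles),
         pStrict = empiricalPvalue(gt, nShuffles),
         pPlusOne = empiricalPvalue(ge, nShuffles, plusOne = TRUE),
         nullCounts = nullCounts)
}
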