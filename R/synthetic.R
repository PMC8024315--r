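## Seeded synthetic data: toy genomes, motifs, ground-truth networks,
## noisy replicate networks with paired data, and SNP panels. Everything
## is deterministic given the seed, so tests and calibration studies can
## regenerate inputs instead of shipping fixtures.

#' Synthetic study configuration
#'
#' Defaults describe the package's toy study: 2 chromosomes of 100 kb,
#' 20 TFs, 100 TGs, 300 regulatory elements, 6 replicates, score noise
#' at 20 percent of the mean truth strength, 10 bp CRM endpoint jitter.
#'
#' @param nChroms,chromLength genome shape.
#' @param nTfs,nTgs,nRes network size.
#' @param motifWidth planted motif width in bases.
#' @param motifThresholdFrac hit threshold as a fraction of each motif's
#'   maximum score; 0.9 keeps essentially only exact matches of the
#'   planted consensus, which makes the truth support identifiable.
#' @param edgeDensity probability a (TF, TG) pair is a truth edge.
#' @param nReplicates number of replicates to simulate.
#' @param sigmaSRel replicate score noise, relative to the mean truth
#'   strength.
#' @param crmJitter CRM endpoint jitter in bp.
#' @param sigmaE expression noise standard deviation.
#' @param windowKb candidate-element window around each TSS.
#' @param seed RNG seed.
#' @return A validated list of class \code{"TruthConfig"}.
#' @export
truthConfig <- function(nChroms = 2, chromLength = 1e5, nTfs = 20,
                        nTgs = 100, nRes = 300, motifWidth = 8,
                        motifThresholdFrac = 0.9,
                        edgeDensity = 0.1, nReplicates = 6,
                        sigmaSRel = 0.2, crmJitter = 10, sigmaE = 0.1,
                        windowKb = 200, seed = 1) {
    cfg <- list(nChroms = nChroms, chromLength = chromLength, nTfs = nTfs,
                nTgs = nTgs, nRes = nRes, motifWidth = motifWidth,
                motifThresholdFrac = motifThresholdFrac,
                edgeDensity = edgeDensity, nReplicates = nReplicates,
                sigmaSRel = sigmaSRel, crmJitter = crmJitter,
                sigmaE = sigmaE, windowKb = windowKb, seed = seed)
    counts <- cfg[c("nChroms", "chromLength", "nTfs", "nTgs", "nRes",
                    "motifWidth", "nReplicates")]
    stopifnot(all(unlist(counts) >= 1),
              cfg$edgeDensity > 0, cfg$edgeDensity <= 1,
              cfg$sigmaSRel >= 0, cfg$crmJitter >= 0, cfg$sigmaE >= 0)
    structure(cfg, class = "TruthConfig")
}

#' Generate a synthetic ground truth
#'
#' Builds a random genome, places non-overlapping regulatory elements,
#' draws one strong motif per TF, samples truth edges at the configured
#' density and plants each edge's motif inside 1-3 candidate elements of
#' its target, giving a truth network (S*, C*) with log-normal strengths
#' and a linear element-to-gene model (I*, intercepts) that generates
#' expression from accessibility.
#'
#' @param config a [truthConfig()].
#' @return List of class \code{"GroundTruth"}: \code{genome} (named
#'   character), \code{genomeIndex}, \code{elements} (\code{GRanges}),
#'   \code{sequences}, \code{pwms}, \code{tss}, \code{candidates},
#'   \code{model}, \code{access}, \code{expr}, \code{network} (the truth
#'   [RegNetwork-class]), \code{config}.
#' @export
generateTruth <- function(config = truthConfig()) {
    cfg <- config
    withSeed(cfg$seed, {
        chromNames <- paste0("chr", seq_len(cfg$nChroms))
        genome <- setNames(vapply(chromNames, function(ch)
            paste(sample(c("A", "C", "G", "T"), cfg$chromLength,
                         replace = TRUE), collapse = ""), ""), chromNames)
        genomeIndex <- setNames(rep(cfg$chromLength, cfg$nChroms),
                                chromNames)
        ## elements: one per block so they can never overlap
        perChrom <- diff(round(seq(0, cfg$nRes, length.out =
                                   cfg$nChroms + 1)))
        reChrom <- rep(chromNames, perChrom)
        reStart <- reWidth <- numeric(cfg$nRes)
        k <- 0L
        for (c2 in seq_len(cfg$nChroms)) {
            nblk <- perChrom[c2]
            if (!nblk) next
            blk <- floor(cfg$chromLength / nblk)
            if (blk < 320) stop("cannot place elements without overlap")
            w <- sample(150:300, nblk, replace = TRUE)
            s <- (seq_len(nblk) - 1) * blk +
                floor(runif(nblk) * (blk - w - 1))
            reStart[k + seq_len(nblk)] <- s
            reWidth[k + seq_len(nblk)] <- w
            k <- k + nblk
        }
        elements <- grFromBed0(reChrom, reStart, reStart + reWidth,
                               id = paste0("RE", seq_len(cfg$nRes)))
        tfs <- paste0("TF", seq_len(cfg$nTfs))
        tgs <- paste0("TG", seq_len(cfg$nTgs))
        genes <- c(tfs, tgs)
        tss <- data.frame(gene = genes,
                          chrom = sample(chromNames, length(genes),
                                         replace = TRUE),
                          pos = floor(runif(length(genes)) *
                                      cfg$chromLength))
        ## one strong motif per TF (dominant-base counts 12 vs 1)
        pwms <- lapply(tfs, function(tf) {
            cons <- sample(1:4, cfg$motifWidth, replace = TRUE)
            counts <- matrix(1, 4, cfg$motifWidth)
            counts[cbind(cons, seq_len(cfg$motifWidth))] <- 12
            motifFromCounts(counts, tf,
                            thresholdFrac = cfg$motifThresholdFrac)
        })
        names(pwms) <- tfs
        consensusOf <- vapply(pwms, function(p)
            paste(c("A", "C", "G", "T")[apply(p@mat, 2L, which.max)],
                  collapse = ""), "")
        candidates <- candidateElements(tss[tss$gene %in% tgs, ],
                                        elements, cfg$windowKb)
        ## truth edges + motif planting. Each element is used by at most
        ## one target gene: reuse across targets would couple one
        ## element's accessibility weight to several genes and make the
        ## truth support unidentifiable even without noise.
        edgeTf <- character(0); edgeTg <- character(0)
        edgeRes <- list()
        avail <- rep(TRUE, cfg$nRes)
        for (j in tgs) {
            D <- candidates[[j]]
            D <- D[avail[D]]
            if (!length(D)) next
            hit <- tfs[runif(cfg$nTfs) < cfg$edgeDensity]
            usedJ <- integer(0)
            for (tf in hit) {
                picked <- D[sample.int(length(D),
                                       min(sample(1:3, 1L), length(D)))]
                edgeTf <- c(edgeTf, tf); edgeTg <- c(edgeTg, j)
                edgeRes <- c(edgeRes, list(sort(picked)))
                usedJ <- union(usedJ, picked)
            }
            avail[usedJ] <- FALSE
        }
        reChromV <- as.character(GenomicRanges::seqnames(elements))
        reS0 <- GenomicRanges::start(elements) - 1
        reW <- GenomicRanges::width(elements)
        ## planted instances within one element must not overwrite each
        ## other (two TFs of the same target may share an element)
        occupied <- vector("list", cfg$nRes)
        for (e in seq_along(edgeTf)) {
            cons <- consensusOf[[edgeTf[e]]]
            for (k2 in edgeRes[[e]]) {
                off <- NA_integer_
                for (try in 1:100) {
                    cand <- sample.int(reW[k2] - cfg$motifWidth, 1L)
                    occ <- occupied[[k2]]
                    if (is.null(occ) ||
                        all(cand + cfg$motifWidth <= occ[, 1L] |
                            cand > occ[, 2L])) {
                        off <- cand
                        break
                    }
                }
                if (is.na(off)) off <- cand
                occupied[[k2]] <- rbind(occupied[[k2]],
                                        c(off, off + cfg$motifWidth - 1L))
                at <- reS0[k2] + off
                substr(genome[[reChromV[k2]]], at + 1L,
                       at + cfg$motifWidth) <- cons
            }
        }
        sequences <- Biostrings::DNAStringSet(setNames(
            vapply(seq_len(cfg$nRes), function(k3)
                substr(genome[[reChromV[k3]]], reS0[k3] + 1L,
                       reS0[k3] + reW[k3]), ""), names(elements)))
        ## truth strengths and CRMs
        sStar <- rlnorm(length(edgeTf), meanlog = 0, sdlog = 0.5)
        crm <- GRangesList(lapply(edgeRes, function(idx)
            GenomicRanges::reduce(sort(elements[idx]))))
        network <- RegNetwork(
            data.frame(tf = edgeTf, tg = edgeTg, score = sStar,
                       stringsAsFactors = FALSE),
            crm, id = "truth")
        ## linear element-to-gene model: nonzero weights exactly on the
        ## elements used by the gene's truth edges
        access <- setNames(rlnorm(cfg$nRes, 0, 0.25), names(elements))
        usedBy <- split(unlist(edgeRes), rep(edgeTg, lengths(edgeRes)))
        intercepts <- setNames(runif(cfg$nTgs, 0, 0.5), tgs)
        weights <- lapply(tgs, function(j) {
            D <- candidates[[j]]
            w <- setNames(rep(0, length(D)), as.character(D))
            used <- intersect(unique(usedBy[[j]]), D)
            w[as.character(used)] <- runif(length(used), 0.8, 1.2)
            w
        })
        names(weights) <- tgs
        model <- structure(list(intercepts = intercepts,
                                weights = weights,
                                candidates = candidates),
                           class = "InteractionModel")
        tgExpr <- vapply(tgs, function(j) {
            w <- weights[[j]]
            intercepts[[j]] + sum(w * access[as.integer(names(w))])
        }, numeric(1))
        expr <- c(setNames(rlnorm(cfg$nTfs, 0.5, 0.4), tfs),
                  pmax(tgExpr, 0))
        structure(list(genome = genome, genomeIndex = genomeIndex,
                       elements = elements, sequences = sequences,
                       pwms = pwms, tss = tss, candidates = candidates,
                       model = model, access = access, expr = expr,
                       network = network, config = cfg),
                  class = "GroundTruth")
    })
}

## jitter CRM interval endpoints by +/- jitter bp, clipped to the
## chromosome, dropping degenerate results back to the original
.jitterCrm0 <- function(df, jitter, genomeIndex) {
    if (!nrow(df) || jitter == 0) return(df)
    s <- df$start + sample(-jitter:jitter, nrow(df), replace = TRUE)
    e <- df$end + sample(-jitter:jitter, nrow(df), replace = TRUE)
    s <- pmax(s, 0)
    e <- pmin(e, genomeIndex[df$chrom])
    bad <- s >= e
    s[bad] <- df$start[bad]; e[bad] <- df$end[bad]
    data.frame(chrom = df$chrom, start = s, end = e)
}

#' Simulate noisy replicate networks and paired data
#'
#' Each replicate's strength matrix is the truth plus i.i.d. Gaussian
#' noise clamped at zero, so noise also creates spurious edges on
#' non-truth pairs (carrying one random candidate element as CRM). Truth
#' CRMs get their endpoints jittered. Paired raw data (expression
#' generated from accessibility through the truth model, plus noise) are
#' emitted alongside the networks.
#'
#' @param truth a \code{"GroundTruth"} from [generateTruth()].
#' @param nReplicates number of replicates (default from the config).
#' @param sigmaS absolute score noise; default
#'   \code{sigmaSRel * mean(truth strengths)}.
#' @param crmJitter,sigmaE noise settings (defaults from the config).
#' @param seed RNG seed.
#' @return List with \code{networks} (list of
#'   [ReplicateNetwork-class]) and \code{data} (per replicate: named
#'   \code{expr} and \code{access} vectors).
#' @export
simulateReplicates <- function(truth, nReplicates = NULL, sigmaS = NULL,
                               crmJitter = NULL, sigmaE = NULL,
                               seed = 1) {
    cfg <- truth$config
    if (is.null(nReplicates)) nReplicates <- cfg$nReplicates
    if (is.null(sigmaS))
        sigmaS <- cfg$sigmaSRel * mean(triplets(truth$network)$score)
    if (is.null(crmJitter)) crmJitter <- cfg$crmJitter
    if (is.null(sigmaE)) sigmaE <- cfg$sigmaE
    tr <- triplets(truth$network)
    tfs <- paste0("TF", seq_len(cfg$nTfs))
    tgs <- paste0("TG", seq_len(cfg$nTgs))
    allPairs <- expand.grid(tf = tfs, tg = tgs, stringsAsFactors = FALSE)
    truthIdx <- match(pairKey(allPairs$tf, allPairs$tg),
                      pairKey(tr$tf, tr$tg))
    sFull <- ifelse(is.na(truthIdx), 0, tr$score[truthIdx])
    ## flat truth CRM table: one row per interval, tagged by truth triplet
    truthGl <- crms(truth$network)
    truthU <- unlist(truthGl, use.names = FALSE)
    truthFlat <- cbind(bed0FromGr(truthU),
                       tripletOf = rep(seq_along(truthGl),
                                       lengths(truthGl)))
    ## candidate lookup for spurious-pair CRMs
    candFlat <- unlist(truth$candidates, use.names = FALSE)
    candLen <- lengths(truth$candidates)
    candOff <- setNames(cumsum(c(0, candLen[-length(candLen)])),
                        names(truth$candidates))
    candLen <- setNames(candLen, names(truth$candidates))
    elDf <- bed0FromGr(truth$elements)
    withSeed(seed, {
        networks <- vector("list", nReplicates)
        data <- vector("list", nReplicates)
        for (r in seq_len(nReplicates)) {
            sR <- sFull + rnorm(length(sFull), 0, sigmaS)
            keep <- which(sR > 0)
            repTr <- data.frame(tf = allPairs$tf[keep],
                                tg = allPairs$tg[keep],
                                score = sR[keep],
                                stringsAsFactors = FALSE)
            posInKeep <- rep(NA_integer_, length(sFull))
            posInKeep[keep] <- seq_along(keep)
            ## truth pairs: jittered truth intervals
            tKeep <- truthFlat[!is.na(posInKeep[match(
                pairKey(tr$tf, tr$tg)[truthFlat$tripletOf],
                pairKey(allPairs$tf, allPairs$tg))]), , drop = FALSE]
            tPair <- match(pairKey(tr$tf, tr$tg)[tKeep$tripletOf],
                           pairKey(allPairs$tf, allPairs$tg))
            tJit <- .jitterCrm0(tKeep, crmJitter, truth$genomeIndex)
            ## spurious pairs: one random candidate element of the target
            sp <- keep[is.na(truthIdx[keep])]
            spTg <- allPairs$tg[sp]
            hasD <- candLen[spTg] > 0
            sp <- sp[hasD]; spTg <- spTg[hasD]
            pick <- candFlat[candOff[spTg] +
                             ceiling(runif(length(sp)) * candLen[spTg])]
            grp <- c(posInKeep[tPair], posInKeep[sp])
            flatDf <- data.frame(
                chrom = c(tJit$chrom, elDf$chrom[pick]),
                start = c(tJit$start, elDf$start[pick]),
                end = c(tJit$end, elDf$end[pick]))
            gr <- grFromBed0(flatDf$chrom, flatDf$start, flatDf$end)
            crm <- GenomicRanges::reduce(S4Vectors::split(
                gr, factor(grp, levels = seq_along(keep))))
            networks[[r]] <- RegNetwork(repTr, crm,
                                        id = paste0("rep", r), weight = 1)
            accessR <- truth$access * exp(rnorm(length(truth$access),
                                                0, 0.1))
            tgExpr <- vapply(tgs, function(j) {
                w <- truth$model$weights[[j]]
                truth$model$intercepts[[j]] +
                    sum(w * accessR[as.integer(names(w))]) +
                    rnorm(1, 0, sigmaE)
            }, numeric(1))
            exprR <- c(truth$expr[tfs] *
                           exp(rnorm(length(tfs), 0, 0.1)),
                       pmax(tgExpr, 0))
            data[[r]] <- list(expr = exprR, access = accessR)
        }
        list(networks = networks, data = data)
    })
}

#' Simulate a SNP association panel
#'
#' Causal SNPs are placed uniformly over the truth CRM bases with
#' minimum-trait p-values drawn as \code{10^-Uniform(5, 9)}; background
#' SNPs are placed uniformly over the genome with Uniform(0, 1)
#' p-values on every trait.
#'
#' @param truth a \code{"GroundTruth"}.
#' @param nCausal,nBackground SNP counts.
#' @param nTraits number of trait p-value columns.
#' @param seed RNG seed.
#' @return SNP data.frame in the [readSnpTable()] layout, causal SNPs
#'   flagged in a \code{causal} attribute.
#' @export
simulateSnpPanel <- function(truth, nCausal = 50, nBackground = 500,
                             nTraits = 3, seed = 1) {
    crmAll <- GenomicRanges::reduce(sort(unlist(crms(truth$network))))
    if (nCausal > 0 && length(crmAll) == 0L)
        stop("truth network has no CRM bases to place causal SNPs in")
    totBases <- sum(GenomicRanges::width(crmAll))
    if (nCausal > totBases) stop("more causal SNPs than CRM bases")
    withSeed(seed, {
        place <- function(n, inCrm) {
            if (!n) return(data.frame(chrom = character(0),
                                      pos = numeric(0),
                                      causal = logical(0)))
            if (inCrm) {
                iv <- sample.int(length(crmAll), n, replace = TRUE,
                                 prob = GenomicRanges::width(crmAll))
                pos <- GenomicRanges::start(crmAll)[iv] - 1 +
                    floor(runif(n) * GenomicRanges::width(crmAll)[iv])
                data.frame(chrom = as.character(
                    GenomicRanges::seqnames(crmAll))[iv], pos = pos,
                    causal = TRUE)
            } else {
                ch <- sample(names(truth$genomeIndex), n, replace = TRUE,
                             prob = truth$genomeIndex)
                data.frame(chrom = ch,
                           pos = floor(runif(n) * truth$genomeIndex[ch]),
                           causal = FALSE)
            }
        }
        df <- rbind(place(nCausal, TRUE), place(nBackground, FALSE))
        n <- nrow(df)
        ref <- substr(mapply(function(ch, p)
            substr(truth$genome[[ch]], p + 1, p + 1),
            df$chrom, df$pos), 1, 1)
        alt <- vapply(ref, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        pmat <- matrix(runif(n * nTraits), n, nTraits)
        if (nCausal > 0) {
            target <- 10^-runif(nCausal, 5, 9)
            hitTrait <- sample.int(nTraits, nCausal, replace = TRUE)
            for (i in seq_len(nCausal)) {
                pmat[i, ] <- pmax(pmat[i, ], target[i])
                pmat[i, hitTrait[i]] <- target[i]
            }
        }
        colnames(pmat) <- paste0("trait", seq_len(nTraits))
        out <- data.frame(chrom = df$chrom, pos = df$pos,
                          rsid = paste0("rs", seq_len(n)),
                          ref = ref, alt = unname(alt), pmat,
                          stringsAsFactors = FALSE)
        attr(out, "traits") <- colnames(pmat)
        attr(out, "causal") <- df$causal
        rownames(out) <- NULL
        out
    })
}
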