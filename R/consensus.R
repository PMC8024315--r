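## Consensus integration of replicate networks.
##
## Given R replicate networks (S^r, C^r), the consensus (S, C) minimizes
##
##   Q = sum_{i,j,r} w_r { (S_ij - S^r_ij)^2 + alpha ||C_ij - C^r_ij||^2 }
##       - beta sum_{i,j} S_ij ||C_ij||_1
##       - gamma sum_{i,j,q} C_ijq C_ij(q-1) + mu ||S||_1
##
## subject to S_ij >= 0 and (relaxed) C_ijq in [0, 1]. The stationarity
## conditions give the fixed-point updates
##
##   S_ij  <- (2 sum_r w_r S^r_ij + beta ||C_ij||_1 - mu) / (2w)
##   C_ijq <- (1/w) sum_r w_r C^r_ijq + beta/(2 w alpha) S_ij
##            + gamma/(2 w alpha) (C_ij(q-1) + C_ij(q+1))
##
## (w = sum_r w_r, boundary neighbours 0), iterated Jacobi-style with the
## previous iterate on the right-hand side and projection onto the
## feasible set after every update.

## ---- frame alignment ----------------------------------------------------

## One frame per (tf, tg) pair: the merged union span of all replicate
## CRMs as 0-based half-open segments, plus an R x L binary matrix with
## one row per replicate (1 exactly on that replicate's CRM bases).

## flatten a network's CRMs once: interval vectors plus, per triplet,
## the rows that belong to it (avoids per-triplet GRanges extraction)
.flatCrms <- function(net) {
    gl <- crms(net)
    u <- unlist(gl, use.names = FALSE)
    n <- length(gl)
    grp <- rep(seq_len(n), lengths(gl))
    list(chrom = as.character(GenomicRanges::seqnames(u)),
         start = GenomicRanges::start(u) - 1,
         end = GenomicRanges::end(u),
         rows = split(seq_along(grp), factor(grp, levels = seq_len(n))))
}

#' Align replicate CRMs onto union coordinate frames
#'
#' For every TF-TG pair present in at least one replicate, builds the
#' union span of the replicate CRMs (sorted merged segments, possibly on
#' several chromosomes) and the per-replicate binary base vectors on that
#' span. Pairs absent from a replicate get an all-zero vector.
#'
#' @param replicates list of [ReplicateNetwork-class] objects.
#' @return List with \code{pairs} (data.frame tf, tg), \code{frames}
#'   (list parallel to pairs; each has \code{chrom}, \code{starts},
#'   \code{ends}, \code{L}, and binary matrix \code{C} of dimension
#'   replicates x L), \code{Srep} (pairs x replicates score matrix) and
#'   \code{weights}.
#' @export
alignCrmFrames <- function(replicates) {
    stopifnot(length(replicates) >= 1L)
    R <- length(replicates)
    keys <- lapply(replicates, function(net) {
        tr <- triplets(net); pairKey(tr$tf, tr$tg)
    })
    allKeys <- unique(unlist(keys))
    split1 <- strsplit(allKeys, "\r", fixed = TRUE)
    pairs <- data.frame(tf = vapply(split1, `[[`, "", 1L),
                        tg = vapply(split1, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    idx <- vapply(keys, function(k) match(allKeys, k),
                  integer(length(allKeys)))
    idx <- matrix(idx, ncol = R)
    Srep <- matrix(0, nrow = length(allKeys), ncol = R)
    flat <- lapply(replicates, .flatCrms)
    for (r in seq_len(R)) {
        sc <- triplets(replicates[[r]])$score
        hit <- which(!is.na(idx[, r]))
        Srep[hit, r] <- sc[idx[hit, r]]
    }
    frames <- vector("list", length(allKeys))
    for (p in seq_along(allKeys)) {
        rowsOf <- lapply(seq_len(R), function(r) {
            i <- idx[p, r]
            if (is.na(i)) integer(0) else flat[[r]]$rows[[i]]
        })
        nAll <- sum(lengths(rowsOf))
        if (!nAll) {
            frames[[p]] <- list(chrom = character(0), starts = numeric(0),
                                ends = numeric(0), L = 0L,
                                C = matrix(0, R, 0))
            next
        }
        allCh <- unlist(lapply(seq_len(R), function(r)
            flat[[r]]$chrom[rowsOf[[r]]]))
        allS <- unlist(lapply(seq_len(R), function(r)
            flat[[r]]$start[rowsOf[[r]]]))
        allE <- unlist(lapply(seq_len(R), function(r)
            flat[[r]]$end[rowsOf[[r]]]))
        chroms <- sort(unique(allCh))
        segC <- character(0); segS <- numeric(0); segE <- numeric(0)
        for (ch in chroms) {
            sel <- allCh == ch
            mg <- mergeIntervals0(allS[sel], allE[sel])
            segC <- c(segC, rep(ch, nrow(mg)))
            segS <- c(segS, unname(mg[, 1L]))
            segE <- c(segE, unname(mg[, 2L]))
        }
        segLen <- segE - segS
        off <- cumsum(c(0, segLen[-length(segLen)]))
        L <- sum(segLen)
        C <- matrix(0, R, L)
        repOf <- rep(seq_len(R), lengths(rowsOf))
        for (q in seq_len(nAll)) {
            seg <- which(segC == allCh[q] & segS <= allS[q] &
                         segE >= allE[q])[1L]
            a <- off[seg] + (allS[q] - segS[seg])
            C[repOf[q], (a + 1):(a + allE[q] - allS[q])] <- 1
        }
        frames[[p]] <- list(chrom = segC, starts = segS, ends = segE,
                            L = L, C = C)
    }
    list(pairs = pairs, frames = frames, Srep = Srep,
         weights = vapply(replicates, replicateWeight, numeric(1)))
}

## relaxed per-base values -> CRM intervals (values >= threshold become 1,
## maximal runs of 1 become intervals in genome coordinates)
.binarizeFrame0 <- function(frame, values, cThreshold) {
    empty <- list(chrom = character(0), start = numeric(0),
                  end = numeric(0))
    if (!length(values)) return(empty)
    b <- values >= cThreshold
    if (!any(b)) return(empty)
    segLen <- frame$ends - frame$starts
    off <- cumsum(c(0, segLen[-length(segLen)]))
    chV <- character(0); sV <- numeric(0); eV <- numeric(0)
    for (seg in seq_along(segLen)) {
        bb <- b[(off[seg] + 1):(off[seg] + segLen[seg])]
        r <- rle(bb)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        on <- which(r$values)
        if (!length(on)) next
        chV <- c(chV, rep(frame$chrom[seg], length(on)))
        sV <- c(sV, frame$starts[seg] + starts[on] - 1)
        eV <- c(eV, frame$starts[seg] + ends[on])
    }
    list(chrom = chV, start = sV, end = eV)
}

## assemble one GRangesList from per-pair interval vectors in one flat
## construction (per-pair GRanges creation is too slow at scale)
.grlFromDfs <- function(dfs) {
    n <- length(dfs)
    nIv <- vapply(dfs, function(d) length(d$start), integer(1))
    gr <- grFromBed0(unlist(lapply(dfs, `[[`, "chrom")),
                     unlist(lapply(dfs, `[[`, "start")),
                     unlist(lapply(dfs, `[[`, "end")))
    S4Vectors::split(gr, factor(rep(seq_len(n), nIv), levels = seq_len(n)))
}

.binarizeFrame <- function(frame, values, cThreshold) {
    df <- .binarizeFrame0(frame, values, cThreshold)
    sort(grFromBed0(df$chrom, df$start, df$end))
}

## ---- the solver ---------------------------------------------------------

#' Consensus optimization over replicate networks
#'
#' Integrates replicate networks into one consensus network by projected
#' fixed-point iteration on the stationarity conditions of the consensus
#' objective (see the package vignette). Iteration stops when both the
#' maximum strength change and the maximum per-base CRM change fall below
#' \code{eps}, or at \code{maxIter} (with a warning).
#'
#' @param replicates list of [ReplicateNetwork-class] objects.
#' @param alpha strength/CRM scale balance (> 0 required when
#'   \code{beta} or \code{gamma} is used).
#' @param beta strength-CRM consistency reward.
#' @param gamma base-continuity reward.
#' @param mu sparsity penalty on strengths.
#' @param eps convergence tolerance (> 0).
#' @param maxIter iteration cap.
#' @param frames optional precomputed [alignCrmFrames()] result (reused
#'   across parameter settings).
#' @param cThreshold relaxed values at or above this become CRM bases in
#'   the returned (binarized) CRMs; see [finalizeNetwork()].
#' @param id identifier for the returned network.
#' @return A [ConsensusNetwork-class] with optimized strengths, relaxed
#'   per-base CRM values, binarized CRMs, and solver diagnostics.
#' @examples
#' tr <- data.frame(tf = "A", tg = "B", score = 1)
#' crm <- GenomicRanges::GRangesList(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1, 10)))
#' reps <- list(RegNetwork(tr, crm, weight = 1),
#'              RegNetwork(transform(tr, score = 3), crm, weight = 1))
#' cn <- consensusOptimize(reps)
#' triplets(cn)  # consensus score 2
#' @export
consensusOptimize <- function(replicates, alpha = 1, beta = 0, gamma = 0,
                              mu = 0, eps = 1e-6, maxIter = 200,
                              frames = NULL, cThreshold = 0.5,
                              id = "consensus") {
    if ((beta > 0 || gamma > 0) && alpha <= 0)
        stop("alpha must be > 0 when beta or gamma is nonzero")
    stopifnot(eps > 0, maxIter >= 1)
    if (is.null(frames)) frames <- alignCrmFrames(replicates)
    wts <- frames$weights
    w <- sum(wts)
    nP <- nrow(frames$pairs)
    SW2 <- 2 * drop(frames$Srep %*% wts)
    m <- lapply(frames$frames, function(f)
        if (f$L) drop(wts %*% f$C) / w else numeric(0))
    bc <- if (alpha > 0) beta / (2 * w * alpha) else 0
    gc <- if (alpha > 0) gamma / (2 * w * alpha) else 0
    Shat <- SW2 / (2 * w)
    Chat <- m
    iter <- 0L; dS <- Inf; dC <- Inf; converged <- FALSE
    while (iter < maxIter) {
        iter <- iter + 1L
        l1 <- vapply(Chat, sum, numeric(1))
        S <- pmax((SW2 + beta * l1 - mu) / (2 * w), 0)
        C <- Chat
        if (bc > 0 || gc > 0) {
            for (p in seq_len(nP)) {
                v <- Chat[[p]]
                if (!length(v)) next
                nb <- if (gc > 0)
                    gc * (c(0, v[-length(v)]) + c(v[-1L], 0)) else 0
                C[[p]] <- pmin(pmax(m[[p]] + bc * Shat[p] + nb, 0), 1)
            }
        }
        dS <- if (nP) max(abs(S - Shat)) else 0
        dC <- if (nP) max(c(0, vapply(seq_len(nP), function(p) {
            if (!length(C[[p]])) 0 else max(abs(C[[p]] - Chat[[p]]))
        }, numeric(1)))) else 0
        if (dS < eps && dC < eps) {
            ## keep the pre-update iterate: at this point one application
            ## of the update maps moves every coordinate by < eps, which
            ## is the fixed-point property reported to callers
            converged <- TRUE
            break
        }
        Shat <- S; Chat <- C
    }
    if (!converged)
        warning("consensus iteration did not converge in ", maxIter,
                " iterations (dS = ", format(dS, digits = 3), ")")
    relaxed <- lapply(seq_len(nP), function(p) {
        f <- frames$frames[[p]]
        list(chrom = f$chrom, starts = f$starts, ends = f$ends,
             values = Chat[[p]])
    })
    crm <- .grlFromDfs(lapply(seq_len(nP), function(p)
        .binarizeFrame0(frames$frames[[p]], Chat[[p]], cThreshold)))
    tripletsDf <- data.frame(tf = frames$pairs$tf, tg = frames$pairs$tg,
                             score = Shat, stringsAsFactors = FALSE)
    new("ConsensusNetwork", triplets = tripletsDf, crm = crm, id = id,
        relaxed = relaxed,
        diagnostics = list(iterations = iter, dS = dS, dC = dC,
                           converged = converged,
                           parameters = list(alpha = alpha, beta = beta,
                                             gamma = gamma, mu = mu,
                                             eps = eps,
                                             weights = wts)))
}

#' Binarize and prune a consensus network
#'
#' Thresholds the relaxed per-base CRM values at \code{cThreshold}
#' (maximal runs of retained bases become CRM intervals) and drops
#' triplets whose strength is at or below \code{keepSmin} or whose
#' binarized CRM is empty.
#'
#' @param cn a [ConsensusNetwork-class] from [consensusOptimize()].
#' @param cThreshold relaxed-value cutoff in [0, 1] (default 0.5).
#' @param keepSmin minimum strength a triplet must exceed (default 0).
#' @return A pruned [ConsensusNetwork-class].
#' @export
finalizeNetwork <- function(cn, cThreshold = 0.5, keepSmin = 0) {
    rel <- relaxedCrm(cn)
    stopifnot(length(rel) == nrow(triplets(cn)))
    crm <- .grlFromDfs(lapply(rel, function(f)
        .binarizeFrame0(f, f$values, cThreshold)))
    keep <- triplets(cn)$score > keepSmin &
        vapply(as.list(crm), length, integer(1)) > 0L
    new("ConsensusNetwork",
        triplets = triplets(cn)[keep, , drop = FALSE],
        crm = crm[keep], id = cn@id, relaxed = rel[keep],
        diagnostics = c(diagnostics(cn),
                        list(cThreshold = cThreshold,
                             keepSmin = keepSmin)))
}

#' Naive replicate integration baselines
#'
#' Union: a TF-TG pair is kept when present in at least one replicate;
#' its strength is the mean over the replicates containing it and its CRM
#' the interval union. Intersection: kept only when present in all
#' replicates; strength is the mean and the CRM the interval
#' intersection (pairs with empty intersection are dropped).
#'
#' @param replicates list of [ReplicateNetwork-class] objects.
#' @param mode \code{"union"} or \code{"intersection"}.
#' @return A [ConsensusNetwork-class] (no relaxed values).
#' @export
baselineIntegrate <- function(replicates,
                              mode = c("union", "intersection")) {
    mode <- match.arg(mode)
    R <- length(replicates)
    frames <- alignCrmFrames(replicates)
    present <- matrix(FALSE, nrow(frames$pairs), R)
    for (r in seq_len(R)) {
        tr <- triplets(replicates[[r]])
        present[, r] <- pairKey(frames$pairs$tf, frames$pairs$tg) %in%
            pairKey(tr$tf, tr$tg)
    }
    nPresent <- rowSums(present)
    keep <- if (mode == "union") nPresent >= 1L else nPresent == R
    score <- rowSums(frames$Srep) / pmax(nPresent, 1L)
    crmFor <- function(p) {
        grs <- lapply(seq_len(R), function(r) {
            if (!present[p, r]) return(NULL)
            tr <- triplets(replicates[[r]])
            i <- match(pairKey(frames$pairs$tf[p], frames$pairs$tg[p]),
                       pairKey(tr$tf, tr$tg))
            crms(replicates[[r]])[[i]]
        })
        grs <- grs[!vapply(grs, is.null, logical(1))]
        if (!length(grs)) return(GenomicRanges::GRanges())
        if (mode == "union")
            GenomicRanges::reduce(sort(do.call(c, grs)))
        else
            Reduce(GenomicRanges::intersect, grs)
    }
    idx <- which(keep)
    crm <- GRangesList(lapply(idx, crmFor))
    tripletsDf <- data.frame(tf = frames$pairs$tf[idx],
                             tg = frames$pairs$tg[idx],
                             score = score[idx], stringsAsFactors = FALSE)
    if (mode == "intersection") {
        nonEmpty <- vapply(as.list(crm), length, integer(1)) > 0L
        tripletsDf <- tripletsDf[nonEmpty, , drop = FALSE]
        crm <- crm[nonEmpty]
    }
    new("ConsensusNetwork", triplets = tripletsDf, crm = crm,
        id = mode, relaxed = list(),
        diagnostics = list(mode = mode))
}

#' Grid search for consensus parameters by F1 against a gold standard
#'
#' Runs the consensus for every parameter setting, scores the finalized
#' edge set against a gold-standard edge list restricted to a gene
#' universe, and returns the setting with the highest F1 (ties: larger
#' recall, then smaller \code{mu}).
#'
#' @param grid data.frame with columns \code{alpha}, \code{beta},
#'   \code{gamma}, \code{mu}.
#' @param replicates list of [ReplicateNetwork-class] objects.
#' @param gold data.frame of gold edges (\code{regulator}, \code{target}).
#' @param universe gene identifiers defining the evaluation frame.
#' @param cThreshold,keepSmin finalization settings.
#' @param eps,maxIter solver settings.
#' @return List with \code{best} (the selected grid row), \code{metrics}
#'   (per-setting precision/recall/F1) and \code{network} (the selected
#'   finalized [ConsensusNetwork-class]).
#' @export
selectParameters <- function(grid, replicates, gold, universe,
                             cThreshold = 0.5, keepSmin = 0,
                             eps = 1e-6, maxIter = 200) {
    stopifnot(nrow(grid) >= 1L,
              all(c("alpha", "beta", "gamma", "mu") %in% colnames(grid)))
    frames <- alignCrmFrames(replicates)
    res <- vector("list", nrow(grid))
    metrics <- data.frame(grid, precision = NA_real_, recall = NA_real_,
                          f1 = NA_real_, edges = NA_integer_)
    for (g in seq_len(nrow(grid))) {
        cn <- consensusOptimize(replicates, alpha = grid$alpha[g],
                                beta = grid$beta[g], gamma = grid$gamma[g],
                                mu = grid$mu[g], eps = eps,
                                maxIter = maxIter, frames = frames)
        fin <- finalizeNetwork(cn, cThreshold = cThreshold,
                               keepSmin = keepSmin)
        res[[g]] <- fin
        if (nrow(triplets(fin))) {
            em <- edgeMetrics(
                setNames(edges(fin), c("regulator", "target")),
                gold, universe)
            metrics$precision[g] <- em$precision
            metrics$recall[g] <- em$recall
            metrics$f1[g] <- em$f1
        }
        metrics$edges[g] <- nrow(triplets(fin))
    }
    if (all(metrics$edges == 0L))
        stop("all parameter settings yield empty networks")
    ok <- which(!is.na(metrics$f1))
    best <- ok[order(-metrics$f1[ok], -metrics$recall[ok],
                     metrics$mu[ok])][1L]
    list(best = grid[best, , drop = FALSE], metrics = metrics,
         network = res[[best]])
}
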