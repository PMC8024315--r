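## Per-replicate regulatory network construction from one paired
## expression/accessibility sample. The trans-regulation score of TF i on
## TG j is
##
##   S_ij = (sum_k B_ik * RE_k * I_kj) * 2^|R_ij| * sqrt(TFA_i * TG_j)
##
## combining motif binding on the TG's candidate elements (B), element
## accessibility (RE), element-to-gene interaction weights learned on a
## paired panel (I), TF-TG expression correlation across the panel (R),
## TF activity (TFA) and TG expression.

#' Candidate regulatory elements per gene
#'
#' Assigns to each gene the elements whose interval lies within a window
#' of its TSS (any overlap of the window with the element counts).
#'
#' @param tss data.frame with columns \code{gene}, \code{chrom},
#'   \code{pos} (0-based TSS position).
#' @param elements \code{GRanges} of regulatory elements (named).
#' @param windowKb window half-width around the TSS, in kb (default 200).
#' @return Named list, gene -> integer indices into \code{elements}.
#' @export
candidateElements <- function(tss, elements, windowKb = 200) {
    w <- windowKb * 1000
    chrom <- as.character(GenomicRanges::seqnames(elements))
    s0 <- GenomicRanges::start(elements) - 1
    e0 <- GenomicRanges::end(elements)
    out <- lapply(seq_len(nrow(tss)), function(i) {
        which(chrom == tss$chrom[i] & s0 < tss$pos[i] + w &
              e0 > tss$pos[i] - w)
    })
    names(out) <- tss$gene
    out
}

#' Fit the element-to-gene interaction model on a paired panel
#'
#' For each gene j with candidate elements D_j, regresses the gene's
#' expression on its candidate elements' accessibility across panel
#' samples: \code{TG_j = I0_j + sum_{k in D_j} I_kj RE_k}. Ordinary least
#' squares when the design has full rank; otherwise a ridge penalty
#' \code{ridgeLambda} on the element weights (intercept unpenalized).
#'
#' @param panelExpr genes x samples matrix of panel expression.
#' @param panelAccess elements x samples matrix of panel accessibility
#'   (rows parallel to the element set the candidate indices refer to).
#' @param candidates named list gene -> integer element indices.
#' @param ridgeLambda ridge penalty; 0 requests plain OLS and errors when
#'   the design is underdetermined.
#' @param coefTol weights with absolute value below this are set to zero
#'   (exact-support recovery on noiseless data); default 0 keeps all.
#' @return List with class \code{"InteractionModel"}: \code{intercepts}
#'   (named numeric), \code{weights} (named list of named numeric vectors,
#'   names = element indices), \code{candidates}.
#' @export
fitInteractionModel <- function(panelExpr, panelAccess, candidates,
                                ridgeLambda = 0, coefTol = 0) {
    nS <- ncol(panelExpr)
    stopifnot(ncol(panelAccess) == nS)
    genes <- names(candidates)
    genes <- genes[genes %in% rownames(panelExpr)]
    intercepts <- setNames(numeric(length(genes)), genes)
    weights <- setNames(vector("list", length(genes)), genes)
    for (g in genes) {
        D <- candidates[[g]]
        y <- panelExpr[g, ]
        if (!length(D)) {
            intercepts[g] <- mean(y)
            weights[[g]] <- setNames(numeric(0), character(0))
            next
        }
        X <- cbind(1, t(panelAccess[D, , drop = FALSE]))
        p <- ncol(X)
        if (nS < p && ridgeLambda <= 0)
            stop("gene '", g, "': ", nS, " panel samples for ", p,
                 " parameters; set ridgeLambda > 0")
        if (ridgeLambda > 0) {
            P <- diag(c(0, rep(ridgeLambda, p - 1L)), p)
            beta <- solve(crossprod(X) + P, crossprod(X, y))
        } else {
            fit <- qr(X)
            if (fit$rank < p)
                stop("gene '", g, "': rank-deficient design; ",
                     "set ridgeLambda > 0")
            beta <- qr.coef(fit, y)
        }
        beta <- drop(beta)
        wts <- beta[-1L]
        if (coefTol > 0) wts[abs(wts) < coefTol] <- 0
        intercepts[g] <- beta[1L]
        weights[[g]] <- setNames(wts, as.character(D))
    }
    structure(list(intercepts = intercepts, weights = weights,
                   candidates = candidates[genes]),
              class = "InteractionModel")
}

#' TF-to-gene expression correlation across a panel
#'
#' Pearson correlation of each TF's and each gene's expression across the
#' panel samples; constant series give 0 by convention.
#'
#' @param panelExpr genes x samples matrix.
#' @param tfs,tgs gene identifiers (must be rows of \code{panelExpr}).
#' @return Matrix TF x TG of correlations in [-1, 1].
#' @export
expressionCorrelation <- function(panelExpr, tfs, tgs) {
    missing <- setdiff(c(tfs, tgs), rownames(panelExpr))
    if (length(missing))
        stop("genes absent from panel: ", paste(missing, collapse = ", "))
    if (ncol(panelExpr) < 3L) stop("need >= 3 panel samples")
    R <- suppressWarnings(
        cor(t(panelExpr[tfs, , drop = FALSE]),
            t(panelExpr[tgs, , drop = FALSE])))
    R[!is.finite(R)] <- 0
    dimnames(R) <- list(tfs, tgs)
    R
}

#' TF activity from expression and motif enrichment
#'
#' \code{TFA_i = sqrt(TF_i * E_i)} where \code{E_i} is the density of
#' motif i's hits in the open-element sequences divided by the mean
#' density over dinucleotide-shuffled copies of the same sequences
#' (floored at 1e-3; a half-hit pseudocount guards empty backgrounds).
#'
#' @param tfExpr named numeric vector of TF expression (names = motif
#'   ids), values >= 0.
#' @param pwms list of [MotifMatrix-class] objects.
#' @param openSequences character vector / \code{DNAStringSet} of open
#'   regulatory-element sequences.
#' @param shuffles number of shuffled background copies (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return Named numeric vector TFA (one entry per pwm), >= 0, zero
#'   exactly where the TF is unexpressed.
#' @export
tfActivity <- function(tfExpr, pwms, openSequences, shuffles = 10,
                       seed = 1) {
    if (shuffles < 1) stop("'shuffles' must be >= 1")
    seqs <- as.character(openSequences)
    totalBases <- sum(nchar(seqs))
    ids <- vapply(pwms, motifId, "")
    stopifnot(all(ids %in% names(tfExpr)), all(tfExpr >= 0))
    countHits <- function(pwm, ss) {
        sum(vapply(ss, function(s) nrow(scanMotif(pwm, s)), numeric(1)))
    }
    obs <- vapply(pwms, countHits, numeric(1), ss = seqs)
    bg <- withSeed(seed, {
        rowMeans(matrix(vapply(seq_len(shuffles), function(b) {
            sh <- vapply(seqs, dinucShuffle, "")
            vapply(pwms, countHits, numeric(1), ss = sh)
        }, numeric(length(pwms))), nrow = length(pwms)))
    })
    E <- pmax((obs + 0.5) / (bg + 0.5), 1e-3)
    setNames(sqrt(tfExpr[ids] * E), ids)
}

#' Trans-regulation score matrix
#'
#' Evaluates \code{S_ij = max(sum_k B_ik RE_k I_kj, 0) * 2^|R_ij| *
#' sqrt(TFA_i * TG_j)} over all TF/TG pairs. The inner sum is clamped at
#' zero so scores honor the non-negativity the consensus model requires.
#'
#' @param B motifs x elements binding matrix ([motifBindingMatrix()]).
#' @param access named numeric vector of element accessibility (parallel
#'   to \code{B} columns), >= 0.
#' @param model an \code{InteractionModel} from [fitInteractionModel()].
#' @param R TF x TG correlation matrix ([expressionCorrelation()]).
#' @param tfa named TF activity vector ([tfActivity()]).
#' @param tgExpr named numeric vector of TG expression, >= 0.
#' @return Non-negative TF x TG score matrix.
#' @export
transRegulationScores <- function(B, access, model, R, tfa, tgExpr) {
    M <- nrow(B)
    tgs <- names(tgExpr)
    if (length(access) != ncol(B))
        stop("accessibility length does not match binding matrix columns")
    if (length(tfa) != M || nrow(R) != M || ncol(R) != length(tgs))
        stop("dimension mismatch between B, R, tfa, tgExpr")
    stopifnot(all(tgExpr >= 0), all(access >= 0))
    inner <- matrix(0, M, length(tgs),
                    dimnames = list(rownames(B), tgs))
    for (j in seq_along(tgs)) {
        wts <- model$weights[[tgs[j]]]
        if (is.null(wts) || !length(wts)) next
        k <- as.integer(names(wts))
        inner[, j] <- drop(B[, k, drop = FALSE] %*% (access[k] * wts))
    }
    pmax(inner, 0) * 2^abs(R) * sqrt(outer(unname(tfa), unname(tgExpr)))
}

#' Build one replicate's regulatory network
#'
#' Runs the full per-replicate pipeline: motif binding on the elements,
#' TF activity, trans-regulation scores, edge retention at a quantile of
#' the positive scores, and CRM assembly. The CRM of a retained (i, j) is
#' the merged set of candidate elements of j on which TF i has a motif
#' hit.
#'
#' @param expr named numeric vector of normalized gene expression for
#'   this sample (TFs and TGs).
#' @param access named numeric vector of normalized element accessibility
#'   (> 0 filter already applied), parallel to \code{elements}.
#' @param elements \code{GRanges} of regulatory elements.
#' @param sequences element sequences (character or \code{DNAStringSet}),
#'   parallel to \code{elements}.
#' @param pwms list of [MotifMatrix-class]; motif ids are TF names.
#' @param model \code{InteractionModel} fitted on the paired panel.
#' @param corMat TF x TG panel expression correlation.
#' @param tgs target genes to score (default: genes of \code{model}).
#' @param tfa optional precomputed TF activity; computed from
#'   \code{expr}/\code{pwms} when \code{NULL}.
#' @param shuffles,seed background-shuffle settings for [tfActivity()].
#' @param sQuantile retain triplets scoring above this quantile of the
#'   positive scores (default 0.5).
#' @param minScore additional absolute floor on retained scores
#'   (default 0, i.e. any positive score can survive the quantile cut).
#' @param weight,id replicate weight and identifier.
#' @return A [ReplicateNetwork-class]; empty (with a warning) when no
#'   triplet survives.
#' @export
buildReplicateNetwork <- function(expr, access, elements, sequences, pwms,
                                  model, corMat,
                                  tgs = names(model$weights), tfa = NULL,
                                  shuffles = 10, seed = 1,
                                  sQuantile = 0.5, minScore = 0,
                                  weight = 1, id = "replicate") {
    tfs <- vapply(pwms, motifId, "")
    stopifnot(all(tfs %in% names(expr)), all(tgs %in% names(expr)))
    B <- motifBindingMatrix(sequences, pwms)
    if (is.null(tfa))
        tfa <- tfActivity(expr[tfs], pwms, sequences, shuffles = shuffles,
                          seed = seed)
    S <- transRegulationScores(B, access, model,
                               corMat[tfs, tgs, drop = FALSE],
                               tfa[tfs], expr[tgs])
    pos <- S[S > minScore]
    if (!length(pos)) {
        warning("empty network after filtering")
        return(RegNetwork(data.frame(tf = character(0), tg = character(0),
                                     score = numeric(0)),
                          id = id, weight = weight))
    }
    cut <- quantile(pos, sQuantile, names = FALSE, type = 7)
    keep <- which(S > minScore & S >= cut, arr.ind = TRUE)
    if (!nrow(keep)) {
        warning("empty network after filtering")
        return(RegNetwork(data.frame(tf = character(0), tg = character(0),
                                     score = numeric(0)),
                          id = id, weight = weight))
    }
    tr <- data.frame(tf = tfs[keep[, 1L]], tg = tgs[keep[, 2L]],
                     score = S[keep], stringsAsFactors = FALSE)
    crm <- GRangesList(lapply(seq_len(nrow(keep)), function(r) {
        D <- model$candidates[[tr$tg[r]]]
        bound <- D[B[keep[r, 1L], D] > 0]
        if (!length(bound)) return(GenomicRanges::GRanges())
        GenomicRanges::reduce(sort(elements[bound]))
    }))
    RegNetwork(tr, crm, id = id, weight = weight)
}
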