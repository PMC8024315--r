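## PWM scanning. Sequences are scored at every offset on both strands;
## a window is a hit when its log-odds score reaches the motif threshold.
## The per-element binding strength B[i, k] is the SUM of passing hit
## scores of motif i on element k, so multiple sites accumulate.

#' @importFrom Biostrings DNAStringSet
NULL

## DNA string -> integer codes 1..4 (A,C,G,T); anything else -> 5, which
## scores -Inf so ambiguous bases never create hits.
.encodeDna <- function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    code <- match(v, c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L
    code
}

.REVCOMP <- c(4L, 3L, 2L, 1L, 5L)

## Score every offset of `codes` with log-odds matrix `mat` (4 x w).
## Returns numeric(n - w + 1); numeric(0) when the motif is wider than
## the sequence.
.scoreOffsets <- function(mat, codes) {
    w <- ncol(mat)
    n <- length(codes)
    if (n < w) return(numeric(0))
    matx <- rbind(mat, rep(-Inf, w))
    sc <- numeric(n - w + 1L)
    for (p in seq_len(w))
        sc <- sc + matx[codes[p:(n - w + p)], p]
    sc
}

#' Scan a sequence with one motif
#'
#' Scores every window on both strands and reports the windows whose
#' log-odds score reaches the motif threshold. Offsets are 1-based
#' positions of the window start on the forward strand.
#'
#' @param pwm a [MotifMatrix-class].
#' @param sequence a character DNA string.
#' @return data.frame with columns \code{offset}, \code{strand},
#'   \code{score}; zero rows when there is no hit.
#' @examples
#' m <- motifFromCounts(matrix(c(12,0,0,0, 0,12,0,0), 4), "AC")
#' scanMotif(m, "TTACGG")
#' @export
scanMotif <- function(pwm, sequence) {
    codes <- .encodeDna(sequence)
    w <- motifWidth(pwm)
    n <- length(codes)
    fwd <- .scoreOffsets(pwm@mat, codes)
    rev <- .scoreOffsets(pwm@mat, .REVCOMP[rev(codes)])
    hitF <- which(fwd >= pwm@threshold)
    hitR <- which(rev >= pwm@threshold)
    data.frame(
        offset = c(hitF, if (length(hitR)) n - w + 2L - hitR else integer(0)),
        strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
        score = c(fwd[hitF], rev[hitR]))
}

## Best both-strand score over all windows (-Inf when none fit).
.bestScore <- function(pwm, codes) {
    fwd <- .scoreOffsets(pwm@mat, codes)
    rev <- .scoreOffsets(pwm@mat, .REVCOMP[rev(codes)])
    if (!length(fwd)) return(-Inf)
    max(fwd, rev)
}

#' Motif binding-strength matrix over regulatory elements
#'
#' For each motif i and element k, \code{B[i, k]} is the sum of the
#' log-odds scores of all both-strand windows of element k scoring at or
#' above motif i's threshold; 0 when there is no hit (including when the
#' motif is wider than the element).
#'
#' @param sequences a \code{DNAStringSet} or character vector of element
#'   sequences (one per regulatory element).
#' @param pwms list of [MotifMatrix-class] objects.
#' @return Non-negative numeric matrix, motifs x elements, dimnames set
#'   from motif ids and sequence names.
#' @export
motifBindingMatrix <- function(sequences, pwms) {
    seqs <- as.character(sequences)
    if (any(!nzchar(seqs))) stop("element without sequence")
    codes <- lapply(seqs, .encodeDna)
    B <- matrix(0, nrow = length(pwms), ncol = length(seqs),
                dimnames = list(vapply(pwms, motifId, ""), names(sequences)))
    for (i in seq_along(pwms)) {
        pwm <- pwms[[i]]
        for (k in seq_along(codes)) {
            fwd <- .scoreOffsets(pwm@mat, codes[[k]])
            if (!length(fwd)) next
            rev <- .scoreOffsets(pwm@mat, .REVCOMP[rev(codes[[k]])])
            sc <- c(fwd[fwd >= pwm@threshold], rev[rev >= pwm@threshold])
            if (length(sc)) B[i, k] <- sum(sc)
        }
    }
    B
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a DNA sequence preserving its exact dinucleotide
#' composition (Altschul-Erickson Euler-path method): edges of the
#' dinucleotide transition multigraph are shuffled and walked after fixing
#' per-vertex last-edges that keep the walk completable.
#'
#' @param sequence character DNA string.
#' @return A shuffled character string with identical dinucleotide counts.
#' @export
dinucShuffle <- function(sequence) {
    v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    n <- length(v)
    if (n < 3L) return(sequence)
    letters4 <- unique(v)
    succ <- lapply(letters4, function(b) v[which(v[-n] == b) + 1L])
    names(succ) <- letters4
    last <- v[n]
    verts <- letters4
    ## choose random last-edges so every vertex reaches `last`
    repeat {
        lastEdge <- vapply(verts, function(b) {
            if (b == last || !length(succ[[b]])) NA_character_
            else succ[[b]][sample.int(length(succ[[b]]), 1L)]
        }, "")
        ## connectivity check: follow last-edges toward `last`
        ok <- TRUE
        for (b in verts) {
            if (b == last || !length(succ[[b]])) next
            cur <- b; seen <- character(0)
            while (!is.na(cur) && cur != last && !(cur %in% seen)) {
                seen <- c(seen, cur)
                cur <- if (cur %in% verts) lastEdge[[cur]] else NA_character_
            }
            if (is.na(cur) || cur != last) { ok <- FALSE; break }
        }
        if (ok) break
    }
    ## shuffle the remaining edges, append the chosen last edge
    bags <- lapply(verts, function(b) {
        e <- succ[[b]]
        if (!is.na(lastEdge[[b]]) && length(e)) {
            drop <- match(lastEdge[[b]], e)
            e <- e[-drop]
        }
        c(if (length(e)) e[sample.int(length(e))] else character(0),
          if (!is.na(lastEdge[[b]])) lastEdge[[b]] else character(0))
    })
    names(bags) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- v[1L]
    cur <- v[1L]
    for (i in 2:n) {
        nxt <- bags[[cur]][ptr[[cur]]]
        ptr[[cur]] <- ptr[[cur]] + 1L
        out[i] <- nxt
        cur <- nxt
    }
    paste(out, collapse = "")
}
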