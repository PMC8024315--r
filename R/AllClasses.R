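#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom S4Vectors mcols
NULL

#' Position weight matrix with background model
#'
#' A log-odds position weight matrix over the DNA alphabet, together with
#' the background base frequencies it was computed against and the score
#' threshold used to call motif hits.
#'
#' @slot id motif identifier (typically the bound transcription factor).
#' @slot mat numeric matrix of per-position log-odds scores (log2 scale),
#'   rows named A, C, G, T.
#' @slot background named numeric vector of background base frequencies,
#'   summing to 1.
#' @slot threshold numeric score at or above which a window counts as a hit.
#'
#' @seealso [readJaspar()], [motifBindingMatrix()], [scanMotif()]
#' @export
setClass("MotifMatrix",
    representation(id = "character", mat = "matrix",
                   background = "numeric", threshold = "numeric"))

setValidity("MotifMatrix", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (!is.numeric(object@mat) || ncol(object@mat) < 1L ||
        nrow(object@mat) != 4L ||
        !identical(rownames(object@mat), c("A", "C", "G", "T")))
        msg <- c(msg, "'mat' must be a 4 x w numeric matrix with rows A,C,G,T")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "'background' must be 4 frequencies summing to 1")
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        msg <- c(msg, "'threshold' must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Regulatory network of TF-CRM-TG triplets
#'
#' Base container for a regulatory network: a table of directed
#' TF -> TG regulations with a strength score, and for each regulation the
#' cis-regulatory module (CRM) mediating it, stored as a \code{GRangesList}
#' parallel to the triplet table.
#'
#' @slot triplets data.frame with columns \code{tf}, \code{tg} (character)
#'   and \code{score} (non-negative numeric).
#' @slot crm \code{GRangesList}, one element per triplet row; the merged,
#'   sorted regulatory-element intervals of the CRM.
#' @slot id network identifier.
#'
#' @export
setClass("RegNetwork",
    representation(triplets = "data.frame", crm = "GRangesList",
                   id = "character"))

.validRegNetwork <- function(object) {
    msg <- character()
    tr <- object@triplets
    if (!all(c("tf", "tg", "score") %in% colnames(tr)))
        msg <- c(msg, "'triplets' needs columns tf, tg, score")
    else {
        if (length(object@crm) != nrow(tr))
            msg <- c(msg, "'crm' must be parallel to 'triplets' rows")
        if (nrow(tr) && any(!is.finite(tr$score) | tr$score < 0))
            msg <- c(msg, "triplet scores must be finite and >= 0")
        if (anyDuplicated(paste(tr$tf, tr$tg, sep = "\r")))
            msg <- c(msg, "duplicate (tf, tg) pairs")
    }
    if (length(msg)) msg else TRUE
}
setValidity("RegNetwork", .validRegNetwork)

#' Single-replicate regulatory network
#'
#' A [RegNetwork-class] inferred from one biological replicate's paired
#' expression/accessibility sample, with the weight it carries in consensus
#' integration.
#'
#' @slot weight positive replicate weight (default 1).
#' @export
setClass("ReplicateNetwork", contains = "RegNetwork",
    representation(weight = "numeric"),
    prototype(weight = 1))

setValidity("ReplicateNetwork", function(object) {
    if (length(object@weight) != 1L || !is.finite(object@weight) ||
        object@weight <= 0)
        "'weight' must be a single positive number"
    else TRUE
})

#' Consensus regulatory network
#'
#' The result of consensus optimization over replicate networks: integrated
#' strengths and binarized CRMs (in the inherited slots), plus the relaxed
#' per-base CRM indicator vectors on the union coordinate frame and solver
#' diagnostics.
#'
#' @slot relaxed list with one element per triplet, each a list with
#'   \code{chrom}, \code{starts}, \code{ends} (0-based half-open union-span
#'   segments) and \code{values} (relaxed per-base indicator in [0,1], one
#'   entry per base of the span, segments concatenated in order).
#' @slot diagnostics list: \code{iterations}, \code{dS}, \code{dC},
#'   \code{converged}, and the parameters used.
#' @export
setClass("ConsensusNetwork", contains = "RegNetwork",
    representation(relaxed = "list", diagnostics = "list"),
    prototype(relaxed = list(), diagnostics = list()))

setValidity("ConsensusNetwork", function(object) {
    msg <- character()
    if (length(object@relaxed) &&
        length(object@relaxed) != nrow(object@triplets))
        msg <- c(msg, "'relaxed' must be empty or parallel to 'triplets'")
    if (length(object@relaxed)) {
        bad <- vapply(object@relaxed, function(x)
            any(x$values < -1e-9 | x$values > 1 + 1e-9), logical(1))
        if (any(bad)) msg <- c(msg, "relaxed CRM values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Annotated subnetwork
#'
#' The subset of a consensus network selected by a gene set, SNP set or
#' region set, with the per-triplet matches that justified retention.
#'
#' @slot selector one of \code{"genes"}, \code{"snps"}, \code{"regions"}.
#' @slot matches list parallel to triplets; the selector members matched.
#' @slot lambda z-score filter threshold applied (\code{NA} if none).
#' @export
setClass("AnnotatedSubnetwork", contains = "RegNetwork",
    representation(selector = "character", matches = "list",
                   lambda = "numeric"),
    prototype(selector = "genes", matches = list(), lambda = NA_real_))

## ---- constructors -------------------------------------------------------

#' Construct a regulatory network from triplets and CRMs
#'
#' @param triplets data.frame with columns \code{tf}, \code{tg},
#'   \code{score}.
#' @param crm \code{GRangesList} parallel to \code{triplets}; defaults to
#'   empty CRMs.
#' @param id network identifier.
#' @param weight replicate weight; when supplied a
#'   [ReplicateNetwork-class] is returned.
#' @return A [RegNetwork-class] or [ReplicateNetwork-class].
#' @examples
#' tr <- data.frame(tf = "TFAP2A", tg = "SOX9", score = 2.5)
#' crm <- GenomicRanges::GRangesList(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(101, 200)))
#' RegNetwork(tr, crm, id = "demo")
#' @export
RegNetwork <- function(triplets, crm = NULL, id = "network", weight = NULL) {
    triplets <- as.data.frame(triplets)
    triplets$tf <- as.character(triplets$tf)
    triplets$tg <- as.character(triplets$tg)
    if (is.null(crm))
        crm <- GRangesList(rep(list(GRanges()), nrow(triplets)))
    crm <- as(crm, "GRangesList")
    if (is.null(weight))
        new("RegNetwork", triplets = triplets, crm = crm, id = id)
    else
        new("ReplicateNetwork", triplets = triplets, crm = crm, id = id,
            weight = weight)
}

## ---- accessors ----------------------------------------------------------

#' @describeIn RegNetwork-class triplet table (tf, tg, score).
#' @param x,object a network object.
#' @export
triplets <- function(x) x@triplets

#' @describeIn RegNetwork-class CRMs as a \code{GRangesList} parallel to
#'   the triplet table.
#' @export
crms <- function(x) x@crm

#' @describeIn RegNetwork-class directed edge list (tf, tg) of the network.
#' @export
edges <- function(x) unique(x@triplets[, c("tf", "tg")])

#' @describeIn ReplicateNetwork-class replicate weight.
#' @export
replicateWeight <- function(x) x@weight

#' @describeIn ConsensusNetwork-class relaxed per-base CRM vectors on the
#'   union frame.
#' @export
relaxedCrm <- function(x) x@relaxed

#' @describeIn ConsensusNetwork-class solver diagnostics.
#' @export
diagnostics <- function(x) x@diagnostics

#' @describeIn MotifMatrix-class motif identifier.
#' @export
motifId <- function(x) x@id

#' @describeIn MotifMatrix-class motif width in bases.
#' @export
motifWidth <- function(x) ncol(x@mat)

#' @describeIn MotifMatrix-class maximum achievable log-odds score.
#' @export
maxScore <- function(x) sum(apply(x@mat, 2L, max))

## ---- show methods -------------------------------------------------------

setMethod("show", "MotifMatrix", function(object) {
    cons <- paste(rownames(object@mat)[apply(object@mat, 2L, which.max)],
                  collapse = "")
    cat("MotifMatrix", object@id, "| width", ncol(object@mat),
        "| consensus", cons,
        "| threshold", format(object@threshold, digits = 4), "\n")
})

setMethod("show", "RegNetwork", function(object) {
    tr <- object@triplets
    cat(class(object), sprintf("'%s'", object@id), "\n")
    cat(" ", nrow(tr), "triplets |", length(unique(tr$tf)), "TFs |",
        length(unique(tr$tg)), "TGs\n")
    if (nrow(tr))
        cat("  score range:",
            paste(format(range(tr$score), digits = 4), collapse = " - "),
            "\n")
})

setMethod("show", "ConsensusNetwork", function(object) {
    callNextMethod()
    d <- object@diagnostics
    if (length(d))
        cat("  solver:", d$iterations, "iterations | converged:",
            isTRUE(d$converged), "\n")
})
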