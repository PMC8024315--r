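## Network-architecture analysis: TF modules, the dense TF subnetwork
## found by a quadratic program over importance vectors, role
## classification, and a density significance test.

#' Cluster TFs into regulatory modules
#'
#' Agglomerative clustering of the TF rows of a strength matrix
#' (Euclidean distance, complete linkage by default), cut at k clusters.
#' Module labels are ordered by decreasing mean row sum, so module 1
#' holds the broadest regulators.
#'
#' @param S TF x TG strength matrix (rownames = TFs).
#' @param k number of modules (2 by default, >= 2).
#' @param method linkage method passed to [stats::hclust()].
#' @return Named integer vector TF -> module label in 1..k.
#' @importFrom stats hclust cutree dist
#' @export
clusterTfModules <- function(S, k = 2, method = "complete") {
    stopifnot(k >= 2)
    if (k > nrow(S)) stop("k exceeds the number of TFs")
    hc <- hclust(dist(S, method = "euclidean"), method = method)
    lab <- cutree(hc, k = k)
    strength <- tapply(rowSums(S), lab, mean)
    remap <- match(names(sort(strength, decreasing = TRUE)), names(strength))
    out <- match(lab, remap)
    setNames(as.integer(out), rownames(S))
}

#' Dense TF subnetwork by quadratic programming
#'
#' Maximizes \code{sum_ij S0_ij u_i v_j} over unit-norm non-negative
#' importance vectors u (out-going) and v (in-coming) by alternating
#' projected power iteration: \code{u <- normalize(max(S0 v, 0))},
#' \code{v <- normalize(max(S0' u, 0))}. For non-negative S0 the optimum
#' equals the leading singular value, attained by non-negative singular
#' vectors (Perron-Frobenius); seeded random restarts guard against
#' non-uniqueness.
#'
#' @param S0 square non-negative TF x TF strength matrix.
#' @param tol convergence tolerance on the objective (default 1e-10).
#' @param maxIter iteration cap per restart.
#' @param restarts random restarts beyond the deterministic uniform start.
#' @param seed RNG seed for the restarts.
#' @return List of class \code{"DenseSubnet"}: \code{u}, \code{v} (named,
#'   unit norm, >= 0), \code{objective}, \code{trace} (objective per
#'   iteration of the winning run).
#' @examples
#' S0 <- matrix(c(2, 0, 0, 1), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' denseSubnetwork(S0)$objective  # 2
#' @export
denseSubnetwork <- function(S0, tol = 1e-10, maxIter = 1000,
                            restarts = 5, seed = 1) {
    if (nrow(S0) != ncol(S0)) stop("S0 must be square")
    if (any(S0 < 0)) stop("S0 must be elementwise non-negative")
    if (all(S0 == 0)) stop("S0 is all zero")
    n <- nrow(S0)
    run <- function(v0) {
        v <- v0 / sqrt(sum(v0^2))
        obj <- -Inf; trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            u <- pmax(S0 %*% v, 0)
            nu <- sqrt(sum(u^2))
            if (nu == 0) return(NULL)
            u <- u / nu
            v <- pmax(crossprod(S0, u), 0)
            nv <- sqrt(sum(v^2))
            if (nv == 0) return(NULL)
            v <- v / nv
            newObj <- drop(crossprod(u, S0 %*% v))
            trace <- c(trace, newObj)
            if (is.finite(obj) && abs(newObj - obj) < tol) {
                obj <- newObj
                break
            }
            obj <- newObj
        }
        list(u = drop(u), v = drop(v), objective = obj, trace = trace)
    }
    starts <- c(list(rep(1, n)),
                withSeed(seed, replicate(restarts, runif(n) + 1e-6,
                                         simplify = FALSE)))
    best <- NULL
    for (v0 in starts) {
        r <- run(v0)
        if (!is.null(r) && (is.null(best) || r$objective > best$objective))
            best <- r
    }
    if (is.null(best)) stop("power iteration collapsed for every start")
    names(best$u) <- rownames(S0)
    names(best$v) <- rownames(S0)
    structure(best, class = "DenseSubnet")
}

#' Classify TF roles from importance vectors
#'
#' With out-going importance u and in-coming importance v: upstream when
#' \code{u >= muC} and \code{v < vC}; core when both are at or above
#' their cutoffs; downstream when \code{u < muC} and \code{v >= vC};
#' otherwise none.
#'
#' @param result a \code{"DenseSubnet"} from [denseSubnetwork()].
#' @param muC out-going importance cutoff (default 0.1).
#' @param vC in-coming importance cutoff (default 0.05).
#' @return Named character vector TF -> role.
#' @export
classifyTfRoles <- function(result, muC = 0.1, vC = 0.05) {
    u <- result$u; v <- result$v
    role <- ifelse(u >= muC & v < vC, "upstream",
            ifelse(u >= muC & v >= vC, "core",
            ifelse(u < muC & v >= vC, "downstream", "none")))
    setNames(role, names(u))
}

#' Significance of a TF subnetwork's density
#'
#' Density is the mean off-diagonal edge weight within the selected node
#' set. The null is the density of uniformly resampled same-size node
#' sets; a one-tailed t-test of the observed density against the null
#' sample is returned alongside the empirical exceedance fraction.
#'
#' @param S TF x TF strength matrix (rownames = TFs).
#' @param selected TF names or indices of the subnetwork.
#' @param draws number of null draws (>= 30).
#' @param seed RNG seed.
#' @return List with \code{density}, \code{nullMean}, \code{nullSd},
#'   \code{p} (t-test, upper tail), \code{exceedance} (empirical
#'   fraction of null draws at or above the observed density).
#' @export
subnetworkDensityPvalue <- function(S, selected, draws = 1000, seed = 1) {
    stopifnot(draws >= 30)
    if (is.character(selected)) selected <- match(selected, rownames(S))
    if (anyNA(selected) || length(selected) > nrow(S))
        stop("'selected' must name at most nrow(S) TFs of the matrix")
    dens <- function(idx) {
        sub <- S[idx, idx, drop = FALSE]
        if (length(idx) < 2L) return(mean(sub))
        mean(sub[row(sub) != col(sub)])
    }
    obs <- dens(selected)
    null <- withSeed(seed, vapply(seq_len(draws), function(b)
        dens(sample.int(nrow(S), length(selected))), numeric(1)))
    sdn <- sd(null)
    p <- if (sdn == 0) {
        if (obs > mean(null)) 0 else if (obs < mean(null)) 1 else 0.5
    } else {
        tstat <- (obs - mean(null)) / sdn
        pt(tstat, df = draws - 1L, lower.tail = FALSE)
    }
    list(density = obs, nullMean = mean(null), nullSd = sdn, p = p,
         exceedance = mean(null >= obs))
}
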