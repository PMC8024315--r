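## a small consensus-style network shared by the extraction tests
annotNet <- function() {
    repNet(c("TF1", "TF2", "TF1"), c("TG1", "TG1", "TG2"),
           c(1, 2, 3),
           list(gr0("chr1", 100, 200),
                gr0("chr1", c(100, 400), c(200, 450)),
                gr0("chr2", 50, 80)),
           id = "net")
}

test_that("subnetwork extraction honors each selector", {
    net <- annotNet()
    ## gene mode: identity when every TG is selected
    all <- extractSubnetwork(net, genes = c("TG1", "TG2"))
    expect_equal(triplets(all), triplets(net))
    one <- extractSubnetwork(net, genes = "TG2")
    expect_equal(triplets(one)$tf, "TF1")

    ## SNP mode: a SNP at the first base of a CRM selects exactly the
    ## triplets whose CRM contains that base (membership oracle below)
    snps <- data.frame(chrom = "chr1", pos = 100, rsid = "rs1")
    sub <- extractSubnetwork(net, snps = snps)
    want <- vapply(seq_len(3), function(i)
        paste("chr1", 101) %in% paste(
            as.character(seqnames(crms(net)[[i]])),
            unlist(mapply(seq, start(crms(net)[[i]]),
                          end(crms(net)[[i]]), SIMPLIFY = FALSE))),
        logical(1))
    expect_equal(pairKey2(triplets(sub)), pairKey2(triplets(net)[want, ]))
    expect_equal(sub@matches, list("rs1", "rs1"))

    ## SNP outside every CRM: empty result is valid
    far <- data.frame(chrom = "chr1", pos = 9999, rsid = "rs2")
    expect_equal(nrow(triplets(extractSubnetwork(net, snps = far))), 0L)

    ## region mode: >= 1 bp overlap
    reg <- gr0("chr1", 440, 500, id = "uce1")
    subR <- extractSubnetwork(net, regions = reg)
    expect_equal(triplets(subR)$tf, "TF2")
    expect_equal(subR@matches, list("uce1"))

    ## monotone in the selector: adding members never removes triplets
    s1 <- extractSubnetwork(net, genes = "TG1")
    s2 <- extractSubnetwork(net, genes = c("TG1", "TG2"))
    expect_true(all(pairKey2(triplets(s1)) %in% pairKey2(triplets(s2))))
    expect_error(extractSubnetwork(net), "exactly one")
})

test_that("z-score filtering keeps dominant CRMs per target", {
    ## strengths (1, 2, 3, 10): mean 4, population sd sqrt(12.5), so
    ## only 10 (z = 1.697) survives lambda = 1.5
    net <- repNet(paste0("TF", 1:4), rep("TG1", 4), c(1, 2, 3, 10),
                  rep(list(gr0("chr1", 0, 10)), 4))
    sub <- extractSubnetwork(net, genes = "TG1")
    fil <- filterByZscore(sub, 1.5)
    expect_equal(triplets(fil)$score, 10)
    ## kept strengths are >= mean + lambda * sd when sd > 0
    expect_true(all(triplets(fil)$score >= 4 + 1.5 * sqrt(12.5)))
    ## a very small lambda is the identity
    expect_equal(nrow(triplets(filterByZscore(sub, -100))), 4L)
    ## single-CRM targets are exempt from the cut
    net1 <- repNet("TF1", "TG9", 0.5, list(gr0("chr1", 0, 5)))
    sub1 <- extractSubnetwork(net1, genes = "TG9")
    expect_equal(nrow(triplets(filterByZscore(sub1, 1.5))), 1L)
})

test_that("SNP fold-change enrichment follows the density ratio", {
    genome <- c(chr1 = 10000)
    snps <- data.frame(chrom = "chr1",
                       pos = c(10, 50, seq(200, 900, length.out = 8)),
                       rsid = paste0("rs", 1:10), ref = "A", alt = "G",
                       traitA = c(1e-6, 1e-6, rep(0.5, 8)))
    attr(snps, "traits") <- "traitA"
    ## P_r = 2, L_r = 100, P = 10, L = 10000 at the loose threshold
    regions <- gr0("chr1", 0, 100)
    fc <- snpRegionFc(snps, regions, genome, ladder = c(1, 1e-5))
    expect_equal(fc$fc[1], (2 / 100) / (10 / 10000))  # 20
    expect_equal(fc$P[1], 10L)
    expect_equal(fc$Pr[2], 2L)
    ## regions covering the genome give FC 1 wherever P > 0
    fcAll <- snpRegionFc(snps, gr0("chr1", 0, 10000), genome,
                         ladder = c(1, 1e-5))
    expect_equal(fcAll$fc, c(1, 1))
    ## invariant to splitting a region into adjacent pieces
    fcSplit <- snpRegionFc(snps, gr0("chr1", c(0, 40), c(40, 100)),
                           genome, ladder = c(1, 1e-5))
    expect_equal(fcSplit$fc, fc$fc)
    ## thresholds with no SNP report a missing FC
    fcNone <- snpRegionFc(snps, regions, genome, ladder = c(1, 1e-9))
    expect_true(is.na(fcNone$fc[2]))
    expect_error(snpRegionFc(snps, regions, genome, ladder = c(1, 1)),
                 "decreasing")
})

test_that("the top trait is the argmin with lexicographic ties", {
    snp <- list(rsid = "rs1", a = 0.01, b = 0.001, c = 0.5)
    out <- snpTopTrait(snp, traits = c("a", "b", "c"))
    expect_equal(out$trait, "b")
    expect_equal(out$p, 0.001)
    tie <- list(z = 0.1, a = 0.1)
    expect_equal(snpTopTrait(tie, traits = c("z", "a"))$trait, "a")
    expect_error(snpTopTrait(list(rsid = "x"), traits = character(0)),
                 "trait")
    ## random tables match an exhaustive argmin oracle
    set.seed(81)
    for (i in 1:20) {
        p <- runif(5)
        names(p) <- paste0("t", sample(5))
        got <- snpTopTrait(as.list(p), traits = names(p))
        expect_equal(got$p, min(p))
    }
})

test_that("allele rescoring detects motif gain and loss", {
    m <- mkMotif("ACGT")
    s <- "TTTACGTTTT"
    ## ref = alt: nothing changes
    same <- alleleMotifDiff(s, 5, "C", "C", list(m))
    expect_equal(same$status, "none")
    expect_equal(same$delta, 0)
    ## G -> T at the motif's third base destroys the only hit
    lost <- alleleMotifDiff(s, 6, "G", "T", list(m))
    expect_equal(lost$status, "lost")
    expect_lt(lost$delta, 0)
    ## the reverse change creates the hit
    s2 <- "TTTACTTTTT"
    gained <- alleleMotifDiff(s2, 6, "T", "G", list(m))
    expect_equal(gained$status, "gained")
    ## ref mismatch is an error
    expect_error(alleleMotifDiff(s, 5, "A", "T", list(m)), "mismatch")
    ## variant outside every scoring window: motif wider than sequence
    wide <- mkMotif(strrep("ACGT", 5))
    out <- alleleMotifDiff("ACGTAC", 2, "C", "A", list(wide))
    expect_equal(out$status, "none")
    expect_equal(out$delta, 0)
})

test_that("empirical overlap p-values are deterministic and bounded", {
    genome <- c(chr1 = 10000, chr2 = 10000)
    res <- gr0(rep(c("chr1", "chr2"), each = 5),
               seq(0, 9000, length.out = 10),
               seq(0, 9000, length.out = 10) + 300)
    set.seed(91)
    el <- gr0(c("chr1", "chr2", "chr2"), c(100, 5000, 7000),
              c(300, 5200, 7100))
    a <- empiricalOverlapPvalue(el, res, genome, nShuffles = 200,
                                seed = 5)
    b <- empiricalOverlapPvalue(el, res, genome, nShuffles = 200,
                                seed = 5)
    expect_identical(a[c("observed", "p", "pStrict")],
                     b[c("observed", "p", "pStrict")])
    expect_true(a$p >= a$pStrict)
    ## elements covering the genome always tie: p = 1
    resAll <- gr0(c("chr1", "chr2"), c(0, 0), c(10000, 10000))
    full <- empiricalOverlapPvalue(el, resAll, genome,
                                   nShuffles = 100, seed = 1)
    expect_equal(full$observed, 3L)
    expect_equal(full$p, 1)
    expect_error(empiricalOverlapPvalue(gr0("chr1", 0, 20000), res,
                                        genome, 100, 1),
                 "longer")
})
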