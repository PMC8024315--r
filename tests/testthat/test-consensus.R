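test_that("CRM frames align replicates onto the union span", {
    ## two replicates, identical single-element CRMs
    reps <- scalarReplicates(c(1, 1), crm = gr0("chr1", 0, 10))
    fr <- alignCrmFrames(reps)
    expect_equal(nrow(fr$pairs), 1L)
    f <- fr$frames[[1]]
    expect_equal(f$L, 10L)
    expect_true(all(f$C == 1))

    ## offset CRMs: [0,10) and [5,15) -> span [0,15), per-base oracle
    repA <- repNet("TF1", "TG1", 1, list(gr0("chr1", 0, 10)), id = "A")
    repB <- repNet("TF1", "TG1", 2, list(gr0("chr1", 5, 15)), id = "B")
    fr <- alignCrmFrames(list(repA, repB))
    f <- fr$frames[[1]]
    expect_equal(f$starts, 0)
    expect_equal(f$ends, 15)
    ## per-base enumeration oracle: base b (0-based) covered iff inside
    expect_equal(f$C[1, ], as.numeric(0:14 %in% 0:9))
    expect_equal(f$C[2, ], as.numeric(0:14 %in% 5:14))

    ## pair present in only 1 of 3 replicates
    repC <- repNet("TF2", "TG9", 3, list(gr0("chr2", 100, 120)),
                   id = "C")
    fr <- alignCrmFrames(list(repA, repB, repC))
    i <- which(fr$pairs$tf == "TF2")
    f <- fr$frames[[i]]
    expect_equal(unname(rowSums(f$C)), c(0, 0, 20))
    expect_equal(unname(fr$Srep[i, ]), c(0, 0, 3))

    ## multi-chromosome CRMs are supported piecewise
    repD <- repNet("TF1", "TG1", 1,
                   list(suppressWarnings(c(gr0("chr1", 0, 5),
                                           gr0("chr2", 0, 5)))))
    fr <- alignCrmFrames(list(repD))
    expect_equal(fr$frames[[1]]$L, 10L)
    expect_equal(fr$frames[[1]]$chrom, c("chr1", "chr2"))
})

test_that("degenerate parameters reduce to weighted replicate means", {
    reps <- scalarReplicates(c(1, 3, 5), weights = c(1, 2, 3))
    cn <- consensusOptimize(reps)  # beta = gamma = mu = 0
    expect_equal(triplets(cn)$score, (1 + 6 + 15) / 6,
                 tolerance = 1e-12)
    expect_true(all(abs(relaxedCrm(cn)[[1]]$values - 1) < 1e-12))
    expect_true(diagnostics(cn)$converged)

    ## sparsity penalty: S^1 = 1, S^2 = 3, unit weights, mu = 0.4:
    ## S = (2*(1+3) - 0.4) / 4 = 1.9
    reps2 <- scalarReplicates(c(1, 3))
    cn2 <- consensusOptimize(reps2, mu = 0.4)
    expect_equal(triplets(cn2)$score, 1.9, tolerance = 1e-9)
})

test_that("converged runs satisfy the clamped update maps within eps", {
    eps <- 1e-8
    set.seed(31)
    for (case in 1:3) {
        ## random small replicate set with overlapping CRMs
        reps <- lapply(1:3, function(r) {
            s0 <- sample(0:20, 2)
            repNet(c("TF1", "TF1"), c("TG1", "TG2"), runif(2, 0.5, 2),
                   list(gr0("chr1", s0[1], s0[1] + 15),
                        gr0("chr1", s0[2], s0[2] + 10)),
                   id = paste0("r", r))
        })
        cn <- consensusOptimize(reps, alpha = 1, beta = 0.2,
                                gamma = 0.3, mu = 0.1, eps = eps,
                                maxIter = 5000)
        expect_true(diagnostics(cn)$converged)
        resid <- fixedPointResidual(cn, reps, alpha = 1, beta = 0.2,
                                    gamma = 0.3, mu = 0.1)
        expect_lt(resid, eps)
    }
})

test_that("alpha is required when beta or gamma is used", {
    reps <- scalarReplicates(c(1, 2))
    expect_error(consensusOptimize(reps, alpha = 0, gamma = 1), "alpha")
    expect_error(consensusOptimize(reps, alpha = 0, beta = 1), "alpha")
})

test_that("finalize binarizes relaxed values and prunes triplets", {
    reps <- scalarReplicates(c(1, 2), crm = gr0("chr1", 0, 10))
    cn <- consensusOptimize(reps)
    ## force relaxed values to known patterns
    cn2 <- cn
    cn2@relaxed[[1]]$values <- rep(0.9, 10)
    fin <- finalizeNetwork(cn2)
    expect_equal(start(crms(fin)[[1]]), 1L)
    expect_equal(end(crms(fin)[[1]]), 10L)

    cn2@relaxed[[1]]$values <- rep(0.1, 10)
    fin <- finalizeNetwork(cn2)
    expect_equal(nrow(triplets(fin)), 0L)  # empty CRM -> dropped

    ## alternating 0.9 / 0.1 blocks map to the 0.9 blocks
    cn2@relaxed[[1]]$values <- rep(c(0.9, 0.1, 0.9, 0.1, 0.9),
                                   each = 2)
    fin <- finalizeNetwork(cn2)
    expect_equal(start(crms(fin)[[1]]) - 1L, c(0L, 4L, 8L))  # 0-based
    expect_equal(end(crms(fin)[[1]]), c(2L, 6L, 10L))
})

test_that("union and intersection baselines behave like set algebra", {
    repA <- repNet(c("TF1", "TF1"), c("TG1", "TG2"), c(1, 2),
                   list(gr0("chr1", 0, 10), gr0("chr1", 20, 30)),
                   id = "A")
    repB <- repNet("TF1", "TG1", 3, list(gr0("chr1", 5, 15)), id = "B")
    repC <- repNet("TF1", "TG1", 5, list(gr0("chr1", 8, 12)), id = "C")

    ## R = 1: union = intersection = the replicate
    u1 <- baselineIntegrate(list(repA), "union")
    i1 <- baselineIntegrate(list(repA), "intersection")
    expect_equal(triplets(u1), triplets(i1))
    expect_equal(triplets(u1)$score, c(1, 2))

    u <- baselineIntegrate(list(repA, repB, repC), "union")
    i <- baselineIntegrate(list(repA, repB, repC), "intersection")
    ## edge in 1 of 3 replicates: in union, not in intersection
    expect_true("TG2" %in% triplets(u)$tg)
    expect_false("TG2" %in% triplets(i)$tg)
    ## union CRM is the merged span, intersection the common core
    j <- which(triplets(u)$tg == "TG1")
    expect_equal(c(start(crms(u)[[j]]) - 1L, end(crms(u)[[j]])),
                 c(0L, 15L))
    j <- which(triplets(i)$tg == "TG1")
    expect_equal(c(start(crms(i)[[j]]) - 1L, end(crms(i)[[j]])),
                 c(8L, 10L))
    ## mean strength over replicates containing the pair
    expect_equal(triplets(i)$score[j], mean(c(1, 3, 5)))
})

test_that("edge count after finalize is non-increasing in mu", {
    truth <- generateTruth(truthConfig(nTfs = 6, nTgs = 20, nRes = 60,
                                       chromLength = 3e4, seed = 41))
    sim <- simulateReplicates(truth, seed = 42)
    frames <- alignCrmFrames(sim$networks)
    counts <- vapply(c(0, 0.2, 0.5, 1, 2), function(mu) {
        fin <- finalizeNetwork(consensusOptimize(sim$networks, mu = mu,
                                                 frames = frames))
        nrow(triplets(fin))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    ## and the baselines bracket the consensus edge count
    nU <- nrow(triplets(baselineIntegrate(sim$networks, "union")))
    nI <- nrow(triplets(baselineIntegrate(sim$networks,
                                          "intersection")))
    expect_true(nU >= counts[1])
    expect_true(counts[length(counts)] >= 0 && nI <= nU)
})

test_that("parameter selection maximizes F1 with documented tie-breaks", {
    truth <- generateTruth(truthConfig(nTfs = 6, nTgs = 20, nRes = 60,
                                       chromLength = 3e4, seed = 51))
    sim <- simulateReplicates(truth, seed = 52)
    gold <- edgeDf(truth$network)
    univ <- c(paste0("TF", 1:6), paste0("TG", 1:20))
    grid <- data.frame(alpha = 1, beta = 0, gamma = 0,
                       mu = c(0, 0.5, 1))
    sel <- selectParameters(grid, sim$networks, gold, univ)
    expect_equal(nrow(sel$metrics), 3L)
    best <- which(sel$metrics$f1 == max(sel$metrics$f1))
    expect_equal(sel$best$mu, sel$metrics$mu[best[1]])

    ## a one-row grid returns that row
    sel1 <- selectParameters(grid[1, ], sim$networks, gold, univ)
    expect_equal(sel1$best$mu, 0)

    ## identical F1 rows break ties toward the smaller mu
    grid2 <- data.frame(alpha = 1, beta = 0, gamma = 0, mu = c(0.3, 0.3))
    grid2$mu <- c(0.4, 0.2)
    sel2 <- selectParameters(grid2, sim$networks, gold, univ)
    expect_equal(sel2$best$mu, 0.2)
})
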