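test_that("interaction model recovers an exact linear relation", {
    set.seed(1)
    acc <- matrix(rlnorm(2 * 30), nrow = 2,
                  dimnames = list(NULL, paste0("s", 1:30)))
    expr <- matrix(2 * acc[1, ] + 1, nrow = 1,
                   dimnames = list("g1", colnames(acc)))
    fit <- fitInteractionModel(expr, acc, list(g1 = 1L))
    expect_equal(unname(fit$weights$g1), 2, tolerance = 1e-8)
    expect_equal(unname(fit$intercepts["g1"]), 1, tolerance = 1e-8)
})

test_that("interaction model equals the lm() oracle on noisy data", {
    set.seed(2)
    for (rep in 1:5) {
        acc <- matrix(rlnorm(3 * 50), nrow = 3)
        colnames(acc) <- paste0("s", 1:50)
        y <- 0.3 + 1.2 * acc[1, ] - 0.4 * acc[3, ] + rnorm(50, 0, 0.2)
        expr <- matrix(y, 1, dimnames = list("g", colnames(acc)))
        fit <- fitInteractionModel(expr, acc, list(g = c(1L, 3L)))
        ref <- coef(lm(y ~ t(acc[c(1, 3), ])))
        expect_equal(unname(fit$intercepts["g"]), unname(ref[1]),
                     tolerance = 1e-10)
        expect_equal(unname(fit$weights$g), unname(ref[2:3]),
                     tolerance = 1e-10)
    }
})

test_that("interaction model recovers planted weights from a 148-sample panel", {
    set.seed(3)
    nRe <- 5; nS <- 148
    acc <- matrix(rlnorm(nRe * nS), nRe)
    colnames(acc) <- paste0("s", seq_len(nS))
    iTrue <- runif(nRe, 0.5, 1.5)
    y <- 0.2 + drop(iTrue %*% acc) + rnorm(nS, 0, 0.1)
    expr <- matrix(y, 1, dimnames = list("g", colnames(acc)))
    fit <- fitInteractionModel(expr, acc, list(g = seq_len(nRe)))
    rmse <- sqrt(mean((unname(fit$weights$g) - iTrue)^2))
    expect_lt(rmse, 0.1)
})

test_that("underdetermined designs demand ridge and ridge handles them", {
    set.seed(4)
    acc <- matrix(rlnorm(10 * 5), 10)
    colnames(acc) <- paste0("s", 1:5)
    expr <- matrix(rnorm(5), 1, dimnames = list("g", colnames(acc)))
    expect_error(fitInteractionModel(expr, acc, list(g = 1:10)),
                 "ridgeLambda")
    fit <- fitInteractionModel(expr, acc, list(g = 1:10),
                               ridgeLambda = 0.5)
    expect_length(fit$weights$g, 10)
    expect_true(all(is.finite(fit$weights$g)))
    ## empty candidate set -> intercept-only model
    fit0 <- fitInteractionModel(expr, acc, list(g = integer(0)))
    expect_equal(unname(fit0$intercepts["g"]), mean(expr["g", ]))
    expect_length(fit0$weights$g, 0)
})

test_that("expression correlation matches the textbook formula", {
    set.seed(5)
    panel <- matrix(rnorm(3 * 50), 3,
                    dimnames = list(c("tf", "tgSame", "tgRand"), NULL))
    panel["tgSame", ] <- panel["tf", ]
    R <- expressionCorrelation(panel, "tf", c("tgSame", "tgRand"))
    expect_equal(unname(R["tf", "tgSame"]), 1)
    ## negated series gives -1
    panel2 <- rbind(panel, tgNeg = -panel["tf", ])
    expect_equal(unname(expressionCorrelation(panel2, "tf",
                                              "tgNeg")[1, 1]), -1)
    ## manual covariance / sd computation
    x <- panel["tf", ]; y <- panel["tgRand", ]
    manual <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(R["tf", "tgRand"]), manual, tolerance = 1e-12)
    ## constant series -> 0 by convention
    panel3 <- rbind(panel, flat = rep(2, 50))
    expect_equal(unname(expressionCorrelation(panel3, "tf",
                                              "flat")[1, 1]), 0)
    expect_error(expressionCorrelation(panel, "tf", "missing"),
                 "missing")
})

test_that("TF activity is zero iff the TF is unexpressed, and seeded", {
    m1 <- mkMotif("ACGTACGT")
    seqs <- c(re1 = "TTTTACGTACGTTTTTACGTACGTTTTT",
              re2 = "GGGGACGTACGTGGGG")
    expr <- c(ACGTACGT = 4)
    a <- tfActivity(expr, list(m1), seqs, shuffles = 3, seed = 9)
    b <- tfActivity(expr, list(m1), seqs, shuffles = 3, seed = 9)
    expect_identical(a, b)
    ## planted motif in every element: enrichment above shuffled
    ## background, so TFA exceeds sqrt(TF * 1)
    expect_gt(unname(a[1]), sqrt(4))
    ## unexpressed TF has zero activity
    z <- tfActivity(c(ACGTACGT = 0), list(m1), seqs, shuffles = 2,
                    seed = 1)
    expect_equal(unname(z[1]), 0)
    expect_error(tfActivity(expr, list(m1), seqs, shuffles = 0),
                 "shuffles")
})

test_that("trans-regulation scores follow the scoring formula", {
    B <- matrix(c(1, 2), 1, dimnames = list("tf1", c("re1", "re2")))
    model <- structure(list(
        intercepts = c(tg1 = 0),
        weights = list(tg1 = c("1" = 1, "2" = 0.5)),
        candidates = list(tg1 = c(1L, 2L))), class = "InteractionModel")
    R <- matrix(1, 1, 1, dimnames = list("tf1", "tg1"))
    S <- transRegulationScores(B, c(0.5, 1), model, R, c(tf1 = 4),
                               c(tg1 = 1))
    ## (1*0.5*1 + 2*1*0.5) * 2^1 * sqrt(4*1) = 1.5 * 2 * 2 = 6
    expect_equal(unname(S[1, 1]), 6)
    ## zero TG expression kills the score
    S0 <- transRegulationScores(B, c(0.5, 1), model, R, c(tf1 = 4),
                                c(tg1 = 0))
    expect_equal(unname(S0[1, 1]), 0)
    ## |R| enters the formula: the sign of the correlation is irrelevant
    Rneg <- matrix(-0.5, 1, 1, dimnames = dimnames(R))
    Rpos <- matrix(0.5, 1, 1, dimnames = dimnames(R))
    expect_equal(
        transRegulationScores(B, c(0.5, 1), model, Rneg, c(tf1 = 4),
                              c(tg1 = 1)),
        transRegulationScores(B, c(0.5, 1), model, Rpos, c(tf1 = 4),
                              c(tg1 = 1)))
    ## linearity in accessibility: doubling every element doubles S
    S2 <- transRegulationScores(B, 2 * c(0.5, 1), model, R, c(tf1 = 4),
                                c(tg1 = 1))
    expect_equal(S2, 2 * S)
    ## a negative inner sum is clamped to zero
    modelNeg <- model
    modelNeg$weights$tg1 <- c("1" = -1, "2" = -0.5)
    Sneg <- transRegulationScores(B, c(0.5, 1), modelNeg, R, c(tf1 = 4),
                                  c(tg1 = 1))
    expect_equal(unname(Sneg[1, 1]), 0)
})

test_that("a single bound element yields a single-triplet network", {
    m <- mkMotif("ACGTACGT")
    elements <- gr0("chr1", 100, 128, id = "re1")
    seqs <- c(re1 = "TTTTACGTACGTTTTTTTTTTTTTTTTT")
    model <- structure(list(
        intercepts = c(tg1 = 0),
        weights = list(tg1 = c("1" = 1)),
        candidates = list(tg1 = 1L)), class = "InteractionModel")
    R <- matrix(0.5, 1, 1, dimnames = list("ACGTACGT", "tg1"))
    net <- buildReplicateNetwork(
        expr = c(ACGTACGT = 2, tg1 = 1), access = c(re1 = 1),
        elements = elements, sequences = seqs, pwms = list(m),
        model = model, corMat = R, tfa = c(ACGTACGT = 1),
        sQuantile = 0, id = "r1")
    expect_s4_class(net, "ReplicateNetwork")
    expect_equal(nrow(triplets(net)), 1L)
    expect_equal(start(crms(net)[[1]]), 101L)
    expect_equal(end(crms(net)[[1]]), 128L)

    ## no binding on any candidate element -> no triplet
    expect_warning(
        net0 <- buildReplicateNetwork(
            expr = c(ACGTACGT = 2, tg1 = 1), access = c(re1 = 1),
            elements = elements, sequences = c(re1 = strrep("T", 28)),
            pwms = list(m), model = model, corMat = R,
            tfa = c(ACGTACGT = 1), sQuantile = 0),
        "empty")
    expect_equal(nrow(triplets(net0)), 0L)
})

test_that("the full pipeline recovers a noiseless truth network exactly", {
    cfg <- truthConfig(nChroms = 1, chromLength = 20000, nTfs = 5,
                       nTgs = 15, nRes = 30, motifWidth = 10,
                       edgeDensity = 0.15, sigmaE = 0, seed = 11)
    truth <- generateTruth(cfg)
    ## paired panel generated exactly from the truth model, no noise
    set.seed(12)
    nPanel <- 60
    panelAcc <- matrix(rlnorm(30 * nPanel), 30,
                       dimnames = list(names(truth$elements),
                                       paste0("p", 1:nPanel)))
    panelExpr <- t(vapply(names(truth$model$weights), function(g) {
        wts <- truth$model$weights[[g]]
        truth$model$intercepts[[g]] +
            drop(wts %*% panelAcc[as.integer(names(wts)), , drop = FALSE])
    }, numeric(nPanel)))
    fit <- fitInteractionModel(panelExpr, panelAcc, truth$candidates,
                               coefTol = 1e-8)
    tfs <- paste0("TF", 1:5)
    tgs <- paste0("TG", 1:15)
    corMat <- matrix(0.5, 5, 15, dimnames = list(tfs, tgs))
    net <- buildReplicateNetwork(
        expr = truth$expr, access = truth$access,
        elements = truth$elements, sequences = truth$sequences,
        pwms = truth$pwms, model = fit, corMat = corMat,
        tfa = setNames(rep(1, 5), tfs),
        sQuantile = 0, minScore = 1e-6, id = "noiseless")
    em <- edgeMetrics(edgeDf(net), edgeDf(truth$network),
                      c(tfs, tgs))
    expect_equal(em$precision, 1)
    expect_equal(em$recall, 1)
})

test_that("every truth edge has a rescannable planted motif", {
    truth <- generateTruth(truthConfig(nChroms = 1, chromLength = 20000,
                                       nTfs = 4, nTgs = 10, nRes = 25,
                                       motifWidth = 10, seed = 21))
    B <- motifBindingMatrix(truth$sequences, truth$pwms)
    tr <- triplets(truth$network)
    for (i in seq_len(nrow(tr))) {
        crmRe <- which(countOverlaps(truth$elements,
                                     crms(truth$network)[[i]]) > 0)
        expect_true(any(B[tr$tf[i], crmRe] > 0),
                    label = paste("edge", tr$tf[i], "->", tr$tg[i],
                                  "has a motif hit"))
    }
})
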