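test_that("mean trajectories follow the scenario", {
    scen <- simScenario(nPerGroup = 5, M = 3, nFeatures = 10, nDaf = 4,
        mu0Range = c(5, 5), effect = "linear", effectSize = 0.2, seed = 1)
    expect_equal(featureMeanProfile(scen, 1, "treatment"), c(5, 6, 7))
    expect_equal(featureMeanProfile(scen, 1, "control"), rep(5, 3))
    expect_equal(featureMeanProfile(scen, 9, "treatment"), rep(5, 3))
    scenExp <- simScenario(nPerGroup = 5, M = 4, nFeatures = 10, nDaf = 4,
        mu0Range = c(2, 2), effect = "exponential", effectSize = 0.5, seed = 1)
    expect_equal(featureMeanProfile(scenExp, 2, "treatment"),
        2 * exp(0.5 * (0:3)))
    # strictly increasing whenever the effect size is positive
    for (eff in c("linear", "exponential")) {
        s <- simScenario(nPerGroup = 5, M = 6, nFeatures = 5, nDaf = 5,
            effect = eff, effectSize = 0.1, seed = 3)
        expect_true(all(diff(featureMeanProfile(s, 1, "treatment")) > 0))
    }
})

test_that("zero probability decreases with the mean", {
    expect_equal(zeroProbability(1, a = 0, b = 1), 0.5)
    expect_equal(zeroProbability(exp(1), a = 0, b = 1), 0.268941, tolerance = 1e-5)
    mu <- sort(runif(20, 0.2, 60))
    expect_true(all(diff(zeroProbability(mu, a = 0.3, b = 1.2)) < 0))
    expect_error(zeroProbability(-1), "mu > 0")
    expect_error(zeroProbability(1, b = 0))
})

test_that("simulated margins match the ZIP closed forms without copula correlation", {
    scen <- simScenario(nPerGroup = 2e4, M = 3, nFeatures = 2, nDaf = 0,
        rho = 0, mu0Range = c(3, 3), seed = 42)
    sim <- simulateFeature(scen, 1)
    n <- scen@nPerGroup
    for (j in 1:3) {
        rhoZ <- sim$rhoZero["control", j]
        mu <- sim$mu["control", j]
        p0 <- zipZeroProb(rhoZ, mu)
        expect_lt(abs(mean(sim$control[, j] == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / n))
        expect_lt(abs(mean(sim$control[, j]) - zipMean(rhoZ, mu)),
            3 * sqrt(zipVar(rhoZ, mu) / n))
    }
})

test_that("simulated marginal CDF matches the ZIP CDF (DKW bound)", {
    scen <- simScenario(nPerGroup = 5e4, M = 2, nFeatures = 1, nDaf = 0,
        rho = 0.6, mu0Range = c(4, 4), seed = 7)
    sim <- simulateFeature(scen, 1)
    y <- sim$control[, 1]
    rhoZ <- sim$rhoZero["control", 1]; mu <- sim$mu["control", 1]
    qs <- 0:max(y)
    gap <- max(abs(ecdf(y)(qs) - zipCdf(qs, rhoZ, mu)))
    expect_lt(gap, sqrt(log(2 / 0.01) / (2 * length(y))))
})

test_that("copula dependence has the requested structure", {
    scen <- simScenario(nPerGroup = 4000, M = 6, nFeatures = 1, nDaf = 0,
        rho = 0.9, structure = "ar1", mu0Range = c(10, 10), seed = 19)
    y <- simulateFeature(scen, 1)$control
    lag1 <- cor(y[, 1], y[, 2], method = "spearman")
    lag5 <- cor(y[, 1], y[, 6], method = "spearman")
    expect_gt(lag1, lag5)
    expect_gt(lag1, 0.5)
    # exchangeable: all pairwise Spearman correlations roughly equal
    scenX <- simScenario(nPerGroup = 4000, M = 4, nFeatures = 1, nDaf = 0,
        rho = 0.6, structure = "exchangeable", mu0Range = c(10, 10), seed = 23)
    yx <- simulateFeature(scenX, 1)$control
    cc <- cor(yx, method = "spearman")
    offs <- cc[upper.tri(cc)]
    expect_lt(max(offs) - min(offs), 0.08)
})

test_that("feature simulation is deterministic and feature-wise reproducible", {
    scen <- simScenario(nPerGroup = 10, M = 4, nFeatures = 6, nDaf = 2, seed = 5)
    expect_identical(simulateFeature(scen, 3), simulateFeature(scen, 3))
    se <- simulateStudy(scen)
    sim <- simulateFeature(scen, 3)
    counts <- SummarizedExperiment::assay(se)
    expect_equal(as.integer(t(sim$control)),
        unname(counts[3, 1:40]))
})

test_that("study assembly is consistent with the scenario", {
    scen <- simScenario(nPerGroup = 6, M = 4, nFeatures = 30, nDaf = 7, seed = 2)
    se <- simulateStudy(scen)
    expect_equal(dim(se), c(30L, 48L))
    rd <- SummarizedExperiment::rowData(se)
    expect_equal(sum(rd$is_daf), 7)
    expect_equal(which(rd$is_daf), 1:7)
    cd <- SummarizedExperiment::colData(se)
    expect_equal(sum(cd$group == "control"), 24)
    expect_true(all(table(cd$subject) == 4))
    # same scenario, different seed: same truth, different counts
    scen2 <- simScenario(nPerGroup = 6, M = 4, nFeatures = 30, nDaf = 7, seed = 99)
    se2 <- simulateStudy(scen2)
    expect_equal(rd$is_daf, SummarizedExperiment::rowData(se2)$is_daf)
    expect_false(identical(SummarizedExperiment::assay(se),
        SummarizedExperiment::assay(se2)))
    # all-null scenario
    scen0 <- simScenario(nPerGroup = 4, M = 3, nFeatures = 8, nDaf = 0, seed = 2)
    expect_false(any(SummarizedExperiment::rowData(simulateStudy(scen0))$is_daf))
})

test_that("group labels are exchangeable under the null", {
    scen <- simScenario(nPerGroup = 2000, M = 3, nFeatures = 2, nDaf = 0,
        rho = 0.5, mu0Range = c(6, 6), seed = 31)
    sim <- simulateFeature(scen, 1)
    for (j in 1:3) {
        mC <- mean(sim$control[, j]); mT <- mean(sim$treatment[, j])
        sePool <- sqrt(var(sim$control[, j]) / 2000 + var(sim$treatment[, j]) / 2000)
        expect_lt(abs(mC - mT), 4 * sePool)
        expect_lt(abs(mean(sim$control[, j] == 0) - mean(sim$treatment[, j] == 0)),
            4 * sqrt(2 * 0.25 / 2000))
    }
})

test_that("scenario validation rejects inconsistent settings", {
    expect_error(simScenario(nFeatures = 10, nDaf = 20), "nDaf")
    expect_error(simScenario(rho = 1), "rho")
    expect_error(simScenario(zeroB = -1), "zeroB")
    expect_error(simScenario(mu0Range = c(5, 1)), "mu0Range")
})
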