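test_that("block working correlations have the stated pattern", {
    for (s in c("independence", "ar1", "exchangeable")) {
        expect_equal(buildWorkingCorrelation(s, 0, 3)@R, diag(6))
    }
    J2 <- matrix(1, 2, 2)
    R <- buildWorkingCorrelation("ar1", 0.5, 3)@R
    expect_equal(R[1:2, 3:4], 0.5 * J2)
    expect_equal(R[1:2, 5:6], 0.25 * J2)
    expect_equal(R[3:4, 5:6], 0.5 * J2)
    expect_equal(R[1:2, 1:2], diag(2))
    R <- buildWorkingCorrelation("exchangeable", 0.3, 3)@R
    for (j in 1:2) for (l in (j + 1):3) {
        expect_equal(R[(2 * j - 1):(2 * j), (2 * l - 1):(2 * l)], 0.3 * J2)
    }
    expect_true(isSymmetric(R))
})

test_that("alpha outside [0, 1) is clamped with a warning", {
    expect_warning(w <- buildWorkingCorrelation("ar1", 1.2, 3), "clamped")
    expect_equal(w@alpha, 0.99)
    expect_warning(w <- buildWorkingCorrelation("exchangeable", -0.1, 3), "clamped")
    expect_equal(w@alpha, 0)
})

test_that("repaired correlation is positive definite across the alpha grid", {
    for (M in c(2, 5, 20, 50)) {
        for (a in c(0, 0.3, 0.45, 0.6, 0.9, 0.99)) {
            for (s in c("ar1", "exchangeable")) {
                w <- buildWorkingCorrelation(s, a, M)
                ev <- eigen(w@R + diag(w@ridge, 2 * M), symmetric = TRUE,
                    only.values = TRUE)$values
                expect_gte(min(ev), 1e-8)
                # factorization consistency
                expect_equal(crossprod(w@cholR),
                    w@R + diag(w@ridge, 2 * M), tolerance = 1e-10,
                    ignore_attr = TRUE)
            }
        }
    }
})

test_that("Pearson residuals standardize the two responses component-wise", {
    # single cell with y = 0: f1 = 1, f2 = 0; moments supplied directly
    p <- featurePanel(matrix(0, 1, 1), matrix(1, 1, 1))
    mom <- list(rho = matrix(0.4, 1, 1), mu = matrix(1, 1, 1),
        h1 = matrix(0.5, 1, 1), h2 = matrix(0.3, 1, 1),
        a1 = matrix(0.25, 1, 1), a2 = matrix(4, 1, 1), zeroPart = TRUE)
    r <- pearsonResiduals(p, 0, 0, moments = mom)
    expect_equal(r$e1[1, 1], (1 - 0.5) / 0.5)
    expect_equal(r$e2[1, 1], (0 - 0.3) / 2)
    # f matching h exactly leaves a zero residual
    mom2 <- mom; mom2$h1[] <- 1; mom2$h2[] <- 0
    r2 <- pearsonResiduals(p, 0, 0, moments = mom2)
    expect_equal(r2$e1[1, 1], 0)
    expect_equal(r2$e2[1, 1], 0)
    # degenerate cell: variance below tolerance is zeroed with a warning
    mom$a1[] <- 1e-14
    expect_warning(r <- pearsonResiduals(p, 0, 0, moments = mom), "degenerate")
    expect_equal(r$e1[1, 1], 0)
})

test_that("residuals have mean 0 and variance 1 under the generating model", {
    panel <- simulatePanel(4000, 4, betaU = c(-1, 0.5), betaV = c(1, 0.3),
        seed = 13)
    r <- pearsonResiduals(panel, c(-1, 0.5), c(1, 0.3))
    n <- length(r$e1)
    for (e in r) {
        expect_lt(abs(mean(e)), 3 / sqrt(n))
        # var of a standardized variable: MC tolerance ~ 3 * sqrt(kurtosis/n)
        expect_lt(abs(stats::var(as.vector(e)) - 1), 0.1)
    }
})

test_that("alpha estimators recover known residual dependence", {
    set.seed(101)
    N <- 500; M <- 10
    # i.i.d. residuals: alpha -> 0
    res <- list(e1 = matrix(rnorm(N * M), N), e2 = matrix(rnorm(N * M), N))
    expect_lt(estimateAlphaAR1(res), 0.1)
    expect_lt(estimateAlphaExchangeable(res), 0.1)
    # lag-1 correlation 0.6 in both components
    ar <- function() t(apply(matrix(0, N, M), 1, function(z) {
        as.vector(arima.sim(list(ar = 0.6), M, sd = sqrt(1 - 0.36)))
    }))
    res <- list(e1 = ar(), e2 = ar())
    expect_lt(abs(estimateAlphaAR1(res) - 0.6), 0.1)
    # common pairwise correlation 0.9
    exch <- function() {
        b <- rnorm(N)
        sqrt(0.9) * matrix(b, N, M) + sqrt(0.1) * matrix(rnorm(N * M), N)
    }
    res <- list(e1 = exch(), e2 = exch())
    expect_lt(abs(estimateAlphaExchangeable(res) - 0.9), 0.1)
})

test_that("alpha estimators are invariant to relabeling and component swap", {
    set.seed(5)
    res <- list(e1 = matrix(rnorm(80), 8), e2 = matrix(rnorm(80), 8))
    perm <- sample(8)
    resPerm <- list(e1 = res$e1[perm, ], e2 = res$e2[perm, ])
    resSwap <- list(e1 = res$e2, e2 = res$e1)
    expect_equal(estimateAlphaAR1(res), estimateAlphaAR1(resPerm))
    expect_equal(estimateAlphaAR1(res), estimateAlphaAR1(resSwap))
    expect_equal(estimateAlphaExchangeable(res), estimateAlphaExchangeable(resSwap))
})

test_that("degenerate alpha inputs fall back sensibly", {
    z <- list(e1 = matrix(0, 4, 3), e2 = matrix(0, 4, 3))
    expect_equal(estimateAlphaAR1(z), 0)
    expect_equal(estimateAlphaExchangeable(z), 0)
    # perfect persistence saturates at the clamp
    o <- list(e1 = matrix(1, 50, 10), e2 = matrix(1, 50, 10))
    expect_equal(estimateAlphaAR1(o), 0.99)
    # too few pairs: N * (M - 1) - 2 <= 0
    tiny <- list(e1 = matrix(1, 1, 2), e2 = matrix(1, 1, 2))
    expect_warning(a <- estimateAlphaAR1(tiny), "falling back")
    expect_equal(a, 0)
})

test_that("exchangeable alpha estimate approaches the brute-force pairwise correlation", {
    set.seed(77)
    N <- 800; M <- 6
    b <- rnorm(N)
    mk <- function() sqrt(0.5) * matrix(b, N, M) + sqrt(0.5) * matrix(rnorm(N * M), N)
    res <- list(e1 = mk(), e2 = mk())
    # oracle: average correlation over all distinct time pairs and components
    avg <- function(e) {
        cc <- cor(e)
        mean(cc[upper.tri(cc)])
    }
    oracle <- (avg(res$e1) + avg(res$e2)) / 2
    expect_lt(abs(estimateAlphaExchangeable(res) - oracle), 0.05)
})
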