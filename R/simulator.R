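#' Create a simulation scenario
#'
#' Defaults reproduce the reference evaluation design: two conditions of 25
#' subjects each followed over 10 time points, 1000 zero-inflated Poisson
#' features of which the first 200 are differentially abundant with a
#' linearly increasing treatment trajectory, and AR(1) Gaussian-copula
#' dependence at \code{rho = 0.6} across time points. Baseline means are
#' log-uniform on \code{[1, 50]} and the structural-zero probability
#' decreases with the mean through \code{plogis(zeroA - zeroB * log(mu))}.
#'
#' @param nPerGroup subjects per condition.
#' @param M time points.
#' @param nFeatures total number of features.
#' @param nDaf number of differentially abundant features (the first
#'   \code{nDaf} feature indices).
#' @param structure copula correlation structure over time points.
#' @param rho copula correlation level.
#' @param mu0Range range of the log-uniform baseline mean distribution.
#' @param zeroA,zeroB zero-link intercept and (positive) slope.
#' @param effect \code{"linear"} or \code{"exponential"} treatment
#'   trajectory for DAFs.
#' @param effectSize slope / rate of the DAF trajectory.
#' @param seed base seed; every feature derives its own sub-seed from it.
#' @return a [SimScenario-class].
#' @examples
#' simScenario(nFeatures = 100, nDaf = 20, seed = 7)
#' @export
simScenario <- function(nPerGroup = 25, M = 10, nFeatures = 1000, nDaf = 200,
                        structure = c("ar1", "exchangeable"), rho = 0.6,
                        mu0Range = c(1, 50), zeroA = 0, zeroB = 1,
                        effect = c("linear", "exponential"), effectSize = 0.2,
                        seed = 1) {
    new("SimScenario", nPerGroup = as.integer(nPerGroup), M = as.integer(M),
        nFeatures = as.integer(nFeatures), nDaf = as.integer(nDaf),
        structure = match.arg(structure), rho = as.numeric(rho),
        mu0Range = as.numeric(mu0Range), zeroA = as.numeric(zeroA),
        zeroB = as.numeric(zeroB), effect = match.arg(effect),
        effectSize = as.numeric(effectSize), seed = as.integer(seed))
}

# per-feature baseline mean, drawn log-uniformly from the scenario range
# with the feature's own sub-seed so it is reproducible feature-by-feature
.featureMu0 <- function(scenario, feature) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(.subSeed(scenario@seed, feature))
    exp(stats::runif(1, log(scenario@mu0Range[1L]), log(scenario@mu0Range[2L])))
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Mean trajectory of a feature
#'
#' Non-differential features, and every feature in the control group, have a
#' static mean \code{mu0}. Differential features in the treatment group grow
#' linearly, \code{mu0 * (1 + s * (j - 1))}, or exponentially,
#' \code{mu0 * exp(r * (j - 1))}, over time points \code{j = 1..M}.
#'
#' @param scenario a [SimScenario-class].
#' @param feature feature index in \code{1..nFeatures}.
#' @param group \code{"control"} or \code{"treatment"}.
#' @return numeric vector of \code{M} positive means.
#' @export
featureMeanProfile <- function(scenario, feature, group = c("control", "treatment")) {
    group <- match.arg(group)
    validObject(scenario)
    stopifnot(feature >= 1L, feature <= scenario@nFeatures)
    mu0 <- .featureMu0(scenario, feature)
    j <- seq_len(scenario@M)
    daf <- feature <= scenario@nDaf
    mu <- if (!daf || group == "control") {
        rep(mu0, scenario@M)
    } else if (scenario@effect == "linear") {
        mu0 * (1 + scenario@effectSize * (j - 1))
    } else {
        mu0 * exp(scenario@effectSize * (j - 1))
    }
    if (any(mu <= 0)) stop("non-positive mean in trajectory")
    mu
}

#' Structural-zero probability link
#'
#' \code{rho = plogis(a - b * log(mu))}: the zero fraction decreases as the
#' mean abundance increases (strictly, for \code{b > 0}).
#'
#' @param mu positive mean(s).
#' @param a link intercept.
#' @param b positive link slope.
#' @return structural-zero probabilities in \code{(0, 1)}.
#' @examples
#' zeroProbability(c(1, exp(1)), a = 0, b = 1)
#' @export
zeroProbability <- function(mu, a = 0, b = 1) {
    stopifnot(all(mu > 0), b > 0)
    stats::plogis(a - b * log(mu))
}

# exact ZIP quantile: P(Y = 0) = rho + (1 - rho) exp(-mu), and for
# u above the zero mass the Poisson quantile at the rescaled probability
.zipQuantile <- function(u, rho, mu) {
    stats::qpois(pmax((u - rho) / (1 - rho), 0), lambda = mu)
}

# M x M copula correlation over time points
.copulaSigma <- function(structure, rho, M) {
    switch(structure,
        ar1 = rho^abs(outer(seq_len(M), seq_len(M), "-")),
        exchangeable = matrix(rho, M, M) + diag(1 - rho, M),
        independence = diag(M))
}

# n x M ZIP draws with Gaussian-copula dependence across columns;
# rho/mu are vectors of length M (per-time marginal parameters)
.copulaZip <- function(n, rhoZero, mu, Sigma) {
    M <- length(mu)
    Z <- matrix(stats::rnorm(n * M), n, M)
    if (!all(Sigma == diag(M))) Z <- Z %*% chol(Sigma)
    U <- stats::pnorm(Z)
    Y <- matrix(0, n, M)
    for (j in seq_len(M)) Y[, j] <- .zipQuantile(U[, j], rhoZero[j], mu[j])
    Y
}

#' Simulate one feature of a two-group study
#'
#' Draws counts for both conditions from zero-inflated Poisson margins tied
#' together over time by a Gaussian copula with the scenario's correlation
#' structure. Uses the feature's sub-seed, so features are mutually
#' independent and individually reproducible.
#'
#' @inheritParams featureMeanProfile
#' @return list with \code{control} and \code{treatment} count matrices
#'   (\code{nPerGroup x M}) and the marginal parameter matrices
#'   \code{mu} and \code{rhoZero} (2 rows: control, treatment).
#' @export
simulateFeature <- function(scenario, feature) {
    validObject(scenario)
    muC <- featureMeanProfile(scenario, feature, "control")
    muT <- featureMeanProfile(scenario, feature, "treatment")
    rhoC <- zeroProbability(muC, scenario@zeroA, scenario@zeroB)
    rhoT <- zeroProbability(muT, scenario@zeroA, scenario@zeroB)
    Sigma <- .copulaSigma(scenario@structure, scenario@rho, scenario@M)
    stopifnot(all(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values > 0))
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(.subSeed(scenario@seed, scenario@nFeatures + feature))
    list(
        control = .copulaZip(scenario@nPerGroup, rhoC, muC, Sigma),
        treatment = .copulaZip(scenario@nPerGroup, rhoT, muT, Sigma),
        mu = rbind(control = muC, treatment = muT),
        rhoZero = rbind(control = rhoC, treatment = rhoT))
}

#' Simulate a full longitudinal study
#'
#' Assembles all features of the scenario into a
#' \code{SummarizedExperiment}: a \code{counts} assay (features x samples),
#' sample metadata (\code{sample_id}, \code{subject}, \code{time},
#' \code{group}) in \code{colData}, and per-feature truth
#' (\code{is_daf}, baseline mean) in \code{rowData}. Samples are ordered
#' subject-major (all time points of subject 1, then subject 2, ...), with
#' control subjects first.
#'
#' @param scenario a [SimScenario-class].
#' @return a \code{SummarizedExperiment}.
#' @examples
#' se <- simulateStudy(simScenario(nPerGroup = 5, M = 4, nFeatures = 10,
#'     nDaf = 2, seed = 11))
#' dim(se)
#' @export
simulateStudy <- function(scenario) {
    validObject(scenario)
    n <- scenario@nPerGroup; M <- scenario@M
    nSamp <- 2L * n * M
    counts <- matrix(0L, scenario@nFeatures, nSamp)
    for (f in seq_len(scenario@nFeatures)) {
        sim <- simulateFeature(scenario, f)
        counts[f, ] <- as.integer(c(t(sim$control), t(sim$treatment)))
    }
    subjects <- paste0(rep(rep(c("C", "T"), each = n), each = M),
        rep(rep(seq_len(n), 2L), each = M))
    time <- rep(seq_len(M), 2L * n)
    group <- rep(c("control", "treatment"), each = n * M)
    sampleIds <- paste0(subjects, ".t", time)
    colnames(counts) <- sampleIds
    rownames(counts) <- sprintf("feature_%04d", seq_len(scenario@nFeatures))
    colData <- S4Vectors::DataFrame(
        sample_id = sampleIds, subject = subjects, time = time, group = group,
        row.names = sampleIds)
    rowData <- S4Vectors::DataFrame(
        feature_id = rownames(counts),
        is_daf = seq_len(scenario@nFeatures) <= scenario@nDaf,
        mu0 = vapply(seq_len(scenario@nFeatures), function(f)
            .featureMu0(scenario, f), numeric(1)))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = colData, rowData = rowData)
}

#' Simulate a single panel with known coefficients
#'
#' Convenience generator for method checks: a two-group design
#' (\code{U = V = [1, group]}) with true zero-part coefficients
#' \code{betaU} (logit link) and count-part coefficients \code{betaV}
#' (log link), ZIP margins and optional Gaussian-copula dependence over
#' time.
#'
#' @param N total subjects (first half control, second half treatment).
#' @param M time points.
#' @param betaU,betaV true coefficient vectors of length 2
#'   (intercept, group).
#' @param structure copula structure (\code{"independence"} for i.i.d.
#'   time points).
#' @param rho copula correlation.
#' @param seed RNG seed.
#' @return a [FeaturePanel-class].
#' @export
simulatePanel <- function(N, M, betaU = c(-1, 0.5), betaV = c(1, 0.3),
                          structure = c("independence", "ar1", "exchangeable"),
                          rho = 0, seed = 1) {
    structure <- match.arg(structure)
    stopifnot(length(betaU) == 2L, length(betaV) == 2L, N >= 2L)
    g <- rep(c(0, 1), c(ceiling(N / 2), floor(N / 2)))
    rhoZ <- stats::plogis(betaU[1L] + betaU[2L] * g)
    mu <- exp(betaV[1L] + betaV[2L] * g)
    Sigma <- .copulaSigma(if (rho == 0) "independence" else structure, rho, M)
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    y <- matrix(0, N, M)
    for (i in seq_len(N)) {
        y[i, ] <- .copulaZip(1L, rep(rhoZ[i], M), rep(mu[i], M), Sigma)
    }
    X <- cbind(`(Intercept)` = 1, group = rep(g, each = M))
    featurePanel(y, X, X)
}
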