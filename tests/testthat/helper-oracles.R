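# Independent oracle implementations used to cross-check the package:
# deliberately naive (loops, dense algebra, brute force) and kept separate
# from the code paths they validate.

# central finite differences of the stacked mean functions h_i
fdJacobian <- function(panel, betaU, betaV, zeroPart = TRUE, eps = 1e-6) {
    N <- nSubjects(panel); M <- nTimes(panel)
    hvec <- function(bU, bV) {
        m <- computeMoments(panel, bU, bV, zeroPart)
        out <- matrix(0, N, 2 * M)
        out[, seq(1, 2 * M, 2)] <- m$h1
        out[, seq(2, 2 * M, 2)] <- m$h2
        out
    }
    pu <- if (zeroPart) length(betaU) else 0
    pv <- length(betaV)
    D <- array(0, dim = c(pu + pv, 2 * M, N))
    for (k in seq_len(pu)) {
        up <- betaU; up[k] <- up[k] + eps
        dn <- betaU; dn[k] <- dn[k] - eps
        D[k, , ] <- t((hvec(up, betaV) - hvec(dn, betaV)) / (2 * eps))
    }
    for (k in seq_len(pv)) {
        up <- betaV; up[k] <- up[k] + eps
        dn <- betaV; dn[k] <- dn[k] - eps
        D[pu + k, , ] <- t((hvec(betaU, up) - hvec(betaU, dn)) / (2 * eps))
    }
    D
}

# literal step-up definition: q_(i) = min_{k >= i} m p_(k) / k, capped at 1
bruteForceBH <- function(p) {
    q <- rep(NA_real_, length(p))
    idx <- which(!is.na(p))
    m <- length(idx)
    if (m == 0) return(q)
    ord <- order(p[idx])
    ps <- p[idx][ord]
    adj <- numeric(m)
    for (i in seq_len(m)) {
        adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
    }
    q[idx[ord]] <- adj
    q
}

# dense double-loop sandwich: forms every V_i explicitly and inverts it
naiveSandwich <- function(panel, fit) {
    zeroPart <- !anyNA(fit@betaU)
    M <- nTimes(panel); N <- nSubjects(panel)
    corr <- corrzidf:::.weightCorr(fit@structure, fit@alphaHat, M)
    mom <- computeMoments(panel, fit@betaU, fit@betaV, zeroPart)
    D <- panelJacobian(panel, fit@betaU, fit@betaV, zeroPart, moments = mom)
    f <- responseFunctions(panel)
    p <- dim(D)[1]
    B <- matrix(0, p, p)
    meat <- matrix(0, p, p)
    Rrep <- corr@R + diag(corr@ridge, 2 * M)
    for (i in seq_len(N)) {
        a <- numeric(2 * M); s <- numeric(2 * M)
        for (j in seq_len(M)) {
            a[2 * j - 1] <- max(mom$a1[i, j], 1e-12)
            a[2 * j] <- max(mom$a2[i, j], 1e-12)
            s[2 * j - 1] <- if (mom$a1[i, j] <= 1e-12) 0 else f$f1[i, j] - mom$h1[i, j]
            s[2 * j] <- if (mom$a2[i, j] <= 1e-12) 0 else f$f2[i, j] - mom$h2[i, j]
        }
        Vi <- diag(sqrt(a)) %*% Rrep %*% diag(sqrt(a))
        Vinv <- solve(Vi)
        Di <- matrix(D[, , i], nrow = p)
        B <- B + Di %*% Vinv %*% t(Di)
        u <- Di %*% Vinv %*% s
        meat <- meat + u %*% t(u)
    }
    Binv <- solve(B)
    S <- Binv %*% meat %*% t(Binv)
    (S + t(S)) / 2
}

# two-part fit that never forms a correlation matrix: elementwise
# inverse-variance weights, damped Newton on the estimating function
directIndependenceFit <- function(panel, tol = 1e-10, maxIter = 100) {
    zeroPart <- any(panel@y == 0)
    pu <- if (zeroPart) ncol(panel@U) else 0
    pv <- ncol(panel@V)
    f <- responseFunctions(panel)
    score <- function(th) {
        bU <- if (zeroPart) th[seq_len(pu)] else rep(0, ncol(panel@U))
        bV <- th[pu + seq_len(pv)]
        mom <- computeMoments(panel, bU, bV, zeroPart)
        D <- panelJacobian(panel, bU, bV, zeroPart, moments = mom)
        U <- numeric(pu + pv)
        for (i in seq_len(nrow(panel@y))) {
            for (j in seq_len(ncol(panel@y))) {
                if (mom$a1[i, j] > 1e-12) {
                    U <- U + D[, 2 * j - 1, i] * (f$f1[i, j] - mom$h1[i, j]) / mom$a1[i, j]
                }
                if (mom$a2[i, j] > 1e-12) {
                    U <- U + D[, 2 * j, i] * (f$f2[i, j] - mom$h2[i, j]) / mom$a2[i, j]
                }
            }
        }
        U
    }
    ini <- corrzidf:::.initCoefs(panel, zeroPart)
    th <- c(if (zeroPart) ini$betaU else numeric(0), ini$betaV)
    p <- length(th)
    for (it in seq_len(maxIter)) {
        U0 <- score(th)
        J <- matrix(0, p, p)
        for (k in seq_len(p)) {
            tp <- th; tp[k] <- tp[k] + 1e-6
            tm <- th; tm[k] <- tm[k] - 1e-6
            J[, k] <- (score(tp) - score(tm)) / 2e-6
        }
        d <- solve(J, -U0)
        n0 <- sqrt(sum(U0^2))
        s <- 1
        while (sqrt(sum(score(th + s * d)^2)) > n0 && s > 1e-6) s <- s / 2
        th <- th + s * d
        if (max(abs(s * d)) < tol) break
    }
    list(betaU = if (zeroPart) th[seq_len(pu)] else rep(NA_real_, ncol(panel@U)),
         betaV = th[pu + seq_len(pv)], zeroPart = zeroPart)
}

# ZIP closed forms
zipZeroProb <- function(rho, mu) rho + (1 - rho) * exp(-mu)
zipMean <- function(rho, mu) (1 - rho) * mu
zipVar <- function(rho, mu) (1 - rho) * mu * (1 + rho * mu)
zipCdf <- function(q, rho, mu) rho + (1 - rho) * ppois(q, mu)

# direct ZIP sampler (mixture definition, independent of the copula path)
rzip <- function(n, rho, mu) ifelse(runif(n) < rho, 0, rpois(n, mu))

# brute-force average correlation of adjacent residual pairs, pooled over
# the two components
alphaLag1Oracle <- function(res) {
    M <- ncol(res$e1)
    x <- c(as.vector(res$e1[, -M]), as.vector(res$e2[, -M]))
    y <- c(as.vector(res$e1[, -1]), as.vector(res$e2[, -1]))
    mean(x * y)
}

# small deterministic panel builder used across tests
toyPanel <- function(y, groups = NULL, times = NULL) {
    y <- as.matrix(y)
    N <- nrow(y); M <- ncol(y)
    if (is.null(groups)) groups <- rep(c(0, 1), length.out = N)
    X <- cbind(`(Intercept)` = 1, group = rep(groups, each = M))
    featurePanel(y, X, X, timeIndex = if (is.null(times)) seq_len(M) else times)
}
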