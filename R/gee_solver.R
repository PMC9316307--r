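#' Control parameters for the GEE fit
#'
#' @param tol convergence tolerance on the largest absolute coefficient
#'   update.
#' @param alphaTol convergence tolerance on the working correlation update.
#' @param maxIter maximum outer iterations (each = one Fisher-scoring step
#'   plus one correlation update).
#' @param maxHalvings maximum step halvings per scoring step.
#' @return list of control values.
#' @export
fitControl <- function(tol = 1e-6, alphaTol = 1e-4, maxIter = 200L, maxHalvings = 10L) {
    stopifnot(tol > 0, alphaTol > 0, maxIter >= 1L)
    list(tol = tol, alphaTol = alphaTol, maxIter = as.integer(maxIter),
        maxHalvings = as.integer(maxHalvings))
}

#' Subject-level working covariance
#'
#' \code{V_i = A_i^{1/2} R(alpha) A_i^{1/2}} where \code{A_i} is the diagonal
#' of working variances \code{(a1_i1, a2_i1, ..., a1_iM, a2_iM)} in the
#' interleaved-by-time order matching the stacked responses.
#'
#' @param moments a [computeMoments()] result.
#' @param corr a [WorkingCorrelation-class].
#' @param subject subject index.
#' @return symmetric \code{2M x 2M} matrix.
#' @export
assembleV <- function(moments, corr, subject) {
    a <- .interleave(moments$a1, moments$a2)[subject, ]
    stopifnot(all(a > 0), length(a) == nrow(corr@R))
    sq <- sqrt(a)
    outer(sq, sq) * corr@R
}

# score, expected information and meat of the estimating equations,
# computed in standardized form: D V^-1 x = (D A^-1/2) R^-1 (A^-1/2 x),
# with R factorized (and ridge-repaired) once per call. Vectorized over
# subjects: for each coefficient the standardized derivative of the stacked
# means is an N x 2M matrix, so all sums reduce to elementwise products and
# one small matmul per coefficient.
.geeQuantities <- function(panel, betaU, betaV, corr, zeroPart = TRUE,
                           needMeat = FALSE) {
    mom <- computeMoments(panel, betaU, betaV, zeroPart)
    f <- responseFunctions(panel)
    N <- nSubjects(panel); M <- nTimes(panel)
    H <- .interleave(mom$h1, mom$h2)
    Fm <- .interleave(f$f1, f$f2)
    A0 <- .interleave(mom$a1, mom$a2)
    A <- pmax(A0, 1e-12)
    sqa <- sqrt(A)
    Es <- (Fm - H) / sqa
    # degenerate cells (vanishing working variance, e.g. rho pinned at the
    # clip boundary) carry no usable information; keep them out of the
    # weighted sums, matching the Pearson-residual convention
    Es[A0 <= 1e-12] <- 0
    Rinv <- chol2inv(corr@cholR)
    rho <- mom$rho; mu <- mom$mu
    emu <- exp(-mu)
    drho <- rho * (1 - rho)
    c1u <- (1 - emu) * drho        # d h1 / d etaU
    c2u <- -drho * mu              # d h2 / d etaU
    c1v <- -(1 - rho) * emu * mu   # d h1 / d etaV
    c2v <- (1 - rho) * mu          # d h2 / d etaV
    pu <- if (zeroPart) ncol(panel@U) else 0L
    pv <- ncol(panel@V)
    p <- pu + pv
    Dls <- vector("list", p)
    for (k in seq_len(pu)) {
        Xk <- matrix(panel@U[, k], N, M, byrow = TRUE)
        Dls[[k]] <- .interleave(c1u * Xk, c2u * Xk) / sqa
    }
    for (k in seq_len(pv)) {
        Xk <- matrix(panel@V[, k], N, M, byrow = TRUE)
        Dls[[pu + k]] <- .interleave(c1v * Xk, c2v * Xk) / sqa
    }
    DR <- lapply(Dls, function(D) D %*% Rinv)
    gmat <- vapply(DR, function(G) rowSums(G * Es), numeric(N))
    gmat <- matrix(gmat, nrow = N)
    score <- colSums(gmat)
    info <- matrix(0, p, p)
    for (j in seq_len(p)) {
        for (k in j:p) {
            info[j, k] <- info[k, j] <- sum(DR[[j]] * Dls[[k]])
        }
    }
    meat <- if (needMeat) crossprod(gmat) else matrix(0, p, p)
    nms <- .paramNames(panel, zeroPart)
    names(score) <- nms
    dimnames(info) <- list(nms, nms)
    dimnames(meat) <- list(nms, nms)
    list(score = score, info = info, meat = meat, ridge = corr@ridge,
        p = p, N = N, moments = mom)
}

.scoreNorm <- function(panel, betaU, betaV, corr, zeroPart) {
    q <- .geeQuantities(panel, betaU, betaV, corr, zeroPart)
    sqrt(sum(q$score^2))
}

#' One Fisher-scoring update of the GEE
#'
#' Solves the estimating equations \code{sum_i D_i V_i^-1 (f_i - h_i) = 0}
#' by one scoring step
#' \code{theta+ = theta + (sum_i D_i V_i^-1 D_i')^-1 sum_i D_i V_i^-1 S_i},
#' halving the step (up to \code{maxHalvings} times) whenever the Euclidean
#' norm of the estimating function does not decrease.
#'
#' @inheritParams computeMoments
#' @param corr a [WorkingCorrelation-class].
#' @param maxHalvings maximum number of step halvings.
#' @return list with updated \code{betaU}, \code{betaV}, the largest
#'   absolute update \code{maxAbsUpdate}, the estimating-function norm at
#'   the accepted point, and a \code{singular} flag.
#' @export
geeStep <- function(panel, betaU, betaV, corr, zeroPart = TRUE, maxHalvings = 10L) {
    q <- .geeQuantities(panel, betaU, betaV, corr, zeroPart)
    sol <- .solveSym(q$info, q$score)
    delta <- drop(sol$x)
    norm0 <- sqrt(sum(q$score^2))
    pu <- if (zeroPart) length(betaU) else 0L
    step <- 1
    for (h in 0:maxHalvings) {
        dU <- if (pu) betaU + step * delta[seq_len(pu)] else betaU
        dV <- betaV + step * delta[pu + seq_along(betaV)]
        norm1 <- .scoreNorm(panel, dU, dV, corr, zeroPart)
        if (norm1 <= norm0 || h == maxHalvings) break
        step <- step / 2
    }
    list(betaU = dU, betaV = dV, maxAbsUpdate = max(abs(step * delta)),
        scoreNorm = norm1, scoreNorm0 = norm0, singular = sol$singular)
}

# weighting matrix actually used by the solver: R built at alpha capped to
# the in-family definiteness boundary, so the inverse weights stay bounded
# while the block correlation shape is preserved (a large diagonal ridge
# would shrink all correlations toward zero and forfeit the efficiency the
# working structure is there to buy)
.weightCorr <- function(structure, alpha, M) {
    if (is.na(alpha)) alpha <- 0
    buildWorkingCorrelation(structure, min(alpha, .alphaCap(structure, M)), M)
}

# damped Newton on the estimating function with a central-difference
# Jacobian; used when plain Fisher scoring stalls (the all-ones cross-
# component blocks of R(alpha) can make the expected information a poor —
# even wrongly signed — curvature proxy along soft directions)
.newtonSolve <- function(panel, betaU, betaV, corr, zeroPart, tol,
                         maxIter = 40L, maxHalvings = 15L) {
    pu <- if (zeroPart) length(betaU) else 0L
    th <- c(if (zeroPart) betaU else numeric(0), betaV)
    p <- length(th)
    split <- function(th) {
        list(bU = if (zeroPart) th[seq_len(pu)] else betaU,
             bV = th[pu + seq_len(p - pu)])
    }
    sc <- function(th) {
        b <- split(th)
        .geeQuantities(panel, b$bU, b$bV, corr, zeroPart)$score
    }
    singular <- FALSE
    upd <- Inf
    U0 <- sc(th)
    n0 <- sqrt(sum(U0^2))
    for (it in seq_len(maxIter)) {
        J <- matrix(0, p, p)
        eps <- 1e-5
        for (k in seq_len(p)) {
            tp <- th; tp[k] <- tp[k] + eps
            tm <- th; tm[k] <- tm[k] - eps
            J[, k] <- (sc(tp) - sc(tm)) / (2 * eps)
        }
        d <- tryCatch(solve(J, -U0), error = function(e) NULL)
        if (is.null(d)) {
            singular <- TRUE
            d <- -.pinv(J) %*% U0
        }
        s <- 1
        for (h in 0:maxHalvings) {
            n1 <- sqrt(sum(sc(th + s * d)^2))
            if (n1 < n0 || h == maxHalvings) break
            s <- s / 2
        }
        th <- th + s * d
        upd <- max(abs(s * d))
        U0 <- sc(th)
        n0 <- sqrt(sum(U0^2))
        if (upd < tol) break
    }
    b <- split(th)
    list(betaU = b$bU, betaV = b$bV, maxAbsUpdate = upd, scoreNorm = n0,
        singular = singular)
}

#' Fit the two-part GEE for one feature
#'
#' Alternates Fisher-scoring updates of the coefficients with moment updates
#' of the working correlation parameter (starting from independence) until
#' the largest coefficient update falls below \code{control$tol} and the
#' correlation update below \code{control$alphaTol}. Zero-part coefficients
#' are initialized from a logistic fit of \code{I(y == 0)} on \code{U},
#' count-part coefficients from a Poisson fit of \code{y} on \code{V}
#' restricted to positive counts.
#'
#' Degenerate features: an all-zero feature is not fit (status
#' \code{"all_zero"}); a feature without zeros is fit with the zero part
#' disabled, pinning \code{rho = 0} (status \code{"no_zeros"}), which keeps
#' the count-part test available while avoiding an unidentifiable mixture
#' weight.
#'
#' @param panel a [FeaturePanel-class].
#' @param structure working correlation structure.
#' @param control a [fitControl()] list.
#' @return a [CorrZidfFit-class] with the robust sandwich covariance.
#' @examples
#' panel <- simulatePanel(40, 5, betaU = c(-1, 0.5), betaV = c(1, 0.3), seed = 1)
#' fit <- fitFeature(panel, "ar1")
#' coefCount(fit)
#' @export
fitFeature <- function(panel, structure = c("independence", "ar1", "exchangeable"),
                       control = fitControl()) {
    structure <- match.arg(structure)
    stopifnot(is(panel, "FeaturePanel"))
    validObject(panel)
    N <- nSubjects(panel); M <- nTimes(panel)
    pu <- ncol(panel@U); pv <- ncol(panel@V)
    if (all(panel@y == 0)) {
        return(new("CorrZidfFit", betaU = rep(NA_real_, pu), betaV = rep(NA_real_, pv),
            alphaHat = NA_real_, sigmaBeta = matrix(numeric(0), 0, 0),
            nIter = 0L, converged = FALSE, maxAbsUpdate = NA_real_,
            structure = structure, status = "all_zero", N = N, M = M))
    }
    zeroPart <- any(panel@y == 0)
    init <- .initCoefs(panel, zeroPart)
    betaU <- init$betaU; betaV <- init$betaV
    alpha <- 0
    corr <- buildWorkingCorrelation(structure, 0, M)
    iter <- 0L
    converged <- FALSE
    maxUpd <- Inf
    singular <- FALSE
    stepA <- 1
    lastDir <- 0
    clampCount <- 0L
    while (iter < control$maxIter) {
        iter <- iter + 1L
        thetaOld <- c(betaU, betaV)
        st <- geeStep(panel, betaU, betaV, corr, zeroPart, control$maxHalvings)
        # fall back to damped Newton when the scoring step no longer shrinks
        # the estimating function (soft / wrongly-curved directions)
        if (st$maxAbsUpdate >= control$tol && st$scoreNorm > 0.9 * st$scoreNorm0) {
            st <- .newtonSolve(panel, st$betaU, st$betaV, corr, zeroPart,
                control$tol)
        }
        betaU <- st$betaU; betaV <- st$betaV
        maxUpd <- max(abs(c(betaU, betaV) - thetaOld))
        singular <- st$singular
        deltaAlpha <- 0
        if (structure != "independence" && M >= 2L) {
            res <- suppressWarnings(pearsonResiduals(panel, betaU, betaV, zeroPart))
            alphaNew <- switch(structure,
                ar1 = estimateAlphaAR1(res),
                exchangeable = estimateAlphaExchangeable(res))
            # damped fixed-point update with adaptive step: halve the step
            # whenever the update direction flips (oscillating alpha map);
            # the fixed point is unchanged
            dir <- sign(alphaNew - alpha)
            if (dir != 0 && lastDir != 0 && dir != lastDir) {
                stepA <- max(stepA / 2, 0.05)
            }
            lastDir <- dir
            deltaAlpha <- abs(alphaNew - alpha)
            alpha <- alpha + stepA * (alphaNew - alpha)
            corr <- .weightCorr(structure, alpha, M)
        }
        if (maxUpd < control$tol && deltaAlpha < control$alphaTol) {
            converged <- TRUE
            break
        }
        # alpha pinned at the clamp with coefficients still moving: the
        # working model cannot represent this feature's residual dependence;
        # stop early and report the failure rather than cycling
        clampCount <- if (alpha >= 0.985) clampCount + 1L else 0L
        if (clampCount >= 5L && maxUpd >= control$tol) break
    }
    if (singular) converged <- FALSE
    fit <- new("CorrZidfFit",
        betaU = if (zeroPart) betaU else rep(NA_real_, pu),
        betaV = betaV, alphaHat = alpha,
        sigmaBeta = matrix(numeric(0), 0, 0),
        nIter = iter, converged = converged, maxAbsUpdate = maxUpd,
        structure = structure,
        status = if (!converged) "not_converged" else if (!zeroPart) "no_zeros" else "ok",
        N = N, M = M)
    fit@sigmaBeta <- sandwichCovariance(panel, fit)
    validObject(fit)
    fit
}

.initCoefs <- function(panel, zeroPart) {
    M <- nTimes(panel)
    yv <- as.vector(t(panel@y))   # subject-major, matches design row order
    pu <- ncol(panel@U); pv <- ncol(panel@V)
    betaU <- rep(0, pu)
    if (zeroPart) {
        z <- as.numeric(yv == 0)
        betaU[1L] <- stats::qlogis(min(max(mean(z), 0.02), 0.98))
        cf <- tryCatch(
            suppressWarnings(stats::glm.fit(panel@U, z,
                family = stats::binomial())$coefficients),
            error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) betaU <- pmin(pmax(cf, -10), 10)
    }
    pos <- yv > 0
    betaV <- rep(0, pv)
    betaV[1L] <- log(max(mean(yv[pos]), 1e-3))
    if (sum(pos) > pv) {
        cf <- tryCatch(
            suppressWarnings(stats::glm.fit(panel@V[pos, , drop = FALSE], yv[pos],
                family = stats::poisson())$coefficients),
            error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) betaV <- pmin(pmax(cf, -10), 10)
    }
    list(betaU = betaU, betaV = betaV)
}

#' Robust sandwich covariance of a fit
#'
#' Plug-in sandwich estimator
#' \deqn{\hat\Sigma_\beta = \hat B^{-1} \Big(\frac1N \sum_i
#'   D_i V_i^{-1} S_i S_i' V_i^{-1} D_i'\Big) \hat B^{-T}, \qquad
#'   \hat B = \frac1N \sum_i D_i V_i^{-1} D_i',}
#' evaluated at the fitted coefficients and correlation. The returned matrix
#' is on the per-estimate scale (\eqn{\hat\Sigma_\beta / N}), numerically
#' symmetrized, so its diagonal square roots are standard errors of the
#' coefficient estimates.
#'
#' @param panel the [FeaturePanel-class] the fit came from.
#' @param fit a [CorrZidfFit-class].
#' @return symmetric covariance matrix with \code{"u:"}/\code{"v:"}-prefixed
#'   dimnames covering the estimated coefficients.
#' @export
sandwichCovariance <- function(panel, fit) {
    if (fit@status == "all_zero") return(matrix(numeric(0), 0, 0))
    zeroPart <- !anyNA(fit@betaU)
    corr <- .weightCorr(fit@structure, fit@alphaHat, nTimes(panel))
    q <- .geeQuantities(panel, fit@betaU, fit@betaV, corr, zeroPart, needMeat = TRUE)
    Binv <- tryCatch(solve(q$info), error = function(e) {
        warning("singular bread matrix; using pseudo-inverse")
        .pinv(q$info)
    })
    # info and meat are raw sums; B-hat = info / N and meat-hat = meat / N, so
    # Sigma / N = info^-1 meat info^-1 exactly
    S <- Binv %*% q$meat %*% t(Binv)
    S <- (S + t(S)) / 2
    # numerical PSD projection: an ill-conditioned bread can leave tiny
    # negative eigenvalues after the triple product
    ev <- eigen(S, symmetric = TRUE)
    if (any(ev$values < 0)) {
        S <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
        S <- (S + t(S)) / 2
    }
    dimnames(S) <- dimnames(q$info)
    S
}

#' Estimating-function norm at given coefficients
#'
#' Mostly a diagnostic: the max-norm of \code{U_N(theta)} should be near 0
#' at a converged solution.
#'
#' @inheritParams geeStep
#' @return largest absolute component of the estimating function.
#' @export
estimatingFunctionNorm <- function(panel, betaU, betaV, corr, zeroPart = TRUE) {
    q <- .geeQuantities(panel, betaU, betaV, corr, zeroPart)
    max(abs(q$score))
}
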