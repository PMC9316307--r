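#' Two-part response functions
#'
#' The distribution-free model works with a bivariate functional response at
#' each observation: the zero indicator \code{f1 = I(y == 0)} and the raw
#' count \code{f2 = y}. Modelling both jointly identifies the two parts of a
#' zero-inflated mixture without a likelihood.
#'
#' @param panel a [FeaturePanel-class].
#' @return list with matrices \code{f1} and \code{f2} (subjects x times).
#' @examples
#' p <- featurePanel(matrix(c(0L, 3L, 0L), 1), matrix(1, 3, 1))
#' responseFunctions(p)
#' @export
responseFunctions <- function(panel) {
    stopifnot(is(panel, "FeaturePanel"))
    validObject(panel)
    list(f1 = (panel@y == 0) * 1, f2 = panel@y)
}

#' Mean and working-variance functions of the two-part model
#'
#' Computes, for every cell of the panel, the structural-zero probability
#' \code{rho = plogis(U betaU)}, the Poisson-part mean \code{mu = exp(V betaV)},
#' the response means
#' \deqn{h_1 = \rho + (1 - \rho) e^{-\mu}, \qquad h_2 = (1 - \rho)\mu,}
#' and the zero-inflated Poisson working variances
#' \deqn{Var(f_1) = h_1 (1 - h_1), \qquad Var(f_2) = (1 - \rho)\mu(1 + \rho\mu).}
#' Linear predictors are clipped to \code{[-30, 30]} before the inverse link
#' so the result is always finite.
#'
#' @param panel a [FeaturePanel-class].
#' @param betaU zero-part coefficients (length \code{ncol(U)}); ignored when
#'   \code{zeroPart = FALSE}.
#' @param betaV count-part coefficients (length \code{ncol(V)}).
#' @param zeroPart set \code{FALSE} to pin \code{rho = 0} exactly (used for
#'   features without any observed zero, where the mixture weight is not
#'   identifiable); the model then reduces to a Poisson-moment model.
#' @return list of subjects-x-times matrices \code{rho}, \code{mu}, \code{h1},
#'   \code{h2}, \code{a1}, \code{a2} (the two working variances), plus the
#'   logical \code{zeroPart}.
#' @examples
#' p <- featurePanel(matrix(c(0L, 3L, 0L), 1), matrix(1, 3, 1))
#' m <- computeMoments(p, betaU = 0, betaV = 0)
#' m$h1[1, 1]  # 0.5 + 0.5 * exp(-1)
#' @export
computeMoments <- function(panel, betaU, betaV, zeroPart = TRUE) {
    stopifnot(is(panel, "FeaturePanel"))
    N <- nSubjects(panel); M <- nTimes(panel)
    if (zeroPart) {
        stopifnot(length(betaU) == ncol(panel@U), all(is.finite(betaU)))
        etaU <- .clip(drop(panel@U %*% betaU))
        rho <- matrix(stats::plogis(etaU), N, M, byrow = TRUE)
    } else {
        rho <- matrix(0, N, M)
    }
    stopifnot(length(betaV) == ncol(panel@V), all(is.finite(betaV)))
    etaV <- .clip(drop(panel@V %*% betaV))
    mu <- matrix(exp(etaV), N, M, byrow = TRUE)
    emu <- exp(-mu)
    h1 <- rho + (1 - rho) * emu
    # keep h1 strictly inside (0, 1): at clipped predictors the sum can
    # round to exactly 1, which would zero the Bernoulli working variance
    h1 <- pmin(pmax(h1, 1e-16), 1 - 1e-16)
    h2 <- (1 - rho) * mu
    a1 <- h1 * (1 - h1)
    a2 <- (1 - rho) * mu * (1 + rho * mu)
    list(rho = rho, mu = mu, h1 = h1, h2 = h2, a1 = a1, a2 = a2,
        zeroPart = zeroPart)
}

#' Analytic Jacobian of the mean functions
#'
#' Partial derivatives of the stacked means \code{(h1_i1, h2_i1, ...,
#' h1_iM, h2_iM)} with respect to \code{(betaU, betaV)}, one matrix per
#' subject. Chain-rule forms:
#' \code{dh1/dbetaU = (1 - exp(-mu)) rho (1 - rho) u},
#' \code{dh1/dbetaV = -(1 - rho) exp(-mu) mu v},
#' \code{dh2/dbetaU = -rho (1 - rho) mu u},
#' \code{dh2/dbetaV = (1 - rho) mu v}.
#' When \code{zeroPart = FALSE} the \code{betaU} rows are absent.
#'
#' @inheritParams computeMoments
#' @param moments optional precomputed [computeMoments()] result.
#' @return array of dimension \code{p x 2M x N} where \code{p} is the number
#'   of estimated coefficients, in the interleaved-by-time column order.
#' @export
panelJacobian <- function(panel, betaU, betaV, zeroPart = TRUE, moments = NULL) {
    if (is.null(moments)) moments <- computeMoments(panel, betaU, betaV, zeroPart)
    N <- nSubjects(panel); M <- nTimes(panel)
    pu <- if (moments$zeroPart) ncol(panel@U) else 0L
    pv <- ncol(panel@V)
    p <- pu + pv
    rho <- moments$rho; mu <- moments$mu
    emu <- exp(-mu)
    D <- array(0, dim = c(p, 2L * M, N))
    rowIdx <- function(i) (i - 1L) * M + seq_len(M)
    for (i in seq_len(N)) {
        Ui <- panel@U[rowIdx(i), , drop = FALSE]
        Vi <- panel@V[rowIdx(i), , drop = FALSE]
        if (moments$zeroPart) {
            drho <- rho[i, ] * (1 - rho[i, ])
            # d h1 / d betaU and d h2 / d betaU
            D[seq_len(pu), 2L * seq_len(M) - 1L, i] <-
                t(Ui * ((1 - emu[i, ]) * drho))
            D[seq_len(pu), 2L * seq_len(M), i] <-
                t(Ui * (-drho * mu[i, ]))
        }
        # d h1 / d betaV and d h2 / d betaV
        D[pu + seq_len(pv), 2L * seq_len(M) - 1L, i] <-
            t(Vi * (-(1 - rho[i, ]) * emu[i, ] * mu[i, ]))
        D[pu + seq_len(pv), 2L * seq_len(M), i] <-
            t(Vi * ((1 - rho[i, ]) * mu[i, ]))
    }
    dimnames(D) <- list(.paramNames(panel, moments$zeroPart), NULL, NULL)
    D
}

.paramNames <- function(panel, zeroPart) {
    c(if (zeroPart) paste0("u:", colnames(panel@U)),
      paste0("v:", colnames(panel@V)))
}
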