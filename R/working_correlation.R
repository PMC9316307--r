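#' Build a block working correlation matrix
#'
#' Assembles the \code{2M x 2M} working correlation for the interleaved
#' two-part responses. Within-time 2x2 blocks are the identity (the zero
#' indicator and the count are not correlated within a time point by the
#' working model); between time points \code{j} and \code{l} the block is
#' \code{c * J2} with \code{J2} the all-ones 2x2 matrix and
#' \code{c = alpha^|j-l|} (AR(1)), \code{c = alpha} (exchangeable) or
#' \code{c = 0} (independence).
#'
#' Note the blocked matrix need not be positive definite for every
#' \code{alpha} in \code{[0, 1)} (the all-ones blocks couple the two
#' components across time); the solver repairs factorization failures with
#' a small diagonal ridge, see [assembleV()].
#'
#' @param structure \code{"independence"}, \code{"ar1"} or
#'   \code{"exchangeable"}.
#' @param alpha correlation parameter; values outside \code{[0, 1)} are
#'   clamped into \code{[0, 0.99]} with a warning.
#' @param M number of time points.
#' @return a [WorkingCorrelation-class].
#' @examples
#' buildWorkingCorrelation("ar1", 0.5, 3)
#' @export
buildWorkingCorrelation <- function(structure = c("independence", "ar1", "exchangeable"),
                                    alpha = 0, M) {
    structure <- match.arg(structure)
    M <- as.integer(M)
    stopifnot(M >= 1L)
    if (!is.finite(alpha) || alpha < 0 || alpha >= 1) {
        alphaNew <- min(max(alpha, 0), 0.99)
        if (!is.finite(alphaNew)) alphaNew <- 0
        warning(sprintf("alpha = %g outside [0, 1); clamped to %g", alpha, alphaNew))
        alpha <- alphaNew
    }
    C <- switch(structure,
        independence = diag(M),
        ar1 = alpha^abs(outer(seq_len(M), seq_len(M), "-")),
        exchangeable = matrix(alpha, M, M) + diag(1 - alpha, M)
    )
    if (structure == "independence") alpha <- 0
    R <- kronecker(C - diag(M), matrix(1, 2L, 2L)) + diag(2L * M)
    rep_ <- .repairedCholesky(R)
    new("WorkingCorrelation", structure = structure, alpha = alpha, M = M,
        R = R, cholR = rep_$chol, ridge = rep_$ridge)
}

#' Standardized two-part Pearson residuals
#'
#' Residuals \code{e1 = (f1 - h1) / sqrt(Var f1)} and
#' \code{e2 = (f2 - h2) / sqrt(Var f2)}, evaluated at the supplied
#' coefficients. These feed the moment estimators of the working
#' correlation parameter.
#'
#' @inheritParams computeMoments
#' @param moments optional precomputed [computeMoments()] result.
#' @return list with matrices \code{e1} and \code{e2} (subjects x times).
#'   Cells with vanishing working variance (below \code{1e-12}) are set to 0
#'   with a warning.
#' @export
pearsonResiduals <- function(panel, betaU, betaV, zeroPart = TRUE, moments = NULL) {
    if (is.null(moments)) moments <- computeMoments(panel, betaU, betaV, zeroPart)
    f <- responseFunctions(panel)
    e1 <- f$f1 - moments$h1
    e2 <- f$f2 - moments$h2
    degenerate <- FALSE
    for (k in 1:2) {
        a <- moments[[c("a1", "a2")[k]]]
        bad <- a <= 1e-12
        if (any(bad)) degenerate <- TRUE
        e <- if (k == 1L) e1 else e2
        e[!bad] <- e[!bad] / sqrt(a[!bad])
        e[bad] <- 0
        if (k == 1L) e1 <- e else e2 <- e
    }
    if (degenerate) warning("degenerate cells with near-zero working variance; residuals set to 0")
    list(e1 = e1, e2 = e2)
}

#' Moment estimators of the working correlation parameter
#'
#' Pool lag-1 (AR(1)) or all off-diagonal (exchangeable) products of the
#' standardized residuals over both response components:
#' \deqn{\hat\alpha_{AR1} = \frac{\sum_i \sum_{j \le M-1} e_{1ij} e_{1i,j+1}
#'   + e_{2ij} e_{2i,j+1}}{2 (K - 2)}, \quad K = N (M - 1),}
#' \deqn{\hat\alpha_{exch} = \frac{\sum_i \sum_{j \ne l} e_{1ij} e_{1il}
#'   + e_{2ij} e_{2il}}{2 (K - 2)}, \quad K = N M (M - 1).}
#' \code{K} counts the (ordered) residual pairs per component; the factor 2
#' pools the two components and the \code{- 2} is a small-sample adjustment.
#' Estimates are clamped to \code{[0, 0.99]}; a non-positive denominator
#' falls back to independence (\code{alpha = 0}) with a warning.
#'
#' @param residuals a [pearsonResiduals()] result.
#' @return scalar \code{alpha} estimate in \code{[0, 0.99]}.
#' @export
estimateAlphaAR1 <- function(residuals) {
    e1 <- residuals$e1; e2 <- residuals$e2
    N <- nrow(e1); M <- ncol(e1)
    stopifnot(M >= 2L)
    num <- sum(e1[, -M, drop = FALSE] * e1[, -1L, drop = FALSE]) +
        sum(e2[, -M, drop = FALSE] * e2[, -1L, drop = FALSE])
    K <- N * (M - 1L)
    .alphaFromMoment(num, K)
}

#' @rdname estimateAlphaAR1
#' @export
estimateAlphaExchangeable <- function(residuals) {
    e1 <- residuals$e1; e2 <- residuals$e2
    N <- nrow(e1); M <- ncol(e1)
    stopifnot(M >= 2L)
    # sum over ordered pairs j != l equals (row sum)^2 - sum of squares
    num <- sum(rowSums(e1)^2 - rowSums(e1^2)) + sum(rowSums(e2)^2 - rowSums(e2^2))
    K <- N * M * (M - 1L)
    .alphaFromMoment(num, K)
}

# largest alpha for which lambda_min(R(alpha)) stays at or above the
# eigenvalue floor, i.e. the in-family definiteness boundary; memoized per
# (structure, M). Weighting with a capped R preserves the block correlation
# shape, which a large diagonal ridge would wash out.
.alphaCapCache <- new.env(parent = emptyenv())

.alphaCap <- function(structure, M, floor = .RIDGE_FLOOR) {
    if (structure == "independence" || M < 2L) return(0.99)
    key <- paste(structure, M, floor)
    if (!is.null(.alphaCapCache[[key]])) return(.alphaCapCache[[key]])
    lmin <- function(a) {
        R <- suppressWarnings(buildWorkingCorrelation(structure, a, M))@R
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) - floor
    }
    cap <- if (lmin(0.99) >= 0) 0.99 else
        stats::uniroot(lmin, c(0, 0.99), tol = 1e-6)$root
    .alphaCapCache[[key]] <- cap
    cap
}

.alphaFromMoment <- function(num, K) {
    denom <- 2 * (K - 2)
    if (denom <= 0) {
        warning("too few residual pairs to estimate alpha; falling back to independence")
        return(0)
    }
    min(max(num / denom, 0), 0.99)
}
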