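#' @import methods
NULL

#' Balanced longitudinal count panel for one feature
#'
#' Holds the observed counts and design matrices for a single microbial
#' feature measured on \code{N} subjects at \code{M} common time points.
#' The two-part model uses two design matrices: \code{U} for the
#' structural-zero (logit) part and \code{V} for the count (log) part.
#' Rows of \code{U} and \code{V} are ordered subject-major, i.e. row
#' \code{(i - 1) * M + j} belongs to subject \code{i} at time \code{j}.
#'
#' @slot y integer-valued matrix, subjects x time points.
#' @slot U numeric design matrix for the zero part, \code{N * M} rows,
#'   first column an intercept of ones.
#' @slot V numeric design matrix for the count part, same row order as
#'   \code{U}, first column an intercept of ones.
#' @slot subjectIds character vector of length \code{N}.
#' @slot timeIndex numeric vector of length \code{M}, strictly increasing.
#'
#' @seealso [featurePanel()] for the user-facing constructor.
#' @export
setClass("FeaturePanel",
    representation(
        y = "matrix",
        U = "matrix",
        V = "matrix",
        subjectIds = "character",
        timeIndex = "numeric"
    )
)

setValidity("FeaturePanel", function(object) {
    y <- object@y
    N <- nrow(y); M <- ncol(y)
    msg <- character()
    if (N < 1L || M < 1L) msg <- c(msg, "panel must have at least one subject and one time point")
    if (anyNA(y) || any(!is.finite(y))) msg <- c(msg, "counts must be finite")
    else {
        if (any(y < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(y != round(y))) msg <- c(msg, "counts must be integral")
    }
    for (nm in c("U", "V")) {
        D <- slot(object, nm)
        if (nrow(D) != N * M) msg <- c(msg, sprintf("%s must have N * M rows", nm))
        if (any(!is.finite(D))) msg <- c(msg, sprintf("%s contains non-finite values", nm))
        else if (ncol(D) < 1L || any(D[, 1L] != 1)) {
            msg <- c(msg, sprintf("first column of %s must be an intercept of ones", nm))
        }
    }
    if (length(object@subjectIds) != N) msg <- c(msg, "subjectIds must have one entry per subject")
    if (length(object@timeIndex) != M) msg <- c(msg, "timeIndex must have one entry per time point")
    else if (M > 1L && any(diff(object@timeIndex) <= 0)) {
        msg <- c(msg, "timeIndex must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeaturePanel
#'
#' @param y counts, subjects x time points (rows may be named by subject).
#' @param U,V design matrices with \code{N * M} rows (subject-major order)
#'   whose first column is an intercept. When a single matrix with \code{M}
#'   identical blocks per subject is wanted for all subjects, pass it
#'   directly; no recycling is performed.
#' @param subjectIds optional subject labels; defaults to rownames of
#'   \code{y} or \code{"S1"..}.
#' @param timeIndex optional time labels; defaults to \code{1..M}.
#' @return A [FeaturePanel-class] object.
#' @examples
#' y <- matrix(c(0L, 3L, 0L, 1L, 0L, 2L), nrow = 2, byrow = TRUE)
#' U <- cbind(1, rep(c(0, 1), each = 3))
#' featurePanel(y, U, U)
#' @export
featurePanel <- function(y, U, V = U, subjectIds = NULL, timeIndex = NULL) {
    y <- as.matrix(y)
    storage.mode(y) <- "double"
    if (is.null(subjectIds)) {
        subjectIds <- if (!is.null(rownames(y))) rownames(y) else paste0("S", seq_len(nrow(y)))
    }
    if (is.null(timeIndex)) timeIndex <- seq_len(ncol(y))
    U <- as.matrix(U); V <- as.matrix(V)
    if (is.null(colnames(U))) colnames(U) <- c("(Intercept)", paste0("u", seq_len(ncol(U) - 1L)))[seq_len(ncol(U))]
    if (is.null(colnames(V))) colnames(V) <- c("(Intercept)", paste0("v", seq_len(ncol(V) - 1L)))[seq_len(ncol(V))]
    new("FeaturePanel", y = y, U = U, V = V,
        subjectIds = as.character(subjectIds), timeIndex = as.numeric(timeIndex))
}

#' Panel dimensions
#'
#' @param x a [FeaturePanel-class]
#' @return number of subjects / time points.
#' @export
nSubjects <- function(x) nrow(x@y)

#' @rdname nSubjects
#' @export
nTimes <- function(x) ncol(x@y)

#' @export
setMethod("show", "FeaturePanel", function(object) {
    cat(sprintf("FeaturePanel: %d subjects x %d time points\n",
        nSubjects(object), nTimes(object)))
    cat(sprintf("  zero fraction: %.3f; zero-part covariates: %s; count-part covariates: %s\n",
        mean(object@y == 0), paste(colnames(object@U), collapse = ", "),
        paste(colnames(object@V), collapse = ", ")))
})

#' Working correlation structure for the stacked two-part responses
#'
#' The subject-level response vector stacks the zero indicator and the count
#' at each time point, interleaved by time, so the working correlation is a
#' \code{2M x 2M} matrix built from 2x2 blocks: identity blocks within a time
#' point and \code{alpha^h J2} (AR(1)) or \code{alpha J2} (exchangeable)
#' blocks between time points, with \code{J2} the 2x2 all-ones matrix.
#'
#' @slot structure one of \code{"independence"}, \code{"ar1"},
#'   \code{"exchangeable"}.
#' @slot alpha correlation parameter in \code{[0, 1)}.
#' @slot M number of time points.
#' @slot R the \code{2M x 2M} working correlation matrix (unit diagonal).
#' @slot cholR upper Cholesky factor of the (ridge-repaired) \code{R}, cached
#'   for the solver.
#' @slot ridge ridge added to \code{R} before factorization (0 when \code{R}
#'   is sufficiently positive definite).
#'
#' @seealso [buildWorkingCorrelation()]
#' @export
setClass("WorkingCorrelation",
    representation(structure = "character", alpha = "numeric", M = "integer",
        R = "matrix", cholR = "matrix", ridge = "numeric")
)

setValidity("WorkingCorrelation", function(object) {
    msg <- character()
    if (!object@structure %in% c("independence", "ar1", "exchangeable")) {
        msg <- c(msg, "unknown structure")
    }
    if (object@alpha < 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in [0, 1)")
    R <- object@R
    if (!isTRUE(all.equal(R, t(R)))) msg <- c(msg, "R must be symmetric")
    if (any(abs(diag(R) - 1) > 1e-12)) msg <- c(msg, "R must have unit diagonal")
    if (nrow(R) != 2L * object@M) msg <- c(msg, "R must be 2M x 2M")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "WorkingCorrelation", function(object) {
    cat(sprintf("WorkingCorrelation: %s, alpha = %.4f, M = %d (%dx%d)\n",
        object@structure, object@alpha, object@M, nrow(object@R), ncol(object@R)))
})

#' Per-feature GEE fit
#'
#' Result of fitting the two-part functional response model to one feature.
#' \code{sigmaBeta} is the robust sandwich covariance of the parameter
#' estimates on the per-estimate scale (the asymptotic covariance of
#' \code{sqrt(N) * (betaHat - beta)} divided by \code{N}), so
#' \code{sqrt(diag(sigmaBeta))} are standard errors.
#'
#' @slot betaU zero-part coefficients (logit scale); \code{NA} when the zero
#'   part is disabled (feature without zeros) or the feature was not fit.
#' @slot betaV count-part coefficients (log scale).
#' @slot alphaHat estimated working correlation parameter.
#' @slot sigmaBeta sandwich covariance of the estimated coefficients, rows
#'   and columns named \code{"u:<covariate>"} / \code{"v:<covariate>"}.
#' @slot nIter outer iterations used.
#' @slot converged logical convergence flag.
#' @slot maxAbsUpdate largest absolute coefficient update at the last step.
#' @slot structure working correlation structure tag.
#' @slot status one of \code{"ok"}, \code{"all_zero"}, \code{"no_zeros"},
#'   \code{"not_converged"} (\code{"no_zeros"} fits are still tested on the
#'   count part).
#' @slot N,M panel dimensions.
#' @export
setClass("CorrZidfFit",
    representation(
        betaU = "numeric", betaV = "numeric", alphaHat = "numeric",
        sigmaBeta = "matrix", nIter = "integer", converged = "logical",
        maxAbsUpdate = "numeric", structure = "character", status = "character",
        N = "integer", M = "integer"
    )
)

setValidity("CorrZidfFit", function(object) {
    msg <- character()
    S <- object@sigmaBeta
    if (nrow(S) != ncol(S)) msg <- c(msg, "sigmaBeta must be square")
    if (length(S) && !isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
        msg <- c(msg, "sigmaBeta must be symmetric")
    }
    if (length(S) && any(diag(S) < -1e-12, na.rm = TRUE)) {
        msg <- c(msg, "sigmaBeta diagonal must be non-negative")
    }
    if (!object@status %in% c("ok", "all_zero", "no_zeros", "not_converged")) {
        msg <- c(msg, "unknown status")
    }
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CorrZidfFit", function(object) {
    cat(sprintf("CorrZidfFit (%s, status = %s): N = %d, M = %d\n",
        object@structure, object@status, object@N, object@M))
    if (object@status %in% c("ok", "no_zeros", "not_converged")) {
        cat("  betaV:", paste(sprintf("%.4f", object@betaV), collapse = " "), "\n")
        if (!anyNA(object@betaU)) {
            cat("  betaU:", paste(sprintf("%.4f", object@betaU), collapse = " "), "\n")
        }
        cat(sprintf("  alphaHat = %.4f, %d iterations, converged = %s\n",
            object@alphaHat, object@nIter, object@converged))
    }
})

#' Accessors for CorrZidfFit
#'
#' @param x a [CorrZidfFit-class]
#' @return \code{coefZero}/\code{coefCount}: named coefficient vectors;
#'   \code{sandwichCov}: the per-estimate sandwich covariance matrix;
#'   \code{alphaHat}: the working correlation estimate.
#' @export
coefCount <- function(x) x@betaV

#' @rdname coefCount
#' @export
coefZero <- function(x) x@betaU

#' @rdname coefCount
#' @export
sandwichCov <- function(x) x@sigmaBeta

#' @rdname coefCount
#' @export
alphaHat <- function(x) x@alphaHat

#' Scenario for simulating a two-group longitudinal zero-inflated count study
#'
#' Defines the generative model used by [simulateStudy()]: zero-inflated
#' Poisson margins whose structural-zero probability decreases with the mean,
#' coupled over time points within a subject by a Gaussian copula with AR(1)
#' or exchangeable correlation. Differentially abundant features (DAFs) get a
#' mean trajectory that grows over time in the treatment group only; all
#' other feature-group combinations are static.
#'
#' @slot nPerGroup subjects per condition.
#' @slot M time points.
#' @slot nFeatures total features; the first \code{nDaf} are DAFs.
#' @slot nDaf number of differentially abundant features.
#' @slot structure copula correlation structure, \code{"ar1"} or
#'   \code{"exchangeable"}.
#' @slot rho copula correlation level in \code{[0, 1)}.
#' @slot mu0Range log-uniform range for per-feature baseline means.
#' @slot zeroA,zeroB zero-link coefficients: structural-zero probability
#'   \code{plogis(zeroA - zeroB * log(mu))}; \code{zeroB > 0} makes the zero
#'   fraction decrease with abundance.
#' @slot effect DAF trajectory shape, \code{"linear"} or
#'   \code{"exponential"}.
#' @slot effectSize slope \code{s} (linear: \code{mu0 * (1 + s * (j - 1))})
#'   or rate \code{r} (exponential: \code{mu0 * exp(r * (j - 1))}).
#' @slot seed base RNG seed; each feature uses a sub-seed derived from it.
#' @seealso [simScenario()], [simulateStudy()]
#' @export
setClass("SimScenario",
    representation(
        nPerGroup = "integer", M = "integer", nFeatures = "integer",
        nDaf = "integer", structure = "character", rho = "numeric",
        mu0Range = "numeric", zeroA = "numeric", zeroB = "numeric",
        effect = "character", effectSize = "numeric", seed = "integer"
    )
)

setValidity("SimScenario", function(object) {
    msg <- character()
    if (object@nDaf > object@nFeatures) msg <- c(msg, "nDaf must be <= nFeatures")
    if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
    if (!object@structure %in% c("ar1", "exchangeable")) msg <- c(msg, "unknown copula structure")
    if (length(object@mu0Range) != 2L || any(object@mu0Range <= 0) ||
        object@mu0Range[1L] > object@mu0Range[2L]) {
        msg <- c(msg, "mu0Range must be positive and increasing")
    }
    if (object@zeroB <= 0) msg <- c(msg, "zeroB must be > 0 (zero fraction decreasing in the mean)")
    if (!object@effect %in% c("linear", "exponential")) msg <- c(msg, "unknown effect pattern")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "SimScenario", function(object) {
    cat(sprintf(paste0(
        "SimScenario: %d features (%d DAFs), %d subjects/group, M = %d\n",
        "  copula: %s, rho = %.2f; margins: ZIP, mu0 ~ logU[%.3g, %.3g],\n",
        "  zero link plogis(%.2f - %.2f log mu); effect: %s, size = %.3g; seed = %d\n"),
        object@nFeatures, object@nDaf, object@nPerGroup, object@M,
        object@structure, object@rho, object@mu0Range[1L], object@mu0Range[2L],
        object@zeroA, object@zeroB, object@effect, object@effectSize, object@seed))
})
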