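#' Wald test on count-part coefficients
#'
#' Quadratic-form test \code{W = b' solve(Sigma_b) b} of the selected
#' count-part coefficients against zero, using the robust sandwich
#' covariance block; \code{W} is referred to a chi-square distribution with
#' \code{length(which)} degrees of freedom (two-sided inference).
#'
#' @param fit a [CorrZidfFit-class].
#' @param which indices into the count-part coefficient vector; defaults to
#'   the second coefficient (the group effect in the standard
#'   intercept-plus-group design) when present, otherwise the first.
#' @return list with \code{stat}, \code{df}, \code{p} (all \code{NA} for an
#'   unfit feature or a singular covariance block).
#' @examples
#' panel <- simulatePanel(40, 5, betaU = c(-1, 0.5), betaV = c(1, 0.6), seed = 2)
#' waldTest(fitFeature(panel, "independence"))
#' @export
waldTest <- function(fit, which = NULL) {
    stopifnot(is(fit, "CorrZidfFit"))
    if (is.null(which)) which <- if (length(fit@betaV) >= 2L) 2L else 1L
    df <- length(which)
    if (fit@status == "all_zero" || anyNA(fit@betaV[which])) {
        return(list(stat = NA_real_, df = df, p = NA_real_))
    }
    vRows <- grep("^v:", rownames(fit@sigmaBeta))
    idx <- vRows[which]
    b <- fit@betaV[which]
    Sig <- fit@sigmaBeta[idx, idx, drop = FALSE]
    sol <- tryCatch(solve(Sig, b), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) {
        return(list(stat = NA_real_, df = df, p = NA_real_))
    }
    W <- drop(crossprod(b, sol))
    list(stat = W, df = df, p = stats::pchisq(W, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across the
#' tested features. \code{NA} entries (untested features) are excluded from
#' the family size and stay \code{NA}.
#'
#' @param p numeric vector of raw p-values in \code{[0, 1]} (NAs allowed).
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    stopifnot(is.numeric(p))
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Summarize a differential-abundance run
#'
#' Tabulates per-feature results and, when simulation truth labels are
#' supplied, the empirical false and true positive rates of the BH-adjusted
#' calls at the given FDR threshold.
#'
#' @param results a \code{DataFrame}/\code{data.frame} as returned by
#'   [corrZidf()] (columns \code{feature_id}, \code{status}, \code{p_raw},
#'   \code{p_adj}, ...).
#' @param alphaFdr FDR threshold for calling a feature significant.
#' @param truth optional logical vector (or vector coercible to logical),
#'   one entry per feature, \code{TRUE} for genuinely differential features.
#' @return list with the annotated \code{table} (a \code{significant}
#'   column added), \code{nTested}, \code{nSignificant}, and — when truth is
#'   given — \code{tpr} (TP / number of true DAFs) and \code{fpr}
#'   (FP / number of null features).
#' @export
summarizeRun <- function(results, alphaFdr = 0.05, truth = NULL) {
    stopifnot(alphaFdr > 0, alphaFdr <= 1)
    results <- as.data.frame(results)
    sig <- !is.na(results$p_adj) & results$p_adj < alphaFdr
    results$significant <- sig
    out <- list(table = results,
        nTested = sum(!is.na(results$p_raw)),
        nSignificant = sum(sig))
    if (!is.null(truth)) {
        truth <- as.logical(truth)
        stopifnot(length(truth) == nrow(results))
        out$tpr <- if (any(truth)) sum(sig & truth) / sum(truth) else NA_real_
        out$fpr <- if (any(!truth)) sum(sig & !truth) / sum(!truth) else NA_real_
    }
    out
}
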