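# internal numerical helpers shared across modules

# linear predictors are clipped before the inverse link so that plogis/exp
# never overflow; +-30 is far outside any plausible logit/log-mean scale
.CLIP <- 30

.clip <- function(x) pmin(pmax(x, -.CLIP), .CLIP)

# interleave two N x M matrices by time: columns (m1[,1], m2[,1], ..., m1[,M], m2[,M])
.interleave <- function(m1, m2) {
    M <- ncol(m1)
    out <- matrix(0, nrow(m1), 2L * M)
    out[, 2L * seq_len(M) - 1L] <- m1
    out[, 2L * seq_len(M)] <- m2
    out
}

# solve a symmetric system, falling back to an SVD pseudo-inverse when the
# Cholesky fails (near-singular information matrix)
.solveSym <- function(A, b) {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (!is.null(ch)) {
        return(list(x = backsolve(ch, forwardsolve(t(ch), b)), singular = FALSE))
    }
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    x <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
    list(x = x, singular = TRUE)
}

.pinv <- function(A) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d, 0) * 1e-12
    if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# ridge repair for indefinite working correlations (the all-ones 2x2 blocks
# make R(alpha) indefinite for moderate alpha): add the smallest ridge that
# lifts the minimum eigenvalue to a fixed floor. The floor bounds the
# inverse-correlation weights (by 1/floor), which keeps the estimating
# equations continuous in alpha; a bare positive-definiteness repair leaves
# a near-null direction with unbounded weight and makes the solution jump
# as alpha crosses the definiteness boundary.
.RIDGE_FLOOR <- 0.05

.repairedCholesky <- function(R, floor = .RIDGE_FLOOR) {
    n <- nrow(R)
    ok <- tryCatch({ chol(R - diag(floor, n)); TRUE }, error = function(e) FALSE)
    if (ok) return(list(chol = chol(R), ridge = 0))
    lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    eps <- floor - lmin
    list(chol = chol(R + diag(eps, n)), ridge = eps)
}

# derive a valid 32-bit sub-seed from a base seed and a stream index
.subSeed <- function(seed, k) {
    as.integer(((as.numeric(seed) %% 2147483647) * 31 + k) %% 2147483646) + 1L
}
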