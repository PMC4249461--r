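#' Linear kernel (Gram matrix) over image features
#'
#' \eqn{K_{ij} = \langle x_i, x_j \rangle} over the masked voxel features.
#' A linear kernel is the standard choice for voxel-level morphometry with
#' far more voxels than subjects and is required for interpretable weight
#' back-projection.
#'
#' @param X a [FeatureMatrix-class] or plain numeric matrix
#'   (subjects x features).
#' @return symmetric positive semidefinite numeric matrix with subject ids
#'   as dimnames.
#' @export
linearKernel <- function(X) {
    M <- if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
    stopIfNot(nrow(M) > 0, "feature matrix must be non-empty")
    K <- tcrossprod(M)
    if (!is.null(rownames(M)))
        dimnames(K) <- list(rownames(M), rownames(M))
    symmetrize(K)
}

#' Confound design matrix from cohort columns
#'
#' Builds the n x p design used for kernel-level confound removal. An
#' intercept column is always included so that removal also centers the
#' kernel; the default single covariate is APOE4 carrier status.
#'
#' @param cohort cohort data.frame (row order must match the kernel).
#' @param columns cohort column names to use as covariates (default
#'   \code{"apoe4"}); use \code{character(0)} for an intercept-only design.
#' @param intercept include the intercept column (default TRUE).
#' @return numeric matrix with labeled columns (possibly 0 columns when
#'   \code{intercept = FALSE} and no covariates).
#' @export
confoundMatrix <- function(cohort, columns = "apoe4", intercept = TRUE) {
    stopIfNot(all(columns %in% names(cohort)),
              paste("unknown confound column(s):",
                    paste(setdiff(columns, names(cohort)), collapse = ", ")))
    C <- matrix(numeric(0), nrow(cohort), 0L)
    if (intercept) {
        C <- cbind(C, rep(1, nrow(cohort)))
        colnames(C) <- "intercept"
    }
    for (cl in columns) {
        v <- cohort[[cl]]
        if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
        C <- cbind(C, as.numeric(v))
        colnames(C)[ncol(C)] <- cl
    }
    C
}

#' Residual-forming projector for a confound design
#'
#' \eqn{R = I - C (C'C)^- C'} with a rank-tolerant pseudoinverse. R is
#' symmetric, idempotent and annihilates the column space of C; applied as
#' \eqn{R K R} it removes confound-spanned structure from a linear kernel.
#'
#' @param C numeric confound design matrix (n x p, p may be 0).
#' @param n number of subjects (needed only when C has no columns).
#' @return n x n projector matrix.
#' @export
residualMatrix <- function(C, n = nrow(C)) {
    if (is.null(C) || ncol(C) == 0L) return(diag(n))
    stopIfNot(nrow(C) >= ncol(C), "need at least as many subjects as confounds")
    R <- diag(nrow(C)) - C %*% MASS::ginv(crossprod(C)) %*% t(C)
    symmetrize(R)
}

#' Remove confound effects from a kernel matrix
#'
#' Returns \eqn{R K R} for the residual projector of the confound design;
#' equals the linear kernel of the explicitly residualized features
#' \eqn{R X}. With an empty design the kernel is returned unchanged.
#'
#' @param K n x n kernel matrix.
#' @param C confound design (n x p) as from [confoundMatrix()], or a
#'   precomputed projector via \code{R}.
#' @param R optional precomputed residual projector (overrides \code{C}).
#' @return confound-removed kernel matrix (symmetric PSD).
#' @export
removeConfounds <- function(K, C = NULL, R = NULL) {
    if (is.null(R)) {
        if (is.null(C) || ncol(C) == 0L) return(K)
        stopIfNot(nrow(C) == nrow(K),
                  "confound design rows must match kernel dimension")
        R <- residualMatrix(C)
    }
    stopIfNot(all(dim(R) == dim(K)),
              "projector dimensions must match the kernel")
    out <- symmetrize(R %*% K %*% R)
    dimnames(out) <- dimnames(K)
    out
}

#' Train-only confound removal of kernel blocks for one CV fold
#'
#' Full-sample removal (the default, [removeConfounds()]) estimates one
#' projector from everybody, which mixes test information into the
#' kernel; when the prediction target is itself a function of the
#' confound this induces anti-learning (cross-validated performance
#' systematically below chance). The fold-wise variant estimates the
#' confound regression on the training subjects only and residualizes
#' the test rows with the train-estimated coefficients:
#' \eqn{\tilde x_{te} = x_{te} - C_{te}(C_{tr}'C_{tr})^- C_{tr}' X_{tr}},
#' all evaluated through kernel blocks.
#'
#' @param K raw n x n kernel over the full sample.
#' @param C n x p confound design aligned to \code{K}.
#' @param train,test row indices of the fold.
#' @return list with \code{train} (residualized training kernel) and
#'   \code{test} (test x train kernel block).
#' @export
removeConfoundsFold <- function(K, C, train, test) {
    K <- unclass(as.matrix(K))
    if (is.null(C) || ncol(C) == 0L)
        return(list(train = K[train, train, drop = FALSE],
                    test = K[test, train, drop = FALSE]))
    Ct <- C[train, , drop = FALSE]
    G <- MASS::ginv(crossprod(Ct))
    Rt <- diag(length(train)) - Ct %*% G %*% t(Ct)
    P <- C[test, , drop = FALSE] %*% G %*% t(Ct)
    list(train = symmetrize(Rt %*% K[train, train, drop = FALSE] %*% Rt),
         test = (K[test, train, drop = FALSE] -
                     P %*% K[train, train, drop = FALSE]) %*% Rt)
}

#' Scale a kernel to unit mean diagonal
#'
#' Divides the kernel by the mean of its diagonal (trace normalization),
#' the standard conditioning step for kernel methods on neuroimaging
#' features: it puts the Gram matrix on a scale commensurate with the
#' soft-margin cost so that a fixed C behaves comparably across samples
#' and subgroups. The scale factor is attached as attribute
#' \code{"kernelScale"} so primal weights can be recovered consistently
#' (see [computeWeights()]).
#'
#' @param K kernel matrix (typically confound-removed).
#' @return scaled kernel with attribute \code{kernelScale}.
#' @export
normalizeKernel <- function(K) {
    s <- mean(diag(K))
    stopIfNot(s > 0, "kernel has non-positive mean diagonal")
    out <- K / s
    attr(out, "kernelScale") <- s
    out
}

#' Persist / load a kernel matrix as delimited text
#'
#' Tab-delimited numeric matrix with the subject order as header row.
#'
#' @param K kernel matrix with subject-id dimnames.
#' @param path file path.
#' @return \code{readKernel} returns the matrix; \code{writeKernel} the
#'   path, invisibly.
#' @export
writeKernel <- function(K, path) {
    utils::write.table(K, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !is.null(colnames(K)))
    invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
    M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
    rownames(M) <- colnames(M)
    M
}
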