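# Exact finite-dimensional embedding of a PSD kernel: rows of Z satisfy
# Z Z' = K (eigendecomposition with negative eigenvalues clipped at 0).
# libsvm is then trained on Z with a linear kernel, which is equivalent
# to training on the precomputed kernel; the dual solution depends on the
# kernel only, so decision values for new subjects need only kernel
# blocks against the training sample.
kernelEmbed <- function(K) {
    e <- eigen(symmetrize(unclass(as.matrix(K))), symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(K))
}

#' Train a soft-margin SVM on a precomputed kernel
#'
#' Solves the standard C-SVC dual on the precomputed (typically
#' confound-removed) kernel with libsvm, and repackages the solution as a
#' [SvmFit-class] with full-length signed dual coefficients and an
#' intercept, oriented so that positive decision values favor the class
#' labeled +1 (the higher-risk class by convention).
#'
#' @param K n x n kernel matrix over the training subjects.
#' @param labels numeric -1/+1 labels (or a factor with those levels).
#' @param Cparam soft-margin cost (default 1).
#' @return a [SvmFit-class].
#' @export
trainSvm <- function(K, labels, Cparam = 1) {
    y <- labelsToPm1(labels)
    stopIfNot(length(unique(y)) == 2L,
              "training labels must contain both classes")
    stopIfNot(nrow(K) == length(y),
              "kernel dimension must match the number of labels")
    m <- e1071::svm(kernelEmbed(K), factor(y), kernel = "linear",
                    cost = Cparam, scale = FALSE, tolerance = 1e-4)
    coefs <- numeric(length(y))
    coefs[m$index] <- m$coefs
    b <- -m$rho
    # libsvm's positive decision side depends on its internal class
    # order; orient it against the fitted training classes.
    f <- as.vector(unclass(as.matrix(K)) %*% coefs + b)
    fit <- as.numeric(as.character(m$fitted))
    if (mean((f >= 0) == (fit == 1)) < 0.5) {
        coefs <- -coefs
        b <- -b
    }
    new("SvmFit", coefs = coefs, b = b, Cparam = Cparam,
        epsilon = NA_real_, svIndex = sort(m$index), type = "C-svc")
}

#' Train epsilon-insensitive support vector regression on a kernel
#'
#' Fits eps-SVR (libsvm) on the precomputed kernel; residuals smaller
#' than \code{epsilon} incur no loss. Targets are typically z-normalized
#' first (see [zNormalize()]).
#'
#' @param K n x n kernel matrix over the training subjects.
#' @param targets numeric targets.
#' @param Cparam cost parameter (default 1).
#' @param epsilon tube width (default 0.1).
#' @return a [SvmFit-class] with \code{type = "eps-svr"}.
#' @export
trainSvr <- function(K, targets, Cparam = 1, epsilon = 0.1) {
    stopIfNot(nrow(K) == length(targets),
              "kernel dimension must match the number of targets")
    m <- e1071::svm(kernelEmbed(K), as.numeric(targets),
                    type = "eps-regression", kernel = "linear",
                    cost = Cparam, epsilon = epsilon, scale = FALSE,
                    tolerance = 1e-4)
    coefs <- numeric(length(targets))
    coefs[m$index] <- m$coefs
    new("SvmFit", coefs = coefs, b = -m$rho, Cparam = Cparam,
        epsilon = epsilon, svIndex = sort(m$index), type = "eps-svr")
}

labelsToPm1 <- function(labels) {
    if (is.factor(labels)) labels <- as.numeric(as.character(labels))
    if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
    stopIfNot(all(labels %in% c(-1, 1)), "labels must be coded -1 / +1")
    as.numeric(labels)
}

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "SvmFit", function(fit, K) {
    K <- unclass(as.matrix(K))
    stopIfNot(ncol(K) == length(fit@coefs),
              "kernel block columns must match the training sample")
    as.vector(K %*% fit@coefs + fit@b)
})
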