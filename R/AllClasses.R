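#' @import methods
NULL

#' Stack of gray-matter probability maps
#'
#' A \code{GMImageSet} holds one 3-D gray-matter probability map per subject
#' on a common voxel grid with a shared voxel-to-world affine. Each voxel
#' intensity is the tissue-segmentation probability that the voxel contains
#' gray matter, so all values lie in \eqn{[0, 1]}.
#'
#' @slot intensities 4-D numeric array, subject x i x j x k.
#' @slot affine 4x4 voxel-to-world transform shared by all subjects.
#' @slot subjectIds character vector, one id per subject, in row order.
#'
#' @seealso [readImages()], [buildMask()], [vectorizeImages()]
#' @export
setClass("GMImageSet",
    representation(
        intensities = "array",
        affine = "matrix",
        subjectIds = "character"
    )
)

setValidity("GMImageSet", function(object) {
    d <- dim(object@intensities)
    if (length(d) != 4L)
        return("intensities must be a 4-D array (subject x i x j x k)")
    if (d[1L] != length(object@subjectIds))
        return("first dimension must match length(subjectIds)")
    if (anyDuplicated(object@subjectIds))
        return("subjectIds must be unique")
    if (!all(dim(object@affine) == c(4L, 4L)))
        return("affine must be a 4x4 matrix")
    v <- range(object@intensities, na.rm = TRUE)
    tol <- 1e-6
    if (v[1L] < -tol || v[2L] > 1 + tol)
        return("voxel intensities must lie in [0, 1] (tolerance 1e-6)")
    TRUE
})

#' Masked subject-by-voxel feature matrix
#'
#' Voxels retained by the analysis mask, flattened to one column each in a
#' fixed, reproducible order (native column-major array order). Row order
#' equals the subject order of the originating [GMImageSet].
#'
#' @slot values numeric matrix, subjects x masked voxels.
#' @slot mask logical 3-D array marking retained voxels.
#' @slot voxelIndex integer matrix (masked voxels x 3) mapping each column
#'   back to its (i, j, k) grid coordinate.
#' @slot affine 4x4 voxel-to-world transform inherited from the image set.
#'
#' @export
setClass("FeatureMatrix",
    representation(
        values = "matrix",
        mask = "array",
        voxelIndex = "matrix",
        affine = "matrix"
    )
)

setValidity("FeatureMatrix", function(object) {
    if (!is.logical(object@mask))
        return("mask must be a logical array")
    if (ncol(object@values) != sum(object@mask))
        return("column count must equal the number of TRUE mask voxels")
    if (nrow(object@voxelIndex) != ncol(object@values))
        return("voxelIndex must have one row per masked voxel")
    TRUE
})

#' Fitted kernel support vector model
#'
#' Dual solution of a support vector machine (classification) or
#' epsilon-insensitive support vector regression fitted on a precomputed
#' kernel. The decision function is
#' \eqn{f(x) = \sum_i c_i K(x, x_i) + b} where \eqn{c_i} are the signed
#' dual coefficients (\eqn{\alpha_i y_i} for classification,
#' \eqn{\alpha_i - \alpha_i^*} for regression), zero for non-support
#' vectors.
#'
#' @slot coefs numeric vector of signed dual coefficients, one per training
#'   subject (zero off the support set).
#' @slot b intercept of the decision function.
#' @slot Cparam soft-margin cost used in training.
#' @slot epsilon tube width for regression fits; \code{NA} for
#'   classification.
#' @slot svIndex integer indices of the support vectors in the training
#'   sample.
#' @slot type \code{"C-svc"} or \code{"eps-svr"}.
#'
#' @seealso [trainSvm()], [trainSvr()], [decisionValues()]
#' @export
setClass("SvmFit",
    representation(
        coefs = "numeric",
        b = "numeric",
        Cparam = "numeric",
        epsilon = "numeric",
        svIndex = "integer",
        type = "character"
    )
)

setValidity("SvmFit", function(object) {
    if (!object@type %in% c("C-svc", "eps-svr"))
        return("type must be 'C-svc' or 'eps-svr'")
    tol <- 1e-3 * max(1, object@Cparam)
    if (max(abs(object@coefs)) > object@Cparam + tol)
        return("dual coefficients must be bounded by Cparam")
    if (abs(sum(object@coefs)) > tol * length(object@coefs))
        return("dual coefficients must sum to zero (equality constraint)")
    TRUE
})

#' Cross-validated classification result
#'
#' Per-subject cross-validated decision values and predictions together
#' with aggregate accuracy, sensitivity (recall of the higher-risk class,
#' coded +1) and specificity (recall of the lower-risk class, coded -1).
#'
#' @slot perSubject data.frame with columns \code{subject}, \code{label},
#'   \code{decision}, \code{predicted}, one row per evaluated subject.
#' @slot accuracy,sensitivity,specificity proportions in \eqn{[0, 1]};
#'   \code{NA} when the denominator is empty.
#' @slot counts named numeric vector of confusion counts
#'   (\code{tp}, \code{fp}, \code{tn}, \code{fn}).
#'
#' @export
setClass("ClassificationResult",
    representation(
        perSubject = "data.frame",
        accuracy = "numeric",
        sensitivity = "numeric",
        specificity = "numeric",
        counts = "numeric"
    )
)

#' Cross-validated regression result
#'
#' Leave-one-out predictions of a (z-normalized) clinical target, with the
#' Pearson correlation between true and predicted values and the mean
#' squared error on the normalized scale.
#'
#' @slot perSubject data.frame with columns \code{subject}, \code{true},
#'   \code{predicted} (normalized scale).
#' @slot r Pearson correlation between true and predicted values.
#' @slot mse mean squared error on the normalized scale.
#' @slot normalization named numeric vector (\code{mean}, \code{sd}) of the
#'   target transform, for mapping predictions back to original units.
#'
#' @export
setClass("RegressionResult",
    representation(
        perSubject = "data.frame",
        r = "numeric",
        mse = "numeric",
        normalization = "numeric"
    )
)

#' Permutation test result
#'
#' Observed statistic, the permuted null distribution obtained by re-running
#' the complete cross-validated pipeline under label/target shuffles, and
#' the proportion-based p-value.
#'
#' @slot observed observed statistic.
#' @slot permuted numeric vector of B permuted statistics.
#' @slot pValue proportion of permuted statistics at or beyond the observed
#'   one (count / B; or (count + 1) / (B + 1) when \code{addOne}).
#' @slot B number of permutations.
#' @slot tail \code{"greater"} (accuracy, r) or \code{"less"} (MSE).
#' @slot seed RNG seed used for the shuffles.
#' @slot addOne whether the add-one small-sample correction was applied.
#'
#' @seealso [permutationTest()]
#' @export
setClass("PermutationResult",
    representation(
        observed = "numeric",
        permuted = "numeric",
        pValue = "numeric",
        B = "integer",
        tail = "character",
        seed = "integer",
        addOne = "logical"
    )
)

setValidity("PermutationResult", function(object) {
    if (length(object@permuted) != object@B)
        return("permuted distribution must hold exactly B values")
    if (object@pValue < 0 || object@pValue > 1)
        return("pValue must lie in [0, 1]")
    TRUE
})

#' Voxel weight map
#'
#' Primal weight vector of a linear kernel model mapped back onto the voxel
#' grid. Weights form one global multivariate pattern: every voxel
#' contributes to the prediction jointly with all others, so no regional or
#' single-voxel inference should be based on individual weight values.
#'
#' @slot weights numeric vector, one weight per masked voxel.
#' @slot mask logical 3-D array locating the masked voxels.
#' @slot normalization \code{"raw"} or \code{"unit"} (Euclidean norm 1).
#'
#' @seealso [computeWeights()], [writeWeightMap()]
#' @export
setClass("WeightMap",
    representation(
        weights = "numeric",
        mask = "array",
        normalization = "character"
    )
)

setValidity("WeightMap", function(object) {
    if (length(object@weights) != sum(object@mask))
        return("weights length must equal the number of TRUE mask voxels")
    if (!object@normalization %in% c("raw", "unit"))
        return("normalization must be 'raw' or 'unit'")
    TRUE
})
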